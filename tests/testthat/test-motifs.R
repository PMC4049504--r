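test_that("PWM construction normalises columns and derives a consensus", {
  counts <- rbind(c(20, 0, 0, 0), c(0, 20, 0, 0), c(0, 0, 20, 0),
                  c(0, 0, 0, 20), c(10, 0, 10, 0))
  p <- pwm(counts, name = "m")
  expect_true(all(abs(colSums(p$matrix) - 1) < 1e-9))
  expect_equal(p$consensus, "ACGTR")
  expect_error(pwm(counts[, 1:3]), "4 columns")
  expect_error(pwm(counts[1:3, ]), "at least 4 positions")
  rc <- crosscourse:::pwm_revcomp(p)
  expect_equal(rc$consensus, "YACGT")
  expect_equal(crosscourse:::pwm_revcomp(rc)$matrix, p$matrix)
})

test_that("binomial seed p-values match direct summation for small counts", {
  set.seed(51)
  for (i in 1:30) {
    n <- sample(50:400, 1)
    q <- runif(1, 0.001, 0.05)
    k <- sample(0:50, 1)
    direct <- sum(vapply(k:n, function(j) {
      choose(n, j) * q^j * (1 - q)^(n - j)
    }, 0))
    expect_equal(pbinom(k - 1, n, q, lower.tail = FALSE), direct,
                 tolerance = 1e-9)
  }
})

test_that("planted motifs are discovered with carriers and small E-values", {
  pr <- generate_promoters(paste0("c", 1:30), "TGACTCA", n_background = 30,
                           length = 150, gc = 0.5, seed = 52)
  res <- discover_motifs(pr$seqs)
  expect_gte(nrow(res), 1)
  expect_true(any(crosscourse:::consensus_matches(res$consensus, "TGACTCA",
                                                  max_mismatch = 1)))
  expect_lte(res$e_value[1], 1e-3)
  top_carriers <- res$carriers[[1]]
  expect_gte(mean(paste0("c", 1:30) %in% top_carriers), 0.8)
})

test_that("discovery is strand-symmetric", {
  pr <- generate_promoters(paste0("c", 1:25), "TGCATGA", n_background = 25,
                           length = 120, gc = 0.5, seed = 53)
  fwd <- discover_motifs(pr$seqs)
  rev_ <- discover_motifs(setNames(crosscourse:::reverse_complement(pr$seqs),
                                   names(pr$seqs)))
  expect_equal(nrow(fwd), nrow(rev_))
  # seeds agree up to reverse complement (canonical k-mers are shared)
  expect_setequal(fwd$seed, rev_$seed)
  expect_equal(fwd$e_value, rev_$e_value, tolerance = 1e-9)
})

test_that("identical sequences yield a motif carried by all of them", {
  one <- generate_promoters("x", "TGACTCA", length = 80, gc = 0.5, seed = 54)
  seqs <- setNames(rep(one$seqs, 10), paste0("s", 1:10))
  res <- discover_motifs(seqs, k_range = 6:8)
  expect_gte(nrow(res), 1)
  expect_length(res$carriers[[1]], 10)
})

test_that("sequences with too many ambiguous bases are skipped", {
  pr <- generate_promoters(paste0("c", 1:12), "TGACTCA", length = 100,
                           gc = 0.5, seed = 55)
  bad <- pr$seqs
  substr(bad[[1]], 1, 40) <- strrep("N", 40)
  expect_warning(discover_motifs(bad, k_range = 6:7), "non-ACGT")
  expect_error(discover_motifs(pr$seqs[1:5]), "at least 10")
})

test_that("duplicate-block masking spares widely shared blocks", {
  set.seed(56)
  base <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
  block <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
  seqs <- vapply(1:10, function(i) {
    s <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
    if (i <= 2) s <- paste0(substr(s, 1, 80), block)
    s
  }, "")
  names(seqs) <- paste0("s", 1:10)
  masked <- mask_shared_duplicates(seqs)
  expect_true(grepl("N", masked[["s1"]]))
  expect_true(grepl("N", masked[["s2"]]))
  expect_false(any(grepl("N", masked[3:10])))
  # a block in every sequence is exempt
  all_share <- setNames(rep(paste0(base, block), 10), paste0("s", 1:10))
  expect_false(any(grepl("N", mask_shared_duplicates(all_share))))
})

test_that("PWM matching is exact on self and reverse-complement queries", {
  set.seed(57)
  lib <- lapply(1:20, function(i) {
    L <- sample(6:10, 1)
    pwm(matrix(rgamma(L * 4, 0.5) + 0.05, L, 4),
        name = sprintf("R%02d", i), source = "reference")
  })
  q <- lib[[7]]
  m <- match_to_reference(q, lib, n_shuffle = 200, seed = 1)
  expect_equal(m$name, "R07")
  expect_equal(m$score, 1, tolerance = 1e-9)

  qrc <- crosscourse:::pwm_revcomp(q)
  mrc <- match_to_reference(qrc, lib, n_shuffle = 200, seed = 1)
  expect_equal(mrc$name, "R07")
  expect_equal(mrc$score, 1, tolerance = 1e-9)
  expect_equal(mrc$strand, "-")

  short <- structure(q, class = "pwm")
  short$matrix <- q$matrix[, 1:3]
  expect_error(pwm_align_score(short, q), "fewer than 4")
  expect_error(match_to_reference(q, list()), "empty")
})

test_that("column-shuffled queries do not match the library", {
  set.seed(58)
  lib <- lapply(1:50, function(i) {
    L <- sample(7:10, 1)
    pwm(matrix(rgamma(L * 4, 0.5) + 0.05, L, 4),
        name = sprintf("R%02d", i), source = "reference")
  })
  high_e <- vapply(1:5, function(s) {
    set.seed(580 + s)
    q <- lib[[sample(50, 1)]]
    q$matrix <- q$matrix[, sample(ncol(q$matrix))]
    match_to_reference(q, lib, n_shuffle = 300, seed = s)$e_value > 0.05
  }, logical(1))
  expect_gte(mean(high_e), 0.8)
})

test_that("TFBS-gene table computes strengths and self-DE flags", {
  hits <- tibble::tibble(
    tfbs = c("KROX", "KROX", "NOVEL"),
    cell_type = c("A", "B", "A"),
    e_value = c(1e-4, 1e-6, 1e-5),
    carriers = list(c("g1", "g2"), c("g2", "g3"), "g9")
  )
  tf_map <- tibble::tibble(tfbs = "KROX", gene_id = "g2")
  de_sets <- list(A = c("g1", "g2"), B = c("g2"))
  expect_warning(tab <- tfbs_gene_network(hits, tf_map, de_sets), "NOVEL")
  krox <- tab[tab$tfbs == "KROX", ]
  expect_equal(unique(krox$strength), (4 * log(10) + 6 * log(10)) / 2)
  expect_true(all(krox$tf_gene_de))
  expect_setequal(krox$gene_id[krox$cell_type == "A"], c("g1", "g2"))
  expect_equal(krox$gene_id[krox$cell_type == "B"], "g2")

  empty <- tfbs_gene_network(hits[0, ], tf_map, de_sets)
  expect_equal(nrow(empty), 0)
})
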