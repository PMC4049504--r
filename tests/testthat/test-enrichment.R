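fake_de <- function(prob, p = NULL) {
  structure(list(
    genes = tibble::tibble(gene_id = paste0("g", seq_along(prob)),
                           posterior_prob = prob,
                           max_abs_logfc = 2),
    timepoints = if (!is.null(p)) {
      tibble::tibble(gene_id = paste0("g", seq_along(p)), time_h = 4,
                     logfc = 1, moderated_t = 1, p_value = p,
                     fdr_bh = p.adjust(p, "BH"))
    }
  ), class = "de_result")
}

test_that("ranking scores follow the stated transforms and caps", {
  de <- fake_de(prob = c(0, 0.5, 1), p = c(exp(-2), 1, 1e-20))
  sc <- compute_ranking_scores(de, "timecourse")
  expect_equal(sc$score, c(0, -log(0.5), -log(1e-12)))
  expect_equal(sc$score[3], 27.631, tolerance = 1e-3)
  sp <- compute_ranking_scores(de, "timepoint", time_h = 4)
  expect_equal(sp$score[1], 2)
  expect_equal(sp$score[2], 0)
  expect_equal(sp$score[3], -log(1e-12))
  de_bad <- fake_de(prob = c(0.5, 1.2))
  expect_error(compute_ranking_scores(de_bad, "timecourse"), "outside")
})

test_that("logistic set test finds shifted sets and respects minimums", {
  set.seed(31)
  scores <- tibble::tibble(gene_id = paste0("g", 1:1000),
                           score = rnorm(1000))
  scores$score[1:50] <- scores$score[1:50] + 3
  r <- logistic_set_test(scores, paste0("g", 1:50))
  expect_lt(r$p_value, 1e-4)
  expect_equal(r$direction, 1)

  r2 <- logistic_set_test(scores, paste0("g", 1:3))
  expect_true(is.na(r2$p_value))
  expect_match(r2$note, "fewer than")

  const <- tibble::tibble(gene_id = paste0("g", 1:100), score = 1)
  r3 <- logistic_set_test(const, paste0("g", 1:10))
  expect_equal(r3$slope, 0)
  expect_equal(r3$p_value, 1)
})

test_that("perfect separation falls back to a penalised fit", {
  scores <- tibble::tibble(gene_id = paste0("g", 1:60),
                           score = c(rep(10, 10), rep(0, 50)))
  r <- logistic_set_test(scores, paste0("g", 1:10))
  expect_equal(r$method, "firth")
  expect_true(is.finite(r$p_value))
  expect_lt(r$p_value, 0.01)
})

test_that("logistic p is invariant under positive affine score rescaling", {
  set.seed(32)
  scores <- tibble::tibble(gene_id = paste0("g", 1:300),
                           score = rexp(300))
  set_ <- paste0("g", sample(300, 40))
  p1 <- logistic_set_test(scores, set_)$p_value
  scores2 <- dplyr::mutate(scores, score = 3.7 * score + 2)
  p2 <- logistic_set_test(scores2, set_)$p_value
  expect_equal(p1, p2, tolerance = 1e-8)
})

test_that("BY adjustment matches the harmonic-penalty step-up oracle", {
  set.seed(33)
  for (i in 1:50) {
    p <- runif(sample(5:60, 1))^sample(1:3, 1)
    expect_equal(p.adjust(p, "BY"), oracle_by(p), tolerance = 1e-12)
  }
})

test_that("hypergeometric over-representation matches the exact sum", {
  u <- paste0("u", 1:100)
  de <- u[1:10]
  r <- hypergeom_overrepresentation(de, u, list(S = u[6:25]))
  expect_equal(r$p_value, oracle_hyper(5, 20, 100, 10), tolerance = 1e-12)
  expect_equal(r$overlap, 5)

  # zero overlap and set = universe are certain events
  r0 <- hypergeom_overrepresentation(de, u, list(S = u[90:100]))
  expect_equal(r0$p_value, 1)
  rall <- hypergeom_overrepresentation(de, u, list(S = u))
  expect_equal(rall$p_value, 1)
  expect_equal(rall$overlap, 10)

  expect_error(hypergeom_overrepresentation(de, character(), list(S = u)),
               "empty universe")
  expect_error(hypergeom_overrepresentation("zzz", u, list(S = u)),
               "subset")
})

test_that("enrich_sets flags planted sets and skips tiny ones", {
  set.seed(34)
  scores <- tibble::tibble(gene_id = paste0("g", 1:500), score = rexp(500))
  scores$score[1:40] <- scores$score[1:40] + 4
  sets <- list(planted = paste0("g", 1:40),
               random = paste0("g", sample(41:500, 40)),
               tiny = paste0("g", 1:3))
  r <- enrich_sets(scores, sets)
  expect_true(r$significant[r$set_id == "planted"])
  expect_false(r$significant[r$set_id == "random"])
  expect_true(is.na(r$p_value[r$set_id == "tiny"]))
  expect_true(all(r$fdr_by >= r$p_value - 1e-12, na.rm = TRUE))
})

test_that("common terms intersect strictly across all cell types", {
  rec <- function(f) tibble::tibble(set_id = c("s1", "s2", "s3"), fdr_by = f)
  per_ct <- list(
    A = rec(c(0.001, 0.049, 0.2)),
    B = rec(c(0.02, 0.049, 0.001)),
    C = rec(c(0.01, 0.049, 0.04)),
    D = rec(c(0.3, 0.049, 0.01)) # s1 significant in only 3 of 4
  )
  ct <- common_terms(per_ct)
  expect_equal(ct$common, "s2")
  expect_equal(nrow(ct$table), 12)

  none <- common_terms(list(A = rec(c(0.9, 0.9, 0.9)),
                            B = rec(c(0.001, 0.001, 0.001))))
  expect_length(none$common, 0)
  expect_equal(nrow(none$table), 6)
  expect_error(common_terms(per_ct["A"]), "at least 2")
})

test_that("reproducibility returns the printed study percentages", {
  r <- reproducibility(human_common_de_genes, a549_reproduced_de_genes,
                       c(human_common_de_genes, paste0("filler", 1:19982)))
  expect_equal(r$n_common, 18)
  expect_equal(r$count, 11)
  expect_equal(r$percent, 61)
  expect_lt(r$hypergeom_p, 1e-9)

  r2 <- reproducibility(c("a", "b"), c("a", "b", "c"),
                        c("a", "b", "c", "d"))
  expect_equal(r2$percent, 100)

  # exact-sum oracle on the documented configuration
  uni <- paste0("u", 1:20000)
  val <- uni[1:1500]
  common <- c(uni[1:11], uni[19000:19006])
  r3 <- reproducibility(common, val, uni)
  expect_equal(r3$hypergeom_p, oracle_hyper(11, 1500, 20000, 18),
               tolerance = 1e-12)
  expect_error(reproducibility(character(), val, uni), "empty common")
})
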