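test_that("generator is deterministic and validates its config", {
  cfg <- synthetic_study_config(n_genes = 50, seed = 3)
  g1 <- generate_expression(cfg)
  g2 <- generate_expression(cfg)
  expect_identical(g1$expression$MPP$expr, g2$expression$MPP$expr)
  expect_identical(g1$truth$homologs, g2$truth$homologs)

  expect_error(synthetic_study_config(frac_de_shared = 0.7,
                                      frac_de_specific = 0.5),
               "sum to at most 1")
  expect_error(synthetic_study_config(effect_amplitude = 0), "positive")
  expect_error(
    synthetic_study_config(cell_types = tibble::tibble(
      name = "X", species = "s", time_h = list(0)
    )),
    "single point"
  )
  expect_error(
    synthetic_study_config(cell_types = tibble::tibble(
      name = "X", species = "s", time_h = list(c(2, 8))
    )),
    "start at 0"
  )
})

test_that("null configuration has mean log fold change near zero", {
  cfg <- synthetic_study_config(
    n_genes = 200, frac_de_shared = 0, frac_de_specific = 0,
    noise_sd = 0.4, seed = 9,
    cell_types = tibble::tibble(name = "A", species = "s",
                                time_h = list(c(0, 4, 24)))
  )
  gen <- generate_expression(cfg)
  prof <- fold_change_profiles(gen$expression$A)
  # mean lfc per gene; SE of the grand mean over 200 genes x 2 times x 3 reps
  grand <- mean(prof$lfc_mean)
  se <- sd(as.vector(prof$lfc)) / sqrt(length(prof$lfc))
  expect_lt(abs(grand), 3 * se + 1e-9)
  expect_equal(length(gen$truth$de_genes$A), 0)
})

test_that("late-curve DE genes reach the configured amplitude at 24 h", {
  cfg <- synthetic_study_config(
    n_genes = 100, frac_de_shared = 0, frac_de_specific = 1,
    effect_curves = "late", effect_amplitude = 2, noise_sd = 0.25,
    frac_up = 1, seed = 5,
    cell_types = tibble::tibble(name = "A", species = "s",
                                time_h = list(c(0, 4, 8, 24)))
  )
  gen <- generate_expression(cfg)
  prof <- fold_change_profiles(gen$expression$A)
  last <- prof$lfc_mean[gen$truth$de_genes$A, ncol(prof$lfc_mean)]
  se <- sd(last) / sqrt(length(last))
  expect_lt(abs(mean(last) - 2), 3 * se)
})

test_that("curve templates are normalised fold-change shapes", {
  tt <- seq(0, 24, by = 0.5)
  for (shape in c("early", "late", "transient", "monotone")) {
    v <- curve_template(shape, tt)
    expect_equal(v[1], 0, tolerance = 1e-12)
    expect_equal(max(abs(v)), 1, tolerance = 1e-6)
  }
  expect_equal(which.max(curve_template("early", tt)), which(tt == 2))
  expect_equal(which.max(curve_template("transient", tt)), which(tt == 4))
  expect_lt(curve_template("transient", 24), 0.05)
  expect_error(curve_template("wiggle", tt), "unknown curve")
})

test_that("planted annotations create real enrichment by construction", {
  cfg <- synthetic_study_config(n_genes = 100, seed = 2)
  gen <- generate_expression(cfg)
  ann <- generate_annotations(gen$truth, n_terms = 20, dag_depth = 2,
                              n_planted = 1, seed = 7)
  expect_s3_class(ann$dag, "ontology_dag")
  p <- ann$planted_terms
  annotated <- ann$gene2term$gene_id[ann$gene2term$term_id == p]
  de <- unique(unlist(gen$truth$de_genes))
  universe <- unique(c(gen$truth$homologs$gene_a, gen$truth$homologs$gene_b))
  expect_gte(mean(de %in% annotated), 0.8)
  non_de <- setdiff(universe, de)
  expect_lte(mean(non_de %in% annotated), 0.10)
  # determinism
  ann2 <- generate_annotations(gen$truth, n_terms = 20, dag_depth = 2,
                               n_planted = 1, seed = 7)
  expect_identical(ann$gene2term, ann2$gene2term)
})

test_that("star DAG at depth one and planted-term capacity are honoured", {
  cfg <- synthetic_study_config(n_genes = 30, seed = 2)
  gen <- generate_expression(cfg)
  ann <- generate_annotations(gen$truth, n_terms = 6, dag_depth = 1,
                              n_planted = 1, seed = 1)
  non_root <- setdiff(ann$dag$terms, ann$dag$roots)
  parents <- unique(ann$dag$edges$parent[ann$dag$edges$child %in% non_root])
  expect_true(all(lengths(
    split(ann$dag$edges$parent, ann$dag$edges$child)
  ) >= 1))
  expect_equal(length(ann$dag$roots), 1)
  expect_error(generate_annotations(gen$truth, n_terms = 1, n_planted = 2),
               "exceed")
})

test_that("promoter generator plants exact instances and matches GC", {
  pr <- generate_promoters(paste0("c", 1:20), "TGACTCA", n_background = 0,
                           length = 200, gc = 0.5, seed = 4)
  expect_true(all(grepl("TGACTCA", pr$seqs, fixed = TRUE)))
  expect_equal(nrow(pr$truth), 20)

  bg <- generate_promoters(character(), "ACGT", n_background = 50,
                           length = 200, gc = 0.5, seed = 8)
  gc_obs <- mean(strsplit(paste(bg$seqs, collapse = ""), NULL)[[1]] %in%
                   c("G", "C"))
  se <- sqrt(0.25 / (50 * 200))
  expect_lt(abs(gc_obs - 0.5), 3 * se)

  expect_error(generate_promoters("g", "TGAXTCA", length = 100),
               "IUPAC")
  expect_error(generate_promoters("g", "TGACTCA", length = 5),
               "at least the motif length")
  # IUPAC degeneracy resolves to a concrete matching instance
  amb <- generate_promoters("g", "TGASTCA", length = 50, seed = 2)
  expect_true(grepl("TGA[CG]TCA", amb$seqs[["g"]]))
})

test_that("network generator includes the planted path at both extremes", {
  pp <- c("a", "b", "c", "d")
  g0 <- generate_network(5, edge_prob = 0, planted_path = pp, seed = 1)
  expect_equal(nrow(g0$edges), 3)
  expect_setequal(paste(g0$edges$from, g0$edges$to),
                  c("a b", "b c", "c d"))
  g1 <- generate_network(5, edge_prob = 1, planted_path = character(),
                         seed = 1)
  expect_equal(nrow(g1$edges), choose(5, 2))
})
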