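test_that("moderated variance combination follows the shrinkage formula", {
  expect_equal(squeeze_variance(1, 2, 4, 2), 2.5)
  # infinite prior df collapses to the prior variance (ordinary t on s0)
  expect_equal(squeeze_variance(c(1, 9), c(2, 2), 4, Inf), c(4, 4))
  # no prior information returns the observed variance
  expect_equal(squeeze_variance(3, 5, 10, 0), 3)
})

test_that("single batch is an identity transform; known shift is removed", {
  x <- toy_expr(G = 40, times = c(0, 4, 24), R = 2, seed = 2)
  expect_identical(adjust_batches(x), x)

  shift_batch <- function(meta) ifelse(meta$replicate == 1, "B1", "B2")
  x2 <- toy_expr(G = 300, times = c(0, 4, 24), R = 4, seed = 3,
                 batch = shift_batch)
  x2$expr[, x2$meta$batch == "B1"] <- x2$expr[, x2$meta$batch == "B1"] + 1
  adj <- adjust_batches(x2)
  diff_before <- mean(x2$expr[, x2$meta$batch == "B1"]) -
    mean(x2$expr[, x2$meta$batch == "B2"])
  diff_after <- mean(adj$expr[, adj$meta$batch == "B1"]) -
    mean(adj$expr[, adj$meta$batch == "B2"])
  expect_gt(abs(diff_before), 0.9)
  expect_lt(abs(diff_after), 0.05)
  expect_equal(dim(adj$expr), dim(x2$expr))

  confounded <- function(meta) ifelse(meta$time_h == 0, "B1", "B2")
  x3 <- toy_expr(G = 20, times = c(0, 4), R = 3, batch = confounded)
  expect_error(adjust_batches(x3), "confounded")
})

test_that("per-timepoint test recovers a planted shift and is calibrated", {
  x <- toy_expr(G = 200, times = c(0, 4), R = 3, noise = 0.3, seed = 4,
                mu = function(g, t) if (g <= 20 && t == 4) 2 else 0)
  tt <- test_timepoint(x, 4)
  expect_equal(nrow(tt), 200)
  top <- tt$gene_id[tt$fdr_bh < 0.01 & abs(tt$logfc) >= 1]
  expect_gte(length(intersect(top, sprintf("g%03d", 1:20))), 18)
  expect_lte(length(setdiff(top, sprintf("g%03d", 1:20))), 2)
  expect_true(all(tt$fdr_bh >= tt$p_value - 1e-12))
  expect_error(test_timepoint(x, 12), "not in the grid")

  # null calibration across a few seeds
  fps <- vapply(1:5, function(s) {
    xn <- toy_expr(G = 1000, times = c(0, 8), R = 3, noise = 0.4, seed = 100 + s)
    tn <- test_timepoint(xn, 8)
    mean(tn$fdr_bh < 0.01)
  }, numeric(1))
  expect_lte(mean(fps), 0.02)
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  set.seed(11)
  for (i in 1:50) {
    p <- runif(sample(5:60, 1))^sample(1:3, 1)
    expect_equal(p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("fold-change profiles drop incomplete time points", {
  x <- toy_expr(G = 10, times = c(0, 2, 8), R = 3, seed = 6)
  keep <- !(x$meta$time_h == 2 & x$meta$replicate == 1)
  meta <- x$meta[keep, ]
  y <- expr_timecourse(x$expr[, meta$sample_id], meta)
  expect_message(prof <- fold_change_profiles(y), "excluding incomplete")
  expect_equal(prof$time_h, 8)
  expect_equal(dim(prof$lfc), c(10, 1, 3))
})

test_that("EB mixture behaves at its analytic limits", {
  x <- toy_expr(G = 300, times = c(0, 2, 8, 24), R = 3, noise = 0.4, seed = 7,
                mu = function(g, t) if (g <= 30) 2 * (t > 0) else 0)
  prof <- fold_change_profiles(x)
  fit <- fit_timecourse_posterior(prof)

  # identical components: Lambda -> 0 makes every posterior equal the prior
  f0 <- fit
  f0$Lambda <- matrix(0, 3, 3)
  S0 <- f0$Sigma / 3
  ll <- crosscourse:::dmvnorm0_log(prof$lfc_mean, S0)
  post <- exp(log(f0$p_de) + ll -
                crosscourse:::logsumexp2(log(f0$p_de) + ll,
                                         log1p(-f0$p_de) + ll))
  expect_equal(unname(post), rep(fit$p_de, 300), tolerance = 1e-12)

  # a huge profile norm forces the posterior to 1
  big <- prof
  big$lfc_mean[1, ] <- 50
  ll1 <- crosscourse:::dmvnorm0_log(big$lfc_mean[1, , drop = FALSE],
                                    fit$Lambda + fit$Sigma / 3)
  ll0 <- crosscourse:::dmvnorm0_log(big$lfc_mean[1, , drop = FALSE],
                                    fit$Sigma / 3)
  p1 <- exp(log(fit$p_de) + ll1 -
              crosscourse:::logsumexp2(log(fit$p_de) + ll1,
                                       log1p(-fit$p_de) + ll0))
  expect_gt(p1, 1 - 1e-6)

  # EM log-likelihood is monotone non-decreasing
  expect_true(all(diff(fit$loglik) >= -1e-6 * abs(fit$loglik[-1])))
  expect_true(all(fit$posterior$posterior_prob >= 0 &
                    fit$posterior$posterior_prob <= 1))
})

test_that("under the global null the mean posterior matches the prior", {
  x <- toy_expr(G = 800, times = c(0, 2, 8, 24), R = 3, noise = 0.5, seed = 8)
  prof <- fold_change_profiles(x)
  fit <- suppressWarnings(fit_timecourse_posterior(prof))
  expect_lt(abs(mean(fit$posterior$posterior_prob) - fit$p_de), 0.05)
})

test_that("detection power grows with effect amplitude", {
  aucs <- vapply(c(0.5, 1, 2), function(amp) {
    mean(vapply(1:3, function(s) {
      cfg <- synthetic_study_config(
        n_genes = 400, frac_de_shared = 0, frac_de_specific = 0.1,
        effect_amplitude = amp, noise_sd = 0.5, seed = 20 + s,
        cell_types = tibble::tibble(name = "A", species = "s",
                                    time_h = list(c(0, 1, 4, 8, 24)))
      )
      gen <- generate_expression(cfg)
      de <- suppressWarnings(de_analysis(gen$expression$A))
      lab <- de$genes$gene_id %in% gen$truth$de_genes$A
      crosscourse:::auc_score(de$genes$posterior_prob, lab)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(aucs) > 0))
})

test_that("DE calling applies the probability and two-fold rules jointly", {
  de <- structure(list(
    genes = tibble::tibble(
      gene_id = c("a", "b", "c"),
      posterior_prob = c(0.995, 0.995, 0.98),
      max_abs_logfc = c(1.2, 0.8, 3.0)
    ),
    timepoints = tibble::tibble(
      gene_id = c("a", "b", "c"), time_h = 4,
      logfc = c(1.2, 0.8, 3.0), moderated_t = 1, p_value = 0.001,
      fdr_bh = c(0.005, 0.005, 0.5)
    )
  ), class = "de_result")
  calls <- call_de(de)
  expect_equal(calls$timecourse, "a")
  expect_equal(calls$timepoint$t4, "a")
  # the boundary |logFC| = 1 is DE-eligible
  de$genes$max_abs_logfc[1] <- 1.0
  expect_equal(call_de(de)$timecourse, "a")
})

test_that("posterior is monotone in the profile norm for isotropic models", {
  fit <- list(p_de = 0.1, Sigma = diag(0.2, 3), Lambda = diag(1, 3))
  S0 <- fit$Sigma / 3
  norms <- seq(0.1, 4, length.out = 20)
  post <- vapply(norms, function(r) {
    xb <- matrix(r * c(1, 1, 1) / sqrt(3), 1)
    l1 <- crosscourse:::dmvnorm0_log(xb, fit$Lambda + S0)
    l0 <- crosscourse:::dmvnorm0_log(xb, S0)
    exp(log(fit$p_de) + l1 -
          crosscourse:::logsumexp2(log(fit$p_de) + l1, log1p(-fit$p_de) + l0))
  }, numeric(1))
  # strictly increasing until saturating at 1 within machine precision
  expect_true(all(diff(post) >= -1e-15))
  expect_gt(post[10], post[1])
})
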