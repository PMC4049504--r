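# Differential expression over stimulation time courses: batch adjustment,
# per-timepoint moderated testing, and an empirical-Bayes two-component
# mixture posterior for whole-time-course differential expression.

#' Batch-adjust an expression time course
#'
#' Location-scale empirical-Bayes adjustment per gene (ComBat): per-batch
#' mean/variance parameters are shrunk toward their across-gene moments and
#' removed on a design that preserves time effects; grand means are restored.
#' With a single batch the transform is the identity.
#'
#' @param x An [expr_timecourse] whose metadata carries a `batch` column.
#' @return An adjusted [expr_timecourse] of the same shape.
#' @export
adjust_batches <- function(x) {
  stopifnot(inherits(x, "expr_timecourse"))
  batches <- x$meta$batch
  if (all(is.na(batches)) || length(unique(batches)) < 2) {
    return(x)
  }
  if (any(table(batches) < 2)) abort("every batch needs at least 2 samples")
  conf <- table(batches, x$meta$time_h)
  if (all(rowSums(conf > 0) == 1)) {
    abort("batch is confounded 1:1 with time; adjustment is inestimable")
  }
  mod <- model.matrix(~ factor(x$meta$time_h))
  adj <- suppressMessages(
    sva::ComBat(dat = x$expr, batch = batches, mod = mod,
                par.prior = TRUE, prior.plots = FALSE)
  )
  out <- x
  out$expr <- adj
  out
}

#' Log2 fold-change profiles relative to baseline
#'
#' Computes per-replicate log2 fold changes at every non-baseline time point:
#' within replicate when the object is paired, otherwise against the mean
#' baseline. Time points missing one or more replicates (for example after a
#' dropped chip) are excluded from the profile with a message, mirroring the
#' exclusion of an incomplete time point from whole-course analysis.
#'
#' @param x An [expr_timecourse].
#' @return An object of class `fc_profiles`: list with `lfc` (array genes x
#'   times x replicates), `lfc_mean` (genes x times matrix), `time_h`,
#'   `gene_ids`, `cell_type`.
#' @export
fold_change_profiles <- function(x) {
  stopifnot(inherits(x, "expr_timecourse"))
  meta <- x$meta
  times <- sort(setdiff(unique(meta$time_h), 0))
  reps <- sort(unique(meta$replicate))
  full <- times[vapply(times, function(t) {
    all(reps %in% meta$replicate[meta$time_h == t])
  }, logical(1))]
  base_full <- all(reps %in% meta$replicate[meta$time_h == 0])
  if (!base_full) {
    reps <- intersect(reps, meta$replicate[meta$time_h == 0])
    full <- times[vapply(times, function(t) {
      all(reps %in% meta$replicate[meta$time_h == t])
    }, logical(1))]
  }
  if (length(full) < length(times)) {
    inform(paste0("excluding incomplete time point(s) ",
                  paste(setdiff(times, full), collapse = ", "),
                  " h from the time-course profile"))
  }
  if (length(full) < 1) abort("no complete non-baseline time points")
  G <- nrow(x$expr)
  lfc <- array(NA_real_, dim = c(G, length(full), length(reps)),
               dimnames = list(rownames(x$expr), paste0("t", full),
                               paste0("r", reps)))
  base_mean <- rowMeans(x$expr[, meta$time_h == 0, drop = FALSE])
  for (ri in seq_along(reps)) {
    r <- reps[ri]
    base_col <- meta$sample_id[meta$time_h == 0 & meta$replicate == r]
    for (ti in seq_along(full)) {
      col <- meta$sample_id[meta$time_h == full[ti] & meta$replicate == r]
      ref <- if (isTRUE(x$paired) && length(base_col) == 1) {
        x$expr[, base_col]
      } else {
        base_mean
      }
      lfc[, ti, ri] <- x$expr[, col] - ref
    }
  }
  structure(
    list(lfc = lfc, lfc_mean = apply(lfc, c(1, 2), mean),
         time_h = full, gene_ids = rownames(x$expr), cell_type = x$cell_type),
    class = "fc_profiles"
  )
}

#' @export
print.fc_profiles <- function(x, ...) {
  cat("<fc_profiles> ", length(x$gene_ids), " genes, time points ",
      paste(x$time_h, collapse = ", "), " h, ", dim(x$lfc)[3],
      " replicates (", x$cell_type, ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.fc_profiles <- function(x, ...) {
  as_tibble(x$lfc_mean) %>%
    mutate(gene_id = x$gene_ids) %>%
    tidyr::pivot_longer(-"gene_id", names_to = "time_h", values_to = "logfc") %>%
    mutate(time_h = as.numeric(sub("^t", "", .data$time_h)))
}

#' Moderated-variance combination
#'
#' The standard empirical-Bayes posterior variance
#' \eqn{\tilde s^2 = (d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g)}; with infinite
#' prior degrees of freedom it collapses to the prior variance.
#'
#' @param s2 Observed residual variances.
#' @param df Their residual degrees of freedom.
#' @param s0_2 Prior variance.
#' @param d0 Prior degrees of freedom (may be `Inf`).
#' @return Moderated variances.
#' @export
squeeze_variance <- function(s2, df, s0_2, d0) {
  if (is.infinite(d0)) return(rep(s0_2, length(s2)))
  (d0 * s0_2 + df * s2) / (d0 + df)
}

#' Per-timepoint moderated test against baseline
#'
#' Fits a per-gene linear model with time (and, for paired designs,
#' replicate) factors, takes the contrast time `t` minus time 0, moderates
#' residual variances by empirical-Bayes shrinkage, and adjusts two-sided
#' p-values by Benjamini-Hochberg across genes.
#'
#' @param x An [expr_timecourse].
#' @param t Time point in hours (must be in the grid, with >= 2 replicates).
#' @return Tibble: `gene_id`, `time_h`, `logfc`, `moderated_t`, `p_value`,
#'   `fdr_bh`.
#' @export
test_timepoint <- function(x, t) {
  stopifnot(inherits(x, "expr_timecourse"))
  meta <- x$meta
  if (!t %in% meta$time_h) abort(paste0("time ", t, " h not in the grid"))
  if (sum(meta$time_h == t) < 2 || sum(meta$time_h == 0) < 2) {
    abort("need >= 2 replicates at the tested time point and baseline")
  }
  tf <- factor(meta$time_h)
  design <- if (isTRUE(x$paired) && length(unique(meta$replicate)) > 1) {
    model.matrix(~ 0 + tf + factor(meta$replicate))
  } else {
    model.matrix(~ 0 + tf)
  }
  colnames(design) <- sub("^tf", "time_", colnames(design))
  colnames(design) <- make.names(colnames(design))
  fit <- limma::lmFit(x$expr, design)
  if (fit$df.residual[1] <= 0) abort("zero residual degrees of freedom")
  cname <- paste0("time_", t)
  contr <- limma::makeContrasts(
    contrasts = paste0(cname, " - time_0"), levels = design
  )
  fit2 <- limma::eBayes(limma::contrasts.fit(fit, contr))
  tibble(
    gene_id = rownames(x$expr),
    time_h = t,
    logfc = as.numeric(fit2$coefficients[, 1]),
    moderated_t = as.numeric(fit2$t[, 1]),
    p_value = as.numeric(fit2$p.value[, 1]),
    fdr_bh = p.adjust(as.numeric(fit2$p.value[, 1]), method = "BH")
  )
}

#' Empirical-Bayes whole-time-course posterior
#'
#' Two-component random-effects mixture on replicate-mean log fold-change
#' profiles \eqn{\bar x_g}: with prior probability \eqn{1-p} the true mean
#' profile is 0 and \eqn{\bar x_g \sim N(0, \Sigma/R)}; with probability
#' \eqn{p} the mean profile is itself Gaussian, \eqn{\mu_g \sim N(0,
#' \Lambda)}, so \eqn{\bar x_g \sim N(0, \Lambda + \Sigma/R)}. The noise
#' covariance \eqn{\Sigma} is estimated from pooled within-gene replicate
#' scatter as a shrunken diagonal; \eqn{(p, \Lambda)} are estimated by EM on
#' the marginal likelihood. The per-gene posterior probability of
#' differential expression is the usual two-component posterior odds ratio.
#'
#' @param profiles An `fc_profiles` object (>= 2 replicates, >= 2 non-baseline
#'   time points).
#' @param max_iter Maximum EM iterations.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param shrink Weight of the median in the diagonal shrinkage of
#'   \eqn{\Sigma}.
#' @return An `eb_timecourse_fit`: list with `p_de`, `Sigma`, `Lambda`,
#'   `loglik`, `converged`, `posterior` tibble (`gene_id`, `posterior_prob`),
#'   `time_h`.
#' @export
fit_timecourse_posterior <- function(profiles, max_iter = 500, tol = 1e-8,
                                     shrink = 0.5) {
  stopifnot(inherits(profiles, "fc_profiles"))
  R <- dim(profiles$lfc)[3]
  Tn <- dim(profiles$lfc)[2]
  if (R < 2) abort("need >= 2 replicates")
  if (Tn < 2) abort("need >= 2 non-baseline time points")
  xbar <- profiles$lfc_mean
  G <- nrow(xbar)

  # pooled within-gene noise: diagonal of replicate scatter, shrunk to median
  resid2 <- apply(profiles$lfc, c(1, 2), var) # per gene, per time
  d <- colMeans(resid2)
  d_shrunk <- (1 - shrink) * d + shrink * median(d)
  Sigma <- diag(d_shrunk, Tn)
  S0 <- Sigma / R

  # init: p = 0.1, Lambda from the top-decile ||xbar|| genes
  p <- 0.1
  nrm <- sqrt(rowSums(xbar^2))
  top <- xbar[nrm >= quantile(nrm, 0.9), , drop = FALSE]
  Lambda <- psd_project(crossprod(top) / nrow(top) - S0, floor = 1e-8)

  ll0 <- dmvnorm0_log(xbar, S0)
  loglik <- numeric()
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    ll1 <- dmvnorm0_log(xbar, Lambda + S0)
    la <- log(p) + ll1
    lb <- log1p(-p) + ll0
    tot <- logsumexp2(la, lb)
    z <- exp(la - tot)
    loglik[it] <- sum(tot)
    if (it > 1 &&
        abs(loglik[it] - loglik[it - 1]) <=
        tol * (abs(loglik[it - 1]) + .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    p <- max(mean(z), 1e-6)
    Sz <- crossprod(xbar * sqrt(z)) / sum(z)
    Lambda <- psd_project(Sz - S0, floor = 1e-8)
  }
  if (!converged) warn("EM did not converge; returning best iterate")

  ll1 <- dmvnorm0_log(xbar, Lambda + S0)
  post <- exp(log(p) + ll1 - logsumexp2(log(p) + ll1, log1p(-p) + ll0))
  structure(
    list(p_de = p, Sigma = Sigma, Lambda = Lambda, loglik = loglik,
         converged = converged, time_h = profiles$time_h,
         posterior = tibble(gene_id = profiles$gene_ids,
                            posterior_prob = pmin(pmax(post, 0), 1))),
    class = "eb_timecourse_fit"
  )
}

#' @export
print.eb_timecourse_fit <- function(x, ...) {
  cat("<eb_timecourse_fit> p_de = ", signif(x$p_de, 3), ", ",
      nrow(x$posterior), " genes, ", length(x$loglik), " EM iterations",
      if (!x$converged) " (not converged)", "\n", sep = "")
  invisible(x)
}

#' @export
tidy.eb_timecourse_fit <- function(x, ...) x$posterior

#' @export
glance.eb_timecourse_fit <- function(x, ...) {
  tibble(p_de = x$p_de, n_genes = nrow(x$posterior),
         iterations = length(x$loglik),
         loglik = x$loglik[length(x$loglik)], converged = x$converged)
}

#' Full DE analysis of one cell type's time course
#'
#' Runs the whole-course empirical-Bayes posterior and the per-timepoint
#' moderated tests, returning both gene-level and gene-by-timepoint tables.
#'
#' @param x An [expr_timecourse].
#' @param ... Passed to [fit_timecourse_posterior()].
#' @return A `de_result`: list with `genes` tibble (`gene_id`,
#'   `posterior_prob`, `max_abs_logfc`), `timepoints` tibble (per gene and
#'   time: `logfc`, `moderated_t`, `p_value`, `fdr_bh`), `fit`, `profiles`,
#'   `cell_type`, `species`.
#' @export
de_analysis <- function(x, ...) {
  prof <- fold_change_profiles(x)
  fit <- fit_timecourse_posterior(prof, ...)
  tps <- sort(setdiff(unique(x$meta$time_h), 0))
  tp_tbl <- bind_rows(map(tps, function(t) test_timepoint(x, t)))
  genes <- fit$posterior %>%
    mutate(max_abs_logfc = apply(abs(prof$lfc_mean), 1, max))
  structure(
    list(genes = genes, timepoints = tp_tbl, fit = fit, profiles = prof,
         cell_type = x$cell_type, species = x$species),
    class = "de_result"
  )
}

#' @export
print.de_result <- function(x, ...) {
  cat("<de_result> ", x$cell_type, ": ", nrow(x$genes), " genes, ",
      length(unique(x$timepoints$time_h)), " tested time points\n", sep = "")
  invisible(x)
}

#' @export
tidy.de_result <- function(x, ...) {
  left_join(x$timepoints, x$genes, by = "gene_id")
}

#' @export
glance.de_result <- function(x, ...) {
  calls <- call_de(x)
  tibble(cell_type = x$cell_type, n_genes = nrow(x$genes),
         p_de = x$fit$p_de,
         n_de_timecourse = length(calls$timecourse))
}

#' Call differentially expressed genes
#'
#' Whole-course DE requires posterior probability above `prob_cut` and at
#' least a two-fold change (maximum absolute log2 fold change of at least
#' `lfc_cut`) at one time point or more; per-timepoint DE requires
#' `fdr_bh` below `fdr_cut` and at least `lfc_cut` absolute log2 fold change
#' at that time point.
#'
#' @param de A `de_result` from [de_analysis()].
#' @param prob_cut Posterior probability cutoff (default 0.99, exclusive).
#' @param lfc_cut Absolute log2 fold-change cutoff (default 1, inclusive).
#' @param fdr_cut Per-timepoint FDR cutoff (default 0.01, exclusive).
#' @return List with `timecourse` (character vector of DE genes) and
#'   `timepoint` (named list of DE gene vectors, one per time point).
#' @export
call_de <- function(de, prob_cut = 0.99, lfc_cut = 1.0, fdr_cut = 0.01) {
  stopifnot(inherits(de, "de_result"))
  tc <- de$genes$gene_id[de$genes$posterior_prob > prob_cut &
                           de$genes$max_abs_logfc >= lfc_cut]
  tp <- de$timepoints %>%
    filter(.data$fdr_bh < fdr_cut, abs(.data$logfc) >= lfc_cut)
  list(
    timecourse = tc,
    timepoint = split(tp$gene_id, paste0("t", tp$time_h))
  )
}

#' Export a DE result to TSV
#'
#' Writes one wide table: per-gene posterior probability plus per-timepoint
#' log fold changes, p-values and FDRs, and DE flags.
#'
#' @param de A `de_result`.
#' @param path Output TSV path.
#' @param ... Thresholds passed to [call_de()].
#' @return The written tibble, invisibly.
#' @export
write_de_result <- function(de, path, ...) {
  calls <- call_de(de, ...)
  wide <- de$timepoints %>%
    tidyr::pivot_wider(
      id_cols = "gene_id", names_from = "time_h",
      values_from = c("logfc", "p_value", "fdr_bh"), names_glue = "{.value}_t{time_h}"
    )
  out <- de$genes %>%
    left_join(wide, by = "gene_id") %>%
    mutate(is_de_timecourse = .data$gene_id %in% calls$timecourse)
  readr::write_tsv(out, path)
  invisible(out)
}
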