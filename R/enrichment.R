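# Ranking-score gene-set association testing, hypergeometric
# over-representation, cross-cell-type commonality, and validation-set
# reproducibility statistics.

#' Per-gene ranking scores
#'
#' Time-point mode uses \eqn{-\ln p}; time-course mode uses
#' \eqn{-\ln(1 - \text{posterior})}. Probabilities at or above
#' \eqn{1 - 10^{-12}} (and p-values at or below \eqn{10^{-12}}) are capped so
#' scores stay finite; larger scores mean stronger evidence.
#'
#' @param de A `de_result` from [de_analysis()].
#' @param mode `"timecourse"` or `"timepoint"`.
#' @param time_h Required in time-point mode: which time point's p-values.
#' @return Tibble: `gene_id`, `score`.
#' @export
compute_ranking_scores <- function(de, mode = c("timecourse", "timepoint"),
                                   time_h = NULL) {
  mode <- match.arg(mode)
  cap <- 1e-12
  if (mode == "timecourse") {
    prob <- de$genes$posterior_prob
    if (any(prob < 0 | prob > 1)) abort("posterior probabilities outside [0,1]")
    tibble(gene_id = de$genes$gene_id,
           score = -log(pmax(1 - prob, cap)))
  } else {
    if (is.null(time_h)) abort("time_h is required in timepoint mode")
    tp <- de$timepoints[de$timepoints$time_h == time_h, , drop = FALSE]
    if (nrow(tp) == 0) abort(paste0("no tested time point at ", time_h, " h"))
    if (any(tp$p_value < 0 | tp$p_value > 1)) abort("p-values outside [0,1]")
    tibble(gene_id = tp$gene_id, score = -log(pmax(tp$p_value, cap)))
  }
}

#' Logistic-regression gene-set association test
#'
#' Regresses set membership on the ranking score
#' (\eqn{\text{member} \sim \alpha + \beta \cdot \text{score}}) by maximum
#' likelihood and tests \eqn{\beta = 0} with a 1-df likelihood-ratio test.
#' The p-value is two-sided; the slope sign gives the direction of
#' association. Under perfect separation a Firth-penalised fit is used and
#' flagged.
#'
#' @param scores Tibble with `gene_id`, `score`.
#' @param gene_set Character vector of member gene ids.
#' @param min_genes Minimum scored members and non-members (below: `NA`
#'   result with a reason).
#' @return One-row tibble: `n_genes_in_set_tested`, `slope`, `direction`,
#'   `p_value`, `method`, `note`.
#' @export
logistic_set_test <- function(scores, gene_set, min_genes = 5) {
  y <- as.integer(scores$gene_id %in% gene_set)
  x <- scores$score
  n1 <- sum(y); n0 <- sum(1 - y)
  if (n1 < min_genes || n0 < min_genes) {
    return(tibble(n_genes_in_set_tested = n1, slope = NA_real_,
                  direction = NA_real_, p_value = NA_real_,
                  method = "skipped",
                  note = paste0("fewer than ", min_genes,
                                " scored members or non-members")))
  }
  if (sd(x) == 0) {
    return(tibble(n_genes_in_set_tested = n1, slope = 0, direction = 0,
                  p_value = 1, method = "lrt", note = "constant scores"))
  }
  fit <- suppressWarnings(glm(y ~ x, family = binomial()))
  separated <- !fit$converged || any(abs(coef(fit)) > 15) ||
    max(fit$fitted.values) > 1 - 1e-8 || min(fit$fitted.values) < 1e-8
  if (!separated) {
    lrt <- fit$null.deviance - fit$deviance
    p <- pchisq(lrt, df = 1, lower.tail = FALSE)
    slope <- coef(fit)[["x"]]
    return(tibble(n_genes_in_set_tested = n1, slope = slope,
                  direction = sign(slope), p_value = p, method = "lrt",
                  note = NA_character_))
  }
  fr <- firth_logistic(x, y)
  tibble(n_genes_in_set_tested = n1, slope = fr$slope,
         direction = sign(fr$slope), p_value = fr$p, method = "firth",
         note = "perfect separation; Firth-penalised fallback")
}

# Firth-penalised univariate logistic regression with a penalised LRT of
# slope = 0. Penalty: + 0.5 log det(X'WX) (Jeffreys prior).
firth_logistic <- function(x, y, max_iter = 100, tol = 1e-8) {
  X <- cbind(1, x)
  fit_pl <- function(Xm) {
    beta <- rep(0, ncol(Xm))
    for (i in seq_len(max_iter)) {
      eta <- drop(Xm %*% beta)
      p <- 1 / (1 + exp(-eta))
      W <- p * (1 - p)
      XtW <- t(Xm * W)
      info <- XtW %*% Xm
      h <- rowSums((Xm %*% solve(info)) * (Xm * W))
      U <- t(Xm) %*% (y - p + h * (0.5 - p))
      step <- solve(info, U)
      beta <- beta + drop(step)
      if (max(abs(step)) < tol) break
    }
    eta <- drop(Xm %*% beta)
    p <- 1 / (1 + exp(-eta))
    W <- p * (1 - p)
    info <- t(Xm * W) %*% Xm
    pl <- sum(y * eta - log1p(exp(eta))) + 0.5 * determinant(info)$modulus
    list(beta = beta, pl = as.numeric(pl))
  }
  full <- fit_pl(X)
  null <- fit_pl(X[, 1, drop = FALSE])
  lrt <- 2 * (full$pl - null$pl)
  list(slope = full$beta[2], p = pchisq(max(lrt, 0), 1, lower.tail = FALSE))
}

#' Test a gene-set collection against ranking scores
#'
#' Runs [logistic_set_test()] for every set, adjusting p-values across tested
#' sets by Benjamini-Yekutieli (valid under arbitrary dependence between
#' sets). Significance is declared at `fdr_by < fdr`.
#'
#' @param scores Tibble with `gene_id`, `score`.
#' @param sets GMT-style tibble (`set_id`, `genes` list-column) or named list.
#' @param fdr BY FDR cutoff (default 0.05).
#' @param min_genes Passed to [logistic_set_test()].
#' @return Tibble: `set_id`, `n_genes_in_set_tested`, `slope`, `direction`,
#'   `p_value`, `fdr_by`, `significant`, `method`, `note`.
#' @export
enrich_sets <- function(scores, sets, fdr = 0.05, min_genes = 5) {
  sets <- as_gene_set_tbl(sets)
  res <- map(sets$genes, function(g) logistic_set_test(scores, g, min_genes))
  out <- bind_cols(tibble(set_id = sets$set_id), bind_rows(res))
  out$fdr_by <- NA_real_
  tested <- !is.na(out$p_value)
  out$fdr_by[tested] <- p.adjust(out$p_value[tested], method = "BY")
  out$significant <- !is.na(out$fdr_by) & out$fdr_by < fdr
  out
}

#' Hypergeometric over-representation test
#'
#' Upper-tail hypergeometric \eqn{P(X \ge k)} of the overlap between a DE set
#' and each gene set, drawing \eqn{|DE|} genes from the universe.
#'
#' @param de_set Character vector of DE genes (must lie in `universe`).
#' @param universe Character vector, the gene universe.
#' @param gene_sets GMT-style tibble or named list of gene sets.
#' @param fdr BY FDR cutoff for the `significant` flag.
#' @return Tibble: `set_id`, `n_set_in_universe`, `overlap`, `p_value`,
#'   `fdr_by`, `significant`.
#' @export
hypergeom_overrepresentation <- function(de_set, universe, gene_sets,
                                         fdr = 0.05) {
  if (length(universe) == 0) abort("empty universe")
  de_set <- unique(de_set)
  if (!all(de_set %in% universe)) abort("de_set must be a subset of universe")
  gene_sets <- as_gene_set_tbl(gene_sets)
  N <- length(unique(universe))
  n <- length(de_set)
  rows <- pmap(gene_sets[, c("set_id", "genes")], function(set_id, genes) {
    K <- length(intersect(genes, universe))
    k <- length(intersect(genes, de_set))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble(set_id = set_id, n_set_in_universe = K, overlap = k, p_value = p)
  })
  out <- bind_rows(rows)
  out$fdr_by <- p.adjust(out$p_value, method = "BY")
  out$significant <- out$fdr_by < fdr
  out
}

#' Terms significant in every cell type
#'
#' Intersects the sets with `fdr_by` below the cutoff across all cell types
#' and emits the heatmap-ready matrix of \eqn{-\log(\text{FDR})} values.
#'
#' @param per_celltype_records Named list (cell type -> enrichment tibble
#'   with `set_id`, `fdr_by`).
#' @param fdr FDR cutoff (default 0.05).
#' @return List with `common` (character vector) and `table` (long tibble:
#'   `set_id`, `cell_type`, `fdr_by`, `neg_log_fdr`, `significant`).
#' @export
common_terms <- function(per_celltype_records, fdr = 0.05) {
  if (length(per_celltype_records) < 2) abort("need at least 2 cell types")
  sig <- map(per_celltype_records, function(r) {
    r$set_id[!is.na(r$fdr_by) & r$fdr_by < fdr]
  })
  common <- Reduce(intersect, sig)
  tab <- bind_rows(imap(per_celltype_records, function(r, ct) {
    tibble(set_id = r$set_id, cell_type = ct, fdr_by = r$fdr_by)
  })) %>%
    mutate(neg_log_fdr = -log(pmax(.data$fdr_by, 1e-300)),
           significant = !is.na(.data$fdr_by) & .data$fdr_by < fdr)
  list(common = common, table = tab)
}

#' Reproducibility of a common set in a validation dataset
#'
#' Counts how many commonly identified items were found again in the
#' validation set, as a rounded percentage, with an upper-tail hypergeometric
#' p-value in the candidate universe.
#'
#' @param common_set Items found in all discovery cell types (non-empty).
#' @param validation_significant_set Items significant in the validation set.
#' @param candidate_universe Universe the items were drawn from.
#' @return One-row tibble: `n_common`, `count`, `percent`, `hypergeom_p`.
#' @export
reproducibility <- function(common_set, validation_significant_set,
                            candidate_universe) {
  common_set <- unique(common_set)
  if (length(common_set) == 0) abort("empty common set")
  validation_significant_set <- unique(validation_significant_set)
  candidate_universe <- unique(candidate_universe)
  count <- length(intersect(common_set, validation_significant_set))
  N <- length(candidate_universe)
  m <- length(intersect(validation_significant_set, candidate_universe))
  p <- phyper(count - 1, m, N - m, length(common_set), lower.tail = FALSE)
  tibble(
    n_common = length(common_set),
    count = count,
    percent = round(100 * count / length(common_set)),
    hypergeom_p = p
  )
}
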