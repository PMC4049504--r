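# Model-based clustering of log fold-change curves: Gaussian mixture over
# spline-basis coefficients fitted by EM, with BIC selection of the number of
# clusters. Run on DE genes' fold changes relative to 0 h, so genes are
# grouped by their response to the stimulus rather than absolute expression.

curve_basis <- function(time_h, df = NULL) {
  Tn <- length(time_h)
  df <- df %||% min(4L, Tn - 1L)
  if (Tn <= 3L || df >= Tn) {
    return(diag(Tn)) # identity basis: too few points for a spline
  }
  b <- splines::ns(time_h, df = df)
  cbind(1, unclass(b))
}

#' Fit a Gaussian mixture over fold-change curves
#'
#' Each gene's curve is modelled as a spline-basis expansion of a cluster
#' mean plus i.i.d. Gaussian noise (per-cluster isotropic variance). EM is
#' run from `n_init` k-means-seeded starts and the best local optimum kept.
#' With three or fewer time points the basis falls back to the raw
#' time-point coordinates.
#'
#' @param profiles An `fc_profiles` object, or a numeric matrix of mean log
#'   fold-change curves (genes x time points) with gene-id rownames.
#' @param K Number of clusters (at most the number of genes).
#' @param seed Integer seed governing all restarts.
#' @param n_init Number of EM restarts.
#' @param max_iter Maximum EM iterations per restart.
#' @param time_h Time grid; required when `profiles` is a bare matrix.
#' @return A `curve_mixture`: list with `K`, `basis` (matrix and df),
#'   `mean_coefficients` (K x df), `mean_curves` (K x T), `noise_variance`,
#'   `mixing_weights`, `responsibilities` (genes x K), `loglik`, `bic`,
#'   `gene_ids`, `time_h`.
#' @export
fit_curve_mixture <- function(profiles, K, seed = 1, n_init = 10,
                              max_iter = 200, time_h = NULL) {
  if (inherits(profiles, "fc_profiles")) {
    Y <- profiles$lfc_mean
    time_h <- profiles$time_h
  } else {
    Y <- as.matrix(profiles)
    if (is.null(time_h)) abort("`time_h` is required for a bare matrix input")
  }
  G <- nrow(Y); Tn <- ncol(Y)
  if (K > G) abort("K exceeds the number of genes")
  B <- curve_basis(time_h)
  P <- ncol(B)
  proj <- solve(crossprod(B), t(B)) # least-squares projector onto the basis

  seeds <- child_seeds(seed, n_init)
  best <- NULL
  for (init in seq_len(n_init)) {
    res <- with_seed(seeds[init], em_curve_mixture(Y, B, proj, K, max_iter))
    if (is.null(best) || res$loglik > best$loglik) best <- res
  }
  n_par <- (K - 1) + K * P + K # weights + mean coefficients + variances
  bic <- -2 * best$loglik + n_par * log(G)
  structure(
    list(K = K,
         basis = list(type = if (Tn <= 3 || ncol(B) >= Tn) "identity" else "natural_spline",
                      df = P, matrix = B),
         mean_coefficients = best$coef,
         mean_curves = matrix(best$coef %*% t(B), nrow = K,
                              dimnames = list(NULL, paste0("t", time_h))),
         noise_variance = best$sigma2,
         mixing_weights = best$pi,
         responsibilities = best$resp,
         loglik = best$loglik, bic = bic,
         gene_ids = rownames(Y) %||% paste0("g", seq_len(G)),
         time_h = time_h),
    class = "curve_mixture"
  )
}

em_curve_mixture <- function(Y, B, proj, K, max_iter) {
  G <- nrow(Y); Tn <- ncol(Y)
  # weak inverse-gamma prior on component variances (scale = average total
  # variance, strength ~ one curve's worth of observations): keeps small
  # components from collapsing onto spurious near-zero-variance optima, the
  # standard regularisation for mixture/BIC model selection
  s2_prior <- mean(apply(Y, 2, var))
  nu_prior <- Tn
  # k-means seeding on the curves themselves
  km <- tryCatch(
    kmeans(Y, centers = K, nstart = 1, iter.max = 20),
    error = function(e) list(cluster = sample(rep_len(seq_len(K), G)))
  )
  resp <- matrix(1e-6, G, K)
  resp[cbind(seq_len(G), km$cluster)] <- 1
  resp <- resp / rowSums(resp)
  pi_k <- rep(1 / K, K)
  coef_k <- matrix(0, K, ncol(B))
  sigma2 <- rep(1, K)
  ll <- -Inf
  for (it in seq_len(max_iter)) {
    # M-step
    nk <- colSums(resp)
    pi_k <- pmax(nk / G, 1e-10); pi_k <- pi_k / sum(pi_k)
    for (k in seq_len(K)) {
      wmean <- colSums(Y * resp[, k]) / nk[k]
      coef_k[k, ] <- drop(proj %*% wmean)
      fitted <- drop(B %*% coef_k[k, ])
      r2 <- rowSums(sweep(Y, 2, fitted)^2)
      sigma2[k] <- max(
        (sum(resp[, k] * r2) + nu_prior * s2_prior) /
          (nk[k] * Tn + nu_prior + 2),
        1e-6
      )
    }
    # E-step
    logd <- vapply(seq_len(K), function(k) {
      fitted <- drop(B %*% coef_k[k, ])
      -0.5 * rowSums(sweep(Y, 2, fitted)^2) / sigma2[k] -
        0.5 * Tn * log(2 * pi * sigma2[k]) + log(pi_k[k])
    }, numeric(G))
    m <- apply(logd, 1, max)
    lse <- m + log(rowSums(exp(logd - m)))
    resp <- exp(logd - lse)
    new_ll <- sum(lse)
    if (is.finite(ll) && abs(new_ll - ll) <= 1e-8 * (abs(ll) + 1)) {
      ll <- new_ll
      break
    }
    ll <- new_ll
  }
  if (any(sigma2 <= 1e-6)) {
    warn("degenerate component variance floored at 1e-6")
  }
  list(coef = coef_k, sigma2 = sigma2, pi = pi_k, resp = resp, loglik = ll)
}

#' @export
print.curve_mixture <- function(x, ...) {
  cat("<curve_mixture> K = ", x$K, ", ", length(x$gene_ids), " genes, BIC = ",
      round(x$bic, 1), " (", x$basis$type, " basis, df ", x$basis$df, ")\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.curve_mixture <- function(x, ...) {
  tibble(
    cluster = seq_len(x$K),
    mixing_weight = x$mixing_weights,
    noise_variance = x$noise_variance,
    n_members = as.integer(table(factor(hard_assignment(x), levels = seq_len(x$K))))
  )
}

#' @export
glance.curve_mixture <- function(x, ...) {
  tibble(K = x$K, loglik = x$loglik, bic = x$bic, n_genes = length(x$gene_ids))
}

hard_assignment <- function(model) {
  # argmax responsibility; ties broken toward the lower cluster index
  unname(apply(model$responsibilities, 1, which.max))
}

#' Select the number of clusters by BIC
#'
#' Fits the curve mixture for each candidate K and returns the fit with the
#' lowest BIC (lower is better: BIC = -2 loglik + params log n).
#'
#' @inheritParams fit_curve_mixture
#' @param k_range Integer vector of candidate cluster counts.
#' @return List with `best_K`, `model` (the winning `curve_mixture`) and
#'   `bic_table` tibble (`K`, `loglik`, `bic`).
#' @export
select_k_bic <- function(profiles, k_range, seed = 1, n_init = 10,
                         time_h = NULL) {
  if (length(k_range) == 0) abort("k_range must be non-empty")
  seeds <- child_seeds(seed, length(k_range))
  fits <- map(seq_along(k_range), function(i) {
    fit_curve_mixture(profiles, K = k_range[i], seed = seeds[i],
                      n_init = n_init, time_h = time_h)
  })
  bics <- map_dbl(fits, "bic")
  best <- which.min(bics)
  list(best_K = k_range[best], model = fits[[best]],
       bic_table = tibble(K = k_range, loglik = map_dbl(fits, "loglik"),
                          bic = bics))
}

#' Cluster membership and mean-curve report
#'
#' Hard assignments are the argmax responsibility with ties broken toward the
#' lower cluster index; the mean-curve table is reproducible from the model.
#'
#' @param model A `curve_mixture`.
#' @param gene_ids Optional gene ids (default: those stored in the model).
#' @return List of tibbles: `members` (`gene_id`, `cluster`,
#'   `responsibility`) and `mean_curves` (`cluster`, `time_h`, `logfc`).
#' @export
cluster_report <- function(model, gene_ids = NULL) {
  stopifnot(inherits(model, "curve_mixture"))
  gene_ids <- gene_ids %||% model$gene_ids
  assign <- hard_assignment(model)
  members <- tibble(
    gene_id = gene_ids,
    cluster = assign,
    responsibility = model$responsibilities[cbind(seq_along(assign), assign)]
  )
  mean_curves <- as_tibble(model$mean_curves) %>%
    mutate(cluster = seq_len(model$K)) %>%
    tidyr::pivot_longer(-"cluster", names_to = "time_h", values_to = "logfc") %>%
    mutate(time_h = as.numeric(sub("^t", "", .data$time_h)))
  list(members = members, mean_curves = mean_curves)
}

#' Cluster DE genes, skipping degenerate inputs
#'
#' Applies the study rule for sparse cell types: when fewer than `2 * min(k_range)`
#' DE genes are available no mixture is fitted and all genes are reported as
#' one group, as was done for the cell type where no clusters could be
#' identified.
#'
#' @param profiles An `fc_profiles` restricted to DE genes (see
#'   [subset_profiles()]).
#' @param k_range Candidate cluster counts.
#' @inheritParams fit_curve_mixture
#' @return As [select_k_bic()], plus `skipped = TRUE` with a single-group
#'   report when clustering was not attempted.
#' @export
cluster_de_genes <- function(profiles, k_range = 2:6, seed = 1, n_init = 10) {
  n <- length(profiles$gene_ids)
  if (n < 2 * min(k_range)) {
    inform("too few DE genes to cluster; treating all DE genes as one group")
    return(list(best_K = 1L, model = NULL, bic_table = NULL, skipped = TRUE,
                members = tibble(gene_id = profiles$gene_ids, cluster = 1L,
                                 responsibility = 1)))
  }
  out <- select_k_bic(profiles, k_range, seed = seed, n_init = n_init)
  out$skipped <- FALSE
  out$members <- cluster_report(out$model)$members
  out
}

#' Restrict fold-change profiles to a gene subset
#'
#' @param profiles An `fc_profiles`.
#' @param genes Character vector of gene ids to keep.
#' @return An `fc_profiles` over the intersection, in `genes` order.
#' @export
subset_profiles <- function(profiles, genes) {
  keep <- intersect(genes, profiles$gene_ids)
  idx <- match(keep, profiles$gene_ids)
  structure(
    list(lfc = profiles$lfc[idx, , , drop = FALSE],
         lfc_mean = profiles$lfc_mean[idx, , drop = FALSE],
         time_h = profiles$time_h, gene_ids = keep,
         cell_type = profiles$cell_type),
    class = "fc_profiles"
  )
}
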