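# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately avoid the package's own implementation paths.

# step-up BH adjustment, straight from the definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# step-up BY adjustment with the harmonic-number penalty
oracle_by <- function(p) {
  n <- length(p)
  cn <- sum(1 / seq_len(n))
  o <- order(p)
  adj <- p[o] * n * cn / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# exact upper-tail hypergeometric by direct combinatorial summation
oracle_hyper <- function(k, K, N, n) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# exhaustive Wang S-values: enumerate every directed path from the term to
# each ancestor and take the maximal product of edge weights
oracle_s_values <- function(term, edges, weights = c(is_a = 0.8, part_of = 0.6)) {
  s <- setNames(1, term)
  walk <- function(node, value) {
    up <- edges[edges$child == node, , drop = FALSE]
    for (i in seq_len(nrow(up))) {
      v <- value * weights[[up$relation[i]]]
      a <- up$parent[i]
      if (is.na(s[a]) || v > s[[a]]) s[a] <<- v
      walk(a, v)
    }
  }
  walk(term, 1)
  s
}

oracle_term_sim <- function(t1, t2, edges) {
  s1 <- oracle_s_values(t1, edges)
  s2 <- oracle_s_values(t2, edges)
  shared <- intersect(names(s1), names(s2))
  sum(s1[shared] + s2[shared]) / (sum(s1) + sum(s2))
}

# random DAG over n terms: edges only from higher index to lower (acyclic)
random_dag_edges <- function(n_terms, p_edge = 0.25) {
  ids <- sprintf("t%02d", seq_len(n_terms))
  rows <- list()
  for (i in 2:n_terms) {
    parents <- which(runif(i - 1) < p_edge)
    if (length(parents) == 0) parents <- sample.int(i - 1, 1)
    rows[[i]] <- tibble::tibble(
      child = ids[i], parent = ids[parents],
      relation = sample(c("is_a", "part_of"), length(parents), replace = TRUE)
    )
  }
  dplyr::bind_rows(rows)
}

# exhaustive minimum-distance simple paths in a small weighted graph
oracle_min_distance <- function(edges, dist, source, target) {
  nodes <- unique(c(edges$from, edges$to))
  adj <- list()
  for (i in seq_len(nrow(edges))) {
    adj[[edges$from[i]]] <- c(adj[[edges$from[i]]], i)
    adj[[edges$to[i]]] <- c(adj[[edges$to[i]]], i)
  }
  best <- Inf
  walk <- function(node, seen, d) {
    if (d > best + 1e-12) return()
    if (node == target) {
      best <<- min(best, d)
      return()
    }
    for (i in adj[[node]]) {
      nxt <- if (edges$from[i] == node) edges$to[i] else edges$from[i]
      if (nxt %in% seen) next
      walk(nxt, c(seen, nxt), d + dist[i])
    }
  }
  if (source == target) return(0)
  walk(source, source, 0)
  best
}

# adjusted Rand index between two partitions (label-free comparison)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# toy expression object: G genes, grid time points, R replicates,
# optional per-gene mean shift function mu(gene, time)
toy_expr <- function(G = 20, times = c(0, 2, 8), R = 3, noise = 0.3,
                     mu = function(g, t) 0, cell_type = "toy",
                     batch = NULL, seed = 1) {
  set.seed(seed)
  meta <- tidyr::expand_grid(time_h = times, replicate = seq_len(R))
  meta$sample_id <- sprintf("s_t%g_r%d", meta$time_h, meta$replicate)
  meta$cell_type <- cell_type
  meta$batch <- if (is.null(batch)) NA_character_ else batch(meta)
  m <- matrix(rnorm(G * nrow(meta), sd = noise), G, nrow(meta))
  for (g in seq_len(G)) {
    m[g, ] <- m[g, ] + 7 + vapply(meta$time_h, function(t) mu(g, t), 0)
  }
  rownames(m) <- sprintf("g%03d", seq_len(G))
  colnames(m) <- meta$sample_id
  expr_timecourse(m, meta)
}
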