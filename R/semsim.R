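# Wang-measure semantic similarity over an ontology DAG, aggregated to genes
# and clusters by best-match averaging, used to find functionally similar
# clusters across cell types.

# S-values of a term over its ancestor closure: S_t(t) = 1 and
# S_t(a) = max over children c of a (on paths to t) of w(c -> a) * S_t(c).
# Relaxation over the closure's edges; terminates because the DAG is acyclic.
term_s_values <- function(term, dag, weights = c(is_a = 0.8, part_of = 0.6)) {
  if (!term %in% dag$terms) abort(paste0("term '", term, "' not in the DAG"))
  up <- dag$edges
  s <- setNames(1, term)
  frontier <- term
  while (length(frontier) > 0) {
    e <- up[up$child %in% frontier, , drop = FALSE]
    if (nrow(e) == 0) break
    cand <- s[e$child] * weights[e$relation]
    upd <- tapply(cand, e$parent, max)
    changed <- character()
    for (a in names(upd)) {
      if (is.null(s[a]) || is.na(s[a]) || upd[[a]] > s[[a]] + 1e-15) {
        s[a] <- upd[[a]]
        changed <- c(changed, a)
      }
    }
    frontier <- changed
  }
  s
}

#' Wang semantic similarity between two ontology terms
#'
#' Propagates decay-weighted S-values from each term over its ancestors
#' (contribution factors 0.8 for `is_a`, 0.6 for `part_of`) and scores
#' \eqn{sim(t_1,t_2) = \sum_{a} (S_{t_1}(a) + S_{t_2}(a)) / (SV(t_1) +
#' SV(t_2))} over the shared terms of the two closures.
#'
#' @param t1,t2 Term ids (must be in the DAG).
#' @param dag An [ontology_dag].
#' @param weights Named contribution factors for `is_a` and `part_of` edges.
#' @return Similarity in \[0, 1\].
#' @export
term_similarity <- function(t1, t2, dag,
                            weights = c(is_a = 0.8, part_of = 0.6)) {
  s1 <- term_s_values(t1, dag, weights)
  s2 <- term_s_values(t2, dag, weights)
  shared <- intersect(names(s1), names(s2))
  sum(s1[shared] + s2[shared]) / (sum(s1) + sum(s2))
}

# Pairwise term-similarity matrix with S-values computed once per term.
term_similarity_matrix <- function(terms, dag,
                                   weights = c(is_a = 0.8, part_of = 0.6)) {
  sv <- map(setNames(terms, terms), term_s_values, dag = dag, weights = weights)
  n <- length(terms)
  m <- matrix(1, n, n, dimnames = list(terms, terms))
  if (n < 2) return(m)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- intersect(names(sv[[i]]), names(sv[[j]]))
      val <- sum(sv[[i]][shared] + sv[[j]][shared]) /
        (sum(sv[[i]]) + sum(sv[[j]]))
      m[i, j] <- m[j, i] <- val
    }
  }
  m
}

# best-match average of a similarity matrix: mean of row maxima and column
# maxima pooled together
bma <- function(simmat) {
  if (length(simmat) == 0) return(NA_real_)
  mean(c(apply(simmat, 1, max), apply(simmat, 2, max)))
}

# informative annotations: drop terms equal to a DAG root
informative_terms <- function(genes, annotations, dag) {
  ann <- annotations[annotations$gene_id %in% genes &
                       !annotations$term_id %in% dag$roots, , drop = FALSE]
  split(ann$term_id, ann$gene_id)
}

#' Semantic similarity between two genes
#'
#' Best-match average over the pairwise Wang similarity matrix of the two
#' genes' annotation sets. Genes annotated only to a DAG root are treated as
#' unannotated and yield `NA`.
#'
#' @param g1,g2 Gene ids.
#' @param annotations Tibble with columns `gene_id`, `term_id`.
#' @param dag An [ontology_dag].
#' @inheritParams term_similarity
#' @return Similarity in \[0, 1\], or `NA` when a gene is unannotated.
#' @export
gene_similarity <- function(g1, g2, annotations, dag,
                            weights = c(is_a = 0.8, part_of = 0.6)) {
  ann <- informative_terms(c(g1, g2), annotations, dag)
  ts1 <- unique(ann[[g1]]); ts2 <- unique(ann[[g2]])
  if (is.null(ts1) || is.null(ts2)) return(NA_real_)
  tm <- term_similarity_matrix(unique(c(ts1, ts2)), dag, weights)
  bma(tm[ts1, ts2, drop = FALSE])
}

#' Semantic similarity between two gene clusters
#'
#' Best-match average over the gene-by-gene similarity matrix between the two
#' clusters; unannotated genes are excluded (not scored as zero). Pairs above
#' the threshold are flagged as highly similar.
#'
#' @param cluster_a,cluster_b Character vectors of gene ids.
#' @param annotations Tibble with `gene_id`, `term_id`.
#' @param dag An [ontology_dag].
#' @param threshold Similarity above which a pair counts as highly similar.
#' @inheritParams term_similarity
#' @return Tibble with `similarity` and `highly_similar`.
#' @export
cluster_similarity <- function(cluster_a, cluster_b, annotations, dag,
                               threshold = 0.7,
                               weights = c(is_a = 0.8, part_of = 0.6)) {
  ann <- informative_terms(unique(c(cluster_a, cluster_b)), annotations, dag)
  ga <- intersect(cluster_a, names(ann))
  gb <- intersect(cluster_b, names(ann))
  if (length(ga) == 0 || length(gb) == 0) {
    return(tibble(similarity = NA_real_, highly_similar = NA))
  }
  terms <- unique(unlist(ann[c(ga, gb)]))
  tm <- term_similarity_matrix(terms, dag, weights)
  gm <- matrix(NA_real_, length(ga), length(gb), dimnames = list(ga, gb))
  for (i in seq_along(ga)) {
    for (j in seq_along(gb)) {
      gm[i, j] <- bma(tm[unique(ann[[ga[i]]]), unique(ann[[gb[j]]]),
                         drop = FALSE])
    }
  }
  s <- bma(gm)
  tibble(similarity = s, highly_similar = s > threshold)
}

#' Cross-cell-type cluster similarity table
#'
#' Computes the Wang/BMA similarity for every pair of clusters between two
#' cell types' cluster membership tables.
#'
#' @param members_a,members_b Tibbles with `gene_id`, `cluster` (as returned
#'   in [cluster_report()]`$members`).
#' @param annotations Tibble with `gene_id`, `term_id`.
#' @param dag An [ontology_dag].
#' @param threshold Highly-similar flag threshold.
#' @return Long tibble: `cluster_a`, `cluster_b`, `similarity`,
#'   `highly_similar`.
#' @export
cluster_similarity_table <- function(members_a, members_b, annotations, dag,
                                     threshold = 0.7) {
  ca <- split(members_a$gene_id, members_a$cluster)
  cb <- split(members_b$gene_id, members_b$cluster)
  grid <- tidyr::expand_grid(cluster_a = names(ca), cluster_b = names(cb))
  res <- pmap(grid, function(cluster_a, cluster_b) {
    cluster_similarity(ca[[cluster_a]], cb[[cluster_b]], annotations, dag,
                       threshold = threshold)
  })
  bind_cols(grid, bind_rows(res))
}
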