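# Homolog-mediated projection of gene sets between species and overlap
# statistics across cell types. Gene identifiers never cross namespaces by
# name matching: every cross-species join goes through the homolog table.

#' Filter a homolog table at an E-value threshold
#'
#' Pairs with E-value strictly below the cutoff are retained; many-to-many
#' relations are kept (when a gene has several passing partners, all are
#' considered). Bit-scores are carried along but not used for filtering.
#'
#' @param pairs Homolog tibble (`gene_a`, `gene_b`, `evalue`, ...).
#' @param e_cut E-value threshold (default 1e-30, strict `<`).
#' @return The filtered tibble.
#' @export
filter_homologs <- function(pairs, e_cut = 1e-30) {
  pairs[pairs$evalue < e_cut, , drop = FALSE]
}

resolve_namespace <- function(pairs, target_namespace) {
  if (all(c("species_a", "species_b") %in% names(pairs)) &&
      nrow(pairs) > 0) {
    if (target_namespace %in% pairs$species_a) return("a")
    if (target_namespace %in% pairs$species_b) return("b")
  }
  if (target_namespace %in% c("a", "b")) return(target_namespace)
  abort(paste0("unknown namespace '", target_namespace, "'"))
}

#' Project a gene set into another species' namespace
#'
#' Returns the union of all homolog partners of the input genes in the target
#' namespace; genes with no passing partner are dropped and counted in the
#' `dropped` attribute.
#'
#' @param genes Character vector of gene ids.
#' @param pairs Filtered homolog tibble (see [filter_homologs()]).
#' @param target_namespace `"a"`/`"b"`, or a species name when the table has
#'   `species_a`/`species_b` columns.
#' @return Character vector of projected gene ids, with attribute `dropped`.
#' @export
project_gene_set <- function(genes, pairs, target_namespace) {
  side <- resolve_namespace(pairs, target_namespace)
  from <- if (side == "a") pairs$gene_b else pairs$gene_a
  to <- if (side == "a") pairs$gene_a else pairs$gene_b
  hit <- from %in% genes
  out <- sort(unique(to[hit]))
  n_dropped <- length(setdiff(genes, from))
  attr(out, "dropped") <- n_dropped
  out
}

#' Overlap statistics between two gene sets
#'
#' Directional overlap fractions \eqn{f_A = |A \cap B| / |A|},
#' \eqn{f_B = |A \cap B| / |B|}, their harmonic mean
#' \eqn{2 / (1/f_A + 1/f_B)} (0 for an empty intersection), and an upper-tail
#' hypergeometric p-value in the given universe.
#'
#' @param set_a,set_b Non-empty character vectors (subsets of `universe`).
#' @param universe Gene universe for the hypergeometric test.
#' @return One-row tibble: `n_a`, `n_b`, `intersection`, `f_a`, `f_b`,
#'   `harmonic_mean`, `hypergeom_p`.
#' @export
overlap_stats <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (length(set_a) == 0 || length(set_b) == 0) abort("empty input set")
  universe <- unique(universe)
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    abort("sets must be subsets of the universe")
  }
  k <- length(intersect(set_a, set_b))
  f_a <- k / length(set_a)
  f_b <- k / length(set_b)
  hm <- if (k == 0) 0 else 2 / (1 / f_a + 1 / f_b)
  p <- phyper(k - 1, length(set_b), length(universe) - length(set_b),
              length(set_a), lower.tail = FALSE)
  tibble(n_a = length(set_a), n_b = length(set_b), intersection = k,
         f_a = f_a, f_b = f_b, harmonic_mean = hm, hypergeom_p = p)
}

#' Cross-cell-type membership matrix in a reference namespace
#'
#' Projects every cell type's gene set into the reference species namespace
#' (sets already in that namespace pass through) and tabulates per-gene
#' membership, the genes found in all cell types, and all pairwise overlaps.
#'
#' @param de_sets Named list: cell type -> character vector of gene ids.
#' @param pairs Filtered homolog tibble.
#' @param species Named character vector: cell type -> species.
#' @param reference_namespace Species name of the reference namespace.
#' @return List with `membership` (tibble, `gene_id` plus one logical column
#'   per cell type and `n_cell_types`), `in_all` (character vector).
#' @export
multi_way_membership <- function(de_sets, pairs, species,
                                 reference_namespace = species[[1]]) {
  stopifnot(all(names(de_sets) %in% names(species)))
  projected <- imap(de_sets, function(g, ct) {
    if (species[[ct]] == reference_namespace) unique(g)
    else project_gene_set(g, pairs, reference_namespace)
  })
  all_genes <- sort(unique(unlist(projected)))
  mem <- tibble(gene_id = all_genes)
  for (ct in names(projected)) {
    mem[[ct]] <- all_genes %in% projected[[ct]]
  }
  counts <- rowSums(as.matrix(mem[, names(projected), drop = FALSE]))
  mem$n_cell_types <- as.integer(counts)
  list(membership = mem,
       in_all = all_genes[counts == length(projected)],
       projected = projected)
}
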