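# Node-weighted interactome path analysis: nodes carry the mean
# whole-time-course DE probability across an organism's cell types, each
# edge costs 2 minus the sum of its incident nodes' weights, and
# minimum-distance (= maximum node weight) paths are found by Dijkstra with
# all tied paths enumerated.

#' Build a node-weighted interaction network
#'
#' Node weight is the mean whole-course posterior probability over the cell
#' types in which the gene was measured; genes measured in none get weight 0
#' (counted). Edge distance is \eqn{2 - (w_u + w_v)}.
#'
#' @param edges Tibble with columns `from`, `to` (undirected; see
#'   [read_network()]).
#' @param posterior_tables Named list (cell type -> tibble with `gene_id`,
#'   `posterior_prob`), all from the same organism.
#' @return A `weighted_network`: list with `nodes` tibble (`gene_id`,
#'   `weight`, `n_measured`), `edges` tibble (`from`, `to`, `distance`),
#'   `n_unmeasured`.
#' @export
weight_nodes <- function(edges, posterior_tables) {
  probs <- bind_rows(imap(posterior_tables, function(tbl, ct) {
    if (any(tbl$posterior_prob < 0 | tbl$posterior_prob > 1)) {
      abort("posterior probabilities outside [0,1]")
    }
    tibble(gene_id = tbl$gene_id, posterior_prob = tbl$posterior_prob,
           cell_type = ct)
  }))
  nodes <- tibble(gene_id = sort(unique(c(edges$from, edges$to))))
  agg <- probs %>%
    group_by(.data$gene_id) %>%
    summarise(weight = mean(.data$posterior_prob),
              n_measured = dplyr::n(), .groups = "drop")
  nodes <- left_join(nodes, agg, by = "gene_id") %>%
    mutate(n_measured = ifelse(is.na(.data$n_measured), 0L, .data$n_measured),
           weight = ifelse(is.na(.data$weight), 0, .data$weight))
  w <- setNames(nodes$weight, nodes$gene_id)
  edges <- edges %>%
    mutate(distance = 2 - unname(w[.data$from] + w[.data$to]))
  structure(
    list(nodes = nodes, edges = edges,
         n_unmeasured = sum(nodes$n_measured == 0L)),
    class = "weighted_network"
  )
}

#' @export
print.weighted_network <- function(x, ...) {
  cat("<weighted_network> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges (", x$n_unmeasured, " unmeasured nodes at weight 0)\n", sep = "")
  invisible(x)
}

#' @export
tidy.weighted_network <- function(x, ...) x$nodes

# adjacency list with edge distances
adjacency <- function(net) {
  e <- net$edges
  both <- bind_rows(
    tibble(a = e$from, b = e$to, d = e$distance),
    tibble(a = e$to, b = e$from, d = e$distance)
  )
  split(both[, c("b", "d")], both$a)
}

# Dijkstra from a source; returns distances and, for tied-path enumeration,
# the set of predecessors attaining each node's distance within tolerance.
dijkstra_all <- function(net, source, tol = 1e-9) {
  nodes <- net$nodes$gene_id
  if (!source %in% nodes) abort(paste0("source '", source, "' not in network"))
  adj <- adjacency(net)
  dist <- setNames(rep(Inf, length(nodes)), nodes)
  dist[source] <- 0
  preds <- setNames(vector("list", length(nodes)), nodes)
  visited <- setNames(rep(FALSE, length(nodes)), nodes)
  repeat {
    cand <- dist
    cand[visited] <- Inf
    u <- names(which.min(cand))
    if (length(u) == 0 || is.infinite(cand[[u]])) break
    visited[u] <- TRUE
    nb <- adj[[u]]
    if (is.null(nb)) next
    for (i in seq_len(nrow(nb))) {
      v <- nb$b[i]
      nd <- dist[[u]] + nb$d[i]
      if (nd < dist[[v]] - tol) {
        dist[v] <- nd
        preds[[v]] <- u
      } else if (abs(nd - dist[[v]]) <= tol) {
        preds[[v]] <- union(preds[[v]], u)
      }
    }
  }
  list(dist = dist, preds = preds)
}

# enumerate all paths from source to target through the shortest-path
# predecessor DAG, capped at max_paths
enumerate_paths <- function(preds, source, target, max_paths = 100) {
  out <- list()
  truncated <- FALSE
  walk <- function(node, suffix) {
    if (truncated) return()
    if (node == source) {
      if (length(out) >= max_paths) {
        truncated <<- TRUE
        return()
      }
      out[[length(out) + 1]] <<- c(source, suffix)
      return()
    }
    for (p in preds[[node]]) walk(p, c(node, suffix))
  }
  walk(target, character())
  list(paths = out, truncated = truncated)
}

#' All minimum-distance paths between two genes
#'
#' Dijkstra under the node-weight-derived edge distances; the shortest-path
#' predecessor DAG is retained and all tied paths (distance equal within
#' `tol`) are enumerated by backward traversal, capped at `max_paths`.
#'
#' @param net A `weighted_network`.
#' @param source,target Gene ids in the network.
#' @param max_paths Cap on the number of enumerated tied paths.
#' @param tol Distance tolerance when deciding ties.
#' @return List with `distance`, `paths` (list of node vectors),
#'   `truncated`, `status` (`"ok"` or `"unreachable"`).
#' @export
min_distance_paths <- function(net, source, target, max_paths = 100,
                               tol = 1e-9) {
  if (!target %in% net$nodes$gene_id) {
    abort(paste0("target '", target, "' not in network"))
  }
  dj <- dijkstra_all(net, source, tol)
  if (is.infinite(dj$dist[[target]])) {
    return(list(distance = Inf, paths = list(), truncated = FALSE,
                status = "unreachable"))
  }
  en <- enumerate_paths(dj$preds, source, target, max_paths)
  list(distance = unname(dj$dist[[target]]), paths = en$paths,
       truncated = en$truncated, status = "ok")
}

#' Minimum-distance representatives of a term's genes
#'
#' Computes the minimum distance from the source to every term gene present
#' in the network and keeps the genes attaining the global minimum (within
#' `tol`), with their tied paths.
#'
#' @param net A `weighted_network`.
#' @param source Source gene id.
#' @param term_gene_set Character vector of the term's gene ids.
#' @param max_paths,tol As in [min_distance_paths()].
#' @return List with `representatives`, `distance`, `paths` (named list per
#'   representative), `status`.
#' @export
term_representatives <- function(net, source, term_gene_set, max_paths = 100,
                                 tol = 1e-9) {
  present <- intersect(term_gene_set, net$nodes$gene_id)
  if (length(present) == 0) {
    abort("no term gene present in the network")
  }
  dj <- dijkstra_all(net, source, tol)
  d <- dj$dist[present]
  if (all(is.infinite(d))) {
    return(list(representatives = character(), distance = Inf,
                paths = list(), status = "unreachable"))
  }
  dmin <- min(d)
  reps <- names(d)[d <= dmin + tol]
  paths <- map(setNames(reps, reps), function(g) {
    enumerate_paths(dj$preds, source, g, max_paths)$paths
  })
  list(representatives = reps, distance = unname(dmin), paths = paths,
       status = "ok")
}

#' Fall back to an alternate source when the primary is absent
#'
#' Returns the first of `source`, then each fallback in order, that is
#' present in the network (the mouse case where the ligand itself is not in
#' the interactome and its receptor is used instead), with a message naming
#' the substitution.
#'
#' @param net A `weighted_network`.
#' @param source Preferred source gene id.
#' @param fallbacks Character vector of fallback gene ids.
#' @return The chosen gene id.
#' @export
resolve_source <- function(net, source, fallbacks = character()) {
  for (g in c(source, fallbacks)) {
    if (g %in% net$nodes$gene_id) {
      if (g != source) {
        inform(paste0("source '", source, "' absent from the network; using '",
                      g, "' instead"))
      }
      return(g)
    }
  }
  abort("neither the source nor any fallback is in the network")
}

#' Export the union of paths as GraphML and SIF
#'
#' Writes the subnetwork spanned by a set of paths with node weights (and
#' optional term memberships) as attributes, in deterministic node and edge
#' order so identical inputs produce byte-identical files.
#'
#' @param paths List of node vectors (paths).
#' @param net The `weighted_network` the paths came from.
#' @param graphml_path,sif_path Output paths (either may be `NULL`).
#' @param annotations Optional tibble `gene_id`, `term_id`: term memberships
#'   written as a node attribute.
#' @return Tibble of the subnetwork's edges, invisibly.
#' @export
export_subnetwork <- function(paths, net, graphml_path = NULL,
                              sif_path = NULL, annotations = NULL) {
  if (length(paths) == 0) abort("no paths to export")
  nodes <- sort(unique(unlist(paths)))
  edge_rows <- bind_rows(map(paths, function(p) {
    if (length(p) < 2) return(NULL)
    tibble(from = pmin(head(p, -1), p[-1]), to = pmax(head(p, -1), p[-1]))
  }))
  edges <- distinct(arrange(edge_rows, .data$from, .data$to))
  w <- setNames(net$nodes$weight, net$nodes$gene_id)
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = tibble(name = nodes))
    igraph::V(g)$weight <- unname(w[nodes])
    if (!is.null(annotations)) {
      terms <- map_chr(nodes, function(n) {
        paste(sort(annotations$term_id[annotations$gene_id == n]),
              collapse = ";")
      })
      igraph::V(g)$terms <- terms
    }
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  if (!is.null(sif_path)) {
    writeLines(paste(edges$from, "pp", edges$to, sep = "\t"), sif_path)
  }
  invisible(edges)
}
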