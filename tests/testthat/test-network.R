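post_tbl <- function(...) {
  v <- c(...)
  tibble::tibble(gene_id = names(v), posterior_prob = unname(v))
}

test_that("node weights average posteriors and set edge distances", {
  el <- tibble::tibble(from = c("a", "b"), to = c("b", "c"))
  net <- weight_nodes(el, list(
    ct1 = post_tbl(a = 0.9, b = 1.0, c = 0.6),
    ct2 = post_tbl(a = 0.7, b = 1.0)
  ))
  w <- setNames(net$nodes$weight, net$nodes$gene_id)
  expect_equal(w[["a"]], 0.8)        # mean over measured cell types only
  expect_equal(w[["c"]], 0.6)
  d <- setNames(net$edges$distance, paste(net$edges$from, net$edges$to))
  expect_equal(d[["a b"]], 2 - (0.8 + 1.0))
  net2 <- weight_nodes(tibble::tibble(from = "u", to = "v"),
                       list(ct = post_tbl(u = 1, v = 1)))
  expect_equal(net2$edges$distance, 0)
  net3 <- weight_nodes(tibble::tibble(from = "u", to = "v"),
                       list(ct = post_tbl(u = 0.6, v = 0.9)))
  expect_equal(net3$edges$distance, 0.5)
  expect_error(weight_nodes(el, list(ct = post_tbl(a = 1.2))), "outside")
  # unmeasured genes get weight 0 and are counted
  net4 <- weight_nodes(el, list(ct = post_tbl(a = 0.5)))
  expect_equal(net4$n_unmeasured, 2)
})

test_that("simple paths and ties are enumerated", {
  el <- tibble::tibble(from = c("s", "a"), to = c("a", "t"))
  net <- weight_nodes(el, list(ct = post_tbl(s = 0, a = 0, t = 0)))
  r <- min_distance_paths(net, "s", "t")
  expect_equal(r$distance, 4)
  expect_equal(r$paths, list(c("s", "a", "t")))

  el2 <- tibble::tibble(from = c("s", "a", "s", "b"),
                        to = c("a", "t", "b", "t"))
  net2 <- weight_nodes(el2, list(ct = post_tbl(s = 0.5, a = 0.2, b = 0.2,
                                               t = 0.5)))
  r2 <- min_distance_paths(net2, "s", "t")
  expect_equal(length(r2$paths), 2)
  expect_setequal(vapply(r2$paths, paste, "", collapse = ">"),
                  c("s>a>t", "s>b>t"))

  lone <- weight_nodes(tibble::tibble(from = c("s", "x"), to = c("a", "t")),
                       list(ct = post_tbl(s = 0)))
  ru <- min_distance_paths(lone, "s", "t")
  expect_equal(ru$status, "unreachable")
  expect_length(ru$paths, 0)
  expect_error(min_distance_paths(net, "zz", "t"), "not in network")
})

test_that("minimum distances equal exhaustive enumeration on random graphs", {
  set.seed(61)
  n_checked <- 0
  for (i in 1:50) {
    n <- sample(4:8, 1)
    nodes <- paste0("v", seq_len(n))
    cmb <- t(combn(nodes, 2))
    keep <- runif(nrow(cmb)) < 0.45
    if (sum(keep) < 2) next
    el <- tibble::tibble(from = cmb[keep, 1], to = cmb[keep, 2])
    w <- setNames(runif(n), nodes)
    net <- weight_nodes(el, list(ct = post_tbl(w)))
    present <- unique(c(el$from, el$to))
    if (length(present) < 2) next
    st <- sample(present, 2)
    r <- min_distance_paths(net, st[1], st[2])
    o <- oracle_min_distance(net$edges, net$edges$distance, st[1], st[2])
    expect_equal(r$distance, o, tolerance = 1e-9)
    if (is.finite(o)) {
      # every returned path realises the minimum distance
      for (p in r$paths) {
        dsum <- sum(vapply(seq_len(length(p) - 1), function(j) {
          e <- net$edges
          hit <- (e$from == p[j] & e$to == p[j + 1]) |
            (e$to == p[j] & e$from == p[j + 1])
          e$distance[hit][1]
        }, 0))
        expect_equal(dsum, o, tolerance = 1e-9)
      }
    }
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 30)
})

test_that("raising a node weight never increases any minimum distance", {
  set.seed(62)
  nodes <- paste0("v", 1:7)
  cmb <- t(combn(nodes, 2))
  keep <- runif(nrow(cmb)) < 0.5
  el <- tibble::tibble(from = cmb[keep, 1], to = cmb[keep, 2])
  w <- setNames(runif(7, 0, 0.5), nodes)
  net1 <- weight_nodes(el, list(ct = post_tbl(w)))
  w2 <- w; w2[["v3"]] <- w[["v3"]] + 0.4
  net2 <- weight_nodes(el, list(ct = post_tbl(w2)))
  for (tgt in setdiff(nodes, "v1")) {
    d1 <- min_distance_paths(net1, "v1", tgt)$distance
    d2 <- min_distance_paths(net2, "v1", tgt)$distance
    expect_lte(d2, d1 + 1e-9)
  }
})

test_that("equal weights reduce to fewest-hop paths (BFS oracle)", {
  set.seed(63)
  nodes <- paste0("v", 1:8)
  cmb <- t(combn(nodes, 2))
  keep <- runif(nrow(cmb)) < 0.35
  el <- tibble::tibble(from = cmb[keep, 1], to = cmb[keep, 2])
  cw <- 0.3
  net <- weight_nodes(el, list(ct = post_tbl(setNames(rep(cw, 8), nodes))))
  g <- igraph::graph_from_data_frame(el, directed = FALSE)
  for (tgt in intersect(setdiff(nodes, "v1"), igraph::V(g)$name)) {
    r <- min_distance_paths(net, "v1", tgt)
    hops <- igraph::distances(g, "v1", tgt)[1, 1]
    if (is.infinite(hops)) {
      expect_equal(r$status, "unreachable")
    } else {
      expect_equal(r$distance, (2 - 2 * cw) * hops, tolerance = 1e-9)
    }
  }
})

test_that("term representatives keep exactly the closest term genes", {
  # s - a - t1 (short), s - b - c - t2 (long), t3 isolated
  el <- tibble::tibble(from = c("s", "a", "s", "b", "c"),
                       to = c("a", "t1", "b", "c", "t2"))
  net <- weight_nodes(el, list(ct = post_tbl(
    s = 0.5, a = 0.5, b = 0.5, c = 0.5, t1 = 0.5, t2 = 0.5
  )))
  r <- term_representatives(net, "s", c("t1", "t2"))
  expect_equal(r$representatives, "t1")
  expect_equal(r$paths$t1, list(c("s", "a", "t1")))
  # ties keep all genes at the minimum
  el2 <- tibble::tibble(from = c("s", "s"), to = c("t1", "t2"))
  net2 <- weight_nodes(el2, list(ct = post_tbl(s = 0, t1 = 0, t2 = 0)))
  r2 <- term_representatives(net2, "s", c("t1", "t2"))
  expect_setequal(r2$representatives, c("t1", "t2"))
  expect_error(term_representatives(net, "s", "zzz"), "no term gene")
})

test_that("the alternate-source rule is honoured", {
  el <- tibble::tibble(from = "a", to = "b")
  net <- weight_nodes(el, list(ct = post_tbl(a = 0.5, b = 0.5)))
  expect_equal(resolve_source(net, "a"), "a")
  expect_message(s <- resolve_source(net, "TGFB1", c("b")), "using 'b'")
  expect_equal(s, "b")
  expect_error(resolve_source(net, "x", "y"), "neither")
})

test_that("subnetwork export is deterministic and unions shared edges", {
  paths <- list(c("s", "a", "t"), c("s", "a", "u"))
  el <- tibble::tibble(from = c("s", "a", "a"), to = c("a", "t", "u"))
  net <- weight_nodes(el, list(ct = post_tbl(s = 0.9, a = 0.5, t = 0.2,
                                             u = 0.1)))
  g1 <- withr::local_tempfile(fileext = ".graphml")
  s1 <- withr::local_tempfile(fileext = ".sif")
  edges <- export_subnetwork(paths, net, graphml_path = g1, sif_path = s1)
  expect_equal(nrow(edges), 3) # s-a written once
  g2 <- withr::local_tempfile(fileext = ".graphml")
  export_subnetwork(paths, net, graphml_path = g2)
  expect_identical(readLines(g1), readLines(g2))
  sif <- readLines(s1)
  expect_length(sif, 3)
  expect_error(export_subnetwork(list(), net), "no paths")
})
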