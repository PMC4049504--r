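# Synthetic multi-cell-type stimulation studies with known ground truth.
# The generator emulates the structure of a two-species TGF-beta study:
# several cell types with short (0-24 h) time grids, 3 replicates, a shared
# DE core linked across species by homologs, cell-type-specific DE genes,
# early/late/transient/monotone response curves and Gaussian noise.

#' Response-curve templates
#'
#' Fixed fold-change templates on \[0, 24\] hours, each normalised so that the
#' value at 0 h is 0 and the maximum absolute value on the interval is 1:
#' `early` rises to its peak by 2 h then decays, `late` is a sigmoid centred
#' at 8 h, `transient` peaks at 4 h and returns to baseline, `monotone` grows
#' linearly in log-time.
#'
#' @param shape One of `"early"`, `"late"`, `"transient"`, `"monotone"`.
#' @param time_h Numeric vector of times in hours.
#' @return Numeric vector of template values at `time_h`.
#' @export
curve_template <- function(shape, time_h) {
  f <- switch(shape,
    early = function(t) (t / 2) * exp(1 - t / 2),
    late = function(t) {
      s <- function(u) 1 / (1 + exp(-(u - 8) / 2))
      (s(t) - s(0)) / (s(24) - s(0))
    },
    transient = function(t) (t / 4) * exp(1 - t / 4),
    monotone = function(t) log1p(t) / log1p(24),
    abort(paste0("unknown curve shape '", shape, "'"))
  )
  f(time_h)
}

#' Configuration for a synthetic study
#'
#' Defaults mirror the layout of the emulated study: two species, four cell
#' types, five-point time grids in 0-24 h, three replicates, a shared DE core
#' plus cell-type-specific DE genes, amplitude 2 on the log2 scale and
#' replicate noise of 0.5 log2 units.
#'
#' @param n_genes Genes per species namespace.
#' @param cell_types Tibble with columns `name`, `species` and a list-column
#'   `time_h` of time grids (hours, starting at 0).
#' @param n_replicates Replicates per time point.
#' @param frac_de_shared Fraction of genes DE in every cell type (linked by
#'   homologs across species).
#' @param frac_de_specific Fraction of genes DE in exactly one cell type.
#' @param effect_curves Curve shapes sampled for DE genes.
#' @param effect_amplitude Peak absolute log2 fold change of DE genes.
#' @param frac_up Fraction of DE genes regulated upward (the rest down).
#' @param noise_sd Replicate noise SD, log2 units.
#' @param batch_sd SD of the additive per-batch shift, log2 units (0 = no
#'   batch structure).
#' @param frac_1to2 Fraction of homolog relations that are 1:2 rather than 1:1.
#' @param bad_chip Optional list `(cell_type, time_h, replicate)` naming one
#'   sample to drop, emulating an excluded low-quality chip.
#' @param seed Integer seed; all randomness derives from it.
#' @return A `synthetic_study_config` list.
#' @export
synthetic_study_config <- function(
    n_genes = 2000,
    cell_types = default_cell_types(),
    n_replicates = 3,
    frac_de_shared = 0.05,
    frac_de_specific = 0.05,
    effect_curves = c("early", "late", "transient", "monotone"),
    effect_amplitude = 2,
    frac_up = 0.5,
    noise_sd = 0.5,
    batch_sd = 0,
    frac_1to2 = 0.05,
    bad_chip = NULL,
    seed = 1) {
  cell_types <- as_tibble(cell_types)
  stopifnot(all(c("name", "species", "time_h") %in% names(cell_types)))
  if (frac_de_shared < 0 || frac_de_specific < 0 ||
      frac_de_shared + frac_de_specific > 1) {
    abort("DE fractions must be in [0,1] and sum to at most 1")
  }
  if (effect_amplitude <= 0) abort("effect_amplitude must be positive")
  for (g in cell_types$time_h) {
    if (length(g) < 2) abort("a time grid with a single point is not a time course")
    if (g[1] != 0) abort("every time grid must start at 0")
  }
  if (!all(effect_curves %in% c("early", "late", "transient", "monotone"))) {
    abort("unknown curve shape in effect_curves")
  }
  structure(as.list(environment()), class = "synthetic_study_config")
}

#' Default cell-type layout for synthetic studies
#' @return Tibble of four cell types in two species with 0-24 h grids.
#' @export
default_cell_types <- function() {
  tibble(
    name = c("MPP", "CDP", "HPC", "MSC"),
    species = c("mouse", "mouse", "human", "human"),
    time_h = list(c(0, 1, 4, 8, 24), c(0, 1, 4, 8, 24),
                  c(0, 1, 4, 8, 24), c(0, 2, 4, 12, 24))
  )
}

gene_names <- function(species, n) {
  sprintf("%s_g%05d", species, seq_len(n))
}

#' Generate a synthetic multi-cell-type expression study
#'
#' Non-DE genes have expected log2 fold change 0 at every time point; DE genes
#' follow their assigned curve template scaled to the configured amplitude,
#' with i.i.d. Gaussian replicate noise and an optional additive per-batch
#' shift. The shared DE core occupies the same gene indices in both species
#' namespaces and is linked by always-passing homolog pairs.
#'
#' @param config A [synthetic_study_config()].
#' @return A list with `expression` (named list of [expr_timecourse], one per
#'   cell type) and `truth` (list: `de_genes` per cell type, `curves` tibble,
#'   `cluster_labels` tibble, `shared_core` per species, `homologs` tibble).
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "synthetic_study_config"))
  cfg <- config
  species_list <- unique(cfg$cell_types$species)
  seeds <- child_seeds(cfg$seed, nrow(cfg$cell_types) + 2L)

  n_shared <- round(cfg$frac_de_shared * cfg$n_genes)
  n_specific <- round(cfg$frac_de_specific * cfg$n_genes)
  shared_idx <- seq_len(n_shared)

  # per-cell-type specific DE indices, disjoint from the shared core and from
  # each other within a species
  specific_idx <- list()
  with_seed(seeds[1], {
    for (sp in species_list) {
      cts <- cfg$cell_types$name[cfg$cell_types$species == sp]
      pool <- setdiff(seq_len(cfg$n_genes), shared_idx)
      for (ct in cts) {
        pick <- sort(sample(pool, min(n_specific, length(pool))))
        specific_idx[[ct]] <- pick
        pool <- setdiff(pool, pick)
      }
    }
  })

  curves_rows <- list()
  labels_rows <- list()
  expression <- list()
  truth_de <- list()

  for (i in seq_len(nrow(cfg$cell_types))) {
    ct <- cfg$cell_types$name[[i]]
    sp <- cfg$cell_types$species[[i]]
    grid <- cfg$cell_types$time_h[[i]]
    genes <- gene_names(sp, cfg$n_genes)
    de_idx <- sort(union(shared_idx, specific_idx[[ct]]))

    with_seed(seeds[1 + i], {
      shape <- sample(cfg$effect_curves, length(de_idx), replace = TRUE)
      sign <- ifelse(runif(length(de_idx)) < cfg$frac_up, 1, -1)
      baseline <- rnorm(cfg$n_genes, mean = 7, sd = 1.5)

      meta <- tidyr::expand_grid(time_h = grid, replicate = seq_len(cfg$n_replicates))
      meta <- mutate(meta,
        sample_id = sprintf("%s_t%g_r%d", ct, .data$time_h, .data$replicate),
        cell_type = ct,
        batch = if (cfg$batch_sd > 0) {
          ifelse(.data$replicate == 1, "B1", "B2")
        } else NA_character_
      )
      if (!is.null(cfg$bad_chip) && identical(cfg$bad_chip$cell_type, ct)) {
        drop <- meta$time_h == cfg$bad_chip$time_h &
          meta$replicate == cfg$bad_chip$replicate
        meta <- meta[!drop, , drop = FALSE]
      }

      mu <- matrix(0, cfg$n_genes, nrow(meta))
      tmpl <- vapply(unique(shape), function(s) curve_template(s, meta$time_h),
                     numeric(nrow(meta)))
      for (j in seq_along(de_idx)) {
        mu[de_idx[j], ] <- sign[j] * cfg$effect_amplitude * tmpl[, shape[j]]
      }
      expr <- baseline + mu +
        matrix(rnorm(cfg$n_genes * nrow(meta), sd = cfg$noise_sd),
               cfg$n_genes, nrow(meta))
      if (cfg$batch_sd > 0) {
        shift <- setNames(rnorm(length(unique(meta$batch)), sd = cfg$batch_sd),
                          unique(meta$batch))
        expr <- expr + matrix(shift[meta$batch], cfg$n_genes, nrow(meta),
                              byrow = TRUE)
      }
      rownames(expr) <- genes
      colnames(expr) <- meta$sample_id

      expression[[ct]] <- expr_timecourse(
        expr, meta[, c("sample_id", "cell_type", "time_h", "replicate", "batch")],
        species = sp
      )
      truth_de[[ct]] <- genes[de_idx]
      curves_rows[[ct]] <- tibble(
        cell_type = ct, gene_id = genes[de_idx], curve = shape, sign = sign
      )
      labels_rows[[ct]] <- tibble(
        cell_type = ct, gene_id = genes[de_idx],
        label = paste0(shape, ifelse(sign > 0, "_up", "_down"))
      )
    })
  }

  homologs <- with_seed(seeds[length(seeds)],
                        make_homologs(cfg, species_list, shared_idx))
  shared_core <- map(setNames(species_list, species_list),
                     function(sp) gene_names(sp, cfg$n_genes)[shared_idx])

  list(
    expression = expression,
    truth = list(
      de_genes = truth_de,
      curves = bind_rows(curves_rows),
      cluster_labels = bind_rows(labels_rows),
      shared_core = shared_core,
      homologs = homologs
    )
  )
}

# Mostly 1:1 homolog map between the two species namespaces with a fraction
# of 1:2 relations; E-values straddle the 1e-30 threshold but shared-core
# pairs always pass it.
make_homologs <- function(cfg, species_list, shared_idx) {
  if (length(species_list) < 2) {
    return(tibble(gene_a = character(), gene_b = character(),
                  evalue = numeric(), bitscore = numeric(),
                  species_a = character(), species_b = character()))
  }
  sp_a <- species_list[[1]]; sp_b <- species_list[[2]]
  ga <- gene_names(sp_a, cfg$n_genes)
  gb <- gene_names(sp_b, cfg$n_genes)
  idx <- seq_len(cfg$n_genes)
  pass <- runif(cfg$n_genes) < 0.9
  pass[shared_idx] <- TRUE
  evalue <- ifelse(pass, 10^runif(cfg$n_genes, -200, -31),
                   10^runif(cfg$n_genes, -29, -5))
  pairs <- tibble(gene_a = ga[idx], gene_b = gb[idx], evalue = evalue)
  n_extra <- round(cfg$frac_1to2 * cfg$n_genes)
  if (n_extra > 0) {
    donor <- sample(setdiff(idx, shared_idx), n_extra)
    partner <- sample(setdiff(idx, shared_idx), n_extra)
    pairs <- bind_rows(pairs, tibble(
      gene_a = ga[donor], gene_b = gb[partner],
      evalue = 10^runif(n_extra, -60, -31)
    ))
  }
  pairs$bitscore <- round(-log10(pmax(pairs$evalue, 1e-300)) * 3.7 + 30, 1)
  pairs$species_a <- sp_a
  pairs$species_b <- sp_b
  pairs
}

#' Generate a GO-style annotation bundle with planted enriched terms
#'
#' Builds a random but valid ontology DAG, annotates genes of every species
#' namespace, and plants enrichment: each planted term annotates 90% of every
#' cell type's DE genes and 5% of non-DE genes, so enrichment is real by
#' construction. A flat pathway collection (GMT-style tibble) built from the
#' same memberships is emitted alongside.
#'
#' @param truth Ground-truth list from [generate_expression()].
#' @param n_terms Total number of ontology terms (must allow the planted ones).
#' @param dag_depth Depth of the random DAG (1 gives a star around one root).
#' @param n_planted Number of planted enriched terms.
#' @param frac_de_annotated Fraction of DE genes annotated to each planted term.
#' @param frac_bg_annotated Fraction of non-DE genes annotated to each planted
#'   term.
#' @param seed Integer seed.
#' @return List with `dag` ([ontology_dag]), `gene2term` tibble, `sets`
#'   (GMT-style tibble), `planted_terms` character vector.
#' @export
generate_annotations <- function(truth, n_terms = 50, dag_depth = 3,
                                 n_planted = 2, frac_de_annotated = 0.9,
                                 frac_bg_annotated = 0.05, seed = 1) {
  if (n_terms < n_planted + 1) abort("n_terms must exceed the planted terms")
  with_seed(seed, {
    term_ids <- sprintf("T%04d", seq_len(n_terms))
    planted <- sprintf("P%04d", seq_len(n_planted))
    all_terms <- c(term_ids, planted)

    # random DAG by levels: each non-root term attaches to 1-2 terms of the
    # previous level; planted terms are leaves
    lev <- c(0L, sample(seq_len(max(dag_depth, 1L)), n_terms - 1L, replace = TRUE))
    edges <- list()
    for (i in seq_along(term_ids)[-1]) {
      parents_pool <- term_ids[lev < lev[i]]
      np <- sample(1:2, 1)
      ps <- sample(parents_pool, min(np, length(parents_pool)))
      edges[[length(edges) + 1]] <- tibble(
        child = term_ids[i], parent = ps,
        relation = sample(c("is_a", "part_of"), length(ps),
                          replace = TRUE, prob = c(0.8, 0.2))
      )
    }
    deepest <- term_ids[lev == max(lev)]
    edges[[length(edges) + 1]] <- tibble(
      child = planted,
      parent = sample(deepest, n_planted, replace = TRUE),
      relation = "is_a"
    )
    dag <- ontology_dag(bind_rows(edges), terms = all_terms)

    g2t <- list()
    for (p in planted) {
      carriers <- unlist(map(truth$de_genes, function(g) {
        g[runif(length(g)) < frac_de_annotated]
      }))
      g2t[[length(g2t) + 1]] <- tibble(gene_id = unique(carriers), term_id = p)
    }
    g2t_planted <- bind_rows(g2t)
    list(dag = dag, planted = planted, term_ids = term_ids,
         g2t_planted = g2t_planted)
  }) -> parts

  # background annotations need the full universe, reconstructed from the
  # homolog table namespaces plus all DE genes
  universe <- unique(c(parts$g2t_planted$gene_id,
                       truth$homologs$gene_a, truth$homologs$gene_b,
                       unlist(truth$de_genes)))
  with_seed(seed + 1L, {
    all_de <- unique(unlist(truth$de_genes))
    non_de <- setdiff(universe, all_de)
    extra_planted <- bind_rows(map(parts$planted, function(p) {
      tibble(gene_id = non_de[runif(length(non_de)) < frac_bg_annotated],
             term_id = p)
    }))
    n_rand <- 2L
    random_ann <- tibble(
      gene_id = rep(universe, n_rand),
      term_id = sample(parts$term_ids, length(universe) * n_rand, replace = TRUE)
    )
    gene2term <- distinct(bind_rows(parts$g2t_planted, extra_planted, random_ann))
    sets <- gene2term %>%
      group_by(.data$term_id) %>%
      summarise(genes = list(unique(.data$gene_id)), .groups = "drop") %>%
      rename(set_id = "term_id") %>%
      mutate(description = .data$set_id) %>%
      select("set_id", "description", "genes")
    list(dag = parts$dag, gene2term = gene2term, sets = sets,
         planted_terms = parts$planted)
  })
}

#' Generate promoter sequences with a planted motif
#'
#' Each carrier promoter contains at least one exact instance of the planted
#' consensus (IUPAC codes resolved per instance) at a uniform random position;
#' background sequences are i.i.d. with the stated GC content.
#'
#' @param carrier_genes Character vector of gene ids to receive the motif.
#' @param pwm_consensus IUPAC consensus string to plant.
#' @param n_background Number of motif-free background promoters.
#' @param length Promoter length in bp (must be at least the motif length).
#' @param gc GC proportion of the background composition.
#' @param seed Integer seed.
#' @return List with `seqs` (named character vector) and `truth` tibble
#'   (`gene`, `is_carrier`, `position`, `instance`).
#' @export
generate_promoters <- function(carrier_genes, pwm_consensus, n_background = 0,
                               length = 2000, gc = 0.5, seed = 1) {
  letters_ok <- strsplit(pwm_consensus, NULL)[[1]]
  if (!all(letters_ok %in% names(IUPAC_MAP))) {
    abort("consensus contains invalid IUPAC code(s)")
  }
  k <- nchar(pwm_consensus)
  if (length < k) abort("promoter length must be at least the motif length")
  base_p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  with_seed(seed, {
    rand_seq <- function(n) {
      paste(sample(names(base_p), n, replace = TRUE, prob = base_p), collapse = "")
    }
    rows <- list()
    seqs <- character()
    for (g in carrier_genes) {
      s <- rand_seq(length)
      inst <- paste(vapply(letters_ok, function(cc) {
        sample(IUPAC_MAP[[cc]], 1)
      }, ""), collapse = "")
      pos <- sample.int(length - k + 1L, 1)
      substr(s, pos, pos + k - 1L) <- inst
      seqs[[g]] <- s
      rows[[length(rows) + 1]] <- tibble(gene = g, is_carrier = TRUE,
                                         position = pos, instance = inst)
    }
    if (n_background > 0) {
      for (i in seq_len(n_background)) {
        g <- sprintf("bg_%04d", i)
        seqs[[g]] <- rand_seq(length)
        rows[[length(rows) + 1]] <- tibble(gene = g, is_carrier = FALSE,
                                           position = NA_integer_,
                                           instance = NA_character_)
      }
    }
    list(seqs = seqs, truth = bind_rows(rows))
  })
}

#' Generate an interaction network with a planted path
#'
#' Erdős–Rényi background plus the consecutive edges of a planted path whose
#' nodes the caller will typically assign high DE probabilities.
#'
#' @param n_nodes Number of background nodes (planted-path nodes are added on
#'   top if not among them).
#' @param edge_prob Erdős–Rényi edge probability.
#' @param planted_path Character vector of node ids forming the planted path.
#' @param seed Integer seed.
#' @param node_names Optional node ids for the background nodes (defaults to
#'   generated `n0001`-style ids); `n_nodes` are drawn from them.
#' @return List with `edges` tibble (`from`, `to`) and `truth` list
#'   (`planted_path`).
#' @export
generate_network <- function(n_nodes, edge_prob, planted_path = character(),
                             seed = 1, node_names = NULL) {
  with_seed(seed, {
    bg <- node_names %||% sprintf("n%04d", seq_len(n_nodes))
    if (length(bg) > n_nodes) bg <- sample(bg, n_nodes)
    nodes <- unique(c(planted_path, bg))
    el <- tibble(from = character(), to = character())
    if (length(nodes) >= 2 && edge_prob > 0) {
      cmb <- utils::combn(sort(nodes), 2)
      keep <- runif(ncol(cmb)) < edge_prob
      el <- tibble(from = cmb[1, keep], to = cmb[2, keep])
    }
    if (length(planted_path) >= 2) {
      pp <- tibble(from = pmin(head(planted_path, -1), planted_path[-1]),
                   to = pmax(head(planted_path, -1), planted_path[-1]))
      el <- distinct(bind_rows(el, pp))
    }
    list(edges = el, truth = list(planted_path = planted_path))
  })
}
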