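# End-to-end orchestration: a bundled synthetic demo study and a driver that
# runs DE -> clustering -> semantic similarity -> enrichment -> motifs ->
# cross-species -> network -> reproducibility from one config.

#' Write a complete synthetic demo study to disk
#'
#' Generates a two-species, four-cell-type study plus an independent
#' validation cell type, with planted DE core, enriched terms, promoter motif
#' and network path, and writes every input format the pipeline reads:
#' expression and metadata TSVs, a gene-set GMT, an ontology edge TSV, a
#' gene-to-term TSV, promoter FASTAs, a PWM library, a TFBS-to-gene map, a
#' homolog table, species interaction networks, the ground truth (JSON), and
#' a YAML config consumed by [run_study()].
#'
#' @param dir Output directory (created if missing).
#' @param seed Integer seed; the whole demo is reproducible from it.
#' @param n_genes Genes per species namespace.
#' @param promoter_length Length of the generated promoter sequences (bp).
#' @return The config file path, invisibly.
#' @export
make_demo <- function(dir, seed = 1, n_genes = 600, promoter_length = 200) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- child_seeds(seed, 10)
  cts <- bind_rows(
    default_cell_types(),
    tibble(name = "A549", species = "human", time_h = list(c(0, 1, 4, 8, 24)))
  )
  config <- synthetic_study_config(
    n_genes = n_genes, cell_types = cts, seed = seeds[1]
  )
  gen <- generate_expression(config)
  truth <- gen$truth

  paths <- list()
  for (ct in names(gen$expression)) {
    ep <- file.path(dir, paste0("expr_", ct, ".tsv"))
    mp <- file.path(dir, paste0("meta_", ct, ".tsv"))
    write_expression_matrix(gen$expression[[ct]], ep, mp)
    paths$cell_types[[ct]] <- list(
      expression = ep, metadata = mp,
      species = gen$expression[[ct]]$species
    )
  }

  ann <- generate_annotations(truth, n_terms = 40, dag_depth = 3,
                              n_planted = 2, seed = seeds[2])
  write_ontology(ann$dag, file.path(dir, "ontology.tsv"))
  readr::write_tsv(ann$gene2term, file.path(dir, "gene2term.tsv"))
  write_gmt(ann$sets, file.path(dir, "sets.gmt"))
  write_homolog_table(truth$homologs, file.path(dir, "homologs.tsv"))

  # promoters per cell type: planted motif in the shared core, background
  # sequences for the remaining DE genes
  consensus <- "TGACTCA"
  for (i in seq_along(truth$de_genes)) {
    ct <- names(truth$de_genes)[i]
    sp <- gen$expression[[ct]]$species
    core <- truth$shared_core[[sp]]
    de <- truth$de_genes[[ct]]
    carriers <- intersect(de, core)
    others <- setdiff(de, core)
    pr <- generate_promoters(carriers, consensus, n_background = 0,
                             length = promoter_length, gc = 0.5,
                             seed = seeds[3] + i)
    bg <- generate_promoters(character(), consensus,
                             n_background = length(others),
                             length = promoter_length, gc = 0.5,
                             seed = seeds[4] + i)
    names(bg$seqs) <- others
    fa <- file.path(dir, paste0("promoters_", ct, ".fa"))
    write_promoters(c(pr$seqs, bg$seqs), fa)
    paths$cell_types[[ct]]$promoters <- fa
  }

  # reference PWM library: the planted consensus as a strong PWM plus random
  # decoys
  lib <- with_seed(seeds[5], {
    planted_counts <- t(vapply(strsplit(consensus, NULL)[[1]], function(b) {
      v <- rep(1, 4); v[match(b, BASES)] <- 20; v
    }, numeric(4)))
    decoys <- map(1:19, function(i) {
      L <- sample(6:10, 1)
      pwm(matrix(rgamma(L * 4, 0.5), L, 4), name = sprintf("DECOY_%02d", i),
          source = "reference")
    })
    c(list(pwm(planted_counts, name = "AP1", source = "reference")), decoys)
  })
  write_pwm_library(lib, file.path(dir, "pwm_library.txt"))
  tf_map <- tibble(
    tfbs = "AP1",
    gene_id = c(truth$shared_core$human[1], truth$shared_core$mouse[1])
  )
  readr::write_tsv(tf_map, file.path(dir, "tf_map.tsv"))

  # per-species interactomes with a planted path from a source gene through
  # shared-core (high-posterior) genes to a planted-term gene
  sources <- list()
  for (sp in unique(cts$species)) {
    core <- truth$shared_core[[sp]]
    path_nodes <- core[seq_len(min(5, length(core)))]
    all_sp_genes <- gene_names(sp, n_genes)
    net <- generate_network(150, edge_prob = 0.03,
                            planted_path = path_nodes, seed = seeds[6],
                            node_names = all_sp_genes)
    np <- file.path(dir, paste0("network_", sp, ".tsv"))
    write_network(net$edges, np)
    paths$networks[[sp]] <- np
    sources[[sp]] <- list(source = path_nodes[1],
                          fallback = path_nodes[2],
                          planted_path = path_nodes)
  }

  truth_out <- list(
    de_genes = truth$de_genes,
    shared_core = truth$shared_core,
    planted_terms = ann$planted_terms,
    motif_consensus = consensus,
    planted_paths = map(sources, "planted_path"),
    cluster_labels = truth$cluster_labels
  )
  jsonlite::write_json(truth_out, file.path(dir, "truth.json"),
                       auto_unbox = TRUE)

  cfg <- list(
    seed = seed,
    cell_types = paths$cell_types,
    validation_cell_type = "A549",
    annotations = list(
      ontology = file.path(dir, "ontology.tsv"),
      gene2term = file.path(dir, "gene2term.tsv"),
      sets = file.path(dir, "sets.gmt")
    ),
    homologs = file.path(dir, "homologs.tsv"),
    pwm_library = file.path(dir, "pwm_library.txt"),
    tf_map = file.path(dir, "tf_map.tsv"),
    networks = paths$networks,
    sources = map(sources, function(s) s[c("source", "fallback")]),
    truth = file.path(dir, "truth.json"),
    thresholds = list(prob_cut = 0.99, lfc_cut = 1.0, fdr_gene = 0.01,
                      fdr_term = 0.05, semsim_cut = 0.7, motif_e = 1e-3,
                      homolog_e = 1e-30),
    k_range = c(2, 3, 4, 5, 6),
    out_dir = file.path(dir, "results")
  )
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  invisible(cfg_path)
}

read_config <- function(config) {
  if (is.character(config)) {
    cfg <- yaml::read_yaml(config)
  } else {
    cfg <- config
  }
  needed <- c("cell_types", "annotations", "thresholds", "out_dir")
  miss <- setdiff(needed, names(cfg))
  if (length(miss) > 0) {
    abort(paste0("config lacks field(s): ", paste(miss, collapse = ", ")))
  }
  paths <- c(
    map_chr(cfg$cell_types, "expression"),
    map_chr(cfg$cell_types, "metadata"),
    unlist(cfg$annotations), cfg$homologs, cfg$pwm_library, cfg$tf_map,
    unlist(cfg$networks)
  )
  missing <- paths[!is.na(paths) & !file.exists(paths)]
  if (length(missing) > 0) {
    abort(paste0("missing input file(s): ", paste(missing, collapse = ", ")))
  }
  cfg
}

#' Run the full cross-cell-type study
#'
#' Executes every stage in order — differential expression, clustering,
#' cluster semantic similarity, set enrichment, promoter motifs,
#' cross-species comparison, network path analysis and (when a validation
#' cell type is configured) reproducibility — writing per-stage TSV outputs
#' under the config's `out_dir` and recording a provenance table. Any stage
#' error halts the run with the stage named.
#'
#' @param config Config list or path to a YAML config (see [make_demo()]).
#' @return A `study_report`: list of per-stage results plus `provenance`
#'   (tibble stage/file) and, when ground truth is available, `recovery`.
#' @export
run_study <- function(config) {
  cfg <- read_config(config)
  out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  th <- cfg$thresholds
  prov <- list()
  note_file <- function(stage, file) {
    prov[[length(prov) + 1]] <<- tibble(stage = stage, file = file)
  }
  run_stage <- function(stage, code) {
    tryCatch(force(code), error = function(e) {
      abort(paste0("stage '", stage, "' failed: ", conditionMessage(e)))
    })
  }

  # --- differential expression -------------------------------------------
  de <- list(); de_sets <- list(); species <- character()
  run_stage("de", {
    for (ct in names(cfg$cell_types)) {
      info <- cfg$cell_types[[ct]]
      x <- read_expression_matrix(info$expression, info$metadata,
                                  species = info$species)
      if (length(unique(stats::na.omit(x$meta$batch))) > 1) {
        x <- adjust_batches(x)
      }
      de[[ct]] <- de_analysis(x)
      species[[ct]] <- info$species
      de_sets[[ct]] <- call_de(de[[ct]], prob_cut = th$prob_cut,
                               lfc_cut = th$lfc_cut,
                               fdr_cut = th$fdr_gene)$timecourse
      f <- file.path(out_dir, paste0("de_", ct, ".tsv"))
      write_de_result(de[[ct]], f, prob_cut = th$prob_cut,
                      lfc_cut = th$lfc_cut, fdr_cut = th$fdr_gene)
      note_file("de", f)
    }
  })
  validation_ct <- cfg$validation_cell_type %||% character()
  main_cts <- setdiff(names(de), validation_ct)

  # --- clustering ---------------------------------------------------------
  clusters <- list()
  run_stage("clustering", {
    for (ct in main_cts) {
      prof <- subset_profiles(de[[ct]]$profiles, de_sets[[ct]])
      clusters[[ct]] <- cluster_de_genes(
        prof, k_range = unlist(cfg$k_range %||% 2:6), seed = cfg$seed %||% 1
      )
      f <- file.path(out_dir, paste0("clusters_", ct, ".tsv"))
      readr::write_tsv(clusters[[ct]]$members, f)
      note_file("clustering", f)
    }
  })

  # --- annotations + cluster semantic similarity --------------------------
  dag <- NULL; g2t <- NULL; sets <- NULL
  semsim <- list()
  run_stage("semsim", {
    dag <- read_ontology(cfg$annotations$ontology)
    g2t <- readr::read_tsv(cfg$annotations$gene2term,
                            col_types = readr::cols(.default = "c"),
                            progress = FALSE)
    sets <- read_gmt(cfg$annotations$sets)
    pairs <- utils::combn(main_cts, 2, simplify = FALSE)
    for (pr in pairs) {
      if (species[[pr[1]]] != species[[pr[2]]]) next # same-namespace pairs
      tabf <- cluster_similarity_table(
        clusters[[pr[1]]]$members, clusters[[pr[2]]]$members, g2t, dag,
        threshold = th$semsim_cut
      )
      key <- paste(pr, collapse = "_vs_")
      semsim[[key]] <- tabf
      f <- file.path(out_dir, paste0("semsim_", key, ".tsv"))
      readr::write_tsv(tabf, f)
      note_file("semsim", f)
    }
  })

  # --- set enrichment + commonality ---------------------------------------
  enrich <- list(); common <- NULL
  run_stage("enrichment", {
    for (ct in names(de)) {
      scores <- compute_ranking_scores(de[[ct]], mode = "timecourse")
      enrich[[ct]] <- enrich_sets(scores, sets, fdr = th$fdr_term)
      f <- file.path(out_dir, paste0("enrichment_", ct, ".tsv"))
      readr::write_tsv(select(enrich[[ct]], -dplyr::any_of("note")), f)
      note_file("enrichment", f)
    }
    common <- common_terms(enrich[main_cts], fdr = th$fdr_term)
    f <- file.path(out_dir, "common_terms.tsv")
    readr::write_tsv(common$table, f)
    note_file("enrichment", f)
  })

  # --- promoter motifs ----------------------------------------------------
  motifs <- list(); motif_hits <- NULL
  run_stage("motifs", {
    lib <- if (!is.null(cfg$pwm_library)) read_pwm_library(cfg$pwm_library)
    hit_rows <- list()
    for (ct in main_cts) {
      fa <- cfg$cell_types[[ct]]$promoters
      if (is.null(fa)) next
      prom <- read_promoters(fa)
      prom <- prom[intersect(names(prom), de_sets[[ct]])]
      if (length(prom) < 10) {
        inform(paste0("too few DE promoters in ", ct, "; motif stage skipped"))
        next
      }
      found <- discover_motifs(prom, e_cut = th$motif_e)
      if (nrow(found) > 0 && !is.null(lib)) {
        matches <- bind_rows(map(found$motif, match_to_reference,
                                 library = lib, seed = cfg$seed %||% 1))
        found <- bind_cols(found, rename(matches, match_name = "name",
                                         match_score = "score",
                                         match_e = "e_value",
                                         match_strand = "strand"))
        hit_rows[[ct]] <- tibble(tfbs = found$match_name, cell_type = ct,
                                 e_value = found$e_value,
                                 carriers = found$carriers)
      }
      motifs[[ct]] <- found
      f <- file.path(out_dir, paste0("motifs_", ct, ".tsv"))
      readr::write_tsv(select(found, -"carriers", -"motif"), f)
      note_file("motifs", f)
    }
    if (length(hit_rows) > 0 && !is.null(cfg$tf_map)) {
      tf_map <- readr::read_tsv(cfg$tf_map,
                                col_types = readr::cols(.default = "c"),
                                progress = FALSE)
      motif_hits <- tfbs_gene_network(bind_rows(hit_rows), tf_map, de_sets)
      f <- file.path(out_dir, "tfbs_gene_network.tsv")
      readr::write_tsv(motif_hits, f)
      note_file("motifs", f)
    }
  })

  # --- cross-species comparison -------------------------------------------
  xsp <- NULL; overlaps <- NULL
  run_stage("cross_species", {
    hom <- filter_homologs(read_homolog_table(cfg$homologs),
                           e_cut = th$homolog_e)
    ref <- species[[main_cts[1]]]
    xsp <- multi_way_membership(de_sets[main_cts], hom,
                                 species[main_cts],
                                 reference_namespace = ref)
    f <- file.path(out_dir, "membership.tsv")
    readr::write_tsv(xsp$membership, f)
    note_file("cross_species", f)
    ov <- list()
    for (pr in utils::combn(main_cts, 2, simplify = FALSE)) {
      if (species[[pr[1]]] != species[[pr[2]]]) next
      sp <- species[[pr[1]]]
      uni <- de[[pr[1]]]$genes$gene_id
      a <- de_sets[[pr[1]]]; b <- de_sets[[pr[2]]]
      if (length(a) == 0 || length(b) == 0) next
      ov[[paste(pr, collapse = "_vs_")]] <-
        overlap_stats(a, b, uni) %>%
        mutate(pair = paste(pr, collapse = "_vs_"), .before = 1)
    }
    overlaps <- bind_rows(ov)
    f <- file.path(out_dir, "overlaps.tsv")
    readr::write_tsv(overlaps, f)
    note_file("cross_species", f)
  })

  # --- network path analysis ----------------------------------------------
  networks <- list()
  run_stage("network", {
    planted_terms <- intersect(unique(g2t$term_id), sets$set_id)
    for (sp in names(cfg$networks %||% list())) {
      el <- read_network(cfg$networks[[sp]])
      post <- map(de[names(species)[species == sp]],
                  function(d) d$genes[, c("gene_id", "posterior_prob")])
      net <- weight_nodes(el, post)
      src_cfg <- cfg$sources[[sp]]
      src <- resolve_source(net, src_cfg$source,
                            unlist(src_cfg$fallback) %||% character())
      term_results <- list()
      for (term in head(planted_terms, 3)) {
        tg <- setdiff(unique(g2t$gene_id[g2t$term_id == term]), src)
        tg <- intersect(tg, net$nodes$gene_id)
        if (length(tg) == 0) next
        term_results[[term]] <- term_representatives(net, src, tg)
      }
      networks[[sp]] <- list(net = net, source = src, terms = term_results)
      all_paths <- unlist(map(term_results, function(tr) tr$paths),
                          recursive = FALSE, use.names = FALSE)
      all_paths <- unlist(all_paths, recursive = FALSE)
      if (length(all_paths) > 0) {
        gml <- file.path(out_dir, paste0("subnetwork_", sp, ".graphml"))
        sif <- file.path(out_dir, paste0("subnetwork_", sp, ".sif"))
        export_subnetwork(all_paths, net, graphml_path = gml,
                          sif_path = sif, annotations = g2t)
        note_file("network", gml); note_file("network", sif)
      }
      path_tbl <- bind_rows(imap(term_results, function(tr, term) {
        tibble(term = term, source = src,
               representative = tr$representatives,
               distance = tr$distance,
               path = map_chr(tr$paths[tr$representatives], function(p) {
                 paste(p[[1]], collapse = ">")
               }))
      }))
      f <- file.path(out_dir, paste0("paths_", sp, ".tsv"))
      readr::write_tsv(path_tbl, f)
      note_file("network", f)
    }
  })

  # --- reproducibility in the validation cell type ------------------------
  repro <- NULL
  run_stage("reproducibility", {
    if (length(validation_ct) == 1 && !is.null(common) &&
        length(common$common) > 0) {
      val_sig <- enrich[[validation_ct]]
      val_set <- val_sig$set_id[val_sig$significant]
      repro <- reproducibility(common$common, val_set, sets$set_id)
      f <- file.path(out_dir, "reproducibility.tsv")
      readr::write_tsv(repro, f)
      note_file("reproducibility", f)
    }
  })

  report <- structure(
    list(de = de, de_sets = de_sets, clusters = clusters, semsim = semsim,
         enrichment = enrich, common = common, motifs = motifs,
         motif_hits = motif_hits, cross_species = xsp, overlaps = overlaps,
         networks = networks, reproducibility = repro,
         species = species, validation_cell_type = validation_ct,
         provenance = bind_rows(prov), config = cfg),
    class = "study_report"
  )
  if (!is.null(cfg$truth) && file.exists(cfg$truth)) {
    report$recovery <- assess_recovery(report, jsonlite::read_json(
      cfg$truth, simplifyVector = TRUE))
  }
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report> ", length(x$de), " cell types; stages: ",
      paste(unique(x$provenance$stage), collapse = ", "), "\n", sep = "")
  if (!is.null(x$recovery)) {
    cat("  planted-structure recovery:\n")
    print(x$recovery)
  }
  invisible(x)
}

#' Compare a study report against planted ground truth
#'
#' @param report A `study_report`.
#' @param truth Ground-truth list (as written by [make_demo()]).
#' @return Tibble of recovery metrics (one row per check).
#' @export
assess_recovery <- function(report, truth) {
  rows <- list()
  for (ct in names(report$de)) {
    g <- report$de[[ct]]$genes
    lab <- g$gene_id %in% truth$de_genes[[ct]]
    if (any(lab) && !all(lab)) {
      rows[[length(rows) + 1]] <- tibble(
        metric = paste0("de_auc_", ct),
        value = auc_score(g$posterior_prob, lab)
      )
    }
  }
  main <- setdiff(names(report$de), report$validation_cell_type)
  ref_sp <- report$species[[main[1]]]
  core_ref <- truth$shared_core[[ref_sp]]
  if (!is.null(report$cross_species)) {
    rows[[length(rows) + 1]] <- tibble(
      metric = "shared_core_in_all_fraction",
      value = mean(core_ref %in% report$cross_species$in_all)
    )
  }
  if (!is.null(report$common)) {
    rows[[length(rows) + 1]] <- tibble(
      metric = "planted_terms_common_fraction",
      value = mean(truth$planted_terms %in% report$common$common)
    )
  }
  found_cons <- unlist(map(report$motifs, function(m) m$consensus))
  rows[[length(rows) + 1]] <- tibble(
    metric = "motif_recovered_celltypes",
    value = sum(map_lgl(report$motifs, function(m) {
      any(consensus_matches(m$consensus, truth$motif_consensus, max_mismatch = 1))
    }))
  )
  for (sp in names(report$networks)) {
    planted <- truth$planted_paths[[sp]]
    reps <- unlist(map(report$networks[[sp]]$terms, "representatives"))
    rows[[length(rows) + 1]] <- tibble(
      metric = paste0("network_source_on_core_", sp),
      value = as.numeric(report$networks[[sp]]$source %in% planted)
    )
  }
  bind_rows(rows)
}

# does any IUPAC consensus match the planted one within max_mismatch
# (comparing resolved base sets positionally, allowing offsets)?
consensus_matches <- function(found, planted, max_mismatch = 1) {
  if (length(found) == 0) return(FALSE)
  targets <- c(planted, reverse_complement(planted))
  map_lgl(found, function(f) {
    any(map_lgl(targets, function(t) {
      kf <- nchar(f); kt <- nchar(t)
      if (kf < kt) return(FALSE)
      for (off in 0:(kf - kt)) {
        mm <- 0
        for (i in seq_len(kt)) {
          bf <- IUPAC_MAP[[substr(f, off + i, off + i)]]
          bt <- IUPAC_MAP[[substr(t, i, i)]]
          if (length(intersect(bf, bt)) == 0) mm <- mm + 1
        }
        if (mm <= max_mismatch) return(TRUE)
      }
      FALSE
    }))
  })
}
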