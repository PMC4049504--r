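# Readers and writers for every external format the pipeline touches.
# All tables are TAB-separated with a mandatory header; decimal point is ".".
# Gene identifiers are opaque, case-sensitive strings; cross-species joins
# happen only through homolog tables.

#' Expression time course container
#'
#' Bundles one cell type's log2 expression matrix (genes x samples) with its
#' sample metadata. Samples are ordered by (time, replicate); genes are
#' deduplicated on construction (first occurrence kept).
#'
#' @param expr Numeric matrix, genes in rows (rownames = gene ids), samples in
#'   columns (colnames = sample ids). Values are log2 expression.
#' @param meta Data frame with columns `sample_id`, `cell_type`, `time_h`,
#'   `replicate` and optionally `batch`, covering every column of `expr`.
#' @param species Species label carried along for cross-species joins.
#' @param paired Logical; `TRUE` when replicate labels pair across time points
#'   so that fold changes are computed within replicate, `FALSE` to compute
#'   them against the mean baseline.
#'
#' @return An object of class `expr_timecourse`: a list with elements `expr`
#'   (matrix), `meta` (tibble), `cell_type`, `species`, `paired` and a
#'   `dropped` log tibble.
#' @export
expr_timecourse <- function(expr, meta, species = NA_character_, paired = TRUE) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    abort("`expr` must be a numeric matrix")
  }
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    abort("`expr` must have gene ids as rownames and sample ids as colnames")
  }
  meta <- as_tibble(meta)
  required <- c("sample_id", "cell_type", "time_h", "replicate")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0) {
    abort(paste0("metadata lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!"batch" %in% names(meta)) meta$batch <- NA_character_
  unknown <- setdiff(colnames(expr), meta$sample_id)
  if (length(unknown) > 0) {
    abort(paste0("sample(s) in matrix missing from metadata: ",
                 paste(unknown, collapse = ", ")))
  }
  meta <- meta[match(colnames(expr), meta$sample_id), , drop = FALSE]
  if (length(unique(meta$cell_type)) != 1) {
    abort("an expression time course holds exactly one cell type")
  }
  validate_sample_metadata(meta)
  if (any(!is.finite(expr))) abort("expression values must be finite")

  dropped <- tibble(event = character(), count = integer(), detail = character())
  dup <- duplicated(rownames(expr))
  if (any(dup)) {
    dropped <- bind_rows(dropped, tibble(
      event = "duplicate_gene_row", count = sum(dup),
      detail = paste(unique(rownames(expr)[dup]), collapse = ",")
    ))
    warn(paste0(sum(dup), " duplicated gene row(s) dropped (first occurrence kept)"))
    expr <- expr[!dup, , drop = FALSE]
  }
  ord <- order(meta$time_h, meta$replicate)
  meta <- meta[ord, , drop = FALSE]
  expr <- expr[, meta$sample_id, drop = FALSE]

  structure(
    list(expr = expr, meta = meta,
         cell_type = meta$cell_type[[1]], species = species,
         paired = paired, dropped = dropped),
    class = "expr_timecourse"
  )
}

#' @export
print.expr_timecourse <- function(x, ...) {
  cat("<expr_timecourse> ", x$cell_type,
      if (!is.na(x$species)) paste0(" (", x$species, ")"), "\n", sep = "")
  cat("  ", nrow(x$expr), " genes x ", ncol(x$expr), " samples; time points [h]: ",
      paste(sort(unique(x$meta$time_h)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.expr_timecourse <- function(x) dim(x$expr)

#' Validate sample metadata invariants
#'
#' Checks that time 0 is present for every cell type, that
#' (cell_type, time_h, replicate) combinations are unique, and that every
#' retained time point has at least two replicates.
#'
#' @param meta Data frame of sample metadata.
#' @return `meta` invisibly; aborts on violation.
#' @export
validate_sample_metadata <- function(meta) {
  meta <- as_tibble(meta)
  for (ct in unique(meta$cell_type)) {
    sub <- meta[meta$cell_type == ct, ]
    if (!any(sub$time_h == 0)) {
      abort(paste0("no baseline: cell type '", ct, "' lacks time 0 samples"))
    }
    key <- paste(sub$time_h, sub$replicate)
    if (anyDuplicated(key)) {
      abort(paste0("duplicate (cell_type, time_h, replicate) in '", ct, "'"))
    }
    reps <- table(sub$time_h)
    if (any(reps < 2)) {
      bad <- names(reps)[reps < 2]
      abort(paste0("cell type '", ct, "' has < 2 replicates at time(s) ",
                   paste(bad, collapse = ", ")))
    }
  }
  if (any(meta$time_h < 0)) abort("time_h must be non-negative")
  invisible(meta)
}

#' Read an expression matrix with its sample metadata
#'
#' Reads a TSV expression matrix (first column `gene_id`, remaining columns
#' one sample each) and a metadata TSV mapping every sample id to cell type,
#' time in hours, replicate and optional batch.
#'
#' @param path Path to the expression TSV.
#' @param metadata_path Path to the metadata TSV.
#' @inheritParams expr_timecourse
#' @return An [expr_timecourse] object.
#' @export
read_expression_matrix <- function(path, metadata_path,
                                   species = NA_character_, paired = TRUE) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 2) abort("expression matrix needs a gene_id column plus samples")
  gene_ids <- raw[[1]]
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(apply(vals, 2, as.numeric))
  if (is.null(dim(num))) num <- matrix(num, nrow = nrow(vals), dimnames = dimnames(vals))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(paste0("non-numeric cell at row ", bad[1, 1] + 1L, " (gene '",
                 gene_ids[bad[1, 1]], "'), column '", colnames(vals)[bad[1, 2]], "'"))
  }
  rownames(num) <- gene_ids
  meta <- readr::read_tsv(metadata_path, col_types = readr::cols(), progress = FALSE)
  expr_timecourse(num, meta, species = species, paired = paired)
}

#' Write an expression time course back to TSV
#'
#' @param x An [expr_timecourse].
#' @param path Output path for the matrix TSV.
#' @param metadata_path Output path for the metadata TSV.
#' @return `x` invisibly.
#' @export
write_expression_matrix <- function(x, path, metadata_path) {
  stopifnot(inherits(x, "expr_timecourse"))
  out <- bind_cols(tibble(gene_id = rownames(x$expr)), as_tibble(x$expr))
  readr::write_tsv(out, path)
  readr::write_tsv(x$meta, metadata_path)
  invisible(x)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, `set_id TAB description TAB gene ...`.
#' Within-set duplicate genes are dropped.
#'
#' @param path Path to the GMT file.
#' @return A tibble with columns `set_id`, `description` and a list-column
#'   `genes` of unique gene-id vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort("empty GMT file")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3)
  if (length(short) > 0) {
    abort(paste0("GMT line ", short[1], " has fewer than 3 fields"))
  }
  tibble(
    set_id = map_chr(parts, 1),
    description = map_chr(parts, 2),
    genes = map(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  )
}

#' Write a gene-set collection to GMT
#'
#' @param sets Tibble as returned by [read_gmt()] (or named list of vectors).
#' @param path Output path.
#' @return `sets` invisibly.
#' @export
write_gmt <- function(sets, path) {
  sets <- as_gene_set_tbl(sets)
  lines <- pmap(sets, function(set_id, description, genes) {
    paste(c(set_id, description, genes), collapse = "\t")
  })
  writeLines(unlist(lines), path)
  invisible(sets)
}

# Accept either the gmt tibble or a named list of gene vectors.
as_gene_set_tbl <- function(sets) {
  if (is.data.frame(sets)) {
    stopifnot(all(c("set_id", "genes") %in% names(sets)))
    if (!"description" %in% names(sets)) sets$description <- sets$set_id
    if (any(lengths(sets$genes) == 0)) abort("gene sets must be non-empty")
    return(as_tibble(sets[, c("set_id", "description", "genes")]))
  }
  if (is.list(sets) && !is.null(names(sets))) {
    if (any(lengths(sets) == 0)) abort("gene sets must be non-empty")
    return(tibble(set_id = names(sets), description = names(sets),
                  genes = map(sets, unique)))
  }
  abort("gene sets must be a tibble with set_id/genes or a named list")
}

#' Ontology DAG container
#'
#' @param edges Tibble with columns `child`, `parent`, `relation`
#'   (`is_a` or `part_of`).
#' @param terms Optional character vector of term ids (defaults to all ids in
#'   `edges`); isolated terms may be included here.
#' @return An `ontology_dag`: list with `terms`, `edges`, `roots`.
#' @export
ontology_dag <- function(edges, terms = NULL) {
  edges <- as_tibble(edges)
  stopifnot(all(c("child", "parent", "relation") %in% names(edges)))
  bad_rel <- setdiff(unique(edges$relation), c("is_a", "part_of"))
  if (length(bad_rel) > 0) {
    abort(paste0("relations must be is_a/part_of; got: ",
                 paste(bad_rel, collapse = ", ")))
  }
  terms <- union(terms %||% character(), union(edges$child, edges$parent))
  cyc <- find_cycle(edges, terms)
  if (!is.null(cyc)) {
    abort(paste0("ontology contains a cycle: ", paste(cyc, collapse = " -> ")))
  }
  roots <- setdiff(terms, unique(edges$child))
  structure(list(terms = terms, edges = edges, roots = roots),
            class = "ontology_dag")
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat("<ontology_dag> ", length(x$terms), " terms, ", nrow(x$edges),
      " edges, root(s): ", paste(x$roots, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Kahn topological sort; returns one cycle (node sequence) or NULL.
find_cycle <- function(edges, terms) {
  indeg <- setNames(integer(length(terms)), terms)
  tab <- table(edges$parent)
  indeg[names(tab)] <- as.integer(tab)
  children <- split(edges$parent, edges$child)
  queue <- names(indeg)[indeg == 0]
  seen <- 0L
  while (length(queue) > 0) {
    v <- queue[[1]]; queue <- queue[-1]; seen <- seen + 1L
    for (p in children[[v]] %||% character()) {
      indeg[[p]] <- indeg[[p]] - 1L
      if (indeg[[p]] == 0L) queue <- c(queue, p)
    }
  }
  if (seen == length(terms)) return(NULL)
  # walk within the residual subgraph to exhibit one cycle
  resid <- names(indeg)[indeg > 0]
  up <- split(edges$parent, edges$child)
  v <- resid[[1]]; path <- v
  repeat {
    nxt <- intersect(up[[v]] %||% character(), resid)[1]
    if (is.na(nxt)) nxt <- (up[[v]] %||% character())[1]
    if (nxt %in% path) {
      i <- match(nxt, path)
      return(c(path[i:length(path)], nxt))
    }
    path <- c(path, nxt); v <- nxt
  }
}

#' Read an ontology (OBO subset or edge TSV)
#'
#' Accepts either a minimal OBO file (stanzas with `id:`, `is_a:` and
#' `relationship: part_of` lines) or a 3-column TSV `child parent relation`.
#' Edges with relations other than `is_a`/`part_of` are dropped with a count
#' reported via a warning.
#'
#' @param path Path to the ontology file.
#' @return An [ontology_dag].
#' @export
read_ontology <- function(path) {
  lines <- readLines(path)
  if (any(grepl("^\\[Term\\]", lines))) {
    edges <- parse_obo_edges(lines)
  } else {
    tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
    if (ncol(tab) < 3) abort("edge TSV needs 3 columns: child, parent, relation")
    names(tab)[1:3] <- c("child", "parent", "relation")
    edges <- as_tibble(tab[, 1:3])
  }
  keep <- edges$relation %in% c("is_a", "part_of")
  if (any(!keep)) {
    warn(paste0(sum(!keep), " edge(s) with unsupported relation dropped"))
  }
  ontology_dag(edges[keep, , drop = FALSE])
}

parse_obo_edges <- function(lines) {
  term_starts <- grep("^\\[Term\\]", lines)
  blocks <- map2(term_starts,
                 c(term_starts[-1] - 1L, length(lines)),
                 function(a, b) lines[a:b])
  rows <- map(blocks, function(bl) {
    id <- sub("^id:\\s*", "", grep("^id:", bl, value = TRUE)[1])
    isa <- sub("\\s*!.*$", "", sub("^is_a:\\s*", "", grep("^is_a:", bl, value = TRUE)))
    rel_lines <- grep("^relationship:", bl, value = TRUE)
    rel_parts <- strsplit(sub("^relationship:\\s*", "", rel_lines), "\\s+")
    out <- list()
    if (length(isa) > 0) {
      out$isa <- tibble(child = id, parent = isa, relation = "is_a")
    }
    if (length(rel_parts) > 0) {
      out$rel <- tibble(child = id,
                        parent = map_chr(rel_parts, 2),
                        relation = map_chr(rel_parts, 1))
    }
    bind_rows(out)
  })
  bind_rows(rows)
}

#' Write an ontology DAG as edge TSV
#'
#' @param dag An [ontology_dag].
#' @param path Output path.
#' @return `dag` invisibly.
#' @export
write_ontology <- function(dag, path) {
  readr::write_tsv(dag$edges, path)
  invisible(dag)
}

#' Read an interaction network (2-column TSV or SIF)
#'
#' Undirected simple graph: self-loops are dropped and duplicate edges
#' (in either orientation) collapsed, each with a warning count.
#'
#' @param path Path to a 2-column TSV (with header) or a SIF file
#'   (`node relation node`, whitespace-separated, no header).
#' @return A tibble with columns `from`, `to` (lexicographically ordered
#'   within row), one row per unique undirected edge.
#' @export
read_network <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warn("empty network file: returning empty graph")
    return(tibble(from = character(), to = character()))
  }
  first <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  is_sif <- grepl("\\.sif$", path, ignore.case = TRUE) ||
    (length(first) == 3 && !identical(tolower(first[1:2]), c("from", "to")))
  if (is_sif) {
    parts <- strsplit(trimws(lines), "\\s+")
    bad <- which(lengths(parts) < 3)
    if (length(bad) > 0) abort(paste0("SIF line ", bad[1], " has fewer than 3 fields"))
    from <- map_chr(parts, 1)
    to <- map_chr(parts, 3)
  } else {
    tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
    if (ncol(tab) < 2) abort("network TSV needs at least 2 columns")
    from <- tab[[1]]; to <- tab[[2]]
  }
  lo <- pmin(from, to)
  hi <- pmax(from, to)
  el <- tibble(from = lo, to = hi)
  loops <- el$from == el$to
  if (any(loops)) warn(paste0(sum(loops), " self-loop(s) dropped"))
  el <- el[!loops, , drop = FALSE]
  dups <- duplicated(el)
  if (any(dups)) warn(paste0(sum(dups), " duplicate edge(s) collapsed"))
  el[!dups, , drop = FALSE]
}

#' Write a network as 2-column TSV or SIF
#'
#' @param edges Tibble with columns `from`, `to`.
#' @param path Output path; `.sif` extension selects SIF with relation `pp`.
#' @return `edges` invisibly.
#' @export
write_network <- function(edges, path) {
  if (grepl("\\.sif$", path, ignore.case = TRUE)) {
    writeLines(paste(edges$from, "pp", edges$to, sep = "\t"), path)
  } else {
    readr::write_tsv(edges[, c("from", "to")], path)
  }
  invisible(edges)
}

#' Read a homolog-pair table
#'
#' @param path TSV with header and columns `gene_a`, `gene_b`, `evalue`,
#'   `bitscore` (extra columns kept).
#' @return Tibble of homolog pairs.
#' @export
read_homolog_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  need <- c("gene_a", "gene_b", "evalue")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    abort(paste0("homolog table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (any(tab$evalue < 0)) abort("E-values must be non-negative")
  as_tibble(tab)
}

#' Write a homolog-pair table
#' @param pairs Tibble with `gene_a`, `gene_b`, `evalue` (and extras).
#' @param path Output path.
#' @return `pairs` invisibly.
#' @export
write_homolog_table <- function(pairs, path) {
  readr::write_tsv(pairs, path)
  invisible(pairs)
}

#' Read promoter sequences from FASTA
#'
#' @param path FASTA path.
#' @return Named character vector of uppercase sequences.
#' @export
read_promoters <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(seqs)), names(seqs))
}

#' Write promoter sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output FASTA path.
#' @return `seqs` invisibly.
#' @export
write_promoters <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 70L)
  invisible(seqs)
}

#' Read a plain-text PWM library (TRANSFAC-like)
#'
#' Records start with `ID <name>` (or `DE <name>`), contain numbered count
#' rows `01 nA nC nG nT`, an optional `P0 A C G T` header, and end with `//`
#' (or `XX`). Counts are converted to column frequencies with a pseudocount.
#'
#' @param path Path to the library file.
#' @param pseudocount Added per base before normalising (default 0.1).
#' @return A list of [pwm] objects.
#' @export
read_pwm_library <- function(path, pseudocount = 0.1) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  pwms <- list()
  name <- NULL
  rows <- list()
  flush <- function() {
    if (!is.null(name) && length(rows) > 0) {
      m <- do.call(rbind, rows)
      pwms[[length(pwms) + 1]] <<- pwm(m, name = name, source = "reference",
                                       pseudocount = pseudocount)
    }
    name <<- NULL; rows <<- list()
  }
  for (ln in lines) {
    if (grepl("^(ID|DE)\\s+", ln)) {
      flush()
      name <- strsplit(ln, "\\s+")[[1]][2]
    } else if (grepl("^(//|XX)", ln)) {
      flush()
    } else if (grepl("^P0", ln)) {
      next
    } else if (grepl("^[0-9]+\\s", ln)) {
      vals <- as.numeric(strsplit(ln, "\\s+")[[1]][2:5])
      rows[[length(rows) + 1]] <- vals
    }
  }
  flush()
  if (length(pwms) == 0) abort("no PWM records found")
  pwms
}

#' Write a PWM list as a TRANSFAC-like library
#'
#' @param pwms List of [pwm] objects.
#' @param path Output path.
#' @param counts_scale Counts written as `round(freq * counts_scale)`.
#' @return `pwms` invisibly.
#' @export
write_pwm_library <- function(pwms, path, counts_scale = 100) {
  out <- character()
  for (p in pwms) {
    out <- c(out, paste("ID", p$name), "P0\tA\tC\tG\tT")
    m <- round(t(p$matrix) * counts_scale)
    for (i in seq_len(nrow(m))) {
      out <- c(out, paste(c(sprintf("%02d", i), m[i, ]), collapse = "\t"))
    }
    out <- c(out, "//")
  }
  writeLines(out, path)
  invisible(pwms)
}
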