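# Simplified de-novo promoter motif discovery and PWM library matching.
# Discovery: k-mer seeds scored by a binomial enrichment test against a
# Markov background, expanded to PWMs by a zero-or-one-occurrence-per-sequence
# EM, with Bonferroni-style E-values over the tested seeds. Matching: ungapped
# column-correlation alignment against a reference library with an empirical
# shuffled-column null.

BASES <- c("A", "C", "G", "T")

#' Position weight matrix
#'
#' @param counts Numeric matrix, positions in rows and the four bases
#'   `A,C,G,T` in columns (counts or frequencies).
#' @param name Motif name.
#' @param source `"discovered"` or `"reference"`.
#' @param pseudocount Added per cell before normalising columns to sum 1.
#' @return A `pwm`: list with `matrix` (4 x L frequency matrix, rows
#'   `A,C,G,T`), `consensus` (IUPAC), `name`, `source`, `pseudocount`.
#' @export
pwm <- function(counts, name = "motif", source = c("discovered", "reference"),
                pseudocount = 0.1) {
  source <- match.arg(source)
  counts <- as.matrix(counts)
  if (ncol(counts) != 4) abort("counts must have 4 columns (A, C, G, T)")
  if (nrow(counts) < 4) abort("a PWM needs at least 4 positions")
  freq <- t((counts + pseudocount) / rowSums(counts + pseudocount))
  rownames(freq) <- BASES
  structure(
    list(matrix = freq, consensus = pwm_consensus(freq), name = name,
         source = source, pseudocount = pseudocount),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm> ", x$name, " (", x$source, "), ", ncol(x$matrix),
      " positions, consensus ", x$consensus, "\n", sep = "")
  invisible(x)
}

# IUPAC consensus: at each column, the code of all bases with frequency
# >= 0.25 (falling back to the single most frequent base).
pwm_consensus <- function(freq) {
  codes <- apply(freq, 2, function(col) {
    hit <- BASES[col >= 0.25]
    if (length(hit) == 0) hit <- BASES[which.max(col)]
    key <- paste(sort(hit), collapse = "")
    iupac <- c(A = "A", C = "C", G = "G", T = "T",
               AG = "R", CT = "Y", CG = "S", AT = "W", GT = "K", AC = "M",
               CGT = "B", AGT = "D", ACT = "H", ACG = "V", ACGT = "N")
    iupac[[key]]
  })
  paste(codes, collapse = "")
}

pwm_revcomp <- function(p) {
  m <- p$matrix[c("T", "G", "C", "A"), rev(seq_len(ncol(p$matrix))), drop = FALSE]
  rownames(m) <- BASES
  out <- p
  out$matrix <- m
  out$consensus <- pwm_consensus(m)
  out
}

seq_to_int <- function(s) {
  match(strsplit(s, NULL)[[1]], BASES) # NA for non-ACGT
}

# log-odds scores of a PWM at every start position of an integer-coded
# sequence (forward strand); windows touching non-ACGT score -Inf
scan_scores <- function(ints, logodds) {
  k <- ncol(logodds)
  L <- length(ints)
  if (L < k) return(numeric(0))
  n <- L - k + 1L
  sc <- numeric(n)
  for (j in seq_len(k)) {
    v <- logodds[, j][ints[j:(j + n - 1L)]]
    v[is.na(v)] <- -Inf
    sc <- sc + v
  }
  sc
}

#' Mask long duplicated subsequences
#'
#' Any exact subsequence of at least `min_len` bp shared between two
#' different promoters is masked to `N` in all sequences carrying it, to
#' keep pairwise segmental homology from mimicking enriched motifs. Blocks
#' present in more than `max_share` of the input sequences are exempt: a
#' block carried by most promoters is candidate enrichment signal, not
#' pairwise homology.
#'
#' @param seqs Named character vector of sequences.
#' @param min_len Minimum duplicate length (default 30).
#' @param max_share Masking applies only to blocks shared by at most this
#'   fraction of the sequences (default 0.5).
#' @return The masked sequences.
#' @export
mask_shared_duplicates <- function(seqs, min_len = 30, max_share = 0.5) {
  k <- min_len
  occ <- imap(seqs, function(s, id) {
    L <- nchar(s)
    if (L < k) return(NULL)
    starts <- seq_len(L - k + 1L)
    tibble(seq = id, pos = starts,
           kmer = substring(s, starts, starts + k - 1L))
  })
  tab <- bind_rows(occ)
  if (nrow(tab) == 0) return(seqs)
  per_seq <- distinct(tab, .data$kmer, .data$seq)
  n_carry <- table(per_seq$kmer)
  shared <- names(which(n_carry > 1 & n_carry <= max_share * length(seqs)))
  shared <- shared[!grepl("N", shared)]
  if (length(shared) == 0) return(seqs)
  bad <- tab[tab$kmer %in% shared, , drop = FALSE]
  for (i in seq_len(nrow(bad))) {
    id <- bad$seq[i]
    substr(seqs[[id]], bad$pos[i], bad$pos[i] + k - 1L) <-
      strrep("N", k)
  }
  seqs
}

# strand-symmetric Markov background of the given order (0 or 1) fitted on
# the sequences and their reverse complements
fit_markov_background <- function(seqs, order = 1) {
  both <- c(seqs, reverse_complement(seqs))
  chars <- unlist(strsplit(both, NULL))
  codes <- match(chars, BASES)
  base_p <- tabulate(codes, 4) + 1
  base_p <- base_p / sum(base_p)
  names(base_p) <- BASES
  if (order == 0) {
    return(list(order = 0, base = base_p, trans = NULL))
  }
  trans <- matrix(1, 4, 4, dimnames = list(BASES, BASES))
  for (s in both) {
    ii <- match(strsplit(s, NULL)[[1]], BASES)
    ok <- !is.na(ii[-length(ii)]) & !is.na(ii[-1])
    idx <- cbind(ii[-length(ii)][ok], ii[-1][ok])
    tt <- table(factor(idx[, 1], 1:4), factor(idx[, 2], 1:4))
    trans <- trans + as.matrix(tt)
  }
  trans <- trans / rowSums(trans)
  list(order = 1, base = base_p, trans = trans)
}

markov_kmer_prob <- function(kmer, bg) {
  # vectorised over equal-width k-mers
  k <- nchar(kmer[1])
  codes <- vapply(seq_len(k), function(j) {
    match(substring(kmer, j, j), BASES)
  }, integer(length(kmer)))
  if (length(kmer) == 1) codes <- matrix(codes, nrow = 1)
  p <- unname(bg$base[codes[, 1]])
  if (bg$order >= 1) {
    for (j in seq_len(k)[-1]) {
      p <- p * bg$trans[cbind(codes[, j - 1], codes[, j])]
    }
  } else if (k > 1) {
    for (j in seq_len(k)[-1]) p <- p * unname(bg$base[codes[, j]])
  }
  p[is.na(p)] <- 0
  p
}

#' Discover enriched promoter motifs
#'
#' Counts k-mers (collapsed with their reverse complements), scores each
#' against an order-`background_order` Markov background with a binomial
#' upper-tail test, expands the top seeds to PWMs by a
#' zero-or-one-occurrence-per-sequence EM, assigns Bonferroni-style E-values
#' (seed p-value times the number of seeds passing a 0.01 pre-filter), keeps
#' motifs at `e_cut`, and greedily removes near-duplicate PWMs. Carrier
#' promoters are those with a log-odds match at 80% or more of the PWM's
#' maximum achievable score.
#'
#' @param promoters Named character vector of promoter sequences (>= 10
#'   sequences, each at least as long as the largest k).
#' @param k_range Integer k-mer widths to scan (default 6:10).
#' @param background_order Markov background order (0 or 1).
#' @param e_cut E-value threshold for reporting (default 1e-3).
#' @param max_seeds Maximum seeds expanded by EM.
#' @param dedup_threshold Alignment score above which two PWMs are considered
#'   duplicates.
#' @return Tibble: `name`, `consensus`, `k`, `seed`, `count`, `expected`,
#'   `p_value`, `e_value`, `n_carriers`, `carriers` (list-column) and `motif`
#'   (list-column of [pwm] objects), sorted by E-value.
#' @export
discover_motifs <- function(promoters, k_range = 6:10, background_order = 1,
                            e_cut = 1e-3, max_seeds = 10,
                            dedup_threshold = 0.8) {
  if (length(promoters) < 10) abort("need at least 10 promoter sequences")
  if (is.null(names(promoters))) {
    names(promoters) <- sprintf("seq_%04d", seq_along(promoters))
  }
  promoters <- toupper(promoters)
  frac_bad <- map_dbl(promoters, function(s) {
    ch <- strsplit(s, NULL)[[1]]
    mean(!ch %in% BASES)
  })
  if (any(frac_bad > 0.1)) {
    warn(paste0(sum(frac_bad > 0.1), " sequence(s) with >10% non-ACGT skipped"))
    promoters <- promoters[frac_bad <= 0.1]
  }
  if (any(nchar(promoters) < max(k_range))) {
    abort("every sequence must be at least as long as the largest k")
  }
  promoters <- mask_shared_duplicates(promoters)
  bg <- fit_markov_background(promoters, order = background_order)
  ints <- map(promoters, seq_to_int)

  seed_tbl <- bind_rows(map(k_range, function(k) {
    counts <- count_kmers_canonical(promoters, k)
    if (nrow(counts) == 0) return(NULL)
    n_pos <- sum(pmax(nchar(promoters) - k + 1L, 0L))
    rc <- reverse_complement(counts$kmer)
    counts$p_pair <- markov_kmer_prob(counts$kmer, bg) +
      ifelse(rc == counts$kmer, 0, markov_kmer_prob(rc, bg))
    counts$expected <- n_pos * counts$p_pair
    counts$p_value <- pbinom(counts$count - 1L, n_pos, counts$p_pair,
                             lower.tail = FALSE)
    counts$k <- k
    counts
  }))
  # multiplicity: every distinct canonical k-mer scored across the k range
  # counts as a tested hypothesis; the 0.01 pre-filter only shortlists seeds
  # for EM expansion
  n_tests <- max(nrow(seed_tbl), 1L)
  pre <- seed_tbl[seed_tbl$p_value < 0.01, , drop = FALSE]
  if (nrow(pre) == 0) return(empty_motif_tbl())
  pre$e_value <- pmin(pre$p_value * n_tests, Inf)
  pre <- arrange(pre, .data$p_value)
  cand <- pre[pre$e_value <= e_cut, , drop = FALSE]
  cand <- head(cand, max_seeds)
  if (nrow(cand) == 0) return(empty_motif_tbl())

  motifs <- map(seq_len(nrow(cand)), function(i) {
    refine_pwm_zoops(cand$kmer[i], ints, bg)
  })

  # greedy dedup by E-value rank
  keep <- logical(nrow(cand))
  kept_pwms <- list()
  for (i in seq_len(nrow(cand))) {
    dup <- FALSE
    for (p0 in kept_pwms) {
      if (pwm_align_score(motifs[[i]], p0)$score > dedup_threshold) {
        dup <- TRUE
        break
      }
    }
    if (!dup) {
      keep[i] <- TRUE
      kept_pwms[[length(kept_pwms) + 1]] <- motifs[[i]]
    }
  }
  cand <- cand[keep, , drop = FALSE]
  motifs <- motifs[keep]

  carriers <- map(motifs, function(p) find_carriers(p, ints, bg))
  tibble(
    name = sprintf("motif_%02d", seq_len(nrow(cand))),
    consensus = map_chr(motifs, "consensus"),
    k = cand$k,
    seed = cand$kmer,
    count = cand$count,
    expected = cand$expected,
    p_value = cand$p_value,
    e_value = cand$e_value,
    n_carriers = lengths(carriers),
    carriers = carriers,
    motif = motifs
  )
}

empty_motif_tbl <- function() {
  tibble(name = character(), consensus = character(), k = integer(),
         seed = character(), count = integer(), expected = numeric(),
         p_value = numeric(), e_value = numeric(), n_carriers = integer(),
         carriers = list(), motif = list())
}

# forward-strand k-mer counts merged over reverse-complement pairs
count_kmers_canonical <- function(seqs, k) {
  kmers <- unlist(map(unname(seqs), function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    substring(s, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L)
  }))
  kmers <- kmers[!grepl("[^ACGT]", kmers)]
  if (length(kmers) == 0) {
    return(tibble(kmer = character(), count = integer()))
  }
  tab <- table(kmers)
  words <- names(tab)
  rc <- reverse_complement(words)
  canon <- pmin(words, rc)
  counts <- tapply(as.integer(tab), canon, sum)
  # counts for the rc partner that never occurred are implicitly 0
  tibble(kmer = names(counts), count = as.integer(counts))
}

# ZOOPS EM refinement of a seed k-mer into a PWM. Each sequence carries at
# most one site on either strand; gamma is the prior fraction of carrier
# sequences. Background is the 0-order base composition.
refine_pwm_zoops <- function(seed, ints, bg, n_iter = 15, pseudocount = 0.1) {
  k <- nchar(seed)
  seed_idx <- match(strsplit(seed, NULL)[[1]], BASES)
  counts0 <- matrix(0.5, k, 4)
  counts0[cbind(seq_len(k), seed_idx)] <- 5
  p <- pwm(counts0, name = seed, source = "discovered",
           pseudocount = pseudocount)
  log_bg <- log(bg$base)
  # per-sequence one-hot window masks (n x k per base), forward and reverse
  # complement; windows with non-ACGT positions carry a FALSE row everywhere
  # in that column, which scores -Inf via the any-N mask
  windows <- map(ints, function(s) {
    n <- length(s) - k + 1L
    if (n < 1) return(NULL)
    fwd <- vapply(seq_len(k), function(j) s[j:(j + n - 1L)], integer(n))
    if (n == 1L) fwd <- matrix(fwd, nrow = 1L)
    rev_ <- (5L - fwd)[, k:1, drop = FALSE]
    fwd[is.na(fwd)] <- 0L
    rev_[is.na(rev_)] <- 0L
    has_n <- rowSums(fwd == 0L) > 0
    list(mf = map(1:4, function(b) fwd == b),
         mr = map(1:4, function(b) rev_ == b),
         has_n = has_n, n = n)
  })
  windows <- windows[!map_lgl(windows, is.null)]
  gamma <- 0.5
  obj_prev <- -Inf
  for (iter in seq_len(n_iter)) {
    lo <- log(p$matrix) - log_bg
    wins <- matrix(0, k, 4)
    gamma_num <- 0
    obj <- 0
    for (w in windows) {
      n <- w$n
      sf <- numeric(n); sr <- numeric(n)
      for (b in 1:4) {
        sf <- sf + drop(w$mf[[b]] %*% lo[b, ])
        sr <- sr + drop(w$mr[[b]] %*% lo[b, ])
      }
      sf[w$has_n] <- -Inf
      sr[w$has_n] <- -Inf
      lsite <- c(sf, sr) + log(gamma) - log(2 * n)
      lall <- c(lsite, log1p(-gamma))
      m <- max(lall)
      tot <- m + log(sum(exp(lall - m)))
      obj <- obj + tot
      r <- exp(lsite - tot)
      rf <- r[seq_len(n)]; rr <- r[n + seq_len(n)]
      for (b in 1:4) {
        wins[, b] <- wins[, b] + colSums(rf * w$mf[[b]]) +
          colSums(rr * w$mr[[b]])
      }
      gamma_num <- gamma_num + sum(r)
    }
    gamma <- min(max(gamma_num / length(windows), 1e-4), 1 - 1e-4)
    p <- pwm(wins, name = seed, source = "discovered",
             pseudocount = pseudocount)
    if (is.finite(obj_prev) && abs(obj - obj_prev) < 1e-6 * (abs(obj_prev) + 1)) {
      break
    }
    obj_prev <- obj
  }
  p
}

# carriers: sequences with a log-odds hit at >= 80% of the PWM's maximum
# achievable score on either strand
find_carriers <- function(p, ints, bg, frac = 0.8) {
  logodds <- log(p$matrix) - log(bg$base)
  logodds_rc <- log(pwm_revcomp(p)$matrix) - log(bg$base)
  smax <- sum(apply(logodds, 2, max))
  thr <- frac * smax
  hits <- map_lgl(ints, function(s) {
    any(scan_scores(s, logodds) >= thr) ||
      any(scan_scores(s, logodds_rc) >= thr)
  })
  names(hits)[hits]
}

# standardize PWM columns so that crossprod gives the Pearson correlation of
# frequency vectors
pwm_zscore <- function(p) {
  m <- p$matrix
  mu <- colMeans(m)
  sdv <- apply(m, 2, sd)
  sdv[sdv == 0] <- Inf
  sweep(sweep(m, 2, mu), 2, sdv * sqrt(3), "/")
}

align_from_corr <- function(C, min_overlap = 4) {
  Lq <- nrow(C); Lr <- ncol(C)
  best <- -Inf
  for (d in (-(Lq - min_overlap)):(Lr - min_overlap)) {
    i <- seq_len(Lq)
    j <- i + d
    ok <- j >= 1 & j <= Lr
    if (sum(ok) < min_overlap) next
    sc <- mean(C[cbind(i[ok], j[ok])])
    if (sc > best) best <- sc
  }
  best
}

#' Alignment score between two PWMs
#'
#' Ungapped alignment over column offsets: each aligned column pair is scored
#' by the Pearson correlation of the two frequency vectors, an alignment by
#' the mean column score over its span (at least `min_overlap` columns), and
#' both orientations of the second PWM are tried.
#'
#' @param query,ref [pwm] objects (query must have >= 4 columns).
#' @param min_overlap Minimum aligned span.
#' @return List with `score` and `strand` (`"+"` or `"-"`).
#' @export
pwm_align_score <- function(query, ref, min_overlap = 4) {
  if (ncol(query$matrix) < 4) abort("query PWM has fewer than 4 columns")
  zq <- pwm_zscore(query)
  sf <- align_from_corr(crossprod(zq, pwm_zscore(ref)), min_overlap)
  sr <- align_from_corr(crossprod(zq, pwm_zscore(pwm_revcomp(ref))),
                        min_overlap)
  if (sf >= sr) list(score = sf, strand = "+") else list(score = sr, strand = "-")
}

#' Match a discovered PWM against a reference library
#'
#' Scores the query against every library PWM with [pwm_align_score()] and
#' reports the top match. The E-value is the empirical fraction of scores at
#' least as good among `n_shuffle` column-shuffled library PWMs, scaled by
#' the library size (expected chance matches at that score).
#'
#' @param query A [pwm].
#' @param library List of reference [pwm] objects (non-empty).
#' @param n_shuffle Shuffled-column null draws (default 1000).
#' @param seed Integer seed for the shuffling.
#' @return One-row tibble: `name`, `score`, `strand`, `e_value`.
#' @export
match_to_reference <- function(query, library, n_shuffle = 1000, seed = 1) {
  if (length(library) == 0) abort("empty PWM library")
  scores <- map(library, function(r) pwm_align_score(query, r))
  sc <- map_dbl(scores, "score")
  top <- which.max(sc)
  null_scores <- with_seed(seed, {
    picks <- sample.int(length(library), n_shuffle, replace = TRUE)
    vapply(picks, function(i) {
      r <- library[[i]]
      perm <- sample.int(ncol(r$matrix))
      r$matrix <- r$matrix[, perm, drop = FALSE]
      pwm_align_score(query, r)$score
    }, numeric(1))
  })
  p_emp <- (1 + sum(null_scores >= sc[top])) / (n_shuffle + 1)
  tibble(name = library[[top]]$name, score = sc[top],
         strand = scores[[top]]$strand,
         e_value = p_emp * length(library))
}

#' Bipartite TFBS-gene table
#'
#' Joins motif hits (matched to reference TFBS names) with a user-supplied
#' TFBS-to-gene map and the DE sets of the cell types involved. Strength is
#' the mean \eqn{-\log E} over the cell types where the TFBS was found. TFBS
#' whose mapped transcription-factor genes are themselves DE are flagged.
#'
#' @param hits Tibble with columns `tfbs`, `cell_type`, `e_value`, `carriers`
#'   (list-column of carrier gene ids).
#' @param tf_map Tibble with columns `tfbs`, `gene_id` mapping binding sites
#'   to transcription-factor genes.
#' @param de_sets Named list: cell type -> character vector of DE genes.
#' @return Tibble: `tfbs`, `gene_id`, `cell_type`, `strength`, `tf_gene_de`,
#'   `mapped`.
#' @export
tfbs_gene_network <- function(hits, tf_map, de_sets) {
  if (nrow(hits) == 0) {
    return(tibble(tfbs = character(), gene_id = character(),
                  cell_type = character(), strength = numeric(),
                  tf_gene_de = logical(), mapped = logical()))
  }
  strength <- hits %>%
    group_by(.data$tfbs) %>%
    summarise(strength = mean(-log(.data$e_value)), .groups = "drop")
  unmapped <- setdiff(unique(hits$tfbs), unique(tf_map$tfbs))
  if (length(unmapped) > 0) {
    warn(paste0("TFBS without a TF mapping: ", paste(unmapped, collapse = ", ")))
  }
  all_de <- unique(unlist(de_sets))
  rows <- pmap(hits[, c("tfbs", "cell_type", "carriers")],
               function(tfbs, cell_type, carriers) {
    genes <- intersect(carriers, de_sets[[cell_type]] %||% character())
    if (length(genes) == 0) return(NULL)
    tibble(tfbs = tfbs, gene_id = genes, cell_type = cell_type)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(tfbs = character(), gene_id = character(),
                  cell_type = character(), strength = numeric(),
                  tf_gene_de = logical(), mapped = logical()))
  }
  tf_de <- tf_map %>%
    group_by(.data$tfbs) %>%
    summarise(tf_gene_de = any(.data$gene_id %in% all_de), .groups = "drop")
  out %>%
    left_join(strength, by = "tfbs") %>%
    left_join(tf_de, by = "tfbs") %>%
    mutate(mapped = .data$tfbs %in% tf_map$tfbs,
           tf_gene_de = ifelse(is.na(.data$tf_gene_de), FALSE, .data$tf_gene_de))
}
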