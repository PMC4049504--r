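# Internal helpers.

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Derive a stream of child seeds from one seed (kept below 2^31).
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Project a symmetric matrix onto the PSD cone (eigenvalue floor).
psd_project <- function(m, floor = 0) {
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  vals <- pmax(e$values, floor)
  e$vectors %*% (vals * t(e$vectors))
}

# log density of a zero-mean multivariate normal for rows of x.
dmvnorm0_log <- function(x, sigma) {
  ch <- chol(sigma)
  z <- backsolve(ch, t(x), transpose = TRUE)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * ncol(x) * log(2 * pi)
}

# Numerically stable log(exp(a) + exp(b)).
logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  m + log(exp(a - m) + exp(b - m))
}

reverse_complement <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", x)
  out <- character(length(x))
  for (k in unique(nchar(comp))) {
    idx <- nchar(comp) == k
    cols <- lapply(k:1, function(j) substring(comp[idx], j, j))
    out[idx] <- do.call(paste0, cols)
  }
  out
}

IUPAC_MAP <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# area under the ROC curve of scores against binary labels
auc_score <- function(score, label) {
  stopifnot(length(score) == length(label))
  pos <- score[label]
  neg <- score[!label]
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

`%||%` <- rlang::`%||%`
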