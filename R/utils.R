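# Internal helpers shared across modules.

# Dense numeric matrix from possibly sparse input, preserving dimnames.
as_dense <- function(m) {
  if (inherits(m, "Matrix")) as.matrix(m) else as.matrix(m)
}

# Validate a cells-x-genes (or spots-x-genes) count matrix: non-negative,
# named rows (cells) and columns (genes).
check_count_matrix <- function(m, arg = "counts") {
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    abort(sprintf("`%s` must carry cell/spot rownames and gene colnames.", arg))
  }
  if (min(m) < 0) abort(sprintf("`%s` contains negative values.", arg))
  invisible(m)
}

# Blockwise k-nearest-neighbour indices under the L1 metric.
# Returns for each query row the index of the nearest reference row;
# ties broken by the lowest reference index (order of scanning).
l1_nearest <- function(query, ref, block = 256L) {
  nq <- nrow(query)
  idx <- integer(nq)
  d <- numeric(nq)
  for (start in seq(1L, nq, by = block)) {
    rows <- start:min(start + block - 1L, nq)
    # |q - r| summed over genes for each (query, ref) pair in the block
    dm <- vapply(seq_len(nrow(ref)), function(j) {
      rowSums(abs(sweep(query[rows, , drop = FALSE], 2L, ref[j, ], "-")))
    }, numeric(length(rows)))
    dm <- matrix(dm, nrow = length(rows))
    idx[rows] <- max.col(-dm, ties.method = "first")
    d[rows] <- dm[cbind(seq_along(rows), idx[rows])]
  }
  list(index = idx, distance = d)
}

# Vectorised two-sided Wilcoxon rank-sum z statistic with tie correction,
# group (rows in `in_group`) vs the rest, computed per column of `x`.
# Matches the normal-approximation form used by standard scanpy-style
# one-vs-all marker scoring.
ranksum_z <- function(x, in_group) {
  n1 <- sum(in_group)
  n2 <- sum(!in_group)
  n <- n1 + n2
  stopifnot(n1 > 0L, n2 > 0L)
  z <- vapply(seq_len(ncol(x)), function(j) {
    r <- rank(x[, j])
    r1 <- sum(r[in_group])
    mu <- n1 * (n + 1) / 2
    ties <- table(x[, j])
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) return(0)
    (r1 - mu) / sqrt(sigma2)
  }, numeric(1))
  names(z) <- colnames(x)
  z
}

# Mann-Whitney / rank-based AUC of scores for a binary label.
rank_auc <- function(scores, positive) {
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Draw a seed for an internal stage from a user seed, keeping within 32-bit.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset) * 7919L) %% 2147483647L
}
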