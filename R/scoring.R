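# Per-cell binned-background gene-set scoring and per-sample ssGSEA-style
# enrichment.

#' Score cells for a gene signature against binned controls
#'
#' The score of a cell is the mean normalized expression of the signature
#' genes minus the mean of a control set: for every signature gene,
#' `n_ctrl` control genes are sampled (with a fixed seed) from the same
#' mean-expression bin, so the comparison is against similarly expressed
#' genes rather than the whole transcriptome.
#'
#' @param expr Normalized cells x genes matrix.
#' @param signature Character vector of genes (those present are used; an
#'   empty intersection is an error).
#' @param n_bins Number of mean-expression bins (default 25).
#' @param n_ctrl Control genes sampled per signature gene (default 50).
#' @param seed Integer seed for control sampling.
#' @return Tibble `cell_id`, `score`.
#' @export
score_cells_binned <- function(expr, signature, n_bins = 25L, n_ctrl = 50L,
                               seed = 1L) {
  assert_normalized(expr)
  signature <- intersect(signature, colnames(expr))
  if (!length(signature)) abort("no signature gene present in the matrix.")
  withr::local_seed(seed)
  gene_means <- colMeans(expr)
  bins <- dplyr::ntile(rank(gene_means, ties.method = "first"), n_bins)
  names(bins) <- colnames(expr)
  ctrl <- unlist(lapply(signature, function(g) {
    pool <- names(bins)[bins == bins[[g]]]
    pool <- setdiff(pool, g)
    if (!length(pool)) return(character(0))
    sample(pool, min(n_ctrl, length(pool)))
  }), use.names = FALSE)
  sig_mean <- rowMeans(expr[, signature, drop = FALSE])
  ctrl_mean <- rowMeans(expr[, unique(ctrl), drop = FALSE])
  tibble::tibble(cell_id = rownames(expr), score = sig_mean - ctrl_mean)
}

# Single-sample enrichment of one gene set in one expression vector:
# rank-weighted running-sum statistic. Depends on the expression values only
# through their ranks, hence invariant to monotone transforms.
ssgsea_one <- function(v, genes, weight = 0.25) {
  n <- length(v)
  in_set <- names(v) %in% genes
  n_set <- sum(in_set)
  if (n_set == 0L || n_set == n) return(NA_real_)
  r <- rank(v, ties.method = "average")      # high expression = high rank
  ord <- order(r, decreasing = TRUE)
  in_set <- in_set[ord]
  w <- r[ord]^weight
  p_hit <- cumsum(ifelse(in_set, w, 0)) / sum(w[in_set])
  p_miss <- cumsum(!in_set) / (n - n_set)
  sum(p_hit - p_miss) / (n - n_set)
}

#' ssGSEA-style per-sample signature scores
#'
#' Computes a rank-weighted running-sum enrichment statistic for each
#' signature in each sample of a bulk expression matrix. Ranks are computed
#' per sample; the hit increment is the rank raised to `weight`, the miss
#' increment uniform, and the running-sum integral is normalized by the
#' number of non-signature genes, following the common single-sample GSEA
#' parameterization.
#'
#' @param expr Samples x genes expression matrix (any monotone scale).
#' @param signatures Named list of gene vectors, or a `signature_set`.
#' @param weight Rank-weight exponent (default 0.25).
#' @return Tibble `sample`, `signature`, `score`.
#' @export
score_samples_ssgsea <- function(expr, signatures, weight = 0.25) {
  if (is.data.frame(signatures)) {
    signatures <- split(signatures$gene, signatures$signature)
  }
  if (!length(signatures)) abort("no signatures given.")
  if (any(lengths(signatures) == 0L)) abort("empty signature supplied.")
  if (is.null(colnames(expr)) || is.null(rownames(expr))) {
    abort("`expr` needs sample rownames and gene colnames.")
  }
  purrr::map_dfr(rownames(expr), function(s) {
    v <- expr[s, ]
    tibble::tibble(sample = s, signature = names(signatures),
                   score = vapply(signatures, function(g) {
                     ssgsea_one(v, g, weight)
                   }, numeric(1)))
  })
}
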