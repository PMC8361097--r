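# Gene co-expression modules from pairwise Pearson correlation.

#' Detect gene co-expression modules
#'
#' Genes are first restricted to those differentially expressed anywhere in
#' the DE table (BH FDR at most `fdr` and |log2 FC| at least `min_abs_lfc`
#' in at least one group), then filtered by connectivity: a gene must have
#' at least `min_degree` partners with absolute Pearson correlation at or
#' above `min_abs_corr`. Surviving genes are clustered hierarchically on the
#' Euclidean distance between their correlation profiles and partitioned
#' into modules, either into `n_modules` groups or at the cut that
#' maximizes the mean silhouette width.
#'
#' @param expr Normalized cells x genes matrix.
#' @param de A `de_table`; set `NULL` to skip the DE pre-filter.
#' @param fdr,min_abs_lfc DE pre-filter thresholds (defaults 0.05, 0.3).
#' @param min_degree Minimum number of correlated partners (default 5).
#' @param min_abs_corr Absolute correlation defining a partner (default 0.4).
#' @param n_modules Optional fixed module count; when `NULL` the silhouette
#'   criterion chooses the cut over 2..`max_modules`.
#' @param max_modules Largest cut considered (default 10).
#' @param linkage Hierarchical linkage (default `"complete"`).
#' @return Tibble (`module_set`) with `module`, `gene` and
#'   `mean_intra_correlation`; empty (with a warning) when no gene survives.
#' @export
coexpression_modules <- function(expr, de = NULL, fdr = 0.05,
                                 min_abs_lfc = 0.3, min_degree = 5L,
                                 min_abs_corr = 0.4, n_modules = NULL,
                                 max_modules = 10L, linkage = "complete") {
  assert_normalized(expr)
  genes <- colnames(expr)
  if (!is.null(de)) {
    passing <- de |>
      dplyr::filter(.data$p_adj <= fdr, abs(.data$log2_fc) >= min_abs_lfc) |>
      dplyr::pull(.data$gene) |>
      unique()
    genes <- intersect(genes, passing)
  }
  empty <- tibble::tibble(module = character(0), gene = character(0),
                          mean_intra_correlation = numeric(0))
  class(empty) <- c("module_set", class(empty))
  if (length(genes) < 2L) {
    warn("no genes survive the DE filter; returning empty module set.")
    return(empty)
  }
  cm <- suppressWarnings(cor(expr[, genes, drop = FALSE]))
  cm[is.na(cm)] <- 0
  adj <- abs(cm) >= min_abs_corr
  diag(adj) <- FALSE
  degree <- rowSums(adj)
  keep <- degree >= min_degree
  if (sum(keep) < 2L) {
    warn("no genes survive the degree filter; returning empty module set.")
    return(empty)
  }
  cm <- cm[keep, keep, drop = FALSE]
  hc <- hclust(dist(cm), method = linkage)
  ks <- if (!is.null(n_modules)) {
    n_modules
  } else {
    2:min(max_modules, sum(keep) - 1L)
  }
  pick <- function(k) cutree(hc, k = k)
  assignment <- if (length(ks) == 1L) {
    pick(ks)
  } else {
    d <- dist(cm)
    sils <- vapply(ks, function(k) {
      mean(cluster::silhouette(pick(k), d)[, "sil_width"])
    }, numeric(1))
    pick(ks[which.max(sils)])
  }
  out <- tibble::tibble(module = sprintf("M%d", assignment),
                        gene = names(assignment)) |>
    dplyr::group_by(.data$module) |>
    dplyr::mutate(mean_intra_correlation = {
      g <- .data$gene
      block <- cm[g, g, drop = FALSE]
      if (length(g) > 1L) mean(block[upper.tri(block)]) else 1
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$module, .data$gene)
  class(out) <- c("module_set", class(out))
  out
}
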