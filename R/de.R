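# One-vs-all Wilcoxon rank-sum differential expression scoring.

#' Rank genes by one-vs-all Wilcoxon tests within a scope
#'
#' For each group, each gene is scored with the two-sided, tie-corrected
#' Wilcoxon rank-sum z statistic of the group's cells against all other
#' cells in scope, alongside the log2 fold change of expm1-ed group means
#' (with a small pseudocount) and the fraction of group cells expressing the
#' gene. Benjamini-Hochberg adjustment is applied within each group's gene
#' list. Groups with fewer than `min_cells` cells are excluded with a
#' warning.
#'
#' @param expr Normalized cells x genes matrix (see [normalize_log()]).
#' @param groups Character/factor vector of group labels, one per cell.
#' @param scope Optional logical or index vector restricting the background
#'   ("rest") and the tested cells to a subset (e.g. one compartment).
#' @param min_cells Minimum group size (default 3).
#' @param pseudocount Added inside the fold-change ratio (default 1e-9).
#' @param expm1_means Undo the log1p transform before averaging for the
#'   fold change (the convention for log-normalized expression). Set
#'   `FALSE` for matrices on a linear scale, e.g. receptor activities,
#'   where the fold change is the plain log2 ratio of group means.
#' @return Tibble (`de_table`) with columns `group`, `gene`, `score`,
#'   `log2_fc`, `p_value`, `p_adj`, `frac_expressing`.
#' @export
de_rank_genes <- function(expr, groups, scope = NULL, min_cells = 3L,
                          pseudocount = 1e-9, expm1_means = TRUE) {
  assert_normalized(expr)
  if (length(groups) != nrow(expr)) abort("one group label per cell required.")
  if (!is.null(scope)) {
    expr <- expr[scope, , drop = FALSE]
    groups <- groups[scope]
  }
  groups <- as.character(groups)
  sizes <- table(groups)
  if (length(sizes) < 2L) abort("at least two groups required within scope.")
  small <- names(sizes)[sizes < min_cells]
  if (length(small)) {
    warn(sprintf("excluding groups with fewer than %d cells: %s",
                 min_cells, paste(small, collapse = ", ")))
  }
  tested <- setdiff(names(sizes), small)
  res <- purrr::map_dfr(tested, function(g) {
    in_g <- groups == g
    z <- ranksum_z(expr, in_g)
    unlog <- if (expm1_means) expm1 else identity
    mean_in <- colMeans(unlog(expr[in_g, , drop = FALSE]))
    mean_out <- colMeans(unlog(expr[!in_g, , drop = FALSE]))
    lfc <- log2((mean_in + pseudocount) / (mean_out + pseudocount))
    p <- unname(2 * pnorm(-abs(z)))
    tibble::tibble(group = g, gene = colnames(expr), score = unname(z),
                   log2_fc = unname(lfc), p_value = p,
                   p_adj = p.adjust(p, method = "BH"),
                   frac_expressing = unname(colMeans(expr[in_g, , drop = FALSE] > 0)))
  })
  class(res) <- c("de_table", class(res))
  res
}
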