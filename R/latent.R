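# Latent-time transfer from normal epithelium to tumor cells.

#' Select genes correlated with latent time in normal cohorts
#'
#' Within each normal sample, genes are ranked by Pearson correlation
#' between normalized expression and latent time; the top `top_n` genes
#' with correlation at least `min_corr` are kept, and the per-sample lists
#' are unioned without duplicates. By default the threshold is applied to
#' the signed correlation (positively time-tracking genes); set
#' `use_absolute = TRUE` to select on |r|.
#'
#' @param cohorts List of normal cohorts; each element is a list with
#'   `expr` (normalized cells x genes matrix) and `latent_time` (numeric,
#'   one per cell).
#' @param top_n Per-sample cap (default 500).
#' @param min_corr Minimum correlation (default 0.3).
#' @param use_absolute Select on absolute correlation instead of signed.
#' @return Character vector of genes (empty, with a warning, when nothing
#'   passes).
#' @export
select_latent_genes <- function(cohorts, top_n = 500L, min_corr = 0.3,
                                use_absolute = FALSE) {
  picks <- lapply(cohorts, function(co) {
    assert_normalized(co$expr)
    r <- suppressWarnings(cor(co$expr, co$latent_time))[, 1]
    r[is.na(r)] <- 0
    stat <- if (use_absolute) abs(r) else r
    passing <- stat[stat >= min_corr]
    names(sort(passing, decreasing = TRUE))[seq_len(min(top_n, length(passing)))]
  })
  genes <- unique(unlist(picks, use.names = FALSE))
  if (!length(genes)) warn("no gene reaches the correlation threshold.")
  genes
}

#' Transfer latent time to tumor cells by L1 nearest normal neighbor
#'
#' Each tumor cell inherits the latent time of the normal cell minimizing
#' the L1 (sum of absolute differences) distance of normalized expression
#' over the latent gene list. Ties are broken by the lowest normal-cell
#' index. Genes absent from either matrix are dropped with a message;
#' inherited times therefore always lie within the normal cohort's observed
#' range.
#'
#' @param tumor_expr,normal_expr Normalized cells x genes matrices.
#' @param normal_times Numeric latent time per normal cell.
#' @param genes Latent gene list (see [select_latent_genes()]).
#' @return Tibble (`latent_annotation`): `cell_id`, `latent_time`, `source`
#'   (`"inherited"`), `nearest_normal`, `l1_distance`.
#' @export
transfer_latent_time <- function(tumor_expr, normal_expr, normal_times,
                                 genes) {
  assert_normalized(tumor_expr, "tumor_expr")
  assert_normalized(normal_expr, "normal_expr")
  if (!length(genes)) abort("empty latent gene list.")
  shared <- intersect(intersect(genes, colnames(tumor_expr)),
                      colnames(normal_expr))
  if (!length(shared)) abort("gene list disjoint from one of the matrices.")
  dropped <- length(genes) - length(shared)
  if (dropped > 0L) {
    rlang::inform(sprintf("dropping %d latent genes absent from a matrix.",
                          dropped))
  }
  nn <- l1_nearest(as_dense(tumor_expr[, shared, drop = FALSE]),
                   as_dense(normal_expr[, shared, drop = FALSE]))
  tibble::tibble(cell_id = rownames(tumor_expr),
                 latent_time = normal_times[nn$index],
                 source = "inherited",
                 nearest_normal = rownames(normal_expr)[nn$index],
                 l1_distance = nn$distance)
}

#' Interval signatures along inherited latent time
#'
#' Bins tumor cells into `n_intervals` equal-width intervals over the
#' observed latent-time range (the last interval right-closed), runs
#' one-vs-all DE between intervals, and takes disjoint top-`top_n`
#' signatures per interval; a gene reaching several intervals' top lists is
#' assigned to the interval with the higher DE score. Empty intervals are
#' reported with a warning.
#'
#' @param expr Normalized tumor cells x genes matrix.
#' @param latent_time Inherited latent time, one per cell.
#' @param n_intervals Number of bins (default 5).
#' @param top_n Signature cap (default 200).
#' @return List with `signatures` (a `signature_set` whose names are
#'   `interval_1` ...) and `intervals` (tibble `cell_id`, `interval`).
#' @export
interval_signatures <- function(expr, latent_time, n_intervals = 5L,
                                top_n = 200L) {
  assert_normalized(expr)
  if (length(latent_time) != nrow(expr)) abort("one time per cell required.")
  rng <- range(latent_time)
  if (rng[1] == rng[2]) {
    warn("all cells at a single latent time; one occupied interval.")
    breaks <- c(rng[1] - 0.5, rng[1] + 0.5)
    idx <- rep(1L, length(latent_time))
  } else {
    breaks <- seq(rng[1], rng[2], length.out = n_intervals + 1L)
    idx <- pmin(findInterval(latent_time, breaks, rightmost.closed = TRUE),
                n_intervals)
  }
  interval <- sprintf("interval_%d", idx)
  empty <- setdiff(sprintf("interval_%d", seq_len(n_intervals)), interval)
  if (length(empty)) {
    warn(sprintf("empty latent-time intervals: %s",
                 paste(empty, collapse = ", ")))
  }
  if (length(unique(interval)) < 2L) {
    sigs <- tibble::tibble(signature = character(0), gene = character(0),
                           score = numeric(0))
    class(sigs) <- c("signature_set", class(sigs))
  } else {
    de <- de_rank_genes(expr, interval)
    sigs <- derive_subtype_signatures(de, top_n = top_n)
  }
  list(signatures = sigs,
       intervals = tibble::tibble(cell_id = rownames(expr),
                                  interval = interval))
}
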