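# QC filters and hashtag-demultiplexing recovery.

#' QC thresholds for nuclei and spot filtering
#'
#' @param max_mito_fraction Nuclei with *more than* this fraction of UMIs on
#'   mitochondrial genes are removed (default 0.10).
#' @param extreme_percentile Tail mass removed from each end of the
#'   unique-gene and total-UMI distributions (default 0.05).
#' @param min_spot_umi Spots must reach *at least* this many total UMIs
#'   (default 1250).
#' @param min_spots_per_gene Genes must be detected (UMI > 0) in at least
#'   this many surviving spots (default 4).
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(max_mito_fraction = 0.10, extreme_percentile = 0.05,
                          min_spot_umi = 1250L, min_spots_per_gene = 4L) {
  if (max_mito_fraction <= 0 || max_mito_fraction >= 1 ||
      extreme_percentile <= 0 || extreme_percentile >= 0.5) {
    abort("fractions must lie in (0, 1) (percentile below 0.5).")
  }
  if (min_spot_umi < 0 || min_spots_per_gene < 0) {
    abort("count thresholds must be non-negative.")
  }
  structure(list(max_mito_fraction = max_mito_fraction,
                 extreme_percentile = extreme_percentile,
                 min_spot_umi = as.integer(min_spot_umi),
                 min_spots_per_gene = as.integer(min_spots_per_gene)),
            class = "qc_thresholds")
}

#' Recover single-hashtag cells from initial negative calls
#'
#' Cells whose initial demultiplexing call is `negative` but whose counts
#' exceed the per-hashtag minimum for exactly one hashtag are reassigned to
#' that hashtag. Initial doublets and negatives that pass the threshold for
#' zero or for two or more hashtags are flagged `removed`; initial singlets
#' pass through unchanged.
#'
#' @param hto Tibble with `cell_id`, one count column per hashtag, and an
#'   `initial_call` column (`"doublet"`, `"negative"` or a hashtag name).
#' @param thresholds Named positive integer vector, one minimum count per
#'   hashtag column.
#' @return Tibble `cell_id`, `initial_call`, `final_call` (hashtag name or
#'   `"removed"`), `recovered` (logical).
#' @export
#' @examples
#' hto <- tibble::tibble(cell_id = "c1", HTO1 = 120, HTO2 = 3,
#'                       initial_call = "negative")
#' demux_recover(hto, c(HTO1 = 100, HTO2 = 100))
demux_recover <- function(hto, thresholds) {
  tags <- names(thresholds)
  if (is.null(tags) || any(thresholds <= 0)) {
    abort("`thresholds` must be a named vector of positive minimum counts.")
  }
  missing <- setdiff(tags, names(hto))
  if (length(missing)) {
    abort(sprintf("HTO table lacks count columns: %s.",
                  paste(missing, collapse = ", ")))
  }
  if (!"initial_call" %in% names(hto)) abort("`initial_call` column required.")
  tag_cols <- setdiff(names(hto), c("cell_id", "initial_call", "true_class"))
  unthresholded <- setdiff(tag_cols, tags)
  if (length(unthresholded)) {
    abort(sprintf("missing threshold for hashtag(s): %s.",
                  paste(unthresholded, collapse = ", ")))
  }
  counts <- as.matrix(hto[, tags, drop = FALSE])
  passes <- sweep(counts, 2L, thresholds, ">")
  n_pass <- rowSums(passes)
  final <- hto$initial_call
  recovered <- rep(FALSE, nrow(hto))
  neg <- hto$initial_call == "negative"
  rec <- neg & n_pass == 1L
  final[rec] <- tags[max.col(passes[rec, , drop = FALSE], ties.method = "first")]
  recovered[rec] <- TRUE
  final[neg & !rec] <- "removed"
  final[hto$initial_call == "doublet"] <- "removed"
  tibble::tibble(cell_id = hto$cell_id, initial_call = hto$initial_call,
                 final_call = final, recovered = recovered)
}

#' Filter nuclei by mitochondrial fraction and expression extremes
#'
#' Applies, in order: (1) removal of cells whose mitochondrial UMI fraction
#' exceeds `max_mito_fraction` (a cell at exactly the threshold is kept);
#' then, on the survivors jointly, (2) removal of cells in the top or bottom
#' `extreme_percentile` of unique-gene count and of total UMI. Cells exactly
#' at a percentile boundary are retained.
#'
#' @param counts Cells x genes count matrix (raw counts).
#' @param mito_genes Character vector of mitochondrial gene names (must be a
#'   subset of the matrix genes).
#' @param thresholds A [qc_thresholds()].
#' @return List with `counts` (filtered matrix) and `log`, a tibble of
#'   removed cells and the rule that fired (`mito`, `genes_low`,
#'   `genes_high`, `umi_low`, `umi_high`).
#' @export
qc_filter_nuclei <- function(counts, mito_genes, thresholds = qc_thresholds()) {
  if (nrow(counts) == 0L) abort("empty count matrix.")
  check_count_matrix(counts)
  if (!all(mito_genes %in% colnames(counts))) {
    abort("`mito_genes` must all be present in the matrix.")
  }
  total <- Matrix::rowSums(counts)
  mito <- Matrix::rowSums(counts[, mito_genes, drop = FALSE])
  frac <- ifelse(total > 0, mito / total, 0)
  n_genes <- Matrix::rowSums(counts > 0)

  rules <- vector("list", nrow(counts))
  mito_out <- frac > thresholds$max_mito_fraction
  for (i in which(mito_out)) rules[[i]] <- "mito"

  keep <- !mito_out
  p <- thresholds$extreme_percentile
  bounds <- function(v) quantile(v, c(p, 1 - p), names = FALSE, type = 7)
  gb <- bounds(n_genes[keep])
  ub <- bounds(total[keep])
  add_rule <- function(idx, rule) {
    for (i in idx) rules[[i]] <<- c(rules[[i]], rule)
  }
  add_rule(which(keep & n_genes < gb[1]), "genes_low")
  add_rule(which(keep & n_genes > gb[2]), "genes_high")
  add_rule(which(keep & total < ub[1]), "umi_low")
  add_rule(which(keep & total > ub[2]), "umi_high")

  removed <- which(!vapply(rules, is.null, logical(1)))
  log <- tibble::tibble(
    cell_id = rownames(counts)[removed],
    rule = vapply(rules[removed], paste, character(1), collapse = ";"))
  keep_idx <- setdiff(seq_len(nrow(counts)), removed)
  list(counts = counts[keep_idx, , drop = FALSE], log = log)
}

#' Filter spatial spots and low-prevalence genes
#'
#' Keeps spots with total UMI at least `min_spot_umi` and mitochondrial
#' fraction strictly below `max_mito_fraction`, then drops genes detected
#' (UMI > 0) in fewer than `min_spots_per_gene` surviving spots.
#'
#' @param sf A `spot_frame`.
#' @param mito_genes Mitochondrial gene names (those present are used).
#' @param thresholds A [qc_thresholds()].
#' @return The filtered `spot_frame`.
#' @export
qc_filter_spots <- function(sf, mito_genes = character(0),
                            thresholds = qc_thresholds()) {
  if (!inherits(sf, "spot_frame")) abort("`sf` must be a spot_frame.")
  if (nrow(sf$counts) == 0L) abort("empty spot frame.")
  counts <- sf$counts
  total <- Matrix::rowSums(counts)
  mito_genes <- intersect(mito_genes, colnames(counts))
  mito <- if (length(mito_genes)) {
    Matrix::rowSums(counts[, mito_genes, drop = FALSE])
  } else rep(0, nrow(counts))
  frac <- ifelse(total > 0, mito / total, 0)
  keep_spot <- total >= thresholds$min_spot_umi &
    frac < thresholds$max_mito_fraction
  counts <- counts[keep_spot, , drop = FALSE]
  prevalence <- Matrix::colSums(counts > 0)
  keep_gene <- prevalence >= thresholds$min_spots_per_gene
  new_spot_frame(counts[, keep_gene, drop = FALSE],
                 sf$spots[keep_spot, , drop = FALSE], sample = sf$sample)
}
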