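# Subtype signature derivation with cross-signature tie-breaking.

#' Derive disjoint top-N subtype signatures from a DE table
#'
#' Takes, for every group, the `top_n` up-regulated genes ranked by the
#' rank-sum score. A gene reaching several groups' top lists is assigned
#' only to the group in which its score is highest, so signatures within a
#' compartment are disjoint. Genes with non-positive scores never enter a
#' signature; groups with fewer than `top_n` positive-score genes yield
#' shorter signatures.
#'
#' @param de A `de_table` from [de_rank_genes()].
#' @param top_n Maximum signature length (default 200).
#' @return Tibble (`signature_set`) with `signature`, `gene`, `score`,
#'   ordered by decreasing score within each signature.
#' @export
derive_subtype_signatures <- function(de, top_n = 200L) {
  top <- de |>
    dplyr::filter(.data$score > 0) |>
    dplyr::group_by(.data$group) |>
    dplyr::slice_max(.data$score, n = top_n, with_ties = FALSE) |>
    dplyr::ungroup()
  # cross-list tie-break: keep each gene only where its score is highest
  out <- top |>
    dplyr::group_by(.data$gene) |>
    dplyr::slice_max(.data$score, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::transmute(signature = .data$group, gene = .data$gene,
                     score = .data$score) |>
    dplyr::arrange(.data$signature, dplyr::desc(.data$score))
  class(out) <- c("signature_set", class(out))
  out
}

#' Quartile stratification of sample scores
#'
#' Assigns each sample to a score quartile (Q1 lowest to Q4 highest) by the
#' empirical quartiles of the score vector; samples exactly at a boundary go
#' to the lower quartile, and exact ties are kept in stable input order. A
#' constant score vector yields all-Q1 with a warning.
#'
#' @param scores Data frame with a `score` column (and any id columns), or a
#'   bare numeric vector.
#' @return Input tibble with a `quartile` factor column added.
#' @export
quartile_stratify <- function(scores) {
  if (is.numeric(scores)) scores <- tibble::tibble(score = scores)
  v <- scores$score
  if (length(unique(v)) == 1L) {
    warn("constant scores: all samples assigned to Q1.")
    scores$quartile <- factor("Q1", levels = paste0("Q", 1:4))
    return(tibble::as_tibble(scores))
  }
  q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  lab <- cut(v, breaks = c(-Inf, q, Inf), labels = paste0("Q", 1:4),
             right = TRUE)
  scores$quartile <- lab
  tibble::as_tibble(scores)
}
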