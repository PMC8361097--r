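# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a niche-detection result
#'
#' One row per niche with its label, size and centroid composition in long
#' form.
#'
#' @param x A `niche_result`.
#' @param ... Unused.
#' @return Tibble `niche`, `label`, `n_cells`, `broad`, `fraction`.
#' @export
tidy.niche_result <- function(x, ...) {
  tibble::as_tibble(x$centroids, rownames = "niche") |>
    tidyr::pivot_longer(-"niche", names_to = "broad", values_to = "fraction") |>
    dplyr::mutate(broad = sub("^frac_", "", .data$broad)) |>
    dplyr::left_join(x$niches[, c("niche", "label", "n_cells")], by = "niche") |>
    dplyr::relocate("niche", "label", "n_cells")
}

#' @rdname tidy.niche_result
#' @return For `glance`: one row with `k`, `n_cells`, `mean_entropy`.
#' @export
glance.niche_result <- function(x, ...) {
  tibble::tibble(k = x$k, n_cells = nrow(x$assignment),
                 n_niches = nrow(x$niches))
}

#' Tidy an AUC-vs-k curve
#'
#' @param x An `auc_curve` from [select_k_niches()].
#' @param ... Unused.
#' @return The underlying tibble.
#' @export
tidy.auc_curve <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("k", "mean_auc")])
}

#' @rdname tidy.auc_curve
#' @return For `glance`: `best_k` (highest mean AUC) and its AUC.
#' @export
glance.auc_curve <- function(x, ...) {
  best <- which.max(x$mean_auc)
  tibble::tibble(best_k = x$k[best], best_auc = x$mean_auc[best])
}
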