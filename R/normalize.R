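#' Library-size normalize and log-transform a count matrix
#'
#' Scales every cell (row) to a common library size of `scale_factor` total
#' counts, then applies `log(1 + x)` (natural log). The result carries a
#' `normalized` attribute; passing an already-normalized matrix returns it
#' unchanged with a warning, so the transform cannot be applied twice.
#'
#' @param counts Cells x genes count matrix (dense or sparse).
#' @param scale_factor Common library size (default 10,000; the CP10K
#'   convention).
#' @return Dense numeric matrix of normalized log expression with
#'   `attr(, "normalized") = TRUE`.
#' @export
#' @examples
#' m <- matrix(c(1, 1, 2, 2), 2, 2, dimnames = list(c("a", "b"), c("g1", "g2")))
#' normalize_log(m)
normalize_log <- function(counts, scale_factor = 1e4) {
  if (isTRUE(attr(counts, "normalized"))) {
    warn("matrix already normalized; returning unchanged.")
    return(counts)
  }
  check_count_matrix(counts)
  m <- as_dense(counts)
  lib <- pmax(rowSums(m), 1)
  out <- log1p(m / lib * scale_factor)
  attr(out, "normalized") <- TRUE
  out
}

assert_normalized <- function(m, arg = "expr") {
  if (!isTRUE(attr(m, "normalized"))) {
    abort(sprintf("`%s` must be normalized (see normalize_log()).", arg))
  }
  invisible(m)
}
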