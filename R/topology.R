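# Hexagonal-grid ring neighborhoods and concurrence testing.

#' Ring coordinates around a reference spot
#'
#' Returns the six array-coordinate offsets of ring index `k` around
#' `(x, y)`:
#' `(x-(k+1), y+(k+1))`, `(x-(k+1), y-(k+1))`, `(x, y+(k+2))`,
#' `(x, y-(k+2))`, `(x+(k+1), y+(k+1))`, `(x+(k+1), y-(k+1))`.
#' At `k = 0` these are the six immediate hexagonal neighbors. For `k >= 1`
#' the two axial positions `(x, y +/- (k+2))` leave the constant-parity
#' lattice whenever `k` is odd; positions that cannot exist on a given grid
#' are reported so callers can mark them missing rather than zero-filling.
#' The full hexagonal ring of `6(k+1)` spots is available with
#' `full_ring = TRUE`.
#'
#' @param x,y Integer array coordinates of the reference spot.
#' @param k Ring index (0 = immediate neighbors).
#' @param full_ring Emit the complete hexagonal ring instead of the six
#'   printed axial positions.
#' @return Tibble with `x`, `y` and `parity_ok` (FALSE where the offset
#'   violates the array's parity rule relative to the reference).
#' @export
#' @examples
#' hex_ring(10, 10, k = 0)
hex_ring <- function(x, y, k = 0L, full_ring = FALSE) {
  if (k < 0L) abort("`k` must be non-negative.")
  if (full_ring) {
    r <- k + 1L
    # walk the hexagon perimeter in doubled-y array coordinates
    dirs <- matrix(c(1L, -1L, 0L, -2L, -1L, -1L, -1L, 1L, 0L, 2L, 1L, 1L),
                   ncol = 2L, byrow = TRUE)
    pos <- matrix(NA_integer_, 6L * r, 2L)
    cur <- c(x, y + 2L * r)
    i <- 0L
    for (d in seq_len(6L)) {
      for (step in seq_len(r)) {
        i <- i + 1L
        pos[i, ] <- cur
        cur <- cur + dirs[d, ]
      }
    }
    out <- tibble::tibble(x = pos[, 1], y = pos[, 2])
  } else {
    out <- tibble::tibble(
      x = c(x - (k + 1L), x - (k + 1L), x, x, x + (k + 1L), x + (k + 1L)),
      y = c(y + (k + 1L), y - (k + 1L), y + (k + 2L), y - (k + 2L),
            y + (k + 1L), y - (k + 1L)))
  }
  out$parity_ok <- (out$x + out$y) %% 2L == (x + y) %% 2L
  out
}

#' Reference spots: top percentile of a module score
#'
#' @param scores Tibble with `spot_id` and `score` (e.g. a module score per
#'   spot).
#' @param top_pct Percentage defining the reference set (default 5): spots
#'   with score at or above the `100 - top_pct` percentile. Ties at the
#'   cutoff are included.
#' @return Character vector of reference spot ids.
#' @export
reference_spots <- function(scores, top_pct = 5) {
  v <- scores$score
  if (length(unique(v)) == 1L) {
    warn("constant module score: every spot ties at the cutoff.")
  }
  cutoff <- quantile(v, 1 - top_pct / 100, names = FALSE, type = 7)
  scores$spot_id[v >= cutoff]
}

#' Mean expression by ring index around reference spots
#'
#' For each ring index `k = 0..max_k` the log-normalized expression of
#' `gene` is averaged over the ring spots that exist on the grid, then over
#' all reference spots; off-grid or parity-violating ring positions are
#' excluded from the mean (never zero-filled).
#'
#' @param sf A `spot_frame` with log-normalized expression available via
#'   `expr` (pass a normalized matrix) or computed from counts.
#' @param references Reference spot ids (see [reference_spots()]).
#' @param gene Gene to profile.
#' @param max_k Largest ring index.
#' @param expr Optional normalized spots x genes matrix; defaults to
#'   [normalize_log()] of the frame's counts.
#' @param full_ring Use complete hexagonal rings instead of the six axial
#'   positions.
#' @return Tibble (`ring_profile`): `k`, `mean_expr`, `n_spots` (existing
#'   ring spots summed over references), `n_missing`.
#' @export
ring_profile <- function(sf, references, gene, max_k = 3L, expr = NULL,
                         full_ring = FALSE) {
  if (is.null(expr)) expr <- normalize_log(sf$counts)
  if (!gene %in% colnames(expr)) abort(sprintf("gene '%s' absent.", gene))
  key <- paste(sf$spots$x, sf$spots$y)
  lookup <- setNames(seq_along(key), key)
  ref_rows <- match(references, sf$spots$spot_id)
  if (anyNA(ref_rows)) abort("unknown reference spot id.")
  purrr::map_dfr(0:max_k, function(k) {
    per_ref <- vapply(ref_rows, function(i) {
      ring <- hex_ring(sf$spots$x[i], sf$spots$y[i], k, full_ring = full_ring)
      idx <- lookup[paste(ring$x, ring$y)]
      idx <- idx[!is.na(idx)]
      c(mean = if (length(idx)) mean(expr[idx, gene]) else NA_real_,
        n = length(idx), miss = nrow(ring) - length(idx))
    }, numeric(3))
    tibble::tibble(k = k,
                   mean_expr = mean(per_ref["mean", ], na.rm = TRUE),
                   n_spots = sum(per_ref["n", ]),
                   n_missing = sum(per_ref["miss", ]))
  })
}

#' Ring profiles for several modules, standardized across modules
#'
#' Computes [ring_profile()] for one gene around each module's reference
#' spots and z-scores the mean-expression profile across modules at each
#' ring index, giving the display form in which a gene's spatial
#' concentration around one module stands out against the others.
#'
#' @param sf A `spot_frame`.
#' @param module_refs Named list: module -> reference spot ids.
#' @param gene Gene to profile.
#' @param max_k,expr,full_ring As in [ring_profile()].
#' @return Tibble `module`, `k`, `mean_expr`, `z`.
#' @export
ring_profile_matrix <- function(sf, module_refs, gene, max_k = 3L,
                                expr = NULL, full_ring = FALSE) {
  if (is.null(expr)) expr <- normalize_log(sf$counts)
  prof <- purrr::imap_dfr(module_refs, function(refs, module) {
    dplyr::mutate(ring_profile(sf, refs, gene, max_k, expr = expr,
                               full_ring = full_ring),
                  module = module)
  })
  prof |>
    dplyr::group_by(.data$k) |>
    dplyr::mutate(z = if (dplyr::n() > 1L && sd(.data$mean_expr) > 0) {
      (.data$mean_expr - mean(.data$mean_expr)) / sd(.data$mean_expr)
    } else 0) |>
    dplyr::ungroup() |>
    dplyr::select("module", "k", "mean_expr", "z")
}

#' Concurrence of module score and gene expression
#'
#' Stratifies spots into the top 5% and bottom 5% of the module score,
#' classifies each spot's expression of `gene` as top-5% versus bottom-95%
#' over all spots, and tests enrichment of high expression among
#' high-score spots with a one-sided Fisher exact test.
#'
#' @param scores Tibble `spot_id`, `score` for every spot.
#' @param expr_values Named numeric vector of the gene's expression per
#'   spot (names = spot ids).
#' @param score_pct,expr_pct Stratum percentages (defaults 5). Ties at
#'   either cutoff fall in the top stratum.
#' @return Tibble with `odds_ratio`, `p_value` and the 2x2 table counts
#'   (`hi_hi`, `hi_lo`, `lo_hi`, `lo_lo`).
#' @export
concurrence_test <- function(scores, expr_values, score_pct = 5,
                             expr_pct = 5) {
  v <- scores$score
  hi_cut <- quantile(v, 1 - score_pct / 100, names = FALSE)
  lo_cut <- quantile(v, score_pct / 100, names = FALSE)
  top <- scores$spot_id[v >= hi_cut]
  bottom <- scores$spot_id[v <= lo_cut & v < hi_cut]
  e_cut <- quantile(expr_values, 1 - expr_pct / 100, names = FALSE)
  expr_hi <- names(expr_values)[expr_values >= e_cut]
  tab <- matrix(c(sum(top %in% expr_hi), sum(!top %in% expr_hi),
                  sum(bottom %in% expr_hi), sum(!bottom %in% expr_hi)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(score = c("top", "bottom"),
                                expr = c("hi", "lo")))
  ft <- fisher.test(tab, alternative = "greater")
  tibble::tibble(odds_ratio = unname(ft$estimate), p_value = ft$p.value,
                 hi_hi = tab[1, 1], hi_lo = tab[1, 2],
                 lo_hi = tab[2, 1], lo_lo = tab[2, 2])
}
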