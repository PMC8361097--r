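# Multi-phase cell typing for multiplexed imaging: declarative gating,
# class balancing, kNN classification and a voting rescue pass.

#' Build a gated training set from declarative intensity rules
#'
#' Gate rules are applied conjunctively per class: a cell enters a class
#' when it satisfies every rule of that class. Cells matching several
#' classes are excluded as ambiguous.
#'
#' @param cells Tibble of cells with intensity / ring-percentage columns.
#' @param gates Named list (class -> list of rules); each rule is a list
#'   with `feature`, `op` (one of `">="`, `"<="`, `">"`, `"<"`), `value`.
#' @return `cells` rows that gate uniquely, with a `gated_class` column.
#' @export
gate_training_set <- function(cells, gates) {
  if (!length(gates)) abort("no gates supplied.")
  hit <- vapply(gates, function(rules) {
    ok <- rep(TRUE, nrow(cells))
    for (r in rules) {
      v <- cells[[r$feature]]
      if (is.null(v)) abort(sprintf("unknown gate feature '%s'.", r$feature))
      ok <- ok & switch(r$op,
                        ">=" = v >= r$value, "<=" = v <= r$value,
                        ">" = v > r$value, "<" = v < r$value,
                        abort(sprintf("unknown gate op '%s'.", r$op)))
    }
    ok
  }, logical(nrow(cells)))
  hit <- matrix(hit, nrow = nrow(cells),
                dimnames = list(NULL, names(gates)))
  n_hit <- rowSums(hit)
  empty <- names(gates)[colSums(hit & n_hit == 1L) == 0L]
  if (length(empty)) {
    warn(sprintf("gates yield no unambiguous cells for: %s",
                 paste(empty, collapse = ", ")))
  }
  keep <- n_hit == 1L
  out <- cells[keep, , drop = FALSE]
  out$gated_class <- colnames(hit)[max.col(hit[keep, , drop = FALSE],
                                           ties.method = "first")]
  tibble::as_tibble(out)
}

#' Balance training classes by uniform subsampling
#'
#' Classes larger than `cap` are uniformly subsampled down to `cap`;
#' smaller classes are kept whole.
#'
#' @param cells Tibble with a class column.
#' @param class_col Name of the class column (default `"gated_class"`).
#' @param cap Per-class ceiling (default 2500).
#' @param seed Integer seed.
#' @return Balanced tibble.
#' @export
balance_classes <- function(cells, class_col = "gated_class", cap = 2500L,
                            seed = 1L) {
  withr::local_seed(seed)
  cells |>
    dplyr::group_by(.data[[class_col]]) |>
    dplyr::group_modify(function(rows, key) {
      if (nrow(rows) > cap) dplyr::slice_sample(rows, n = cap) else rows
    }) |>
    dplyr::ungroup()
}

# Robust (median/IQR) scaling fitted on the training block; constant
# features pass through unscaled.
robust_scale_fit <- function(x) {
  med <- apply(x, 2L, median)
  iqr <- apply(x, 2L, stats::IQR)
  iqr[iqr == 0] <- 1
  list(center = med, scale = iqr)
}

robust_scale_apply <- function(x, fit) {
  sweep(sweep(x, 2L, fit$center, "-"), 2L, fit$scale, "/")
}

#' kNN cell-type classification with robust-scaled features
#'
#' Features are robust-scaled (per-feature median/IQR fitted on the
#' training cells), queries are assigned the modal label among their `k`
#' Euclidean nearest training cells with uniform weighting, and label-order
#' tie-breaking makes the vote deterministic.
#'
#' @param training Tibble with feature columns and a label column.
#' @param query Tibble with the same feature columns.
#' @param features Character vector of feature column names.
#' @param k Number of neighbors (200 for broad typing, 100 for T-cell
#'   subsets by convention).
#' @param label_col Label column in `training` (default `"gated_class"`).
#' @return Character vector of predicted labels, one per query row.
#' @export
knn_classify <- function(training, query, features, k = 200L,
                         label_col = "gated_class") {
  k <- min(k, nrow(training))
  tr <- as.matrix(training[, features, drop = FALSE])
  qu <- as.matrix(query[, features, drop = FALSE])
  fit <- robust_scale_fit(tr)
  tr <- robust_scale_apply(tr, fit)
  qu <- robust_scale_apply(qu, fit)
  labels <- training[[label_col]]
  level_order <- sort(unique(labels))
  nn <- FNN::get.knnx(tr, qu, k = k)
  apply(nn$nn.index, 1L, function(idx) {
    votes <- table(factor(labels[idx], levels = level_order))
    level_order[which.max(votes)]
  })
}

#' Rescue-classify unresolved cells by repeated subsampled kNN voting
#'
#' Runs `rounds` classification rounds; each round draws up to `per_class`
#' training cells per subtype and applies [knn_classify()] with `k`
#' neighbors. A cell receives the most frequent label across rounds
#' (label-order tie-break). Cells whose winning label belongs to
#' `reject_classes` (immune subtypes, by the study's convention) are
#' flagged removed rather than relabeled.
#'
#' @param unresolved Tibble of query cells.
#' @param pool Tibble of labeled cells to draw training rounds from.
#' @param features Feature columns.
#' @param label_col Label column in `pool`.
#' @param rounds,per_class,k Voting parameters (defaults 10, 500, 20).
#' @param reject_classes Labels that invalidate a rescue.
#' @param seed Integer seed.
#' @return Tibble `label` (winning label or `NA` when rejected), `removed`
#'   (logical), `votes` (list-column of per-round labels).
#' @export
rescue_classify <- function(unresolved, pool, features,
                            label_col = "gated_class", rounds = 10L,
                            per_class = 500L, k = 20L,
                            reject_classes = character(0), seed = 1L) {
  ballots <- matrix(NA_character_, nrow(unresolved), rounds)
  for (r in seq_len(rounds)) {
    train <- balance_classes(pool, class_col = label_col, cap = per_class,
                             seed = derive_seed(seed, r))
    ballots[, r] <- knn_classify(train, unresolved, features, k = k,
                                 label_col = label_col)
  }
  level_order <- sort(unique(pool[[label_col]]))
  label <- apply(ballots, 1L, function(v) {
    votes <- table(factor(v, levels = level_order))
    level_order[which.max(votes)]
  })
  removed <- label %in% reject_classes
  tibble::tibble(label = ifelse(removed, NA_character_, label),
                 removed = removed,
                 votes = lapply(seq_len(nrow(ballots)), function(i) ballots[i, ]))
}
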