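# Cellular-niche detection from spatial neighborhood composition profiles,
# with diversity, enrichment and proximity statistics.

#' Neighborhood composition profiles
#'
#' For every cell, takes up to `k` nearest cells (Euclidean, within the
#' same spot/core) no farther than `max_dist`, includes the reference
#' cell's own type, and tallies the fraction of each broad type among this
#' neighborhood. Profiles always sum to 1; an isolated cell's profile is
#' 100% its own type.
#'
#' @param cells Tibble with `cell_id`, `spot_id`, `x`, `y`, `broad`.
#' @param k Number of neighbors (default 10).
#' @param max_dist Maximum neighbor distance, image coordinate units
#'   (default 200).
#' @return Tibble with `cell_id`, `spot_id`, `n_neighbors`, and one
#'   fraction column per broad type (prefixed `frac_`).
#' @export
neighborhood_profiles <- function(cells, k = 10L, max_dist = 200) {
  types <- sort(unique(cells$broad))
  out <- cells |>
    dplyr::group_by(.data$spot_id) |>
    dplyr::group_modify(function(rows, key) {
      xy <- as.matrix(rows[, c("x", "y")])
      kk <- min(k, nrow(rows) - 1L)
      counts <- matrix(0L, nrow(rows), length(types),
                       dimnames = list(NULL, types))
      counts[cbind(seq_len(nrow(rows)), match(rows$broad, types))] <- 1L
      n_nb <- integer(nrow(rows))
      if (kk > 0L) {
        nn <- FNN::get.knn(xy, k = kk)
        for (i in seq_len(nrow(rows))) {
          nb <- nn$nn.index[i, nn$nn.dist[i, ] <= max_dist]
          n_nb[i] <- length(nb)
          for (j in nb) {
            tj <- match(rows$broad[j], types)
            counts[i, tj] <- counts[i, tj] + 1L
          }
        }
      }
      frac <- counts / rowSums(counts)
      colnames(frac) <- paste0("frac_", types)
      dplyr::bind_cols(rows["cell_id"], tibble::as_tibble(frac),
                       tibble::tibble(n_neighbors = n_nb))
    }) |>
    dplyr::ungroup()
  dplyr::relocate(out, "cell_id", "spot_id")
}

profile_matrix <- function(profiles) {
  as.matrix(profiles[, grep("^frac_", names(profiles)), drop = FALSE])
}

# One 1-vs-all ridge-logistic classifier per cluster on a half split;
# rank-based AUC on the holdout. Returns the mean AUC over clusters.
cluster_auc <- function(pm, assignment, seed) {
  withr::local_seed(seed)
  n <- nrow(pm)
  train <- sample(n, floor(n / 2))
  test <- setdiff(seq_len(n), train)
  aucs <- vapply(sort(unique(assignment)), function(cl) {
    y <- as.integer(assignment == cl)
    if (length(unique(y[train])) < 2L || length(unique(y[test])) < 2L) {
      return(NA_real_)
    }
    fit <- glmnet::glmnet(pm[train, , drop = FALSE], y[train],
                          family = "binomial", alpha = 0, lambda = 0.01)
    score <- as.numeric(predict(fit, pm[test, , drop = FALSE]))
    rank_auc(score, y[test] == 1L)
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

#' Choose the niche count by classifier-based AUC screening
#'
#' For each candidate `k`, the profiles are k-means clustered (restart-
#' stabilized, fixed seed), split half/half, a 1-vs-all ridge-logistic
#' classifier is fitted per cluster on the training half, and the rank
#' (Mann-Whitney) AUC of each classifier is evaluated on the holdout; the
#' mean over clusters is reported. `k = 1` is degenerate and skipped with a
#' warning.
#'
#' @param profiles Output of [neighborhood_profiles()].
#' @param k_grid Candidate cluster counts.
#' @param seed Integer seed.
#' @return Tibble (`auc_curve`): `k`, `mean_auc`.
#' @export
select_k_niches <- function(profiles, k_grid = 2:10, seed = 1L) {
  if (any(k_grid < 2L)) {
    warn("k = 1 is degenerate for 1-vs-all screening; skipping.")
    k_grid <- k_grid[k_grid >= 2L]
  }
  pm <- profile_matrix(profiles)
  out <- purrr::map_dfr(k_grid, function(k) {
    withr::local_seed(derive_seed(seed, k))
    km <- kmeans(pm, centers = k, nstart = 10L, iter.max = 50L)
    tibble::tibble(k = k,
                   mean_auc = cluster_auc(pm, km$cluster,
                                          derive_seed(seed, 1000L + k)))
  })
  class(out) <- c("auc_curve", class(out))
  out
}

#' Detect cellular niches by clustering neighborhood profiles
#'
#' k-means (restart-stabilized, fixed seed) partitions the profiles into
#' `k` niches; each niche is labeled by the broad types with the largest
#' positive coefficients of its 1-vs-all ridge-logistic classifier.
#'
#' @param profiles Output of [neighborhood_profiles()].
#' @param k Number of niches.
#' @param seed Integer seed.
#' @param n_label_types Broad types used in the niche label (default 2).
#' @return List of class `niche_result`: `assignment` (tibble `cell_id`,
#'   `spot_id`, `niche`), `niches` (tibble `niche`, `label`, `n_cells` and
#'   centroid fractions), `centroids` (matrix).
#' @export
detect_niches <- function(profiles, k, seed = 1L, n_label_types = 2L) {
  pm <- profile_matrix(profiles)
  withr::local_seed(derive_seed(seed, k))
  km <- kmeans(pm, centers = k, nstart = 10L, iter.max = 50L)
  types <- sub("^frac_", "", colnames(pm))
  labels <- vapply(seq_len(k), function(cl) {
    y <- as.integer(km$cluster == cl)
    if (length(unique(y)) < 2L) return(paste(types[1], collapse = "+"))
    fit <- glmnet::glmnet(pm, y, family = "binomial", alpha = 0,
                          lambda = 0.01)
    coefs <- as.numeric(fit$beta)
    top <- order(coefs, decreasing = TRUE)
    top <- top[coefs[top] > 0]
    paste(types[head(top, n_label_types)], collapse = "+")
  }, character(1))
  niche_ids <- sprintf("CN%02d", seq_len(k))
  centroids <- km$centers / rowSums(km$centers)
  rownames(centroids) <- niche_ids
  assignment <- tibble::tibble(cell_id = profiles$cell_id,
                               spot_id = profiles$spot_id,
                               niche = niche_ids[km$cluster])
  niches <- dplyr::bind_cols(
    tibble::tibble(niche = niche_ids, label = labels,
                   n_cells = as.integer(table(factor(km$cluster,
                                                     levels = seq_len(k))))),
    tibble::as_tibble(centroids))
  structure(list(assignment = assignment, niches = niches,
                 centroids = centroids, k = k, seed = seed),
            class = "niche_result")
}

#' @export
print.niche_result <- function(x, ...) {
  cat("<niche_result>", x$k, "niches over", nrow(x$assignment), "cells\n")
  print(x$niches[, c("niche", "label", "n_cells")], n = x$k)
  invisible(x)
}

#' Merge niches with similar composition
#'
#' Merges either an explicitly named pair or every pair whose centroid
#' Pearson correlation is at or above `similarity_threshold`. Members are
#' unioned and the merged centroid recomputed as the member mean profile.
#'
#' @param result A `niche_result`.
#' @param profiles The profiles the result was built from.
#' @param pair Character vector of two niche ids, or `NULL` to use the
#'   threshold rule.
#' @param similarity_threshold Centroid correlation triggering a merge.
#' @return A `niche_result` with the merged niches (merged ids joined with
#'   `"+"`).
#' @export
merge_niches <- function(result, profiles, pair = NULL,
                         similarity_threshold = NULL) {
  if (is.null(pair) == is.null(similarity_threshold)) {
    abort("give exactly one of `pair` or `similarity_threshold`.")
  }
  pairs <- if (!is.null(pair)) {
    if (length(pair) != 2L || !all(pair %in% result$niches$niche)) {
      abort("`pair` must name two existing niches.")
    }
    list(pair)
  } else {
    cc <- cor(Matrix::t(result$centroids))
    hits <- which(upper.tri(cc) & cc >= similarity_threshold, arr.ind = TRUE)
    lapply(seq_len(nrow(hits)), function(i) {
      rownames(cc)[c(hits[i, 1], hits[i, 2])]
    })
  }
  assignment <- result$assignment
  for (p in pairs) {
    merged_id <- paste(sort(p), collapse = "+")
    assignment$niche[assignment$niche %in% p] <- merged_id
  }
  pm <- profile_matrix(profiles)
  ids <- sort(unique(assignment$niche))
  centroids <- do.call(rbind, lapply(ids, function(id) {
    colMeans(pm[assignment$niche == id, , drop = FALSE])
  }))
  rownames(centroids) <- ids
  niches <- result$niches |>
    dplyr::mutate(niche = purrr::map_chr(.data$niche, function(id) {
      hit <- vapply(pairs, function(p) id %in% p, logical(1))
      if (any(hit)) paste(sort(pairs[[which(hit)[1]]]), collapse = "+") else id
    })) |>
    dplyr::group_by(.data$niche) |>
    dplyr::summarise(label = paste(unique(.data$label), collapse = "|"),
                     n_cells = sum(.data$n_cells), .groups = "drop")
  structure(list(assignment = assignment, niches = niches,
                 centroids = centroids, k = length(ids), seed = result$seed),
            class = "niche_result")
}

#' Shannon-entropy diversity of a niche
#'
#' `S = -sum_i P(x_i) log P(x_i)` over the subtype frequencies of the
#' niche's unique member cells, natural log. A pure niche has S = 0; a
#' niche with `n` equally frequent subtypes has S = log(n).
#'
#' @param subtypes Character vector: subtype of each unique member cell.
#' @return Entropy in nats.
#' @export
#' @examples
#' niche_entropy(c("a", "a", "b", "b"))  # log(2)
niche_entropy <- function(subtypes) {
  if (!length(subtypes)) abort("empty niche.")
  p <- table(subtypes) / length(subtypes)
  -sum(p * log(p))
}

#' Niche-wise subtype enrichment (Fisher exact)
#'
#' Two-sided Fisher exact test of the 2x2 table (in niche vs not) x (is
#' subtype vs not) for every subtype-niche combination. Empty niches are
#' skipped with a warning.
#'
#' @param cells Tibble with `subtype` and `niche` columns.
#' @return Tibble `niche`, `subtype`, `odds_ratio`, `p_value`, `p_adj`
#'   (BH within niche).
#' @export
subtype_enrichment <- function(cells) {
  niches <- sort(unique(cells$niche))
  subtypes <- sort(unique(cells$subtype))
  purrr::map_dfr(niches, function(cn) {
    in_n <- cells$niche == cn
    if (!any(in_n)) {
      warn(sprintf("empty niche %s skipped.", cn))
      return(NULL)
    }
    res <- purrr::map_dfr(subtypes, function(st) {
      is_s <- cells$subtype == st
      tab <- matrix(c(sum(in_n & is_s), sum(in_n & !is_s),
                      sum(!in_n & is_s), sum(!in_n & !is_s)), 2L)
      ft <- fisher.test(tab)
      tibble::tibble(niche = cn, subtype = st,
                     odds_ratio = unname(ft$estimate), p_value = ft$p.value)
    })
    res$p_adj <- p.adjust(res$p_value, "BH")
    res
  })
}

#' Marker-intensity enrichment of a subtype between niches
#'
#' Two-sided Wilcoxon rank-sum test of `marker` intensity on `subtype`
#' cells inside `niche` versus the same subtype elsewhere (or in
#' `reference_niche`). Sides with fewer than `min_cells` cells are skipped
#' (NA result).
#'
#' @param cells Tibble with `subtype`, `niche` and the marker column.
#' @param subtype,marker,niche The comparison to run.
#' @param reference_niche Optional explicit comparison niche.
#' @param min_cells Minimum cells per side (default 3).
#' @return Tibble `subtype`, `marker`, `niche`, `n_in`, `n_out`,
#'   `median_in`, `median_out`, `p_value`.
#' @export
marker_enrichment <- function(cells, subtype, marker, niche,
                              reference_niche = NULL, min_cells = 3L) {
  sub <- cells[cells$subtype == subtype, , drop = FALSE]
  inside <- sub[[marker]][sub$niche == niche]
  outside <- if (is.null(reference_niche)) {
    sub[[marker]][sub$niche != niche]
  } else {
    sub[[marker]][sub$niche == reference_niche]
  }
  p <- if (length(inside) < min_cells || length(outside) < min_cells) {
    warn("too few cells on one side; test skipped.")
    NA_real_
  } else {
    suppressWarnings(stats::wilcox.test(inside, outside)$p.value)
  }
  tibble::tibble(subtype = subtype, marker = marker, niche = niche,
                 n_in = length(inside), n_out = length(outside),
                 median_in = median(inside), median_out = median(outside),
                 p_value = p)
}

#' Query-to-target nearest-neighbor proximity per spot
#'
#' For each spot with at least `min_examples` cells of every type under
#' examination, computes the median over query cells of the Euclidean
#' distance to the nearest target cell (a cell is never its own nearest
#' target when the types coincide). When two query subtypes are given,
#' their spot-level medians are compared with a two-sided Mann-Whitney
#' test.
#'
#' @param cells Tibble with `spot_id`, `x`, `y` and a type column.
#' @param query Query subtype (or two subtypes to compare).
#' @param target Target type.
#' @param type_col Column holding the types (default `"subtype"`).
#' @param min_examples Per-spot minimum for every type examined
#'   (default 25).
#' @return List with `medians` (tibble `spot_id`, `query`,
#'   `median_distance`) and `p_value` (NA unless two query subtypes).
#' @export
proximity_analysis <- function(cells, query, target, type_col = "subtype",
                               min_examples = 25L) {
  types_needed <- unique(c(query, target))
  med_one <- function(q, rows) {
    qx <- as.matrix(rows[rows[[type_col]] == q, c("x", "y")])
    tx <- as.matrix(rows[rows[[type_col]] == target, c("x", "y")])
    self <- q == target
    k <- if (self) 2L else 1L
    if (nrow(tx) < k) return(NA_real_)
    nn <- FNN::get.knnx(tx, qx, k = k)
    median(nn$nn.dist[, k])
  }
  medians <- cells |>
    dplyr::group_by(.data$spot_id) |>
    dplyr::group_modify(function(rows, key) {
      n_by_type <- table(rows[[type_col]])
      ok <- all(types_needed %in% names(n_by_type)) &&
        all(n_by_type[types_needed] >= min_examples)
      if (!ok) return(tibble::tibble(query = character(0),
                                     median_distance = numeric(0)))
      tibble::tibble(query = query,
                     median_distance = unname(vapply(query, med_one,
                                                     numeric(1), rows = rows)))
    }) |>
    dplyr::ungroup()
  p <- NA_real_
  if (length(query) == 2L && nrow(medians) > 0L) {
    a <- medians$median_distance[medians$query == query[1]]
    b <- medians$median_distance[medians$query == query[2]]
    if (length(a) && length(b)) {
      p <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
    }
  }
  list(medians = medians, p_value = p)
}
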