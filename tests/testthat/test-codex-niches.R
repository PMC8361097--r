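test_that("neighborhood profiles follow their arithmetic contracts", {
  # isolated cell: profile is 100% its own type
  lone <- tibble::tibble(cell_id = "c1", spot_id = "s1", x = 0, y = 0,
                         broad = "CD8T")
  p1 <- neighborhood_profiles(lone)
  expect_equal(p1$frac_CD8T, 1)
  expect_equal(p1$n_neighbors, 0L)
  # a B cell ringed by 10 close A cells: (A: 10/11, B: 1/11)
  ring <- tibble::tibble(
    cell_id = sprintf("c%02d", 1:11), spot_id = "s1",
    x = c(0, 10 * cos(2 * pi * (1:10) / 10)),
    y = c(0, 10 * sin(2 * pi * (1:10) / 10)),
    broad = c("B", rep("A", 10)))
  p2 <- neighborhood_profiles(ring, k = 10, max_dist = 200)
  self <- p2[p2$cell_id == "c01", ]
  expect_equal(self$frac_A, 10 / 11)
  expect_equal(self$frac_B, 1 / 11)
  # far-away cells are excluded by the distance cap
  far <- ring
  far$x[2:11] <- far$x[2:11] + 500
  p3 <- neighborhood_profiles(far, k = 10, max_dist = 200)
  expect_equal(p3$frac_B[p3$cell_id == "c01"], 1)
})

test_that("profiles match a brute-force distance sort on a toy", {
  withr::with_seed(31, {
    toy <- tibble::tibble(
      cell_id = sprintf("c%03d", 1:300), spot_id = "s1",
      x = runif(300, 0, 400), y = runif(300, 0, 400),
      broad = sample(c("A", "B", "C"), 300, replace = TRUE))
  })
  prof <- neighborhood_profiles(toy, k = 10, max_dist = 200)
  types <- sort(unique(toy$broad))
  for (i in c(1, 57, 123, 300)) {
    d <- sqrt((toy$x - toy$x[i])^2 + (toy$y - toy$y[i])^2)
    d[i] <- Inf
    nb <- order(d)[1:10]
    nb <- nb[d[nb] <= 200]
    tab <- table(factor(toy$broad[c(i, nb)], levels = types))
    want <- as.numeric(tab / sum(tab))
    got <- as.numeric(prof[prof$cell_id == toy$cell_id[i],
                           paste0("frac_", types)])
    expect_equal(got, want, tolerance = 1e-12)
  }
  expect_equal(unname(rowSums(as.matrix(
    prof[, paste0("frac_", types)]))), rep(1, 300), tolerance = 1e-9)
})

test_that("the AUC curve stays high through the planted k then declines", {
  cfg <- cfg_default()
  cx <- generate_codex(cfg, seed = 4, n_cells = 5000)
  prof <- neighborhood_profiles(cx$cells)
  expect_warning(curve <- select_k_niches(prof, k_grid = 1:6, seed = 1),
                 "degenerate")
  expect_equal(curve$k, 2:6)
  planted <- length(cfg$niche_compositions)
  expect_true(all(curve$mean_auc[curve$k <= planted] >= 0.9))
  expect_lt(curve$mean_auc[curve$k == 6], curve$mean_auc[curve$k == planted])
  expect_identical(curve,
                   suppressWarnings(select_k_niches(prof, k_grid = 1:6,
                                                    seed = 1)))
})

test_that("planted niches are recovered with high ARI and unit centroids", {
  cfg <- cfg_default()
  cx <- generate_codex(cfg, seed = 4, n_cells = 5000)
  prof <- neighborhood_profiles(cx$cells)
  res <- detect_niches(prof, k = 3, seed = 1)
  joined <- dplyr::left_join(cx$cells,
                             res$assignment[, c("cell_id", "niche")],
                             by = "cell_id")
  expect_gte(mclust::adjustedRandIndex(joined$niche, joined$true_niche), 0.8)
  expect_equal(unname(rowSums(res$centroids)), rep(1, 3), tolerance = 1e-9)
  expect_identical(res$assignment, detect_niches(prof, k = 3, seed = 1)$assignment)
  # niche labels name their defining broad types
  expect_true(any(grepl("CD8T", res$niches$label)))
})

test_that("merging reduces the niche count and preserves membership", {
  cfg <- cfg_default()
  cx <- generate_codex(cfg, seed = 4, n_cells = 3000)
  prof <- neighborhood_profiles(cx$cells)
  res <- detect_niches(prof, k = 4, seed = 2)
  merged <- merge_niches(res, prof, pair = c("CN01", "CN02"))
  expect_equal(merged$k, 3L)
  expect_equal(nrow(merged$niches), 3L)
  expect_setequal(merged$assignment$cell_id, res$assignment$cell_id)
  was <- res$assignment$niche %in% c("CN01", "CN02")
  expect_true(all(merged$assignment$niche[was] == "CN01+CN02"))
  # merged centroid equals the member mean profile
  pm <- as.matrix(prof[, grep("^frac_", names(prof))])
  expect_equal(unname(merged$centroids["CN01+CN02", ]),
               unname(colMeans(pm[was, ])), tolerance = 1e-12)
  expect_error(merge_niches(res, prof, pair = c("CN01", "nope")), "existing")
  expect_error(merge_niches(res, prof), "exactly one")
})

test_that("niche entropy matches its closed forms and a frequency tally", {
  expect_equal(niche_entropy(rep("a", 20)), 0)
  for (n in 2:5) {
    expect_equal(niche_entropy(rep(letters[1:n], each = 7)), log(n))
  }
  withr::with_seed(41, {
    members <- sample(c("t1", "t2", "t3", "t4"), 50, replace = TRUE,
                      prob = c(0.5, 0.3, 0.15, 0.05))
  })
  p <- as.numeric(table(members)) / 50
  expect_equal(niche_entropy(members), -sum(p * log(p)), tolerance = 1e-12)
  expect_lte(niche_entropy(members), log(length(unique(members))))
  expect_error(niche_entropy(character(0)), "empty")
})

test_that("subtype enrichment flags planted niches and stays flat under the null", {
  cfg <- cfg_default()
  cx <- generate_codex(cfg, seed = 4, n_cells = 4000)
  cells <- dplyr::mutate(cx$cells, niche = true_niche)
  enr <- subtype_enrichment(cells)
  hit <- enr[enr$niche == "immune" & enr$subtype == "CD8T", ]
  expect_lt(hit$p_value, 1e-6)
  expect_gt(hit$odds_ratio, 1)
  # random niche labels: uniform p-values
  withr::with_seed(8, {
    null_cells <- dplyr::mutate(cells, niche = sample(niche))
  })
  enr0 <- subtype_enrichment(null_cells)
  expect_lt(mean(enr0$p_value < 0.05), 0.2)
})

test_that("marker enrichment detects the planted intensity shift and skips tiny sides", {
  cfg <- cfg_default()
  cx <- generate_codex(cfg, seed = 4, n_cells = 4000)
  cells <- dplyr::mutate(cx$cells, niche = true_niche)
  hit <- marker_enrichment(cells, subtype = "CD8T", marker = "mem_CD49a",
                           niche = "tumor")
  expect_lt(hit$p_value, 0.05)
  expect_gt(hit$median_in, hit$median_out)
  few <- cells[c(which(cells$subtype == "CD8T")[1:2],
                 which(cells$subtype == "CD8T" & cells$niche != "tumor")[1:5]), ]
  expect_warning(sk <- marker_enrichment(few, "CD8T", "mem_CD49a", "tumor"),
                 "too few")
  expect_true(is.na(sk$p_value))
})

test_that("proximity medians match a brute-force scan and honor the 25-cell rule", {
  # interleaved vs segregated layouts on two spots
  withr::with_seed(51, {
    inter <- tibble::tibble(
      cell_id = sprintf("i%03d", 1:120), spot_id = "mixed",
      x = runif(120, 0, 100), y = runif(120, 0, 100),
      subtype = rep(c("Q", "T"), 60))
    seg <- tibble::tibble(
      cell_id = sprintf("s%03d", 1:120), spot_id = "apart",
      x = c(runif(60, 0, 100), runif(60, 400, 500)),
      y = runif(120, 0, 100),
      subtype = rep(c("Q", "T"), each = 60))
  })
  both <- dplyr::bind_rows(inter, seg)
  res <- proximity_analysis(both, query = "Q", target = "T")
  m <- res$medians
  expect_lt(m$median_distance[m$spot_id == "mixed"],
            m$median_distance[m$spot_id == "apart"])
  # brute-force oracle on the mixed spot
  q <- inter[inter$subtype == "Q", ]; t <- inter[inter$subtype == "T", ]
  d <- vapply(seq_len(nrow(q)), function(i) {
    min(sqrt((t$x - q$x[i])^2 + (t$y - q$y[i])^2))
  }, numeric(1))
  expect_equal(m$median_distance[m$spot_id == "mixed"], median(d))
  # query == target: self-distance excluded, median > 0
  self <- proximity_analysis(inter, query = "Q", target = "Q")
  expect_true(all(self$medians$median_distance > 0))
  # a spot with only 24 target cells is excluded
  short <- inter[-(which(inter$subtype == "T")[1:36]), ]  # 24 targets left
  res24 <- proximity_analysis(short, query = "Q", target = "T")
  expect_equal(nrow(res24$medians), 0L)
  # two query subtypes produce a cross-group comparison p-value; every
  # evaluated spot must carry enough cells of both queries and the target
  relabel <- function(df) {
    qs <- which(df$subtype == "Q")
    df$subtype[qs] <- rep(c("Q1", "Q2"), length.out = length(qs))
    df
  }
  three <- dplyr::bind_rows(
    relabel(inter),
    relabel(dplyr::mutate(inter, cell_id = paste0("x", cell_id),
                          spot_id = "mixed2")))
  cmp <- proximity_analysis(three, query = c("Q1", "Q2"), target = "T",
                            min_examples = 20)
  expect_false(is.na(cmp$p_value))
})
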