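test_that("tumor cohort has the requested shape and ground-truth labels", {
  cfg <- synth_config(
    n_cells = c(S1 = 200L, S2 = 200L, S3 = 200L, S4 = 200L, S5 = 200L),
    compartments = c(S1 = "epithelial", S2 = "epithelial", S3 = "epithelial",
                     S4 = "fibroblast", S5 = "fibroblast"),
    n_genes = 300L, marker_genes = 5L)
  sim <- generate_tumor_cohort(cfg, seed = 11)
  expect_equal(dim(sim$counts), c(1000L, 300L))
  expect_equal(unname(table(sim$cells$subtype)[paste0("S", 1:5)]),
               rep(200L, 5), ignore_attr = TRUE)
  expect_true(all(sim$counts@x >= 0))
  expect_true(all(sim$mito_genes %in% colnames(sim$counts)))
  expect_setequal(unique(sim$hto$true_class),
                  c("singlet", "doublet", "negative", "recoverable"))
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- cfg_small()
  expect_identical(generate_tumor_cohort(cfg, seed = 3),
                   generate_tumor_cohort(cfg, seed = 3))
  expect_identical(generate_normal_cohort(cfg, seed = 3, n_cells = 50),
                   generate_normal_cohort(cfg, seed = 3, n_cells = 50))
  expect_identical(generate_visium(cfg, seed = 3), generate_visium(cfg, seed = 3))
  expect_identical(generate_codex(cfg, seed = 3, n_cells = 300),
                   generate_codex(cfg, seed = 3, n_cells = 300))
  expect_identical(generate_lr_prior(cfg, seed = 3),
                   generate_lr_prior(cfg, seed = 3))
  expect_false(identical(generate_visium(cfg, seed = 3),
                         generate_visium(cfg, seed = 4)))
})

test_that("planted marker fold changes are recovered empirically", {
  cfg <- cfg_default()
  sim <- generate_tumor_cohort(cfg, seed = 1)
  m <- as.matrix(sim$counts)
  for (s in unique(sim$markers$subtype)) {
    genes <- sim$markers$gene[sim$markers$subtype == s]
    in_s <- sim$cells$subtype == s
    lfc <- log2(mean(m[in_s, genes]) / mean(m[!in_s, genes]))
    expect_lt(abs(lfc - cfg$marker_lfc), 0.3)
  }
})

test_that("zero or invalid cell requests are rejected", {
  expect_error(synth_config(n_cells = c(A = 0L)), "positive")
  expect_error(synth_config(niche_compositions = list(bad = c(a = 0.5, b = 0.4))),
               "probability")
})

test_that("normal cohort time genes correlate with latent time", {
  cfg <- cfg_default()
  sim <- generate_normal_cohort(cfg, seed = 2, n_cells = 500)
  r <- cor(as.matrix(sim$counts[, sim$time_genes]), sim$cells$latent_time)[, 1]
  expect_gte(mean(r >= 0.3), 0.9)
  expect_true(all(sim$cells$latent_time >= 0 & sim$cells$latent_time <= 1))
  # with no time genes nothing correlates beyond chance
  null <- generate_normal_cohort(cfg, seed = 2, n_cells = 300, n_time_genes = 0)
  r0 <- cor(as.matrix(null$counts), null$cells$latent_time)[, 1]
  expect_lt(mean(abs(r0) >= 0.3, na.rm = TRUE), 0.02)
})

test_that("spot grids obey the parity rule and rank the planted region high", {
  cfg <- synth_config(grid_rows = 30L, grid_cols = 30L)
  v <- generate_visium(cfg, seed = 3)
  expect_equal(length(unique((v$spots$x + v$spots$y) %% 2)), 1L)
  expr <- normalize_log(v$counts)
  score <- rowMeans(expr[, sprintf("MOD-%d", 1:5)])
  top5 <- rank(-score) <= ceiling(0.05 * length(score))
  expect_gte(mean(v$spots$in_region[top5]), 0.8)
  # totals straddle the 1,250-UMI quality boundary
  totals <- Matrix::rowSums(v$counts)
  expect_gt(sum(totals < 1250), 0)
  expect_gt(sum(totals >= 1250), 0)
})

test_that("planted niche compositions are reproduced in the imaging table", {
  cfg <- cfg_default()
  cx <- generate_codex(cfg, seed = 4, n_cells = 5000)
  for (nm in names(cfg$niche_compositions)) {
    target <- cfg$niche_compositions[[nm]]
    obs <- table(factor(cx$cells$broad[cx$cells$true_niche == nm],
                        levels = names(target))) /
      sum(cx$cells$true_niche == nm)
    expect_lt(sum(abs(as.numeric(obs) - target)), 0.1)
  }
})

test_that("a zero marker shift leaves intensities exchangeable across niches", {
  cfg <- synth_config(marker_shift = 0)
  cx <- generate_codex(cfg, seed = 9, n_cells = 4000)
  cd8 <- cx$cells[cx$cells$broad == "CD8T", ]
  p <- wilcox.test(mem_CD49a ~ true_niche == "tumor", data = cd8)$p.value
  expect_gt(p, 0.01)
})

test_that("ligand-receptor prior respects the small-signature fraction", {
  cfg <- synth_config(lr_pairs = 30L, small_sig_fraction = 0.1)
  prior <- generate_lr_prior(cfg, seed = 5)
  expect_equal(nrow(prior), 30L)
  expect_equal(sum(prior$n_signature_genes < 5), 3L)
  uni <- sprintf("GENE-%04d", 1:600)
  pr2 <- generate_lr_prior(cfg, gene_universe = uni, seed = 5)
  expect_true(all(unlist(pr2$signature) %in% uni))
  dup <- dplyr::bind_rows(pr2[1, ], pr2)
  expect_error(validate_lr_prior(dup), "duplicated")
})

test_that("mask image generator plants known ring positivity", {
  img <- generate_mask_image(seed = 7, n_nuclei = 10)
  expect_true(all(dim(img$mask) == dim(img$intensity)))
  expect_equal(sort(unique(img$mask[img$mask > 0])), img$truth$label)
  expect_equal(sum(img$truth$ring_positive), 5L)
})
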