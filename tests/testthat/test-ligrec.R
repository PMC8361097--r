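test_that("receptors need at least five signature genes", {
  prior <- tibble::tibble(
    ligand = c("L1", "L2", "L3"),
    receptor = c("R4", "R5", "R6"),
    signature = list(paste0("g", 1:4), paste0("g", 1:5), paste0("g", 1:9)))
  out <- build_receptor_signatures(prior)
  expect_setequal(out$prior$receptor, c("R5", "R6"))
  expect_equal(out$excluded$receptor, "R4")
  expect_error(build_receptor_signatures(prior[0, ]), "empty")
})

test_that("receptor activity follows its closed forms and a brute-force oracle", {
  withr::with_seed(13, {
    m <- matrix(rnorm(20 * 10, mean = 3), 20, 10,
                dimnames = list(sprintf("c%02d", 1:20), sprintf("g%02d", 1:10)))
  })
  attr(m, "normalized") <- TRUE
  broad <- rep(c("epi", "fib"), each = 10L)
  prior <- tibble::tibble(ligand = "L", receptor = "R",
                          signature = list(sprintf("g%02d", 1:5)))
  act <- receptor_activity(m, broad, prior)
  # brute force per cell
  for (i in 1:20) {
    bg <- colMeans(m[broad == broad[i], 1:5])
    expect_equal(act[i, "R"], mean(abs(m[i, 1:5] - bg)), tolerance = 1e-12)
  }
  # closed forms: cells at the compartment mean score 0; cells offset
  # symmetrically by +/- delta/2 each score exactly delta/2
  delta <- 0.7
  flat <- matrix(2, 4, 6, dimnames = list(paste0("c", 1:4), paste0("g", 1:6)))
  flat[3, 1:5] <- 2 + delta / 2
  flat[4, 1:5] <- 2 - delta / 2
  attr(flat, "normalized") <- TRUE
  prior2 <- tibble::tibble(ligand = "L", receptor = "R",
                           signature = list(paste0("g", 1:5)))
  act2 <- receptor_activity(flat, c("a", "a", "b", "b"), prior2)
  expect_equal(unname(act2[1:2, "R"]), c(0, 0))
  expect_equal(unname(act2[3:4, "R"]), c(delta / 2, delta / 2))
})

test_that("ligand and receptor calls enforce their thresholds inclusively", {
  de <- tibble::tibble(
    group = "S", gene = c("l_pass", "l_border", "l_lowfc", "l_rarely"),
    score = 5, log2_fc = c(1, 0.5, 0.49, 1),
    p_value = 0.001, p_adj = c(0.01, 0.05, 0.01, 0.01),
    frac_expressing = c(0.5, 0.10, 0.5, 0.09))
  got <- call_available_ligands(de, de$gene)
  expect_setequal(got$ligand, c("l_pass", "l_border"))
})

test_that("the spatial co-expression boundary is inclusive at 25%", {
  spots <- hex_grid(8, 10)
  n <- nrow(spots)
  mk <- function(lig_pos, rec_pos) {
    counts <- matrix(0L, n, 2, dimnames = list(spots$spot_id, c("L", "R")))
    counts[lig_pos, "L"] <- 1L
    counts[rec_pos, "R"] <- 1L
    new_spot_frame(counts, spots)
  }
  pairs <- tibble::tibble(ligand = "L", receptor = "R")
  # 10 of 40 ligand+ spots are receptor+: exactly 25%, kept
  keep <- spatial_coexpression_filter(list(mk(1:40, 31:40)), pairs)
  expect_true(keep$spatially_coexpressed)
  # 9 of 40 in every sample: dropped
  drop <- spatial_coexpression_filter(list(mk(1:40, 32:40), mk(1:40, 32:40)),
                                      pairs)
  expect_false(drop$spatially_coexpressed)
  # brute-force enumeration oracle on a random toy
  withr::with_seed(21, {
    counts <- matrix(rbinom(n * 2, 1, 0.3), n, 2,
                     dimnames = list(spots$spot_id, c("L", "R")))
  })
  sf <- new_spot_frame(counts, spots)
  res <- spatial_coexpression_filter(list(sf), pairs)
  lig_spots <- which(counts[, "L"] > 0)
  oracle <- sum(counts[lig_spots, "R"] > 0) / length(lig_spots)
  expect_equal(res$coexpression_frac, oracle)
  # unknown genes are dropped with a warning
  expect_warning(
    gone <- spatial_coexpression_filter(list(sf),
                                        tibble::tibble(ligand = "X",
                                                       receptor = "Y")),
    "absent")
  expect_equal(nrow(gone), 0L)
})

test_that("interaction potential is a product of means", {
  lig <- c(1, 2, 3, 4, 0)
  act <- c(0.5, 1.5)
  expect_equal(interaction_potential(lig, act), mean(lig) * mean(act))
  expect_equal(interaction_potential(rep(0, 5), act), 0)
  expect_equal(interaction_potential(lig * 2, act),
               2 * interaction_potential(lig, act))
})

test_that("ribbon transparency follows the printed formula", {
  expect_equal(ribbon_transparency(1, 1), 0)
  expect_equal(ribbon_transparency(0, 1), 0.9)
  expect_equal(ribbon_transparency(0.5, 1), 0.75)
  v <- ribbon_transparency(seq(0, 2, by = 0.1), 2)
  expect_true(all(diff(v) <= 0))
  expect_true(all(v >= 0 & v <= 0.9))
  expect_error(ribbon_transparency(2, 1), "lie in")
  expect_error(ribbon_transparency(1, 0), "positive")
})

test_that("a planted interaction is called and a discordant pair filtered", {
  cfg <- cfg_default()
  sim <- generate_tumor_cohort(cfg, seed = 1)
  expr <- normalize_log(sim$counts)
  lig <- "MK-CDH12-01"; rec <- "GENE-0001"
  lig2 <- "MK-CDH12-02"; rec2 <- "GENE-0002"
  planted <- tibble::tibble(
    ligand = c(lig, lig2), receptor = c(rec, rec2),
    signature = list(sprintf("MK-iCAF-%02d", 1:6),
                     sprintf("MK-iCAF-%02d", 5:10)))
  prior <- generate_lr_prior(cfg, gene_universe = colnames(expr), seed = 5,
                             planted = planted)
  # one sample: both pairs present, second pair spatially exclusive
  v <- generate_visium(cfg, seed = 3, module_genes = c(lig, rec),
                       region_genes = lig2, anti_genes = rec2)
  res <- call_interactions(expr, sim$cells, prior, list(v),
                           sender = "CDH12",
                           receiver_compartment = "fibroblast")
  expect_true(any(res$ligand == lig & res$receptor == rec &
                    res$receiver == "iCAF"))
  expect_false(any(res$receptor == rec2))
  expect_true(all(res$transparency >= 0 & res$transparency <= 0.9))
  expect_equal(min(res$transparency), 0)  # strongest ribbon fully opaque
})
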