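# Synthetic spatial inputs: hexagonal-array spot transcriptomics and
# multiplexed-imaging single-cell tables with planted niches.

#' Hexagonal array coordinates for a spot grid
#'
#' Array frame with a doubled second coordinate: row `r` and column `c` map
#' to `x = r`, `y = 2c + (r mod 2)`, so `x + y` has constant (even) parity
#' across the slide and the six immediate hexagonal neighbors of a spot sit
#' at offsets `(x +/- 1, y +/- 1)` and `(x, y +/- 2)` — the frame in which
#' the ring formulas of [hex_ring()] are written.
#'
#' @param rows,cols Grid dimensions.
#' @return Tibble with `spot_id`, `x`, `y`.
#' @export
hex_grid <- function(rows, cols) {
  r <- rep(seq_len(rows) - 1L, each = cols)
  c <- rep(seq_len(cols) - 1L, times = rows)
  tibble::tibble(spot_id = sprintf("spot-%04d", seq_along(r)),
                 x = r, y = 2L * c + r %% 2L)
}

#' Simulate a hexagonal-grid spatial transcriptomics sample
#'
#' Spots are laid out on a parity-constrained hexagonal array. A contiguous
#' planted region (spots nearest the region center in array space) carries an
#' elevated "module" program plus co-elevated companion genes, emulating a
#' tumor-cell program with exhaustion markers concentrated around it. A
#' handful of high-expression housekeeping genes carry the UMI totals, which
#' straddle the usual 1,250-UMI quality boundary; the remaining genes are
#' sparse so presence/absence co-expression is informative.
#'
#' @param cfg A [synth_config()] (supplies grid size and dispersion).
#' @param seed Integer seed.
#' @param module_genes,companion_genes Names of planted module and companion
#'   genes (created if not already in `extra_genes`).
#' @param region_genes Genes expressed only *inside* the planted region.
#' @param anti_genes Genes expressed only *outside* the planted region
#'   (pairing a `region_genes` ligand with an `anti_genes` receptor plants
#'   a spatially discordant gene pair).
#' @param n_background_genes Number of additional sparse background genes.
#' @param region_frac Fraction of spots in the planted region.
#' @param sample_id Sample label.
#' @return A `spot_frame`: list with `counts` (spots x genes sparse matrix),
#'   `spots` (tibble `spot_id`, `x`, `y`, `in_region`) and `sample`.
#' @export
generate_visium <- function(cfg, seed = 1L,
                            module_genes = sprintf("MOD-%d", 1:5),
                            companion_genes = sprintf("EXH-%d", 1:3),
                            region_genes = character(0),
                            anti_genes = character(0),
                            n_background_genes = 80L,
                            region_frac = 0.05,
                            sample_id = "V1") {
  validate_synth_config(cfg)
  withr::local_seed(seed)
  spots <- hex_grid(cfg$grid_rows, cfg$grid_cols)
  n <- nrow(spots)

  background <- sprintf("BG-%04d", seq_len(n_background_genes))
  housekeeping <- sprintf("HK-%02d", 1:20)
  genes <- unique(c(module_genes, companion_genes, region_genes, anti_genes,
                    background, housekeeping))

  # planted region: spots nearest a central reference in physical space
  # (x spans rows at sqrt(3)/2 spacing, the doubled y halves to columns)
  center <- c(x = stats::median(spots$x), y = stats::median(spots$y))
  d <- sqrt(0.75 * (spots$x - center["x"])^2 +
              0.25 * (spots$y - center["y"])^2)
  n_region <- max(1L, ceiling(region_frac * n))
  in_region <- rank(d, ties.method = "first") <= n_region

  mu <- matrix(0.25, nrow = n, ncol = length(genes),
               dimnames = list(spots$spot_id, genes))
  mu[, housekeeping] <- 70
  mu[in_region, module_genes] <- 0.25 * 12
  mu[in_region, companion_genes] <- 0.25 * 8
  if (length(region_genes)) {
    mu[, region_genes] <- 0
    mu[in_region, region_genes] <- 3
  }
  if (length(anti_genes)) {
    mu[, anti_genes] <- 1.5
    mu[in_region, anti_genes] <- 0
  }
  # per-spot depth factor spreads totals across the 1,250-UMI boundary
  depth <- stats::rlnorm(n, meanlog = 0, sdlog = 0.25)
  mu <- mu * depth
  counts <- matrix(rnbinom(length(mu), mu = mu, size = cfg$nb_dispersion),
                   nrow = n, dimnames = dimnames(mu))
  spots$in_region <- in_region
  new_spot_frame(counts = Matrix::Matrix(counts, sparse = TRUE),
                 spots = spots, sample = sample_id)
}

#' Construct a spot frame
#'
#' A `spot_frame` couples a spots x genes count matrix with the array
#' coordinates of each spot. All spatial operations in the package take and
#' return this container.
#'
#' @param counts Spots x genes matrix (rows named by `spot_id`).
#' @param spots Tibble with at least `spot_id`, `x`, `y`; coordinates must be
#'   unique and obey the constant-parity rule of the hexagonal array.
#' @param sample Sample label.
#' @return A `spot_frame` object.
#' @export
new_spot_frame <- function(counts, spots, sample = "sample") {
  if (!all(rownames(counts) == spots$spot_id)) {
    abort("`counts` rows must align with `spots$spot_id`.")
  }
  if (anyDuplicated(spots[, c("x", "y")])) abort("duplicate spot coordinates.")
  parity <- (spots$x + spots$y) %% 2L
  if (length(unique(parity)) > 1L) {
    abort("spot coordinates violate the hexagonal parity rule.")
  }
  structure(list(counts = counts, spots = spots, sample = sample),
            class = "spot_frame")
}

#' @export
print.spot_frame <- function(x, ...) {
  cat("<spot_frame> sample", x$sample, "-", nrow(x$counts), "spots x",
      ncol(x$counts), "genes\n")
  invisible(x)
}

imaging_marker_panel <- function() {
  tibble::tribble(
    ~broad,          ~marker,
    "Epithelial",    "PanCytoK",
    "EpithelialCDH", "CDH12",
    "Stromal",       "aSMA",
    "Endothelial",   "CD31",
    "CD8T",          "CD8",
    "CD4T",          "CD4",
    "Bcell",         "CD20",
    "Macrophage",    "CD68")
}

#' Simulate a multiplexed-imaging single-cell table with planted niches
#'
#' Cells are scattered over rectangular cores (tissue-microarray spots); each
#' core is divided into vertical bands, one per configured niche, and cell
#' types are drawn from that niche's broad-type composition. Each broad type
#' has an identity marker whose membrane intensity is high on that type and
#' low elsewhere; a functional marker (`shift_marker`, default CD49a) is
#' additionally elevated by `cfg$marker_shift` on `shift_subtype` cells
#' inside `shift_niche`, emulating residency-marker induction within a
#' specific niche.
#'
#' @param cfg A [synth_config()] (supplies `niche_compositions`,
#'   `marker_shift`).
#' @param seed Integer seed.
#' @param n_cells Total cells across all cores.
#' @param n_cores Number of cores (spots).
#' @param core_size Side length of each square core, image coordinate units.
#' @param shift_marker,shift_subtype,shift_niche The planted intensity shift.
#' @return List with `cells` (tibble: `cell_id`, `spot_id`, `x`, `y`,
#'   intensity columns `mem_*` and `nuc_DAPI`, `broad`, `subtype`,
#'   `true_niche`) and `markers` (panel tibble).
#' @export
generate_codex <- function(cfg, seed = 1L, n_cells = 5000L, n_cores = 3L,
                           core_size = 1000, shift_marker = "CD49a",
                           shift_subtype = "CD8T",
                           shift_niche = names(cfg$niche_compositions)[1]) {
  validate_synth_config(cfg)
  if (n_cells <= 0L) abort("`n_cells` must be positive.")
  withr::local_seed(seed)
  panel <- imaging_marker_panel()
  types_all <- unique(unlist(lapply(cfg$niche_compositions, names)))
  if (!all(types_all %in% panel$broad)) {
    abort("niche compositions name broad types outside the imaging panel.")
  }
  niches <- names(cfg$niche_compositions)
  k <- length(niches)
  core <- rep(seq_len(n_cores), length.out = n_cells)
  x <- runif(n_cells, 0, core_size)
  y <- runif(n_cells, 0, core_size)
  band <- pmin(k, 1L + floor(x / (core_size / k)))
  niche <- niches[band]
  broad <- unname(vapply(niche, function(nm) {
    p <- cfg$niche_compositions[[nm]]
    sample(names(p), 1L, prob = p)
  }, character(1)))

  markers <- c(panel$marker, shift_marker)
  inten <- matrix(pmax(0, rnorm(n_cells * length(markers), mean = 8, sd = 3)),
                  nrow = n_cells, dimnames = list(NULL, markers))
  id_marker <- panel$marker[match(broad, panel$broad)]
  inten[cbind(seq_len(n_cells), match(id_marker, markers))] <-
    pmax(0, rnorm(n_cells, mean = 40, sd = 5))
  shifted <- broad == shift_subtype & niche == shift_niche
  inten[shifted, shift_marker] <- inten[shifted, shift_marker] + cfg$marker_shift

  cells <- tibble::tibble(
    cell_id = sprintf("cx-%05d", seq_len(n_cells)),
    spot_id = sprintf("core-%d", core),
    x = x, y = y)
  mem <- tibble::as_tibble(inten)
  names(mem) <- paste0("mem_", names(mem))
  cells <- dplyr::bind_cols(cells, mem)
  cells$nuc_DAPI <- pmax(0, rnorm(n_cells, mean = 50, sd = 5))
  cells$broad <- broad
  # light subtype structure below the broad level (split epithelium by KRT)
  cells$subtype <- ifelse(broad == "Epithelial",
                          sample(c("Epithelial_KRT13", "Epithelial_KRT17"),
                                 n_cells, replace = TRUE),
                          broad)
  cells$true_niche <- niche
  list(cells = cells, markers = panel)
}

#' Simulate a labeled nuclear mask and matching intensity image
#'
#' Places non-overlapping disc nuclei on a small image and paints a marker
#' intensity channel in which a chosen fraction of nuclei are ring-positive:
#' pixels in a band just outside the nucleus exceed the positivity threshold.
#' Used to exercise membrane-mask expansion and ring-percentage extraction.
#'
#' @param seed Integer seed.
#' @param n_nuclei Number of nuclei.
#' @param size Image side length in pixels.
#' @param radius Nuclear radius in pixels.
#' @param ring_width Width of the positive ring band, pixels.
#' @param positive_fraction Fraction of nuclei made ring-positive.
#' @param ring_intensity,background_intensity Painted intensities.
#' @return List with `mask` (integer label matrix), `intensity` (numeric
#'   matrix) and `truth` (tibble: `label`, `ring_positive`).
#' @export
generate_mask_image <- function(seed = 1L, n_nuclei = 12L, size = 96L,
                                radius = 5L, ring_width = 3L,
                                positive_fraction = 0.5,
                                ring_intensity = 60,
                                background_intensity = 5) {
  withr::local_seed(seed)
  mask <- matrix(0L, size, size)
  centers <- matrix(NA_real_, 0, 2)
  margin <- radius + ring_width + 2L
  tries <- 0L
  while (nrow(centers) < n_nuclei && tries < 5000L) {
    tries <- tries + 1L
    cand <- runif(2, margin, size - margin)
    if (nrow(centers) == 0 ||
        min(sqrt(colSums((t(centers) - cand)^2))) > 2 * (radius + ring_width) + 2) {
      centers <- rbind(centers, cand)
    }
  }
  n_nuclei <- nrow(centers)
  xs <- row(mask); ys <- col(mask)
  for (i in seq_len(n_nuclei)) {
    d2 <- (xs - centers[i, 1])^2 + (ys - centers[i, 2])^2
    mask[d2 <= radius^2] <- i
  }
  positive <- seq_len(n_nuclei) <= round(positive_fraction * n_nuclei)
  intensity <- matrix(background_intensity, size, size)
  for (i in which(positive)) {
    d2 <- (xs - centers[i, 1])^2 + (ys - centers[i, 2])^2
    band <- d2 > radius^2 & d2 <= (radius + ring_width)^2
    intensity[band] <- ring_intensity
  }
  list(mask = mask, intensity = intensity,
       truth = tibble::tibble(label = seq_len(n_nuclei),
                              ring_positive = positive))
}
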