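#' Configuration for the synthetic-data generators
#'
#' Bundles the parameters shared by the synthetic cohort, spatial and prior
#' generators. Defaults describe a small but realistic study: five annotated
#' subtypes across two compartments, sparse negative-binomial UMI counts with
#' a mitochondrial fraction in the usual nuclei range, a hexagonal spot grid
#' with one planted co-expression region, and three spatial niches with
#' distinct broad-type compositions.
#'
#' @param n_cells Named integer vector: cells to simulate per subtype.
#' @param compartments Named character vector mapping each subtype to its
#'   broad compartment (e.g. epithelial, fibroblast).
#' @param n_genes Total number of genes in the single-cell gene universe
#'   (markers and mitochondrial genes included).
#' @param marker_genes Number of planted marker genes per subtype.
#' @param marker_lfc Planted log2 fold change of a subtype's markers in that
#'   subtype relative to all other cells.
#' @param n_mito_genes Number of genes flagged mitochondrial (named `MT-*`).
#' @param nb_mean,nb_dispersion Negative-binomial mean and dispersion (`size`)
#'   of baseline per-gene expression.
#' @param mito_fraction_range Length-2 interval for the expected per-cell
#'   mitochondrial UMI fraction.
#' @param n_hashtags Number of hashtag oligos in the HTO table.
#' @param doublet_rate,recoverable_rate,negative_rate HTO class rates; the
#'   singlet rate is the remainder.
#' @param grid_rows,grid_cols Hexagonal array dimensions for spot data.
#' @param niche_compositions Named list of probability vectors (one per
#'   niche) over broad imaging cell types; each must sum to 1.
#' @param marker_shift Intensity elevation added to a designated functional
#'   marker inside its designated niche.
#' @param lr_pairs Number of ligand-receptor pairs in the synthetic prior.
#' @param small_sig_fraction Fraction of receptors given fewer than 5
#'   signature genes (to exercise the exclusion rule).
#'
#' @return A list of class `synth_config`.
#' @export
#' @examples
#' cfg <- synth_config()
#' cfg$n_cells
synth_config <- function(n_cells = c(CDH12 = 200L, KRT13 = 200L, UPK = 200L,
                                     iCAF = 200L, myCAF = 200L,
                                     periCAF = 200L),
                         compartments = c(CDH12 = "epithelial",
                                          KRT13 = "epithelial",
                                          UPK = "epithelial",
                                          iCAF = "fibroblast",
                                          myCAF = "fibroblast",
                                          periCAF = "fibroblast"),
                         n_genes = 600L,
                         marker_genes = 10L,
                         marker_lfc = 3,
                         n_mito_genes = 10L,
                         nb_mean = 0.8,
                         nb_dispersion = 2,
                         mito_fraction_range = c(0.02, 0.08),
                         n_hashtags = 6L,
                         doublet_rate = 0.08,
                         recoverable_rate = 0.06,
                         negative_rate = 0.04,
                         grid_rows = 30L,
                         grid_cols = 30L,
                         niche_compositions = list(
                           tumor = c(Epithelial = 0.60, EpithelialCDH = 0.15,
                                     Stromal = 0.10, CD8T = 0.10,
                                     Macrophage = 0.05),
                           immune = c(Epithelial = 0.10, EpithelialCDH = 0.00,
                                      Stromal = 0.10, CD8T = 0.50,
                                      Macrophage = 0.30),
                           stroma = c(Epithelial = 0.10, EpithelialCDH = 0.00,
                                      Stromal = 0.70, CD8T = 0.10,
                                      Macrophage = 0.10)),
                         marker_shift = 15,
                         lr_pairs = 30L,
                         small_sig_fraction = 0.1) {
  cfg <- list(n_cells = n_cells, compartments = compartments,
              n_genes = as.integer(n_genes),
              marker_genes = as.integer(marker_genes),
              marker_lfc = marker_lfc,
              n_mito_genes = as.integer(n_mito_genes),
              nb_mean = nb_mean, nb_dispersion = nb_dispersion,
              mito_fraction_range = mito_fraction_range,
              n_hashtags = as.integer(n_hashtags),
              doublet_rate = doublet_rate,
              recoverable_rate = recoverable_rate,
              negative_rate = negative_rate,
              grid_rows = as.integer(grid_rows),
              grid_cols = as.integer(grid_cols),
              niche_compositions = niche_compositions,
              marker_shift = marker_shift,
              lr_pairs = as.integer(lr_pairs),
              small_sig_fraction = small_sig_fraction)
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  if (length(cfg$n_cells) == 0L || any(cfg$n_cells <= 0L)) {
    abort("`n_cells` must name at least one subtype with a positive count.")
  }
  if (is.null(names(cfg$n_cells))) abort("`n_cells` must be named by subtype.")
  if (!all(names(cfg$n_cells) %in% names(cfg$compartments))) {
    abort("every subtype in `n_cells` needs a compartment assignment.")
  }
  if (cfg$n_genes <= length(cfg$n_cells) * cfg$marker_genes + cfg$n_mito_genes) {
    abort("`n_genes` too small for the requested markers and mito genes.")
  }
  if (cfg$nb_mean <= 0 || cfg$nb_dispersion <= 0) {
    abort("`nb_mean` and `nb_dispersion` must be positive.")
  }
  rng <- cfg$mito_fraction_range
  if (length(rng) != 2L || any(rng < 0) || any(rng > 1) || rng[1] > rng[2]) {
    abort("`mito_fraction_range` must be an interval inside [0, 1].")
  }
  rates <- c(cfg$doublet_rate, cfg$recoverable_rate, cfg$negative_rate)
  if (any(rates < 0) || sum(rates) >= 1) {
    abort("HTO class rates must be non-negative and sum to less than 1.")
  }
  for (nm in names(cfg$niche_compositions)) {
    p <- cfg$niche_compositions[[nm]]
    if (abs(sum(p) - 1) > 1e-9 || any(p < 0)) {
      abort(sprintf("niche composition '%s' is not a probability vector.", nm))
    }
  }
  if (cfg$grid_rows <= 0L || cfg$grid_cols <= 0L) {
    abort("grid dimensions must be positive.")
  }
  invisible(cfg)
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  cat("  subtypes:", paste0(names(x$n_cells), " (", x$n_cells, ")",
                            collapse = ", "), "\n")
  cat("  genes:", x$n_genes, " markers/subtype:", x$marker_genes,
      " mito:", x$n_mito_genes, "\n")
  cat("  grid:", x$grid_rows, "x", x$grid_cols,
      " niches:", length(x$niche_compositions), "\n")
  invisible(x)
}
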