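# Synthetic single-nucleus cohorts: tumor (with planted subtype markers,
# mitochondrial genes and an HTO table) and normal epithelium (with a latent
# differentiation-time axis and time-correlated genes).

# Shared gene universe: ordinary genes, per-subtype marker blocks, MT- genes.
build_gene_universe <- function(cfg) {
  subtypes <- names(cfg$n_cells)
  marker_list <- lapply(seq_along(subtypes), function(i) {
    sprintf("MK-%s-%02d", subtypes[i], seq_len(cfg$marker_genes))
  })
  names(marker_list) <- subtypes
  mito <- sprintf("MT-%02d", seq_len(cfg$n_mito_genes))
  n_other <- cfg$n_genes - length(mito) - cfg$marker_genes * length(subtypes)
  other <- sprintf("GENE-%04d", seq_len(n_other))
  list(genes = c(unlist(marker_list, use.names = FALSE), mito, other),
       markers = marker_list, mito = mito)
}

#' Simulate a hashed tumor single-nucleus cohort
#'
#' Draws sparse negative-binomial UMI counts for a multi-subtype tumor
#' cohort. Each subtype carries a block of planted marker genes whose mean is
#' elevated by `cfg$marker_lfc` (log2) in that subtype; a set of `MT-` genes
#' receives a per-cell scaling so the expected mitochondrial UMI fraction
#' falls in `cfg$mito_fraction_range`. A hashtag-oligo (HTO) count table with
#' singlets, doublets, true negatives and recoverable negatives accompanies
#' the matrix.
#'
#' @param cfg A [synth_config()].
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list with elements
#'   * `counts`: sparse cells x genes integer matrix (`dgCMatrix`),
#'   * `cells`: tibble of per-cell truth (`cell_id`, `sample`, `compartment`,
#'     `subtype`),
#'   * `hto`: tibble of HTO counts, the initial demultiplexing call, and the
#'     ground-truth class (`singlet`, `doublet`, `negative`, `recoverable`),
#'   * `markers`: tibble of planted markers with their log2 fold change,
#'   * `mito_genes`: character vector of mitochondrial gene names,
#'   * `hto_thresholds`: named per-hashtag minimum counts.
#' @export
#' @examples
#' sim <- generate_tumor_cohort(synth_config(), seed = 1)
#' dim(sim$counts)
generate_tumor_cohort <- function(cfg, seed = 1L) {
  validate_synth_config(cfg)
  withr::local_seed(seed)
  uni <- build_gene_universe(cfg)
  subtypes <- names(cfg$n_cells)
  n_cells <- sum(cfg$n_cells)
  subtype <- rep(subtypes, times = cfg$n_cells)
  cell_id <- sprintf("cell-%05d", seq_len(n_cells))

  # baseline per-gene means; markers kept off the sparse tail so their
  # empirical fold change is estimable at a few hundred cells
  base_mu <- stats::rlnorm(length(uni$genes), meanlog = log(cfg$nb_mean),
                           sdlog = 0.4)
  names(base_mu) <- uni$genes
  for (s in subtypes) base_mu[uni$markers[[s]]] <- pmax(base_mu[uni$markers[[s]]], cfg$nb_mean)

  mu <- matrix(rep(base_mu, each = n_cells), nrow = n_cells,
               dimnames = list(cell_id, uni$genes))
  for (s in subtypes) {
    mu[subtype == s, uni$markers[[s]]] <-
      mu[subtype == s, uni$markers[[s]]] * 2^cfg$marker_lfc
  }
  # per-cell mitochondrial load: scale MT- genes to hit a target fraction
  target_frac <- runif(n_cells, cfg$mito_fraction_range[1],
                       cfg$mito_fraction_range[2])
  non_mito_total <- rowSums(mu[, setdiff(uni$genes, uni$mito), drop = FALSE])
  mito_base <- sum(base_mu[uni$mito])
  scale_mt <- target_frac / (1 - target_frac) * non_mito_total / mito_base
  mu[, uni$mito] <- mu[, uni$mito] * scale_mt

  counts <- matrix(rnbinom(length(mu), mu = mu, size = cfg$nb_dispersion),
                   nrow = n_cells, dimnames = dimnames(mu))
  cells <- tibble::tibble(
    cell_id = cell_id,
    sample = sprintf("S%d", 1L + (seq_len(n_cells) - 1L) %% cfg$n_hashtags),
    compartment = unname(cfg$compartments[subtype]),
    subtype = subtype)

  markers <- tidyr::unnest(
    tibble::tibble(subtype = subtypes,
                   gene = unname(uni$markers[subtypes])),
    "gene")
  markers$planted_lfc <- cfg$marker_lfc

  hto <- simulate_hto(cells, cfg)

  list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
       cells = cells, hto = hto$table, markers = markers,
       mito_genes = uni$mito, hto_thresholds = hto$thresholds)
}

# HTO counts: the true hashtag is high for singlets; doublets carry two high
# hashtags; negatives are low everywhere; "recoverable" cells exceed the
# threshold for exactly one hashtag yet enter with an initial negative call.
simulate_hto <- function(cells, cfg) {
  n <- nrow(cells)
  tags <- sprintf("HTO%d", seq_len(cfg$n_hashtags))
  thresholds <- setNames(rep(100L, cfg$n_hashtags), tags)
  class_probs <- c(doublet = cfg$doublet_rate,
                   recoverable = cfg$recoverable_rate,
                   negative = cfg$negative_rate)
  class <- sample(c(names(class_probs), "singlet"), n, replace = TRUE,
                  prob = c(class_probs, 1 - sum(class_probs)))
  true_tag <- match(cells$sample, sprintf("S%d", seq_len(cfg$n_hashtags)))
  counts <- matrix(rnbinom(n * cfg$n_hashtags, mu = 8, size = 2), nrow = n,
                   dimnames = list(cells$cell_id, tags))
  high <- function(k) rnbinom(k, mu = 400, size = 6)
  mid <- function(k) 120L + rnbinom(k, mu = 60, size = 6)  # clears threshold
  sing <- class == "singlet"
  counts[cbind(which(sing), true_tag[sing])] <- high(sum(sing))
  dbl <- which(class == "doublet")
  if (length(dbl)) {
    other <- vapply(true_tag[dbl], function(t) {
      sample(setdiff(seq_len(cfg$n_hashtags), t), 1L)
    }, integer(1))
    counts[cbind(dbl, true_tag[dbl])] <- high(length(dbl))
    counts[cbind(dbl, other)] <- high(length(dbl))
  }
  rec <- which(class == "recoverable")
  if (length(rec)) counts[cbind(rec, true_tag[rec])] <- mid(length(rec))
  initial <- ifelse(class == "singlet", tags[true_tag],
                    ifelse(class == "doublet", "doublet", "negative"))
  tbl <- tibble::as_tibble(counts)
  tbl <- dplyr::bind_cols(tibble::tibble(cell_id = cells$cell_id), tbl)
  tbl$initial_call <- initial
  tbl$true_class <- class
  list(table = tbl, thresholds = thresholds)
}

#' Simulate a normal-epithelium cohort with a latent differentiation time
#'
#' Each cell receives a latent time drawn uniformly on \[0, 1\] (or supplied
#' via `times`); a configured number of "time genes" have negative-binomial
#' means linear in latent time, giving positive count-time correlation, while
#' all remaining genes are time-independent.
#'
#' @param cfg A [synth_config()] (supplies `n_genes`, `nb_mean`,
#'   `nb_dispersion`).
#' @param seed Integer seed.
#' @param n_cells Number of cells.
#' @param n_time_genes Number of genes whose mean tracks latent time.
#' @param time_slope Multiplicative range of the time-gene mean across the
#'   time axis (mean at t = 1 is `1 + time_slope` times the mean at t = 0).
#' @param time_dispersion Residual negative-binomial dispersion (`size`) of
#'   time genes after conditioning on latent time. Larger than the global
#'   `nb_dispersion` because the time trend absorbs most of these genes'
#'   biological variance, leaving count-time correlations around 0.5-0.7.
#' @param times Optional numeric vector of latent times in \[0, 1\]; its
#'   length overrides `n_cells`. Useful for simulating tumor-like query
#'   cells at known positions along the axis.
#' @param sample_id Sample label recorded for every cell.
#' @param base_seed Seed for the per-gene baseline means. Kept separate
#'   from `seed` so different cohorts (e.g. a normal reference and
#'   tumor-like queries) share the same gene-level baselines, as cells of
#'   one tissue do, while their cells and counts differ.
#' @return List with `counts` (sparse cells x genes), `cells` (tibble with
#'   `cell_id`, `sample`, `latent_time`) and `time_genes`.
#' @export
generate_normal_cohort <- function(cfg, seed = 1L, n_cells = 500L,
                                   n_time_genes = 50L, time_slope = 6,
                                   time_dispersion = 20,
                                   times = NULL, sample_id = "N1",
                                   base_seed = 1000L) {
  validate_synth_config(cfg)
  withr::local_seed(seed)
  if (is.null(times)) {
    times <- runif(n_cells)
  } else {
    if (any(times < 0 | times > 1)) abort("`times` must lie in [0, 1].")
    n_cells <- length(times)
  }
  if (n_cells <= 0L) abort("`n_cells` must be positive.")
  genes <- sprintf("NGENE-%04d", seq_len(cfg$n_genes))
  time_genes <- character(0)
  if (n_time_genes > 0L) {
    if (n_time_genes > cfg$n_genes) abort("more time genes than genes.")
    time_genes <- genes[seq_len(n_time_genes)]
  }
  cell_id <- sprintf("%s-cell-%05d", sample_id, seq_len(n_cells))
  base_mu <- withr::with_seed(base_seed, {
    stats::rlnorm(cfg$n_genes, meanlog = log(cfg$nb_mean * 2), sdlog = 0.4)
  })
  mu <- matrix(rep(base_mu, each = n_cells), nrow = n_cells,
               dimnames = list(cell_id, genes))
  if (length(time_genes)) {
    mu[, time_genes] <- mu[, time_genes] * (1 + time_slope * times)
  }
  size <- matrix(cfg$nb_dispersion, n_cells, cfg$n_genes,
                 dimnames = dimnames(mu))
  if (length(time_genes)) size[, time_genes] <- time_dispersion
  counts <- matrix(rnbinom(length(mu), mu = mu, size = size),
                   nrow = n_cells, dimnames = dimnames(mu))
  list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
       cells = tibble::tibble(cell_id = cell_id, sample = sample_id,
                              latent_time = times),
       time_genes = time_genes)
}
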