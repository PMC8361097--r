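# Synthetic ligand-receptor prior: pairs plus receptor signature gene lists,
# standing in for a curated pair table with downstream-signaling signatures.

#' Simulate a ligand-receptor prior table
#'
#' Draws ligand and receptor genes from a gene universe and attaches to each
#' receptor a downstream signature gene list. A configured fraction of
#' receptors receives fewer than five signature genes so the minimum-size
#' exclusion rule is exercised downstream.
#'
#' @param cfg A [synth_config()] (supplies `lr_pairs`,
#'   `small_sig_fraction`).
#' @param gene_universe Character vector of genes to draw from. Defaults to
#'   a generic universe large enough for the configured pair count.
#' @param seed Integer seed.
#' @param planted Optional tibble with columns `ligand`, `receptor`,
#'   `signature` (list-column of character vectors) prepended verbatim, for
#'   planting known interactions.
#' @return Tibble with columns `ligand`, `receptor`, `signature`
#'   (list-column) and `n_signature_genes`.
#' @export
generate_lr_prior <- function(cfg, gene_universe = NULL, seed = 1L,
                              planted = NULL) {
  validate_synth_config(cfg)
  withr::local_seed(seed)
  n <- cfg$lr_pairs
  if (is.null(gene_universe)) {
    gene_universe <- sprintf("GENE-%04d", seq_len(max(20L * n, 200L)))
  }
  need <- 2L * n + 10L * n
  if (length(gene_universe) < need) {
    abort("gene universe too small for the requested number of pairs.")
  }
  pool <- sample(gene_universe)
  ligand <- pool[seq_len(n)]
  receptor <- pool[n + seq_len(n)]
  sig_pool <- pool[-(seq_len(2L * n))]
  n_small <- round(cfg$small_sig_fraction * n)
  sizes <- c(sample(2:4, n_small, replace = TRUE),
             sample(5:10, n - n_small, replace = TRUE))
  sizes <- sample(sizes)
  offsets <- cumsum(c(0L, head(sizes, -1L)))
  signature <- lapply(seq_len(n), function(i) {
    sig_pool[offsets[i] + seq_len(sizes[i])]
  })
  prior <- tibble::tibble(ligand = ligand, receptor = receptor,
                          signature = signature)
  if (!is.null(planted)) prior <- dplyr::bind_rows(planted, prior)
  prior$n_signature_genes <- lengths(prior$signature)
  validate_lr_prior(prior)
}

#' Validate a ligand-receptor prior table
#'
#' @param prior Tibble with `ligand`, `receptor` and a `signature`
#'   list-column.
#' @param gene_universe Optional; when given, every ligand, receptor and
#'   signature gene must be present in it.
#' @return The validated prior (invisibly re-typed as tibble).
#' @export
validate_lr_prior <- function(prior, gene_universe = NULL) {
  req <- c("ligand", "receptor", "signature")
  if (!all(req %in% names(prior))) {
    abort("prior must have columns ligand, receptor, signature.")
  }
  if (anyDuplicated(prior[, c("ligand", "receptor")])) {
    abort("duplicated ligand-receptor pair rows in prior.")
  }
  if (!is.null(gene_universe)) {
    used <- unique(c(prior$ligand, prior$receptor,
                     unlist(prior$signature, use.names = FALSE)))
    missing <- setdiff(used, gene_universe)
    if (length(missing)) {
      abort(sprintf("%d prior genes absent from the gene universe (e.g. %s).",
                    length(missing), missing[1]))
    }
  }
  tibble::as_tibble(prior)
}
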