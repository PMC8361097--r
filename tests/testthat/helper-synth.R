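# Shared fixtures: small configurations keep unit tests fast; the default
# configuration is reserved for the pipeline-level recovery tests.

cfg_default <- function() synth_config()

# Five subtypes x 200 cells, compact gene universe.
cfg_small <- function() {
  synth_config(
    n_cells = c(A = 60L, B = 60L, C = 60L, X = 60L, Y = 60L),
    compartments = c(A = "epithelial", B = "epithelial", C = "epithelial",
                     X = "fibroblast", Y = "fibroblast"),
    n_genes = 200L, marker_genes = 5L, grid_rows = 12L, grid_cols = 12L)
}

# Tiny deterministic count matrix with named axes.
toy_counts <- function(n_cells = 10L, n_genes = 6L, seed = 42L) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n_cells * n_genes, 5), n_cells, n_genes,
                dimnames = list(sprintf("c%02d", seq_len(n_cells)),
                                sprintf("g%02d", seq_len(n_genes))))
    m
  })
}

expect_tibble <- function(x) testthat::expect_s3_class(x, "tbl_df")
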