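# Disk interchange: MatrixMarket count matrices with TSV sidecars, GMT gene
# sets, spot-frame CSV+MTX directories.

#' Write / read a count matrix as MatrixMarket with sidecars
#'
#' The on-disk layout is the conventional triplet: `matrix.mtx` holding
#' genes x cells counts, `genes.tsv` and `barcodes.tsv` naming the axes.
#'
#' @param counts Cells x genes matrix.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly (write) or a sparse cells x genes matrix (read).
#' @export
write_count_matrix <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- Matrix::Matrix(Matrix::t(counts), sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(m), file.path(dir, "genes.tsv"))
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  rownames(m) <- readLines(file.path(dir, "genes.tsv"))
  colnames(m) <- readLines(file.path(dir, "barcodes.tsv"))
  methods::as(Matrix::t(m), "CsparseMatrix")
}

#' Write / read gene signatures in GMT format
#'
#' @param signatures Named list of character vectors, or a signature set as
#'   returned by [derive_subtype_signatures()].
#' @param path File path.
#' @return `path` invisibly (write); named list of gene vectors (read).
#' @export
write_gmt <- function(signatures, path) {
  if (is.data.frame(signatures)) {
    signatures <- split(signatures$gene, signatures$signature)
  }
  lines <- vapply(names(signatures), function(nm) {
    paste(c(nm, "nichemap", signatures[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  sets
}

#' Write / read a spot frame as CSV + MTX
#'
#' @param sf A `spot_frame`.
#' @param dir Directory.
#' @return `dir` invisibly (write); a `spot_frame` (read).
#' @export
write_spot_frame <- function(sf, dir) {
  write_count_matrix(sf$counts, dir)
  utils::write.csv(sf$spots, file.path(dir, "spots.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_spot_frame
#' @export
read_spot_frame <- function(dir, sample = basename(dir)) {
  counts <- read_count_matrix(dir)
  spots <- tibble::as_tibble(utils::read.csv(file.path(dir, "spots.csv")))
  new_spot_frame(counts, spots, sample = sample)
}
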