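# Readers and writers for the pipeline's on-disk formats: Matrix Market
# counts with features/barcodes TSVs, annotation TSVs, and GMT gene sets.
# All TSVs are UTF-8 with a header row and no quoting.

#' Read a sparse count matrix from Matrix Market files
#'
#' Expects a coordinate-format MTX with 1-based indices (genes stored on
#' whichever axis matches `features`), a features TSV and a barcodes TSV.
#' The returned matrix is nuclei x genes. The declared entry count is
#' validated against the body.
#'
#' @param mtx,features,barcodes file paths. `features` and `barcodes` are
#'   one-column (or first-column-used) TSVs without headers.
#' @return dgCMatrix with barcode rownames and feature colnames.
#' @export
read_counts_mtx <- function(mtx, features, barcodes) {
  for (f in c(mtx, features, barcodes)) {
    if (!file.exists(f)) abort(paste0("file not found: ", f))
  }
  header <- readLines(mtx, n = 1)
  if (!grepl("matrixmarket matrix coordinate (integer|real) general", tolower(header))) {
    abort("MTX header must declare 'matrix coordinate integer general' format.")
  }
  m <- withCallingHandlers(
    Matrix::readMM(mtx),
    warning = function(w) {
      abort(paste0("malformed MTX body in counts: ", conditionMessage(w)))
    }
  )
  feats <- readr::read_tsv(features, col_names = FALSE, show_col_types = FALSE)[[1]]
  bcs <- readr::read_tsv(barcodes, col_names = FALSE, show_col_types = FALSE)[[1]]
  if (nrow(m) == length(feats) && ncol(m) == length(bcs)) {
    m <- Matrix::t(m) # stored genes x cells; orient nuclei x genes
  } else if (!(nrow(m) == length(bcs) && ncol(m) == length(feats))) {
    abort(sprintf(
      "counts dimensions %d x %d match neither features (%d) nor barcodes (%d).",
      nrow(m), ncol(m), length(feats), length(bcs)
    ))
  }
  m <- methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
  dimnames(m) <- list(bcs, feats)
  m
}

write_plain_tsv <- function(x, path) {
  readr::write_tsv(x, path, quote = "none", escape = "none")
}

#' Write a dataset to MTX + TSV files
#'
#' Emits `matrix.mtx` (coordinate, 1-based, genes x cells), `features.tsv`,
#' `barcodes.tsv`, `cells.tsv`, `samples.tsv` and, when truth is supplied,
#' `ground_truth.tsv`, into `dir`.
#'
#' @param data an [sn_dataset()].
#' @param dir output directory (created if needed).
#' @param truth optional ground-truth ledger (the `truth` element of
#'   [simulate_dataset()]).
#' @return `dir`, invisibly.
#' @export
write_sn_dataset <- function(data, dir, truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::t(data$counts), file.path(dir, "matrix.mtx"))
  writeLines(colnames(data$counts), file.path(dir, "features.tsv"))
  writeLines(rownames(data$counts), file.path(dir, "barcodes.tsv"))
  write_plain_tsv(data$cells, file.path(dir, "cells.tsv"))
  write_plain_tsv(data$samples, file.path(dir, "samples.tsv"))
  if (!is.null(truth)) {
    write_plain_tsv(truth$deg_table, file.path(dir, "ground_truth.tsv"))
  }
  invisible(dir)
}

#' Read a dataset from MTX + TSV files
#'
#' @param dir directory written by [write_sn_dataset()] (or following the
#'   same layout).
#' @param control_label control genotype label.
#' @return an [sn_dataset()].
#' @export
read_sn_dataset <- function(dir, control_label = "control") {
  counts <- read_counts_mtx(
    file.path(dir, "matrix.mtx"),
    file.path(dir, "features.tsv"),
    file.path(dir, "barcodes.tsv")
  )
  cells <- readr::read_tsv(file.path(dir, "cells.tsv"), show_col_types = FALSE)
  samples <- readr::read_tsv(file.path(dir, "samples.tsv"), show_col_types = FALSE)
  if (!identical(rownames(counts), cells$cell_id)) {
    if (!setequal(rownames(counts), cells$cell_id)) {
      abort("counts barcodes do not match cells.tsv annotations.")
    }
    counts <- counts[cells$cell_id, , drop = FALSE]
  }
  sn_dataset(counts, cells, samples, control_label = control_label)
}

#' Read gene sets in GMT format
#'
#' @param path GMT file: one set per line, tab-separated
#'   `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' @return named list of character gene vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(p) {
    if (length(p) < 3) abort("GMT lines need a name, description and >= 1 gene.")
    p[-(1:2)]
  })
  names(sets) <- vapply(strsplit(lines, "\t"), `[`, "", 1)
  sets
}
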