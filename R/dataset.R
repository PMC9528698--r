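#' Annotated single-nucleus count dataset
#'
#' Bundles a sparse nuclei x genes count matrix with its per-nucleus cell
#' annotations and per-sample metadata. This is the universal input of the
#' pipeline; [simulate_dataset()] produces one and [read_sn_dataset()] loads
#' one from MTX/TSV files.
#'
#' @param counts sparse (or dense, coerced) nonnegative integer matrix,
#'   nuclei in rows, genes in columns. Row names are cell ids, column names
#'   gene symbols.
#' @param cells data frame with one row per nucleus: `cell_id`, `cell_type`,
#'   `cell_state`, `sample_id`, in the row order of `counts`.
#' @param samples data frame with one row per sample: `sample_id`,
#'   `patient_id`, `genotype`, `region`, `sex`, `age`.
#' @param control_label genotype label denoting controls.
#'
#' @return An object of class `sn_dataset`: a list with elements `counts`
#'   (`dgCMatrix`), `cells` (tibble), `samples` (tibble), `control_label`.
#' @export
sn_dataset <- function(counts, cells, samples, control_label = "control") {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  cells <- as_tibble(cells)
  samples <- as_tibble(samples)
  need_cells <- c("cell_id", "cell_type", "cell_state", "sample_id")
  need_samples <- c("sample_id", "patient_id", "genotype", "region", "sex", "age")
  if (!all(need_cells %in% names(cells))) {
    abort(paste0("`cells` must contain columns: ", paste(need_cells, collapse = ", ")))
  }
  if (!all(need_samples %in% names(samples))) {
    abort(paste0("`samples` must contain columns: ", paste(need_samples, collapse = ", ")))
  }
  if (nrow(counts) != nrow(cells)) {
    abort(sprintf(
      "counts has %d rows but cells has %d rows; every nucleus needs an annotation.",
      nrow(counts), nrow(cells)
    ))
  }
  if (any(counts@x < 0) || any(counts@x != round(counts@x))) {
    abort("counts must be nonnegative integers.")
  }
  missing_samples <- setdiff(unique(cells$sample_id), samples$sample_id)
  if (length(missing_samples) > 0) {
    abort(paste0(
      "cells reference sample ids absent from sample metadata: ",
      paste(missing_samples, collapse = ", ")
    ))
  }
  if (anyDuplicated(samples$sample_id)) {
    abort("sample ids must be unique in sample metadata.")
  }
  rownames(counts) <- cells$cell_id
  structure(
    list(
      counts = counts, cells = cells, samples = samples,
      control_label = control_label
    ),
    class = "sn_dataset"
  )
}

#' @export
print.sn_dataset <- function(x, ...) {
  cat(sprintf(
    "<sn_dataset> %d nuclei x %d genes | %d samples, %d patients\n",
    nrow(x$counts), ncol(x$counts), nrow(x$samples),
    length(unique(x$samples$patient_id))
  ))
  cat(
    "genotypes:",
    paste(names(table(x$samples$genotype)), table(x$samples$genotype),
      sep = "=", collapse = " "
    ), "\n"
  )
  invisible(x)
}

#' @export
dim.sn_dataset <- function(x) dim(x$counts)

# cells joined with their sample metadata (genotype, region, patient, ...).
cell_metadata <- function(data) {
  left_join(data$cells, data$samples, by = "sample_id")
}

# Subset an sn_dataset by a logical/integer nucleus index.
subset_nuclei <- function(data, idx) {
  counts <- data$counts[idx, , drop = FALSE]
  cells <- data$cells[idx, , drop = FALSE]
  keep <- data$samples$sample_id %in% unique(cells$sample_id)
  sn_dataset(counts, cells, data$samples[keep, , drop = FALSE],
    control_label = data$control_label
  )
}
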