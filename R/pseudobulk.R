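#' Aggregate nuclei into pseudobulk units
#'
#' Sums raw counts over nuclei within each (sample, cell category) unit at
#' the requested annotation level. Units with fewer than `min_nuclei` nuclei
#' are dropped with a message; downstream tests treat each surviving unit as
#' one bulk replicate.
#'
#' @param data an [sn_dataset()].
#' @param level `"type"` or `"state"`.
#' @param min_nuclei minimum nuclei per retained unit (default 10).
#' @return A `pseudobulk` object: list with `counts` (dense units x genes
#'   matrix), `units` (tibble: unit_id, sample_id, category, n_nuclei,
#'   lib_size plus sample metadata) and `level`.
#' @export
aggregate_pseudobulk <- function(data, level = c("type", "state"), min_nuclei = 10L) {
  level <- match.arg(level)
  if (min_nuclei < 1) abort("`min_nuclei` must be >= 1.")
  col <- if (level == "type") "cell_type" else "cell_state"
  grp <- paste(data$cells$sample_id, data$cells[[col]], sep = "|")
  ind <- Matrix::fac2sparse(factor(grp))
  counts <- as.matrix(ind %*% data$counts)
  n_nuclei <- as.integer(table(factor(grp))[rownames(counts)])
  parts <- strsplit(rownames(counts), "|", fixed = TRUE)
  units <- tibble(
    unit_id = rownames(counts),
    sample_id = vapply(parts, `[`, "", 1),
    category = vapply(parts, `[`, "", 2),
    n_nuclei = n_nuclei,
    lib_size = unname(rowSums(counts))
  ) |>
    left_join(data$samples, by = "sample_id")
  keep <- units$n_nuclei >= min_nuclei
  if (any(!keep)) {
    inform(sprintf(
      "dropped %d pseudobulk unit(s) with < %d nuclei.", sum(!keep), min_nuclei
    ))
  }
  structure(
    list(
      counts = counts[keep, , drop = FALSE],
      units = units[keep, , drop = FALSE],
      level = level,
      control_label = data$control_label
    ),
    class = "pseudobulk"
  )
}

#' @export
print.pseudobulk <- function(x, ...) {
  cat(sprintf(
    "<pseudobulk> %d units x %d genes (level: %s)\n",
    nrow(x$counts), ncol(x$counts), x$level
  ))
  invisible(x)
}

#' Expression filter and TMM-style normalization factors
#'
#' Keeps genes with CPM > `cpm_cut` in at least `min(arm sizes)` units and
#' computes trimmed-mean-of-M normalization factors: the reference unit is
#' the one whose 75th count-proportion quantile is closest to the mean; per
#' unit, gene-wise log2 ratios vs the reference are doubly trimmed (30% on M,
#' 5% on A) and averaged with inverse-variance weights; factors are rescaled
#' so their logs average 0.
#'
#' @param counts units x genes matrix of summed counts.
#' @param groups factor of length `nrow(counts)` giving the contrast arm of
#'   each unit (used only for the filter's minimum-arm rule; may be a single
#'   level).
#' @param cpm_cut CPM threshold (default 1).
#' @return list with `keep` (logical per gene), `norm_factors` (per unit,
#'   log-mean 0) and `offsets` (`log(lib_size * factor)` per unit).
#' @export
filter_and_normalize <- function(counts, groups = NULL, cpm_cut = 1) {
  lib <- rowSums(counts)
  if (any(lib == 0)) abort("pseudobulk unit with zero library size.")
  cpm <- counts / lib * 1e6
  min_arm <- if (is.null(groups)) nrow(counts) else min(table(groups))
  keep <- colSums(cpm > cpm_cut) >= min_arm
  if (!any(keep)) abort("all genes removed by the expression filter.")
  y <- counts[, keep, drop = FALSE]
  f <- tmm_factors(y)
  list(
    keep = keep,
    norm_factors = f,
    offsets = log(rowSums(counts) * f)
  )
}

# Trimmed weighted mean of M-values, one factor per unit (row).
tmm_factors <- function(y, trim_m = 0.3, trim_a = 0.05) {
  lib <- rowSums(y)
  uq <- apply(y, 1, function(v) quantile(v / sum(v), 0.75, names = FALSE))
  ref <- which.min(abs(uq - mean(uq)))
  yr <- y[ref, ]
  nr <- lib[ref]
  f <- vapply(seq_len(nrow(y)), function(i) {
    if (i == ref) return(1)
    yi <- y[i, ]
    ni <- lib[i]
    ok <- yi > 0 & yr > 0
    yi <- yi[ok]
    yk <- yr[ok]
    m <- log2((yi / ni) / (yk / nr))
    a <- 0.5 * (log2(yi / ni) + log2(yk / nr))
    w <- (ni - yi) / (ni * yi) + (nr - yk) / (nr * yk)
    n <- length(m)
    lo_m <- floor(n * trim_m) + 1
    hi_m <- n + 1 - lo_m
    lo_a <- floor(n * trim_a) + 1
    hi_a <- n + 1 - lo_a
    rm_ <- rank(m, ties.method = "first")
    ra_ <- rank(a, ties.method = "first")
    keep <- rm_ >= lo_m & rm_ <= hi_m & ra_ >= lo_a & ra_ <= hi_a
    if (!any(keep)) return(1)
    2^(sum(w[keep] * m[keep]) / sum(w[keep]))
  }, numeric(1))
  f / exp(mean(log(f)))
}
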