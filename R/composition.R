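#' Cell-type or cell-state composition of each sample
#'
#' Counts nuclei per (sample, category) at the requested annotation level and
#' joins sample metadata. Categories unobserved in a sample get 0; a category
#' absent everywhere is retained as a zero column if it is listed in
#' `categories`. Samples without any nuclei are excluded with a warning.
#'
#' @param data an [sn_dataset()].
#' @param level `"type"` or `"state"`.
#' @param categories optional character vector fixing the category universe
#'   (defaults to the categories observed in the data).
#' @return A tibble with one row per sample: metadata columns, then one
#'   integer count column per category; attributes `categories` and `level`.
#' @export
compute_composition <- function(data, level = c("type", "state"), categories = NULL) {
  level <- match.arg(level)
  col <- if (level == "type") "cell_type" else "cell_state"
  cells <- data$cells
  if (!col %in% names(cells)) abort(sprintf("annotation column '%s' missing.", col))
  categories <- categories %||% sort(unique(cells[[col]]))
  counts <- cells |>
    count(.data$sample_id, category = factor(.data[[col]], levels = categories)) |>
    tidyr::complete(.data$sample_id, .data$category, fill = list(n = 0L)) |>
    pivot_wider(names_from = "category", values_from = "n", values_fill = 0L)
  empty <- setdiff(data$samples$sample_id, counts$sample_id)
  if (length(empty) > 0) {
    warn(paste0("samples with no nuclei excluded from composition: ",
      paste(empty, collapse = ", ")))
  }
  out <- inner_join(data$samples, counts, by = "sample_id")
  attr(out, "categories") <- categories
  attr(out, "level") <- level
  attr(out, "control_label") <- data$control_label
  out
}

composition_categories <- function(table) {
  cats <- attr(table, "categories")
  if (is.null(cats)) {
    cats <- setdiff(
      names(table),
      c("sample_id", "patient_id", "genotype", "region", "sex", "age")
    )
  }
  cats
}

#' Centered log-ratio transform of a composition table
#'
#' Adds a positive pseudocount to every count, takes natural logs, and
#' centres each sample's log counts on their mean, so each row of the CLR
#' matrix sums to zero.
#'
#' @param table output of [compute_composition()].
#' @param pseudocount positive additive constant applied to counts before
#'   the log (default 0.5).
#' @return Tibble with the same metadata columns and CLR values in the
#'   category columns; attribute `pseudocount`.
#' @export
clr_transform <- function(table, pseudocount = 0.5) {
  check_positive_scalar(pseudocount, "pseudocount")
  cats <- composition_categories(table)
  m <- log(as.matrix(table[, cats]) + pseudocount)
  m <- m - rowMeans(m)
  out <- table
  out[, cats] <- as_tibble(m)
  attr(out, "pseudocount") <- pseudocount
  attr(out, "categories") <- cats
  attr(out, "level") <- attr(table, "level")
  attr(out, "control_label") <- attr(table, "control_label")
  out
}

#' Covariate-adjusted abundance test on CLR values
#'
#' For each category, fits an ordinary least squares model
#' `clr ~ condition + covariates` on the samples of one genotype-vs-control
#' contrast and reports the two-sided t-test of the condition coefficient,
#' with Benjamini-Hochberg adjustment across categories within the contrast.
#'
#' @param clr output of [clr_transform()].
#' @param genotype disease genotype to contrast against controls.
#' @param control control label (defaults to the table's recorded label).
#' @param covariates subset of `c("age", "sex", "region")` to adjust for.
#' @param region optional region filter applied before testing (e.g. `"LV"`).
#' @return Tibble: `category`, `contrast`, `estimate` (CLR units),
#'   `std.error`, `statistic`, `p.value`, `fdr`.
#' @export
test_abundance <- function(clr, genotype, control = NULL,
                           covariates = character(), region = NULL) {
  control <- control %||% attr(clr, "control_label") %||% "control"
  if (length(covariates) > 0) {
    covariates <- unique(match.arg(covariates, c("age", "sex", "region"), several.ok = TRUE))
  }
  cats <- composition_categories(clr)
  dat <- clr
  if (!is.null(region)) dat <- dat[dat$region %in% region, , drop = FALSE]
  dat <- dat[dat$genotype %in% c(genotype, control), , drop = FALSE]
  dat$condition <- factor(dat$genotype, levels = c(control, genotype))
  if (min(table(dat$condition)) < 2) {
    abort("need at least 2 samples per contrast arm after region filtering.")
  }
  constant <- covariates[vapply(covariates, function(cv) {
    length(unique(dat[[cv]])) < 2
  }, logical(1))]
  if (length(constant) > 0) {
    abort(paste0("design is rank deficient; collinear term(s): ",
      paste(constant, collapse = ", ")))
  }
  rhs <- paste(c("condition", covariates), collapse = " + ")
  mm <- model.matrix(stats::as.formula(paste("~", rhs)), data = dat)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    dropped <- colnames(mm)[qr_mm$pivot[seq(qr_mm$rank + 1, ncol(mm))]]
    abort(paste0("design is rank deficient; collinear term(s): ",
      paste(dropped, collapse = ", ")))
  }
  res <- purrr::map_dfr(cats, function(cc) {
    fit <- lm(stats::as.formula(paste0("`", cc, "` ~ ", rhs)), data = dat)
    sm <- summary(fit)$coefficients
    row <- sm[paste0("condition", genotype), ]
    tibble(
      category = cc,
      contrast = paste0(genotype, "_vs_", control),
      estimate = unname(row["Estimate"]),
      std.error = unname(row["Std. Error"]),
      statistic = unname(row["t value"]),
      p.value = unname(row["Pr(>|t|)"])
    )
  })
  res$fdr <- bh_adjust(res$p.value)
  res
}

#' Pairwise cell-type abundance ratio test
#'
#' For every ordered category pair (A, B) computes per-sample
#' `r = log2((A + pseudocount) / (B + pseudocount))` and contrasts disease vs
#' control with a Welch (unequal-variance) t-test. The reported `difference`
#' is disease mean minus control mean and `fold_change = 2^difference`.
#' BH adjustment is applied across all pairs of the contrast.
#'
#' @inheritParams test_abundance
#' @param table output of [compute_composition()] (raw counts).
#' @param pseudocount additive constant (default 0.5).
#' @param pairs optional two-column data frame of ordered pairs to test
#'   (defaults to all ordered pairs of distinct categories).
#' @return Tibble: `category_a`, `category_b`, `mean_disease`,
#'   `mean_control`, `difference`, `fold_change`, `p.value`, `fdr`.
#' @export
pairwise_ratio_test <- function(table, genotype, control = NULL, region = NULL,
                                pseudocount = 0.5, pairs = NULL) {
  control <- control %||% attr(table, "control_label") %||% "control"
  cats <- composition_categories(table)
  if (is.null(pairs)) {
    pairs <- tidyr::crossing(category_a = cats, category_b = cats) |>
      filter(.data$category_a != .data$category_b)
  } else {
    pairs <- tibble(category_a = pairs[[1]], category_b = pairs[[2]])
    missing <- setdiff(unique(c(pairs$category_a, pairs$category_b)), cats)
    if (length(missing) > 0) {
      abort(paste0("categories not present in the composition table: ",
        paste(missing, collapse = ", ")))
    }
  }
  dat <- table
  if (!is.null(region)) dat <- dat[dat$region %in% region, , drop = FALSE]
  dis <- dat[dat$genotype == genotype, , drop = FALSE]
  ctl <- dat[dat$genotype == control, , drop = FALSE]
  if (nrow(dis) < 2 || nrow(ctl) < 2) {
    abort("need at least 2 samples per arm for the Welch test.")
  }
  res <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    a <- pairs$category_a[i]
    b <- pairs$category_b[i]
    r_dis <- log2((dis[[a]] + pseudocount) / (dis[[b]] + pseudocount))
    r_ctl <- log2((ctl[[a]] + pseudocount) / (ctl[[b]] + pseudocount))
    p <- tryCatch(t.test(r_dis, r_ctl, var.equal = FALSE)$p.value,
      error = function(e) NA_real_) # degenerate zero-variance ratios
    tibble(
      category_a = a, category_b = b,
      contrast = paste0(genotype, "_vs_", control),
      mean_disease = mean(r_dis), mean_control = mean(r_ctl),
      difference = mean(r_dis) - mean(r_ctl),
      fold_change = 2^(mean(r_dis) - mean(r_ctl)),
      p.value = p
    )
  })
  res$fdr <- bh_adjust(res$p.value)
  res
}

#' Pearson correlation of cell-type proportions between replicate samples
#'
#' @param table output of [compute_composition()].
#' @param pairs data frame with columns `sample_a`, `sample_b` naming
#'   replicate sample pairs.
#' @return Tibble: `sample_a`, `sample_b`, `pearson_r` (NA with a warning
#'   when a proportion vector is constant).
#' @export
replicate_correlation <- function(table, pairs) {
  cats <- composition_categories(table)
  m <- as.matrix(table[, cats])
  props <- m / rowSums(m)
  rownames(props) <- table$sample_id
  purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    a <- pairs$sample_a[i]
    b <- pairs$sample_b[i]
    if (!a %in% rownames(props) || !b %in% rownames(props)) {
      abort(sprintf("replicate pair (%s, %s) not found in the table.", a, b))
    }
    va <- props[a, ]
    vb <- props[b, ]
    r <- if (sd(va) == 0 || sd(vb) == 0) {
      warn(sprintf("constant proportion vector in pair (%s, %s); correlation undefined.", a, b))
      NA_real_
    } else {
      cor(va, vb)
    }
    tibble(sample_a = a, sample_b = b, pearson_r = r)
  })
}
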