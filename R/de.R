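# Negative-binomial pseudobulk differential expression: grid-based
# Cox-Reid dispersion estimation with shrinkage toward a common value,
# then a per-gene likelihood-ratio test of the condition coefficient.

# NB log-likelihood, phi = dispersion (1/size); phi -> 0 uses Poisson.
nb_loglik_rows <- function(y, mu, phi) {
  # y, mu: genes x units matrices; phi: per-gene vector. Returns per-gene sum.
  ll <- matrix(0, nrow(y), ncol(y))
  pois <- phi < 1e-12
  if (any(pois)) {
    ll[pois, ] <- dpois(y[pois, , drop = FALSE], lambda = mu[pois, , drop = FALSE], log = TRUE)
  }
  if (any(!pois)) {
    i <- which(!pois)
    ll[i, ] <- dnbinom(y[i, , drop = FALSE],
      mu = mu[i, , drop = FALSE],
      size = 1 / phi[i], log = TRUE
    )
  }
  rowSums(ll)
}

# Vectorised one-way NB fit by Fisher scoring: one coefficient per group,
# offsets per unit, dispersion per gene. y is genes x units.
nb_fit_oneway <- function(y, offsets, groups, phi, max_iter = 100L, tol = 1e-10) {
  groups <- as.factor(groups)
  levs <- levels(groups)
  g <- nrow(y)
  beta <- matrix(0, g, length(levs), dimnames = list(NULL, levs))
  converged <- rep(TRUE, g)
  eo <- exp(offsets)
  for (li in seq_along(levs)) {
    idx <- which(groups == levs[li])
    yg <- y[, idx, drop = FALSE]
    eog <- eo[idx]
    b <- log((rowSums(yg) + 0.5) / sum(eog))
    conv <- rep(FALSE, g)
    for (it in seq_len(max_iter)) {
      mu <- tcrossprod(exp(b), eog)
      denom <- 1 + phi * mu
      score <- rowSums((yg - mu) / denom)
      info <- rowSums(mu / denom)
      step <- score / pmax(info, 1e-12)
      step <- pmin(pmax(step, -5), 5)
      b <- b + step
      done <- abs(step) < tol
      conv <- done
      if (all(done)) break
    }
    converged <- converged & (conv | rowSums(yg) == 0)
    beta[, li] <- b
  }
  mu <- exp(beta[, as.integer(groups), drop = FALSE] +
    matrix(offsets, g, length(offsets), byrow = TRUE))
  list(
    beta = beta, mu = mu,
    loglik = nb_loglik_rows(y, mu, phi),
    converged = converged
  )
}

# Cox-Reid adjusted profile log-likelihood for the one-way fit:
# loglik - 0.5 * sum_groups log(sum_i w_i), w = mu/(1+phi*mu).
nb_apl_oneway <- function(y, offsets, groups, phi_scalar) {
  phi <- rep(phi_scalar, nrow(y))
  fit <- nb_fit_oneway(y, offsets, groups, phi)
  w <- fit$mu / (1 + phi * fit$mu)
  adj <- 0
  for (lev in levels(as.factor(groups))) {
    idx <- which(as.factor(groups) == lev)
    adj <- adj + log(pmax(rowSums(w[, idx, drop = FALSE]), 1e-300))
  }
  fit$loglik - 0.5 * adj
}

#' Moderated NB dispersion estimation on a likelihood grid
#'
#' Maximises the Cox-Reid adjusted profile likelihood of a one-way NB model
#' on a fixed log2-spaced dispersion grid. The common dispersion maximises
#' the profile summed over genes; each gene's shrunken dispersion maximises
#' its own profile plus `prior_df` times the average (common) profile, and
#' is clamped to lie between the raw and common estimates.
#'
#' @param counts units x genes matrix (filtered).
#' @param groups factor giving each unit's arm.
#' @param offsets per-unit log effective library sizes (from
#'   [filter_and_normalize()]).
#' @param grid dispersion grid (default 50 points on `2^seq(-15, 5)`).
#' @param prior_df weight of the common-likelihood contribution (default 10).
#' @return list with `common` (scalar), and per-gene `raw`, `shrunken`
#'   vectors, plus `prior_df` and `grid`.
#' @export
estimate_dispersion <- function(counts, groups, offsets,
                                grid = 2^seq(-15, 5, length.out = 50),
                                prior_df = 10) {
  groups <- as.factor(groups)
  if (length(offsets) != nrow(counts)) abort("offsets must match units.")
  n <- nrow(counts)
  p <- nlevels(groups)
  if (n - p < 1) abort("residual degrees of freedom must be >= 1.")
  y <- t(counts)
  apl <- vapply(grid, function(phi) nb_apl_oneway(y, offsets, groups, phi),
    numeric(nrow(y))
  )
  raw <- grid[max.col(apl, ties.method = "first")]
  common_idx <- which.max(colSums(apl))
  common <- grid[common_idx]
  apl_bar <- colMeans(apl)
  score <- apl + prior_df * matrix(apl_bar, nrow(apl), ncol(apl), byrow = TRUE)
  shrunken <- grid[max.col(score, ties.method = "first")]
  lo <- pmin(raw, common)
  hi <- pmax(raw, common)
  shrunken <- pmin(pmax(shrunken, lo), hi)
  list(common = common, raw = raw, shrunken = shrunken,
    prior_df = prior_df, grid = grid)
}

#' Per-gene NB likelihood-ratio test of a two-arm contrast
#'
#' Fits the one-way NB log-linear model (offset = log effective library
#' size) under the full (two groups) and null (single group) designs and
#' reports the 1-df likelihood-ratio chi-square test per gene, with BH
#' adjustment over the tested genes. Genes whose fit does not converge get
#' `p.value = NA` and are flagged.
#'
#' @param counts units x genes matrix of the contrast's units (filtered).
#' @param condition factor with the control level first.
#' @param offsets per-unit log effective library size.
#' @param dispersion per-gene dispersion (e.g. `$shrunken` from
#'   [estimate_dispersion()]); scalar recycled. Use 0 for Poisson.
#' @return Tibble per gene: `gene`, `logFC` (log2, disease vs control),
#'   `logCPM`, `dispersion`, `statistic` (LRT chi-square), `p.value`, `fdr`,
#'   `converged`.
#' @export
test_de <- function(counts, condition, offsets, dispersion) {
  condition <- as.factor(condition)
  if (nlevels(condition) != 2) abort("`condition` must have exactly two levels.")
  if (min(table(condition)) < 1) abort("both contrast arms must be non-empty.")
  y <- t(counts)
  phi <- rep_len(dispersion, nrow(y))
  full <- nb_fit_oneway(y, offsets, condition, phi)
  null <- nb_fit_oneway(y, offsets, factor(rep("all", ncol(y))), phi)
  lrt <- pmax(2 * (full$loglik - null$loglik), 0)
  converged <- full$converged & null$converged
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  p[!converged] <- NA_real_
  logcpm <- log2(rowMeans(t(t(y) / exp(offsets)) * 1e6) + 0.25)
  out <- tibble(
    gene = colnames(counts) %||% as.character(seq_len(ncol(counts))),
    logFC = (full$beta[, levels(condition)[2]] - full$beta[, levels(condition)[1]]) / log(2),
    logCPM = logcpm,
    dispersion = phi,
    statistic = lrt,
    p.value = p,
    converged = converged
  )
  out$fdr <- bh_adjust(out$p.value)
  out
}

#' Pseudobulk differential expression for one genotype contrast
#'
#' Convenience wrapper chaining [filter_and_normalize()],
#' [estimate_dispersion()] and [test_de()] for one (genotype, region, cell
#' category) contrast against controls.
#'
#' @param pb a [aggregate_pseudobulk()] result.
#' @param genotype disease genotype.
#' @param category cell category (type or state) to test.
#' @param control control label (defaults to the object's).
#' @param region optional region filter.
#' @param min_units minimum units per arm (default 2).
#' @param prior_df dispersion shrinkage weight.
#' @return [test_de()] tibble with `genotype`, `region`, `category` columns
#'   prepended.
#' @export
de_test <- function(pb, genotype, category, control = NULL, region = NULL,
                    min_units = 2L, prior_df = 10) {
  control <- control %||% pb$control_label %||% "control"
  sel <- pb$units$category == category &
    pb$units$genotype %in% c(control, genotype)
  if (!is.null(region)) sel <- sel & pb$units$region %in% region
  units <- pb$units[sel, , drop = FALSE]
  counts <- pb$counts[sel, , drop = FALSE]
  condition <- factor(units$genotype, levels = c(control, genotype))
  if (nlevels(droplevels(condition)) < 2 || min(table(condition)) < min_units) {
    abort(sprintf(
      "contrast %s vs %s in category '%s' has an empty or undersized arm.",
      genotype, control, category
    ))
  }
  fn <- filter_and_normalize(counts, condition)
  kept <- counts[, fn$keep, drop = FALSE]
  disp <- estimate_dispersion(kept, condition, fn$offsets, prior_df = prior_df)
  res <- test_de(kept, condition, fn$offsets, disp$shrunken)
  mutate(res,
    genotype = genotype, region = paste(region %||% "all", collapse = "+"),
    category = category, .before = 1
  )
}

#' Partition differentially expressed genes into shared and specific sets
#'
#' A gene is a DEG for a genotype when `fdr <= fdr_cut`. The shared set
#' contains genes differentially expressed in every genotype; a genotype's
#' specific percentage is the share of its DEGs found in no other genotype.
#'
#' @param results tibble with columns `genotype`, `gene`, `fdr` (e.g. bound
#'   rows of [de_test()] across genotypes for one category).
#' @param fdr_cut DEG threshold (default 0.05).
#' @return Tibble per genotype: `n_deg`, `n_specific`, `pct_specific`
#'   (NA when the genotype has no DEGs), plus attribute `shared_genes`.
#' @export
partition_degs <- function(results, fdr_cut = 0.05) {
  genos <- unique(results$genotype)
  universes <- lapply(genos, function(g) sort(unique(results$gene[results$genotype == g])))
  if (length(unique(vapply(universes, paste, "", collapse = ","))) != 1) {
    abort("all genotypes must be tested on the same gene universe.")
  }
  sets <- lapply(genos, function(g) {
    r <- results[results$genotype == g, ]
    unique(r$gene[!is.na(r$fdr) & r$fdr <= fdr_cut])
  })
  names(sets) <- genos
  shared <- Reduce(intersect, sets)
  out <- purrr::map_dfr(genos, function(g) {
    others <- unique(unlist(sets[setdiff(genos, g)]))
    n_deg <- length(sets[[g]])
    n_spec <- length(setdiff(sets[[g]], others))
    tibble(
      genotype = g, n_deg = n_deg, n_specific = n_spec,
      pct_specific = if (n_deg == 0) NA_real_ else 100 * n_spec / n_deg
    )
  })
  attr(out, "shared_genes") <- shared
  out
}

#' Gene-set activation score per nucleus
#'
#' log1p counts-per-10k normalises the matrix, z-scores each set gene using
#' the control cohort's mean and SD within the nucleus's cell type, and
#' averages the z-scores over the set. Control nuclei therefore score ~0 by
#' construction.
#'
#' @param data an [sn_dataset()].
#' @param genes character vector of set genes.
#' @param set_name label attached to the result.
#' @param control control genotype label (defaults to the dataset's).
#' @return Tibble per nucleus: `cell_id`, `cell_type`, `sample_id`,
#'   `genotype`, `score`, `set`.
#' @export
gene_set_score <- function(data, genes, set_name = "set", control = NULL) {
  if (length(genes) == 0) abort("gene set is empty; the score is undefined.")
  control <- control %||% data$control_label
  present <- intersect(genes, colnames(data$counts))
  if (length(present) == 0) {
    abort(paste0("no set gene detected in the matrix; missing: ",
      paste(genes, collapse = ", ")))
  }
  norm <- normalize_log1p_cp10k(data$counts)
  meta <- cell_metadata(data)
  x <- as.matrix(norm[, present, drop = FALSE])
  is_control <- meta$genotype == control
  scores <- rep(NA_real_, nrow(x))
  for (ct in unique(meta$cell_type)) {
    rows <- meta$cell_type == ct
    ctl <- rows & is_control
    if (!any(ctl)) {
      warn(sprintf("no control nuclei of type '%s'; scores set to NA.", ct))
      next
    }
    m <- colMeans(x[ctl, , drop = FALSE])
    s <- apply(x[ctl, , drop = FALSE], 2, sd)
    ok <- s > 0
    if (!any(ok)) next
    z <- sweep(sweep(x[rows, ok, drop = FALSE], 2, m[ok]), 2, s[ok], "/")
    scores[rows] <- rowMeans(z)
  }
  tibble(
    cell_id = meta$cell_id, cell_type = meta$cell_type,
    sample_id = meta$sample_id, genotype = meta$genotype,
    score = scores, set = set_name
  )
}

#' One-sided Fisher enrichment of a candidate gene list among DEGs
#'
#' Tests whether candidate genes are over-represented among DEGs with a
#' one-sided (greater) hypergeometric test on the 2x2 table
#' (candidate x DEG). The odds ratio is the cross-product `ad/bc`, with a
#' Haldane 0.5 correction applied only when a zero cell occurs.
#'
#' @param candidate candidate gene set (subset of `universe`).
#' @param deg DEG set (subset of `universe`).
#' @param universe full gene universe.
#' @return Tibble: cell counts `a` (candidate & DEG), `b`, `c`, `d`,
#'   `odds_ratio`, `p.value`.
#' @export
fisher_enrichment <- function(candidate, deg, universe) {
  if (length(universe) == 0) abort("empty gene universe.")
  candidate <- unique(candidate)
  deg <- unique(deg)
  if (!all(candidate %in% universe)) abort("candidate genes must be a subset of the universe.")
  if (!all(deg %in% universe)) abort("DEGs must be a subset of the universe.")
  a <- length(intersect(candidate, deg))
  b <- length(setdiff(candidate, deg))
  c_ <- length(setdiff(deg, candidate))
  d <- length(universe) - a - b - c_
  p <- phyper(a - 1, a + b, c_ + d, a + c_, lower.tail = FALSE)
  if (min(a, b, c_, d) == 0) {
    or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  } else {
    or <- (a * d) / (b * c_)
  }
  tibble(a = a, b = b, c = c_, d = d, odds_ratio = or, p.value = p)
}
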