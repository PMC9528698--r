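# Ligand-receptor interaction inference: trimean-based group expression,
# a Hill-type interaction probability, and a label-permutation null.

#' Group-level expression summary for interaction scoring
#'
#' log1p counts-per-10k normalises the matrix and summarises each
#' (group, gene) by the Tukey trimean (type-7 linearly interpolated
#' quartiles) together with the fraction of expressing nuclei. Expression is
#' set to 0 where the expressing fraction falls below `min_frac`; groups
#' smaller than `min_cells` are excluded with a message.
#'
#' @param data an [sn_dataset()].
#' @param group_by annotation column defining groups (default
#'   `"cell_state"`).
#' @param genes genes to summarise (default: all); restricting to the
#'   ligand/receptor universe keeps permutation tests fast.
#' @param min_frac detection filter on the expressing fraction (default 0.1).
#' @param min_cells minimum group size (default 10).
#' @return Tibble: `group`, `gene`, `trimean`, `frac_expressing`, `n_cells`.
#' @export
group_expression <- function(data, group_by = "cell_state", genes = NULL,
                             min_frac = 0.1, min_cells = 10L) {
  meta <- cell_metadata(data)
  if (!group_by %in% names(meta)) abort(sprintf("grouping column '%s' missing.", group_by))
  labels <- meta[[group_by]]
  genes <- genes %||% colnames(data$counts)
  missing <- setdiff(genes, colnames(data$counts))
  if (length(missing) > 0) {
    warn(paste0("genes absent from the matrix skipped: ", paste(missing, collapse = ", ")))
    genes <- setdiff(genes, missing)
  }
  norm <- as.matrix(normalize_log1p_cp10k(data$counts)[, genes, drop = FALSE])
  summarise_groups(norm, labels, min_frac, min_cells)
}

# Trimean and expressing-fraction matrices (groups x genes) for a list of
# row-index groups; the detection filter zeroes undetected entries. This is
# the hot path of the permutation test, so it stays in plain matrices.
group_trimeans <- function(norm, idx_list, min_frac) {
  tm <- matrix(0, length(idx_list), ncol(norm),
    dimnames = list(names(idx_list), colnames(norm)))
  fr <- tm
  for (gi in seq_along(idx_list)) {
    sub <- norm[idx_list[[gi]], , drop = FALSE]
    tm[gi, ] <- apply(sub, 2, trimean)
    fr[gi, ] <- colMeans(sub > 0)
  }
  tm[fr < min_frac] <- 0
  list(trimean = tm, frac = fr)
}

# Core summary on a dense nuclei x genes matrix; reused by the permutation
# test with shuffled labels.
summarise_groups <- function(norm, labels, min_frac, min_cells) {
  idx <- split(seq_along(labels), factor(labels))
  keep <- lengths(idx) >= min_cells
  if (any(!keep)) {
    inform(sprintf("excluded %d group(s) smaller than %d nuclei.",
      sum(!keep), min_cells))
  }
  idx <- idx[keep]
  gt <- group_trimeans(norm, idx, min_frac)
  tibble(
    group = rep(names(idx), each = ncol(norm)),
    gene = rep(colnames(norm), times = length(idx)),
    trimean = as.vector(t(gt$trimean)),
    frac_expressing = as.vector(t(gt$frac)),
    n_cells = rep(lengths(idx), each = ncol(norm))
  )
}

#' Hill-type ligand-receptor interaction probability
#'
#' `P = (L * R) / (K + L * R)` with `L` the sender group's ligand trimean and
#' `R` the receiver group's receptor trimean; `P` is 0 whenever either side
#' fails the detection filter and is always strictly below 1.
#'
#' @param ligand_expr,receptor_expr nonnegative trimean expression values.
#' @param K Hill constant (default 0.5).
#' @return probability in `[0, 1)`.
#' @export
interaction_probability <- function(ligand_expr, receptor_expr, K = 0.5) {
  check_positive_scalar(K, "K")
  lr <- ligand_expr * receptor_expr
  lr / (K + lr)
}

#' Read a ligand-receptor pair table
#'
#' @param path TSV with columns `pair_id`, `ligand`, `receptor`, `pathway`.
#' @return validated tibble.
#' @export
read_lr_pairs <- function(path) {
  pairs <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("pair_id", "ligand", "receptor", "pathway")
  if (!all(need %in% names(pairs))) {
    abort(paste0("LR table must have columns: ", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(pairs$pair_id)) abort("pair ids must be unique.")
  if (any(!nzchar(pairs$ligand)) || any(!nzchar(pairs$receptor)) ||
    any(!nzchar(pairs$pathway))) {
    abort("ligand, receptor and pathway must be non-empty.")
  }
  pairs
}

#' Score all sender-receiver-pair combinations with a permutation null
#'
#' Computes the observed interaction probability for every
#' (sender group, receiver group, ligand-receptor pair) combination, then
#' permutes group labels over nuclei `nperm` times and reports
#' `p = (1 + #\{perm P >= observed P\}) / (nperm + 1)`. Observed zero
#' probabilities therefore get p = 1, and p is bounded below by
#' `1/(nperm + 1)`.
#'
#' @param data an [sn_dataset()].
#' @param pairs ligand-receptor table ([read_lr_pairs()] schema). Pairs whose
#'   ligand or receptor is absent from the matrix are skipped with one
#'   warning per gene.
#' @param group_by grouping annotation column.
#' @param K Hill constant.
#' @param min_frac,min_cells detection filter and group-size threshold.
#' @param nperm permutations (default 100).
#' @param seed RNG seed for the permutations.
#' @param cohort label stored in the result.
#' @return Tibble: `sender`, `receiver`, `pair_id`, `pathway`,
#'   `probability`, `p.value`, `cohort`.
#' @export
score_interactions <- function(data, pairs, group_by = "cell_state", K = 0.5,
                               min_frac = 0.1, min_cells = 10L, nperm = 100L,
                               seed = 1L, cohort = "cohort") {
  if (nperm < 1) abort("`nperm` must be >= 1.")
  genes <- unique(c(pairs$ligand, pairs$receptor))
  present <- intersect(genes, colnames(data$counts))
  absent <- setdiff(genes, present)
  if (length(absent) > 0) {
    warn(paste0("LR genes absent from the matrix; their pairs are skipped: ",
      paste(absent, collapse = ", ")))
    pairs <- pairs[pairs$ligand %in% present & pairs$receptor %in% present, , drop = FALSE]
  }
  if (nrow(pairs) == 0) abort("no scoreable ligand-receptor pairs.")
  meta <- cell_metadata(data)
  labels <- meta[[group_by]]
  norm <- as.matrix(normalize_log1p_cp10k(data$counts)[, present, drop = FALSE])

  idx <- split(seq_along(labels), factor(labels))
  keep <- lengths(idx) >= min_cells
  if (any(!keep)) {
    inform(sprintf("excluded %d group(s) smaller than %d nuclei.",
      sum(!keep), min_cells))
  }
  idx <- idx[keep]
  groups <- names(idx)
  if (length(groups) < 2) {
    warn("fewer than two groups survive the size filter; p-values degenerate to 1.")
  }
  observed <- tidyr::crossing(sender = groups, receiver = groups) |>
    tidyr::crossing(pairs)
  si <- match(observed$sender, groups)
  ri <- match(observed$receiver, groups)
  li <- match(observed$ligand, present)
  rei <- match(observed$receptor, present)
  prob_from <- function(tm) {
    interaction_probability(tm[cbind(si, li)], tm[cbind(ri, rei)], K = K)
  }
  observed$probability <- prob_from(group_trimeans(norm, idx, min_frac)$trimean)
  exceed <- numeric(nrow(observed))
  with_seed(seed, {
    for (b in seq_len(nperm)) {
      # permuted labels keep every group's size, so the group set is unchanged
      perm_idx <- split(seq_along(labels), factor(sample(labels)))[groups]
      p_perm <- prob_from(group_trimeans(norm, perm_idx, min_frac)$trimean)
      exceed <- exceed + as.numeric(p_perm >= observed$probability)
    }
  })
  observed$p.value <- (1 + exceed) / (nperm + 1)
  if (length(groups) < 2) observed$p.value <- 1
  observed$cohort <- cohort
  select(observed, "sender", "receiver", "pair_id", "pathway",
    "probability", "p.value", "cohort")
}

#' Permutation p-value for a single sender-receiver-pair combination
#'
#' Thin wrapper around [score_interactions()] restricted to one pair and one
#' (sender, receiver) combination; exposed for property tests of the
#' permutation machinery.
#'
#' @inheritParams score_interactions
#' @param sender,receiver group labels.
#' @param pair one-row ligand-receptor table.
#' @return list with `probability` and `p.value`.
#' @export
permutation_test <- function(data, pair, sender, receiver,
                             group_by = "cell_state", K = 0.5, min_frac = 0.1,
                             min_cells = 10L, nperm = 100L, seed = 1L) {
  res <- score_interactions(data, pair,
    group_by = group_by, K = K,
    min_frac = min_frac, min_cells = min_cells, nperm = nperm, seed = seed
  )
  row <- res[res$sender == sender & res$receiver == receiver, ]
  if (nrow(row) == 0) abort("requested sender/receiver group not scored (size filter?).")
  list(probability = row$probability[[1]], p.value = row$p.value[[1]])
}

#' Aggregate interaction scores and contrast disease vs control
#'
#' Keeps significant scores (`p <= alpha`), maps state-level senders and
#' receivers to cell types via `state_map`, sums probabilities within
#' (pathway or pair, sender type, receiver type), and reports
#' `log2((S_disease + eps) / (S_control + eps))`. Combinations with zero
#' strength in both cohorts are emitted as `n/a` (`log2fc = NA`).
#'
#' @param disease,control [score_interactions()] tibbles on the same pair
#'   universe.
#' @param level `"pathway"` or `"pair"`.
#' @param state_map optional data frame `state`, `cell_type`; by default the
#'   state label up to the last `.` is used as the type.
#' @param alpha significance threshold on permutation p-values (default
#'   0.05).
#' @param eps pseudocount on summed strengths (default 1e-3).
#' @return Tibble: `unit` (pathway or pair id), `sender_type`,
#'   `receiver_type`, `strength_disease`, `strength_control`, `log2fc`
#'   (NA for n/a), `significant` (either cohort's score significant).
#' @export
aggregate_and_contrast <- function(disease, control, level = c("pathway", "pair"),
                                   state_map = NULL, alpha = 0.05, eps = 1e-3) {
  level <- match.arg(level)
  if (!setequal(unique(disease$pair_id), unique(control$pair_id))) {
    abort("disease and control cohorts must be scored on the same pair universe.")
  }
  map_type <- function(x) {
    if (is.null(state_map)) {
      sub("\\.[^.]*$", "", x)
    } else {
      unname(setNames(state_map$cell_type, state_map$state)[x])
    }
  }
  unit_col <- if (level == "pathway") "pathway" else "pair_id"
  summarise_cohort <- function(sc) {
    sc |>
      mutate(
        unit = .data[[unit_col]],
        sender_type = map_type(.data$sender),
        receiver_type = map_type(.data$receiver),
        sig = .data$p.value <= alpha
      ) |>
      group_by(.data$unit, .data$sender_type, .data$receiver_type) |>
      summarise(
        strength = sum(.data$probability[.data$sig]),
        any_sig = any(.data$sig & .data$probability > 0),
        .groups = "drop"
      )
  }
  d <- summarise_cohort(disease)
  c_ <- summarise_cohort(control)
  all_units <- dplyr::full_join(d, c_,
    by = c("unit", "sender_type", "receiver_type"),
    suffix = c("_disease", "_control")
  ) |>
    mutate(
      strength_disease = dplyr::coalesce(.data$strength_disease, 0),
      strength_control = dplyr::coalesce(.data$strength_control, 0),
      significant = dplyr::coalesce(.data$any_sig_disease, FALSE) |
        dplyr::coalesce(.data$any_sig_control, FALSE),
      log2fc = dplyr::if_else(
        .data$strength_disease == 0 & .data$strength_control == 0,
        NA_real_,
        log2((.data$strength_disease + eps) / (.data$strength_control + eps))
      )
    ) |>
    select("unit", "sender_type", "receiver_type",
      "strength_disease", "strength_control", "log2fc", "significant")
  all_units
}
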