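# ggplot2 helpers for the main result types.

#' Stacked cell-type composition bars per sample
#'
#' @param table a [compute_composition()] tibble.
#' @param facet_by metadata column used for facetting (default `genotype`).
#' @return a ggplot.
#' @export
plot_composition <- function(table, facet_by = "genotype") {
  cats <- composition_categories(table)
  long <- table |>
    pivot_longer(dplyr::all_of(cats), names_to = "category", values_to = "n") |>
    group_by(.data$sample_id) |>
    mutate(proportion = .data$n / sum(.data$n)) |>
    ungroup()
  ggplot2::ggplot(long, ggplot2::aes(.data$sample_id, .data$proportion,
    fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(stats::reformulate(facet_by), scales = "free_x",
      space = "free_x") +
    ggplot2::labs(x = NULL, y = "proportion of nuclei", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, size = 6))
}

#' Abundance-test coefficients with significance
#'
#' @param result a [test_abundance()] tibble (possibly several contrasts
#'   bound together).
#' @param fdr_cut highlighting threshold (default 0.05).
#' @return a ggplot of the CLR-unit condition coefficients.
#' @export
plot_abundance <- function(result, fdr_cut = 0.05) {
  ggplot2::ggplot(result, ggplot2::aes(.data$estimate, .data$category,
    colour = .data$fdr <= fdr_cut)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(
      xmin = .data$estimate - 1.96 * .data$std.error,
      xmax = .data$estimate + 1.96 * .data$std.error
    ), height = 0.2) +
    ggplot2::facet_wrap(~contrast) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey40"),
      name = sprintf("FDR <= %.2f", fdr_cut)) +
    ggplot2::labs(x = "CLR coefficient (disease vs control)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential-expression result
#'
#' @param de a [de_test()] / [test_de()] tibble.
#' @param fdr_cut highlighting threshold.
#' @return a ggplot.
#' @export
plot_volcano <- function(de, fdr_cut = 0.05) {
  ggplot2::ggplot(de, ggplot2::aes(.data$logFC, -log10(pmax(.data$p.value, 1e-300)),
    colour = !is.na(.data$fdr) & .data$fdr <= fdr_cut)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey55"),
      name = sprintf("FDR <= %.2f", fdr_cut)) +
    ggplot2::labs(x = "log2 fold-change (disease vs control)",
      y = "-log10 p") +
    ggplot2::theme_minimal()
}

#' Dot plot of differential interaction strength
#'
#' @param diffs an [aggregate_and_contrast()] tibble (optionally with a
#'   `genotype` column from the pipeline).
#' @return a ggplot; `n/a` combinations are omitted.
#' @export
plot_interactions <- function(diffs) {
  d <- diffs[!is.na(diffs$log2fc), , drop = FALSE]
  d$pairing <- paste(d$sender_type, "→", d$receiver_type)
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$pairing, .data$unit,
    size = abs(.data$log2fc), colour = .data$log2fc)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_gradient2(low = "navy", mid = "grey85",
      high = "firebrick", name = "log2 FC") +
    ggplot2::labs(x = "sender → receiver", y = NULL, size = "|log2 FC|") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if ("genotype" %in% names(d)) p <- p + ggplot2::facet_wrap(~genotype)
  p
}

#' Stacked per-patient genotype probability bars
#'
#' @param patient_predictions an [aggregate_patient()] tibble.
#' @param scope which aggregate to show (default `"aggregate"`).
#' @return a ggplot.
#' @export
plot_patient_predictions <- function(patient_predictions, scope = "aggregate") {
  d <- patient_predictions[patient_predictions$scope == scope, , drop = FALSE]
  prob_cols <- grep("^prob_", names(d), value = TRUE)
  long <- d |>
    pivot_longer(dplyr::all_of(prob_cols), names_to = "class",
      values_to = "probability") |>
    mutate(class = sub("^prob_", "", .data$class))
  ggplot2::ggplot(long, ggplot2::aes(.data$patient_id, .data$probability,
    fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(~genotype, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = NULL, y = "aggregated genotype probability", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, size = 6))
}

#' @describeIn plot_patient_predictions autoplot method for `genotype_cv`.
#' @param object a `genotype_cv` object.
#' @param ... unused.
#' @export
autoplot.genotype_cv <- function(object, ...) {
  plot_patient_predictions(object$patient_predictions)
}

#' Training curves of a GAT fit
#'
#' @param object a [train_gat()] fit.
#' @param ... unused.
#' @return a ggplot of train/validation loss per epoch.
#' @export
autoplot.gat_fit <- function(object, ...) {
  long <- pivot_longer(object$log, c("train_loss", "val_loss"),
    names_to = "series", values_to = "loss")
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$loss,
    colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2,
      colour = "grey60") +
    ggplot2::labs(x = "epoch", y = "cross-entropy") +
    ggplot2::theme_minimal()
}
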