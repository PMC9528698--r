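# broom-style tidiers.

#' Tidy a GAT fit
#'
#' @param x a [train_gat()] fit.
#' @param ... unused.
#' @return the training log as a tibble (epoch, train_loss, val_loss,
#'   train_acc).
#' @export
tidy.gat_fit <- function(x, ...) {
  x$log
}

#' Glance at a GAT fit
#'
#' @param x a [train_gat()] fit.
#' @param ... unused.
#' @return one-row tibble: best epoch, best validation loss, final training
#'   accuracy, parameter count.
#' @export
glance.gat_fit <- function(x, ...) {
  tibble(
    best_epoch = x$best_epoch,
    val_loss = min(x$log$val_loss),
    train_acc = x$log$train_acc[which.min(x$log$val_loss)],
    n_parameters = length(gat_flatten(x$params)),
    epochs_run = nrow(x$log)
  )
}

#' Tidy a cross-validated genotype classification
#'
#' @param x a [classify_genotype()] result.
#' @param ... unused.
#' @return pooled per-nucleus test predictions.
#' @export
tidy.genotype_cv <- function(x, ...) {
  x$node_predictions
}

#' Glance at a cross-validated genotype classification
#'
#' @param x a [classify_genotype()] result.
#' @param ... unused.
#' @return one-row tibble: patient-level accuracy and per-cell-type
#'   nucleus-level accuracies in wide form.
#' @export
glance.genotype_cv <- function(x, ...) {
  acc <- x$metrics$per_type_accuracy
  wide <- setNames(as.list(acc$accuracy), paste0("accuracy_", acc$cell_type))
  bind_cols(
    tibble(patient_accuracy = x$metrics$patient_accuracy),
    as_tibble(wide)
  )
}
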