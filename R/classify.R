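# Patient-held-out genotype classification across cell types.

# Assign patients to folds, round-robin within genotype, seeded.
make_patient_folds <- function(samples, folds, seed) {
  pts <- distinct(samples, .data$patient_id, .data$genotype)
  with_seed(seed, {
    assign <- purrr::map_dfr(split(pts, pts$genotype), function(g) {
      g <- g[sample(nrow(g)), , drop = FALSE]
      g$fold <- rep_len(seq_len(folds), nrow(g))
      g
    })
  })
  assign
}

#' Patient-held-out GAT genotype classification per cell type
#'
#' For each requested cell type: PCA-embeds the nuclei, builds a kNN graph,
#' and runs patient-grouped cross-validation of a GAT genotype classifier.
#' Every nucleus of a patient falls entirely in train or test; a random
#' fraction of training nuclei (within training patients) is used for early
#' stopping. Test-fold predictions are pooled across folds and aggregated to
#' patients.
#'
#' @param data an [sn_dataset()].
#' @param cell_types cell types to classify on (default the four informative
#'   types `CM`, `FB`, `EC`, `Myeloid`).
#' @param region region filter (default `"LV"`; `NULL` for all).
#' @param folds patient-grouped folds (default 3).
#' @param d,n_hvg,k embedding and graph parameters (see [pca_embed()],
#'   [build_knn_graph()]).
#' @param heads,hidden_dim,epochs,patience,lr,optimizer GAT training
#'   parameters (see [train_gat()]).
#' @param max_nuclei per-type cap on graph size; nuclei are subsampled
#'   (seeded, stratified by sample) above it. Default `Inf`.
#' @param val_frac fraction of training nuclei held out for early stopping.
#' @param seed master seed.
#' @return A `genotype_cv` object: list with `node_predictions`,
#'   `patient_predictions`, `metrics` (list: per-type accuracy, patient
#'   accuracy, confusion, recall), `folds`, `config`.
#' @export
classify_genotype <- function(data, cell_types = c("CM", "FB", "EC", "Myeloid"),
                              region = "LV", folds = 3L, d = 30L, n_hvg = 1000L,
                              k = 15L, heads = 8L, hidden_dim = 8L,
                              epochs = 200L, patience = 20L, lr = 0.05,
                              optimizer = "gd", max_nuclei = Inf,
                              val_frac = 0.1, seed = 1L) {
  fold_map <- make_patient_folds(data$samples, folds, hash_seed(seed, "folds"))
  classes <- sort(unique(data$samples$genotype))
  node_preds <- list()
  for (ct in cell_types) {
    emb <- pca_embed(data, ct, d = d, n_hvg = n_hvg, region = region)
    cells <- emb$cells
    X <- emb$embedding
    if (nrow(X) > max_nuclei) {
      with_seed(hash_seed(seed, paste0("sub/", ct)), {
        keep <- sort(unlist(lapply(
          split(seq_len(nrow(X)), cells$sample_id),
          function(ix) {
            m <- max(1L, floor(length(ix) * max_nuclei / nrow(X)))
            sample(ix, min(length(ix), m))
          }
        ), use.names = FALSE))
      })
      X <- X[keep, , drop = FALSE]
      cells <- cells[keep, , drop = FALSE]
    }
    graph <- build_knn_graph(X, k = k, nodes = cells)
    labels <- factor(cells$genotype, levels = classes)
    cell_fold <- fold_map$fold[match(cells$patient_id, fold_map$patient_id)]
    for (f in sort(unique(fold_map$fold))) {
      test_idx <- which(cell_fold == f)
      pool <- which(cell_fold != f)
      if (length(test_idx) == 0) next
      stopifnot(length(intersect(
        cells$patient_id[test_idx], cells$patient_id[pool]
      )) == 0)
      with_seed(hash_seed(seed, paste0("val/", ct, "/", f)), {
        val_idx <- sort(unlist(lapply(
          split(pool, labels[pool]),
          function(ix) sample(ix, max(1L, round(length(ix) * val_frac)))
        ), use.names = FALSE))
      })
      train_idx <- setdiff(pool, val_idx)
      fit <- train_gat(graph, X, labels, train_idx, val_idx,
        heads = heads, hidden_dim = hidden_dim, epochs = epochs,
        patience = patience, lr = lr, optimizer = optimizer,
        seed = hash_seed(seed, paste0("gat/", ct, "/", f))
      )
      pr <- predict(fit, graph, X)[test_idx, , drop = FALSE]
      pr$fold <- f
      node_preds[[paste(ct, f)]] <- pr
    }
  }
  node_predictions <- bind_rows(node_preds)
  patient_predictions <- aggregate_patient(node_predictions, classes,
    cell_types = cell_types)
  metrics <- evaluate_predictions(node_predictions, patient_predictions, classes)
  structure(
    list(
      node_predictions = node_predictions,
      patient_predictions = patient_predictions,
      metrics = metrics, folds = fold_map,
      config = list(
        cell_types = cell_types, region = region, folds = folds, d = d,
        n_hvg = n_hvg, k = k, heads = heads, hidden_dim = hidden_dim,
        epochs = epochs, lr = lr, seed = seed
      )
    ),
    class = "genotype_cv"
  )
}

#' Aggregate per-nucleus genotype probabilities to patients
#'
#' The patient-level probability vector is the unweighted mean of the
#' per-nucleus probability vectors pooled over the specified cell types
#' (a convex combination, so it stays on the simplex); per-cell-type
#' sub-aggregates are also returned. Patients without test nuclei are
#' reported with a message and omitted.
#'
#' @param preds tibble of node predictions with `patient_id`, `cell_type`,
#'   `genotype` and `prob_<class>` columns (see [predict.gat_fit()]).
#' @param classes class labels (default: inferred from the prob columns).
#' @param cell_types cell types to pool (default: all present).
#' @param all_patients optional full patient id vector, used to report
#'   patients with zero test nuclei.
#' @return Tibble per (patient, scope): `patient_id`, `genotype`,
#'   `scope` (`"aggregate"` or a cell type), `n_nuclei`, `prob_<class>`
#'   columns, `predicted`.
#' @export
aggregate_patient <- function(preds, classes = NULL, cell_types = NULL,
                              all_patients = NULL) {
  prob_cols <- grep("^prob_", names(preds), value = TRUE)
  classes <- classes %||% sub("^prob_", "", prob_cols)
  prob_cols <- paste0("prob_", classes)
  cell_types <- cell_types %||% unique(preds$cell_type)
  pooled <- preds[preds$cell_type %in% cell_types, , drop = FALSE]
  if (!is.null(all_patients)) {
    missing <- setdiff(all_patients, unique(pooled$patient_id))
    if (length(missing) > 0) {
      inform(paste0("patients with no test nuclei omitted: ",
        paste(missing, collapse = ", ")))
    }
  }
  agg_one <- function(df, scope) {
    df |>
      group_by(.data$patient_id, .data$genotype) |>
      summarise(
        n_nuclei = dplyr::n(),
        across(dplyr::all_of(prob_cols), mean),
        .groups = "drop"
      ) |>
      mutate(scope = scope, .after = "genotype")
  }
  out <- bind_rows(
    agg_one(pooled, "aggregate"),
    purrr::map_dfr(cell_types, function(ct) {
      agg_one(pooled[pooled$cell_type == ct, , drop = FALSE], ct)
    })
  )
  pm <- as.matrix(out[, prob_cols])
  out$predicted <- classes[max.col(pm)]
  out
}

evaluate_predictions <- function(node_predictions, patient_predictions, classes) {
  per_type <- node_predictions |>
    group_by(.data$cell_type) |>
    summarise(
      n = dplyr::n(),
      accuracy = mean(.data$predicted == .data$genotype),
      .groups = "drop"
    )
  pat <- patient_predictions[patient_predictions$scope == "aggregate", ]
  confusion <- table(
    truth = factor(pat$genotype, levels = classes),
    predicted = factor(pat$predicted, levels = classes)
  )
  recall <- diag(confusion) / pmax(rowSums(confusion), 1)
  list(
    per_type_accuracy = per_type,
    patient_accuracy = mean(pat$predicted == pat$genotype),
    confusion = confusion,
    per_class_recall = recall
  )
}

#' Evaluate pooled cross-validation predictions
#'
#' @param cv a [classify_genotype()] result.
#' @return list with per-cell-type nucleus-level accuracy, patient-level
#'   accuracy, the patient confusion matrix and per-class recall.
#' @export
evaluate <- function(cv) {
  stopifnot(inherits(cv, "genotype_cv"))
  cv$metrics
}

#' @export
print.genotype_cv <- function(x, ...) {
  cat("<genotype_cv>\n")
  acc <- x$metrics$per_type_accuracy
  for (i in seq_len(nrow(acc))) {
    cat(sprintf("  %-10s nucleus accuracy %.3f (n=%d)\n",
      acc$cell_type[i], acc$accuracy[i], acc$n[i]))
  }
  cat(sprintf("  patient-level accuracy %.3f\n", x$metrics$patient_accuracy))
  invisible(x)
}
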