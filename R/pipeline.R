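#' Pipeline configuration
#'
#' Validated bundle of stage toggles and parameters for [run_pipeline()].
#' Unknown keys are rejected.
#'
#' @param outdir output directory.
#' @param seed master seed for every stochastic stage.
#' @param stages subset of `c("simulate", "composition", "de", "interact",
#'   "classify")`, run in that order.
#' @param generator a [generator_config()]; rebuilt with `seed` when NULL.
#' @param input_dir optional directory of an existing dataset
#'   ([read_sn_dataset()] layout); when set, the simulate stage loads
#'   instead of simulating.
#' @param min_nuclei pseudobulk unit threshold.
#' @param fdr_cut DEG threshold.
#' @param de_region,de_level region and annotation level of the DE stage.
#' @param lr_pairs optional ligand-receptor table (tibble or TSV path); a
#'   small built-in demonstration panel over the generator's marker genes is
#'   used when NULL.
#' @param nperm interaction permutations.
#' @param classify_cell_types,classify_folds,classify_epochs,classify_lr,
#'   classify_max_nuclei,classify_optimizer GAT stage parameters.
#' @param verbose print progress.
#' @return `pipeline_config` list.
#' @export
pipeline_config <- function(outdir = "cardiostrat_out", seed = 1L,
                            stages = c("simulate", "composition", "de",
                              "interact", "classify"),
                            generator = NULL, input_dir = NULL,
                            min_nuclei = 10L, fdr_cut = 0.05,
                            de_region = "LV", de_level = "type",
                            lr_pairs = NULL, nperm = 100L,
                            classify_cell_types = c("CM", "FB", "EC", "Myeloid"),
                            classify_folds = 3L, classify_epochs = 60L,
                            classify_lr = 0.02, classify_max_nuclei = 1200L,
                            classify_optimizer = "adam",
                            verbose = TRUE) {
  known <- c("simulate", "composition", "de", "interact", "classify")
  bad <- setdiff(stages, known)
  if (length(bad) > 0) abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  structure(
    list(
      outdir = outdir, seed = as.integer(seed), stages = stages,
      generator = generator, input_dir = input_dir,
      min_nuclei = min_nuclei, fdr_cut = fdr_cut,
      de_region = de_region, de_level = de_level,
      lr_pairs = lr_pairs, nperm = nperm,
      classify_cell_types = classify_cell_types,
      classify_folds = classify_folds, classify_epochs = classify_epochs,
      classify_lr = classify_lr, classify_max_nuclei = classify_max_nuclei,
      classify_optimizer = classify_optimizer,
      verbose = verbose
    ),
    class = "pipeline_config"
  )
}

# Demonstration ligand-receptor panel over generator marker genes: each
# cell type's first markers act as ligands, the next as receptors.
default_lr_panel <- function(config) {
  nt <- length(config$cell_types)
  mb <- config$marker_block
  purrr::map_dfr(seq_len(nt), function(i) {
    base <- (i - 1L) * mb
    tibble(
      pair_id = sprintf("%s_pair%d", config$cell_types[i], 1:3),
      ligand = gene_names(config$n_genes)[base + 1:3],
      receptor = gene_names(config$n_genes)[base + 4:6],
      pathway = sprintf("PW_%s", config$cell_types[i])
    )
  })
}

pipe_log <- function(cfg, con, ...) {
  msg <- sprintf(...)
  line <- sprintf("ts=%s stage_log=\"%s\"", format(Sys.time(), "%H:%M:%S"), msg)
  writeLines(line, con)
  if (cfg$verbose) message(msg)
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in order simulate -> composition -> de ->
#' interact -> classify, writing each stage's TSV outputs under
#' `config$outdir` before the next stage starts. A run log (key=value
#' lines: seed, parameters, stage timings) is written to `run.log`.
#' Reruns with the same seed reproduce the tables byte for byte.
#'
#' @param config a [pipeline_config()].
#' @return named list of the in-memory stage results, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file(file.path(config$outdir, "run.log"), open = "wt")
  on.exit(close(logfile), add = TRUE)
  writeLines(sprintf("seed=%d stages=%s", config$seed,
    paste(config$stages, collapse = ",")), logfile)
  results <- list()

  gen <- config$generator %||% generator_config(seed = config$seed)
  if ("simulate" %in% config$stages) {
    pipe_log(config, logfile, "stage=simulate start")
    if (!is.null(config$input_dir)) {
      data <- read_sn_dataset(config$input_dir)
      truth <- NULL
    } else {
      sim <- simulate_dataset(gen)
      data <- sim$data
      truth <- sim$truth
      write_plain_tsv(truth$deg_table, file.path(config$outdir, "ground_truth.tsv"))
    }
    write_plain_tsv(data$cells, file.path(config$outdir, "cells.tsv"))
    write_plain_tsv(data$samples, file.path(config$outdir, "samples.tsv"))
    results$data <- data
    results$truth <- truth
    pipe_log(config, logfile, "stage=simulate done nuclei=%d genes=%d",
      nrow(data$counts), ncol(data$counts))
  } else {
    if (is.null(config$input_dir)) abort("config error: no simulate stage and no input_dir.")
    results$data <- read_sn_dataset(config$input_dir)
  }
  data <- results$data
  disease <- setdiff(unique(data$samples$genotype), data$control_label)

  if ("composition" %in% config$stages) {
    pipe_log(config, logfile, "stage=composition start")
    comp <- compute_composition(data, level = "type")
    clr <- clr_transform(comp)
    abund <- purrr::map_dfr(disease, function(g) {
      test_abundance(clr, g, covariates = c("age", "sex"), region = config$de_region)
    })
    ratios <- purrr::map_dfr(disease, function(g) {
      pairwise_ratio_test(comp, g, region = config$de_region)
    })
    write_plain_tsv(comp, file.path(config$outdir, "composition.tsv"))
    write_plain_tsv(abund, file.path(config$outdir, "abundance_tests.tsv"))
    write_plain_tsv(ratios, file.path(config$outdir, "ratio_tests.tsv"))
    results$composition <- list(table = comp, clr = clr, abundance = abund,
      ratios = ratios)
    pipe_log(config, logfile, "stage=composition done contrasts=%d", length(disease))
  }

  if ("de" %in% config$stages) {
    pipe_log(config, logfile, "stage=de start")
    pb <- aggregate_pseudobulk(data, level = config$de_level,
      min_nuclei = config$min_nuclei)
    cats <- sort(unique(pb$units$category))
    de_all <- purrr::map_dfr(disease, function(g) {
      purrr::map_dfr(cats, function(cc) {
        tryCatch(
          de_test(pb, g, cc, region = config$de_region),
          error = function(e) tibble()
        )
      })
    })
    write_plain_tsv(de_all, file.path(config$outdir, "de_results.tsv"))
    sharing <- purrr::map_dfr(cats, function(cc) {
      sub <- de_all[de_all$category == cc, ]
      if (length(unique(sub$genotype)) < 2) return(tibble())
      mutate(partition_degs(sub, fdr_cut = config$fdr_cut), category = cc, .before = 1)
    })
    write_plain_tsv(sharing, file.path(config$outdir, "deg_sharing.tsv"))
    results$de <- list(pseudobulk = pb, results = de_all, sharing = sharing)
    pipe_log(config, logfile, "stage=de done tests=%d", nrow(de_all))
  }

  if ("interact" %in% config$stages) {
    pipe_log(config, logfile, "stage=interact start")
    pairs <- config$lr_pairs
    if (is.character(pairs)) pairs <- read_lr_pairs(pairs)
    if (is.null(pairs)) pairs <- default_lr_panel(gen)
    meta <- cell_metadata(data)
    in_region <- if (is.null(config$de_region)) rep(TRUE, nrow(meta)) else
      meta$region %in% config$de_region
    ctrl_data <- subset_nuclei(data, in_region & meta$genotype == data$control_label)
    ctrl_scores <- score_interactions(ctrl_data, pairs,
      nperm = config$nperm, seed = hash_seed(config$seed, "interact/control"),
      cohort = data$control_label)
    dis_scores <- purrr::map_dfr(disease, function(g) {
      d <- subset_nuclei(data, in_region & meta$genotype == g)
      score_interactions(d, pairs,
        nperm = config$nperm, seed = hash_seed(config$seed, paste0("interact/", g)),
        cohort = g)
    })
    diffs <- purrr::map_dfr(disease, function(g) {
      mutate(
        aggregate_and_contrast(
          dis_scores[dis_scores$cohort == g, ], ctrl_scores, level = "pathway"
        ),
        genotype = g, .before = 1
      )
    })
    write_plain_tsv(bind_rows(ctrl_scores, dis_scores),
      file.path(config$outdir, "interactions.tsv"))
    write_plain_tsv(diffs, file.path(config$outdir, "differential_interactions.tsv"))
    results$interaction <- list(control = ctrl_scores, disease = dis_scores,
      differential = diffs)
    pipe_log(config, logfile, "stage=interact done pairs=%d", nrow(pairs))
  }

  if ("classify" %in% config$stages) {
    pipe_log(config, logfile, "stage=classify start")
    cv <- classify_genotype(data,
      cell_types = config$classify_cell_types, region = config$de_region,
      folds = config$classify_folds, epochs = config$classify_epochs,
      lr = config$classify_lr, optimizer = config$classify_optimizer,
      max_nuclei = config$classify_max_nuclei, seed = config$seed
    )
    write_plain_tsv(cv$node_predictions,
      file.path(config$outdir, "node_predictions.tsv"))
    write_plain_tsv(cv$patient_predictions,
      file.path(config$outdir, "patient_predictions.tsv"))
    write_plain_tsv(cv$metrics$per_type_accuracy,
      file.path(config$outdir, "metrics.tsv"))
    results$classification <- cv
    pipe_log(config, logfile, "stage=classify done patient_accuracy=%.3f",
      cv$metrics$patient_accuracy)
  }
  invisible(results)
}
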