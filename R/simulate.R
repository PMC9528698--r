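#' Configuration for the synthetic snRNA-seq cohort generator
#'
#' Describes a multi-patient, multi-genotype, two-chamber single-nucleus
#' cohort with known genotype effects on cell-type composition
#' (multiplicative folds on expected proportions) and on expression
#' (log2 fold-changes on a negative-binomial count model with per-patient
#' random intercepts and log-normal library sizes). The defaults emulate a
#' cardiomyopathy cohort: a control arm plus five genotype arms (four
#' pathogenic-variant genes and a variant-negative group), left and right
#' ventricle samples per patient, and six major cardiac cell types with
#' cardiomyocyte depletion and endothelial/immune expansion in most disease
#' genotypes.
#'
#' @param genotypes character vector of condition labels; must contain
#'   `control`.
#' @param control label of the control arm.
#' @param patients_per_genotype patients simulated per genotype.
#' @param regions chamber labels; one sample is generated per
#'   (patient, region).
#' @param cell_types cell-type names.
#' @param baseline_composition named probability vector over `cell_types`
#'   (control expected proportions; sums to 1).
#' @param composition_effects named list: genotype -> named numeric vector of
#'   multiplicative folds on expected proportions (renormalised after
#'   multiplication). Genotypes absent from the list get no composition
#'   effect.
#' @param n_genes number of genes.
#' @param shared_deg data frame (`gene`, `log2fc`): program applied in every
#'   disease genotype, all cell types.
#' @param specific_deg data frame (`genotype`, `gene`, `log2fc`,
#'   `cell_types`): genotype-private programs; `cell_types` is `"all"` or a
#'   comma-separated subset of `cell_types`.
#' @param nb_dispersion per-gene NB dispersion (1/size); scalar recycled.
#' @param libsize_log_mean,libsize_log_sd log-normal library-size parameters
#'   (natural-log scale).
#' @param patient_effect_sd SD of per-(patient, gene) log-scale random
#'   intercepts, shared across both regions of a patient.
#' @param nuclei_per_sample nuclei drawn per sample.
#' @param marker_strength fold applied to each cell type's marker genes in
#'   its base expression profile.
#' @param state_marker_strength fold applied to the second cell state's
#'   marker genes (each type carries two states split on a small marker
#'   program).
#' @param profile_shape gamma shape of the base per-gene expression weights.
#' @param seed integer master seed; every patient and sample derives its own
#'   RNG stream from it, so generation is order-independent.
#'
#' @return A `generator_config` list, validated.
#' @export
generator_config <- function(genotypes = c("control", "LMNA", "TTN", "RBM20", "PKP2", "PVneg"),
                             control = "control",
                             patients_per_genotype = 3,
                             regions = c("LV", "RV"),
                             cell_types = c("CM", "FB", "EC", "Mural", "Myeloid", "Lymphoid"),
                             baseline_composition = c(
                               CM = 0.40, FB = 0.22, EC = 0.16,
                               Mural = 0.10, Myeloid = 0.08, Lymphoid = 0.04
                             ),
                             composition_effects = list(
                               LMNA = c(EC = 1.5, Myeloid = 1.5, Lymphoid = 1.5),
                               TTN = c(CM = 0.60, EC = 1.5, Myeloid = 1.6, Lymphoid = 1.6),
                               RBM20 = c(CM = 0.45, EC = 1.8, Myeloid = 1.8, Lymphoid = 2.0),
                               PKP2 = c(CM = 0.70),
                               PVneg = c(CM = 0.40, EC = 1.8, Myeloid = 2.0, Lymphoid = 2.2)
                             ),
                             n_genes = 1000,
                             shared_deg = NULL,
                             specific_deg = NULL,
                             nb_dispersion = 0.3,
                             libsize_log_mean = log(2000),
                             libsize_log_sd = 0.35,
                             patient_effect_sd = 0.15,
                             nuclei_per_sample = 550,
                             marker_strength = 8,
                             state_marker_strength = 6,
                             profile_shape = 1.5,
                             seed = 1L) {
  disease <- setdiff(genotypes, control)
  n_types <- length(cell_types)
  # Default gene layout: type markers, then state markers, then DEG blocks.
  marker_block <- 10L
  state_block <- 5L
  if (is.null(shared_deg)) {
    start <- n_types * (marker_block + state_block) + 11L
    genes <- seq(start, length.out = 30L)
    shared_deg <- tibble(gene = genes, log2fc = rep_len(c(1.5, -1.5), 30L))
  }
  if (is.null(specific_deg)) {
    start <- max(shared_deg$gene) + 11L
    specific_deg <- purrr::map2_dfr(disease, seq_along(disease), function(g, i) {
      genes <- seq(start + (i - 1L) * 20L, length.out = 20L)
      tibble(
        genotype = g, gene = genes,
        log2fc = rep_len(c(1.5, -1.5), 20L), cell_types = "all"
      )
    })
  }
  shared_deg <- as_tibble(shared_deg)
  specific_deg <- as_tibble(specific_deg)
  if (!"cell_types" %in% names(specific_deg) && nrow(specific_deg) > 0) {
    specific_deg$cell_types <- "all"
  }
  config <- structure(
    list(
      genotypes = genotypes, control = control,
      patients_per_genotype = as.integer(patients_per_genotype),
      regions = regions, cell_types = cell_types,
      baseline_composition = baseline_composition,
      composition_effects = composition_effects,
      n_genes = as.integer(n_genes),
      shared_deg = shared_deg, specific_deg = specific_deg,
      nb_dispersion = rep_len(nb_dispersion, n_genes),
      libsize_log_mean = libsize_log_mean, libsize_log_sd = libsize_log_sd,
      patient_effect_sd = patient_effect_sd,
      nuclei_per_sample = as.integer(nuclei_per_sample),
      marker_strength = marker_strength,
      state_marker_strength = state_marker_strength,
      profile_shape = profile_shape,
      marker_block = marker_block, state_block = state_block,
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
  validate_generator_config(config)
}

validate_generator_config <- function(config) {
  bc <- config$baseline_composition
  if (length(bc) != length(config$cell_types)) {
    abort("baseline_composition must have one entry per cell type.")
  }
  if (any(bc < 0) || abs(sum(bc) - 1) > 1e-9) {
    abort("baseline_composition entries must be nonnegative and sum to 1 (tol 1e-9).")
  }
  if (is.null(names(bc))) names(config$baseline_composition) <- config$cell_types
  if (sum(config$genotypes == config$control) != 1) {
    abort("exactly one genotype must be the designated control.")
  }
  bad_geno <- setdiff(names(config$composition_effects), config$genotypes)
  if (length(bad_geno) > 0) {
    abort(paste0("composition_effects name unknown genotypes: ", paste(bad_geno, collapse = ", ")))
  }
  for (g in names(config$composition_effects)) {
    f <- config$composition_effects[[g]]
    if (any(f <= 0)) abort("all composition fold parameters must be strictly positive.")
    if (!all(names(f) %in% config$cell_types)) {
      abort(sprintf("composition_effects[[%s]] names unknown cell types.", g))
    }
  }
  if (any(config$nb_dispersion <= 0)) abort("nb_dispersion must be strictly positive.")
  for (g in unique(config$specific_deg$genotype)) {
    overlap <- intersect(config$shared_deg$gene, config$specific_deg$gene[config$specific_deg$genotype == g])
    if (length(overlap) > 0) {
      abort(sprintf("shared and genotype-specific DEG sets overlap for %s.", g))
    }
  }
  all_deg <- c(config$shared_deg$gene, config$specific_deg$gene)
  if (length(all_deg) > 0 && (max(all_deg) > config$n_genes || min(all_deg) < 1)) {
    abort("DEG gene indices must lie in 1..n_genes.")
  }
  if (config$nuclei_per_sample < 1 || config$patients_per_genotype < 1 || config$n_genes < 1) {
    abort("nuclei_per_sample, patients_per_genotype and n_genes must be positive.")
  }
  config
}

#' Expected and sampled cell-type composition of one sample
#'
#' Expected proportions are the baseline composition multiplied by the
#' genotype's fold vector and renormalised; control samples use the baseline
#' exactly. `sample_composition()` draws per-type nucleus counts from a
#' multinomial with total `nuclei_per_sample` using the current RNG state.
#'
#' @param config a [generator_config()].
#' @param genotype condition label of the sample.
#' @return `expected_composition()`: named numeric proportions.
#'   `sample_composition()`: named integer counts summing to
#'   `nuclei_per_sample`.
#' @export
expected_composition <- function(config, genotype) {
  if (!genotype %in% config$genotypes) {
    abort(sprintf("unknown genotype '%s' (configured: %s).", genotype,
      paste(config$genotypes, collapse = ", ")))
  }
  p <- config$baseline_composition
  if (is.null(names(p))) names(p) <- config$cell_types
  if (genotype != config$control) {
    fold <- config$composition_effects[[genotype]]
    if (!is.null(fold)) {
      p[names(fold)] <- p[names(fold)] * fold
    }
  }
  p / sum(p)
}

#' @rdname expected_composition
#' @export
sample_composition <- function(config, genotype) {
  p <- expected_composition(config, genotype)
  counts <- rmultinom(1, config$nuclei_per_sample, p)[, 1]
  names(counts) <- names(p)
  counts
}

# Base expression profiles: genes x cell types weight matrix plus the state-B
# marker index per type. Deterministic given config$seed.
build_profiles <- function(config) {
  with_seed(hash_seed(config$seed, "profiles"), {
    w <- rgamma(config$n_genes, shape = config$profile_shape, rate = 1) + 0.05
    n_types <- length(config$cell_types)
    mb <- config$marker_block
    sb <- config$state_block
    weights <- matrix(w, nrow = config$n_genes, ncol = n_types,
      dimnames = list(NULL, config$cell_types))
    state_markers <- vector("list", n_types)
    names(state_markers) <- config$cell_types
    for (i in seq_len(n_types)) {
      markers <- seq((i - 1L) * mb + 1L, length.out = mb)
      weights[markers, i] <- weights[markers, i] * config$marker_strength
      state_markers[[i]] <- seq(n_types * mb + (i - 1L) * sb + 1L, length.out = sb)
    }
    list(weights = weights, state_markers = state_markers)
  })
}

# Per-gene log2 fold-change vector for one (genotype, cell type).
genotype_log2fc <- function(config, genotype, cell_type) {
  lfc <- numeric(config$n_genes)
  if (genotype == config$control) {
    return(lfc)
  }
  if (nrow(config$shared_deg) > 0) {
    lfc[config$shared_deg$gene] <- lfc[config$shared_deg$gene] + config$shared_deg$log2fc
  }
  sp <- config$specific_deg[config$specific_deg$genotype == genotype, , drop = FALSE]
  if (nrow(sp) > 0) {
    applies <- sp$cell_types == "all" |
      vapply(strsplit(sp$cell_types, ","), function(ct) cell_type %in% trimws(ct), logical(1))
    sp <- sp[applies, , drop = FALSE]
    lfc[sp$gene] <- lfc[sp$gene] + sp$log2fc
  }
  lfc
}

#' Simulate the nuclei of one sample
#'
#' Draws a cell-type composition (multinomial) and then per-nucleus gene
#' counts from `NB(mean = libsize_i * p_g * 2^lfc_g * exp(u_pg),
#' dispersion = nb_dispersion_g)`, where `p_g` is the (state-specific)
#' normalised expression profile of the nucleus's cell type, `lfc_g` sums the
#' applicable shared and genotype-specific log2 fold-changes, and `u_pg` is
#' the patient's per-gene random intercept.
#'
#' @inheritParams expected_composition
#' @param sample_id id used to derive the sample's RNG stream.
#' @param patient_effect per-gene patient intercept (log scale); defaults to
#'   zero.
#' @param nuclei_by_type optional named per-type nucleus counts overriding
#'   the multinomial draw.
#' @return list with `counts` (dgCMatrix nuclei x genes) and `cells`
#'   (tibble: cell_id, cell_type, cell_state, sample_id).
#' @export
simulate_sample <- function(config, genotype, sample_id = "S1",
                            patient_effect = NULL, nuclei_by_type = NULL) {
  profiles <- build_profiles(config)
  if (is.null(patient_effect)) patient_effect <- numeric(config$n_genes)
  with_seed(hash_seed(config$seed, sample_id), {
    if (is.null(nuclei_by_type)) {
      nuclei_by_type <- sample_composition(config, genotype)
    }
    blocks <- list()
    cells <- list()
    idx <- 0L
    for (ct in config$cell_types) {
      n_ct <- if (ct %in% names(nuclei_by_type)) as.integer(nuclei_by_type[[ct]]) else 0L
      if (n_ct == 0L) next
      lib <- rlnorm(n_ct, config$libsize_log_mean, config$libsize_log_sd)
      state <- ifelse(runif(n_ct) < 0.5, paste0(ct, ".1"), paste0(ct, ".2"))
      w <- profiles$weights[, ct]
      w2 <- w
      w2[profiles$state_markers[[ct]]] <- w2[profiles$state_markers[[ct]]] *
        config$state_marker_strength
      p1 <- w / sum(w)
      p2 <- w2 / sum(w2)
      base <- rbind(p1, p2)[ifelse(state == paste0(ct, ".1"), 1L, 2L), , drop = FALSE]
      gene_fold <- 2^genotype_log2fc(config, genotype, ct) * exp(patient_effect)
      mu <- (lib * base) * rep(gene_fold, each = n_ct)
      y <- rnbinom(length(mu), mu = as.vector(mu),
        size = rep(1 / config$nb_dispersion, each = n_ct))
      m <- matrix(y, nrow = n_ct)
      blocks[[ct]] <- methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
      cells[[ct]] <- tibble(
        cell_id = sprintf("%s_c%04d", sample_id, idx + seq_len(n_ct)),
        cell_type = ct, cell_state = state, sample_id = sample_id
      )
      idx <- idx + n_ct
    }
    counts <- do.call(rbind, blocks)
    colnames(counts) <- gene_names(config$n_genes)
    list(counts = counts, cells = bind_rows(cells))
  })
}

gene_names <- function(n) sprintf("g%04d", seq_len(n))

#' Simulate a full multi-patient, two-chamber cohort
#'
#' Generates one sample per (patient, region) with the configured genotype
#' effects on composition and expression, and returns the dataset together
#' with a ground-truth ledger (patient table, realised expected proportions,
#' true DEG table, signal genes). Identical seeds give identical output.
#'
#' @param config a [generator_config()].
#' @return list with `data` (an [sn_dataset()]) and `truth` (list of tibbles
#'   `patients`, `composition_expected`, `deg_table`, `signal_genes`).
#' @export
simulate_dataset <- function(config) {
  validate_generator_config(config)
  patients <- purrr::map_dfr(config$genotypes, function(g) {
    purrr::map_dfr(seq_len(config$patients_per_genotype), function(k) {
      pid <- sprintf("P_%s_%02d", g, k)
      with_seed(hash_seed(config$seed, pid), {
        sex <- if (rbinom(1, 1, 0.5) == 1) "M" else "F"
        age <- 0
        while (age < 20 || age > 75) age <- rnorm(1, 50, 10)
        tibble(patient_id = pid, genotype = g, sex = sex, age = round(age, 1))
      })
    })
  })
  patient_effects <- lapply(patients$patient_id, function(pid) {
    with_seed(hash_seed(config$seed, paste0(pid, "/effect")), {
      rnorm(config$n_genes, 0, config$patient_effect_sd)
    })
  })
  names(patient_effects) <- patients$patient_id

  samples <- tidyr::crossing(patients, region = config$regions) |>
    mutate(sample_id = sprintf("S_%s_%s", .data$patient_id, .data$region)) |>
    select("sample_id", "patient_id", "genotype", "region", "sex", "age") |>
    arrange(.data$sample_id)

  sims <- purrr::map(seq_len(nrow(samples)), function(i) {
    simulate_sample(config, samples$genotype[i],
      sample_id = samples$sample_id[i],
      patient_effect = patient_effects[[samples$patient_id[i]]]
    )
  })
  counts <- do.call(rbind, purrr::map(sims, "counts"))
  cells <- bind_rows(purrr::map(sims, "cells"))
  data <- sn_dataset(counts, cells, samples, control_label = config$control)

  comp_expected <- purrr::map_dfr(seq_len(nrow(samples)), function(i) {
    p <- expected_composition(config, samples$genotype[i])
    tibble(
      sample_id = samples$sample_id[i], cell_type = names(p),
      expected_proportion = unname(p)
    )
  })
  disease <- setdiff(config$genotypes, config$control)
  deg_table <- bind_rows(
    tidyr::crossing(config$shared_deg, genotype = disease) |>
      mutate(cell_type = "all", origin = "shared"),
    config$specific_deg |>
      rename(cell_type = "cell_types") |>
      mutate(origin = "specific")
  ) |>
    select("gene", "genotype", "cell_type", "log2fc", "origin") |>
    mutate(gene_name = gene_names(config$n_genes)[.data$gene])
  truth <- list(
    patients = patients,
    composition_expected = comp_expected,
    deg_table = deg_table,
    signal_genes = sort(unique(deg_table$gene))
  )
  list(data = data, truth = truth)
}
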