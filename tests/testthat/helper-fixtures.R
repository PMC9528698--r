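# Shared fixtures, built in code and cached per test session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# A small but complete cohort: 6 genotypes x 2 patients x 2 regions.
small_config <- function(seed = 7, ...) {
  generator_config(
    patients_per_genotype = 2, nuclei_per_sample = 120, n_genes = 400,
    seed = seed, ...
  )
}

small_sim <- function() fixture("small_sim", simulate_dataset(small_config()))

# Hand-built three-nucleus dataset for exact bookkeeping checks.
tiny_dataset <- function() {
  counts <- Matrix::Matrix(
    matrix(c(1, 2, 3, 4, 0, 5), nrow = 3, byrow = TRUE,
      dimnames = list(c("c1", "c2", "c3"), c("gA", "gB"))),
    sparse = TRUE
  )
  cells <- tibble::tibble(
    cell_id = c("c1", "c2", "c3"),
    cell_type = c("CM", "CM", "FB"),
    cell_state = c("CM.1", "CM.2", "FB.1"),
    sample_id = "S1"
  )
  samples <- tibble::tibble(
    sample_id = "S1", patient_id = "P1", genotype = "control",
    region = "LV", sex = "F", age = 50
  )
  sn_dataset(counts, cells, samples)
}

# Dataset with a prescribed dense count matrix and per-nucleus annotation.
make_dataset <- function(counts, cell_type, sample_id, genotype,
                         cell_state = NULL, region = "LV") {
  n <- nrow(counts)
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("g%03d", seq_len(ncol(counts)))
  }
  cells <- tibble::tibble(
    cell_id = sprintf("c%05d", seq_len(n)),
    cell_type = rep_len(cell_type, n),
    cell_state = rep_len(cell_state %||% paste0(cell_type, ".1"), n),
    sample_id = rep_len(sample_id, n)
  )
  samples <- tibble::tibble(sample_id = unique(cells$sample_id)) |>
    dplyr::mutate(
      patient_id = paste0("P_", sample_id),
      genotype = genotype[match(sample_id, unique(cells$sample_id))],
      region = region, sex = "M", age = 50
    )
  sn_dataset(Matrix::Matrix(counts, sparse = TRUE), cells, samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Config with genotype programs of graded strength per cell type, used by
# the classifier checks: strongly separable expression signatures.
separable_config <- function(seed = 21, nuclei_per_sample = 240,
                             strength = c(CM = 2.5, FB = 2.0,
                               Myeloid = 1.4, EC = 0.7)) {
  genos <- c("control", "LMNA", "TTN", "RBM20", "PKP2", "PVneg")
  types <- names(strength)
  spec <- purrr::map_dfr(seq_along(genos[-1]), function(i) {
    g <- genos[-1][i]
    genes <- 200 + (i - 1) * 25 + 1:25
    purrr::map_dfr(types, function(t) {
      tibble::tibble(
        genotype = g, gene = genes,
        log2fc = rep_len(c(1, -1), 25) * strength[[t]], cell_types = t
      )
    })
  })
  w <- c(CM = 0.4, FB = 0.3, Myeloid = 0.15, EC = 0.15)[types]
  generator_config(
    genotypes = genos, patients_per_genotype = 3, regions = "LV",
    cell_types = types,
    baseline_composition = w / sum(w),
    composition_effects = list(), n_genes = 600,
    shared_deg = data.frame(gene = integer(), log2fc = numeric()),
    specific_deg = spec, nuclei_per_sample = nuclei_per_sample, seed = seed
  )
}
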