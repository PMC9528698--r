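test_that("expected composition applies genotype folds with renormalisation", {
  cfg <- generator_config(
    genotypes = c("control", "dz"), cell_types = c("typeA", "typeB"),
    baseline_composition = c(typeA = 0.5, typeB = 0.5),
    composition_effects = list(dz = c(typeA = 0.5)),
    shared_deg = data.frame(gene = integer(), log2fc = numeric()),
    specific_deg = data.frame(genotype = character(), gene = integer(),
      log2fc = numeric(), cell_types = character()),
    n_genes = 50
  )
  expect_equal(unname(expected_composition(cfg, "control")), c(0.5, 0.5))
  expect_equal(unname(expected_composition(cfg, "dz")), c(1 / 3, 2 / 3))
  expect_error(expected_composition(cfg, "nope"), "unknown genotype")
})

test_that("multinomial draws match configured expectations (Monte Carlo)", {
  cfg <- generator_config(
    genotypes = c("control", "dz"), cell_types = c("typeA", "typeB"),
    baseline_composition = c(typeA = 0.5, typeB = 0.5),
    composition_effects = list(dz = c(typeA = 0.5)),
    shared_deg = data.frame(gene = integer(), log2fc = numeric()),
    specific_deg = data.frame(genotype = character(), gene = integer(),
      log2fc = numeric(), cell_types = character()),
    n_genes = 50, nuclei_per_sample = 1000
  )
  set.seed(42)
  reps <- 10000
  draws <- vapply(seq_len(reps), function(i) sample_composition(cfg, "dz")[["typeA"]],
    numeric(1))
  p <- 1 / 3
  se <- sqrt(p * (1 - p) / 1000 / reps)
  expect_lt(abs(mean(draws) / 1000 - p), 3 * se)
})

test_that("composition draws pass a chi-square goodness-of-fit sweep", {
  cfg <- small_config()
  p <- expected_composition(cfg, "RBM20")
  set.seed(1)
  rejected <- 0
  for (s in 1:100) {
    counts <- sample_composition(cfg, "RBM20")
    pv <- suppressWarnings(stats::chisq.test(counts, p = p)$p.value)
    if (pv < 0.01) rejected <- rejected + 1
  }
  expect_lte(rejected, 5)
})

test_that("negative-binomial moments match the configured dispersion", {
  base <- list(
    genotypes = c("control", "dz"), cell_types = "CM",
    baseline_composition = c(CM = 1), composition_effects = list(),
    shared_deg = data.frame(gene = integer(), log2fc = numeric()),
    specific_deg = data.frame(genotype = character(), gene = integer(),
      log2fc = numeric(), cell_types = character()),
    n_genes = 20, libsize_log_mean = log(200), libsize_log_sd = 0,
    state_marker_strength = 1, nuclei_per_sample = 50000, seed = 5
  )
  cfg <- do.call(generator_config, c(base, list(nb_dispersion = 0.4)))
  s <- simulate_sample(cfg, "control")
  m <- as.matrix(s$counts)
  mu <- colMeans(m)
  v <- apply(m, 2, var)
  expect_true(all(abs(v / (mu + 0.4 * mu^2) - 1) < 0.10))

  cfg0 <- do.call(generator_config, c(base, list(nb_dispersion = 1e-8)))
  s0 <- simulate_sample(cfg0, "control")
  m0 <- as.matrix(s0$counts)
  ratio <- apply(m0, 2, var) / colMeans(m0)
  expect_true(all(abs(ratio - 1) < 0.05))
})

test_that("planted log2 fold-changes shift pseudobulk means as configured", {
  cfg <- generator_config(
    genotypes = c("control", "dz"), cell_types = "CM",
    baseline_composition = c(CM = 1), composition_effects = list(),
    shared_deg = data.frame(gene = integer(), log2fc = numeric()),
    specific_deg = data.frame(genotype = "dz", gene = 30, log2fc = 1,
      cell_types = "all"),
    n_genes = 50, libsize_log_sd = 0, patient_effect_sd = 0,
    state_marker_strength = 1, nuclei_per_sample = 20000, seed = 9
  )
  dz <- simulate_sample(cfg, "dz", sample_id = "Sdz")
  ct <- simulate_sample(cfg, "control", sample_id = "Sct")
  ratio <- sum(dz$counts[, 30]) / sum(ct$counts[, 30])
  expect_lt(abs(ratio - 2), 0.1)
  off <- setdiff(seq_len(50), 30)
  expect_lt(abs(sum(dz$counts[, off]) / sum(ct$counts[, off]) - 1), 0.05)
})

test_that("generation is deterministic and order-independent given the seed", {
  cfg <- small_config(seed = 3)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(as.matrix(a$data$counts), as.matrix(b$data$counts))
  expect_identical(a$truth$deg_table, b$truth$deg_table)
  # per-sample streams: a sample simulated alone matches its slice
  sid <- a$data$samples$sample_id[5]
  pid <- a$data$samples$patient_id[5]
  pe <- with(list(), {
    cardiostrat:::with_seed(
      cardiostrat:::hash_seed(cfg$seed, paste0(pid, "/effect")),
      rnorm(cfg$n_genes, 0, cfg$patient_effect_sd)
    )
  })
  solo <- simulate_sample(cfg, a$data$samples$genotype[5], sample_id = sid,
    patient_effect = pe)
  slice <- a$data$counts[a$data$cells$sample_id == sid, ]
  m_solo <- as.matrix(solo$counts)
  m_slice <- as.matrix(slice)
  dimnames(m_solo) <- dimnames(m_slice) <- NULL
  expect_identical(m_solo, m_slice)
})

test_that("cohort layout and ground-truth ledger are complete", {
  sim <- small_sim()
  cfg <- small_config()
  expect_equal(nrow(sim$data$samples), 6 * 2 * 2)
  n_disease <- 5
  expect_equal(
    nrow(sim$truth$deg_table),
    nrow(cfg$shared_deg) * n_disease + nrow(cfg$specific_deg)
  )
  expect_true(all(sim$truth$deg_table$gene <= cfg$n_genes))
  expect_true(all(sim$truth$deg_table$genotype %in% cfg$genotypes))
  # both regions of a patient exist and nuclei counts match config
  per_sample <- table(sim$data$cells$sample_id)
  expect_true(all(per_sample == cfg$nuclei_per_sample))
})

test_that("invalid generator configurations are rejected", {
  expect_error(
    generator_config(baseline_composition = c(CM = 0.5, FB = 0.4, EC = 0.2,
      Mural = 0.1, Myeloid = 0.05, Lymphoid = 0.05)),
    "sum to 1"
  )
  expect_error(generator_config(nb_dispersion = -1), "positive")
  expect_error(
    generator_config(
      shared_deg = data.frame(gene = 300, log2fc = 1),
      specific_deg = data.frame(genotype = "TTN", gene = 300, log2fc = 1,
        cell_types = "all")
    ),
    "overlap"
  )
  expect_error(
    generator_config(genotypes = c("a", "b"), control = "nope"),
    "control"
  )
})
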