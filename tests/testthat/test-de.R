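test_that("pseudobulk aggregation sums counts exactly and applies thresholds", {
  data <- tiny_dataset()
  pb <- suppressMessages(aggregate_pseudobulk(data, "type", min_nuclei = 1))
  cm <- pb$counts[pb$units$category == "CM", ]
  expect_equal(unname(cm), c(1 + 3, 2 + 4))
  pb2 <- suppressMessages(aggregate_pseudobulk(data, "type", min_nuclei = 2))
  expect_false("FB" %in% pb2$units$category)

  sim <- small_sim()
  pb3 <- suppressMessages(aggregate_pseudobulk(sim$data, "type", min_nuclei = 1))
  # brute-force oracle over the annotation mask
  meta <- sim$data$cells
  for (u in sample(pb3$units$unit_id, 5)) {
    parts <- strsplit(u, "|", fixed = TRUE)[[1]]
    mask <- meta$sample_id == parts[1] & meta$cell_type == parts[2]
    oracle <- colSums(as.matrix(sim$data$counts[mask, , drop = FALSE]))
    expect_equal(unname(pb3$counts[u, ]), unname(oracle))
  }
  # conservation: unit sums equal total nucleus counts
  expect_equal(unname(colSums(pb3$counts)),
    unname(Matrix::colSums(sim$data$counts)))
})

test_that("TMM-style factors satisfy their construction constraints", {
  set.seed(1)
  y <- matrix(rnbinom(8 * 2000, mu = 50, size = 5), nrow = 8)
  colnames(y) <- sprintf("g%04d", 1:2000)
  same <- matrix(rep(y[1, ], each = 4), nrow = 4, byrow = FALSE)
  fn_same <- filter_and_normalize(same)
  expect_equal(unname(fn_same$norm_factors), rep(1, 4), tolerance = 1e-8)

  y2 <- rbind(y, 2 * y[1, ])
  f <- cardiostrat:::tmm_factors(y2)
  expect_lt(abs(log(f[9] / f[1])), 0.02) # doubling all genes is pure depth
  expect_lt(abs(sum(log(f))), 1e-8)
  f_any <- filter_and_normalize(y)$norm_factors
  expect_lt(abs(sum(log(f_any))), 1e-8)
})

test_that("TMM factors track an independent reference implementation", {
  # graded one-sided composition shifts so the true factors differ by unit
  set.seed(2)
  mu <- rexp(1500, 1 / 40)
  frac <- c(0, 0, 0, 0, 0.1, 0.2, 0.3, 0.4)
  y <- t(vapply(1:8, function(i) {
    f <- rep(1, 1500)
    if (frac[i] > 0) f[sample(1500, 1500 * frac[i])] <- 6
    rnbinom(1500, mu = mu * f * runif(1, 0.5, 2), size = 8)
  }, numeric(1500)))
  ours <- cardiostrat:::tmm_factors(y)
  ref <- edgeR::calcNormFactors(t(y), method = "TMM")
  expect_gt(cor(log(ours), log(ref)), 0.98)
  expect_lt(max(abs(log(ours) - log(ref))), 0.1)
})

test_that("dispersion estimation recovers simulated values with shrinkage", {
  set.seed(4)
  n_units <- 20
  groups <- factor(rep(c("a", "b"), each = n_units / 2))
  offsets <- rep(log(5e4), n_units)

  pois <- matrix(rpois(n_units * 500, lambda = 60), ncol = n_units)
  dp <- estimate_dispersion(t(pois), groups, offsets)
  expect_lt(median(dp$shrunken), 0.01)

  nb <- matrix(rnbinom(n_units * 2000, mu = 60, size = 1 / 0.4), ncol = n_units)
  dn <- estimate_dispersion(t(nb), groups, offsets)
  expect_gt(median(dn$shrunken), 0.3)
  expect_lt(median(dn$shrunken), 0.5)
  expect_true(all(dn$shrunken >= pmin(dn$raw, dn$common) - 1e-12))
  expect_true(all(dn$shrunken <= pmax(dn$raw, dn$common) + 1e-12))
})

test_that("NB LRT with zero dispersion agrees with the Poisson GLM", {
  set.seed(5)
  n_units <- 10
  condition <- factor(rep(c("ctl", "dz"), each = 5), levels = c("ctl", "dz"))
  offsets <- log(runif(n_units, 3e4, 6e4))
  counts <- matrix(rpois(n_units * 100, lambda = exp(log(30) +
    rep(c(0, 0.4), each = 5))), nrow = n_units)
  colnames(counts) <- sprintf("g%03d", 1:100)
  res <- test_de(counts, condition, offsets, dispersion = 0)
  for (j in seq_len(100)) {
    fit <- glm(counts[, j] ~ condition + offset(offsets), family = poisson())
    fit0 <- glm(counts[, j] ~ 1 + offset(offsets), family = poisson())
    lrt <- fit0$deviance - fit$deviance
    expect_equal(res$statistic[j], lrt, tolerance = 1e-6)
    expect_equal(res$logFC[j], unname(coef(fit)[2]) / log(2), tolerance = 1e-6)
  }
})

test_that("DE calibration holds under the generator null", {
  cfg <- generator_config(
    genotypes = c("control", "dz"), patients_per_genotype = 6, regions = "LV",
    cell_types = "CM", baseline_composition = c(CM = 1),
    composition_effects = list(), n_genes = 600,
    shared_deg = data.frame(gene = integer(), log2fc = numeric()),
    specific_deg = data.frame(genotype = character(), gene = integer(),
      log2fc = numeric(), cell_types = character()),
    nuclei_per_sample = 200, seed = 31
  )
  sim <- simulate_dataset(cfg)
  pb <- suppressMessages(aggregate_pseudobulk(sim$data, "type"))
  de <- de_test(pb, "dz", "CM")
  frac <- mean(de$p.value < 0.05, na.rm = TRUE)
  expect_gt(frac, 0.01)
  expect_lt(frac, 0.09)
})

test_that("DEG partitioning matches its set-algebra definition", {
  mk <- function(genotype, sig) {
    tibble::tibble(genotype = genotype, gene = sprintf("g%02d", 1:20),
      fdr = ifelse(1:20 %in% sig, 0.01, 0.5))
  }
  disjoint <- dplyr::bind_rows(mk("a", 1:5), mk("b", 6:10))
  pd <- partition_degs(disjoint)
  expect_equal(pd$pct_specific, c(100, 100))
  same <- dplyr::bind_rows(mk("a", 1:5), mk("b", 1:5))
  pd2 <- partition_degs(same)
  expect_equal(pd2$pct_specific, c(0, 0))
  expect_equal(sort(attr(pd2, "shared_genes")), sprintf("g%02d", 1:5))
  none <- dplyr::bind_rows(mk("a", integer(0)), mk("b", 1:3))
  expect_true(is.na(partition_degs(none)$pct_specific[1]))
  expect_error(
    partition_degs(dplyr::bind_rows(mk("a", 1), mk("b", 1)[1:10, ])),
    "universe"
  )
})

test_that("gene-set scores are centred on controls and detect planted shifts", {
  cfg <- generator_config(
    genotypes = c("control", "dz"), patients_per_genotype = 4, regions = "LV",
    cell_types = c("CM", "FB"), baseline_composition = c(CM = 0.6, FB = 0.4),
    composition_effects = list(), n_genes = 300,
    shared_deg = data.frame(gene = integer(), log2fc = numeric()),
    specific_deg = data.frame(genotype = "dz", gene = 201:220, log2fc = 1.2,
      cell_types = "CM"),
    nuclei_per_sample = 150, seed = 13
  )
  sim <- simulate_dataset(cfg)
  genes <- sprintf("g%04d", 201:220)
  sc <- gene_set_score(sim$data, genes, set_name = "program")
  ctl <- sc[sc$genotype == "control", ]
  expect_lt(abs(mean(ctl$score[ctl$cell_type == "CM"])), 0.05)
  cm <- sc[sc$cell_type == "CM", ]
  tt <- t.test(cm$score[cm$genotype == "dz"], cm$score[cm$genotype == "control"])
  expect_gt(mean(cm$score[cm$genotype == "dz"]), 0)
  expect_lt(tt$p.value, 0.01)
  # single-gene set equals that gene's z-score
  one <- gene_set_score(sim$data, genes[1], set_name = "solo")
  both <- gene_set_score(sim$data, genes[1:2], set_name = "duo")
  expect_false(isTRUE(all.equal(one$score, both$score)))
  expect_error(gene_set_score(sim$data, "absent_gene"), "missing")
  expect_error(gene_set_score(sim$data, character(0)), "empty")
})

test_that("Fisher enrichment matches the exhaustive hypergeometric oracle", {
  universe <- sprintf("u%03d", 1:120)
  candidate <- universe[1:20]
  deg <- universe[c(1:10, 21:30)]
  res <- fisher_enrichment(candidate, deg, universe)
  expect_equal(res$a, 10)
  expect_equal(res$odds_ratio, (10 * 90) / (10 * 10))
  # exhaustive tail enumeration on the same margins
  m <- res$a + res$b
  k <- res$a + res$c
  n_tot <- 120
  tail_p <- sum(vapply(res$a:min(m, k), function(x) {
    choose(m, x) * choose(n_tot - m, k - x) / choose(n_tot, k)
  }, numeric(1)))
  expect_equal(res$p.value, tail_p, tolerance = 1e-12)
  # degenerate margin: candidate = universe
  expect_equal(fisher_enrichment(universe, deg, universe)$p.value, 1)
  expect_error(fisher_enrichment("x", "y", character(0)), "universe|subset")
})

test_that("BH adjustment equals the running-minimum construction", {
  set.seed(8)
  p <- runif(50)^2
  manual <- function(p) {
    n <- length(p)
    o <- order(p, decreasing = TRUE)
    ro <- order(o)
    pmin(1, cummin(n / (n:1) * p[o]))[ro]
  }
  expect_equal(cardiostrat:::bh_adjust(p), manual(p))
})
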