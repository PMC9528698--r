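test_that("kNN graph matches geometry and a brute-force oracle", {
  # three collinear points, k = 1: the middle point gets degree 3
  emb <- matrix(c(0, 1, 2.1), ncol = 1)
  g <- build_knn_graph(emb, k = 1)
  deg <- Matrix::rowSums(g$adj)
  expect_equal(unname(deg[2]), 3)
  expect_true(Matrix::isSymmetric(g$adj))

  set.seed(7)
  emb2 <- matrix(rnorm(200 * 5), 200, 5)
  g2 <- build_knn_graph(emb2, k = 10)
  d <- as.matrix(dist(emb2))
  diag(d) <- Inf
  a_oracle <- matrix(0, 200, 200)
  for (i in 1:200) {
    nn <- order(d[i, ], seq_len(200))[1:10]
    a_oracle[i, nn] <- 1
  }
  a_oracle <- pmax(a_oracle, t(a_oracle))
  diag(a_oracle) <- 1
  expect_equal(as.matrix(g2$adj), a_oracle, ignore_attr = TRUE)
  expect_identical(as.matrix(g2$adj), t(as.matrix(g2$adj)))
  expect_error(build_knn_graph(emb, k = 3), "smaller")
})

test_that("PCA embedding is deterministic with ordered variances", {
  sim <- small_sim()
  e1 <- pca_embed(sim$data, "CM", d = 10, n_hvg = 200)
  e2 <- pca_embed(sim$data, "CM", d = 10, n_hvg = 200)
  expect_identical(e1$embedding, e2$embedding)
  expect_true(all(diff(e1$var_explained) <= 1e-12))
  # column variances of the projection equal the eigenvalue spectrum
  v <- apply(e1$embedding, 2, var)
  n <- nrow(e1$embedding)
  expect_equal(v, e1$var_explained * sum(v) / sum(e1$var_explained),
    tolerance = 1e-8, ignore_attr = TRUE)
  # rank-1 data: first component dominates
  x <- outer(rnorm(50), rnorm(12))
  counts <- matrix(rpois(50 * 12, lambda = exp(2 + x - min(x))), 50, 12)
  d1 <- make_dataset(counts, "CM", "S1", "control")
  e3 <- pca_embed(d1, "CM", d = 5, n_hvg = 12)
  expect_gt(e3$var_explained[1] / sum(e3$var_explained), 0.5)
})

# Straight-line re-implementation of the layer equations with explicit loops.
gat_layer_loops <- function(H, adj, W, a, slope) {
  n <- nrow(H)
  d_out <- ncol(W)
  Z <- H %*% W
  out <- matrix(0, n, d_out)
  for (i in seq_len(n)) {
    nbrs <- which(adj[i, ] > 0)
    e <- vapply(nbrs, function(j) {
      v <- sum(a * c(Z[i, ], Z[j, ]))
      if (v > 0) v else slope * v
    }, numeric(1))
    al <- exp(e - max(e))
    al <- al / sum(al)
    for (jj in seq_along(nbrs)) {
      out[i, ] <- out[i, ] + al[jj] * Z[nbrs[jj], ]
    }
  }
  out
}

test_that("the forward pass matches an independent loop implementation", {
  set.seed(9)
  X <- matrix(rnorm(10 * 4), 10, 4)
  g <- build_knn_graph(X, k = 3)
  params <- gat_init(4, 3, heads = 2, hidden_dim = 3, seed = 2)
  fwd <- gat_forward(g, X, params, return_cache = TRUE)
  adj <- as.matrix(g$adj)
  l1 <- params$layers[[1]]
  pre <- cbind(
    gat_layer_loops(X, adj, l1$W[[1]], l1$a[[1]], params$slope),
    gat_layer_loops(X, adj, l1$W[[2]], l1$a[[2]], params$slope)
  )
  hidden <- ifelse(pre > 0, pre, exp(pmin(pre, 0)) - 1)
  l2 <- params$layers[[2]]
  logits <- (gat_layer_loops(hidden, adj, l2$W[[1]], l2$a[[1]], params$slope) +
    gat_layer_loops(hidden, adj, l2$W[[2]], l2$a[[2]], params$slope)) / 2
  prob <- exp(logits - apply(logits, 1, max))
  prob <- prob / rowSums(prob)
  expect_equal(fwd$prob, prob, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("attention rows are normalised and symmetric cases split evenly", {
  set.seed(10)
  X <- matrix(rnorm(12 * 3), 12, 3)
  g <- build_knn_graph(X, k = 4)
  params <- gat_init(3, 2, heads = 3, hidden_dim = 4, seed = 4)
  fwd <- gat_forward(g, X, params, return_cache = TRUE)
  for (h in 1:3) {
    s <- rowsum(fwd$cache$layer1[[h]]$alpha, g$i)
    expect_lt(max(abs(s - 1)), 1e-6)
  }
  expect_lt(max(abs(rowSums(fwd$prob) - 1)), 1e-6)

  # two identical nodes attending over each other: alpha = 1/2 each
  X2 <- matrix(1, 2, 3)
  g2 <- build_knn_graph(X2, k = 1)
  fwd2 <- gat_forward(g2, X2, params, return_cache = TRUE)
  expect_equal(unname(fwd2$cache$layer1[[1]]$alpha), rep(0.5, 4))

  # isolated node (self-loop only): alpha_ii = 1
  g_iso <- structure(list(
    adj = Matrix::Diagonal(1), i = 1L, j = 1L,
    by_i = list(`1` = 1L), n = 1L, k = 0L,
    nodes = tibble::tibble(node = 1L)
  ), class = "knn_graph")
  fwd3 <- gat_forward(g_iso, matrix(1, 1, 3), params, return_cache = TRUE)
  expect_equal(unname(fwd3$cache$layer1[[1]]$alpha), 1)
})

test_that("analytic gradients match central finite differences", {
  set.seed(3)
  X <- matrix(rnorm(10 * 4), 10, 4)
  g <- build_knn_graph(X, k = 3)
  labels <- factor(sample(c("a", "b", "c"), 10, replace = TRUE))
  params <- gat_init(4, 3, heads = 2, hidden_dim = 3, seed = 5)
  yi <- as.integer(labels)
  mask <- 1:7
  lg <- cardiostrat:::gat_loss_grad(g, X, params, yi, mask)
  theta <- cardiostrat:::gat_flatten(params)
  gvec <- unlist(lg$grad, use.names = FALSE)
  h <- 1e-5
  f <- function(th) {
    cardiostrat:::gat_loss_grad(g, X,
      cardiostrat:::gat_unflatten(params, th), yi, mask)$loss
  }
  num <- vapply(seq_along(theta), function(p) {
    tp <- theta
    tp[p] <- tp[p] + h
    tm <- theta
    tm[p] <- tm[p] - h
    (f(tp) - f(tm)) / (2 * h)
  }, numeric(1))
  rel <- abs(gvec - num) / pmax(abs(num), 1e-6)
  expect_lt(max(rel), 1e-4)
})

test_that("predictions are invariant to node relabelling", {
  set.seed(12)
  X <- matrix(rnorm(30 * 4), 30, 4)
  g <- build_knn_graph(X, k = 5)
  params <- gat_init(4, 3, heads = 2, hidden_dim = 3, seed = 6)
  p1 <- gat_forward(g, X, params)$prob
  perm <- sample(30)
  g2 <- build_knn_graph(X[perm, , drop = FALSE], k = 5)
  p2 <- gat_forward(g2, X[perm, , drop = FALSE], params)$prob
  expect_equal(p2, p1[perm, ], tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("training bookkeeping, class checks and loss improvement hold", {
  set.seed(13)
  n <- 60
  cls <- rep(c("a", "b", "c"), each = 20)
  X <- matrix(rnorm(n * 4, mean = rep(c(-2, 0, 2), each = 20)), n, 4)
  g <- build_knn_graph(X, k = 5)
  labels <- factor(cls)
  fit <- train_gat(g, X, labels, train_idx = 1:45, val_idx = 46:60,
    heads = 2, hidden_dim = 4, epochs = 80, lr = 0.05, optimizer = "adam",
    seed = 2)
  expect_s3_class(fit, "gat_fit")
  expect_lt(min(fit$log$val_loss), fit$log$val_loss[1])
  expect_gt(dplyr::last(fit$log$train_acc), 0.8)
  expect_equal(glance(fit)$best_epoch, fit$best_epoch)
  expect_error(
    train_gat(g, X, labels, train_idx = 1:20, val_idx = 46:60,
      heads = 2, hidden_dim = 4, epochs = 5),
    "absent"
  )
})

test_that("patient aggregation is a convex combination with exact arithmetic", {
  preds <- tibble::tibble(
    patient_id = c("P1", "P1", "P2"),
    genotype = c("a", "a", "b"),
    cell_type = c("CM", "CM", "CM"),
    prob_a = c(0.8, 0.4, 1), prob_b = c(0.2, 0.6, 0)
  )
  agg <- aggregate_patient(preds)
  p1 <- agg[agg$patient_id == "P1" & agg$scope == "aggregate", ]
  expect_equal(c(p1$prob_a, p1$prob_b), c(0.6, 0.4))
  p2 <- agg[agg$patient_id == "P2" & agg$scope == "aggregate", ]
  expect_equal(p2$prob_a, 1)
  expect_equal(p2$predicted, "a")
  sums <- rowSums(as.matrix(agg[, c("prob_a", "prob_b")]))
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_message(
    aggregate_patient(preds, all_patients = c("P1", "P2", "P3")),
    "P3"
  )
})

test_that("cross-validation is leakage-safe and covers every patient", {
  cfg <- separable_config(seed = 33, nuclei_per_sample = 60,
    strength = c(CM = 2.5, EC = 0.7))
  sim <- simulate_dataset(cfg)
  cv <- suppressMessages(classify_genotype(sim$data, cell_types = "CM",
    region = "LV", folds = 3, epochs = 15, lr = 0.02, optimizer = "adam",
    k = 8, seed = 5))
  np <- cv$node_predictions
  # every nucleus of the cell type predicted exactly once
  expect_equal(anyDuplicated(np$cell_id), 0)
  # fold/patient partition: a patient appears in exactly one fold
  by_pat <- dplyr::distinct(np, patient_id, fold)
  expect_equal(anyDuplicated(by_pat$patient_id), 0)
  expect_setequal(unique(np$patient_id), unique(sim$data$samples$patient_id))
  # probabilities live on the simplex
  pm <- as.matrix(np[, grep("^prob_", names(np))])
  expect_lt(max(abs(rowSums(pm) - 1)), 1e-6)
  expect_s3_class(glance(cv), "tbl_df")
})
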