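# Graph attention network for multinomial genotype classification.
# Forward and backward passes are written directly from the layer equations
# (edge-list form) so gradients can be verified against finite differences.

#' PCA embedding of one cell type's nuclei
#'
#' log1p counts-per-10k normalises, selects the `n_hvg` highest-dispersion
#' (variance/mean) genes, z-scales each gene (clipped at +/-10), and projects
#' onto the top `d` principal components. Component signs follow a
#' deterministic convention: the largest-magnitude gene loading of each
#' component is positive.
#'
#' @param data an [sn_dataset()].
#' @param cell_type cell type to embed.
#' @param d number of components (default 30).
#' @param n_hvg number of high-dispersion genes (default 1000; all genes are
#'   used with a message when fewer are available).
#' @param region optional region filter.
#' @return list with `embedding` (nuclei x d, rownames cell ids),
#'   `var_explained` (length d, decreasing), `genes` (HVG names) and
#'   `cells` (annotation tibble of the embedded nuclei).
#' @export
pca_embed <- function(data, cell_type, d = 30L, n_hvg = 1000L, region = NULL) {
  meta <- cell_metadata(data)
  sel <- meta$cell_type == cell_type
  if (!is.null(region)) sel <- sel & meta$region %in% region
  if (sum(sel) < d + 1) {
    abort(sprintf("need at least d+1 = %d nuclei of type '%s'.", d + 1, cell_type))
  }
  norm <- normalize_log1p_cp10k(data$counts[sel, , drop = FALSE])
  mu <- Matrix::colMeans(norm)
  ex2 <- Matrix::colMeans(norm^2)
  v <- (ex2 - mu^2) * nrow(norm) / max(nrow(norm) - 1, 1)
  disp <- ifelse(mu > 0, v / mu, 0)
  n_hvg_eff <- min(n_hvg, sum(mu > 0))
  if (n_hvg_eff < n_hvg) {
    inform(sprintf("only %d expressed genes available; using all.", n_hvg_eff))
  }
  hvg <- order(disp, decreasing = TRUE)[seq_len(n_hvg_eff)]
  x <- as.matrix(norm[, hvg, drop = FALSE])
  s <- apply(x, 2, sd)
  keep <- s > 0
  x <- scale(x[, keep, drop = FALSE])
  x[x > 10] <- 10
  x[x < -10] <- -10
  d <- min(d, ncol(x), nrow(x) - 1)
  sv <- svd(x, nu = d, nv = d)
  scores <- sv$u %*% diag(sv$d[seq_len(d)], d)
  loadings <- sv$v
  for (cc in seq_len(d)) {
    top <- which.max(abs(loadings[, cc]))
    if (loadings[top, cc] < 0) {
      loadings[, cc] <- -loadings[, cc]
      scores[, cc] <- -scores[, cc]
    }
  }
  rownames(scores) <- meta$cell_id[sel]
  list(
    embedding = scores,
    var_explained = (sv$d[seq_len(d)]^2) / sum(sv$d^2),
    genes = colnames(data$counts)[hvg][keep],
    cells = meta[sel, , drop = FALSE]
  )
}

#' k-nearest-neighbour graph on an embedding
#'
#' Euclidean kNN (self excluded, distance ties broken by node index), edges
#' symmetrised by union, self-loops added. The adjacency is exactly
#' symmetric with unit diagonal.
#'
#' @param embedding numeric matrix, one row per node.
#' @param k neighbours per node (default 15; must be < number of nodes).
#' @param nodes optional tibble of per-node metadata (cell_id, cell_type,
#'   patient_id, genotype, ...).
#' @return A `knn_graph`: list with `adj` (sparse symmetric 0/1 matrix with
#'   diagonal), directed edge vectors `i`, `j` (every ordered pair incl.
#'   self-loops), `by_i` (edge indices grouped by attending node), `n`, `k`,
#'   `nodes`.
#' @export
build_knn_graph <- function(embedding, k = 15L, nodes = NULL) {
  n <- nrow(embedding)
  if (n <= k) abort("`k` must be smaller than the number of nodes.")
  nn <- matrix(0L, n, k)
  block <- 512L
  sq <- rowSums(embedding^2)
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    d2 <- outer(sq[rows], sq, "+") - 2 * embedding[rows, , drop = FALSE] %*% t(embedding)
    for (ri in seq_along(rows)) {
      node <- rows[ri]
      dd <- d2[ri, ]
      dd[node] <- Inf
      ord <- order(dd, seq_len(n))
      nn[node, ] <- ord[seq_len(k)]
    }
  }
  a <- Matrix::sparseMatrix(
    i = c(rep(seq_len(n), each = k), as.vector(t(nn))),
    j = c(as.vector(t(nn)), rep(seq_len(n), each = k)),
    x = 1, dims = c(n, n)
  )
  a <- methods::as(a > 0, "CsparseMatrix") * 1
  Matrix::diag(a) <- 1
  tri <- methods::as(a, "TsparseMatrix")
  i <- tri@i + 1L
  j <- tri@j + 1L
  ord <- order(i, j)
  i <- i[ord]
  j <- j[ord]
  structure(
    list(
      adj = a, i = i, j = j,
      by_i = split(seq_along(i), factor(i, levels = seq_len(n))),
      n = n, k = k,
      nodes = nodes %||% tibble(node = seq_len(n))
    ),
    class = "knn_graph"
  )
}

# --- parameters -------------------------------------------------------------

#' Initialise GAT parameters
#'
#' One hidden multi-head layer (concatenated heads, ELU) followed by an
#' output layer whose heads are averaged before the class softmax. Weights
#' use Glorot-uniform initialisation; attention vectors `a` have length
#' `2 * d_out` (first half scores the attending node, second half the
#' neighbour).
#'
#' @param d_in input feature dimension.
#' @param n_class number of genotype classes.
#' @param heads attention heads per layer (default 8).
#' @param hidden_dim per-head hidden dimension (default 8).
#' @param slope negative slope of the attention LeakyReLU (default 0.2).
#' @param seed RNG seed.
#' @return `gat_params` list.
#' @export
gat_init <- function(d_in, n_class, heads = 8L, hidden_dim = 8L,
                     slope = 0.2, seed = 1L) {
  glorot <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(runif(nr * nc, -lim, lim), nr, nc)
  }
  with_seed(seed, {
    l1 <- list(
      W = lapply(seq_len(heads), function(h) glorot(d_in, hidden_dim)),
      a = lapply(seq_len(heads), function(h) as.vector(glorot(2 * hidden_dim, 1)))
    )
    l2 <- list(
      W = lapply(seq_len(heads), function(h) glorot(heads * hidden_dim, n_class)),
      a = lapply(seq_len(heads), function(h) as.vector(glorot(2 * n_class, 1)))
    )
    structure(
      list(layers = list(l1, l2), heads = heads, hidden_dim = hidden_dim,
        slope = slope, d_in = d_in, n_class = n_class),
      class = "gat_params"
    )
  })
}

group_sum <- function(x, g, n) {
  out <- numeric(n)
  s <- rowsum(x, g)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

group_max <- function(x, by_i) {
  vapply(by_i, function(ix) max(x[ix]), numeric(1))
}

# Forward through one GAT layer for one head; returns aggregation and cache.
gat_head_forward <- function(H, graph, W, a, slope) {
  d_out <- ncol(W)
  Z <- H %*% W
  a_src <- a[seq_len(d_out)]
  a_dst <- a[d_out + seq_len(d_out)]
  s <- as.vector(Z %*% a_src)
  t_ <- as.vector(Z %*% a_dst)
  epre <- s[graph$i] + t_[graph$j]
  e <- ifelse(epre > 0, epre, slope * epre)
  m <- group_max(e, graph$by_i)
  w <- exp(e - m[graph$i])
  denom <- group_sum(w, graph$i, graph$n)
  alpha <- w / denom[graph$i]
  agg <- rowsum(alpha * Z[graph$j, , drop = FALSE], graph$i)
  list(agg = agg, Z = Z, alpha = alpha, epre = epre,
    a_src = a_src, a_dst = a_dst)
}

# Backward for one head given dAgg; returns gradients and dH contribution.
gat_head_backward <- function(H, graph, W, cache, dAgg, slope) {
  Z <- cache$Z
  alpha <- cache$alpha
  i <- graph$i
  j <- graph$j
  dZ_agg <- rowsum(alpha * dAgg[i, , drop = FALSE], j)
  g_e <- rowSums(dAgg[i, , drop = FALSE] * Z[j, , drop = FALSE])
  S <- group_sum(alpha * g_e, i, graph$n)
  de <- alpha * (g_e - S[i])
  depre <- de * ifelse(cache$epre > 0, 1, slope)
  ds <- group_sum(depre, i, graph$n)
  dt <- group_sum(depre, j, graph$n)
  da_src <- as.vector(crossprod(Z, ds))
  da_dst <- as.vector(crossprod(Z, dt))
  dZ <- dZ_agg + outer(ds, cache$a_src) + outer(dt, cache$a_dst)
  list(
    dW = crossprod(H, dZ),
    da = c(da_src, da_dst),
    dH = dZ %*% t(W)
  )
}

softmax_rows <- function(x) {
  m <- apply(x, 1, max)
  e <- exp(x - m)
  e / rowSums(e)
}

#' GAT forward pass
#'
#' @param graph a [build_knn_graph()] result.
#' @param features nodes x d_in matrix.
#' @param params a [gat_init()] object.
#' @param return_cache keep intermediate activations (for the backward
#'   pass / attention inspection).
#' @return list with `prob` (nodes x classes, rows on the simplex), `logits`
#'   and, if requested, `cache` (per layer/head, incl. attention
#'   coefficients `alpha` and edge indices).
#' @export
gat_forward <- function(graph, features, params, return_cache = FALSE) {
  if (ncol(features) != params$d_in) {
    abort(sprintf("feature dimension %d does not match layer-1 input %d.",
      ncol(features), params$d_in))
  }
  heads <- params$heads
  l1 <- params$layers[[1]]
  caches1 <- lapply(seq_len(heads), function(h) {
    gat_head_forward(features, graph, l1$W[[h]], l1$a[[h]], params$slope)
  })
  pre_hidden <- do.call(cbind, lapply(caches1, `[[`, "agg"))
  hidden <- ifelse(pre_hidden > 0, pre_hidden, exp(pmin(pre_hidden, 0)) - 1) # ELU
  if (any(!is.finite(hidden))) abort("NaN in activations at layer 1.")
  l2 <- params$layers[[2]]
  caches2 <- lapply(seq_len(heads), function(h) {
    gat_head_forward(hidden, graph, l2$W[[h]], l2$a[[h]], params$slope)
  })
  logits <- Reduce(`+`, lapply(caches2, `[[`, "agg")) / heads
  if (any(!is.finite(logits))) abort("NaN in activations at layer 2.")
  prob <- softmax_rows(logits)
  out <- list(prob = prob, logits = logits)
  if (return_cache) {
    out$cache <- list(
      layer1 = caches1, pre_hidden = pre_hidden, hidden = hidden,
      layer2 = caches2
    )
  }
  out
}

# Cross-entropy loss on masked nodes plus full parameter gradient.
gat_loss_grad <- function(graph, features, params, y_idx, mask) {
  fwd <- gat_forward(graph, features, params, return_cache = TRUE)
  n_train <- length(mask)
  p <- fwd$prob
  loss <- -mean(log(pmax(p[cbind(mask, y_idx[mask])], 1e-300)))
  dlogits <- matrix(0, nrow(p), ncol(p))
  Y <- matrix(0, nrow(p), ncol(p))
  Y[cbind(mask, y_idx[mask])] <- 1
  dlogits[mask, ] <- (p[mask, , drop = FALSE] - Y[mask, , drop = FALSE]) / n_train
  heads <- params$heads
  l2 <- params$layers[[2]]
  dHidden <- matrix(0, nrow(fwd$cache$hidden), ncol(fwd$cache$hidden))
  grad2 <- list(W = vector("list", heads), a = vector("list", heads))
  for (h in seq_len(heads)) {
    bk <- gat_head_backward(fwd$cache$hidden, graph, l2$W[[h]],
      fwd$cache$layer2[[h]], dlogits / heads, params$slope)
    grad2$W[[h]] <- bk$dW
    grad2$a[[h]] <- bk$da
    dHidden <- dHidden + bk$dH
  }
  pre <- fwd$cache$pre_hidden
  dPre <- dHidden * ifelse(pre > 0, 1, exp(pmin(pre, 0)))
  l1 <- params$layers[[1]]
  grad1 <- list(W = vector("list", heads), a = vector("list", heads))
  hd <- params$hidden_dim
  for (h in seq_len(heads)) {
    cols <- (h - 1L) * hd + seq_len(hd)
    bk <- gat_head_backward(features, graph, l1$W[[h]],
      fwd$cache$layer1[[h]], dPre[, cols, drop = FALSE], params$slope)
    grad1$W[[h]] <- bk$dW
    grad1$a[[h]] <- bk$da
  }
  list(loss = loss, grad = list(grad1, grad2), prob = p)
}

gat_flatten <- function(params) {
  unlist(params$layers, use.names = FALSE)
}

gat_unflatten <- function(params, theta) {
  rel <- utils::relist(theta, params$layers)
  params$layers <- rel
  params
}

#' Train a GAT by full-batch gradient descent with early stopping
#'
#' Minimises cross-entropy on the training nuclei (all nuclei of a patient
#' are entirely in train or test). Plain gradient descent with a fixed step
#' and gradient clipping by default; Adam available via `optimizer`.
#' Training stops after `patience` epochs without improvement of the
#' validation loss and the best-validation parameters are returned.
#'
#' @param graph a [build_knn_graph()] result.
#' @param features node feature matrix.
#' @param labels factor of per-node genotype labels.
#' @param train_idx,val_idx integer node indices (disjoint).
#' @param heads,hidden_dim,slope architecture, see [gat_init()].
#' @param epochs maximum epochs (default 200).
#' @param patience early-stopping window (default 20).
#' @param lr step size.
#' @param clip gradient-norm clip (default 5).
#' @param optimizer `"gd"` (default) or `"adam"`.
#' @param seed initialisation seed.
#' @return `gat_fit` object: `params` (best), `classes`, `log` tibble
#'   (epoch, train_loss, val_loss, train_acc), `best_epoch`.
#' @export
train_gat <- function(graph, features, labels, train_idx, val_idx,
                      heads = 8L, hidden_dim = 8L, slope = 0.2,
                      epochs = 200L, patience = 20L, lr = 0.05, clip = 5,
                      optimizer = c("gd", "adam"), seed = 1L) {
  optimizer <- match.arg(optimizer)
  labels <- as.factor(labels)
  classes <- levels(labels)
  missing_class <- setdiff(classes, unique(as.character(labels[train_idx])))
  if (length(missing_class) > 0) {
    abort(paste0("class absent from training nuclei: ",
      paste(missing_class, collapse = ", ")))
  }
  y_idx <- as.integer(labels)
  params <- gat_init(ncol(features), length(classes),
    heads = heads, hidden_dim = hidden_dim, slope = slope, seed = seed)
  theta <- gat_flatten(params)
  m <- v <- numeric(length(theta))
  best <- list(loss = Inf, theta = theta, epoch = 0L)
  log <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    params <- gat_unflatten(params, theta)
    lg <- gat_loss_grad(graph, features, params, y_idx, train_idx)
    g <- unlist(lg$grad, use.names = FALSE)
    gn <- sqrt(sum(g^2))
    if (gn > clip) g <- g * clip / gn
    if (optimizer == "gd") {
      theta <- theta - lr * g
    } else {
      m <- 0.9 * m + 0.1 * g
      v <- 0.999 * v + 0.001 * g^2
      mh <- m / (1 - 0.9^ep)
      vh <- v / (1 - 0.999^ep)
      theta <- theta - lr * mh / (sqrt(vh) + 1e-8)
    }
    val_loss <- if (length(val_idx) > 0) {
      pv <- lg$prob[val_idx, , drop = FALSE]
      -mean(log(pmax(pv[cbind(seq_along(val_idx), y_idx[val_idx])], 1e-300)))
    } else {
      lg$loss
    }
    train_acc <- mean(max.col(lg$prob[train_idx, , drop = FALSE]) == y_idx[train_idx])
    log[[ep]] <- tibble(epoch = ep, train_loss = lg$loss,
      val_loss = val_loss, train_acc = train_acc)
    if (val_loss < best$loss - 1e-9) {
      best <- list(loss = val_loss, theta = theta, epoch = ep)
    } else if (ep - best$epoch >= patience) {
      log <- log[seq_len(ep)]
      break
    }
  }
  params <- gat_unflatten(params, best$theta)
  structure(
    list(
      params = params, classes = classes,
      log = bind_rows(log), best_epoch = best$epoch
    ),
    class = "gat_fit"
  )
}

#' @export
print.gat_fit <- function(x, ...) {
  cat(sprintf(
    "<gat_fit> %d classes, %d heads x %d hidden | best epoch %d (val loss %.4f)\n",
    length(x$classes), x$params$heads, x$params$hidden_dim,
    x$best_epoch, min(x$log$val_loss)
  ))
  invisible(x)
}

#' Predict per-nucleus genotype probabilities
#'
#' @param object a [train_gat()] fit.
#' @param graph,features the graph and features to score.
#' @param ... unused.
#' @return Tibble: node metadata columns, one `prob_<class>` column per
#'   class (rows sum to 1), and `predicted` (argmax class).
#' @export
predict.gat_fit <- function(object, graph, features, ...) {
  fwd <- gat_forward(graph, features, object$params)
  prob <- fwd$prob
  colnames(prob) <- paste0("prob_", object$classes)
  out <- bind_cols(graph$nodes, as_tibble(prob))
  out$predicted <- object$classes[max.col(prob)]
  out
}
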