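# Internal helpers shared across modules.

# Deterministic 31-bit hash of (seed, id) used to give every sample/patient
# its own RNG stream, so generation is independent of the order in which
# samples are drawn.
hash_seed <- function(seed, id) {
  codes <- utf8ToInt(as.character(id))
  h <- as.numeric(seed) %% 2147483647
  for (c in codes) {
    h <- (h * 31 + c) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under a local RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# log1p counts-per-10k normalisation of a sparse nuclei x genes matrix.
# Returns a dgCMatrix with the same dimnames.
normalize_log1p_cp10k <- function(counts, scale_factor = 1e4) {
  lib <- Matrix::rowSums(counts)
  lib[lib == 0] <- 1
  x <- methods::as(Matrix::Diagonal(x = scale_factor / lib) %*% counts, "CsparseMatrix")
  x@x <- log1p(x@x)
  dimnames(x) <- dimnames(counts)
  x
}

# Benjamini-Hochberg adjustment; thin wrapper kept so the family definition
# (adjust within one contrast) is applied consistently.
bh_adjust <- function(p) p.adjust(p, method = "BH")

# Tukey trimean with type-7 (linear interpolation) quartiles.
trimean <- function(x) {
  q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  (q[1] + 2 * q[2] + q[3]) / 4
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number.", name))
  }
  invisible(x)
}
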