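# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so generators do not disturb the
# session RNG stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Row-wise variance of a numeric matrix (denominator n - 1).
row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2L) stop("need at least 2 columns for a variance", call. = FALSE)
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (n - 1)
}

# Dirichlet draws: n vectors of concentration `alpha` (recycled to length k).
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

stop_input <- function(...) stop(..., call. = FALSE)

check_aligned <- function(beta, mat, what) {
  if (!identical(dim(beta), dim(mat)) ||
      !identical(rownames(beta), rownames(mat)) ||
      !identical(colnames(beta), colnames(mat))) {
    stop_input("matrix `", what, "` is not aligned with the beta matrix ",
               "(same probes and samples in the same order required)")
  }
  invisible(TRUE)
}

# Fixed-format numeric rendering used by all table writers: 6 significant
# digits, p/q-like columns in 3-digit scientific notation.
format_num <- function(x, scientific = FALSE) {
  if (scientific) formatC(x, format = "e", digits = 3)
  else formatC(x, format = "g", digits = 6)
}
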