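# Internal helpers shared across modules.

# Stage offsets for deriving child seeds from the master seed.  Keeping the
# offsets fixed (rather than consuming one stream sequentially) means a stage
# can be re-run in isolation and still see the same draws.
.seed_offsets <- c(
  population = 0L, phenotype = 1L, layout = 2L, homolog = 3L,
  hits = 4L, dropout = 5L, snp = 6L
)

.child_seed <- function(seed, stage) {
  stopifnot(stage %in% names(.seed_offsets))
  (as.integer(seed) + .seed_offsets[[stage]]) %% .Machine$integer.max
}

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  expr
}

.assert_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != floor(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

.assert_prob <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single value in [0, 1]", name), call. = FALSE)
  }
  invisible(as.numeric(x))
}

.assert_binary_matrix <- function(m, name = "matrix") {
  if (!is.matrix(m) || !all(m %in% c(0L, 1L))) {
    stop(sprintf("`%s` must be a binary (0/1) matrix", name), call. = FALSE)
  }
  invisible(m)
}

# Dirichlet draws via independent gammas.
.rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = alpha, rate = 1), nrow = n,
              ncol = k, byrow = TRUE)
  zero <- rowSums(g) == 0  # all gammas underflowed (tiny alpha): one-hot row
  if (any(zero)) {
    g[zero, ] <- t(stats::rmultinom(sum(zero), 1L, rep(1, k)))
  }
  g / rowSums(g)
}

# Balding-Nichols subpopulation frequencies around an ancestral frequency p
# with differentiation F; F = 0 returns p unchanged.
.balding_nichols <- function(p, f) {
  if (f <= 0) return(p)
  p <- pmin(1 - 1e-6, pmax(1e-6, p))  # guard Beta shapes against underflow
  a <- p * (1 - f) / f
  b <- (1 - p) * (1 - f) / f
  out <- stats::rbeta(length(p), a, b)
  bad <- !is.finite(out)
  out[bad] <- p[bad]
  out
}
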