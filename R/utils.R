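# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. `seed = NULL` means "use the current stream".
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic derived seeds so one user seed drives many independent
# draws; arithmetic in doubles (exact below 2^53) to avoid integer overflow.
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.numeric(seed) * 69069 + as.numeric(k) * 1013) %% 2147483587
}

# Truncated-normal diameters: mean `mu` (nm), coefficient of variation `cv`,
# redrawing non-positive values (truncation at zero).
rdiameter <- function(n, mu, cv) {
  stopifnot(mu > 0, cv >= 0, n >= 0)
  if (n == 0L) return(numeric(0))
  if (cv == 0) return(rep(mu, n))
  d <- stats::rnorm(n, mu, cv * mu)
  bad <- which(d <= 0)
  while (length(bad)) {
    d[bad] <- stats::rnorm(length(bad), mu, cv * mu)
    bad <- bad[d[bad] <= 0]
  }
  d
}

# Log-spaced histogram edges covering [lo, hi] at `n_per_decade` bins per
# decade, snapped outward to the bin lattice anchored at 1.
log_edges <- function(lo, hi, n_per_decade = 24) {
  stopifnot(lo > 0, hi >= lo, n_per_decade >= 1)
  i0 <- floor(log10(lo) * n_per_decade)
  i1 <- ceiling(log10(hi) * n_per_decade)
  if (i1 == i0) i1 <- i0 + 1
  10^(seq(i0, i1) / n_per_decade)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Boltzmann constant, J/K
.kB <- 1.380649e-23
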