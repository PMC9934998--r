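# Internal numerical helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` with a temporary RNG state seeded at `seed`; the caller's
# stream is restored afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Moving average with shrinking windows at the edges (no NA padding).
smooth_ma <- function(x, k) {
  k <- as.integer(k)
  if (k <= 1L) return(x)
  n <- length(x)
  half <- k %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Centered finite difference; one-sided at the ends. dt in ms.
cderiv <- function(x, dt) {
  n <- length(x)
  if (n < 3L) return(rep(0, n))
  d <- numeric(n)
  d[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / (2 * dt)
  d[1L] <- (x[2L] - x[1L]) / dt
  d[n] <- (x[n] - x[n - 1L]) / dt
  d
}

# Half-up rounding (base round() is half-even); used for reported percents.
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

# Sub-sample refinement of a local extremum at index i by fitting a parabola
# through (i-1, i, i+1). Returns c(t, y). Skipped on plateaus/degenerate fits
# so that discrete earliest-tie-break semantics are preserved.
refine_peak <- function(t, y, i) {
  n <- length(y)
  if (i <= 1L || i >= n) return(c(t[i], y[i]))
  y1 <- y[i - 1L]; y2 <- y[i]; y3 <- y[i + 1L]
  den <- y1 - 2 * y2 + y3
  if (!is.finite(den) || abs(den) < 1e-12 * max(abs(c(y1, y2, y3)), 1e-300)) {
    return(c(t[i], y[i]))
  }
  delta <- 0.5 * (y1 - y3) / den
  delta <- max(-0.5, min(0.5, delta))
  dt <- t[i + 1L] - t[i]
  c(t[i] + delta * dt, y2 - 0.25 * (y1 - y3) * delta)
}

# Linear-interpolated time at which y crosses `level`, between samples j and
# j+1 (y[j] and y[j+1] must bracket the level).
interp_cross <- function(t, y, j, level) {
  if (j < 1L || j >= length(y)) return(t[max(1L, min(j, length(t)))])
  y0 <- y[j]; y1 <- y[j + 1L]
  if (!is.finite(y0) || !is.finite(y1) || y1 == y0) return(t[j])
  t[j] + (level - y0) / (y1 - y0) * (t[j + 1L] - t[j])
}

stop_if_not_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  invisible(x)
}
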