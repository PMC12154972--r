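# Independent oracles used across the test suite. These deliberately share
# no code with the implementation paths they check.

# Brute-force exact two-sided Mann-Whitney p: enumerate all C(n1+n2, n1)
# labelings of the pooled sample, compute U for each, and take
# min(1, 2 * min(P(U <= u), P(U >= u))) over the enumeration distribution.
brute_force_mw_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  u_of <- function(idx) {
    x <- pooled[idx]; y <- pooled[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2L, u_of)
  lo <- mean(us <= u_obs + 1e-9)
  hi <- mean(us >= u_obs - 1e-9)
  list(U = u_obs, p = min(1, 2 * min(lo, hi)))
}

# same enumeration for tie-free data, but U of each labeling is taken from
# the rank sums (valid without ties), which makes 200-sample sweeps cheap
brute_force_mw_p_tiefree <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  stopifnot(!any(duplicated(pooled)))
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  us <- colSums(matrix(rk[combs], nrow(combs))) - n1 * (n1 + 1) / 2
  lo <- mean(us <= u_obs + 1e-9)
  hi <- mean(us >= u_obs - 1e-9)
  list(U = u_obs, p = min(1, 2 * min(lo, hi)))
}

# Exhaustive 256-bin between-class-variance scan (Otsu criterion).
otsu_scan <- function(values, levels = 256L) {
  br <- seq(0, 1, length.out = levels + 1L)
  h <- hist(values, breaks = br, plot = FALSE)$counts
  mids <- (br[-1L] + br[-length(br)]) / 2
  best <- -Inf; best_t <- NA_real_
  for (k in seq_len(levels - 1L)) {
    w0 <- sum(h[1:k]); w1 <- sum(h[(k + 1L):levels])
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(h[1:k] * mids[1:k]) / w0
    m1 <- sum(h[(k + 1L):levels] * mids[(k + 1L):levels]) / w1
    v <- w0 * w1 * (m0 - m1)^2
    if (v > best) { best <- v; best_t <- br[k + 1L] }
  }
  best_t
}

# between-class variance achieved by a given threshold
otsu_objective <- function(values, t) {
  lo <- values[values <= t]; hi <- values[values > t]
  if (length(lo) == 0L || length(hi) == 0L) return(0)
  length(lo) * length(hi) * (mean(lo) - mean(hi))^2
}

# Arc length of y = A sin(2 pi x / lambda + phase) over [0, span] by
# adaptive quadrature, independent of the package's quadrature helpers.
sinusoid_arc_quadrature <- function(A, lambda, span, phase = 0) {
  k <- 2 * pi / lambda
  stats::integrate(function(x) sqrt(1 + (A * k * cos(k * x + phase))^2),
                   0, span, rel.tol = 1e-10, subdivisions = 500L)$value
}

# a plain straight horizontal dark ribbon on bright background
make_ribbon_image <- function(nr = 120L, nc = 200L, width_px = 20L,
                              pixel_size_nm = 10, dark = 0.2, bright = 0.85) {
  m <- matrix(bright, nr, nc)
  r0 <- (nr - width_px) %/% 2L + 1L
  m[r0:(r0 + width_px - 1L), ] <- dark
  list(image = calibrated_image(m, pixel_size_nm, "TEM"),
       center_row = r0 + (width_px - 1) / 2, width_px = width_px)
}
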