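# Independent oracles and fixture builders used across the suite. These
# deliberately avoid the package's own code paths: the smoother oracle is a
# naive dense solve built from base R difference matrices, and the peak
# oracle is an exhaustive triple-loop scan.

# Dense reference for the separable difference-penalised smoother.
dense_whittaker_smooth <- function(Y, lambda_user) {
  n <- nrow(Y)
  lam <- n / lambda_user
  E <- diag(n)
  D1 <- diff(E)
  D2 <- diff(E, differences = 2)
  A <- E + 2 * lam * t(D1) %*% D1 + lam^2 * t(D2) %*% D2
  Z <- solve(A, Y)
  t(solve(A, t(Z)))
}

# Exhaustive 8-neighbour local-maximum scan (no merging).
brute_force_peaks <- function(values, min_height) {
  n <- nrow(values); m <- ncol(values)
  hits <- NULL
  for (i in seq_len(n)) for (j in seq_len(m)) {
    v <- values[i, j]
    if (v < min_height) next
    ok <- TRUE
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      a <- i + di; b <- j + dj
      if (a >= 1 && a <= n && b >= 1 && b <= m && values[a, b] > v) {
        ok <- FALSE
      }
    }
    if (ok) hits <- rbind(hits, c(i, j))
  }
  hits
}

# Build a density_grid directly from a values matrix (for crafted surfaces
# that no series would produce).
fake_grid <- function(values, lo = 0, hi = 1, normalized = FALSE) {
  nb <- nrow(values)
  stopifnot(nb == ncol(values))
  edges <- seq(lo, hi, length.out = nb + 1L)
  structure(
    list(values = values, x_edges = edges, y_edges = edges,
         total_count = sum(values), max_count_m = max(values),
         normalized = normalized, n_out_of_range = 0L),
    class = "density_grid"
  )
}

# Normalised grid holding a 2D Gaussian bump (optionally two of them).
gaussian_grid <- function(nb = 60L, centers = 0.5, heights = 1,
                          sd = 0.08, lo = 0, hi = 1) {
  edges <- seq(lo, hi, length.out = nb + 1L)
  cx <- (edges[-1L] + edges[-(nb + 1L)]) / 2
  v <- matrix(0, nb, nb)
  for (k in seq_along(centers)) {
    g <- exp(-(cx - centers[k])^2 / (2 * sd^2))
    v <- v + heights[k] * outer(g, g)
  }
  fake_grid(v / max(v), lo, hi, normalized = TRUE)
}

# Series with one beat per second spanning exactly `span_sec` seconds.
metronome_series <- function(span_sec, rr = 1) {
  n <- ceiling(span_sec / rr) + 1L
  rr_series(onset_times = (seq_len(n) - 1L) * rr,
            intervals = rep(rr, n), label = "metronome")
}

expect_same_series <- function(a, b, tol = 1e-6) {
  expect_equal(a$intervals, b$intervals, tolerance = tol)
  expect_equal(a$onset_times, b$onset_times, tolerance = tol)
}
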