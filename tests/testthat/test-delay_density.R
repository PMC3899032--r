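# Delay pairs, 2D/1D histograms, max-normalisation, smoothing, shuffling.

test_that("delay pairs follow the lag construction and its edge cases", {
  s <- rr_series(intervals = c(0.5, 0.7, 0.9))
  p <- make_delay_pairs(s, lag = 1)
  expect_equal(p$x, c(0.5, 0.7))
  expect_equal(p$y, c(0.7, 0.9))
  # lag-consistency: x shifted by lag equals y
  s2 <- gen_iid(n_beats = 50, seed = 1)
  p2 <- make_delay_pairs(s2, lag = 3)
  expect_equal(p2$x[-(1:3)], p2$y[seq_len(length(p2$y) - 3)])
  expect_error(make_delay_pairs(rr_series(intervals = c(0.5, 0.6)), lag = 2),
               "more than lag")
  pc <- make_delay_pairs(rr_series(intervals = rep(0.7, 10)))
  expect_true(all(pc$x == pc$y))
})

test_that("2D histogram bins with half-open intervals and conserves mass", {
  s <- rr_series(intervals = rep(c(0.5, 0.5), 5))
  g <- compute_histogram2d(make_delay_pairs(s), nbins = 4, range = c(0, 1))
  expect_equal(sum(g$values), 9)
  expect_equal(sum(g$values > 0), 1)
  # interior edge -> upper bin: 0.5 is the edge between bins 2 and 3
  expect_equal(g$values[3, 3], 9)
  # value exactly at hi -> last bin
  s2 <- rr_series(intervals = rep(1, 5))
  g2 <- compute_histogram2d(make_delay_pairs(s2), nbins = 4, range = c(0, 1))
  expect_equal(g2$values[4, 4], 4)
  # conservation on random inputs, out-of-range pairs counted not binned
  withr::local_seed(1)
  for (i in 1:20) {
    si <- rr_series(intervals = runif(200, 0.2, 1.6))
    gi <- compute_histogram2d(make_delay_pairs(si), nbins = 17,
                              range = c(0.4, 1.2))
    expect_equal(sum(gi$values), gi$total_count)
    expect_equal(gi$total_count + gi$n_out_of_range, 199)
  }
  expect_error(compute_histogram2d(make_delay_pairs(s), nbins = 1), "nbins")
  expect_error(compute_histogram2d(make_delay_pairs(s), range = c(1, 1)),
               "lo < hi")
})

test_that("zero in-range pairs give an empty grid, not an error", {
  s <- rr_series(intervals = rep(2, 10))
  g <- compute_histogram2d(make_delay_pairs(s), nbins = 5, range = c(0, 1))
  expect_equal(g$total_count, 0)
  expect_true(all(g$values == 0))
  expect_equal(g$n_out_of_range, 9)
})

test_that("max-normalisation divides by the highest bin", {
  g <- fake_grid(matrix(c(2, 0, 4, 4), 2, 2))
  n <- normalize_to_unit_max(g)
  expect_equal(n$values, matrix(c(0.5, 0, 1, 1), 2, 2))
  expect_equal(n$max_count_m, 4)
  expect_true(n$normalized)
  expect_error(normalize_to_unit_max(n), "already")
  # all-zero grid: no division by zero
  z <- normalize_to_unit_max(fake_grid(matrix(0, 3, 3)))
  expect_true(all(z$values == 0) && z$normalized)
  # argmax is preserved
  withr::local_seed(2)
  for (i in 1:10) {
    v <- matrix(runif(64), 8, 8)
    expect_equal(which.max(normalize_to_unit_max(fake_grid(v))$values),
                 which.max(v))
  }
})

test_that("smoothing matches a dense solve, keeps constants and mass", {
  withr::local_seed(3)
  for (nb in c(5, 10, 20)) for (lu in c(5, 20, 100)) {
    v <- matrix(rpois(nb * nb, 3), nb, nb)
    sm <- smooth_density_2d(fake_grid(v), lambda_user = lu)
    expect_equal(sm$values, dense_whittaker_smooth(v, lu), tolerance = 1e-8)
    expect_lt(abs(sum(sm$values) - sum(v)) / sum(v), 1e-8)
  }
  const <- smooth_density_2d(fake_grid(matrix(2.5, 12, 12)))
  expect_equal(const$values, matrix(2.5, 12, 12), tolerance = 1e-10)
  expect_error(smooth_density_2d(fake_grid(matrix(1, 2, 2))), "nbins >= 3")
  expect_error(smooth_density_2d(fake_grid(matrix(1, 5, 5)), 0),
               "lambda_user")
})

test_that("an impulse is flattened more as the penalty grows", {
  v <- matrix(0, 21, 21); v[11, 11] <- 1
  heavy <- smooth_density_2d(fake_grid(v), lambda_user = 5)   # lam = nb/5
  light <- smooth_density_2d(fake_grid(v), lambda_user = 1e6) # lam ~ 0
  expect_lt(heavy$values[11, 11], 1)
  expect_gt(min(heavy$values[10:12, 10:12]), 0)
  expect_lt(heavy$values[11, 11], light$values[11, 11])
  expect_equal(light$values, v, tolerance = 1e-3)
})

test_that("the map pipeline composes its stages and is deterministic", {
  s <- gen_bistable(bistable_spec(n_beats = 2000, seed = 5))
  rng <- default_range(s$intervals)
  m <- compute_density_map(s, nbins = 50, range = rng)
  expect_equal(max(m$values), 1)
  manual <- normalize_to_unit_max(
    compute_histogram2d(make_delay_pairs(s), nbins = 50, range = rng))
  m_raw <- compute_density_map(s, nbins = 50, range = rng, smooth = FALSE)
  expect_identical(m_raw$values, manual$values)
  expect_identical(compute_density_map(s, nbins = 50, range = rng), m)
})

test_that("shuffling permutes the interval multiset exactly", {
  s <- gen_bistable(bistable_spec(n_beats = 3000, seed = 6))
  sh <- shuffle_intervals(s, seed = 10)
  expect_identical(sort(sh$intervals), sort(s$intervals))
  expect_identical(shuffle_intervals(s, seed = 10), sh)
  expect_false(identical(sh$intervals, s$intervals))
  # 1D histograms are exactly equal under shuffling
  rng <- default_range(s$intervals)
  expect_identical(as.integer(histogram1d(s, 40, rng)),
                   as.integer(histogram1d(sh, 40, rng)))
  expect_error(shuffle_intervals(rr_series(intervals = 0.8)), "2 beats")
})

test_that("a 2-beat shuffle hits both permutations about equally often", {
  s <- rr_series(intervals = c(0.5, 0.9))
  first <- vapply(1:1000, function(k) shuffle_intervals(s, seed = k)$intervals[1],
                  0)
  expect_lt(abs(mean(first == 0.5) - 0.5), 0.05)
})

test_that("1D histogram conserves counts and handles out-of-range input", {
  withr::local_seed(7)
  for (i in 1:10) {
    s <- rr_series(intervals = runif(300, 0.2, 1.6))
    hs <- histogram1d(s, 23, range = c(0.4, 1.2))
    expect_equal(sum(hs) + attr(hs, "n_out_of_range"), 300)
  }
  out <- histogram1d(rr_series(intervals = rep(5, 10)), 8, range = c(0, 1))
  expect_true(all(out == 0))
})

test_that("transposing a map equals the map of the reversed series", {
  s <- gen_bistable(bistable_spec(n_beats = 2000, seed = 8))
  rng <- default_range(s$intervals)
  fwd <- compute_density_map(s, nbins = 40, range = rng, smooth = FALSE)
  rev_s <- rr_series(intervals = rev(s$intervals))
  bwd <- compute_density_map(rev_s, nbins = 40, range = rng, smooth = FALSE)
  expect_identical(t(fwd$values), bwd$values)
})

test_that("density grids export as readable plain text", {
  g <- compute_density_map(gen_iid(n_beats = 500, seed = 9), nbins = 10)
  f <- withr::local_tempfile(fileext = ".txt")
  write_density_grid(g, f)
  lines <- readLines(f)
  expect_match(lines[1], "^# nbins 10$")
  body <- do.call(rbind, lapply(lines[-(1:3)],
                                function(l) scan(text = l, quiet = TRUE)))
  expect_equal(body, g$values, tolerance = 1e-7)
})
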