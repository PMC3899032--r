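# States (local density maxima), separating minima, occupancy and the map
# divergence statistic.

test_that("peak detection agrees with an exhaustive neighbour scan", {
  withr::local_seed(1)
  for (i in 1:8) {
    nb <- sample(5:50, 1)
    v <- matrix(runif(nb * nb), nb, nb)
    v <- v / max(v)
    g <- fake_grid(v, normalized = TRUE)
    got <- find_density_maxima(g, min_height = 0.3, min_separation = 0)
    want <- brute_force_peaks(v, 0.3)
    expect_setequal(paste(got$row, got$col), paste(want[, 1], want[, 2]))
    expect_true(all(diff(got$height) <= 0))
    expect_equal(got$height, v[cbind(got$row, got$col)])
  }
})

test_that("a single Gaussian bump yields one peak at its mode", {
  g <- gaussian_grid(nb = 60, centers = 0.5)
  p <- find_density_maxima(g)
  expect_equal(nrow(p), 1)
  bw <- diff(g$x_edges[1:2])
  expect_lt(abs(p$x_center - 0.5), 1.5 * bw)
})

test_that("a flat plateau reports only its lowest-index bin", {
  v <- matrix(0, 9, 9)
  v[4:6, 4:6] <- 1
  p <- find_density_maxima(fake_grid(v, normalized = TRUE),
                           min_separation = 0)
  expect_equal(nrow(p), 1)
  expect_equal(c(p$row, p$col), c(4, 4))
})

test_that("nearby peaks merge keeping the higher one", {
  g <- gaussian_grid(nb = 80, centers = c(0.48, 0.52), heights = c(1, 0.8),
                     sd = 0.02)
  merged <- find_density_maxima(g, min_separation = 0.1)
  expect_equal(nrow(merged), 1)
  expect_lt(abs(merged$x_center - 0.48), 0.02)
  split <- find_density_maxima(g, min_separation = 0.01)
  expect_equal(nrow(split), 2)
})

test_that("empty and invalid inputs are handled", {
  empty <- normalize_to_unit_max(fake_grid(matrix(0, 5, 5)))
  expect_equal(nrow(find_density_maxima(empty)), 0)
  g <- gaussian_grid()
  expect_error(find_density_maxima(fake_grid(matrix(1, 3, 3))),
               "normalized")
  expect_error(find_density_maxima(g, min_height = 0), "min_height")
  expect_error(find_density_maxima(g, min_separation = -1),
               "min_separation")
})

test_that("the separating minimum lies between two symmetric states", {
  g <- gaussian_grid(nb = 110, centers = c(0.65, 1.0), heights = c(1, 1),
                     sd = 0.05, lo = 0.3, hi = 1.4)
  p <- find_density_maxima(g)
  expect_equal(nrow(p), 2)
  b <- find_separating_minimum(g, p[1, ], p[2, ])
  expect_lt(abs(b - 0.825), 1.5 * diff(g$x_edges[1:2]))
})

test_that("the separating minimum is always strictly interior", {
  withr::local_seed(2)
  for (i in 1:100) {
    c1 <- runif(1, 0.2, 0.45); c2 <- runif(1, 0.55, 0.8)
    g <- gaussian_grid(nb = 60, centers = c(c1, c2),
                       heights = c(1, runif(1, 0.3, 1)),
                       sd = runif(1, 0.03, 0.07))
    p <- find_density_maxima(g, min_height = 0.1, min_separation = 0.05)
    p <- p[order(p$x_center), ]
    if (nrow(p) < 2) next
    b <- find_separating_minimum(g, p[1, ], p[2, ])
    expect_gt(b, p$x_center[1])
    expect_lt(b, p$x_center[2])
  }
  g <- gaussian_grid()
  p <- find_density_maxima(g)
  expect_error(find_separating_minimum(g, p[1, ], p[1, ]), "same bin")
})

test_that("occupancy partitions beats and weights slow beats by duration", {
  s <- rr_series(intervals = c(0.5, 0.5, 0.5, 1.0, 1.0))
  sp <- state_occupancy(s, 0.75)
  expect_equal(sum(sp$occupancy), 1)
  expect_equal(sp$occupancy, c(0.6, 0.4))
  expect_equal(sp$occupancy_duration, c(1.5, 2.0) / 3.5)
  expect_equal(sum(unlist(sp$dwell_times)), sum(s$intervals))
  low <- state_occupancy(rr_series(intervals = rep(0.5, 5)), 0.5)
  expect_equal(low$occupancy, c(0, 1))  # RR >= boundary is the slow state
  expect_error(state_occupancy(s, 2), "outside")
})

test_that("bistable occupancy matches the chain's stationary law", {
  spec <- bistable_spec(n_beats = 30000, seed = 3)
  s <- gen_bistable(spec)
  sp <- state_occupancy(s, 0.825)
  # symmetric chain: half the beats in each state; duration weighting
  # favours the slow (1.0 s) state by 1.0 / (0.65 + 1.0)
  expect_lt(abs(sp$occupancy[1] - 0.5), 0.1)
  expect_lt(abs(sp$occupancy_duration[2] - 1.0 / 1.65), 0.1)
  expect_gt(sp$occupancy_duration[2], sp$occupancy[2])
})

test_that("map divergence is a metric bounded by 2", {
  g <- compute_density_map(gen_iid(n_beats = 1000, seed = 4), nbins = 20)
  expect_equal(map_divergence(g, g), 0)
  a <- fake_grid(matrix(c(5, 0, 0, 0), 2, 2))
  b <- fake_grid(matrix(c(0, 0, 0, 3), 2, 2))
  expect_equal(map_divergence(a, b), 2)
  withr::local_seed(5)
  for (i in 1:10) {
    gs <- lapply(1:3, function(k) fake_grid(matrix(runif(25), 5, 5)))
    dab <- map_divergence(gs[[1]], gs[[2]])
    expect_equal(dab, map_divergence(gs[[2]], gs[[1]]))
    expect_lte(dab, map_divergence(gs[[1]], gs[[3]]) +
                    map_divergence(gs[[3]], gs[[2]]) + 1e-12)
  }
  wrong <- fake_grid(matrix(1, 5, 5), lo = 0.1, hi = 0.9)
  expect_error(map_divergence(fake_grid(matrix(1, 5, 5)), wrong),
               "mismatched")
})
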