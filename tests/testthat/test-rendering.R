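# Colourisation and composite frame rendering.

make_window <- function(seed = 1, n = 1200) {
  s <- gen_bistable(bistable_spec(n_beats = n, seed = seed))
  rng <- default_range(s$intervals)
  ws <- suppressMessages(iter_windows(s, window_spec(300, 150)))
  grids <- lapply(ws, function(w)
    compute_density_map(w$series, nbins = 60, range = rng))
  list(series = s, range = rng, windows = ws, grids = grids)
}

test_that("densities map linearly onto the jet colour table", {
  pal <- jet_colors(64)
  expect_equal(map_to_colour(0), pal[1])            # dark blue end
  expect_equal(map_to_colour(1), pal[64])           # dark red-brown end
  expect_equal(toupper(pal[1]), "#00008F")
  expect_equal(toupper(pal[64]), "#7F0000")
  h <- seq(0, 1, length.out = 101)
  pos <- match(map_to_colour(h), pal)
  expect_true(all(diff(pos) >= 0))                  # no reversals
  expect_warning(out <- map_to_colour(c(-0.2, 0.5, 1.3)), "clamped")
  expect_equal(out[c(1, 3)], pal[c(1, 64)])
  # equal h always means equal colour
  expect_equal(map_to_colour(rep(0.375, 5)), rep(map_to_colour(0.375), 5))
  expect_error(map_to_colour(0.5, "nope"), "unknown colormap")
})

test_that("frames render deterministically byte-for-byte", {
  fx <- make_window()
  cfg <- render_config(axis_range = fx$range, width_px = 280,
                       height_px = 360)
  f1 <- withr::local_tempfile(fileext = ".png")
  f2 <- withr::local_tempfile(fileext = ".png")
  render_frame(fx$windows[[1]], fx$grids[[1]], cfg, f1)
  render_frame(fx$windows[[1]], fx$grids[[1]], cfg, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("consecutive frames share fixed axes", {
  fx <- make_window()
  cfg <- render_config(axis_range = fx$range, width_px = 280,
                       height_px = 360)
  f1 <- withr::local_tempfile(fileext = ".png")
  f2 <- withr::local_tempfile(fileext = ".png")
  r1 <- render_frame(fx$windows[[1]], fx$grids[[1]], cfg, f1)
  r2 <- render_frame(fx$windows[[2]], fx$grids[[2]], cfg, f2)
  expect_identical(attr(r1, "axis_range"), attr(r2, "axis_range"))
  # the margin strip holding the axis annotation is pixel-identical even
  # though the data regions differ
  a <- png::readPNG(f1); b <- png::readPNG(f2)
  expect_identical(a[, 1:30, ], b[, 1:30, ])
  expect_false(identical(a, b))
})

test_that("contour-only frames drop the surface panel but keep geometry", {
  fx <- make_window()
  cfg <- render_config(axis_range = fx$range, width_px = 280,
                       height_px = 360)
  f3d <- withr::local_tempfile(fileext = ".png")
  f2d <- withr::local_tempfile(fileext = ".png")
  f2d_b <- withr::local_tempfile(fileext = ".png")
  render_frame(fx$windows[[1]], fx$grids[[1]], cfg, f3d)
  render_contour_only(fx$windows[[1]], fx$grids[[1]], cfg, f2d)
  render_contour_only(fx$windows[[1]], fx$grids[[1]], cfg, f2d_b)
  expect_identical(readBin(f2d, "raw", file.size(f2d)),
                   readBin(f2d_b, "raw", file.size(f2d_b)))
  expect_false(identical(readBin(f3d, "raw", file.size(f3d)),
                         readBin(f2d, "raw", file.size(f2d))))
})

test_that("contour levels are linear in density and bounded in count", {
  lv <- contour_levels(10)
  expect_length(lv, 10)
  expect_equal(diff(lv), rep(lv[2] - lv[1], 9))
  expect_true(all(lv > 0 & lv < 1))
  # a unimodal surface has at most one closed curve per level
  g <- gaussian_grid(nb = 60, centers = 0.5)
  cl <- grDevices::contourLines(bin_centers(g, "x"), bin_centers(g, "y"),
                                g$values, levels = contour_levels(10))
  expect_lte(length(cl), 10)
})

test_that("empty windows render without error", {
  fx <- make_window()
  empty_seg <- structure(
    list(t_start = 0, t_end = 300,
         series = rr_series(intervals = numeric(0)), index = 1L),
    class = "segment")
  empty_grid <- normalize_to_unit_max(
    compute_histogram2d(structure(list(x = double(), y = double(),
                                       lag = 1L), class = "delay_pairs"),
                        nbins = 30, range = fx$range))
  f <- withr::local_tempfile(fileext = ".png")
  expect_no_error(render_frame(empty_seg, empty_grid,
                               render_config(axis_range = fx$range,
                                             width_px = 240,
                                             height_px = 320), f))
  expect_true(file.size(f) > 0)
})

test_that("render configuration is validated", {
  expect_error(render_config(n_contour_levels = 1), "n_contour_levels")
  expect_error(render_config(colormap = "nope"), "unknown colormap")
})
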