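# Colourisation and per-window composite figures: 3D surface Poincare plot
# (top), colourised 2D contour map (middle), interbeat-interval time-series
# segment (bottom). All frames of one animation share axis limits so that
# states do not appear to drift.

# classic 9-anchor jet table (blue -> cyan -> yellow -> red), pinned here
# for cross-backend stability
JET_ANCHORS <- c("#00008F", "#0000FF", "#007FFF", "#00FFFF", "#7FFF7F",
                 "#FFFF00", "#FF7F00", "#FF0000", "#7F0000")

#' Jet colour ramp
#'
#' @param n Number of colours.
#' @return Character vector of `n` hex colours from dark blue (low density)
#'   to dark red-brown (high density).
#' @export
jet_colors <- function(n = 64L) {
  grDevices::colorRampPalette(JET_ANCHORS, space = "rgb")(n)
}

#' Map relative densities onto a colourmap
#'
#' Linear lookup of `h` values in `[0, 1]` into the named colourmap's
#' anchor table: `h = 0` maps to the first anchor (dark blue for jet),
#' `h = 1` to the last (dark red-brown). Out-of-range values are clamped
#' with a warning.
#'
#' @param h Numeric vector of relative densities.
#' @param colormap `"jet"` (default), `"viridis"` or `"gray"`.
#' @param n_colors Number of discrete colours in the lookup table.
#' @return Character vector of hex colours, one per `h`.
#' @export
map_to_colour <- function(h, colormap = "jet", n_colors = 64L) {
  if (any(h < 0 | h > 1, na.rm = TRUE)) {
    warning("map_to_colour: h values outside [0, 1] clamped")
    h <- pmin(pmax(h, 0), 1)
  }
  pal <- colormap_palette(colormap, n_colors)
  pal[pmin(floor(h * n_colors) + 1L, n_colors)]
}

colormap_palette <- function(colormap, n_colors) {
  switch(colormap,
         jet = jet_colors(n_colors),
         viridis = grDevices::hcl.colors(n_colors, "viridis"),
         gray = grDevices::gray.colors(n_colors, start = 0, end = 1),
         stop(sprintf("unknown colormap '%s'", colormap), call. = FALSE))
}

#' Rendering configuration
#'
#' @param colormap Colourmap name (default `"jet"`).
#' @param n_contour_levels Number of contour levels, linear in relative
#'   density over `[0, 1]` (>= 2; default 10).
#' @param n_colors Discrete colours in the density colour table (default
#'   64; a small table keeps exported GIF palettes exact).
#' @param width_px,height_px Frame size in pixels.
#' @param axis_range RR axis limits `(lo, hi)` in seconds, shared by every
#'   frame of an animation; `NULL` means derive from the data per call
#'   (only sensible for single figures).
#' @param surface Include the 3D surface panel? (`FALSE` gives the
#'   contour + time-series layout.)
#' @return A `render_config` list.
#' @export
render_config <- function(colormap = "jet", n_contour_levels = 10L,
                          n_colors = 64L, width_px = 480L, height_px = 640L,
                          axis_range = NULL, surface = TRUE) {
  if (n_contour_levels < 2L) {
    stop("render_config: n_contour_levels must be >= 2", call. = FALSE)
  }
  colormap_palette(colormap, 2L)  # validate the name early
  structure(list(colormap = colormap,
                 n_contour_levels = as.integer(n_contour_levels),
                 n_colors = as.integer(n_colors),
                 width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 axis_range = axis_range, surface = isTRUE(surface)),
            class = "render_config")
}

#' Contour levels used by the renderer
#'
#' Levels are equally spaced in relative density over (0, 1), excluding
#' both endpoints.
#'
#' @param n_levels Number of levels.
#' @return Numeric vector of `n_levels` density levels.
#' @export
contour_levels <- function(n_levels) {
  seq(0, 1, length.out = n_levels + 2L)[-c(1L, n_levels + 2L)]
}

draw_contour_panel <- function(grid, config) {
  cx <- bin_centers(grid, "x"); cy <- bin_centers(grid, "y")
  pal <- colormap_palette(config$colormap, config$n_colors)
  graphics::image(cx, cy, grid$values, zlim = c(0, 1), col = pal,
                  xlab = "RR(n) [s]", ylab = "RR(n+1) [s]",
                  useRaster = TRUE)
  if (max(grid$values) > 0) {
    graphics::contour(cx, cy, grid$values,
                      levels = contour_levels(config$n_contour_levels),
                      drawlabels = FALSE, add = TRUE,
                      col = "grey20", lwd = 0.5)
  }
  graphics::abline(0, 1, lty = 3, col = "grey40")
  graphics::box()
}

draw_surface_panel <- function(grid, config) {
  cx <- bin_centers(grid, "x"); cy <- bin_centers(grid, "y")
  v <- grid$values
  pal <- colormap_palette(config$colormap, config$n_colors)
  # facet colour = mean relative density of the facet's 4 corners
  nb <- nrow(v)
  fh <- (v[-1L, -1L] + v[-1L, -nb] + v[-nb, -1L] + v[-nb, -nb]) / 4
  fcol <- pal[pmin(floor(fh * config$n_colors) + 1L, config$n_colors)]
  graphics::persp(cx, cy, v, zlim = c(0, 1), col = fcol, border = NA,
                  theta = -37.5, phi = 30, expand = 0.6,
                  xlab = "RR(n)", ylab = "RR(n+1)", zlab = "h",
                  box = TRUE, ticktype = "simple", shade = NA)
}

draw_series_panel <- function(segment, config, width_sec) {
  s <- segment$series
  ylim <- config$axis_range
  if (is.null(ylim)) {
    ylim <- if (length(s) > 0L) default_range(s$intervals) else c(0, 2)
  }
  graphics::plot(NA, xlim = c(0, width_sec), ylim = ylim,
                 xlab = "time in window [s]", ylab = "RR [s]")
  if (length(s) > 0L) {
    graphics::lines(s$onset_times - segment$t_start, s$intervals,
                    col = "grey30")
    graphics::points(s$onset_times - segment$t_start, s$intervals,
                     pch = 20, cex = 0.3)
  } else {
    graphics::text(width_sec / 2, mean(ylim), "no beats in window",
                   col = "grey50")
  }
}

render_panels <- function(segment, grid, config, path) {
  grDevices::png(path, width = config$width_px, height = config$height_px,
                 type = "cairo", antialias = "none")
  on.exit(grDevices::dev.off())
  if (config$surface) {
    graphics::layout(matrix(1:3, ncol = 1L), heights = c(1.3, 1.2, 0.8))
  } else {
    graphics::layout(matrix(1:2, ncol = 1L), heights = c(1.4, 0.8))
  }
  graphics::par(mar = c(4, 4, 1, 1), cex = 0.8)
  cfg <- config
  if (is.null(cfg$axis_range)) {
    cfg$axis_range <- c(grid$x_edges[1L],
                        grid$x_edges[length(grid$x_edges)])
  }
  if (cfg$surface) {
    graphics::par(mar = c(1, 1, 1, 1))
    draw_surface_panel(grid, cfg)
    graphics::par(mar = c(4, 4, 1, 1))
  }
  draw_contour_panel(grid, cfg)
  if (length(segment$series) == 0L) {
    graphics::mtext("empty window", side = 3, line = -1.2, cex = 0.7,
                    col = "grey40")
  }
  draw_series_panel(segment, cfg, width_sec = segment$t_end - segment$t_start)
  invisible(path)
}

#' Render one window as a composite frame
#'
#' Writes a PNG with the full density-delay-map layout: colourised 3D
#' surface Poincare plot on top, colourised 2D contour map in the middle,
#' and the window's interbeat-interval series at the bottom. Rendering is
#' deterministic: identical inputs produce byte-identical files. An empty
#' window renders blank panels with a caption flag rather than erroring.
#'
#' @param segment A window from [iter_windows()].
#' @param grid The normalised `density_grid` of that window, computed on
#'   the shared full-record range.
#' @param config A [render_config()].
#' @param path Output PNG path.
#' @return The path, invisibly, with attribute `"axis_range"` (the RR
#'   limits actually used).
#' @export
render_frame <- function(segment, grid, config = render_config(), path) {
  stopifnot(inherits(segment, "segment"), inherits(grid, "density_grid"))
  cfg <- config
  cfg$surface <- TRUE
  render_panels(segment, grid, cfg, path)
  used <- if (is.null(config$axis_range))
    c(grid$x_edges[1L], grid$x_edges[length(grid$x_edges)])
  else config$axis_range
  invisible(structure(path, axis_range = used))
}

#' Render one window as a contour-only frame
#'
#' As [render_frame()] but without the surface panel: colourised 2D contour
#' map on top and the window's time series below.
#'
#' @inheritParams render_frame
#' @return The path, invisibly, with attribute `"axis_range"`.
#' @export
render_contour_only <- function(segment, grid, config = render_config(),
                                path) {
  stopifnot(inherits(segment, "segment"), inherits(grid, "density_grid"))
  cfg <- config
  cfg$surface <- FALSE
  render_panels(segment, grid, cfg, path)
  used <- if (is.null(config$axis_range))
    c(grid$x_edges[1L], grid$x_edges[length(grid$x_edges)])
  else config$axis_range
  invisible(structure(path, axis_range = used))
}
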