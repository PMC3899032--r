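# End-to-end driver: read -> window -> density per window -> render per
# window -> animate, with a machine-readable run summary.

#' Full run configuration
#'
#' Resolved settings for one end-to-end run. Precedence when building a
#' configuration from the command line is flag > config file > preset >
#' default; this constructor holds the fully resolved result.
#'
#' @param window A [window_spec()] (or the result of [window_preset()]).
#' @param nbins Bins per axis for the density maps.
#' @param range RR axis range in seconds, or `NULL` to use the 2% padded
#'   full-record range (computed once and shared by all windows).
#' @param lambda_user Smoothing parameter ([smooth_density_2d()]).
#' @param smooth Apply smoothing to each window's histogram?
#' @param lag Delay in beats.
#' @param colormap,n_contour_levels,width_px,height_px See
#'   [render_config()].
#' @param mode `"3d"` (surface + contour + series frames) or `"2d"`
#'   (contour + series).
#' @param fps Animation frame rate.
#' @param format Animation container: `"gif"` or `"avi"` (or `"mp4"` with
#'   ffmpeg available).
#' @param seed Seed for any randomised steps.
#' @return A `run_config` list.
#' @export
run_config <- function(window = window_spec(), nbins = 200L, range = NULL,
                       lambda_user = 20, smooth = TRUE, lag = 1L,
                       colormap = "jet", n_contour_levels = 10L,
                       width_px = 480L, height_px = 640L,
                       mode = c("3d", "2d"), fps = 10, format = "gif",
                       seed = 1L) {
  stopifnot(inherits(window, "window_spec"))
  structure(list(window = window, nbins = as.integer(nbins), range = range,
                 lambda_user = lambda_user, smooth = isTRUE(smooth),
                 lag = as.integer(lag), colormap = colormap,
                 n_contour_levels = as.integer(n_contour_levels),
                 width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 mode = match.arg(mode), fps = fps, format = format,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full density-delay-map pipeline
#'
#' Executes every stage on one series: windowing, per-window density maps
#' on the shared full-record axis range, frame rendering
#' (`frame_%05d.png`), and animation assembly. Also computes the
#' full-record map and its peak table for the run summary, which is written
#' as JSON next to the animation.
#'
#' @param series An [rr_series] (use [read_rr_ascii()] for files).
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param basename Stem for output files (default `"d3map"`).
#' @return A list with `animation` (path), `frames` (paths), `summary`
#'   (list) and `summary_path`, invisibly.
#' @export
run_pipeline <- function(series, config = run_config(), out_dir,
                         basename = "d3map") {
  stopifnot(inherits(series, "rr_series"), inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rng <- if (is.null(config$range)) default_range(series$intervals)
         else config$range
  windows <- iter_windows(series, config$window)
  rcfg <- render_config(colormap = config$colormap,
                        n_contour_levels = config$n_contour_levels,
                        n_colors = 64L,
                        width_px = config$width_px,
                        height_px = config$height_px,
                        axis_range = rng,
                        surface = config$mode == "3d")
  frame_dir <- file.path(out_dir, "frames")
  dir.create(frame_dir, showWarnings = FALSE)
  render_one <- if (config$mode == "3d") render_frame else render_contour_only
  pair_counts <- integer(length(windows))
  dropped <- integer(length(windows))
  frames <- character(length(windows))
  for (w in windows) {
    grid <- if (length(w$series) <= config$lag) {
      # silent window: too few beats for a delay pair -> empty grid
      normalize_to_unit_max(compute_histogram2d(
        structure(list(x = double(), y = double(), lag = config$lag),
                  class = "delay_pairs"),
        nbins = config$nbins, range = rng))
    } else {
      tryCatch(
        compute_density_map(w$series, nbins = config$nbins, range = rng,
                            lambda_user = config$lambda_user,
                            smooth = config$smooth, lag = config$lag),
        error = function(e) {
          stop(sprintf("run_pipeline: density stage failed at window %d: %s",
                       w$index, conditionMessage(e)), call. = FALSE)
        })
    }
    pair_counts[w$index] <- grid$total_count
    dropped[w$index] <- grid$n_out_of_range
    message(sprintf("window %d/%d: %d pairs binned, %d out of range",
                    w$index, length(windows), grid$total_count,
                    grid$n_out_of_range))
    frames[w$index] <- file.path(frame_dir,
                                 sprintf("frame_%05d.png", w$index))
    render_one(w, grid, rcfg, frames[w$index])
  }
  anim_path <- file.path(out_dir, paste0(basename, ".", config$format))
  write_animation(frames, fps = config$fps, path = anim_path,
                  format = config$format)
  full_map <- compute_density_map(series, nbins = config$nbins, range = rng,
                                  lambda_user = config$lambda_user,
                                  smooth = config$smooth, lag = config$lag)
  peaks <- find_density_maxima(full_map)
  summary <- list(
    label = series$label, n_beats = length(series),
    elapsed_sec = elapsed_time(series),
    window_width_sec = config$window$width_sec,
    window_shift_sec = config$window$shift_sec,
    n_windows = length(windows),
    nbins = config$nbins, range = rng, lambda_user = config$lambda_user,
    smooth = config$smooth, lag = config$lag, mode = config$mode,
    fps = config$fps, format = config$format, seed = config$seed,
    pairs_per_window = pair_counts, dropped_pairs = dropped,
    full_record_peaks = peaks)
  summary_path <- file.path(out_dir, paste0(basename, "_summary.json"))
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(animation = anim_path, frames = frames, summary = summary,
                 summary_path = summary_path))
}
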