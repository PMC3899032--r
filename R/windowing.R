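# Time-based segmentation of a series into overlapping windows. Windows are
# quoted in seconds (not beat counts) because RR series are irregularly
# sampled in beat number, and are anchored at the first beat's onset.

#' Moving-window specification
#'
#' @param width_sec Window width in seconds (> 0; default 500).
#' @param shift_sec Shift between consecutive windows in seconds
#'   (0 < shift <= width; default 10).
#' @return A `window_spec` list.
#' @export
window_spec <- function(width_sec = 500, shift_sec = 10) {
  if (!is.numeric(width_sec) || width_sec <= 0) {
    stop("window_spec: width_sec must be > 0", call. = FALSE)
  }
  if (!is.numeric(shift_sec) || shift_sec <= 0 || shift_sec > width_sec) {
    stop("window_spec: need 0 < shift_sec <= width_sec", call. = FALSE)
  }
  structure(list(width_sec = as.double(width_sec),
                 shift_sec = as.double(shift_sec)),
            class = "window_spec")
}

#' Built-in window presets
#'
#' `"sleep"` is a 500 s window shifted 10 s at a time (overnight recordings,
#' fine-grained state transitions); `"af"` is a 1200 s window shifted 300 s
#' (day-long atrial-fibrillation recordings).
#'
#' @param name `"sleep"` or `"af"`.
#' @return A [window_spec()].
#' @export
window_preset <- function(name = c("sleep", "af")) {
  switch(match.arg(name),
         sleep = window_spec(500, 10),
         af = window_spec(1200, 300))
}

#' Segment a series into overlapping windows
#'
#' Window `k` (k = 0, 1, ...) spans
#' `[t0 + k*shift, t0 + k*shift + width)` where `t0` is the first beat's
#' onset; a beat belongs to a window when its onset time falls in that
#' half-open interval. With total elapsed time `T` (span of onsets) there
#' are exactly `floor((T - width) / shift) + 1` windows; trailing data
#' shorter than one window is dropped (a message reports how much). Windows
#' that happen to contain no beats are kept, so downstream stages can render
#' silent frames. Delay pairs are formed within a segment only.
#'
#' @param series An [rr_series].
#' @param spec A [window_spec()] (or preset name via [window_preset()]).
#' @return A list of `segment` objects, each with `t_start`, `t_end`,
#'   `series` (the [rr_series] slice) and `index` (frame ordinal from 1).
#' @export
iter_windows <- function(series, spec = window_spec()) {
  stopifnot(inherits(series, "rr_series"), inherits(spec, "window_spec"))
  T_total <- elapsed_time(series)
  if (T_total < spec$width_sec) {
    stop(sprintf(
      "iter_windows: record spans %.1f s, shorter than the %.1f s window",
      T_total, spec$width_sec), call. = FALSE)
  }
  n_win <- floor((T_total - spec$width_sec) / spec$shift_sec) + 1
  t0 <- series$onset_times[1L]
  starts <- t0 + (seq_len(n_win) - 1) * spec$shift_sec
  tail_sec <- T_total - (starts[n_win] - t0 + spec$width_sec)
  if (tail_sec > 0) {
    message(sprintf("iter_windows: dropping trailing %.1f s (< one window)",
                    tail_sec))
  }
  ot <- series$onset_times
  lapply(seq_len(n_win), function(k) {
    a <- starts[k]; b <- a + spec$width_sec
    sel <- ot >= a & ot < b
    structure(
      list(t_start = a, t_end = b,
           series = rr_series(onset_times = ot[sel],
                              intervals = series$intervals[sel],
                              label = sprintf("%s [%0.0f-%0.0f s]",
                                              series$label, a, b)),
           index = k),
      class = "segment"
    )
  })
}

#' @export
print.segment <- function(x, ...) {
  cat(sprintf("<segment #%d> [%.1f, %.1f) s, %d beats\n",
              x$index, x$t_start, x$t_end, length(x$series)))
  invisible(x)
}
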