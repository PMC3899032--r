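#' RR-interval time series
#'
#' An `rr_series` holds an ordered sequence of cardiac interbeat (RR)
#' intervals together with the onset time of each beat, both in seconds.
#' It is the basic container consumed by every other function in the
#' package.
#'
#' @param onset_times Numeric vector of per-beat onset times in seconds,
#'   non-decreasing. If `NULL`, onset times are reconstructed by cumulative
#'   summation of the intervals starting at 0 (the onset of beat `n` is the
#'   sum of the first `n - 1` intervals).
#' @param intervals Numeric vector of RR intervals in seconds, one per beat;
#'   all strictly positive.
#' @param label Free-text identifier carried through windowing and reporting.
#'
#' @return An object of class `rr_series`: a list with elements
#'   `onset_times`, `intervals` and `label`.
#'
#' @examples
#' s <- rr_series(intervals = c(0.8, 0.9, 0.7))
#' s$onset_times  # 0.0 0.8 1.7
#' @export
rr_series <- function(onset_times = NULL, intervals, label = "") {
  intervals <- as.double(intervals)
  if (anyNA(intervals)) {
    stop("rr_series: intervals contain missing values", call. = FALSE)
  }
  if (length(intervals) > 0L && any(intervals <= 0)) {
    stop("rr_series: all RR intervals must be > 0 seconds", call. = FALSE)
  }
  if (is.null(onset_times)) {
    onset_times <- cumsum(c(0, intervals))[seq_along(intervals)]
  } else {
    onset_times <- as.double(onset_times)
    if (length(onset_times) != length(intervals)) {
      stop("rr_series: onset_times and intervals must have equal length",
           call. = FALSE)
    }
    if (length(onset_times) > 1L && any(diff(onset_times) < 0)) {
      stop("rr_series: onset_times must be non-decreasing", call. = FALSE)
    }
  }
  structure(
    list(onset_times = onset_times, intervals = intervals,
         label = as.character(label)[1L]),
    class = "rr_series"
  )
}

#' @export
length.rr_series <- function(x) length(x$intervals)

#' @export
print.rr_series <- function(x, ...) {
  n <- length(x)
  cat(sprintf("<rr_series> %s: %d beats",
              if (nzchar(x$label)) x$label else "(unlabelled)", n))
  if (n > 0L) {
    cat(sprintf(", %.1f s elapsed, RR in [%.3f, %.3f] s",
                diff(range(x$onset_times)),
                min(x$intervals), max(x$intervals)))
  }
  cat("\n")
  invisible(x)
}

#' Total elapsed time of a series
#'
#' The span of beat onsets, `max(onset_times) - min(onset_times)`, in
#' seconds. This is the duration used by [iter_windows()] to count windows.
#'
#' @param series An [rr_series].
#' @return Elapsed time in seconds (0 for series with fewer than 2 beats).
#' @export
elapsed_time <- function(series) {
  stopifnot(inherits(series, "rr_series"))
  if (length(series) < 2L) return(0)
  diff(range(series$onset_times))
}

#' Read an RR-interval series from a plain-ASCII file
#'
#' Reads whitespace-delimited ASCII beat tables as distributed with
#' PhysioNet-derived RR exports: either two columns (beat time or index,
#' RR interval in seconds) or a single column of RR intervals. Lines whose
#' first non-blank character is `#` are skipped. Intervals always come from
#' the RR column; onset times are recomputed from the cumulative sum of the
#' intervals, so the series is internally consistent regardless of whether
#' column 1 held elapsed time or a beat index (the analysis only ever uses
#' elapsed time).
#'
#' @param path Path to the file.
#' @param column_layout `"two_column_time_rr"` (default; RR is column 2) or
#'   `"one_column_rr"` (RR is column 1).
#' @param ms If `TRUE`, input values are in milliseconds and are divided by
#'   1000.
#' @param label Series label; defaults to the file name.
#'
#' @return An [rr_series].
#' @export
read_rr_ascii <- function(path,
                          column_layout = c("two_column_time_rr",
                                            "one_column_rr"),
                          ms = FALSE, label = basename(path)) {
  column_layout <- match.arg(column_layout)
  if (!file.exists(path)) {
    stop(sprintf("read_rr_ascii: file not found: '%s'", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) < 2L) {
    stop("read_rr_ascii: fewer than 2 beats in file", call. = FALSE)
  }
  fields <- strsplit(trimws(lines), "\\s+")
  ncol_needed <- if (column_layout == "two_column_time_rr") 2L else 1L
  vals <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) < ncol_needed) {
      stop(sprintf("read_rr_ascii: line %d has %d column(s), need %d",
                   lineno[i], length(f), ncol_needed), call. = FALSE)
    }
    v <- suppressWarnings(as.double(f[seq_len(ncol_needed)]))
    if (anyNA(v)) {
      stop(sprintf("read_rr_ascii: non-numeric value on line %d", lineno[i]),
           call. = FALSE)
    }
    v
  })
  m <- do.call(rbind, vals)
  rr <- m[, ncol_needed]
  if (ms) rr <- rr / 1000
  if (any(rr <= 0)) {
    bad <- lineno[which(rr <= 0)[1L]]
    stop(sprintf("read_rr_ascii: non-positive RR interval on line %d", bad),
         call. = FALSE)
  }
  rr_series(intervals = rr, label = label)
}

#' Write an RR-interval series to a plain-ASCII file
#'
#' Writes the two-column (onset time, RR interval) whitespace-delimited
#' layout read by [read_rr_ascii()], with 6 decimal places and no header.
#'
#' @param series An [rr_series] with at least one beat.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_rr_ascii <- function(series, path) {
  stopifnot(inherits(series, "rr_series"))
  if (length(series) < 1L) {
    stop("write_rr_ascii: empty series", call. = FALSE)
  }
  txt <- sprintf("%.6f %.6f", series$onset_times, series$intervals)
  ok <- tryCatch({ writeLines(txt, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) {
    stop(sprintf("write_rr_ascii: cannot write '%s'", path), call. = FALSE)
  }
  invisible(path)
}
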