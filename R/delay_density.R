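# Lag-k delay pairs and binned 2D density surfaces: the mathematical core
# of the density delay map.

#' Lag-k delay pairs of an RR series
#'
#' Builds the point set of a Poincare (return) map: `x = RR(n)` against
#' `y = RR(n + lag)`, in beat order.
#'
#' @param series An [rr_series] with more than `lag` beats.
#' @param lag Delay in beats (default 1).
#' @return A `delay_pairs` list with numeric `x`, `y` (each of length
#'   `N - lag`) and the `lag` used.
#' @export
make_delay_pairs <- function(series, lag = 1L) {
  stopifnot(inherits(series, "rr_series"))
  lag <- as.integer(lag)
  if (lag < 1L) stop("make_delay_pairs: lag must be >= 1", call. = FALSE)
  n <- length(series)
  if (n <= lag) {
    stop(sprintf("make_delay_pairs: need more than lag=%d beats, have %d",
                 lag, n), call. = FALSE)
  }
  rr <- series$intervals
  structure(
    list(x = rr[seq_len(n - lag)], y = rr[seq.int(lag + 1L, n)], lag = lag),
    class = "delay_pairs"
  )
}

#' @export
length.delay_pairs <- function(x) length(x$x)

bin_index <- function(v, edges) {
  # half-open [e_i, e_{i+1}) bins, last bin closed at the upper range limit
  findInterval(v, edges, rightmost.closed = TRUE)
}

new_density_grid <- function(values, x_edges, y_edges, total_count,
                             max_count_m, normalized, n_out_of_range) {
  structure(
    list(values = values, x_edges = x_edges, y_edges = y_edges,
         total_count = total_count, max_count_m = max_count_m,
         normalized = normalized, n_out_of_range = n_out_of_range),
    class = "density_grid"
  )
}

#' @export
print.density_grid <- function(x, ...) {
  nb <- nrow(x$values)
  cat(sprintf(
    "<density_grid> %dx%d bins on [%.3f, %.3f] s, %d pairs binned%s%s\n",
    nb, nb, x$x_edges[1L], x$x_edges[nb + 1L], x$total_count,
    if (x$n_out_of_range > 0)
      sprintf(" (%d out of range)", x$n_out_of_range) else "",
    if (x$normalized) ", max-normalized" else ""))
  invisible(x)
}

#' Bin centres of a density grid axis
#' @param grid A `density_grid`.
#' @param axis `"x"` or `"y"`.
#' @return Numeric vector of bin-centre coordinates in seconds.
#' @export
bin_centers <- function(grid, axis = c("x", "y")) {
  axis <- match.arg(axis)
  e <- if (axis == "x") grid$x_edges else grid$y_edges
  (e[-length(e)] + e[-1L]) / 2
}

#' Unnormalised 2D histogram of delay pairs
#'
#' Bins delay pairs on a uniform `nbins` x `nbins` grid over `range` on both
#' axes. Bins are half-open `[e_i, e_{i+1})` with the last bin closed, so a
#' pair exactly on an interior edge falls in the upper bin and a pair at the
#' upper range limit falls in the last bin. Pairs outside the range are
#' dropped and counted in `n_out_of_range`. `values[i, j]` counts pairs with
#' `x` in bin `i` and `y` in bin `j`.
#'
#' A grid with zero in-range pairs is returned with all-zero values (an
#' "empty grid"), not an error, so that silent windows of an animation can
#' be rendered blank.
#'
#' @param pairs A [make_delay_pairs()] result.
#' @param nbins Number of bins per axis (>= 2; default 200).
#' @param range Length-2 numeric `(lo, hi)` in seconds, `lo < hi`.
#' @return An unnormalised `density_grid`.
#' @export
compute_histogram2d <- function(pairs, nbins = 200L, range = NULL) {
  stopifnot(inherits(pairs, "delay_pairs"))
  nbins <- as.integer(nbins)
  if (nbins < 2L) stop("compute_histogram2d: nbins must be >= 2",
                       call. = FALSE)
  if (is.null(range)) range <- default_range(c(pairs$x, pairs$y))
  lo <- range[1L]; hi <- range[2L]
  if (!(lo < hi)) stop("compute_histogram2d: need range lo < hi",
                       call. = FALSE)
  edges <- seq(lo, hi, length.out = nbins + 1L)
  ix <- bin_index(pairs$x, edges)
  iy <- bin_index(pairs$y, edges)
  ok <- ix >= 1L & ix <= nbins & iy >= 1L & iy <= nbins
  counts <- matrix(0, nbins, nbins)
  if (any(ok)) {
    tab <- tabulate((iy[ok] - 1L) * nbins + ix[ok], nbins * nbins)
    counts[] <- tab
  }
  new_density_grid(counts, edges, edges,
                   total_count = sum(ok), max_count_m = max(counts),
                   normalized = FALSE, n_out_of_range = sum(!ok))
}

#' Default axis range for a record
#'
#' `[min, max]` of the values, padded by 2% of the span on each side. One
#' full-record range is meant to be computed once and shared by every window
#' of an animation so that frames are comparable.
#'
#' @param values Numeric vector (e.g. the full record's intervals).
#' @return Length-2 numeric range in seconds.
#' @export
default_range <- function(values) {
  r <- range(values)
  pad <- 0.02 * diff(r)
  if (pad == 0) pad <- max(0.01, 0.02 * abs(r[1L]))
  c(r[1L] - pad, r[2L] + pad)
}

#' Max-normalise a density grid
#'
#' Divides every bin by the value of the highest bin, mapping the surface
#' onto `[0, 1]` (a relative occupancy of the delay phase space, not a
#' probability density). An all-zero grid is returned unchanged with the
#' normalised flag set. Normalising twice is an error.
#'
#' @param grid An unnormalised `density_grid`.
#' @return The grid with `values` scaled so `max(values) == 1` (when any
#'   pair was binned) and `normalized = TRUE`; `max_count_m` records the
#'   pre-normalisation maximum.
#' @export
normalize_to_unit_max <- function(grid) {
  stopifnot(inherits(grid, "density_grid"))
  if (grid$normalized) {
    stop("normalize_to_unit_max: grid is already normalized", call. = FALSE)
  }
  m <- max(grid$values)
  grid$max_count_m <- m
  if (m > 0) grid$values <- grid$values / m
  grid$normalized <- TRUE
  grid
}

# Penalised-least-squares (Whittaker-type) smoothing matrix for one axis:
# solve (I + 2*lam*D1'D1 + lam^2*D2'D2) z = y. Both penalties annihilate
# constants, and their columns sum to zero, so column sums of y are
# preserved exactly.
whittaker_operator <- function(n, lam) {
  D1 <- Matrix::bandSparse(n - 1L, n, k = 0:1,
                           diagonals = list(rep(-1, n - 1L), rep(1, n - 1L)))
  D2 <- Matrix::bandSparse(n - 2L, n, k = 0:2,
                           diagonals = list(rep(1, n - 2L), rep(-2, n - 2L),
                                            rep(1, n - 2L)))
  Matrix::Diagonal(n) + 2 * lam * Matrix::crossprod(D1) +
    lam^2 * Matrix::crossprod(D2)
}

# Cache of Cholesky factorizations keyed by (n, lam): the same operator is
# reused for every window of an animation and every resampling replicate.
.whittaker_cache <- new.env(parent = emptyenv())

whittaker_factor <- function(n, lam) {
  key <- sprintf("%d_%.12g", n, lam)
  f <- .whittaker_cache[[key]]
  if (is.null(f)) {
    A <- Matrix::forceSymmetric(whittaker_operator(n, lam))
    f <- Matrix::Cholesky(A, LDL = FALSE)
    .whittaker_cache[[key]] <- f
  }
  f
}

#' Smooth a density grid by penalised least squares
#'
#' Separable Whittaker-type smoothing with combined first- and
#' second-difference penalties: each column of the grid is replaced by the
#' solution of `(I + 2*lambda*D1'D1 + lambda^2*D2'D2) z = y`, then the same
#' smoother is applied to the rows of the result. The effective penalty is
#' `lambda = nbins / lambda_user`; this is the grid smoother used by
#' density-coloured scatter plots in flow cytometry, with the same default
#' user parameter (20). Constant surfaces pass through unchanged and total
#' mass is conserved (the penalty matrices have zero column sums).
#'
#' @param grid A `density_grid` (normalised or not) with `nbins >= 3`.
#' @param lambda_user Positive user smoothing parameter; larger values
#'   smooth less (default 20).
#' @return The grid with smoothed `values`.
#' @export
smooth_density_2d <- function(grid, lambda_user = 20) {
  stopifnot(inherits(grid, "density_grid"))
  if (!is.numeric(lambda_user) || lambda_user <= 0) {
    stop("smooth_density_2d: lambda_user must be > 0", call. = FALSE)
  }
  n <- nrow(grid$values)
  if (n < 3L) {
    stop("smooth_density_2d: need nbins >= 3 for second differences",
         call. = FALSE)
  }
  lam <- n / lambda_user
  f <- whittaker_factor(n, lam)
  Z <- Matrix::solve(f, grid$values)          # smooth columns
  Z <- Matrix::t(Matrix::solve(f, Matrix::t(Z)))  # then rows
  grid$values <- as.matrix(Z)
  dimnames(grid$values) <- NULL
  grid
}

#' Compute a density delay map for a series or segment
#'
#' The full per-segment pipeline: build lag-`lag` delay pairs, bin them on a
#' shared grid, optionally smooth the raw counts, then max-normalise so the
#' final surface has maximum exactly 1 (smoothing precedes normalisation).
#'
#' @param series An [rr_series] (typically one window's segment).
#' @param nbins Bins per axis (default 200).
#' @param range Shared axis range `(lo, hi)` in seconds; defaults to the 2%
#'   padded range of this series (pass the full-record range when mapping
#'   windows).
#' @param lambda_user Smoothing parameter, see [smooth_density_2d()].
#' @param smooth Apply smoothing? Default `TRUE`.
#' @param lag Delay in beats (default 1).
#' @return A normalised `density_grid`.
#' @export
compute_density_map <- function(series, nbins = 200L, range = NULL,
                                lambda_user = 20, smooth = TRUE, lag = 1L) {
  pairs <- make_delay_pairs(series, lag = lag)
  grid <- compute_histogram2d(pairs, nbins = nbins, range = range)
  if (smooth) grid <- smooth_density_2d(grid, lambda_user = lambda_user)
  normalize_to_unit_max(grid)
}

#' Shuffle the order of RR intervals
#'
#' Applies a uniform random permutation to the intervals and recomputes
#' onset times from their cumulative sum. The multiset of intervals — and
#' hence the 1D histogram — is exactly preserved, while serial correlations
#' are destroyed, which is what makes the delay map (unlike the histogram)
#' sensitive to temporal structure.
#'
#' @param series An [rr_series] with at least 2 beats.
#' @param seed Integer seed for the permutation.
#' @return A shuffled [rr_series].
#' @export
shuffle_intervals <- function(series, seed = 1L) {
  stopifnot(inherits(series, "rr_series"))
  n <- length(series)
  if (n < 2L) stop("shuffle_intervals: need at least 2 beats", call. = FALSE)
  perm <- with_seed(seed, sample.int(n))
  rr_series(intervals = series$intervals[perm],
            label = paste0(series$label, " [shuffled]"))
}

#' 1D histogram of RR intervals
#'
#' Same binning convention as [compute_histogram2d()], on one axis.
#'
#' @param series An [rr_series].
#' @param nbins Number of bins (>= 2).
#' @param range Length-2 `(lo, hi)` in seconds; defaults to the padded
#'   range of the series.
#' @return Integer vector of counts, with attributes `edges` and
#'   `n_out_of_range`.
#' @export
histogram1d <- function(series, nbins = 200L, range = NULL) {
  stopifnot(inherits(series, "rr_series"))
  nbins <- as.integer(nbins)
  if (nbins < 2L) stop("histogram1d: nbins must be >= 2", call. = FALSE)
  if (is.null(range)) range <- default_range(series$intervals)
  if (!(range[1L] < range[2L])) {
    stop("histogram1d: need range lo < hi", call. = FALSE)
  }
  edges <- seq(range[1L], range[2L], length.out = nbins + 1L)
  idx <- bin_index(series$intervals, edges)
  ok <- idx >= 1L & idx <= nbins
  counts <- tabulate(idx[ok], nbins)
  structure(counts, edges = edges, n_out_of_range = sum(!ok))
}

#' Export a density grid as plain text
#'
#' Writes a whitespace-delimited matrix preceded by a 3-line header
#' (`# nbins`, `# x-range`, `# y-range`), readable by any numeric text
#' parser.
#'
#' @param grid A `density_grid`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_density_grid <- function(grid, path) {
  stopifnot(inherits(grid, "density_grid"))
  nb <- nrow(grid$values)
  hdr <- c(sprintf("# nbins %d", nb),
           sprintf("# x-range %.9g %.9g", grid$x_edges[1L],
                   grid$x_edges[nb + 1L]),
           sprintf("# y-range %.9g %.9g", grid$y_edges[1L],
                   grid$y_edges[nb + 1L]))
  body <- apply(grid$values, 1L, function(r) paste(sprintf("%.9g", r),
                                                   collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}
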