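# Quantitative summaries of what the animated maps show: local density
# maxima ("states"), the density minimum separating two on-diagonal states,
# how much time the system spends in each state, and an L1 divergence
# between maps used for the shuffle comparison.

#' Find local density maxima ("states") in a delay map
#'
#' A peak is a bin whose value is greater than or equal to all of its (up
#' to) 8 neighbours and at least `min_height`. Peaks closer together than
#' `min_separation` (Euclidean distance between bin centres, in seconds)
#' are merged, keeping the higher; ties are broken deterministically by the
#' lowest (row, column) index, so a flat plateau contributes only its
#' lowest-index bin.
#'
#' @param grid A normalised `density_grid`.
#' @param min_height Minimum relative density of a reported peak, in (0, 1).
#' @param min_separation Minimum separation between reported peaks in
#'   seconds (>= 0). The defaults (0.2 and 0.1 s) resolve states a few
#'   hundred milliseconds apart while suppressing smoothing ripples.
#' @return A data.frame of peaks sorted by decreasing height, with columns
#'   `x_center`, `y_center`, `height`, `row`, `col`. Zero rows if none (or
#'   if the grid is empty).
#' @export
find_density_maxima <- function(grid, min_height = 0.2,
                                min_separation = 0.1) {
  stopifnot(inherits(grid, "density_grid"))
  if (!grid$normalized) {
    stop("find_density_maxima: grid must be normalized", call. = FALSE)
  }
  if (min_height <= 0 || min_height >= 1) {
    stop("find_density_maxima: min_height must be in (0, 1)", call. = FALSE)
  }
  if (min_separation < 0) {
    stop("find_density_maxima: min_separation must be >= 0", call. = FALSE)
  }
  v <- grid$values
  n <- nrow(v)
  empty <- data.frame(x_center = double(), y_center = double(),
                      height = double(), row = integer(), col = integer())
  if (max(v) <= 0) return(empty)
  # pad with -Inf and compare against the 8 shifted copies; a tie with a
  # neighbour that precedes this bin in (row, col) order disqualifies it,
  # so a flat plateau contributes only its lowest-index bin
  p <- matrix(-Inf, n + 2L, n + 2L)
  p[2:(n + 1L), 2:(n + 1L)] <- v
  is_max <- matrix(TRUE, n, n)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    nb <- p[(2:(n + 1L)) + di, (2:(n + 1L)) + dj]
    precedes <- di < 0L || (di == 0L && dj < 0L)
    is_max <- is_max & (if (precedes) v > nb else v >= nb)
  }
  idx <- which(is_max & v >= min_height, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty)
  cx <- bin_centers(grid, "x"); cy <- bin_centers(grid, "y")
  peaks <- data.frame(x_center = cx[idx[, 1L]], y_center = cy[idx[, 2L]],
                      height = v[idx], row = idx[, 1L], col = idx[, 2L])
  # height-descending, ties by lowest (row, col)
  peaks <- peaks[order(-peaks$height, peaks$row, peaks$col), , drop = FALSE]
  # greedy merge: keep a peak only if no higher kept peak is within
  # min_separation
  keep <- logical(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    d <- sqrt((peaks$x_center[keep] - peaks$x_center[i])^2 +
              (peaks$y_center[keep] - peaks$y_center[i])^2)
    keep[i] <- all(d >= min_separation)
  }
  peaks <- peaks[keep, , drop = FALSE]
  rownames(peaks) <- NULL
  peaks
}

#' Density minimum separating two on-diagonal states
#'
#' Scans the density profile along the main diagonal of the map strictly
#' between the diagonal positions of two peaks and returns the RR value of
#' the interior minimum — the operational version of the dashed line drawn
#' through the region of minimum density between two states.
#'
#' @param grid A normalised `density_grid`.
#' @param peak_a,peak_b Single-row peak data.frames (rows of
#'   [find_density_maxima()] output) in distinct bins.
#' @return The boundary RR value in seconds.
#' @export
find_separating_minimum <- function(grid, peak_a, peak_b) {
  stopifnot(inherits(grid, "density_grid"))
  ia <- as.integer(peak_a$row[1L]); ib <- as.integer(peak_b$row[1L])
  if (ia == ib && as.integer(peak_a$col[1L]) == as.integer(peak_b$col[1L])) {
    stop("find_separating_minimum: peaks are in the same bin", call. = FALSE)
  }
  lo <- min(ia, ib); hi <- max(ia, ib)
  if (hi - lo < 2L) {
    stop("find_separating_minimum: no interior bins between the peaks",
         call. = FALSE)
  }
  interior <- seq.int(lo + 1L, hi - 1L)
  prof <- grid$values[cbind(interior, interior)]
  cx <- bin_centers(grid, "x")
  cx[interior[which.min(prof)]]
}

#' State occupancy relative to an RR threshold
#'
#' Assigns each beat to the fast state (`RR < boundary_rr`) or the slow
#' state (`RR >= boundary_rr`) and summarises how much of the recording the
#' system spends in each: by beat count and by elapsed time (each beat
#' weighted by its own RR interval — slow beats last longer). Dwell times
#' are the durations of maximal runs in one state.
#'
#' @param series An [rr_series].
#' @param boundary_rr Threshold in seconds, within the observed RR range.
#' @return A `state_partition` list: `boundary_rr`, `occupancy` (beat
#'   fractions, sums to 1), `occupancy_duration` (time fractions),
#'   `dwell_times` (list of per-visit durations in seconds, per state).
#' @export
state_occupancy <- function(series, boundary_rr) {
  stopifnot(inherits(series, "rr_series"))
  rr <- series$intervals
  if (boundary_rr < min(rr) || boundary_rr > max(rr)) {
    stop("state_occupancy: boundary_rr outside the observed RR range",
         call. = FALSE)
  }
  state <- ifelse(rr < boundary_rr, 1L, 2L)
  occ <- c(mean(state == 1L), mean(state == 2L))
  occ_dur <- c(sum(rr[state == 1L]), sum(rr[state == 2L])) / sum(rr)
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  durs <- vapply(seq_along(r$values),
                 function(i) sum(rr[starts[i]:ends[i]]), 0)
  structure(
    list(boundary_rr = boundary_rr,
         occupancy = occ, occupancy_duration = occ_dur,
         dwell_times = split(durs, factor(r$values, levels = 1:2))),
    class = "state_partition"
  )
}

#' @export
print.state_partition <- function(x, ...) {
  cat(sprintf(
    "<state_partition> boundary %.3f s | beats: %.1f%% / %.1f%% | time: %.1f%% / %.1f%%\n",
    x$boundary_rr, 100 * x$occupancy[1L], 100 * x$occupancy[2L],
    100 * x$occupancy_duration[1L], 100 * x$occupancy_duration[2L]))
  invisible(x)
}

#' L1 divergence between two density maps
#'
#' The L1 distance between the two grids after each is normalised to unit
#' total mass; it lies in `[0, 2]` (2 = disjoint supports). Used to
#' quantify how much shuffling a series alters its delay map even though
#' the 1D histogram is unchanged.
#'
#' @param grid_a,grid_b `density_grid`s on identical edges.
#' @return A dimensionless distance in `[0, 2]`.
#' @export
map_divergence <- function(grid_a, grid_b) {
  stopifnot(inherits(grid_a, "density_grid"),
            inherits(grid_b, "density_grid"))
  if (!isTRUE(all.equal(grid_a$x_edges, grid_b$x_edges)) ||
      !isTRUE(all.equal(grid_a$y_edges, grid_b$y_edges))) {
    stop("map_divergence: grids have mismatched bin edges", call. = FALSE)
  }
  pa <- grid_a$values; pb <- grid_b$values
  sa <- sum(pa); sb <- sum(pb)
  if (sa > 0) pa <- pa / sa
  if (sb > 0) pb <- pb / sb
  sum(abs(pa - pb))
}

#' Shuffle comparison of a delay map against its resampling null
#'
#' Computes the divergence between the density map of `series` and that of
#' one shuffled copy, and compares it with the null distribution of the
#' divergence between pairs of independent shuffles (which share the 1D
#' histogram but have no serial structure). A correlated series sits far
#' above the null; an i.i.d. series does not.
#'
#' @param series An [rr_series].
#' @param seed Integer seed driving the shuffles.
#' @param n_null Number of null resampling pairs (default 200).
#' @param nbins,range,lambda_user,smooth Passed to [compute_density_map()].
#' @return A list: `divergence`, `null` (vector of `n_null` null
#'   divergences), `null_q99`, and `exceeds_null` (logical).
#' @export
shuffle_comparison <- function(series, seed = 1L, n_null = 200L,
                               nbins = 200L, range = NULL,
                               lambda_user = 20, smooth = TRUE) {
  stopifnot(inherits(series, "rr_series"))
  if (is.null(range)) range <- default_range(series$intervals)
  dm <- function(s) compute_density_map(s, nbins = nbins, range = range,
                                        lambda_user = lambda_user,
                                        smooth = smooth)
  g0 <- dm(series)
  g1 <- dm(shuffle_intervals(series, seed = seed))
  d_obs <- map_divergence(g0, g1)
  null <- vapply(seq_len(n_null), function(i) {
    a <- dm(shuffle_intervals(series, seed = seed + 2L * i))
    b <- dm(shuffle_intervals(series, seed = seed + 2L * i + 1L))
    map_divergence(a, b)
  }, 0)
  q99 <- stats::quantile(null, 0.99, names = FALSE, type = 7)
  list(divergence = d_obs, null = null, null_q99 = q99,
       exceeds_null = d_obs > q99)
}
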