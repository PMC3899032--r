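# Synthetic RR generators emulating the three exemplar dynamics: bistable
# sleep-like switching, uncorrelated (typical AF-like) intervals, and
# persistent two-level alternation producing four delay-map clusters
# (atypical AF-like).

# Run code under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion")
  force(code)
}

# Physiologic positivity floor for generated RR intervals (seconds).
RR_FLOOR <- 0.2

#' Specification of a bistable RR process
#'
#' Parameters of a two-state hidden Markov RR generator: the hidden state
#' follows a symmetric 2-state Markov chain, and within each state the RR
#' interval is the state mean plus an AR(1) fluctuation with stationary
#' standard deviation `sd_rr`. Defaults mimic a sleep recording that flips
#' between states centred near 0.65 s and 1.0 s.
#'
#' @param mean_rr Two distinct state means, seconds.
#' @param sd_rr Within-state fluctuation SD, seconds.
#' @param stay_prob Per-beat probability of remaining in the current state.
#' @param ar_coeff Lag-1 autocorrelation of within-state fluctuations,
#'   in `[0, 1)`.
#' @param n_beats Number of beats to generate.
#' @param seed Integer seed; fixed seed gives bitwise-identical output.
#' @return A `bistable_spec` list.
#' @export
bistable_spec <- function(mean_rr = c(0.65, 1.0), sd_rr = 0.03,
                          stay_prob = 0.998, ar_coeff = 0.9,
                          n_beats = 30000L, seed = 1L) {
  spec <- list(mean_rr = as.double(mean_rr), sd_rr = as.double(sd_rr),
               stay_prob = as.double(stay_prob),
               ar_coeff = as.double(ar_coeff),
               n_beats = as.integer(n_beats), seed = as.integer(seed))
  if (length(spec$mean_rr) != 2L || spec$mean_rr[1] == spec$mean_rr[2]) {
    stop("bistable_spec: mean_rr must be two distinct values", call. = FALSE)
  }
  if (spec$sd_rr <= 0) stop("bistable_spec: sd_rr must be > 0", call. = FALSE)
  if (spec$stay_prob <= 0 || spec$stay_prob > 1) {
    stop("bistable_spec: stay_prob must be in (0, 1]", call. = FALSE)
  }
  if (spec$ar_coeff < 0 || spec$ar_coeff >= 1) {
    stop("bistable_spec: ar_coeff must be in [0, 1)", call. = FALSE)
  }
  if (spec$n_beats < 2L) stop("bistable_spec: n_beats must be >= 2",
                              call. = FALSE)
  structure(spec, class = "bistable_spec")
}

#' Generate a bistable RR series
#'
#' Simulates the two-state switching dynamics described by a
#' [bistable_spec()]: a hidden symmetric 2-state Markov chain selects the
#' state mean each beat, and an AR(1) process supplies short-range-correlated
#' within-state fluctuations. The state-switch draws and the noise draws come
#' from separate blocks of one seeded stream, so changing `stay_prob` leaves
#' the noise realisation unchanged. Intervals are floored at 0.2 s.
#'
#' @param spec A [bistable_spec()].
#' @return An [rr_series] with attribute `"state"` (integer vector of hidden
#'   state indices, 1 or 2).
#' @export
gen_bistable <- function(spec = bistable_spec()) {
  stopifnot(inherits(spec, "bistable_spec"))
  n <- spec$n_beats
  with_seed(spec$seed, {
    u <- stats::runif(n)            # state sub-stream
    z <- stats::rnorm(n)            # noise sub-stream
    switches <- c(FALSE, u[-1L] > spec$stay_prob)
    state <- 1L + cumsum(switches) %% 2L
    # AR(1) with stationary sd sd_rr: e_n = a e_{n-1} + sd*sqrt(1-a^2) z_n
    a <- spec$ar_coeff
    innov <- spec$sd_rr * sqrt(1 - a^2) * z
    innov[1L] <- spec$sd_rr * z[1L]  # start in the stationary distribution
    e <- stats::filter(innov, a, method = "recursive")
    rr <- pmax(spec$mean_rr[state] + as.double(e), RR_FLOOR)
    out <- rr_series(intervals = rr,
                     label = sprintf("bistable(seed=%d)", spec$seed))
    attr(out, "state") <- state
    out
  })
}

#' Generate an uncorrelated RR series
#'
#' Independent, identically distributed Gaussian RR intervals truncated
#' below at 0.2 s, emulating the uncorrelated ventricular response of
#' typical atrial fibrillation whose delay map is a single circular locus.
#'
#' @param mean_rr Mean RR, seconds.
#' @param sd_rr SD of RR, seconds; must be > 0.
#' @param n_beats Number of beats (>= 2).
#' @param seed Integer seed.
#' @return An [rr_series].
#' @export
gen_iid <- function(mean_rr = 0.6, sd_rr = 0.1, n_beats = 20000L, seed = 1L) {
  if (sd_rr <= 0) stop("gen_iid: sd_rr must be > 0", call. = FALSE)
  if (n_beats < 2L) stop("gen_iid: n_beats must be >= 2", call. = FALSE)
  with_seed(seed, {
    # truncated-normal draw via the inverse CDF, exact and vectorised
    plo <- stats::pnorm(RR_FLOOR, mean_rr, sd_rr)
    u <- stats::runif(n_beats, plo, 1)
    rr <- stats::qnorm(u, mean_rr, sd_rr)
    rr_series(intervals = rr, label = sprintf("iid(seed=%d)", seed))
  })
}

#' Specification of a two-level cluster-switching RR process
#'
#' Parameters of a generator that alternates between two RR levels in runs
#' of at least `min_run` beats, producing the four-cluster delay map of an
#' atypical atrial-fibrillation ventricular response: on-diagonal loci at
#' (`l1`,`l1`) and (`l2`,`l2`) from within-run pairs, off-diagonal loci at
#' (`l1`,`l2`) and (`l2`,`l1`) from the level changes.
#'
#' @param levels Two distinct RR levels, seconds.
#' @param min_run Minimum run length in beats (>= 1).
#' @param switch_prob Per-beat probability of switching once `min_run` beats
#'   at the current level have elapsed, in `(0, 1]`.
#' @param sd_rr Gaussian jitter SD around each level, seconds.
#' @param n_beats Number of beats.
#' @param seed Integer seed.
#' @return A `cluster_switch_spec` list.
#' @export
cluster_switch_spec <- function(levels = c(0.4, 0.8), min_run = 3L,
                                switch_prob = 0.3, sd_rr = 0.02,
                                n_beats = 20000L, seed = 1L) {
  spec <- list(levels = as.double(levels), min_run = as.integer(min_run),
               switch_prob = as.double(switch_prob), sd_rr = as.double(sd_rr),
               n_beats = as.integer(n_beats), seed = as.integer(seed))
  if (length(spec$levels) != 2L || spec$levels[1] == spec$levels[2]) {
    stop("cluster_switch_spec: levels must be two distinct values",
         call. = FALSE)
  }
  if (spec$min_run < 1L) stop("cluster_switch_spec: min_run must be >= 1",
                              call. = FALSE)
  if (spec$switch_prob <= 0 || spec$switch_prob > 1) {
    stop("cluster_switch_spec: switch_prob must be in (0, 1]", call. = FALSE)
  }
  if (spec$sd_rr <= 0) stop("cluster_switch_spec: sd_rr must be > 0",
                            call. = FALSE)
  if (spec$n_beats < 2L) stop("cluster_switch_spec: n_beats must be >= 2",
                              call. = FALSE)
  structure(spec, class = "cluster_switch_spec")
}

#' Generate a cluster-switching RR series
#'
#' Simulates persistent alternation between two RR levels per a
#' [cluster_switch_spec()]: run lengths are `min_run` plus a geometric
#' number of extra beats (success probability `switch_prob`), levels
#' alternate between runs, and Gaussian jitter of SD `sd_rr` is added around
#' each level (floored at 0.2 s).
#'
#' @param spec A [cluster_switch_spec()].
#' @return An [rr_series] with attribute `"level"` (1 or 2 per beat).
#' @export
gen_cluster_switching <- function(spec = cluster_switch_spec()) {
  stopifnot(inherits(spec, "cluster_switch_spec"))
  n <- spec$n_beats
  with_seed(spec$seed, {
    # generous upper bound on the number of runs needed
    n_runs <- max(4L, ceiling(2 * n / (spec$min_run + 1 / spec$switch_prob)))
    repeat {
      extra <- stats::rgeom(n_runs, spec$switch_prob)
      lens <- spec$min_run + extra
      if (sum(lens) >= n) break
      n_runs <- n_runs * 2L
    }
    run_id <- rep.int(seq_along(lens), lens)[seq_len(n)]
    level <- 1L + (run_id - 1L) %% 2L
    rr <- pmax(spec$levels[level] + spec$sd_rr * stats::rnorm(n), RR_FLOOR)
    out <- rr_series(intervals = rr,
                     label = sprintf("cluster(seed=%d)", spec$seed))
    attr(out, "level") <- level
    out
  })
}
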