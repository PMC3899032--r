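---
title: "Dynamical density delay maps: method and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamical density delay maps: method and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 5,
                      fig.height = 5)
library(d3map)
```

## The problem

A time series of cardiac interbeat (RR) intervals carries information that
neither its graph nor its histogram shows well. The histogram discards the
order of the beats entirely, so it cannot reveal serial correlation. A
standard Poincaré plot — the scatter of RR(n) against RR(n+1) — restores
the lag-1 correlation structure but discards *density*: a cloud visited
once and a cloud visited ten thousand times look the same. And any plot
built from the whole record discards *time*: a system that spends its
first half in one state and its second half in another is
indistinguishable from one that flips between them every few minutes.

The dynamical density delay map addresses all three losses at once. The
record is cut into overlapping time windows; each window's lag-1 pairs are
binned into a 2D histogram; the histogram is smoothed, scaled so its
highest bin equals 1, and colourised; and the resulting per-window surfaces
are played back as an animation. Nonstationarity appears as motion;
multistability appears as multiple persistent density maxima; hidden
periodic structure appears as off-diagonal clusters.

## The pipeline

For a series $x(n)$, $n = 1,\dots,N$, with beat onset times $t(n)$:

1. **Windowing.** Windows of width $W$ seconds start every $S$ seconds
   from the first beat's onset; a beat belongs to the window whose
   half-open interval $[t_0 + kS,\, t_0 + kS + W)$ contains its onset.
   With elapsed time $T$ (the span of onsets) there are exactly
   $\lfloor (T - W)/S \rfloor + 1$ windows. Two presets mirror common
   usage: 500/10 s for overnight recordings and 1200/300 s for day-long
   arrhythmia recordings.
2. **Delay pairs.** Each window contributes the pairs
   $(x(n), x(n+1))$ formed within the window only.
3. **Binning.** Pairs are counted on an `nbins × nbins` uniform grid over
   a *fixed* range shared by every window (default: the full record's
   min–max padded by 2%). Bins are half-open with the last bin closed;
   out-of-range pairs are dropped and counted, never silently lost.
4. **Smoothing.** The raw counts are smoothed by a separable
   difference-penalised (Whittaker-type) least-squares smoother; see
   below.
5. **Max-normalisation.** The surface is divided by its highest bin, so
   $h \in [0, 1]$. $h$ is a *relative occupancy* of the delay phase
   space, not a probability density (the division is by the maximum, not
   the sum). Smoothing precedes normalisation so the displayed maximum is
   exactly 1.
6. **Colourisation and composition.** $h$ is looked up linearly in a
   colourmap (default: the classic jet ramp, blue = rare, dark red =
   frequent). Each frame stacks the 3D surface, its 2D contour map (the
   surface's far side is invisible at any fixed view angle, so the
   contour panel compensates), and the window's RR trace.
7. **Animation.** Frames are encoded as an animated GIF (natively,
   losslessly for frames of at most 256 colours) or an uncompressed AVI.

```{r pipeline-demo}
s <- gen_bistable(bistable_spec(n_beats = 20000, seed = 1))
map <- compute_density_map(s, nbins = 200, range = c(0.3, 1.4))
find_density_maxima(map)
```

## The smoother

Each column $y$ of the count matrix is replaced by the solution of

$$ (I + 2\lambda D_1^\top D_1 + \lambda^2 D_2^\top D_2)\, z = y, $$

where $D_1$ and $D_2$ are the first- and second-difference matrices and
$\lambda = \texttt{nbins}/\texttt{lambda\_user}$; the same smoother is then
applied to the rows of the result. This is the grid smoother popularised by
density-coloured scatter plots in flow cytometry, with the same default
user parameter (`lambda_user = 20`). Two exact properties make it easy to
test and safe to use on count data:

* both penalties annihilate constant vectors, so a flat surface passes
  through unchanged, and
* the columns of $D^\top D$ sum to zero, so every column sum — and hence
  the total mass — is conserved exactly.

The system is pentadiagonal and symmetric positive definite; it is solved
by a sparse Cholesky factorisation that is cached and reused across
windows and resampling replicates. The test suite checks the sparse path
against an independently constructed dense solve to $10^{-8}$ on grids up
to 20×20.

## States, boundaries and occupancy

A *state* is a local density maximum: a bin at least as high as its eight
neighbours, above a height floor (`min_height`, default 0.2). Peaks closer
together than `min_separation` (default 0.1 s) merge into the higher one;
the defaults resolve states a few hundred milliseconds apart — the scale
of the landmark structures at 0.65/1.0 s and 0.4/0.8 s — while ignoring
smoothing ripples. Ties on a flat plateau go to the lowest (row, column)
bin so detection is deterministic; after smoothing, exact plateaus have
measure zero anyway.

The boundary between two on-diagonal states is operationalised as the
minimum of the density profile along the main diagonal, strictly between
the two peaks, and state membership of a beat as a scalar threshold on its
RR value. A 2D separating curve would be more faithful to the picture, but
the scalar reduction is testable, and for on-diagonal states the two
coincide to within a bin. Occupancy is reported both beat-weighted and
duration-weighted (each beat weighted by its own RR interval): slow-state
beats last longer, so the duration-weighted share of the slow state always
exceeds its beat-weighted share.

```{r states-demo}
peaks <- find_density_maxima(map)
b <- find_separating_minimum(map, peaks[1, ], peaks[2, ])
b
state_occupancy(s, b)
```

## The shuffle comparison

Shuffling the intervals preserves their multiset — the 1D histogram is
*identical*, which the suite asserts exactly — but destroys serial
correlation, which reshapes the delay map completely. The package
quantifies this with the L1 distance between mass-normalised maps (a total
variation distance, in $[0, 2]$), compared against a resampling null: the
same distance between pairs of independent shuffles. For a correlated
series the observed divergence sits far above the null's 99th percentile
(around 1.1 versus 0.03 under the bistable generator's defaults); for an
i.i.d. series it sits inside the null, which is exactly the sense in which
an uncorrelated map is "shuffle-invariant".

## What the synthetic generators emulate

No generative model accompanies the real recordings, so the package ships
three generators whose parameters were chosen once to reproduce the
landmark structure of the three exemplar dynamics, and are documented as
package choices:

* `gen_bistable()` — a symmetric two-state hidden Markov chain
  (`stay_prob = 0.998`, so dwell times of ~500 beats) selecting state
  means of 0.65 and 1.0 s, plus AR(1) within-state fluctuations
  (`ar_coeff = 0.9`, stationary sd 0.03 s). This mimics an overnight
  recording flipping between a faster and a slower heart-rate state (about
  92 and 60 beats/min).
* `gen_iid()` — truncated-Gaussian i.i.d. intervals (mean 0.6 s, sd
  0.1 s), mimicking the uncorrelated ventricular response of typical
  atrial fibrillation: one circular locus.
* `gen_cluster_switching()` — alternation between 0.4 s and 0.8 s levels
  in runs of at least 3 beats (geometric run extensions with switch
  probability 0.3, jitter sd 0.02 s), producing the four-cluster map: two
  on-diagonal loci from within-run pairs and two off-diagonal loci from
  the level changes.

All noise is Gaussian with a 0.2 s positivity floor — a physiologic lower
bound on RR. Each generator is driven by a single seeded stream (state
draws and noise draws in separate blocks, so the noise realisation is
invariant to `stay_prob`), and a fixed seed gives bitwise-identical
output.

What passing tests on these generators do **not** show: real RR series
have respiratory and circadian modulation, ectopic beats, measurement
artefacts and drifting state means, none of which are modelled. The
generators validate the *machinery* — that the pipeline recovers known
structure at known locations — not the physiology.

## Numerical choices and degenerate inputs

* **Binning convention:** half-open bins, last bin closed; a pair exactly
  on an interior edge goes to the upper bin. This makes mass conservation
  an exact, testable identity.
* **Shared axes:** one range for all windows of an animation; per-window
  ranges would make stationary states appear to drift.
* **Empty windows** (possible during long pauses) produce an all-zero
  grid and a blank frame, never an exception, so animations tolerate
  silent stretches.
* **All-zero grids** normalise to all-zero (no division by zero);
  double normalisation is an error rather than a silent no-op.
* **Trailing data** shorter than one window is dropped with a message.
* **Determinism:** fixed seeds and a fixed cairo PNG backend make frames
  byte-reproducible; re-encoding the same frames yields byte-identical
  GIFs.

## Problem sizes

The package's own validation runs on synthetic records of 15,000–30,000
beats (roughly 3–7 hours of heart dynamics), 200×200 grids, 200-replicate
resampling nulls, and 20-seed parameter-recovery sweeps; these sizes give
sampling error comfortably inside the assertion tolerances while keeping
the whole suite fast. Animations in the tests use short records and small
frames; full-length renders (a 6-hour record at the 500/10 preset yields
2111 frames) scale linearly in frame count.

## Known limitations

* Only lag-1 (and user-chosen lag-k) 2D maps are produced; no
  higher-dimensional embeddings.
* MP4 export shells out to an external `ffmpeg` binary when one is
  available; GIF and AVI are produced natively.
* The state boundary is a scalar RR threshold, which cannot represent
  genuinely two-dimensional state geometry (e.g. states separated only
  off-diagonal).
* Peak detection operates on the smoothed surface; states weaker than
  `min_height` after smoothing are not reported.
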