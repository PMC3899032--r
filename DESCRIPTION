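Package: d3map
Title: Dynamical Density Delay Maps for Interbeat-Interval Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for visualising nonstationarity, multistability and hidden
    temporal structure in interbeat (RR) interval time series using dynamical
    density delay maps: sliding-window, smoothed, max-normalised
    two-dimensional histograms of lag-1 return pairs (Poincare plots),
    colourised and assembled into animations. Includes readers and writers for
    plain-ASCII RR files, synthetic generators of bistable, uncorrelated and
    cluster-switching RR dynamics, a difference-penalised (Whittaker-type) 2D
    density smoother, detection of local density maxima ("states") with
    occupancy statistics, a shuffle-based test for serial correlation
    structure, and renderers producing composite surface/contour/time-series
    frames exported as animated GIF or uncompressed AVI.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
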