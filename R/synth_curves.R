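#' Synthetic fossil diversity curves (common signal + noise)
#'
#' Emulates the statistical structure of a set of fossil diversity curves
#' drawn from heterogeneous databases: one smooth common richness signal,
#' observed by each database through its own positive scale, offset and
#' independent observation noise. The default signal is a smooth random
#' curve (a few low-frequency cosine modes of age); a custom signal can be
#' supplied.
#'
#' @param ages Target ages (Ma), strictly monotone.
#' @param n_curves Number of curves (default 5).
#' @param noise_sd Observation noise standard deviation on the 0-1 signal
#'   scale (default 0.15).
#' @param seed Integer seed.
#' @param signal Optional numeric vector (the common signal at `ages`).
#' @return A list: `curves` (list of [age_series()]), `signal` (the true
#'   common signal as an [age_series()]).
#' @export
synth_fossil_curves <- function(ages, n_curves = 5, noise_sd = 0.15,
                                seed = 1L, signal = NULL) {
  stopifnot(n_curves >= 2, noise_sd >= 0)
  ages <- sort(unique(as.numeric(ages)), decreasing = TRUE)
  n <- length(ages)
  with_local_seed(as.integer(seed), {
    if (is.null(signal)) {
      span <- max(ages) - min(ages)
      ph <- stats::runif(3, 0, 2 * pi)
      amp <- stats::runif(3, 0.5, 1)
      signal <- amp[1] * cos(2 * pi * ages / span + ph[1]) +
        amp[2] * cos(4 * pi * ages / span + ph[2]) +
        amp[3] * cos(6 * pi * ages / span + ph[3])
      signal <- (signal - min(signal)) / (max(signal) - min(signal))
    }
    stopifnot(length(signal) == n)
    curves <- lapply(seq_len(n_curves), function(i) {
      scale_i <- stats::runif(1, 0.5, 3)
      offset_i <- stats::runif(1, 0, 100)
      age_series(ages,
                 offset_i + scale_i *
                   (signal + stats::rnorm(n, sd = noise_sd)),
                 sprintf("synthetic curve %d", i))
    })
    list(curves = curves, signal = age_series(ages, signal, "true signal"))
  })
}

#' Synthetic continental fragmentation index
#'
#' A smooth noisy curve in \[0, 1\] on an age axis, emulating an externally
#' supplied fragmentation series (0 = all land in one block, 1 = every
#' plate separate) for pipelines that ingest and interpolate such an
#' index.
#'
#' @param ages Target ages (Ma).
#' @param seed Integer seed.
#' @param noise_sd Noise standard deviation before squashing to \[0, 1\].
#' @return An [age_series()].
#' @export
synth_fragmentation_index <- function(ages, seed = 1L, noise_sd = 0.05) {
  ages <- sort(unique(as.numeric(ages)), decreasing = TRUE)
  span <- max(ages) - min(ages)
  with_local_seed(as.integer(seed), {
    ph <- stats::runif(2, 0, 2 * pi)
    x <- 0.5 + 0.35 * cos(2 * pi * ages / span + ph[1]) +
      0.1 * cos(6 * pi * ages / span + ph[2]) +
      stats::rnorm(length(ages), sd = noise_sd)
    age_series(ages, pmin(pmax(x, 0), 1), "fragmentation index")
  })
}
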