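# Synthetic auditory brainstem responses.
#
# The evoked template is a train of five Gabor-like deflections (Gaussian
# envelope, sigma 0.4 ms; 1 kHz carrier) so its energy lies inside the
# 600-1500 Hz analysis band and zero-phase filtering preserves peak
# positions. Wave latencies at 80 dBSPL are 1.5, 2.4, 3.3, 4.2 and 5.1 ms
# with relative amplitudes 1.0, 0.6, 0.7, 0.5, 0.4 (wave 1 dominant, as in
# mouse ABRs).

abr_wave_latencies <- c(1.5, 2.4, 3.3, 4.2, 5.1)
abr_wave_amplitudes <- c(1.0, 0.6, 0.7, 0.5, 0.4)

# time axis of one epoch: [-3, +9) ms around pulse onset
abr_time_ms <- function(fs) {
  n <- round(0.012 * fs)
  -3 + (seq_len(n) - 1) / fs * 1000
}

# noise-free evoked template at a given latency shift (ms) and gain
abr_template <- function(fs, shift_ms = 0, gain = 1) {
  t <- abr_time_ms(fs)
  x <- numeric(length(t))
  for (k in seq_along(abr_wave_latencies)) {
    d <- t - abr_wave_latencies[k] - shift_ms
    x <- x + abr_wave_amplitudes[k] * exp(-d^2 / (2 * 0.4^2)) *
      cos(2 * pi * 1.0 * d)
  }
  gain * x
}

# amplitude growth with intensity: square root of the normalized level
# above threshold, so the response at the threshold intensity is still
# ~0.32x the 80-dB response in the worst case and never drowns in the
# averaged noise floor; zero below threshold.
abr_growth <- function(intensity, threshold) {
  ifelse(intensity >= threshold,
         sqrt((intensity - threshold + 5) / (85 - threshold)), 0)
}

#' Synthesize an ABR epoch stack for one frequency band
#'
#' For each intensity of the 80..35 dBSPL grid (5-dB steps) emits
#' `n_epochs` epochs of `[-3, +9)` ms around the pulse onset (3-ms
#' narrow-band noise pulses presented at 10 Hz, 529 repetitions). Peak
#' amplitudes scale down with intensity following a square-root growth law
#' and vanish below the animal's threshold for the band; every wave's
#' latency increases by `latency_step_ms` per 5-dB step below 80 dBSPL.
#' Independent Gaussian noise of SD `gt$noise_sd` is added per epoch.
#'
#' @param gt A [ground_truth_animal()] with `threshold_by_band` covering
#'   `band`.
#' @param band Band label, one of [abr_bands()].
#' @param seed Integer seed.
#' @param fs Sampling rate, Hz (> 3000).
#' @param n_epochs Epochs per intensity (default 529).
#' @param latency_step_ms Per-5-dB-step latency increment, ms (<= 0.3).
#' @return An `abr_stack`: list with `band`, `fs`, `intensities`,
#'   `epochs` (list of samples x epochs matrices, one per intensity),
#'   and `ground_truth`.
#' @export
#' @examples
#' gt <- ground_truth_animal(list(pre = c("8-10" = 0.8)),
#'                           threshold_by_band = c("8-10" = 50),
#'                           noise_sd = 0.5)
#' stk <- synth_abr_stack(gt, "8-10", seed = 1, n_epochs = 8)
synth_abr_stack <- function(gt, band, seed = 1L, fs = 30000,
                            n_epochs = 529, latency_step_ms = 0.1) {
  stopifnot(inherits(gt, "ground_truth_animal"))
  if (latency_step_ms > 0.3)
    stop("latency_step_ms must be <= 0.3 ms", call. = FALSE)
  thr <- unname(gt$threshold_by_band[band])
  if (length(thr) != 1 || is.null(thr) || is.na(thr))
    stop("no threshold ground truth for band ", band, call. = FALSE)
  if (thr %% 5 != 0 || thr < 35 || thr > 80)
    stop("threshold off the 5-dB grid 35..80", call. = FALSE)
  ints <- abr_intensities()
  n <- length(abr_time_ms(fs))
  epochs <- with_seed(seed, {
    lapply(ints, function(I) {
      tmpl <- abr_template(fs, shift_ms = (80 - I) / 5 * latency_step_ms,
                           gain = abr_growth(I, thr))
      tmpl + matrix(stats::rnorm(n * n_epochs, sd = gt$noise_sd),
                    n, n_epochs)
    })
  })
  names(epochs) <- as.character(ints)
  structure(list(band = band, fs = fs, intensities = ints,
                 epochs = epochs, ground_truth = gt),
            class = "abr_stack")
}

#' @export
print.abr_stack <- function(x, ...) {
  cat(sprintf("<abr_stack> band %s kHz, %d intensities x %d epochs @ %g Hz\n",
              x$band, length(x$intensities), ncol(x$epochs[[1]]), x$fs))
  invisible(x)
}
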