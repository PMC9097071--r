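#' Ground-truth parameters for one synthetic animal
#'
#' Bundles the quantities the analysis chain is meant to recover:
#' per-session, per-band gap-induced startle suppression, the startle burst
#' amplitude, per-band hearing thresholds and the sensor noise level.
#' Sessions mirror the experimental timeline: `pre` (before noise
#' exposure), `nacl` (after exposure, vehicle injection) and `cno` (after
#' exposure, under chemogenetic inhibition).
#'
#' @param suppression Named list of numeric vectors, one per session
#'   (`pre`, `nacl`, `cno`), each named by band label, values in `[0, 1]`:
#'   the fraction by which the silent gap suppresses the startle burst.
#' @param startle_peak_amp Peak amplitude of the startle burst, transducer
#'   units. Default 1.
#' @param threshold_by_band Named numeric vector of hearing thresholds
#'   (dBSPL) on the 5-dB grid 35..80, one per tested band.
#' @param noise_sd Additive Gaussian noise standard deviation, transducer
#'   units (for startle traces) or epoch units (for ABR epochs).
#' @return An object of class `ground_truth_animal`.
#' @export
#' @examples
#' gt <- ground_truth_animal(
#'   suppression = list(pre = c("9-11" = 0.8)),
#'   threshold_by_band = c("9-11" = 45))
ground_truth_animal <- function(suppression,
                                startle_peak_amp = 1,
                                threshold_by_band = NULL,
                                noise_sd = 0.1) {
  if (is.numeric(suppression)) suppression <- list(pre = suppression)
  stopifnot(is.list(suppression), length(suppression) >= 1)
  for (s in suppression) {
    if (is.null(names(s)) || any(!nzchar(names(s))))
      stop("each suppression vector must be named by band", call. = FALSE)
    if (any(s < 0 | s > 1))
      stop("suppression must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(threshold_by_band)) {
    if (any(threshold_by_band %% 5 != 0 | threshold_by_band < 35 |
            threshold_by_band > 80))
      stop("thresholds must lie on the 5-dB grid 35..80 dBSPL",
           call. = FALSE)
  }
  stopifnot(startle_peak_amp > 0, noise_sd >= 0)
  structure(
    list(suppression = suppression,
         startle_peak_amp = startle_peak_amp,
         threshold_by_band = threshold_by_band,
         noise_sd = noise_sd),
    class = "ground_truth_animal")
}

#' Ground-truth parameters for one synthetic single unit
#'
#' Describes a Gaussian frequency-response area: an evoked firing rate that
#' peaks at the unit's best frequency and falls off with a Gaussian profile
#' across band centers, grows with stimulus intensity, and is scaled
#' multiplicatively under CNO.
#'
#' @param bf_khz Center of the Gaussian tuning curve, kHz.
#' @param sigma_khz Tuning spread (Gaussian SD), kHz; must be positive.
#' @param peak_rate Evoked firing rate at best frequency and 80 dBSPL, Hz.
#' @param baseline_rate Spontaneous rate, Hz.
#' @param rate_intensity_slope Additive evoked-rate change per dB below
#'   80 dBSPL, Hz/dB (applied before the Gaussian frequency factor).
#' @param cno_gain Multiplicative factor on the evoked rate under CNO;
#'   `< 1` models chemogenetic inhibition.
#' @param depth_mm Recording depth, mm (pass-through metadata).
#' @return An object of class `ground_truth_unit`.
#' @export
#' @examples
#' ground_truth_unit(bf_khz = 11, sigma_khz = 1.5, peak_rate = 20)
ground_truth_unit <- function(bf_khz,
                              sigma_khz,
                              peak_rate,
                              baseline_rate = 1,
                              rate_intensity_slope = 0.2,
                              cno_gain = 1,
                              depth_mm = NA_real_) {
  stopifnot(peak_rate >= 0, sigma_khz > 0, cno_gain > 0, baseline_rate >= 0)
  structure(
    list(bf_khz = bf_khz, sigma_khz = sigma_khz, peak_rate = peak_rate,
         baseline_rate = baseline_rate,
         rate_intensity_slope = rate_intensity_slope,
         cno_gain = cno_gain, depth_mm = depth_mm),
    class = "ground_truth_unit")
}
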