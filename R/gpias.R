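# Gap-prepulse-inhibition quantification from raw transducer traces.

#' Filter a startle recording into a single analysis trace
#'
#' Piezoelectric recordings are zero-phase bandpass filtered 70-400 Hz
#' (4th-order Butterworth). Accelerometer recordings are zero-phase lowpass
#' filtered below 50 Hz per axis and the absolute values of the three axes
#' are averaged per sample. Zero-phase (forward-backward) filtering is used
#' so burst latency relative to the pulse mark is preserved. Rectifying and
#' axis-averaging commute with slicing, so the result can be sliced
#' directly.
#'
#' @param rec A `session_recording` (see [synth_gpias_session()]).
#' @return Numeric vector: the filtered single-channel trace.
#' @export
preprocess_trace <- function(rec) {
  stopifnot(inherits(rec, "session_recording"))
  x <- rec$traces
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  if (rec$sensor == "piezo") {
    if (ncol(x) != 1)
      stop("piezo recordings carry a single channel", call. = FALSE)
    zp_butter(x[, 1], rec$fs, c(70, 400), "pass")
  } else if (rec$sensor == "accelerometer") {
    if (ncol(x) != 3)
      stop("accelerometer recordings carry three axes", call. = FALSE)
    f <- zp_butter(x, rec$fs, 50, "low")
    rowMeans(abs(f))
  } else {
    stop("unknown sensor kind: ", rec$sensor, call. = FALSE)
  }
}

#' Slice trials around the loud pulse and average them
#'
#' Cuts a `[-100, +100)` ms window around each loud-pulse onset of the
#' requested band and trial type (onset is the first sample of the post
#' half) and returns the point-wise mean across trials. The schedule is
#' expected to provide 9 trials per (band, type); a different count is
#' accepted with a warning.
#'
#' @param trace Filtered single-channel trace (see [preprocess_trace()]).
#' @param ttl_times Loud-pulse onset times, seconds (one per schedule row).
#' @param schedule The session's `gpias_schedule`.
#' @param band Band label.
#' @param trial_type `"gap"` or `"startle"`.
#' @param fs Sampling rate, Hz.
#' @return Numeric vector of length `2 * round(0.1 * fs)`: the averaged
#'   segment.
#' @export
slice_and_average <- function(trace, ttl_times, schedule, band,
                              trial_type, fs) {
  sel <- which(schedule$band == band & schedule$trial_type == trial_type)
  if (length(sel) == 0)
    stop("no trials for band ", band, " / ", trial_type, call. = FALSE)
  if (length(sel) != 9)
    warning(length(sel), " trials for band ", band, " / ", trial_type,
            " (expected 9); averaging available trials", call. = FALSE)
  npre <- round(0.1 * fs)
  onset <- round(ttl_times[sel] * fs) + 1L
  lo <- onset - npre
  hi <- onset + npre - 1L
  if (any(lo < 1L) || any(hi > length(trace)))
    stop("slice exceeds record bounds", call. = FALSE)
  segs <- vapply(seq_along(sel),
                 function(i) trace[lo[i]:hi[i]],
                 numeric(2L * npre))
  rowMeans(segs)
}

#' Instantaneous amplitude via the analytic signal
#'
#' Computes the per-sample magnitude of the discrete analytic signal
#' (Hilbert-transform envelope) of a segment: the one-sided spectrum is
#' doubled, negative frequencies zeroed, and the inverse FFT's modulus
#' returned.
#'
#' @param segment Finite numeric vector.
#' @return Numeric vector of the same length: the envelope.
#' @export
#' @examples
#' t <- seq(0, 1, by = 1/500)
#' max(abs(instantaneous_amplitude(sin(2 * pi * 50 * t))[100:400] - 1))
instantaneous_amplitude <- function(segment) {
  if (!all(is.finite(segment)))
    stop("segment must be finite-valued", call. = FALSE)
  n <- length(segment)
  if (n == 1L) return(abs(segment))
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(stats::fft(segment) * h, inverse = TRUE) / n)
}

#' Baseline-corrected response amplitude of an envelope
#'
#' Mean envelope over the post-pulse half (`[0, +100)` ms) minus the mean
#' over the pre-pulse half (`[-100, 0)` ms). The subtraction corrects for
#' baseline offsets; the result may be negative on noise.
#'
#' @param envelope Envelope covering `[-100, +100)` ms (even length; first
#'   half pre, second half post).
#' @return Scalar response amplitude.
#' @export
response_amplitude <- function(envelope) {
  n <- length(envelope)
  if (n %% 2 != 0)
    stop("envelope must have even length (equal pre/post halves)",
         call. = FALSE)
  half <- n / 2
  mean(envelope[(half + 1):n]) - mean(envelope[1:half])
}

#' Gap-prepulse inhibition index
#'
#' `(1 - gap_amp / startle_amp) * 100`: the percentage by which the silent
#' gap suppressed the startle response. 0 means no suppression, 100 full
#' suppression; negative values indicate facilitation. Undefined when the
#' startle amplitude is not positive (possible after baseline subtraction
#' on noise) — an error is raised rather than an unbounded index.
#'
#' @param startle_amp Response amplitude of the averaged Startle trials.
#' @param gap_amp Response amplitude of the averaged Gap-startle trials.
#' @return Index in percent (`<= 100`, may be negative).
#' @export
#' @examples
#' gpias_index(10, 2)   # 80
#' gpias_index(10, 12)  # -20, facilitation
gpias_index <- function(startle_amp, gap_amp) {
  if (!is.finite(startle_amp) || startle_amp <= 0)
    stop("undefined index: startle amplitude must be positive",
         call. = FALSE)
  (1 - gap_amp / startle_amp) * 100
}

#' Quantify one startle session
#'
#' Runs the full per-band chain on a recording: filter, slice
#' `[-100, +100)` ms around the pulse marks, average the 9 trials per
#' (band, type), take the Hilbert envelope of the averaged segment, compute
#' baseline-corrected response amplitudes, and form the suppression index.
#' Bands whose startle amplitude is not positive are marked unusable
#' (`index` `NA`, `usable` `FALSE`).
#'
#' @param rec A `session_recording`.
#' @return Data frame with one row per band: `band`, `startle_amp`,
#'   `gap_amp`, `index`, `usable`.
#' @export
analyze_gpias <- function(rec) {
  stopifnot(inherits(rec, "session_recording"))
  trace <- preprocess_trace(rec)
  bands <- unique(rec$schedule$band)
  rows <- lapply(bands, function(b) {
    amps <- vapply(c("startle", "gap"), function(tt) {
      seg <- slice_and_average(trace, rec$ttl_times, rec$schedule,
                               b, tt, rec$fs)
      response_amplitude(instantaneous_amplitude(seg))
    }, numeric(1))
    usable <- is.finite(amps[["startle"]]) && amps[["startle"]] > 0
    data.frame(band = b,
               startle_amp = amps[["startle"]],
               gap_amp = amps[["gap"]],
               index = if (usable) gpias_index(amps[["startle"]],
                                               amps[["gap"]]) else NA_real_,
               usable = usable,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Most affected frequency between two sessions
#'
#' The band with the greatest index drop from the `before` to the `after`
#' session, reported per animal as the behavioral tinnitus frequency. Ties
#' are broken toward the lowest band center (then the lower band edge).
#'
#' @param results_before,results_after Data frames with columns `band` and
#'   `index` covering the same band set (e.g. from [analyze_gpias()]).
#' @return List with `band` (label) and `shift`
#'   (`index_before - index_after`, percentage points).
#' @export
most_affected_frequency <- function(results_before, results_after) {
  if (!setequal(results_before$band, results_after$band))
    stop("sessions cover different band sets", call. = FALSE)
  b <- results_before$band
  shift <- results_before$index -
    results_after$index[match(b, results_after$band)]
  ord <- band_order(b)
  b <- b[ord]; shift <- shift[ord]
  k <- which.max(shift)   # first maximum = lowest center on ties
  list(band = b[k], shift = shift[k])
}

#' Screen an animal for gap-detection capability
#'
#' A band passes when its suppression index is at least `threshold`
#' percent. Animals failing any band are re-tested the next day on the
#' failed bands only; an animal is included when at least two bands pass
#' after the retest stage.
#'
#' @param initial_session Data frame `band`, `index` of the screening
#'   session (all tested bands).
#' @param retest_session Data frame `band`, `index` of the retest, or
#'   `NULL` if no retest was run. Rows for bands that had already passed
#'   are ignored with a warning.
#' @param threshold Pass threshold, percent (default 30).
#' @return List of class `screen_decision`: `pass_by_band` (named logical),
#'   `retested_bands`, `included`.
#' @export
screen_animal <- function(initial_session, retest_session = NULL,
                          threshold = 30) {
  b <- initial_session$band
  pass <- stats::setNames(initial_session$index >= threshold, b)
  pass[is.na(pass)] <- FALSE
  failed <- names(pass)[!pass]
  retested <- character(0)
  if (!is.null(retest_session) && length(failed)) {
    extra <- setdiff(retest_session$band, failed)
    if (length(extra))
      warning("retest covers band(s) that had passed; ignored: ",
              paste(extra, collapse = ", "), call. = FALSE)
    re <- retest_session[retest_session$band %in% failed, , drop = FALSE]
    retested <- re$band
    pass[re$band] <- !is.na(re$index) & re$index >= threshold
  }
  structure(list(pass_by_band = pass,
                 retested_bands = retested,
                 included = sum(pass) >= 2),
            class = "screen_decision")
}
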