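#' Synthesize one startle-session recording
#'
#' Emulates a transducer recording of a startle session: Gaussian sensor
#' noise plus, at every loud-pulse onset, a damped-oscillation startle
#' burst. Gap trials scale the burst by `1 - suppression` for the trial's
#' band; Startle trials use the full amplitude. The burst is a decaying
#' sinusoid (decay constant 30 ms) whose carrier sits inside the sensor's
#' analysis passband: 150 Hz for the piezoelectric sensor (analyzed
#' 70-400 Hz) and 20 Hz for the accelerometer (analyzed below 50 Hz). The
#' accelerometer emits three channels with the burst split across axes.
#' Burst onset coincides with pulse onset (reflex latency is not modeled).
#'
#' @param gt A [ground_truth_animal()] object.
#' @param schedule A [make_gpias_schedule()] schedule covering the bands in
#'   `gt$suppression[[session]]`.
#' @param fs Sampling rate, Hz; at least 2000 for the piezo sensor.
#' @param sensor `"piezo"` (1 channel) or `"accelerometer"` (3 channels).
#' @param seed Integer seed for the noise.
#' @param session Which suppression session to synthesize
#'   (`"pre"`, `"nacl"` or `"cno"`; must name an entry of
#'   `gt$suppression`).
#' @return A `session_recording`: list with `traces` (samples x channels
#'   matrix), `fs`, `ttl_times` (loud-pulse onsets, seconds), `schedule`,
#'   `sensor`, `session` and `ground_truth`.
#' @export
#' @examples
#' gt <- ground_truth_animal(list(pre = c("9-11" = 0.8)), noise_sd = 0)
#' sched <- make_gpias_schedule("9-11", seed = 2)
#' rec <- synth_gpias_session(gt, sched, fs = 2000, seed = 3)
synth_gpias_session <- function(gt, schedule, fs = 3000,
                                sensor = c("piezo", "accelerometer"),
                                seed = 1L, session = "pre") {
  sensor <- match.arg(sensor)
  stopifnot(inherits(gt, "ground_truth_animal"),
            inherits(schedule, "gpias_schedule"))
  if (sensor == "piezo" && fs < 2000)
    stop("piezo emulation needs fs >= 2000 Hz", call. = FALSE)
  supp <- gt$suppression[[session]]
  if (is.null(supp))
    stop("ground truth has no session '", session, "'", call. = FALSE)
  missing_bands <- setdiff(unique(schedule$band), names(supp))
  if (length(missing_bands))
    stop("no suppression ground truth for band(s): ",
         paste(missing_bands, collapse = ", "), call. = FALSE)

  carrier <- switch(sensor, piezo = 150, accelerometer = 20)
  axis_w <- switch(sensor, piezo = 1, accelerometer = c(0.5, 0.35, 0.15))
  nchan <- length(axis_w)

  onset_idx <- round(schedule$pulse_onset_time * fs) + 1L
  ttl_times <- (onset_idx - 1L) / fs           # sample-aligned pulse marks
  n <- max(onset_idx) + round(1.0 * fs)        # 1 s tail after last pulse

  tb <- seq(0, 0.2, by = 1 / fs)
  burst <- sin(2 * pi * carrier * tb) * exp(-tb / 0.03)
  burst <- burst / max(abs(burst))

  traces <- with_seed(seed, {
    m <- matrix(stats::rnorm(n * nchan, sd = gt$noise_sd), n, nchan)
    for (k in seq_len(nrow(schedule))) {
      amp <- gt$startle_peak_amp
      if (schedule$trial_type[k] == "gap")
        amp <- amp * (1 - supp[[schedule$band[k]]])
      idx <- onset_idx[k] + seq_along(burst) - 1L
      keep <- idx <= n
      m[idx[keep], ] <- m[idx[keep], ] +
        outer(burst[keep], axis_w) * amp
    }
    m
  })

  structure(
    list(traces = traces, fs = fs, ttl_times = ttl_times,
         schedule = schedule, sensor = sensor, session = session,
         ground_truth = gt),
    class = "session_recording")
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf(
    "<session_recording> %s, %d ch x %d samples @ %g Hz, %d pulses\n",
    x$sensor, ncol(x$traces), nrow(x$traces), x$fs, length(x$ttl_times)))
  invisible(x)
}
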