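#' Synthesize a single-unit spike train over the sound-stimulation grid
#'
#' Generates an inhomogeneous Poisson spike train for one unit stimulated
#' with the ABR grid: for each band and each intensity (80..35 dBSPL),
#' `n_pulses` short sound pulses at `pulse_rate` Hz. The rate is
#' `baseline_rate` everywhere plus, in the 50 ms after each pulse, an
#' evoked rate
#' `max(0, peak_rate + slope * (I - 80)) * exp(-(center - bf)^2 / (2 sigma^2))`,
#' multiplied by `cno_gain` when `treatment = "CNO"`. Stimulation cells are
#' laid out sequentially with 10 s of silence between intensities.
#'
#' @param gt A [ground_truth_unit()].
#' @param treatment `"NaCl"` or `"CNO"`.
#' @param seed Integer seed.
#' @param bands Band labels of the stimulus grid (default [abr_bands()]).
#' @param intensities Intensity grid, dBSPL (default [abr_intensities()]).
#' @param n_pulses Pulses per (band, intensity) cell (default 529).
#' @param pulse_rate Pulse presentation rate, Hz (default 10).
#' @param evoked_window Evoked-response window after each pulse, seconds.
#' @param unit_id Identifier carried through to outputs.
#' @return A `spike_train`: list with `unit_id`, `times` (sorted, seconds),
#'   `duration`, `treatment`, `depth_mm`, `ttl` (data frame `time`, `band`,
#'   `intensity`) and `ground_truth`.
#' @export
#' @examples
#' u <- ground_truth_unit(bf_khz = 11, sigma_khz = 1, peak_rate = 20)
#' st <- synth_unit_spikes(u, seed = 1, n_pulses = 20)
synth_unit_spikes <- function(gt, treatment = c("NaCl", "CNO"), seed = 1L,
                              bands = abr_bands(),
                              intensities = abr_intensities(),
                              n_pulses = 529, pulse_rate = 10,
                              evoked_window = 0.05,
                              unit_id = "u1") {
  treatment <- match.arg(treatment)
  stopifnot(inherits(gt, "ground_truth_unit"))
  centers <- band_center(bands)
  cell_dur <- n_pulses / pulse_rate
  gap <- 10                                   # silence between intensities
  grid <- expand.grid(intensity = intensities, band = bands,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("band", "intensity")]
  cell_t0 <- (seq_len(nrow(grid)) - 1) * (cell_dur + gap)
  duration <- nrow(grid) * (cell_dur + gap)

  ttl <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    data.frame(time = cell_t0[i] + (seq_len(n_pulses) - 1) / pulse_rate,
               band = grid$band[i], intensity = grid$intensity[i],
               stringsAsFactors = FALSE)
  }))

  gain <- if (treatment == "CNO") gt$cno_gain else 1
  tuning <- exp(-(centers - gt$bf_khz)^2 / (2 * gt$sigma_khz^2))
  names(tuning) <- bands
  evoked_rate <- pmax(0, gt$peak_rate +
                         gt$rate_intensity_slope * (grid$intensity - 80)) *
    tuning[grid$band] * gain

  times <- with_seed(seed, {
    base <- if (gt$baseline_rate > 0) {
      n_base <- stats::rpois(1, gt$baseline_rate * duration)
      stats::runif(n_base, 0, duration)
    } else numeric(0)
    ev <- lapply(seq_len(nrow(grid)), function(i) {
      counts <- stats::rpois(n_pulses, evoked_rate[i] * evoked_window)
      tot <- sum(counts)
      if (tot == 0) return(numeric(0))
      pulse_t <- cell_t0[i] + (seq_len(n_pulses) - 1) / pulse_rate
      rep(pulse_t, counts) + stats::runif(tot, 0, evoked_window)
    })
    sort(c(base, unlist(ev)))
  })

  structure(list(unit_id = unit_id, times = times, duration = duration,
                 treatment = treatment, depth_mm = gt$depth_mm,
                 ttl = ttl, ground_truth = gt),
            class = "spike_train")
}

#' Construct a spike train from an event list
#'
#' Wraps externally detected spike times (e.g. from [detect_events()] or a
#' CSV event list) into the `spike_train` container used by the unit
#' analysis functions.
#'
#' @param times Spike times, seconds.
#' @param duration Recording duration, seconds (> 0).
#' @param unit_id Identifier.
#' @param treatment `"NaCl"` or `"CNO"` (or `NA`).
#' @param ttl Optional TTL map data frame (`time`, `band`, `intensity`).
#' @param depth_mm Recording depth, mm.
#' @return A `spike_train` object.
#' @export
spike_train <- function(times, duration, unit_id = "u1",
                        treatment = NA_character_, ttl = NULL,
                        depth_mm = NA_real_) {
  stopifnot(duration > 0)
  times <- sort(as.numeric(times))
  if (length(times) && (times[1] < 0 || times[length(times)] > duration))
    stop("spike times must lie within [0, duration]", call. = FALSE)
  structure(list(unit_id = unit_id, times = times, duration = duration,
                 treatment = treatment, depth_mm = depth_mm, ttl = ttl,
                 ground_truth = NULL),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %s (%s): %d events over %.1f s\n",
              x$unit_id, x$treatment, length(x$times), x$duration))
  invisible(x)
}
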