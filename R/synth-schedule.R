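#' Build a pseudo-random startle trial schedule
#'
#' Generates the trial timeline of one startle session: per frequency band,
#' 9 Gap-startle trials (40 ms of silence in the background noise, 100 ms
#' before the loud pulse) and 9 Startle trials (noise filling the gap
#' portion), presented in a seeded pseudo-random order. Each trial is
#' preceded by an integer number of seconds of background noise drawn
#' uniformly from 12..22, and consists of 40 ms gap portion, 100 ms
#' background, a 50 ms loud pulse (105 dBSPL) and 510 ms of final
#' background. Timestamp marks exist only for the loud-pulse onset; gap
#' timing is derived from the schedule.
#'
#' @param bands Character vector of band labels (see [gpias_bands()]).
#' @param seed Integer seed for the trial permutation and inter-trial
#'   intervals.
#' @param background_level Background noise level, dBSPL.
#' @param pulse_level Loud-pulse level, dBSPL.
#' @param iti_range Closed integer interval for the inter-trial background
#'   duration, seconds.
#' @return A data frame of class `gpias_schedule` with columns `band`,
#'   `trial_type` (`"gap"` or `"startle"`), `iti_s` and
#'   `pulse_onset_time` (seconds, strictly increasing), plus attributes
#'   `background_level`, `pulse_level` and `fs_free` trial-part durations.
#' @export
#' @examples
#' sched <- make_gpias_schedule(gpias_bands(), seed = 1)
#' nrow(sched)  # 6 bands x 18 trials
make_gpias_schedule <- function(bands,
                                seed = 1L,
                                background_level = 60,
                                pulse_level = 105,
                                iti_range = c(12L, 22L)) {
  if (length(bands) == 0)
    stop("`bands` must name at least one frequency band", call. = FALSE)
  band_edges(bands)  # validates labels
  gap_s <- 0.040; pre_s <- 0.100; pulse_s <- 0.050; post_s <- 0.510
  trials <- expand.grid(band = bands,
                        trial_type = c("gap", "startle"),
                        rep = seq_len(9),
                        KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  with_seed(seed, {
    ord <- sample.int(nrow(trials))
    trials <- trials[ord, c("band", "trial_type")]
    iti <- sample(seq(iti_range[1], iti_range[2]), nrow(trials),
                  replace = TRUE)
  })
  head_s <- iti + gap_s + pre_s                 # start of trial -> pulse onset
  len_s <- head_s + pulse_s + post_s            # full trial duration
  onset <- cumsum(len_s) - pulse_s - post_s     # pulse onset times
  out <- data.frame(band = trials$band,
                    trial_type = trials$trial_type,
                    iti_s = iti,
                    pulse_onset_time = onset,
                    row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(out,
            background_level = background_level,
            pulse_level = pulse_level,
            trial_parts = c(gap = gap_s, pre = pre_s, pulse = pulse_s,
                            post = post_s),
            class = c("gpias_schedule", "data.frame"))
}
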