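# ABR hearing-threshold estimation: SD-rule peak detection and
# cross-intensity latency tracking.

#' Band-limit ABR epochs to 600-1500 Hz
#'
#' Zero-phase 4th-order Butterworth bandpass. Accepts a single trace or a
#' samples x epochs matrix (filtered column-wise). Because the filter is
#' linear and zero-phase, filtering the epoch average equals averaging
#' filtered epochs.
#'
#' @param epochs Numeric vector or samples x epochs matrix.
#' @param fs Sampling rate, Hz; must exceed 3000.
#' @return Filtered object of the same shape.
#' @export
filter_epochs <- function(epochs, fs) {
  if (fs <= 3000)
    stop("fs must exceed 3000 Hz for the 600-1500 Hz band", call. = FALSE)
  zp_butter(epochs, fs, c(600, 1500), "pass")
}

#' Average an epoch stack
#'
#' Point-wise mean across epochs.
#'
#' @param epochs Samples x epochs matrix (or a list of equal-length
#'   vectors).
#' @return Numeric vector: the averaged trace.
#' @export
average_epochs <- function(epochs) {
  if (is.list(epochs)) {
    if (length(unique(lengths(epochs))) != 1)
      stop("ragged epochs", call. = FALSE)
    epochs <- do.call(cbind, epochs)
  }
  if (!is.matrix(epochs)) epochs <- matrix(epochs, ncol = 1)
  rowMeans(epochs)
}

#' Detect response peaks in an averaged ABR trace
#'
#' A sample is a peak when it exceeds the trace mean by one standard
#' deviation, is larger than the previous sample and larger than or equal
#' to the next (so the left edge of a flat plateau counts). Mean and SD are
#' computed over the full 12-ms trace. On a constant trace the SD is zero
#' and the strict comparisons fail, so no peaks are returned.
#'
#' @param trace Averaged (filtered) trace covering `[-3, +9)` ms.
#' @param fs Sampling rate, Hz.
#' @param t0_ms Time of the first sample relative to pulse onset, ms.
#' @return Data frame `latency_ms`, `height` (value minus trace mean),
#'   `index`; zero rows when nothing qualifies.
#' @export
detect_peaks <- function(trace, fs, t0_ms = -3) {
  n <- length(trace)
  if (n < 3) stop("trace too short for peak detection", call. = FALSE)
  m <- mean(trace)
  th <- m + stats::sd(trace)
  i <- 2:(n - 1)
  idx <- i[trace[i] > th & trace[i] > trace[i - 1] &
             trace[i] >= trace[i + 1]]
  data.frame(latency_ms = t0_ms + (idx - 1) / fs * 1000,
             height = trace[idx] - m,
             index = idx)
}

#' Track valid peaks across intensities and estimate the hearing threshold
#'
#' Peaks detected at the highest intensity seed the tracks. At each lower
#' intensity a candidate peak is valid when it (a) passes the SD rule on
#' its own trace ([detect_peaks()]), (b) has a latency greater than a
#' predecessor peak at the intensity 5 dB above, by at most
#' `latency_tolerance` ms, and (c) retains at least `min_height_ratio` of
#' that predecessor's height (wave amplitude shrinks gradually with
#' intensity; an abrupt collapse marks a spurious noise maximum, whose
#' continuation would otherwise be scale-free). The hearing threshold is
#' the lowest intensity holding at least one valid peak; a valid peak at
#' the lowest tested intensity yields the floor sentinel (`at_floor`,
#' reported as `<= 35` dBSPL).
#'
#' @param avgs Named list of averaged filtered traces, one per intensity,
#'   ordered 80 down to 35 dBSPL in 5-dB steps.
#' @param fs Sampling rate, Hz.
#' @param latency_tolerance Maximum latency increase per 5-dB step, ms.
#' @param min_height_ratio Minimum height retained relative to the matched
#'   predecessor peak.
#' @param t0_ms Time of the first sample relative to pulse onset, ms.
#' @return List of class `abr_threshold_result`: `threshold` (dBSPL),
#'   `at_floor` (logical sentinel), `tracks` (named list of per-intensity
#'   valid-peak data frames).
#' @export
track_threshold <- function(avgs, fs, latency_tolerance = 0.5,
                            min_height_ratio = 0.5, t0_ms = -3) {
  ints <- as.numeric(names(avgs))
  if (is.null(names(avgs)) || any(is.na(ints)))
    stop("`avgs` must be named by intensity", call. = FALSE)
  if (any(diff(ints) != -5) || ints[1] != 80)
    stop("intensities must form the descending 5-dB grid starting at 80",
         call. = FALSE)
  cur <- detect_peaks(avgs[[1]], fs, t0_ms)
  if (nrow(cur) == 0)
    stop("no response: no peaks detected at the highest intensity",
         call. = FALSE)
  tracks <- stats::setNames(vector("list", length(ints)),
                            as.character(ints))
  tracks[[1]] <- cur
  threshold <- ints[1]
  for (j in seq_along(ints)[-1]) {
    cand <- detect_peaks(avgs[[j]], fs, t0_ms)
    if (nrow(cand) == 0) break
    valid <- vapply(seq_len(nrow(cand)), function(r) {
      any(cand$latency_ms[r] > cur$latency_ms &
            cand$latency_ms[r] <= cur$latency_ms + latency_tolerance &
            cand$height[r] >= min_height_ratio * cur$height)
    }, logical(1))
    if (!any(valid)) break
    cur <- cand[valid, , drop = FALSE]
    tracks[[j]] <- cur
    threshold <- ints[j]
  }
  structure(list(threshold = threshold,
                 at_floor = threshold == ints[length(ints)],
                 tracks = Filter(Negate(is.null), tracks)),
            class = "abr_threshold_result")
}

#' @export
print.abr_threshold_result <- function(x, ...) {
  cat(sprintf("<abr_threshold_result> threshold %s%g dBSPL\n",
              if (x$at_floor) "<= " else "", x$threshold))
  invisible(x)
}

#' Wave-1 amplitude and growth function
#'
#' Wave 1 is the earliest-latency valid peak at each tracked intensity.
#' Its amplitude is the peak height above the trace mean (the same
#' statistic the detector thresholds on); the growth function is the
#' per-intensity amplitude divided by the amplitude at 80 dBSPL.
#'
#' @param tracks An `abr_threshold_result` (see [track_threshold()]).
#' @return Data frame `intensity`, `amplitude`, `normalized` (1 at
#'   80 dBSPL by construction).
#' @export
wave1_metrics <- function(tracks) {
  stopifnot(inherits(tracks, "abr_threshold_result"))
  if (is.null(tracks$tracks[["80"]]))
    stop("missing 80 dBSPL track", call. = FALSE)
  ints <- as.numeric(names(tracks$tracks))
  amp <- vapply(tracks$tracks, function(pk) {
    pk$height[which.min(pk$latency_ms)]
  }, numeric(1))
  data.frame(intensity = ints,
             amplitude = unname(amp),
             normalized = unname(amp / amp[["80"]]))
}

#' Estimate the hearing threshold of one ABR stack
#'
#' Full chain on a synthetic or recorded stack: per intensity, average the
#' epochs and band-limit the average (equivalent to filtering each epoch
#' first), then track peaks across intensities and extract wave-1 metrics.
#'
#' @param stack An `abr_stack` (see [synth_abr_stack()]).
#' @param ... Passed to [track_threshold()].
#' @return List: `threshold` (the `abr_threshold_result`), `wave1`
#'   (data frame), `averages` (named list of averaged filtered traces).
#' @export
analyze_abr <- function(stack, ...) {
  stopifnot(inherits(stack, "abr_stack"))
  avgs <- lapply(stack$epochs, function(ep)
    filter_epochs(average_epochs(ep), stack$fs))
  thr <- track_threshold(avgs, stack$fs, ...)
  list(threshold = thr, wave1 = wave1_metrics(thr), averages = avgs)
}
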