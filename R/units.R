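# Unit analysis: event detection, PSTH, frequency-response areas, tuning
# features and treatment comparisons.

#' Threshold-based spike event detection
#'
#' Simple single-unit surrogate for template-matching sorters: the trace is
#' band-limited (500-14250 Hz, zero-phase 4th-order Butterworth), and an
#' event is registered at every local minimum below `-k` times the trace
#' SD, with a 1-ms refractory lockout after each accepted event.
#'
#' @param trace Raw extracellular channel, numeric vector.
#' @param fs Sampling rate, Hz; must exceed 29000.
#' @param k Threshold in SD multiples, within the conventional 2..4.5
#'   range.
#' @param filter Band-limit before detection (default `TRUE`; set `FALSE`
#'   for an already filtered trace).
#' @return Numeric vector of event times, seconds.
#' @export
detect_events <- function(trace, fs, k = 4.5, filter = TRUE) {
  if (k < 2 || k > 4.5)
    stop("`k` must lie within [2, 4.5]", call. = FALSE)
  if (fs <= 29000)
    stop("fs must exceed 29 kHz for the 500-14250 Hz band", call. = FALSE)
  x <- if (filter) zp_butter(trace, fs, c(500, 14250), "pass") else trace
  s <- stats::sd(x)
  if (s == 0) return(numeric(0))
  n <- length(x)
  i <- 2:(n - 1)
  mins <- i[x[i] < -k * s & x[i] < x[i - 1] & x[i] <= x[i + 1]]
  if (!length(mins)) return(numeric(0))
  lock <- max(1L, round(0.001 * fs))
  keep <- mins[1]
  for (m in mins[-1]) if (m - keep[length(keep)] >= lock) keep <- c(keep, m)
  (keep - 1) / fs
}

#' Peri-stimulus time histogram
#'
#' Counts spikes in 100 one-millisecond bins covering `[-50, +50)` ms
#' around each TTL mark, summed over all TTLs. Bin `b` covers
#' `[-50 + b - 1, -50 + b)` ms. TTL windows must not overlap (guaranteed at
#' the 10-Hz stimulation rate).
#'
#' @param train A `spike_train`.
#' @param ttl_times TTL times, seconds (default: the train's own TTL map).
#' @return Object of class `psth`: list with `counts` (length 100),
#'   `breaks_ms` (length 101) and `n_ttl`.
#' @export
psth <- function(train, ttl_times = NULL) {
  stopifnot(inherits(train, "spike_train"))
  if (is.null(ttl_times)) ttl_times <- train$ttl$time
  ttl_times <- sort(ttl_times)
  if (length(ttl_times) > 1 && any(diff(ttl_times) < 0.1))
    stop("TTL windows overlap (spacing < 100 ms)", call. = FALSE)
  counts <- integer(100)
  if (length(train$times)) {
    idx <- findInterval(train$times, ttl_times - 0.05)
    ok <- idx >= 1
    ok[ok] <- train$times[ok] < ttl_times[idx[ok]] + 0.05
    off_ms <- (train$times[ok] - ttl_times[idx[ok]]) * 1000
    b <- floor(off_ms) + 51L          # bin 1 covers [-50, -49) ms
    b[b > 100L] <- 100L               # guard against fp edge at +50 ms
    counts <- tabulate(b, nbins = 100L)
  }
  structure(list(counts = counts, breaks_ms = seq(-50, 50, by = 1),
                 n_ttl = length(ttl_times)),
            class = "psth")
}

#' Overall firing rate
#'
#' Spike events per second over the whole recording, stimulation period
#' included.
#'
#' @param train A `spike_train`.
#' @return Rate, Hz.
#' @export
overall_rate <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  if (train$duration <= 0) stop("zero recording duration", call. = FALSE)
  length(train$times) / train$duration
}

#' Frequency-response area of a unit
#'
#' For every (band, intensity) cell of the stimulus grid, the firing rate
#' in the evoked window (`[0, +window)` s after each pulse) pooled over the
#' cell's pulses: total in-window spikes divided by total window time.
#'
#' @param train A `spike_train` whose `ttl` map labels each pulse with
#'   `band` and `intensity`.
#' @param window Evoked window, seconds (default 0.05, the post half of
#'   the PSTH).
#' @return Object of class `fra`: rate matrix bands x intensities with
#'   `dimnames`, plus attributes `band_centers` and `intensities`
#'   (descending).
#' @export
build_fra <- function(train, window = 0.05) {
  stopifnot(inherits(train, "spike_train"))
  ttl <- train$ttl
  if (is.null(ttl)) stop("train carries no TTL map", call. = FALSE)
  bands <- unique(ttl$band)
  ints <- sort(unique(ttl$intensity), decreasing = TRUE)
  tt <- sort(ttl$time)
  hit <- integer(nrow(ttl))
  if (length(train$times)) {
    idx <- findInterval(train$times, tt)
    ok <- idx >= 1
    ok[ok] <- train$times[ok] - tt[idx[ok]] < window
    hit <- tabulate(idx[ok], nbins = length(tt))
  }
  # map counts back onto the (possibly unsorted) ttl rows
  counts <- hit[match(ttl$time, tt)]
  m <- matrix(NA_real_, length(bands), length(ints),
              dimnames = list(bands, as.character(ints)))
  for (b in bands) for (I in ints) {
    sel <- ttl$band == b & ttl$intensity == I
    if (any(sel)) m[b, as.character(I)] <- sum(counts[sel]) /
        (sum(sel) * window)
  }
  structure(m, band_centers = band_center(bands), intensities = ints,
            class = c("fra", "matrix", "array"))
}

#' Bilinear 3x upsampling of a frequency-response area
#'
#' Upsamples the rate grid by `factor` in both dimensions using bilinear
#' interpolation on pixel-centered coordinates, so every original node
#' reappears unchanged at an aligned position and all values stay within
#' the input range (edges are clamped). Intended for pseudocolor display;
#' tuning statistics are computed on the raw grid.
#'
#' @param fra An `fra` grid (see [build_fra()]).
#' @param factor Integer upsampling factor per dimension (default 3).
#' @return Numeric matrix `factor * nrow` x `factor * ncol`.
#' @export
upsample_fra <- function(fra, factor = 3L) {
  m <- unclass(fra)
  if (any(is.na(m))) stop("grid has absent cells", call. = FALSE)
  nr <- nrow(m); nc <- ncol(m)
  ro <- (seq_len(factor * nr) - 0.5) / factor + 0.5
  co <- (seq_len(factor * nc) - 0.5) / factor + 0.5
  ro <- pmin(pmax(ro, 1), nr)         # clamp: replicate edges
  co <- pmin(pmax(co, 1), nc)
  g <- expand.grid(r = ro, c = co)
  v <- pracma::interp2(x = seq_len(nc), y = seq_len(nr), Z = m,
                       xp = g$c, yp = g$r, method = "linear")
  matrix(v, length(ro), length(co))
}

# rate profile across bands at the reference intensity (80 dBSPL)
fra_top_row <- function(fra, intensity = 80) {
  col <- as.character(intensity)
  if (!col %in% colnames(fra))
    stop("grid lacks the ", intensity, " dBSPL column", call. = FALSE)
  r <- unclass(fra)[, col]
  if (any(is.na(r))) stop("grid has absent cells at ", intensity, " dBSPL",
                          call. = FALSE)
  r
}

#' Tuning width of a unit
#'
#' Mean of the max-normalized firing rates across the tested bands at
#' 80 dBSPL, computed on the raw grid. 1 means a flat (broad) profile;
#' values near `1/n_bands` mean sharp tuning. Undefined when no band
#' responds.
#'
#' @param fra An `fra` grid.
#' @return Tuning width in `(0, 1]`.
#' @export
#' @examples
#' # one-hot profile over 5 bands -> 0.2; flat profile -> 1
tuning_width <- function(fra) {
  r <- fra_top_row(fra)
  mx <- max(r)
  if (mx <= 0) stop("undefined tuning: all-zero 80 dBSPL row",
                    call. = FALSE)
  mean(r / mx)
}

#' Best frequency of a unit
#'
#' Center of the band eliciting the highest firing rate at 80 dBSPL; ties
#' go to the lowest band center.
#'
#' @param fra An `fra` grid.
#' @return Best frequency, kHz.
#' @export
best_frequency <- function(fra) {
  r <- fra_top_row(fra)
  if (max(r) <= 0) stop("undefined best frequency: all-zero 80 dBSPL row",
                        call. = FALSE)
  centers <- attr(fra, "band_centers")
  ord <- order(centers)
  r <- r[ord]; centers <- centers[ord]
  centers[which.max(r)]
}

#' Per-unit feature set
#'
#' Firing rate at 80 dBSPL at the unit's best frequency, tuning width and
#' best frequency, from the unit's frequency-response area.
#'
#' @param train A `spike_train` with a TTL map, or an `fra` grid.
#' @return List `firing_rate` (Hz), `tuning_width`, `best_frequency`
#'   (kHz).
#' @export
unit_features <- function(train) {
  fra <- if (inherits(train, "fra")) train else build_fra(train)
  r <- fra_top_row(fra)
  bf <- best_frequency(fra)
  centers <- attr(fra, "band_centers")
  list(firing_rate = unname(r[which(centers == bf)[1]]),
       tuning_width = tuning_width(fra),
       best_frequency = bf)
}

#' Classify per-feature change between treatments
#'
#' Sign of (CNO - NaCl) per feature: negative is `"decreased"`, positive
#' `"increased"`, an exact tie `"no_change"` (genuine for best frequency on
#' the discrete band grid).
#'
#' @param features_nacl,features_cno Feature lists from [unit_features()]
#'   (or any named numeric lists with common names).
#' @return Named character vector of labels.
#' @export
classify_change <- function(features_nacl, features_cno) {
  nm <- intersect(names(features_nacl), names(features_cno))
  if (!length(nm)) stop("no common features", call. = FALSE)
  vapply(nm, function(f) {
    d <- features_cno[[f]] - features_nacl[[f]]
    if (is.na(d)) NA_character_
    else if (d < 0) "decreased"
    else if (d > 0) "increased"
    else "no_change"
  }, character(1))
}

#' Classify a unit as sound-responding
#'
#' Surrogate responder criterion (a package-defined stand-in for external
#' responder-classification methods): per stimulus pulse, spikes are
#' counted in the pre-window (`[-window, 0)` s) and post-window
#' (`[0, +window)` s); the unit responds when the post counts exceed the
#' pre counts in a one-sided paired Wilcoxon signed-rank test at level
#' `alpha`.
#'
#' @param train A `spike_train` with a TTL map.
#' @param window Half-window, seconds (default 0.05).
#' @param alpha Significance level.
#' @return List: `responding` (logical), `p`, `mean_pre`, `mean_post`
#'   (counts per pulse).
#' @export
responding_unit <- function(train, window = 0.05, alpha = 0.05) {
  stopifnot(inherits(train, "spike_train"))
  if (is.null(train$ttl)) stop("train carries no TTL map", call. = FALSE)
  tt <- sort(train$ttl$time)
  count_in <- function(lo, hi) {
    idx <- findInterval(train$times, lo)
    ok <- idx >= 1
    ok[ok] <- train$times[ok] < hi[idx[ok]]
    tabulate(idx[ok], nbins = length(lo))
  }
  pre <- count_in(tt - window, tt)
  post <- count_in(tt, tt + window)
  if (all(pre == post))
    return(list(responding = FALSE, p = 1, mean_pre = mean(pre),
                mean_post = mean(post)))
  wt <- suppressWarnings(stats::wilcox.test(post, pre, paired = TRUE,
                                            alternative = "greater",
                                            exact = FALSE))
  list(responding = wt$p.value < alpha, p = wt$p.value,
       mean_pre = mean(pre), mean_post = mean(post))
}

#' Pairwise Pearson correlations between unit features
#'
#' Pearson r and the p-value testing non-correlation for every feature
#' pair, Bonferroni-corrected across the comparisons made (corrected p
#' capped at 1). Zero-variance features give undefined r, reported as
#' `NA`.
#'
#' @param features Data frame of per-unit features (numeric columns).
#' @param columns Which columns to correlate (default: all numeric).
#' @param bonferroni_m Correction family size; default the number of pairs
#'   computed here.
#' @return Data frame `feature_a`, `feature_b`, `r`, `p`, `p_corrected`.
#' @export
feature_correlations <- function(features, columns = NULL,
                                 bonferroni_m = NULL) {
  if (is.null(columns))
    columns <- names(features)[vapply(features, is.numeric, logical(1))]
  if (length(columns) < 2) stop("need at least two features", call. = FALSE)
  if (nrow(features) < 3) stop("need n >= 3 observations", call. = FALSE)
  pairs <- utils::combn(columns, 2)
  m <- if (is.null(bonferroni_m)) ncol(pairs) else bonferroni_m
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- features[[pairs[1, j]]]; b <- features[[pairs[2, j]]]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      r <- NA_real_; p <- NA_real_
    } else {
      ct <- stats::cor.test(a, b, method = "pearson")
      r <- unname(ct$estimate); p <- ct$p.value
    }
    data.frame(feature_a = pairs[1, j], feature_b = pairs[2, j],
               r = r, p = p, p_corrected = pmin(1, m * p),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
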