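# internal helpers shared across modules

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded generators do not
#' disturb the caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

#' Frequency bands used in the startle protocol
#'
#' The six narrow-band noise bands of the behavioral test. Labels are
#' `"<lo>-<hi>"` in kHz.
#'
#' @return Character vector of band labels.
#' @export
#' @examples
#' gpias_bands()
gpias_bands <- function() {
  c("8-10", "9-11", "10-12", "12-14", "14-16", "8-18")
}

#' Frequency bands used for brainstem-response and unit stimulation
#'
#' Same as [gpias_bands()] without the wide 8-18 kHz band.
#'
#' @return Character vector of band labels.
#' @export
abr_bands <- function() {
  c("8-10", "9-11", "10-12", "12-14", "14-16")
}

#' Stimulus intensity grid, 80 down to 35 dBSPL in 5-dB steps
#' @return Numeric vector of intensities (dBSPL), descending.
#' @export
abr_intensities <- function() {
  seq(80, 35, by = -5)
}

#' Band edges and center
#'
#' Parses a `"lo-hi"` kHz band label. The reported band center is the
#' arithmetic midpoint of the edges (e.g. 12-14 kHz -> 13 kHz).
#'
#' @param band Character vector of band labels.
#' @return For `band_edges()`, a 2-column matrix (lo, hi); for
#'   `band_center()`, a numeric vector in kHz.
#' @export
#' @examples
#' band_center("12-14")
band_edges <- function(band) {
  parts <- strsplit(as.character(band), "-", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("malformed band label(s): ",
                     paste(band[bad], collapse = ", "), call. = FALSE)
  m <- t(vapply(parts, function(p) as.numeric(p), numeric(2)))
  if (any(!is.finite(m))) stop("non-numeric band edges", call. = FALSE)
  colnames(m) <- c("lo", "hi")
  m
}

#' @rdname band_edges
#' @export
band_center <- function(band) {
  e <- band_edges(band)
  unname((e[, "lo"] + e[, "hi"]) / 2)
}

# order bands by center, then by lower edge (deterministic tie-break)
band_order <- function(band) {
  e <- band_edges(band)
  order(band_center(band), e[, "lo"])
}

# zero-phase 4th-order Butterworth, vector or column-wise on a matrix
zp_butter <- function(x, fs, w, type) {
  stopifnot(is.numeric(fs), fs > 0)
  if (any(w >= fs / 2))
    stop("filter corner frequency at or above Nyquist (fs = ", fs, " Hz)",
         call. = FALSE)
  flt <- signal::butter(4, w / (fs / 2), type = type)
  if (is.matrix(x)) apply(x, 2, function(col) signal::filtfilt(flt, col))
  else signal::filtfilt(flt, x)
}
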