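# Recording containers: one little-endian binary array file per channel
# plus a JSON sidecar with sampling metadata, TTLs, schedule and ground
# truth. Traces are stored as float32 (quantized on first write); event
# times and TTLs are kept at full float64/JSON precision.

write_f32 <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(x), con, size = 4, endian = "little")
}

read_f32 <- function(path, n) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "numeric", n = n, size = 4, endian = "little")
}

gt_animal_to_list <- function(gt) {
  if (is.null(gt)) return(NULL)
  list(type = "animal",
       suppression = lapply(gt$suppression, as.list),
       startle_peak_amp = gt$startle_peak_amp,
       threshold_by_band = as.list(gt$threshold_by_band),
       noise_sd = gt$noise_sd)
}

list_to_gt_animal <- function(l) {
  if (is.null(l)) return(NULL)
  thr <- unlist(l$threshold_by_band)
  ground_truth_animal(
    suppression = lapply(l$suppression, unlist),
    startle_peak_amp = l$startle_peak_amp,
    threshold_by_band = if (length(thr)) thr else NULL,
    noise_sd = l$noise_sd)
}

#' Write a recording container to disk
#'
#' Serializes a `session_recording`, `abr_stack` or `spike_train` into a
#' directory holding little-endian float32 array files (one per channel or
#' intensity) plus a `sidecar.json` with all metadata. Spike times are
#' stored as float64.
#'
#' @param x The recording object.
#' @param dir Target directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_recording <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  UseMethod("write_recording")
}

#' @export
write_recording.session_recording <- function(x, dir) {
  for (ch in seq_len(ncol(x$traces)))
    write_f32(x$traces[, ch], file.path(dir, sprintf("ch%02d.bin", ch)))
  sched <- as.data.frame(x$schedule)
  side <- list(kind = "session_recording", fs = x$fs, sensor = x$sensor,
               session = x$session, n_samples = nrow(x$traces),
               n_channels = ncol(x$traces), ttl_times = x$ttl_times,
               schedule = sched,
               background_level = attr(x$schedule, "background_level"),
               pulse_level = attr(x$schedule, "pulse_level"),
               ground_truth = gt_animal_to_list(x$ground_truth))
  jsonlite::write_json(side, file.path(dir, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @export
write_recording.abr_stack <- function(x, dir) {
  for (nm in names(x$epochs))
    write_f32(x$epochs[[nm]], file.path(dir, sprintf("int%s.bin", nm)))
  side <- list(kind = "abr_stack", band = x$band, fs = x$fs,
               intensities = x$intensities,
               n_samples = nrow(x$epochs[[1]]),
               n_epochs = ncol(x$epochs[[1]]),
               ground_truth = gt_animal_to_list(x$ground_truth))
  jsonlite::write_json(side, file.path(dir, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @export
write_recording.spike_train <- function(x, dir) {
  con <- file(file.path(dir, "times.bin"), "wb")
  writeBin(as.numeric(x$times), con, size = 8, endian = "little")
  close(con)
  if (!is.null(x$ttl))
    utils::write.csv(x$ttl, file.path(dir, "ttl.csv"), row.names = FALSE)
  side <- list(kind = "spike_train", unit_id = x$unit_id,
               duration = x$duration, treatment = x$treatment,
               depth_mm = x$depth_mm, n_events = length(x$times))
  jsonlite::write_json(side, file.path(dir, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a recording container from disk
#'
#' Counterpart of [write_recording()]; the container kind is taken from
#' the sidecar.
#'
#' @param dir Container directory.
#' @return The deserialized recording object.
#' @export
read_recording <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "sidecar.json"),
                              simplifyVector = TRUE)
  switch(
    side$kind,
    session_recording = {
      traces <- vapply(seq_len(side$n_channels), function(ch)
        read_f32(file.path(dir, sprintf("ch%02d.bin", ch)), side$n_samples),
        numeric(side$n_samples))
      sched <- as.data.frame(side$schedule, stringsAsFactors = FALSE)
      sched <- structure(sched,
                         background_level = side$background_level,
                         pulse_level = side$pulse_level,
                         trial_parts = c(gap = 0.04, pre = 0.1,
                                         pulse = 0.05, post = 0.51),
                         class = c("gpias_schedule", "data.frame"))
      structure(list(traces = traces, fs = side$fs,
                     ttl_times = side$ttl_times, schedule = sched,
                     sensor = side$sensor, session = side$session,
                     ground_truth = list_to_gt_animal(side$ground_truth)),
                class = "session_recording")
    },
    abr_stack = {
      eps <- lapply(side$intensities, function(I) {
        matrix(read_f32(file.path(dir, sprintf("int%d.bin", I)),
                        side$n_samples * side$n_epochs),
               side$n_samples, side$n_epochs)
      })
      names(eps) <- as.character(side$intensities)
      structure(list(band = side$band, fs = side$fs,
                     intensities = side$intensities, epochs = eps,
                     ground_truth = list_to_gt_animal(side$ground_truth)),
                class = "abr_stack")
    },
    spike_train = {
      con <- file(file.path(dir, "times.bin"), "rb")
      times <- readBin(con, "numeric", n = side$n_events, size = 8,
                       endian = "little")
      close(con)
      ttl_path <- file.path(dir, "ttl.csv")
      ttl <- if (file.exists(ttl_path))
        utils::read.csv(ttl_path, stringsAsFactors = FALSE) else NULL
      structure(list(unit_id = side$unit_id, times = times,
                     duration = side$duration, treatment = side$treatment,
                     depth_mm = side$depth_mm, ttl = ttl,
                     ground_truth = NULL),
                class = "spike_train")
    },
    stop("unknown container kind: ", side$kind, call. = FALSE))
}
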