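# End-to-end orchestration mirroring the experimental timeline:
# screening -> ABR (before) -> noise exposure -> ABR (after) ->
# GPIAS under NaCl -> GPIAS under CNO -> unit recordings (NaCl, CNO).

#' Pipeline configuration
#'
#' Collects the knobs of a synthetic end-to-end run. Defaults emulate the
#' study conditions at desk scale: a small cohort, two frequency bands,
#' strong pre-exposure suppression that collapses after exposure under
#' vehicle and partially recovers under CNO, unchanged hearing thresholds,
#' and chemogenetically halved evoked unit rates.
#'
#' @param seed Master seed; all per-stage seeds derive from it.
#' @param n_animals Cohort size.
#' @param bands Frequency bands simulated (GPIAS, ABR and units).
#' @param fs_gpias,fs_abr Sampling rates, Hz.
#' @param sensor Startle transducer kind.
#' @param noise_sd_gpias Startle-trace noise SD (fraction of the unit
#'   burst amplitude).
#' @param noise_sd_abr Per-epoch ABR noise SD.
#' @param suppression_pre,suppression_nacl,suppression_cno Length-2 ranges
#'   the per-animal, per-band suppression is drawn from for each session.
#' @param cno_gain Multiplicative evoked-rate factor under CNO.
#' @param n_epochs ABR epochs per intensity.
#' @param run_abr,run_post_gpias,run_units Stage switches; post-exposure
#'   GPIAS needs the ABR stage (its background level is set 10 dBSPL above
#'   the animal's hearing threshold).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            n_animals = 2L,
                            bands = c("9-11", "10-12"),
                            fs_gpias = 2000,
                            fs_abr = 30000,
                            sensor = "piezo",
                            noise_sd_gpias = 0.1,
                            noise_sd_abr = 0.5,
                            suppression_pre = c(0.72, 0.88),
                            suppression_nacl = c(0.0, 0.08),
                            suppression_cno = c(0.22, 0.42),
                            cno_gain = 0.5,
                            n_epochs = 529,
                            run_abr = TRUE,
                            run_post_gpias = TRUE,
                            run_units = TRUE) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(config), tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

#' Run the synthetic end-to-end experiment
#'
#' Draws a seeded cohort, then executes the experimental timeline:
#' gap-detection screening, pre-exposure ABR, noise exposure (a ground
#' truth event: suppression collapses), post-exposure ABR, post-exposure
#' GPIAS under NaCl and under CNO (background level wired to 10 dBSPL
#' above the animal's tracked hearing threshold), and unit recordings
#' under both treatments. All randomness derives from `config$seed`, so a
#' fixed configuration reproduces bit-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out Optional directory; when given, result tables are written as
#'   CSV and the run log as JSON.
#' @return List of class `pipeline_result`: `gpias` (animal x session x
#'   band index table), `screening`, `abr` (thresholds before/after),
#'   `most_affected`, `units` (per-unit features and change classes),
#'   `log` (config echo, hash, stage timestamps, package version).
#' @export
run_experiment <- function(config = pipeline_config(), out = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (config$run_post_gpias && !config$run_abr)
    stop("post-exposure GPIAS requires the ABR stage: its background ",
         "level is 10 dBSPL above the tracked hearing threshold",
         call. = FALSE)
  log <- list(started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              version = as.character(utils::packageVersion("tinnipipe")),
              config_hash = config_hash(config), stages = character(0))
  stage <- function(nm) log$stages <<- c(log$stages, nm)
  seed0 <- as.integer(config$seed)
  bands <- config$bands

  # seeded cohort ground truth
  cohort <- with_seed(seed0, lapply(seq_len(config$n_animals), function(a) {
    draw <- function(rg) stats::setNames(
      stats::runif(length(bands), rg[1], rg[2]), bands)
    ground_truth_animal(
      suppression = list(pre = draw(config$suppression_pre),
                         nacl = draw(config$suppression_nacl),
                         cno = draw(config$suppression_cno)),
      threshold_by_band = stats::setNames(
        sample(seq(35, 50, by = 5), length(bands), replace = TRUE), bands),
      noise_sd = config$noise_sd_gpias)
  }))

  gpias_rows <- list(); screen_rows <- list(); abr_rows <- list()
  maf_rows <- list(); unit_rows <- list()

  run_gpias <- function(gt, a, session, background, seed) {
    sched <- make_gpias_schedule(bands, seed = seed,
                                 background_level = background)
    rec <- synth_gpias_session(gt, sched, fs = config$fs_gpias,
                               sensor = config$sensor, seed = seed + 1L,
                               session = session)
    res <- analyze_gpias(rec)
    cbind(animal = a, session = session, res,
          background_level = background)
  }

  for (a in seq_len(config$n_animals)) {
    gt <- cohort[[a]]
    base_seed <- seed0 + 1000L * a

    # screening (pre-exposure, 60 dBSPL background)
    pre <- run_gpias(gt, a, "pre", 60, base_seed)
    gpias_rows[[length(gpias_rows) + 1]] <- pre
    dec <- screen_animal(pre[, c("band", "index")])
    screen_rows[[length(screen_rows) + 1]] <-
      data.frame(animal = a, included = dec$included,
                 n_pass = sum(dec$pass_by_band))
    stage(sprintf("screen:%d", a))

    thr_after <- NULL
    if (config$run_abr) {
      gt_abr <- gt
      gt_abr$noise_sd <- config$noise_sd_abr
      for (phase in c("before", "after")) {
        for (b in bands) {
          stk <- synth_abr_stack(gt_abr, b,
                                 seed = base_seed +
                                   10L * match(b, bands) +
                                   (phase == "after"),
                                 fs = config$fs_abr,
                                 n_epochs = config$n_epochs)
          res <- analyze_abr(stk)
          abr_rows[[length(abr_rows) + 1]] <- data.frame(
            animal = a, phase = phase, band = b,
            threshold = res$threshold$threshold,
            at_floor = res$threshold$at_floor,
            wave1_at_80 = res$wave1$amplitude[res$wave1$intensity == 80])
          if (phase == "after")
            thr_after <- c(thr_after,
                           stats::setNames(res$threshold$threshold, b))
        }
        stage(sprintf("abr_%s:%d", phase, a))
      }
    }

    stage(sprintf("noise_exposure:%d", a))

    if (config$run_post_gpias) {
      # background wired to 10 dBSPL above the per-animal threshold
      bg <- max(thr_after) + 10
      for (session in c("nacl", "cno")) {
        res <- run_gpias(gt, a, session, bg,
                         base_seed + 100L + 7L * (session == "cno"))
        gpias_rows[[length(gpias_rows) + 1]] <- res
        stage(sprintf("gpias_%s:%d", session, a))
      }
      gp <- do.call(rbind, gpias_rows)
      gp <- gp[gp$animal == a, ]
      maf <- most_affected_frequency(
        gp[gp$session == "pre", c("band", "index")],
        gp[gp$session == "nacl", c("band", "index")])
      maf_rows[[length(maf_rows) + 1]] <-
        data.frame(animal = a, band = maf$band, shift = maf$shift)
    }

    if (config$run_units) {
      u <- with_seed(base_seed + 500L, ground_truth_unit(
        bf_khz = stats::runif(1, 9, 15),
        sigma_khz = stats::runif(1, 1, 2.5),
        peak_rate = stats::runif(1, 18, 30),
        baseline_rate = 1,
        cno_gain = config$cno_gain))
      feats <- lapply(c("NaCl", "CNO"), function(tr) {
        st <- synth_unit_spikes(u, treatment = tr,
                                seed = base_seed + 600L + (tr == "CNO"),
                                bands = bands,
                                unit_id = sprintf("a%d_u1", a))
        unit_features(st)
      })
      names(feats) <- c("NaCl", "CNO")
      cls <- classify_change(feats$NaCl, feats$CNO)
      unit_rows[[length(unit_rows) + 1]] <- data.frame(
        animal = a, unit_id = sprintf("a%d_u1", a),
        fr_nacl = feats$NaCl$firing_rate, fr_cno = feats$CNO$firing_rate,
        tw_nacl = feats$NaCl$tuning_width, tw_cno = feats$CNO$tuning_width,
        bf_nacl = feats$NaCl$best_frequency,
        bf_cno = feats$CNO$best_frequency,
        fr_change = cls[["firing_rate"]],
        stringsAsFactors = FALSE)
      stage(sprintf("units:%d", a))
    }
  }

  res <- structure(
    list(gpias = do.call(rbind, gpias_rows),
         screening = do.call(rbind, screen_rows),
         abr = if (length(abr_rows)) do.call(rbind, abr_rows) else NULL,
         most_affected = if (length(maf_rows)) do.call(rbind, maf_rows)
                         else NULL,
         units = if (length(unit_rows)) do.call(rbind, unit_rows)
                 else NULL,
         log = log),
    class = "pipeline_result")

  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    for (nm in c("gpias", "screening", "abr", "most_affected", "units"))
      if (!is.null(res[[nm]]))
        utils::write.csv(res[[nm]], file.path(out, paste0(nm, ".csv")),
                         row.names = FALSE)
    jsonlite::write_json(res$log, file.path(out, "runlog.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<pipeline_result> %d animals, %d startle sessions, %d ABR rows\n",
    length(unique(x$gpias$animal)),
    length(unique(paste(x$gpias$animal, x$gpias$session))),
    if (is.null(x$abr)) 0L else nrow(x$abr)))
  invisible(x)
}
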