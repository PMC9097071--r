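fake_rec <- function(traces, fs = 2000, sensor = "piezo",
                     ttl = numeric(0), sched = NULL) {
  structure(list(traces = as.matrix(traces), fs = fs, ttl_times = ttl,
                 schedule = sched, sensor = sensor, session = "pre",
                 ground_truth = NULL),
            class = "session_recording")
}

test_that("piezo preprocessing bandpasses 70-400 Hz and zeroes stay zero", {
  fs <- 2000
  expect_equal(preprocess_trace(fake_rec(numeric(4000), fs)),
               numeric(4000))
  t <- (0:(fs * 4 - 1)) / fs
  out50 <- preprocess_trace(fake_rec(sin(2 * pi * 50 * t), fs))
  expect_lt(max(abs(out50[2000:6000])), 10^(-20 / 20))  # >= 20 dB down
  out150 <- preprocess_trace(fake_rec(sin(2 * pi * 150 * t), fs))
  expect_equal(max(abs(out150[2000:6000])), 1, tolerance = 0.05)
})

test_that("accelerometer preprocessing lowpasses each axis then averages rectified axes", {
  fs <- 2000
  a <- 0.6
  x <- cbind(rep(a, 4000), rep(-a, 4000), rep(0, 4000))
  out <- preprocess_trace(fake_rec(x, fs, sensor = "accelerometer"))
  expect_equal(out[1000:3000], rep(2 * a / 3, 2001), tolerance = 1e-6)
  expect_error(preprocess_trace(fake_rec(x[, 1:2], fs,
                                         sensor = "accelerometer")),
               "three axes")
})

test_that("trial slicing covers [-100, +100) ms and averages match a brute-force mean", {
  fs <- 2000
  npre <- round(0.1 * fs)
  sched <- make_gpias_schedule("9-11", seed = 1)
  onsets <- round(sched$pulse_onset_time * fs) + 1
  ttl <- (onsets - 1) / fs
  n <- max(onsets) + 2000

  set.seed(11)
  trace <- rnorm(n)
  avg <- slice_and_average(trace, ttl, sched, "9-11", "startle", fs)
  expect_length(avg, 2 * npre)
  sel <- which(sched$trial_type == "startle")
  manual <- rep(0, 2 * npre)
  for (k in sel)
    manual <- manual + trace[(onsets[k] - npre):(onsets[k] + npre - 1)]
  expect_equal(avg, manual / length(sel), tolerance = 1e-12)

  # 9 identical slices average to the slice; s and -s cancel
  trace2 <- numeric(n)
  s <- sin(seq(0, 6 * pi, length.out = 2 * npre))
  for (k in sel) trace2[(onsets[k] - npre):(onsets[k] + npre - 1)] <- s
  expect_equal(slice_and_average(trace2, ttl, sched, "9-11", "startle",
                                 fs), s)
  trace3 <- numeric(n)
  trace3[(onsets[sel[1]] - npre):(onsets[sel[1]] + npre - 1)] <- s
  trace3[(onsets[sel[2]] - npre):(onsets[sel[2]] + npre - 1)] <- -s
  expect_equal(slice_and_average(trace3, ttl, sched, "9-11", "startle",
                                 fs), rep(0, 2 * npre))

  expect_error(slice_and_average(trace[1:100], ttl, sched, "9-11",
                                 "startle", fs), "bounds")
  sched9 <- sched[-which(sched$trial_type == "gap")[1], ]
  expect_warning(slice_and_average(trace, ttl[-which(sched$trial_type ==
                                                       "gap")[1]],
                                   sched9, "9-11", "gap", fs),
                 "expected 9")
})

test_that("Hilbert envelope matches the full-DFT analytic-signal oracle and known closed forms", {
  expect_equal(instantaneous_amplitude(numeric(64)), numeric(64))
  fs <- 500
  t <- (0:(fs - 1)) / fs
  env <- instantaneous_amplitude(2.5 * sin(2 * pi * 50 * t))
  expect_equal(env[100:400], rep(2.5, 301), tolerance = 0.01)
  set.seed(21)
  for (i in 1:10) {
    x <- rnorm(64)
    expect_lt(max(abs(instantaneous_amplitude(x) - oracle_envelope(x))),
              1e-9)
  }
  expect_error(instantaneous_amplitude(c(1, NA, 3)), "finite")
})

test_that("envelope dominates the rectified signal everywhere", {
  set.seed(22)
  for (i in 1:20) {
    x <- rnorm(128)
    expect_true(all(instantaneous_amplitude(x) >= abs(x) - 1e-10))
  }
})

test_that("response amplitude is the post-minus-pre envelope mean", {
  expect_equal(response_amplitude(rep(3.2, 200)), 0)
  expect_equal(response_amplitude(c(rep(1.5, 100), rep(4, 100))), 2.5)
  set.seed(23)
  env <- c(numeric(100), abs(rnorm(100)))
  expect_equal(response_amplitude(env), sum(env[101:200]) / 100)
  expect_error(response_amplitude(rep(1, 201)), "even length")
})

test_that("suppression index follows (1 - gap/startle) * 100", {
  expect_equal(gpias_index(7, 7), 0)
  expect_equal(gpias_index(10, 2), 80)
  expect_equal(gpias_index(10, 12), -20)
  expect_error(gpias_index(0, 1), "positive")
  expect_error(gpias_index(-2, 1), "positive")
})

test_that("noise-free sessions recover the programmed suppression exactly", {
  for (s in c(0.25, 0.8)) {
    rec <- synth_gpias_session(gt1(s), make_gpias_schedule("9-11",
                                                           seed = 7),
                               fs = 2000, seed = 8)
    expect_equal(analyze_gpias(rec)$index, 100 * s, tolerance = 1e-8)
  }
  # accelerometer route too
  rec <- synth_gpias_session(gt1(0.4), make_gpias_schedule("9-11",
                                                           seed = 7),
                             fs = 2000, sensor = "accelerometer",
                             seed = 8)
  expect_equal(analyze_gpias(rec)$index, 40, tolerance = 1e-8)
})

test_that("scaling a recording leaves the index unchanged and scales amplitudes", {
  rec <- synth_gpias_session(gt1(0.6, noise_sd = 0.1),
                             make_gpias_schedule("9-11", seed = 9),
                             fs = 2000, seed = 10)
  r1 <- analyze_gpias(rec)
  rec$traces <- rec$traces * 3.7
  r2 <- analyze_gpias(rec)
  expect_equal(r2$startle_amp, 3.7 * r1$startle_amp)
  expect_equal(r2$gap_amp, 3.7 * r1$gap_amp)
  expect_equal(r2$index, r1$index)
})

test_that("permuting trial order within a band leaves the index unchanged", {
  rec <- synth_gpias_session(gt1(0.6, noise_sd = 0.1),
                             make_gpias_schedule("9-11", seed = 12),
                             fs = 2000, seed = 13)
  r1 <- analyze_gpias(rec)
  set.seed(1)
  p <- sample(nrow(rec$schedule))
  rec$schedule <- rec$schedule[p, ]
  rec$ttl_times <- rec$ttl_times[p]
  expect_equal(analyze_gpias(rec)$index, r1$index)
})

test_that("most affected frequency maximizes the index drop with lowest-center tie-break", {
  before <- data.frame(band = gpias_bands(), index = rep(80, 6))
  after <- before
  after$index[after$band == "9-11"] <- 3
  maf <- most_affected_frequency(before, after)
  expect_equal(maf$band, "9-11")
  expect_equal(maf$shift, 77)
  tie <- most_affected_frequency(before, before)
  expect_equal(tie$shift, 0)
  expect_equal(tie$band, "8-10")  # lowest band center among the tie
  set.seed(31)
  for (i in 1:20) {
    b4 <- data.frame(band = gpias_bands(), index = runif(6, -20, 90))
    af <- data.frame(band = sample(gpias_bands()),
                     index = runif(6, -20, 90))
    maf <- most_affected_frequency(b4, af)
    sh <- b4$index - af$index[match(b4$band, af$band)]
    expect_equal(maf$shift, max(sh))
    winners <- b4$band[sh == max(sh)]
    expect_equal(maf$band,
                 winners[order(band_center(winners))[1]])
  }
  expect_error(most_affected_frequency(before,
                                       data.frame(band = "9-11",
                                                  index = 1)),
               "different band sets")
})

test_that("screening passes bands at >= 30% suppression and includes animals with >= 2 passes after retest", {
  all_good <- data.frame(band = gpias_bands(), index = rep(80, 6))
  d <- screen_animal(all_good)
  expect_true(d$included)
  expect_length(d$retested_bands, 0)

  one_pass <- data.frame(band = gpias_bands(),
                         index = c(45, rep(10, 5)))
  retest_fail <- data.frame(band = gpias_bands()[-1],
                            index = rep(12, 5))
  expect_false(screen_animal(one_pass, retest_fail)$included)

  # retest rows for passed bands are ignored with a warning
  retest_extra <- data.frame(band = gpias_bands(),
                             index = c(99, rep(50, 5)))
  expect_warning(d2 <- screen_animal(one_pass, retest_extra),
                 "had passed")
  expect_true(d2$included)

  # randomized pass patterns against the brute-force rule
  set.seed(32)
  for (i in 1:25) {
    init <- data.frame(band = gpias_bands(),
                       index = runif(6, 0, 60))
    failed <- init$band[init$index < 30]
    re <- data.frame(band = failed, index = runif(length(failed), 0, 60))
    d <- screen_animal(init, if (nrow(re)) re else NULL)
    pass <- init$index >= 30
    pass[match(re$band, init$band)] <- re$index >= 30
    expect_identical(unname(d$pass_by_band[init$band]), pass)
    expect_identical(d$included, sum(pass) >= 2)
  }
})
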