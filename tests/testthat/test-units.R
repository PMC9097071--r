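test_that("threshold event detection recovers injected spikes and stays quiet on noise", {
  fs <- 30000
  expect_length(detect_events(numeric(fs), fs), 0)

  set.seed(51)
  noise <- rnorm(10 * fs)
  spike_t <- seq(0.5, 9.5, by = 0.25)
  shape <- -exp(-abs(seq(-15, 15)) / 4)   # ~1 ms biphasic-ish dip
  trace <- noise
  for (ts in spike_t) {
    i0 <- round(ts * fs)
    trace[i0 + seq_along(shape)] <- trace[i0 + seq_along(shape)] +
      10 * sd(noise) * shape
  }
  ev <- detect_events(trace, fs, k = 4.5)
  # every injected spike recovered within 0.2 ms, no extras
  expect_equal(length(ev), length(spike_t))
  match_err <- abs(ev - (spike_t + 16 / fs))
  expect_true(all(match_err < 2e-4))

  # pure noise at k = 4.5: false positives well under 1 event/s
  fp <- detect_events(rnorm(30 * fs), fs, k = 4.5)
  expect_lt(length(fp) / 30, 0.5)
  expect_error(detect_events(noise, fs, k = 5), "2, 4.5")
  expect_error(detect_events(noise, 20000), "29 kHz")
})

test_that("PSTH bins 1-ms counts around each TTL and conserves the windowed spike count", {
  st <- spike_train(numeric(0), 10, ttl = data.frame(
    time = c(2, 4), band = "8-10", intensity = 80))
  expect_equal(psth(st)$counts, integer(100))

  st2 <- spike_train(2 + 0.0054, 10)
  h <- psth(st2, ttl_times = 2)
  # [5, 6) ms is the 56th of the 100 bins spanning [-50, 50) ms
  expect_equal(h$counts[56], 1L)
  expect_equal(h$breaks_ms[56], 5)
  expect_equal(sum(h$counts), 1L)

  set.seed(52)
  ttl <- seq(1, 59, by = 0.2)
  times <- sort(runif(3000, 0, 60))
  stp <- spike_train(times, 60)
  h2 <- psth(stp, ttl_times = ttl)
  # naive double-loop oracle
  manual <- 0L
  for (tt in ttl) manual <- manual +
      sum(times >= tt - 0.05 & times < tt + 0.05)
  expect_equal(sum(h2$counts), manual)
  expect_error(psth(stp, ttl_times = c(1, 1.05)), "overlap")
})

test_that("overall rate is events per second over the whole recording", {
  expect_equal(overall_rate(spike_train(seq(0.05, 9.95, length.out = 100),
                                        10)), 10)
  expect_equal(overall_rate(spike_train(numeric(0), 5)), 0)
  set.seed(53)
  tr <- spike_train(sort(runif(rpois(1, 20 * 60), 0, 60)), 60)
  expect_equal(overall_rate(tr), 20, tolerance = 0.12)  # ~4 SE
})

test_that("FRA cells hold evoked-window rates matching construction and analytic expectation", {
  ttl <- expand.grid(time = NA, pulse = 1:10,
                     intensity = abr_intensities(), band = abr_bands())
  ttl$time <- seq_len(nrow(ttl)) * 0.2
  ttl <- ttl[, c("time", "band", "intensity")]

  st0 <- spike_train(numeric(0), max(ttl$time) + 1, ttl = ttl)
  expect_true(all(unclass(build_fra(st0)) == 0))

  # exactly one in-window spike per pulse in one cell -> 20 Hz
  sel <- ttl$band == "10-12" & ttl$intensity == 60
  st1 <- spike_train(ttl$time[sel] + 0.01, max(ttl$time) + 1, ttl = ttl)
  fra1 <- build_fra(st1)
  expect_equal(unclass(fra1)["10-12", "60"], 20)
  expect_equal(sum(unclass(fra1)), 20)

  # Gaussian unit: cells match the closed-form expected rates
  u <- ground_truth_unit(bf_khz = 11, sigma_khz = 2, peak_rate = 30,
                         baseline_rate = 0, rate_intensity_slope = 0.2)
  st <- synth_unit_spikes(u, seed = 54)
  fra <- build_fra(st)
  centers <- band_center(abr_bands())
  for (b in seq_along(centers)) for (I in c(80, 50)) {
    lam <- max(0, 30 + 0.2 * (I - 80)) *
      exp(-(centers[b] - 11)^2 / (2 * 4))
    got <- unclass(fra)[b, as.character(I)]
    tol <- 5 * sqrt(lam / (529 * 0.05)) + 0.5   # Poisson error on a rate
    expect_lt(abs(got - lam), tol)
  }
})

test_that("bilinear 3x upsampling preserves nodes, bounds and linear ramps", {
  flat <- make_fra(matrix(4, 5, 10))
  up <- upsample_fra(flat)
  expect_equal(dim(up), c(15, 30))
  expect_true(all(up == 4))

  ramp <- make_fra(outer(1:5, 1:10, function(i, j) 2 * i + 3 * j))
  upr <- upsample_fra(ramp)
  # original nodes at aligned (pixel-centered) positions
  expect_equal(upr[seq(2, 14, by = 3), seq(2, 29, by = 3)],
               unclass(ramp), ignore_attr = TRUE)
  # interior follows the plane exactly (bilinearity)
  expect_equal(upr[7, 13], 2 * (7 / 3 + 1 / 3) + 3 * (13 / 3 + 1 / 3))

  set.seed(55)
  rnd <- make_fra(matrix(runif(50), 5, 10))
  upn <- upsample_fra(rnd)
  expect_true(all(upn >= min(rnd) - 1e-12 & upn <= max(rnd) + 1e-12))
  ro <- pmin(pmax((seq_len(15) - 0.5) / 3 + 0.5, 1), 5)
  co <- pmin(pmax((seq_len(30) - 0.5) / 3 + 0.5, 1), 10)
  for (i in c(1, 4, 9, 15)) for (j in c(1, 7, 22, 30))
    expect_equal(upn[i, j], oracle_bilinear(unclass(rnd), ro[i], co[j]),
                 tolerance = 1e-12)
  missing <- make_fra(matrix(c(NA, runif(49)), 5, 10))
  expect_error(upsample_fra(missing), "absent")
})

test_that("tuning width is the mean max-normalized 80-dB rate and grows with tuning spread", {
  flat <- make_fra(matrix(rep(7, 50), 5, 10))
  expect_equal(tuning_width(flat), 1)
  onehot <- make_fra(matrix(c(9, 0, 0, 0, 0), 5, 10))
  expect_equal(tuning_width(onehot), 0.2)
  centers <- band_center(abr_bands())
  tw <- vapply(c(0.3, 0.8, 1.5, 3, 5), function(s) {
    rates <- exp(-(centers - 11)^2 / (2 * s^2))
    tuning_width(make_fra(matrix(rates, 5, 10)))
  }, numeric(1))
  expect_true(all(diff(tw) > 0))
  expect_true(all(tw > 0 & tw <= 1))
  zero <- make_fra(matrix(0, 5, 10))
  expect_error(tuning_width(zero), "undefined tuning")
})

test_that("best frequency is the argmax band center with lowest-center tie-break", {
  m <- matrix(0, 5, 10)
  m[4, 1] <- 12   # 12-14 band at 80 dB
  expect_equal(best_frequency(make_fra(m)), 13)
  flat <- make_fra(matrix(5, 5, 10))
  expect_equal(best_frequency(flat), 9)
  centers <- band_center(abr_bands())
  gauss <- make_fra(matrix(exp(-(centers - 10.2)^2 / 2), 5, 10))
  expect_equal(best_frequency(gauss), 10)  # 9-11 band center
  expect_error(best_frequency(make_fra(matrix(0, 5, 10))), "undefined")
})

test_that("treatment change classification follows the sign of CNO minus NaCl", {
  f1 <- list(firing_rate = 15, tuning_width = 0.8, best_frequency = 13)
  f2 <- list(firing_rate = 8, tuning_width = 0.9, best_frequency = 13)
  cls <- classify_change(f1, f2)
  expect_equal(unname(cls), c("decreased", "increased", "no_change"))
  set.seed(56)
  for (i in 1:20) {
    a <- list(x = rnorm(1), y = sample(c(-1, 0, 1), 1))
    b <- list(x = rnorm(1), y = sample(c(-1, 0, 1), 1))
    cls <- classify_change(a, b)
    for (f in c("x", "y")) {
      d <- b[[f]] - a[[f]]
      expect_equal(unname(cls[f]),
                   if (d < 0) "decreased" else if (d > 0) "increased"
                   else "no_change")
    }
  }
})

test_that("the surrogate responder criterion separates evoked from baseline-only units", {
  u_ev <- ground_truth_unit(bf_khz = 11, sigma_khz = 2, peak_rate = 20,
                            baseline_rate = 2)
  st_ev <- synth_unit_spikes(u_ev, seed = 59)
  expect_true(responding_unit(st_ev)$responding)

  # baseline-only units are flagged at most at the nominal 5% rate
  u_base <- ground_truth_unit(bf_khz = 11, sigma_khz = 2, peak_rate = 0,
                              baseline_rate = 5)
  fp <- vapply(60:69, function(s) {
    r <- responding_unit(synth_unit_spikes(u_base, seed = s))
    expect_equal(r$mean_pre, r$mean_post, tolerance = 0.1)
    r$responding
  }, logical(1))
  expect_lte(sum(fp), 2)

  silent <- spike_train(numeric(0), 10, ttl = data.frame(
    time = c(2, 4), band = "8-10", intensity = 80))
  expect_false(responding_unit(silent)$responding)
})

test_that("feature correlations match the covariance formula with capped Bonferroni p", {
  x <- 1:10
  d <- data.frame(a = x, b = 2 * x + 1, c = rnorm(10))
  res <- feature_correlations(d)
  expect_equal(res$r[res$feature_a == "a" & res$feature_b == "b"], 1)
  expect_true(all(res$p_corrected <= 1))
  expect_true(all(res$p_corrected >= res$p))
  set.seed(57)
  d2 <- data.frame(u = rnorm(10), v = rnorm(10))
  r2 <- feature_correlations(d2)
  expect_equal(r2$r, oracle_pearson(d2$u, d2$v), tolerance = 1e-12)
  dz <- data.frame(u = rep(1, 10), v = rnorm(10))
  expect_true(is.na(feature_correlations(dz)$r))
})

test_that("synthetic units recover best frequency and chemogenetic firing-rate decrease", {
  set.seed(58)
  hits <- 0
  for (i in 1:10) {
    bf <- sample(c(9, 10, 11, 13, 15), 1) + runif(1, -0.3, 0.3)
    u <- ground_truth_unit(bf_khz = bf, sigma_khz = runif(1, 0.8, 2),
                           peak_rate = 25, baseline_rate = 1,
                           cno_gain = 0.5)
    st_na <- synth_unit_spikes(u, "NaCl", seed = 580 + i)
    st_cn <- synth_unit_spikes(u, "CNO", seed = 680 + i)
    f_na <- unit_features(st_na)
    f_cn <- unit_features(st_cn)
    centers <- band_center(abr_bands())
    nearest <- centers[which.min(abs(centers - bf))]
    hits <- hits + (f_na$best_frequency == nearest)
    expect_equal(unname(classify_change(f_na, f_cn)["firing_rate"]),
                 "decreased")
  }
  expect_gte(hits, 9)
})
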