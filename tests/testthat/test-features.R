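test_that("pitch estimate equals velocity times median peak interval", {
  # impulses every 10 samples = 0.01 s at 1000/s; 4 cm/s -> 400 um exactly
  tr <- rep(0, 2000)
  tr[seq(10, 2000, by = 10)] <- 1
  expect_equal(estimate_pitch(tr, velocity = 4), 400)
  # 10x the interval scales the estimate linearly
  tr2 <- rep(0, 2000)
  tr2[seq(100, 2000, by = 100)] <- 1
  expect_equal(estimate_pitch(tr2, velocity = 4), 4000)
  # doubling velocity at fixed trace doubles the estimate
  expect_equal(estimate_pitch(tr, velocity = 8), 800)
})

test_that("pitch recovery on simulated slides matches an autocorrelation oracle", {
  cfg <- sim_config(noise = 0)
  for (pitch in c(1000, 2500, 5000)) {
    tr <- simulate_slide(test_material(pitch_um = pitch), 4, 2, cfg)
    est <- estimate_pitch(tr, 4)
    # autocorrelation-lag oracle: first local max of the acf away from 0
    ac <- stats::acf(tr, lag.max = 800, plot = FALSE)$acf[-1]
    lag <- tactileavatar:::find_signal_peaks(ac, k = 0, min_dist = 5)[1]
    oracle <- 4 * 1e4 * lag / 1000
    expect_equal(est, oracle, tolerance = 0.02)
    expect_equal(est, pitch, tolerance = 0.05)
  }
  expect_error(estimate_pitch(rep(0, 100), 4),
    class = "tactileavatar_estimation_failure")
})

test_that("pitch recovery holds within 5% on the noisy default corpus", {
  fx <- small_corpus()
  ft <- feature_table(fx$corpus)
  med <- tapply(ft$pitch_estimate, ft$material_id, stats::median, na.rm = TRUE)
  sel <- fx$lib$true_rank >= 12 # peak-interval reading needs coarse pitches
  relerr <- abs(med[sel] - fx$lib$pitch_um[sel]) / fx$lib$pitch_um[sel]
  expect_lt(stats::median(relerr), 0.05)
})

test_that("touch slope estimation is exact on a ramp and unbiased under noise", {
  ramp <- c(rep(0, 50), seq(0, 1, length.out = 101)[-1], rep(1, 100))
  expect_equal(estimate_touch_slope(ramp, onset = 51), 10, tolerance = 1e-10)
  # Monte-Carlo bias check: mean estimate within 2% of truth
  ests <- vapply(1:100, function(i) {
    withr::with_seed(i, {
      noisy <- ramp + rnorm(length(ramp), 0, 0.02)
      estimate_touch_slope(noisy, onset = 51)
    })
  }, numeric(1))
  expect_equal(mean(ests), 10, tolerance = 0.02)
  expect_error(estimate_touch_slope(rep(0, 200)),
    class = "tactileavatar_estimation_failure")
})

test_that("simulated touch slopes increase across the 5 hardness bins", {
  cfg <- sim_config(noise = 0)
  bin_centers <- c(30, 45, 55, 65, 80)
  slopes <- vapply(bin_centers, function(d) {
    estimate_touch_slope(simulate_touch(test_material(durometer = d), 1.2, cfg))
  }, numeric(1))
  expect_true(all(diff(slopes) > 0))
})

test_that("slide spectrum has the stated bin, normalization and DC behaviour", {
  t <- seq(0, 2 - 1e-3, by = 1e-3)
  pure <- sin(2 * pi * 100 * t)
  spec <- slide_spectrum(pure)
  expect_length(spec, 500)
  expect_true(all(spec >= 0))
  expect_equal(which.max(spec), 100)
  expect_equal(max(spec), 1)
  # DC-only trace: nothing in 1..500 Hz
  expect_lt(max(slide_spectrum(rep(3.7, 1000))), 1e-9)
  # invariance to trace mean, equivariance to amplitude before normalization
  expect_equal(slide_spectrum(pure + 5), spec, tolerance = 1e-8)
  expect_equal(slide_spectrum(3 * pure), spec, tolerance = 1e-8)
  expect_error(slide_spectrum(pure, sample_rate = 500),
    class = "tactileavatar_invalid_argument")
  expect_error(slide_spectrum(1:5), class = "tactileavatar_invalid_argument")
})

test_that("two-tone spectrum preserves the amplitude ratio", {
  t <- seq(0, 2 - 1e-3, by = 1e-3)
  two <- 2 * sin(2 * pi * 50 * t) + sin(2 * pi * 150 * t)
  spec <- slide_spectrum(two)
  expect_equal(spec[50] / spec[150], 2, tolerance = 0.01)
})

test_that("touch window is onset-anchored and 400 samples long", {
  tr <- c(rep(0, 100), seq(0, 1, length.out = 60), rep(1, 840))
  w <- touch_window(tr, onset = 101)
  expect_length(w, 400)
  expect_equal(w, tr[101:500])
  expect_error(touch_window(tr[1:450], onset = 101),
    class = "tactileavatar_invalid_argument")
  # detected onset agrees with the configured onset on simulated traces
  cfg <- sim_config(noise = 0.1)
  set.seed(3)
  sim <- simulate_touch(test_material(), 1.2, cfg)
  onset <- detect_onset(sim)
  expect_equal(onset, cfg$onset_time * cfg$sample_rate + 1, tolerance = 6)
  # noiseless window slope equals the slope estimate (internal consistency)
  cfg0 <- sim_config(noise = 0)
  sim0 <- simulate_touch(test_material(durometer = 60), 1.2, cfg0)
  w0 <- touch_window(sim0)
  rise <- seq_len(cfg0$rise_time * cfg0$sample_rate)
  slope_window <- unname(stats::coef(stats::lm(w0[rise] ~ rise))[2]) * cfg0$sample_rate
  expect_equal(slope_window, estimate_touch_slope(sim0), tolerance = 0.05)
})

test_that("corpus features stack to the network input shapes", {
  fx <- small_corpus()
  expect_equal(dim(fx$features$touch), c(nrow(fx$corpus), 400))
  expect_equal(dim(fx$features$slide), c(nrow(fx$corpus), 500))
  expect_equal(fx$features$material_id, fx$corpus$material_id)
  # two noiseless recordings of one material give identical features
  lib1 <- test_material()
  cfg0 <- sim_config(n_materials = 1, n_trials_per_material = 2, noise = 0)
  f0 <- corpus_features(record_corpus(lib1, cfg0))
  expect_identical(f0$touch[1, ], f0$touch[2, ])
  expect_identical(f0$slide[1, ], f0$slide[2, ])
})
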