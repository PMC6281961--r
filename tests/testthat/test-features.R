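# Smoothing, peak detection with the 180 ms refractory rule, contact-bout
# segmentation, and per-trial feature extraction.

test_that("moving-average smoothing matches a direct windowed mean", {
  cfg <- feature_config()
  expect_equal(smooth_force(rep(2.5, 40), cfg), rep(2.5, 40))
  cfg1 <- feature_config(smoothing_kernel = 3, dt = 3)  # 1-sample window
  x <- rnorm(20)
  expect_equal(smooth_force(x, cfg1), x)

  # linear ramp: unchanged in the interior, truncated windows at the edges
  ramp <- seq(0, 10, length.out = 50)
  sm <- smooth_force(ramp, cfg)
  h <- 7  # (15 - 1) / 2 samples half-window
  expect_equal(sm[(h + 1):(50 - h)], ramp[(h + 1):(50 - h)])
  oracle <- vapply(seq_along(ramp), function(i) {
    mean(ramp[max(1, i - h):min(50, i + h)])
  }, numeric(1))
  expect_equal(sm, oracle)

  # oracle check on an arbitrary signal too
  set.seed(1)
  y <- cumsum(rnorm(100))
  oracle_y <- vapply(seq_along(y), function(i) {
    mean(y[max(1, i - h):min(100, i + h)])
  }, numeric(1))
  expect_equal(smooth_force(y, cfg), oracle_y)
  expect_error(smooth_force(numeric(0)), "empty")
})

test_that("peak detection finds apexes and applies the refractory rule", {
  cfg <- feature_config()
  pulse <- simulate_indentation_pulse(5, 300, 3)
  pk <- detect_peaks(pulse$force_N, pulse$t_ms, cfg)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$time, 150)
  expect_equal(pk$force, 5)

  # two pulses 500 ms apart survive (apexes on the 3 ms grid)
  t2 <- seq(0, 1200, by = 3)
  f2 <- 5 * pmax(0, sin(pi * (t2 - 99) / 300)) * (t2 >= 99 & t2 <= 399) +
    4 * pmax(0, sin(pi * (t2 - 600) / 300)) * (t2 >= 600 & t2 <= 900)
  pk2 <- detect_peaks(f2, t2, cfg)
  expect_equal(nrow(pk2), 2)
  expect_equal(pk2$force, c(5, 4))

  # two local maxima 90 ms apart: only the larger (5 N) survives
  t3 <- seq(0, 300, by = 3)
  f3 <- approx(x = c(0, 60, 105, 150, 300), y = c(0, 5, 3, 4, 0), xout = t3)$y
  pk3 <- detect_peaks(f3, t3, cfg)
  expect_equal(nrow(pk3), 1)
  expect_equal(pk3$force, 5)
  expect_equal(pk3$time, 60)

  # plateau: peak placed on the first plateau sample
  f4 <- c(0, 1, 2, 2, 2, 1, 0)
  pk4 <- detect_peaks(f4, seq(0, by = 3, length.out = 7), cfg)
  expect_equal(pk4$index, 3)

  expect_equal(nrow(detect_peaks(rep(0, 50))), 0)
})

test_that("segmentation assigns peaks to contact bouts with stimulus ids", {
  cfg <- feature_config()
  # below-threshold trace yields no indentations
  low <- tibble::tibble(t_ms = seq(0, 900, 3),
                        force_N = 0.05 * sin(pi * seq(0, 900, 3) / 900),
                        stimulus_id = "hard_s")
  expect_equal(nrow(segment_indentations(low, cfg)), 0)

  # 3 pulses on the left stimulus then 2 on the right
  mk <- function(onsets, sides, peak = 4) {
    t <- seq(0, max(onsets) + 600, by = 3)
    f <- numeric(length(t))
    sid <- rep("none", length(t))
    for (k in seq_along(onsets)) {
      sel <- t >= onsets[k] & t <= onsets[k] + 300
      f[sel] <- peak * sin(pi * (t[sel] - onsets[k]) / 300)
      sid[sel & f > 0] <- sides[k]
    }
    tibble::tibble(t_ms = t, force_N = f, stimulus_id = sid)
  }
  tr <- mk(onsets = c(100, 700, 1300, 1900, 2500),
           sides = c("L", "L", "L", "R", "R"))
  seg <- segment_indentations(tr, cfg)
  expect_equal(nrow(seg), 5)
  expect_equal(seg$stimulus_id, c("L", "L", "L", "R", "R"))
  expect_equal(seg$ordinal, 1:5)
  expect_true(all(seg$onset < seg$peak_time & seg$peak_time < seg$offset))

  # apex exactly at the 0.1 N threshold is excluded (strict > reading)
  cfg_id <- feature_config(smoothing_kernel = 3)  # identity smoothing
  border <- tibble::tibble(t_ms = seq(0, 300, 3),
                           force_N = 0.1 * sin(pi * seq(0, 300, 3) / 300),
                           stimulus_id = "hard_s")
  expect_equal(nrow(segment_indentations(border, cfg_id)), 0)
  above <- border
  above$force_N <- above$force_N * 2
  expect_equal(nrow(segment_indentations(above, cfg_id)), 1)
})

test_that("trial features summarize the indentation sequence", {
  ind <- tibble::tibble(ordinal = 1:3, stimulus_id = c("L", "R", "R"),
                        peak_time = c(200, 800, 1400),
                        peak_force = c(5, 7, 9),
                        onset = c(100, 700, 1300), offset = c(400, 1000, 1600))
  f <- extract_trial_features(ind, response = "R")
  expect_equal(f$n_indentations, 3)
  expect_equal(f$first_peak, 5)
  expect_equal(f$middle_peak, 7)
  expect_equal(f$last_peak, 9)
  expect_equal(f$effort, 21)
  expect_true(f$last_touch_matches_choice)

  one <- ind[1, ]
  f1 <- extract_trial_features(one)
  expect_equal(f1$first_peak, f1$last_peak)
  expect_equal(f1$middle_peak, 5)
  expect_equal(f1$effort, 5)

  # effort is additive over concatenated indentation lists
  ind2 <- ind
  ind2$ordinal <- 4:6
  both <- rbind(ind, ind2)
  expect_equal(extract_trial_features(both)$effort,
               extract_trial_features(ind)$effort +
                 extract_trial_features(ind2)$effort)
  expect_error(extract_trial_features(ind[0, ]), "no indentations")
})

test_that("extraction recovers planted features from rendered traces", {
  sch <- small_exp1_schedule(seed = 3)[1:8, ]
  eff <- quiet_effects()
  ds <- simulate_dataset(sch, eff, seed = 21, traces = TRUE)
  feats <- extract_features(ds$traces, ds$trials)
  expect_equal(nrow(feats), 8)
  got <- feats[order(feats$trial_uid), ]
  want <- ds$trials[order(ds$trials$trial_uid), ]
  expect_equal(got$n_indentations, want$n_indentations)
  expect_equal(got$first_peak, want$first_peak, tolerance = 1e-10)
  expect_equal(got$last_peak, want$last_peak, tolerance = 1e-10)
  expect_equal(got$effort, want$effort, tolerance = 1e-10)
  qc <- attr(feats, "qc")
  expect_equal(qc$n_excluded, 0)

  # with noise and shaking enabled, features match within the artifact bound
  eff_n <- effect_config()
  dsn <- simulate_dataset(sch, eff_n, seed = 22, traces = TRUE)
  fn <- extract_features(dsn$traces, dsn$trials)
  gotn <- fn[order(fn$trial_uid), ]
  wantn <- dsn$trials[order(dsn$trials$trial_uid), ]
  expect_equal(gotn$n_indentations, wantn$n_indentations)
  bound <- eff_n$shaking_amplitude + 6 * eff_n$sd_noise
  expect_true(all(abs(gotn$first_peak - wantn$first_peak) < bound))
  expect_true(all(abs(gotn$last_peak - wantn$last_peak) < bound))
})

test_that("peak count ignores sub-threshold baseline offsets", {
  cfg <- feature_config()
  pulse <- simulate_indentation_pulse(4, 300, 3)
  t <- seq(0, 900, by = 3)
  f <- numeric(length(t))
  f[t >= 300 & t <= 600] <- pulse$force_N
  base <- detect_peaks(smooth_force(f, cfg), t, cfg)
  shifted <- detect_peaks(smooth_force(f + 0.04, cfg), t, cfg)
  expect_equal(nrow(base), nrow(shifted))
})
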