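test_that("evoked template is a sum of Gaussian components", {
  times <- seq(-100, 800, by = 1000 / 512)
  expect_identical(evoked_template(data.frame(latency_ms = numeric(0),
                                              width_ms = numeric(0),
                                              amplitude_uv = numeric(0)),
                                   times),
                   numeric(length(times)))
  one <- data.frame(latency_ms = 200, width_ms = 40, amplitude_uv = 10)
  w <- evoked_template(one, times)
  # peak amplitude at the sample nearest the component latency (the exact
  # 10 uV peak lies between samples)
  expect_equal(max(w), 10, tolerance = 1e-3)
  expect_equal(times[which.max(w)], times[which.min(abs(times - 200))])

  # additivity: two overlapping components equal the sample-wise sum of
  # the single-component calls
  a <- data.frame(latency_ms = 200, width_ms = 40, amplitude_uv = 10)
  b <- data.frame(latency_ms = 250, width_ms = 60, amplitude_uv = -5)
  expect_equal(evoked_template(rbind(a, b), times),
               evoked_template(a, times) + evoked_template(b, times))

  expect_error(evoked_template(data.frame(latency_ms = NA, width_ms = 1,
                                          amplitude_uv = 1), times),
               "finite")
})

test_that("generator config validates its invariants", {
  expect_error(generator_config(epoch_window = c(100, 800)), "straddle")
  expect_error(generator_config(effect_window_late = c(400, 900)), "within")
  expect_error(generator_config(noise_sd = -1), "noise_sd")
  expect_error(generator_config(polarity_flip_prob = 1.5), "probabilities")
  expect_error(generator_config(trials_per_condition = 0), "positive")
  expect_error(generator_config(n_ltc_left = 0, n_hipp_left = 0,
                                n_ltc_right = 0, n_hipp_right = 0),
               "counts")
})

test_that("generated datasets are deterministic in the seed and carry the declared structure", {
  cfg <- left_config(seed = 11, trials = 10, n_ltc = 2, n_hipp = 2)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$epochs$data, d2$epochs$data)
  expect_identical(d1$meta, d2$meta)
  d3 <- generate_dataset(left_config(seed = 12, trials = 10, n_ltc = 2, n_hipp = 2))
  expect_false(identical(d1$epochs$data, d3$epochs$data))

  # times axis contract
  e <- d1$epochs
  expect_equal(e$times[1], -100)
  expect_equal(diff(e$times), rep(1000 / 512, length(e$times) - 1))
  # artifact trials are not pre-flagged
  expect_false(any(e$rejected))
})

test_that("adding electrodes does not perturb existing electrode substreams", {
  small <- generate_dataset(left_config(seed = 5, n_ltc = 2, n_hipp = 2,
                                        trials = 8))
  big <- generate_dataset(left_config(seed = 5, n_ltc = 2, n_hipp = 3,
                                      trials = 8))
  shared <- small$meta$electrode_id[small$meta$region == "LTC"]
  expect_identical(small$epochs$data[, shared, ], big$epochs$data[, shared, ])
})

test_that("with zero effects and zero noise the condition means coincide", {
  cfg <- generator_config(n_ltc_left = 2, n_hipp_left = 2, n_ltc_right = 0,
                          n_hipp_right = 0, trials_per_condition = 5,
                          early_effect = 0, late_effect = 0, noise_sd = 0,
                          polarity_flip_prob = 0, artifact_rate = 0, seed = 3)
  d <- generate_dataset(cfg)
  ev <- average_evoked(d$epochs)
  expect_equal(ev$waveforms[, "now", ], ev$waveforms[, "then", ])
})

test_that("injected effects appear in the intended region x window cells", {
  # noise-free: LTC differs between conditions only inside the early
  # window, HIPP only inside the late window
  cfg <- generator_config(n_ltc_left = 1, n_hipp_left = 1, n_ltc_right = 0,
                          n_hipp_right = 0, trials_per_condition = 5,
                          noise_sd = 0, polarity_flip_prob = 0,
                          artifact_rate = 0, seed = 3)
  d <- generate_dataset(cfg)
  ev <- average_evoked(d$epochs)
  dlt <- ev$waveforms[1, "then", ] - ev$waveforms[1, "now", ]  # LTC
  dhp <- ev$waveforms[2, "then", ] - ev$waveforms[2, "now", ]  # HIPP
  tms <- ev$times
  expect_true(all(abs(dlt[tms < 100 | tms > 300]) < 1e-12))
  expect_gt(max(abs(dlt[tms >= 100 & tms <= 300])), 1)
  expect_true(all(abs(dhp[tms < 400 | tms > 600]) < 1e-12))
  expect_gt(max(abs(dhp[tms >= 400 & tms <= 600])), 1)
})

test_that("LTC modulation is predominantly early and hippocampal modulation late across seeds", {
  # Monte-Carlo check of the construction: features taken from plain
  # trial averages so the check sees the generator, not the filter.
  hits <- 0L
  n_seeds <- 100L
  for (s in seq_len(n_seeds)) {
    d <- generate_dataset(left_config(seed = s, trials = 20, fs = 256,
                                      artifacts = 0))
    f <- features_for_dataset(average_evoked(d$epochs), meta = d$meta)
    ltc <- f$region == "LTC"
    if (mean(f$early[ltc]) > mean(f$late[ltc]) &&
        mean(f$late[!ltc]) > mean(f$early[!ltc])) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("polarity flips leave modulation features unchanged", {
  d <- generate_dataset(left_config(seed = 21, trials = 10, n_ltc = 3,
                                    n_hipp = 3))
  f1 <- features_for_dataset(average_evoked(d$epochs), meta = d$meta)
  flipped <- d$epochs
  flipped$data <- -flipped$data
  f2 <- features_for_dataset(average_evoked(flipped), meta = d$meta)
  expect_equal(f1$early, f2$early)
  expect_equal(f1$late, f2$late)
})
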