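test_that("band-pass removes DC and keeps in-band amplitudes", {
  fs <- 1024
  n <- length(seq(-100, 800, by = 1000 / fs))
  tsec <- (seq_len(n) - 1) / fs

  # constant signal: nothing but DC, output exactly zero
  ep <- toy_epochs(matrix(5, 4, n), fs = fs)
  out <- bandpass(ep)
  expect_lt(max(abs(out$data)), 1e-6 * 5)

  # frequency response on single tones, mid-epoch (edges excluded)
  mid <- tsec > 0.2 & tsec < 0.7
  tone <- function(f) matrix(rep(sin(2 * pi * f * tsec), each = 4), 4, n)
  in_band <- bandpass(toy_epochs(tone(50), fs = fs))
  expect_lt(abs(max(abs(in_band$data[1, 1, mid])) - 1), 0.05)
  out_band <- bandpass(toy_epochs(tone(200), fs = fs))
  expect_lt(max(abs(out_band$data[1, 1, mid])), 0.1)
})

test_that("band-pass rejects configurations at or above Nyquist", {
  ep <- toy_epochs(matrix(rnorm(4 * 90), 4, 90), fs = 200)
  expect_error(bandpass(ep, 1, 120), "Nyquist")
  expect_error(bandpass(ep, 50, 10), "low_hz")
})

test_that("robust rejection finds planted transients and spares clean data", {
  set.seed(401)
  n_samp <- 200
  mat <- matrix(rnorm(40 * n_samp), 40, n_samp)
  # plant a 10x transient in trial 7
  mat[7, 90:110] <- mat[7, 90:110] + 10 * exp(-((90:110) - 100)^2 / 50)
  ep <- toy_epochs(mat, fs = 256)
  out <- reject_epochs(ep, z_threshold = 6)
  expect_true(out$rejected[7])

  # infinite threshold flags nothing
  expect_false(any(reject_epochs(ep, z_threshold = Inf)$rejected))

  # false-positive rate on artifact-free Gaussian data across seeds
  flagged <- 0L; total <- 0L
  for (s in 1:100) {
    set.seed(s)
    ep2 <- toy_epochs(matrix(rnorm(24 * 120), 24, 120), fs = 256)
    flagged <- flagged + sum(reject_epochs(ep2, 6)$rejected)
    total <- total + 24L
  }
  expect_lte(flagged / total, 0.05)
})

test_that("rejection refuses to empty a condition", {
  set.seed(402)
  mat <- matrix(rnorm(6 * 50), 6, 50)
  # spike transients in two of the three "now" trials, at different samples
  mat[1, 10] <- mat[1, 10] + 60
  mat[3, 30] <- mat[3, 30] + 60
  ep <- toy_epochs(mat, fs = 256,
                   condition = rep(c("now", "then"), 3))
  expect_error(reject_epochs(ep, 6), "fewer than 2")
})

test_that("condition collapsing conserves trials and validates the mapping", {
  n <- 120
  mat <- matrix(rnorm(n * 30), n, 30)
  cond <- rep(c("past", "future", "now"), each = 40)
  ep <- toy_epochs(mat, fs = 256, condition = cond)
  out <- collapse_conditions(ep)
  expect_equal(sum(out$condition == "then"), 80)
  expect_equal(sum(out$condition == "now"), 40)
  expect_equal(length(out$condition), n)
  expect_identical(out$data, ep$data)

  # idempotent on collapsed data
  again <- collapse_conditions(out)
  expect_identical(again$condition, out$condition)

  # identity mapping leaves labels alone
  idm <- c(past = "past", future = "future", now = "now")
  expect_identical(collapse_conditions(ep, idm)$condition, cond)

  # mapping missing a present label errors
  expect_error(collapse_conditions(ep, c(past = "then", now = "now")),
               "future")
})

test_that("evoked averaging matches direct computation and respects flags", {
  # two constant trials per condition
  mat <- rbind(matrix(1, 1, 20), matrix(3, 1, 20),
               matrix(2, 1, 20), matrix(4, 1, 20))
  ep <- toy_epochs(mat, fs = 500, condition = c("now", "now", "then", "then"))
  ev <- average_evoked(ep)
  expect_equal(unname(ev$waveforms["e01", "now", ]), rep(2, 20))
  expect_equal(unname(ev$waveforms["e01", "then", ]), rep(3, 20))
  expect_equal(unname(ev$n_trials["e01", ]), c(now = 2L, then = 2L),
               ignore_attr = TRUE)

  # flagged trials excluded: mean over remaining rows matches a direct
  # masked recomputation
  set.seed(77)
  mat <- matrix(rnorm(12 * 40), 12, 40)
  rej <- rep(FALSE, 12); rej[c(2, 9)] <- TRUE
  cond <- rep(c("now", "then"), 6)
  ep <- toy_epochs(mat, fs = 512, condition = cond, rejected = rej)
  ev <- average_evoked(ep)
  for (cc in c("now", "then")) {
    keep <- cond == cc & !rej
    expect_equal(unname(ev$waveforms["e01", cc, ]), colMeans(mat[keep, ]))
    expect_equal(unname(ev$n_trials["e01", cc]), sum(keep))
  }
  # bookkeeping: per-condition counts plus rejections cover all trials
  expect_equal(sum(ev$n_trials["e01", ]) + sum(rej), 12)
})

test_that("noise-free generated data averages back to the injected template", {
  cfg <- generator_config(n_ltc_left = 1, n_hipp_left = 1, n_ltc_right = 0,
                          n_hipp_right = 0, trials_per_condition = 4,
                          noise_sd = 0, polarity_flip_prob = 0,
                          artifact_rate = 0, seed = 2)
  d <- generate_dataset(cfg)
  ev <- average_evoked(d$epochs)
  tmpl <- evoked_template(cfg$component_spec, ev$times)
  expect_equal(unname(ev$waveforms[1, "now", ]), tmpl)
  expect_equal(unname(ev$waveforms[2, "now", ]), tmpl)
})

test_that("the preprocessing chain runs end to end and is idempotent where declared", {
  d <- generate_dataset(left_config(seed = 31, n_ltc = 2, n_hipp = 2,
                                    trials = 8, fs = 256))
  pp <- preprocess(d$epochs)
  expect_s3_class(pp$evoked, "evoked_table")
  expect_setequal(pp$evoked$conditions, c("now", "then"))
  # averaging an already-averaged-compatible object again is stable
  ev2 <- average_evoked(pp$epochs)
  expect_equal(ev2$waveforms, pp$evoked$waveforms)
})
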