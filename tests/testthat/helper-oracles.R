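# Independent oracles and small fixture builders used across the suite.

# Fine-grid Riemann oracle for window integrals: midpoint sum on a grid
# `factor` times finer than the sampling step, waveform linearly
# interpolated (the waveform is defined as piecewise linear between
# samples).
fine_grid_integral <- function(waveform, times, window, factor = 100) {
  w0 <- max(window[1], times[1]); w1 <- min(window[2], times[length(times)])
  h <- (times[2] - times[1]) / factor
  mids <- seq(w0 + h / 2, w1, by = h)
  mids <- mids[mids < w1]
  vals <- stats::approx(times, waveform, xout = mids)$y
  sum(vals * h) + {
    # remainder strip if (w1 - w0) is not a multiple of h
    last <- w0 + length(mids) * h
    if (last < w1) stats::approx(times, waveform, xout = (last + w1) / 2)$y * (w1 - last) else 0
  }
}

# Brute-force run scanner for suprathreshold clusters, independent of the
# rle-based implementation.
scan_clusters <- function(t_series, crit) {
  out <- list()
  for (sgn in c(1, -1)) {
    inrun <- FALSE; i0 <- 0
    for (i in seq_along(t_series)) {
      over <- sgn * t_series[i] > crit
      if (over && !inrun) { inrun <- TRUE; i0 <- i }
      if ((!over || i == length(t_series)) && inrun) {
        i1 <- if (over) i else i - 1
        out[[length(out) + 1]] <- c(istart = i0, iend = i1, sign = sgn,
                                    mass = sum(t_series[i0:i1]))
        inrun <- FALSE
      }
    }
  }
  if (!length(out)) return(NULL)
  m <- do.call(rbind, out)
  m[order(m[, "istart"]), , drop = FALSE]
}

# Naive classification-chain oracle (scipy dual-QP SVM, explicit loops),
# entirely independent of the package implementation.
pipeline_oracle <- function(x_raw, y, grid = ieptask::default_c_grid()) {
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(X = as.matrix(x_raw), y = y, grid = grid),
                       f, auto_unbox = TRUE, digits = NA)
  out <- system2("python", c(shQuote(test_path("oracle_pipeline.py")),
                             shQuote(f)), stdout = TRUE, stderr = FALSE)
  jsonlite::fromJSON(paste(out, collapse = ""))
}

# Single-electrode epoch set from a trials x samples matrix.
toy_epochs <- function(mat, fs = 512, t0 = -100, condition = NULL,
                       task = "time", rejected = NULL) {
  n <- nrow(mat)
  times <- t0 + (seq_len(ncol(mat)) - 1) * 1000 / fs
  if (is.null(condition))
    condition <- rep(task_pair(task), length.out = n)
  epoch_set(array(mat, dim = c(n, 1, ncol(mat)),
                  dimnames = list(NULL, "e01", NULL)),
            times, fs, condition, rejected = rejected, task = task)
}

task_pair <- function(task) if (task == "space") c("here", "there") else c("now", "then")

# Compact left-hemisphere-only generator config for simulations.
left_config <- function(seed, n_ltc = 6L, n_hipp = 6L, trials = 60L,
                        fs = 512, early = 0.5, late = 0.5, noise = 2,
                        flip = 0.25, artifacts = 0.02) {
  generator_config(n_ltc_left = n_ltc, n_hipp_left = n_hipp,
                   n_ltc_right = 0L, n_hipp_right = 0L,
                   trials_per_condition = trials, sampling_rate = fs,
                   early_effect = early, late_effect = late,
                   noise_sd = noise, polarity_flip_prob = flip,
                   artifact_rate = artifacts, seed = seed)
}
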