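#' Configuration for the synthetic iEP generator
#'
#' Builds and validates the parameter set for [generate_dataset()]. The
#' defaults emulate the recording setup the pipeline targets: bitemporal
#' depth electrodes in the lateral temporal cortex (LTC) and hippocampus,
#' two conditions per task ("now"/"then" or "here"/"there"), epochs from
#' -100 to +800 ms around stimulus onset, and condition effects that are
#' region- and latency-specific -- an early (100--300 ms) amplitude
#' modulation at LTC electrodes and a late (400--600 ms) modulation at
#' hippocampal electrodes.
#'
#' @param n_ltc_left,n_hipp_left,n_ltc_right,n_hipp_right electrode counts
#'   per region and hemisphere. Defaults 6/6 left and 3/5 right.
#' @param trials_per_condition trials per condition (after collapsing the
#'   past/future factor), default 60 so a block holds ~120 trials.
#' @param sampling_rate sampling rate in Hz (512 default; 1024 supported).
#' @param epoch_window epoch limits in ms relative to stimulus onset.
#' @param component_spec data.frame with columns `latency_ms`, `width_ms`
#'   (Gaussian sd) and `amplitude_uv` describing the evoked kernel shared by
#'   all electrodes. The default is a biphasic early complex plus a late
#'   deflection, so both the early and late analysis windows carry signal.
#' @param early_effect,late_effect dimensionless multiplicative condition
#'   effects: inside its effect window the non-reference condition template
#'   equals the reference template scaled by `1 + effect`.
#' @param effect_window_early,effect_window_late effect windows in ms.
#' @param noise_sd additive i.i.d. Gaussian noise sd in microvolts.
#' @param polarity_flip_prob probability that an electrode's entire signal
#'   is sign-flipped (polarity reversal across a local generator).
#' @param artifact_rate fraction of trials receiving a high-amplitude
#'   transient (amplitude 10 x `noise_sd`). Artifact trials are not
#'   pre-flagged; rejection has to find them.
#' @param task task label, `"time"` or `"space"`.
#' @param seed integer RNG seed; the same seed reproduces the dataset
#'   bit-identically.
#'
#' @return a validated list of class `generator_config`.
#' @export
generator_config <- function(n_ltc_left = 6L, n_hipp_left = 6L,
                             n_ltc_right = 3L, n_hipp_right = 5L,
                             trials_per_condition = 60L,
                             sampling_rate = 512,
                             epoch_window = c(-100, 800),
                             component_spec = default_components(),
                             early_effect = 0.5, late_effect = 0.5,
                             effect_window_early = c(100, 300),
                             effect_window_late = c(400, 600),
                             noise_sd = 2,
                             polarity_flip_prob = 0.25,
                             artifact_rate = 0.02,
                             task = "time",
                             seed = 1L) {
  counts <- c(n_ltc_left, n_hipp_left, n_ltc_right, n_hipp_right)
  if (any(!is.finite(counts)) || any(counts < 0) || sum(counts) == 0)
    stop_input("electrode counts must be non-negative and sum to > 0")
  if (!is.finite(trials_per_condition) || trials_per_condition < 1)
    stop_input("trials_per_condition must be a positive count")
  if (!(length(epoch_window) == 2 && epoch_window[1] < 0 && 0 < epoch_window[2]))
    stop_input("epoch_window must straddle 0 (start < 0 < end)")
  for (w in list(effect_window_early, effect_window_late)) {
    if (!(w[1] < w[2] && w[1] >= 0 && w[2] <= epoch_window[2]))
      stop_input("effect windows must lie within [0, epoch end] with start < end")
  }
  if (!is.finite(noise_sd) || noise_sd < 0) stop_input("noise_sd must be >= 0")
  for (p in c(polarity_flip_prob, artifact_rate))
    if (!is.finite(p) || p < 0 || p > 1) stop_input("probabilities must be in [0, 1]")
  if (!is.finite(sampling_rate) || sampling_rate <= 0)
    stop_input("sampling_rate must be positive")
  validate_components(component_spec)
  task_conditions(task)  # errors on unknown task

  structure(list(
    n_ltc_left = as.integer(n_ltc_left), n_hipp_left = as.integer(n_hipp_left),
    n_ltc_right = as.integer(n_ltc_right), n_hipp_right = as.integer(n_hipp_right),
    trials_per_condition = as.integer(trials_per_condition),
    sampling_rate = sampling_rate, epoch_window = epoch_window,
    component_spec = component_spec,
    early_effect = early_effect, late_effect = late_effect,
    effect_window_early = effect_window_early,
    effect_window_late = effect_window_late,
    noise_sd = noise_sd, polarity_flip_prob = polarity_flip_prob,
    artifact_rate = artifact_rate, task = task, seed = as.integer(seed)
  ), class = "generator_config")
}

#' Default evoked kernel components
#'
#' A biphasic early complex (positive deflection at 180 ms, negative at
#' 300 ms) followed by a late positive deflection at 550 ms. Amplitudes are
#' in microvolts; widths are Gaussian standard deviations in ms. The signed
#' area of the kernel is well away from zero in both the early (100--400 ms)
#' and late (400--800 ms) analysis windows, so modulation denominators are
#' never degenerate on clean data.
#'
#' @return data.frame with columns `latency_ms`, `width_ms`, `amplitude_uv`.
#' @export
default_components <- function() {
  data.frame(
    latency_ms   = c(180, 300, 550),
    width_ms     = c(40, 50, 60),
    amplitude_uv = c(10, -4, 6)
  )
}

validate_components <- function(spec) {
  if (is.null(spec)) stop_input("component_spec must be a data.frame (possibly empty)")
  need <- c("latency_ms", "width_ms", "amplitude_uv")
  if (!all(need %in% names(spec)))
    stop_input("component_spec needs columns: ", paste(need, collapse = ", "))
  vals <- unlist(spec[need])
  if (length(vals) && any(!is.finite(vals)))
    stop_input("component_spec parameters must be finite")
  if (nrow(spec) && any(spec$width_ms <= 0))
    stop_input("component widths must be positive")
  invisible(spec)
}

#' Evoked-template kernel: sum of Gaussian deflections
#'
#' Evaluates `sum_k A_k * exp(-(t - mu_k)^2 / (2 sigma_k^2))` on the given
#' time axis. An empty component table yields an all-zero waveform.
#'
#' @param component_spec data.frame as in [generator_config()].
#' @param times time axis in ms.
#' @return numeric waveform in microvolts, same length as `times`.
#' @export
evoked_template <- function(component_spec, times) {
  validate_components(component_spec)
  if (!all(is.finite(times))) stop_input("times must be finite")
  w <- numeric(length(times))
  if (nrow(component_spec) == 0) return(w)
  for (k in seq_len(nrow(component_spec))) {
    mu <- component_spec$latency_ms[k]
    sg <- component_spec$width_ms[k]
    a  <- component_spec$amplitude_uv[k]
    w <- w + a * exp(-(times - mu)^2 / (2 * sg^2))
  }
  w
}

# Raised-cosine effect taper: 1 on the window interior, cosine ramps of
# `ramp_ms` just inside each edge, 0 outside. Smooth edges keep the
# injected condition difference free of filter ringing.
effect_taper <- function(times, window, ramp_ms = 20) {
  w0 <- window[1]; w1 <- window[2]
  ramp <- min(ramp_ms, (w1 - w0) / 2)
  tp <- numeric(length(times))
  inside <- times >= w0 & times <= w1
  tp[inside] <- 1
  up <- inside & times < w0 + ramp
  tp[up] <- 0.5 * (1 - cos(pi * (times[up] - w0) / ramp))
  dn <- inside & times > w1 - ramp
  tp[dn] <- 0.5 * (1 - cos(pi * (w1 - times[dn]) / ramp))
  tp
}

#' Construct an epoch set
#'
#' Low-level constructor/validator for the trial x electrode x sample
#' container used throughout the pipeline.
#'
#' @param data numeric array, trials x electrodes x samples (microvolts),
#'   with electrode ids as the second dimnames.
#' @param times time axis in ms (length = samples).
#' @param fs sampling rate in Hz.
#' @param condition character per-trial condition labels.
#' @param rejected logical per-trial rejection flags.
#' @param task task label (`"time"` or `"space"`).
#' @param phase optional per-trial metadata factor (e.g. the before/after
#'   stimulus subcondition, carried but not analyzed).
#' @return an object of class `epoch_set`.
#' @export
epoch_set <- function(data, times, fs, condition, rejected = NULL, task = "time",
                      phase = NULL) {
  if (length(dim(data)) != 3) stop_input("data must be a 3-d array (trials x electrodes x samples)")
  n_trials <- dim(data)[1]; n_samp <- dim(data)[3]
  if (length(times) != n_samp) stop_input("length(times) must equal the sample dimension")
  dt <- 1000 / fs
  if (max(abs(diff(times) - dt)) > 1e-6)
    stop_input("times spacing must equal 1000/fs ms")
  if (is.null(rejected)) rejected <- rep(FALSE, n_trials)
  if (length(condition) != n_trials || length(rejected) != n_trials)
    stop_input("condition and rejected must have one entry per trial")
  conds <- allowed_conditions(task)
  if (!all(condition %in% conds))
    stop_input("condition labels must be drawn from the task design (",
               paste(conds, collapse = "/"), ")")
  keep <- table(condition[!rejected])
  if (any(keep < 2))
    stop_input("need at least 2 non-rejected trials per condition")
  if (is.null(dimnames(data)[[2]]))
    dimnames(data)[[2]] <- sprintf("e%02d", seq_len(dim(data)[2]))
  structure(list(data = data, times = times, fs = fs,
                 condition = as.character(condition),
                 rejected = as.logical(rejected), task = task,
                 phase = phase),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d electrodes x %d samples @ %g Hz, task '%s'\n",
              d[1], d[2], d[3], x$fs, x$task))
  cat("  conditions:", paste(sprintf("%s=%d", names(table(x$condition)),
                                     table(x$condition)), collapse = ", "),
      sprintf("| rejected: %d\n", sum(x$rejected)))
  invisible(x)
}

electrode_ids <- function(n, hemi, region) {
  if (n == 0) return(character(0))
  sprintf("%s-%s-%02d", hemi, region, seq_len(n))
}

#' Generate a synthetic trial-level iEP dataset
#'
#' Simulates epochs for every configured electrode. All electrodes share
#' the evoked kernel from `config$component_spec`; the non-reference
#' condition ("then"/"there") is the reference template multiplied by
#' `1 + early_effect` inside the early effect window at LTC electrodes and
#' by `1 + late_effect` inside the late window at hippocampal electrodes,
#' with a 20 ms raised-cosine taper at the window edges. Trials are the
#' template plus i.i.d. Gaussian noise; each electrode's sign is flipped
#' with probability `polarity_flip_prob` (identically across its trials and
#' conditions); a fraction `artifact_rate` of trials receives a Gaussian
#' transient of amplitude `10 * noise_sd` at a random latency on one random
#' electrode, and such trials are deliberately not pre-flagged.
#'
#' Each electrode draws from a deterministic substream of `config$seed`, so
#' adding electrodes does not perturb existing ones, and the same seed
#' reproduces the dataset bit-identically.
#'
#' @param config a [generator_config()].
#' @return list with elements `epochs` (an [epoch_set()]) and `meta`
#'   (data.frame: `electrode_id`, `region`, `hemisphere`, `patient`).
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "generator_config"))
    stop_input("config must be a generator_config")
  fs <- config$sampling_rate
  dt <- 1000 / fs
  times <- seq(config$epoch_window[1], config$epoch_window[2], by = dt)
  conds <- task_conditions(config$task)

  meta <- data.frame(
    electrode_id = c(electrode_ids(config$n_ltc_left,  "L", "LTC"),
                     electrode_ids(config$n_hipp_left, "L", "HIPP"),
                     electrode_ids(config$n_ltc_right, "R", "LTC"),
                     electrode_ids(config$n_hipp_right, "R", "HIPP")),
    region = c(rep("LTC", config$n_ltc_left), rep("HIPP", config$n_hipp_left),
               rep("LTC", config$n_ltc_right), rep("HIPP", config$n_hipp_right)),
    hemisphere = c(rep("L", config$n_ltc_left + config$n_hipp_left),
                   rep("R", config$n_ltc_right + config$n_hipp_right)),
    stringsAsFactors = FALSE
  )
  meta$patient <- sprintf("P%d", (seq_len(nrow(meta)) - 1L) %% 3L + 1L)
  n_elec <- nrow(meta)
  if (n_elec == 0) stop_input("empty electrode set")
  n_per <- config$trials_per_condition
  n_trials <- 2L * n_per
  n_samp <- length(times)

  base <- evoked_template(config$component_spec, times)
  taper_early <- effect_taper(times, config$effect_window_early)
  taper_late  <- effect_taper(times, config$effect_window_late)

  # Deterministic trial order: conditions interleaved, before/after phase
  # alternating within condition (metadata only, no injected effect).
  condition <- rep(conds, n_per)
  phase <- rep(c("before", "after"), length.out = n_trials)

  data <- array(0, dim = c(n_trials, n_elec, n_samp),
                dimnames = list(NULL, meta$electrode_id, NULL))
  idx_b <- which(condition == conds[2])

  for (e in seq_len(n_elec)) {
    region <- meta$region[e]
    tmpl_a <- base
    tmpl_b <- switch(region,
      LTC  = base * (1 + config$early_effect * taper_early),
      HIPP = base * (1 + config$late_effect * taper_late),
      base)
    local_seed(substream_seed(config$seed, e), {
      flip <- if (stats::runif(1) < config$polarity_flip_prob) -1 else 1
      noise <- matrix(stats::rnorm(n_trials * n_samp, sd = config$noise_sd),
                      n_trials, n_samp)
      m <- matrix(rep(tmpl_a, each = n_trials), n_trials, n_samp)
      m[idx_b, ] <- matrix(rep(tmpl_b, each = length(idx_b)),
                           length(idx_b), n_samp)
      data[, e, ] <- flip * (m + noise)
    })
  }

  # Artifact transients: drawn from substream 0 so they are independent of
  # the electrode noise substreams.
  local_seed(substream_seed(config$seed, 0L), {
    art <- which(stats::runif(n_trials) < config$artifact_rate)
    for (tr in art) {
      e <- sample.int(n_elec, 1)
      lat <- stats::runif(1, min = 0, max = config$epoch_window[2])
      transient <- 10 * config$noise_sd * exp(-(times - lat)^2 / (2 * 15^2))
      data[tr, e, ] <- data[tr, e, ] + transient
    }
  })

  epochs <- epoch_set(data, times, fs, condition, task = config$task,
                      phase = phase)
  list(epochs = epochs, meta = meta)
}

#' Combine two epoch sets recorded on disjoint electrodes
#'
#' Used to assemble hemispheres generated with different effect settings
#' into one dataset. Trial structure (labels, counts, time axis) must
#' match; electrode ids must be disjoint.
#'
#' @param a,b `epoch_set` objects.
#' @return an `epoch_set` over the union of electrodes.
#' @export
combine_electrodes <- function(a, b) {
  if (!identical(a$condition, b$condition) || !identical(a$times, b$times) ||
      !identical(a$task, b$task))
    stop_input("epoch sets must share trial structure, time axis and task")
  if (length(intersect(dimnames(a$data)[[2]], dimnames(b$data)[[2]])) > 0)
    stop_input("electrode ids must be disjoint")
  d <- array(0, dim = c(dim(a$data)[1], dim(a$data)[2] + dim(b$data)[2],
                        dim(a$data)[3]),
             dimnames = list(NULL, c(dimnames(a$data)[[2]], dimnames(b$data)[[2]]),
                             NULL))
  d[, seq_len(dim(a$data)[2]), ] <- a$data
  d[, dim(a$data)[2] + seq_len(dim(b$data)[2]), ] <- b$data
  epoch_set(d, a$times, a$fs, a$condition,
            rejected = a$rejected | b$rejected, task = a$task, phase = a$phase)
}
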