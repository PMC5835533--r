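#' Zero-phase Butterworth band-pass filter
#'
#' Applies a 4th-order Butterworth band-pass forward and backward
#' (`signal::filtfilt`, zero phase) to every trial x electrode trace. Each
#' trace is demeaned first, so DC is removed exactly rather than left to
#' the slow edge transient of a 1 Hz high-pass on a sub-second epoch. The
#' first and last 50 ms of a filtered epoch remain edge-contaminated and
#' are recorded as untrusted in the `edge_untrusted_ms` attribute.
#'
#' @param epochs an [epoch_set()].
#' @param low_hz,high_hz band edges in Hz (defaults 1 and 120).
#' @return the filtered `epoch_set`.
#' @export
bandpass <- function(epochs, low_hz = 1, high_hz = 120) {
  if (!inherits(epochs, "epoch_set")) stop_input("epochs must be an epoch_set")
  nyq <- epochs$fs / 2
  if (!(low_hz > 0 && low_hz < high_hz)) stop_input("need 0 < low_hz < high_hz")
  if (high_hz >= nyq)
    stop_input("high_hz (", high_hz, ") must be below the Nyquist frequency (",
               nyq, " Hz)")
  filt <- signal::butter(4, c(low_hz, high_hz) / nyq, type = "pass")
  d <- epochs$data
  for (e in seq_len(dim(d)[2])) {
    m <- d[, e, , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    m <- m - rowMeans(m)
    d[, e, ] <- t(apply(m, 1, function(x) signal::filtfilt(filt, x)))
  }
  epochs$data <- d
  attr(epochs, "edge_untrusted_ms") <- 50
  attr(epochs, "bandpass_hz") <- c(low_hz, high_hz)
  epochs
}

#' Baseline-correct epochs
#'
#' Subtracts the per-trial, per-electrode mean amplitude over the baseline
#' window (default the full pre-stimulus interval).
#'
#' @param epochs an [epoch_set()].
#' @param window baseline window in ms, default `c(-100, 0)`.
#' @return the corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs, window = c(-100, 0)) {
  sel <- epochs$times >= window[1] & epochs$times < window[2]
  if (!any(sel)) stop_input("baseline window contains no samples")
  bl <- rowSums(epochs$data[, , sel, drop = FALSE], dims = 2) / sum(sel)
  epochs$data <- epochs$data - array(bl, dim = dim(epochs$data))
  attr(epochs, "baseline_ms") <- window
  epochs
}

#' Flag artifact trials by robust amplitude z-score
#'
#' Automated stand-in for visual rejection of epochs with epileptic
#' discharges. For each electrode and time sample, amplitudes across trials
#' are standardized robustly (median / 1.4826 x MAD); a trial is flagged if
#' any of its samples on any electrode exceeds `z_threshold` in absolute
#' robust z. Standardizing per time sample removes the evoked template, so
#' the statistic sees only trial-to-trial deviations. Existing flags are
#' never cleared.
#'
#' @param epochs an [epoch_set()].
#' @param z_threshold robust z cutoff, default 6. `Inf` flags nothing.
#' @return the `epoch_set` with updated `rejected` flags.
#' @export
reject_epochs <- function(epochs, z_threshold = 6) {
  if (!inherits(epochs, "epoch_set")) stop_input("epochs must be an epoch_set")
  tab <- table(epochs$condition)
  if (any(tab < 3)) stop_input("need at least 3 trials per condition before rejection")
  flag <- rep(FALSE, dim(epochs$data)[1])
  if (is.finite(z_threshold)) {
    for (e in seq_len(dim(epochs$data)[2])) {
      m <- epochs$data[, e, , drop = TRUE]
      if (is.null(dim(m))) m <- matrix(m, nrow = 1)
      med <- apply(m, 2, stats::median)
      sc <- 1.4826 * apply(m, 2, stats::mad, constant = 1)
      dev <- abs(sweep(m, 2, med))
      z <- sweep(dev, 2, sc, "/")
      z[is.nan(z)] <- 0        # 0/0: no deviation, no flag
      flag <- flag | apply(z > z_threshold, 1, any)
    }
  }
  rejected <- epochs$rejected | flag
  left <- table(epochs$condition[!rejected])
  if (length(left) < length(tab) || any(left < 2))
    stop_input("rejection would leave fewer than 2 trials in a condition")
  epochs$rejected <- rejected
  epochs
}

#' Collapse condition labels
#'
#' Relabels trials, e.g. merging the past and future conditions into a
#' single "then" condition to obtain the 2 x 2 design analyzed downstream.
#' Pure relabeling: trial counts and data are untouched; applying the
#' default mapping to already-collapsed data is a no-op.
#'
#' @param epochs an [epoch_set()].
#' @param mapping named character vector, `old_label = new_label`. Every
#'   label present in the data must appear among the names.
#' @return the relabeled `epoch_set`.
#' @export
collapse_conditions <- function(epochs,
                                mapping = c(past = "then", future = "then",
                                            now = "now", then = "then")) {
  present <- unique(epochs$condition)
  miss <- setdiff(present, names(mapping))
  if (length(miss))
    stop_input("mapping missing label(s) present in data: ",
               paste(miss, collapse = ", "))
  epochs$condition <- unname(mapping[epochs$condition])
  bad <- setdiff(unique(epochs$condition), allowed_conditions(epochs$task))
  if (length(bad))
    stop_input("mapping produces labels outside the task design: ",
               paste(bad, collapse = ", "))
  epochs
}

#' Average epochs into per-condition evoked potentials
#'
#' Arithmetic mean over non-rejected trials for every (electrode,
#' condition) cell, the iEP proper.
#'
#' @param epochs an [epoch_set()].
#' @return an object of class `evoked_table`: list with `waveforms`
#'   (electrode x condition x sample array, microvolts), `n_trials`
#'   (electrode x condition matrix), `times`, `fs`, `task`, `conditions`.
#' @export
average_evoked <- function(epochs) {
  if (!inherits(epochs, "epoch_set")) stop_input("epochs must be an epoch_set")
  conds <- sort(unique(epochs$condition))
  ids <- dimnames(epochs$data)[[2]]
  n_samp <- dim(epochs$data)[3]
  wf <- array(NA_real_, dim = c(length(ids), length(conds), n_samp),
              dimnames = list(ids, conds, NULL))
  n_tr <- matrix(0L, length(ids), length(conds), dimnames = list(ids, conds))
  for (ci in seq_along(conds)) {
    keep <- epochs$condition == conds[ci] & !epochs$rejected
    if (sum(keep) < 2)
      stop_input("fewer than 2 non-rejected trials in condition ", conds[ci])
    sub <- epochs$data[keep, , , drop = FALSE]
    wf[, ci, ] <- colMeans(sub)   # averages over the trial dimension
    n_tr[, ci] <- sum(keep)
  }
  structure(list(waveforms = wf, n_trials = n_tr, times = epochs$times,
                 fs = epochs$fs, task = epochs$task, conditions = conds),
            class = "evoked_table")
}

#' @export
print.evoked_table <- function(x, ...) {
  cat(sprintf("<evoked_table> %d electrodes x %d conditions x %d samples @ %g Hz (task '%s')\n",
              dim(x$waveforms)[1], dim(x$waveforms)[2], dim(x$waveforms)[3],
              x$fs, x$task))
  invisible(x)
}

#' Standard preprocessing chain
#'
#' Filter, reject, collapse, average -- in that order.
#'
#' @param epochs an [epoch_set()].
#' @param low_hz,high_hz band-pass edges in Hz.
#' @param z_threshold robust rejection threshold (see [reject_epochs()]).
#' @param baseline logical; subtract the pre-stimulus mean per trial
#'   (default TRUE). Kept configurable because the modulation features'
#'   denominator is sensitive to DC offsets.
#' @param mapping condition collapse map (see [collapse_conditions()]).
#' @return list with `epochs` (processed) and `evoked` (an `evoked_table`).
#' @export
preprocess <- function(epochs, low_hz = 1, high_hz = 120, z_threshold = 6,
                       baseline = TRUE,
                       mapping = c(past = "then", future = "then",
                                   now = "now", then = "then")) {
  x <- bandpass(epochs, low_hz, high_hz)
  if (baseline) x <- baseline_correct(x)
  x <- reject_epochs(x, z_threshold)
  if (identical(x$task, "time")) x <- collapse_conditions(x, mapping)
  list(epochs = x, evoked = average_evoked(x))
}
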