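#' Trapezoidal window integral of a sampled waveform
#'
#' Integrates the waveform over the continuous interval `[w0, w1]` by the
#' trapezoid rule, linearly interpolating at the window edges when they
#' fall between samples. Because the waveform is treated as piecewise
#' linear, integrals over abutting windows add exactly:
#' `window_integral(w, t, c(a, b)) + window_integral(w, t, c(b, c))`
#' equals `window_integral(w, t, c(a, c))` to rounding error, so a shared
#' boundary (e.g. 400 ms between the early and late periods) is never
#' double-counted.
#'
#' @param waveform numeric amplitudes (microvolts).
#' @param times sample times in ms (strictly increasing).
#' @param window length-2 numeric, `c(start_ms, end_ms)`; must lie within
#'   the range of `times` and have positive length. A nominal window edge
#'   may overshoot the sampled extent by at most one sample interval (the
#'   epoch end rarely falls exactly on a sample) and is clipped to it.
#' @return signed area in microvolt-milliseconds.
#' @export
window_integral <- function(waveform, times, window) {
  if (length(window) != 2 || !all(is.finite(window)) || window[1] >= window[2])
    stop_input("window must be c(start, end) with start < end")
  dt <- times[2] - times[1]
  if (window[1] < times[1] - dt || window[2] > times[length(times)] + dt)
    stop_input("window [", window[1], ", ", window[2],
               "] outside the sampled time range")
  window <- c(max(window[1], times[1]), min(window[2], times[length(times)]))
  if (window[1] >= window[2]) stop_input("window collapses to zero length")
  if (length(waveform) != length(times)) stop_input("waveform/times length mismatch")
  inner <- times > window[1] & times < window[2]
  grid <- c(window[1], times[inner], window[2])
  vals <- stats::approx(times, waveform, xout = grid)$y
  sum(diff(grid) * (utils::head(vals, -1) + utils::tail(vals, -1)) / 2)
}

#' Raw condition modulation over a window
#'
#' Absolute signed area between two evoked waveforms:
#' `|integral over window of (S_b - S_a)|`.
#'
#' @param s_a,s_b evoked waveforms for the reference and comparison
#'   condition.
#' @param times sample times in ms.
#' @param window integration window in ms.
#' @return non-negative area in microvolt-milliseconds.
#' @export
raw_modulation <- function(s_a, s_b, times, window) {
  abs(window_integral(s_b - s_a, times, window))
}

#' Normalized task modulation of one electrode
#'
#' The raw modulation divided by the absolute signed area of the reference
#' condition over the same window:
#'
#'   `modulation = |int (S_b - S_a) dt| / |int S_a dt|`
#'
#' The statistic is dimensionless, invariant under a common rescaling (or
#' sign flip) of both waveforms, and therefore insensitive to electrode
#' polarity reversal. When the denominator is degenerate (below
#' `eps_scale * window length * max|S_a|`) the value is `NA` and a
#' `degenerate_denominator` warning is signalled: such electrodes carry no
#' usable normalization and are excluded from classification rather than
#' silently zeroed.
#'
#' @inheritParams raw_modulation
#' @param eps_scale relative degeneracy threshold, default `1e-9`.
#' @param abs_auc if `TRUE`, normalize by the rectified area
#'   `int |S_a| dt` instead of the absolute signed area. The signed-area
#'   denominator is the default reading of the statistic; the rectified
#'   variant is offered because "area under the curve" is often read that
#'   way.
#' @return dimensionless non-negative scalar, or `NA_real_` if degenerate.
#' @export
task_modulation <- function(s_a, s_b, times, window, eps_scale = 1e-9,
                            abs_auc = FALSE) {
  num <- raw_modulation(s_a, s_b, times, window)
  den <- if (abs_auc) window_integral(abs(s_a), times, window)
         else abs(window_integral(s_a, times, window))
  eps <- eps_scale * (window[2] - window[1]) * max(abs(s_a), 1e-300)
  if (den <= eps) {
    warning(warningCondition(
      sprintf("degenerate denominator (|area| = %.3g) in window [%g, %g] ms",
              den, window[1], window[2]),
      class = "degenerate_denominator"))
    return(NA_real_)
  }
  num / den
}

#' Early/late task-modulation features for every electrode
#'
#' Computes the (early, late) modulation pair per electrode from a
#' per-condition evoked table, using the condition pair of the task
#' ("now" vs "then", or "here" vs "there"; the first is the reference).
#' Electrodes with a degenerate denominator in either window are returned
#' with `degenerate = TRUE` and `NA` features, with a single collected
#' warning.
#'
#' @param evoked an `evoked_table` from [average_evoked()].
#' @param early_window,late_window analysis windows in ms; defaults
#'   `c(100, 400)` and `c(400, 800)`.
#' @param meta optional electrode metadata to join onto the result.
#' @param abs_auc see [task_modulation()].
#' @return data.frame: `electrode_id`, `task`, `early`, `late`,
#'   `degenerate`, plus metadata columns when `meta` is supplied. Window
#'   bounds are recorded in the `early_window` / `late_window` attributes.
#' @export
features_for_dataset <- function(evoked, early_window = c(100, 400),
                                 late_window = c(400, 800), meta = NULL,
                                 abs_auc = FALSE) {
  if (!inherits(evoked, "evoked_table")) stop_input("evoked must be an evoked_table")
  pair <- task_conditions(evoked$task)
  miss <- setdiff(pair, evoked$conditions)
  if (length(miss))
    stop_input("evoked table lacks condition(s): ", paste(miss, collapse = ", "))
  ids <- dimnames(evoked$waveforms)[[1]]
  out <- data.frame(electrode_id = ids, task = evoked$task,
                    early = NA_real_, late = NA_real_, degenerate = FALSE,
                    stringsAsFactors = FALSE)
  degen <- character(0)
  for (i in seq_along(ids)) {
    s_a <- evoked$waveforms[i, pair[1], ]
    s_b <- evoked$waveforms[i, pair[2], ]
    vals <- withCallingHandlers({
      c(task_modulation(s_a, s_b, evoked$times, early_window, abs_auc = abs_auc),
        task_modulation(s_a, s_b, evoked$times, late_window, abs_auc = abs_auc))
    }, degenerate_denominator = function(w) invokeRestart("muffleWarning"))
    out$early[i] <- vals[1]; out$late[i] <- vals[2]
    if (anyNA(vals)) { out$degenerate[i] <- TRUE; degen <- c(degen, ids[i]) }
  }
  if (length(degen))
    warning("electrode(s) with degenerate modulation denominator excluded ",
            "from classification: ", paste(degen, collapse = ", "),
            call. = FALSE)
  if (!is.null(meta))
    out <- merge(out, meta, by = "electrode_id", sort = FALSE)
  attr(out, "early_window") <- early_window
  attr(out, "late_window") <- late_window
  out
}
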