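# Reduced-electrode power analysis: classification over all electrode
# subsets of one hemisphere matching another hemisphere's composition.

#' Enumerate electrode subsets with fixed per-region sizes
#'
#' All subsets of one hemisphere's electrodes containing exactly
#' `n_hipp_subset` hippocampal and `n_ltc_subset` LTC electrodes —
#' exhaustive, duplicate-free, in deterministic lexicographic order
#' (hippocampal combination varying slowest).
#'
#' @param meta electrode metadata (`electrode_id`, `region`, `hemisphere`).
#' @param n_hipp_subset,n_ltc_subset subset sizes per region (defaults 5
#'   and 3, the right-hemisphere composition).
#' @param hemisphere hemisphere to draw from, default `"L"`.
#' @return list of character vectors of electrode ids, of length
#'   `choose(N_hipp, n_hipp_subset) * choose(N_ltc, n_ltc_subset)`.
#' @export
enumerate_subsets <- function(meta, n_hipp_subset = 5, n_ltc_subset = 3,
                              hemisphere = "L") {
  hipp <- sort(meta$electrode_id[meta$hemisphere == hemisphere &
                                   meta$region == "HIPP"])
  ltc <- sort(meta$electrode_id[meta$hemisphere == hemisphere &
                                  meta$region == "LTC"])
  if (length(hipp) < n_hipp_subset || length(ltc) < n_ltc_subset)
    stop_input("hemisphere ", hemisphere, " has ", length(hipp), " HIPP / ",
               length(ltc), " LTC electrodes; cannot draw subsets of (",
               n_hipp_subset, ", ", n_ltc_subset, ")")
  hc <- utils::combn(hipp, n_hipp_subset, simplify = FALSE)
  lc <- utils::combn(ltc, n_ltc_subset, simplify = FALSE)
  out <- vector("list", length(hc) * length(lc))
  k <- 0L
  for (h in hc) for (l in lc) { k <- k + 1L; out[[k]] <- c(h, l) }
  out
}

#' Classification over all matched electrode subsets
#'
#' Runs the full classification chain ([classify_electrodes()], including
#' per-subset z-scoring, penalty selection and the exhaustive permutation
#' test) on every subset from [enumerate_subsets()], and aggregates the
#' accuracy and p-value distributions. Used to ask how often a reduced
#' electrode complement would still have detected the separation.
#'
#' @inheritParams enumerate_subsets
#' @param features feature data.frame from [features_for_dataset()].
#' @param task task label; defaults to the features' task.
#' @param accuracy_threshold accuracy cut for the `frac_accuracy_above`
#'   summary (strict inequality), default 0.75.
#' @param alpha significance level for `frac_significant`, default 0.05.
#' @param c_grid penalty grid.
#' @param exhaustive_cap see [permutation_test()].
#' @return object of class `subset_report`: `subset_spec`, `n_subsets`,
#'   `per_subset` (data.frame: `subset`, `electrodes`, `loo_accuracy`,
#'   `p_value`, `selected_C`), `frac_accuracy_above`, `frac_significant`,
#'   `accuracy_threshold`, `alpha`.
#' @export
subset_analysis <- function(features, meta, n_hipp_subset = 5,
                            n_ltc_subset = 3, hemisphere = "L", task = NULL,
                            accuracy_threshold = 0.75, alpha = 0.05,
                            c_grid = default_c_grid(),
                            exhaustive_cap = 20000) {
  subsets <- enumerate_subsets(meta, n_hipp_subset, n_ltc_subset, hemisphere)
  task <- task %||% features$task[1]
  rows <- vector("list", length(subsets))
  for (k in seq_along(subsets)) {
    ids <- subsets[[k]]
    res <- classify_electrodes(features[features$electrode_id %in% ids, ,
                                        drop = FALSE],
                               meta[meta$electrode_id %in% ids, , drop = FALSE],
                               hemisphere = hemisphere, task = task,
                               c_grid = c_grid, exhaustive_cap = exhaustive_cap)
    rows[[k]] <- data.frame(subset = k,
                            electrodes = paste(ids, collapse = ","),
                            loo_accuracy = res$loo_accuracy,
                            p_value = res$p_value,
                            selected_C = res$selected_C,
                            stringsAsFactors = FALSE)
  }
  per_subset <- do.call(rbind, rows)
  structure(list(
    subset_spec = c(n_hipp_subset = n_hipp_subset, n_ltc_subset = n_ltc_subset),
    hemisphere = hemisphere, task = task,
    n_subsets = length(subsets),
    per_subset = per_subset,
    frac_accuracy_above = mean(per_subset$loo_accuracy > accuracy_threshold),
    frac_significant = mean(per_subset$p_value < alpha),
    accuracy_threshold = accuracy_threshold, alpha = alpha
  ), class = "subset_report")
}

#' @export
print.subset_report <- function(x, ...) {
  cat(sprintf("<subset_report> hemisphere %s, task '%s': %d subsets of (%d HIPP, %d LTC)\n",
              x$hemisphere, x$task, x$n_subsets,
              x$subset_spec["n_hipp_subset"], x$subset_spec["n_ltc_subset"]))
  cat(sprintf("  accuracy > %.0f%%: %d/%d (%.2f)   p < %.2f: %d/%d (%.2f)\n",
              100 * x$accuracy_threshold,
              round(x$frac_accuracy_above * x$n_subsets), x$n_subsets,
              x$frac_accuracy_above,
              x$alpha, round(x$frac_significant * x$n_subsets), x$n_subsets,
              x$frac_significant))
  invisible(x)
}
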