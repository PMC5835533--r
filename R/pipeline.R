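#' Configuration for a full analysis run
#'
#' Bundles every stage's settings with a single top seed. The default
#' scenario mirrors the study structure the pipeline targets: a time task
#' whose left-hemisphere electrodes carry the region-specific early/late
#' effects, a right hemisphere with no injected effect, and a space task
#' with no injected effect anywhere — so the expected report pattern is a
#' clean left/time separation and null results elsewhere.
#'
#' @param seed top-level RNG seed; every stage's randomness derives from it.
#' @param trials_per_condition,sampling_rate,noise_sd,polarity_flip_prob,artifact_rate
#'   generator settings shared by all cells (see [generator_config()]).
#' @param early_effect,late_effect left-hemisphere time-task effect sizes.
#' @param right_early_effect,right_late_effect right-hemisphere time-task
#'   effects, default 0.
#' @param space_effect effect size for the space task (both regions,
#'   respective windows), default 0.
#' @param low_hz,high_hz,z_threshold,baseline preprocessing settings.
#' @param early_window,late_window feature windows in ms.
#' @param c_grid,fold_safe_scaling,exhaustive_cap,n_mc classifier settings
#'   (see [classify_electrodes()]).
#' @param cluster_n_perm permutations per cluster test (0 disables the
#'   cluster stage).
#' @param cluster_electrodes electrode ids to cluster-test, `NULL` = all.
#' @param do_subsets run the left-hemisphere subset power analysis for the
#'   time task.
#' @param n_hipp_subset,n_ltc_subset subset composition.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       trials_per_condition = 60L, sampling_rate = 512,
                       noise_sd = 2, polarity_flip_prob = 0.25,
                       artifact_rate = 0.02,
                       early_effect = 0.5, late_effect = 0.5,
                       right_early_effect = 0, right_late_effect = 0,
                       space_effect = 0,
                       low_hz = 1, high_hz = 120, z_threshold = 6,
                       baseline = TRUE,
                       early_window = c(100, 400), late_window = c(400, 800),
                       c_grid = default_c_grid(), fold_safe_scaling = FALSE,
                       exhaustive_cap = 20000, n_mc = 2000,
                       cluster_n_perm = 1000, cluster_electrodes = NULL,
                       do_subsets = TRUE, n_hipp_subset = 5, n_ltc_subset = 3) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop_input("stage '", name, "' failed: ", conditionMessage(e)))
}

#' Run the full analysis pipeline
#'
#' simulate -> preprocess -> features -> classify for every hemisphere x
#' task cell, plus per-electrode cluster tests and the left-hemisphere
#' subset power analysis. Deterministic given `config$seed`.
#'
#' @param config a [run_config()].
#' @param out optional output directory; when given, the report JSON and
#'   per-task feature TSVs are written there.
#' @return list of class `run_report`: `classification` (named list
#'   `L.time`, `R.time`, `L.space`, `R.space`), `features` (per task),
#'   `clusters`, `subsets`, `config`.
#' @export
run_all <- function(config = run_config(), out = NULL) {
  if (!inherits(config, "run_config")) stop_input("config must be a run_config")
  report <- list(classification = list(), features = list(), clusters = list(),
                 subsets = NULL, config = config)
  meta_all <- list()
  seed_of <- function(k) (config$seed + 101L * k) %% 2147483647

  for (ti in seq_along(c("time", "space"))) {
    task <- c("time", "space")[ti]
    eff <- function(hemi, which) {
      if (task == "space") return(config$space_effect)
      if (hemi == "L") {
        if (which == "early") config$early_effect else config$late_effect
      } else {
        if (which == "early") config$right_early_effect else config$right_late_effect
      }
    }
    gen <- function(hemi, k) {
      generator_config(
        n_ltc_left = if (hemi == "L") 6L else 0L,
        n_hipp_left = if (hemi == "L") 6L else 0L,
        n_ltc_right = if (hemi == "R") 3L else 0L,
        n_hipp_right = if (hemi == "R") 5L else 0L,
        trials_per_condition = config$trials_per_condition,
        sampling_rate = config$sampling_rate,
        early_effect = eff(hemi, "early"), late_effect = eff(hemi, "late"),
        noise_sd = config$noise_sd,
        polarity_flip_prob = config$polarity_flip_prob,
        artifact_rate = config$artifact_rate,
        task = task, seed = seed_of(k))
    }
    left <- stage("simulate", generate_dataset(gen("L", 2L * ti)))
    right <- stage("simulate", generate_dataset(gen("R", 2L * ti + 1L)))
    epochs <- stage("simulate", combine_electrodes(left$epochs, right$epochs))
    meta <- rbind(left$meta, right$meta)
    meta_all[[task]] <- meta

    pp <- stage("preprocess",
                preprocess(epochs, config$low_hz, config$high_hz,
                           config$z_threshold, config$baseline))
    feats <- stage("features",
                   features_for_dataset(pp$evoked, config$early_window,
                                        config$late_window, meta = meta))
    report$features[[task]] <- feats

    for (hemi in c("L", "R")) {
      report$classification[[paste(hemi, task, sep = ".")]] <-
        stage("classify",
              classify_electrodes(feats, meta, hemisphere = hemi, task = task,
                                  c_grid = config$c_grid,
                                  fold_safe_scaling = config$fold_safe_scaling,
                                  exhaustive_cap = config$exhaustive_cap,
                                  n_mc = config$n_mc,
                                  seed = seed_of(10L + 2L * ti +
                                                   (hemi == "R"))))
    }

    if (config$cluster_n_perm > 0) {
      ids <- config$cluster_electrodes %||% dimnames(pp$epochs$data)[[2]]
      pair <- task_conditions(task)
      cl <- lapply(seq_along(ids), function(i)
        stage("cluster_test",
              cluster_test(pp$epochs, ids[i], pair[1], pair[2],
                           n_perm = config$cluster_n_perm,
                           seed = seed_of(100L + 10L * ti + i))))
      names(cl) <- ids
      report$clusters[[task]] <- cl
    }
  }

  if (config$do_subsets)
    report$subsets <- stage("subsets",
      subset_analysis(report$features$time, meta_all$time,
                      n_hipp_subset = config$n_hipp_subset,
                      n_ltc_subset = config$n_ltc_subset,
                      hemisphere = "L", task = "time",
                      c_grid = config$c_grid,
                      exhaustive_cap = config$exhaustive_cap))

  class(report) <- "run_report"
  if (!is.null(out)) write_report(report, out)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> hemisphere x task classification grid\n")
  for (nm in names(x$classification)) {
    r <- x$classification[[nm]]
    cat(sprintf("  %-8s accuracy %6.2f%%  p = %.4g (%d labelings)\n",
                nm, 100 * r$loo_accuracy, r$p_value, r$n_permutations))
  }
  if (!is.null(x$subsets))
    cat(sprintf("  subsets: %d; accuracy>%.0f%%: %.2f; significant: %.2f\n",
                x$subsets$n_subsets, 100 * x$subsets$accuracy_threshold,
                x$subsets$frac_accuracy_above, x$subsets$frac_significant))
  invisible(x)
}

# Serialize a run report: JSON summary + per-task feature TSVs.
write_report <- function(report, out) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  for (task in names(report$features))
    data.table::fwrite(report$features[[task]],
                       file.path(out, sprintf("features_%s.tsv", task)),
                       sep = "\t")
  js <- list(
    config = report$config[setdiff(names(report$config), "c_grid")],
    c_grid = report$config$c_grid,
    classification = lapply(report$classification, function(r)
      list(hemisphere = r$hemisphere, task = r$task,
           n_per_class = as.list(r$n_per_class),
           selected_C = r$selected_C, cv_by_c = as.list(r$cv_by_c),
           loo_accuracy = r$loo_accuracy, p_value = r$p_value,
           n_permutations = r$n_permutations, exhaustive = r$exhaustive,
           hyperplane = r$hyperplane)),
    clusters = lapply(report$clusters, function(task_cl)
      lapply(task_cl, function(cl)
        list(electrode_id = cl$electrode_id, significant = cl$significant,
             clusters = cl$clusters, n_permutations = cl$n_permutations))),
    subsets = if (!is.null(report$subsets))
      report$subsets[c("subset_spec", "n_subsets", "frac_accuracy_above",
                       "frac_significant", "accuracy_threshold", "alpha")]
  )
  jsonlite::write_json(js, file.path(out, "report.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  if (!is.null(report$subsets))
    data.table::fwrite(report$subsets$per_subset,
                       file.path(out, "subsets.tsv"), sep = "\t")
  invisible(out)
}
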