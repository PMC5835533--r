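#' Z-score feature columns
#'
#' Centers each column and divides by its population standard deviation
#' (divisor n, not n - 1), so the two features -- whose raw numeric ranges
#' can differ by orders of magnitude -- contribute comparably to the
#' margin. A constant column is mapped to all zeros with a warning.
#'
#' @param x numeric matrix (observations x features).
#' @return scaled matrix of the same shape.
#' @export
zscore_features <- function(x) {
  x <- as.matrix(x)
  for (j in seq_len(ncol(x))) {
    mu <- mean(x[, j])
    sd_pop <- sqrt(mean((x[, j] - mu)^2))
    if (sd_pop == 0) {
      warning("feature column ", j, " is constant; scaled to zeros", call. = FALSE)
      x[, j] <- 0
    } else {
      x[, j] <- (x[, j] - mu) / sd_pop
    }
  }
  x
}

# Solver stopping tolerance, scaled with C: KKT violations scale with the
# penalty, so a fixed absolute epsilon is effectively C times tighter at
# large C, where the SMO solver then burns its iteration cap on
# inseparable labelings. Small/selected C gets a very tight solve (pins
# down near-boundary predictions); large C relaxes toward the customary
# default.
svm_tol <- function(C) min(1e-3, max(1e-8, 1e-6 * C))

# Fit a soft-margin linear SVM and predict; a single-class training set
# predicts its own (majority) label.
svm_predict <- function(x_train, y_train, x_test, C) {
  lev <- unique(as.character(y_train))
  if (length(lev) == 1) return(rep(lev, nrow(x_test)))
  fit <- e1071::svm(x_train, factor(y_train), kernel = "linear", cost = C,
                    scale = FALSE, type = "C-classification",
                    tolerance = svm_tol(C))
  as.character(stats::predict(fit, x_test))
}

#' Leave-one-out cross-validation accuracy of a linear SVM
#'
#' For every observation, a soft-margin linear max-margin classifier with
#' penalty `C` is trained on the remaining n - 1 observations and used to
#' predict the held-out one; the returned accuracy is the fraction of
#' correct predictions (the N-fold, i.e. leave-one-out, estimate). A
#' training fold containing a single class predicts that class.
#'
#' @param x numeric feature matrix (observations x features), already
#'   scaled unless `fold_safe_scaling`.
#' @param y binary labels (character or factor).
#' @param C SVM penalty parameter, > 0.
#' @param fold_safe_scaling if `TRUE`, z-scoring is re-estimated inside
#'   each training fold and applied to the held-out point, avoiding the
#'   (mild) leakage of scaling on the full set.
#' @return accuracy in `[0, 1]`, a multiple of `1/n`.
#' @export
loo_accuracy <- function(x, y, C, fold_safe_scaling = FALSE) {
  x <- as.matrix(x); y <- as.character(y)
  n <- nrow(x)
  if (length(unique(y)) != 2) stop_input("labels must be binary")
  if (min(table(y)) < 2) stop_input("need at least 2 observations per class")
  if (!is.finite(C) || C <= 0) stop_input("C must be positive")
  if (!fold_safe_scaling) {
    # n-fold cross-validation with singleton folds is exactly the LOO
    # loop below (verified against it); one solver call instead of n.
    fit <- e1071::svm(x, factor(y), kernel = "linear", cost = C,
                      scale = FALSE, type = "C-classification",
                      tolerance = svm_tol(C), cross = n)
    return(fit$tot.accuracy / 100)
  }
  correct <- logical(n)
  for (i in seq_len(n)) {
    xtr <- x[-i, , drop = FALSE]; xte <- x[i, , drop = FALSE]
    if (fold_safe_scaling) {
      mu <- colMeans(xtr)
      sd_pop <- sqrt(colMeans(sweep(xtr, 2, mu)^2))
      sd_pop[sd_pop == 0] <- 1
      xtr <- sweep(sweep(xtr, 2, mu), 2, sd_pop, "/")
      xte <- sweep(sweep(xte, 2, mu), 2, sd_pop, "/")
    }
    correct[i] <- svm_predict(xtr, y[-i], xte, C) == y[i]
  }
  mean(correct)
}

#' Default penalty grid: ten C values log-spaced over [1e-3, 1e3]
#' @return numeric vector `10^seq(-3, 3, length.out = 10)`.
#' @export
default_c_grid <- function() 10^seq(-3, 3, length.out = 10)

#' Select the SVM penalty by cross-validation
#'
#' Evaluates [loo_accuracy()] at each grid value and returns the arg-max;
#' ties go to the smallest C (strongest regularization), which makes the
#' selection deterministic.
#'
#' @inheritParams loo_accuracy
#' @param grid candidate C values, default [default_c_grid()].
#' @return list with `selected_C` and `cv_by_c` (named accuracy vector).
#' @export
select_C <- function(x, y, grid = default_c_grid(),
                     fold_safe_scaling = FALSE) {
  grid <- sort(grid)
  acc <- vapply(grid, function(C) loo_accuracy(x, y, C, fold_safe_scaling),
                numeric(1))
  names(acc) <- format(grid, trim = TRUE)
  list(selected_C = grid[which.max(acc)], cv_by_c = acc)
}

# All distinct labelings with the observed class sizes, as an index matrix:
# each column holds the positions assigned the first label.
class_size_labelings <- function(n, n1) utils::combn(n, n1)

#' Label-permutation test of classification accuracy
#'
#' Tests the null hypothesis that the class labels are independent of the
#' features. Every distinct labeling that preserves the observed class
#' sizes (n choose n1 of them; permuting identical labels is a no-op) is
#' scored by its leave-one-out accuracy with `C` held fixed at the
#' observed-data selection; the p-value is the proportion of labelings --
#' the observed one included -- whose accuracy is at least the observed
#' accuracy, so p is never 0. When the number of labelings exceeds
#' `exhaustive_cap`, a seeded Monte-Carlo sample of labelings is used
#' instead, with the add-one convention.
#'
#' @inheritParams loo_accuracy
#' @param exhaustive_cap largest labeling count enumerated exhaustively
#'   (default 20000).
#' @param n_mc Monte-Carlo sample size used beyond the cap (default 2000).
#' @param seed RNG seed for the Monte-Carlo branch.
#' @return list: `p_value`, `perm_distribution` (accuracy per labeling),
#'   `n_permutations`, `observed_accuracy`, `exhaustive` (logical).
#' @export
permutation_test <- function(x, y, C, fold_safe_scaling = FALSE,
                             exhaustive_cap = 20000, n_mc = 2000,
                             seed = NULL) {
  x <- as.matrix(x); y <- as.character(y)
  lev <- unique(y)
  if (length(lev) != 2) stop_input("labels must be binary")
  obs <- loo_accuracy(x, y, C, fold_safe_scaling)
  n <- length(y); n1 <- sum(y == lev[1])
  n_lab <- choose(n, n1)
  if (n_lab <= exhaustive_cap) {
    idx <- class_size_labelings(n, n1)
    dist <- apply(idx, 2, function(pos) {
      yp <- rep(lev[2], n); yp[pos] <- lev[1]
      loo_accuracy(x, yp, C, fold_safe_scaling)
    })
    p <- sum(dist >= obs - 1e-12) / length(dist)
    exhaustive <- TRUE
  } else {
    if (is.null(seed)) stop_input("Monte-Carlo permutation branch requires a seed")
    dist <- local_seed(seed, {
      vapply(seq_len(n_mc),
             function(i) loo_accuracy(x, sample(y), C, fold_safe_scaling),
             numeric(1))
    })
    p <- (1 + sum(dist >= obs - 1e-12)) / (n_mc + 1)
    exhaustive <- FALSE
  }
  list(p_value = p, perm_distribution = dist, n_permutations = length(dist),
       observed_accuracy = obs, exhaustive = exhaustive)
}

#' Classify electrodes by region from their modulation features
#'
#' The full inference chain for one hemisphere and task: select LTC and
#' hippocampal electrodes, build the (early, late) feature matrix, z-score
#' both features over the full set, select the SVM penalty on the
#' 10-point log grid, estimate leave-one-out accuracy, and assign it a
#' p-value by the exhaustive label-permutation test with C fixed at the
#' observed selection. Degenerate-denominator electrodes are excluded.
#'
#' @param features feature data.frame from [features_for_dataset()].
#' @param meta electrode metadata (`electrode_id`, `region`, `hemisphere`).
#' @param hemisphere `"L"` or `"R"`.
#' @param task task label; defaults to the features' task.
#' @param c_grid penalty grid, default [default_c_grid()].
#' @param fold_safe_scaling re-scale within folds (see [loo_accuracy()]);
#'   default `FALSE`: scaling is done once on the full electrode set,
#'   which mildly leaks information across folds but matches how the
#'   statistic is defined here.
#' @param reselect_C_per_perm if `TRUE`, the penalty grid search is re-run
#'   inside every permutation (sensitivity analysis); default holds C
#'   fixed.
#' @param exhaustive_cap,n_mc,seed see [permutation_test()].
#' @return object of class `classification_result`.
#' @export
classify_electrodes <- function(features, meta, hemisphere, task = NULL,
                                c_grid = default_c_grid(),
                                fold_safe_scaling = FALSE,
                                reselect_C_per_perm = FALSE,
                                exhaustive_cap = 20000, n_mc = 2000,
                                seed = NULL) {
  task <- task %||% features$task[1]
  if (!"region" %in% names(features))
    features <- merge(features, meta, by = "electrode_id", sort = FALSE)
  sel <- features$hemisphere == hemisphere & features$task == task &
    features$region %in% c("LTC", "HIPP") & !features$degenerate
  f <- features[sel, , drop = FALSE]
  y <- f$region
  if (length(unique(y)) < 2 || min(table(y)) < 2)
    stop_input("need at least 2 electrodes per class in hemisphere ",
               hemisphere, " (have ", paste(names(table(y)), table(y),
               sep = "=", collapse = ", "), ")")
  x_raw <- as.matrix(f[, c("early", "late")])
  rownames(x_raw) <- f$electrode_id
  x <- if (fold_safe_scaling) x_raw else zscore_features(x_raw)

  cs <- select_C(x, y, c_grid, fold_safe_scaling)
  acc <- loo_accuracy(x, y, cs$selected_C, fold_safe_scaling)
  if (reselect_C_per_perm) {
    lev <- unique(y); n <- length(y); n1 <- sum(y == lev[1])
    if (choose(n, n1) > exhaustive_cap)
      stop_input("per-permutation C re-selection is exhaustive-only")
    idx <- class_size_labelings(n, n1)
    dist <- apply(idx, 2, function(pos) {
      yp <- rep(lev[2], n); yp[pos] <- lev[1]
      cp <- select_C(x, yp, c_grid, fold_safe_scaling)
      loo_accuracy(x, yp, cp$selected_C, fold_safe_scaling)
    })
    perm <- list(p_value = sum(dist >= acc - 1e-12) / length(dist),
                 perm_distribution = dist, n_permutations = length(dist),
                 observed_accuracy = acc, exhaustive = TRUE)
  } else {
    perm <- permutation_test(x, y, cs$selected_C, fold_safe_scaling,
                             exhaustive_cap, n_mc, seed)
  }

  # Separating line from the final model on all electrodes, for plotting.
  fit <- e1071::svm(x, factor(y), kernel = "linear", cost = cs$selected_C,
                    scale = FALSE, type = "C-classification",
                    tolerance = svm_tol(cs$selected_C))
  w <- drop(t(fit$coefs) %*% fit$SV)
  structure(list(
    hemisphere = hemisphere, task = task,
    electrode_id = f$electrode_id, region = y,
    n_per_class = table(y),
    features_scaled = x,
    c_grid = sort(c_grid), cv_by_c = cs$cv_by_c, selected_C = cs$selected_C,
    loo_accuracy = acc,
    perm_distribution = perm$perm_distribution,
    n_permutations = perm$n_permutations,
    exhaustive = perm$exhaustive,
    p_value = perm$p_value,
    hyperplane = list(w = w, b = -fit$rho),
    fold_safe_scaling = fold_safe_scaling
  ), class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> hemisphere %s, task '%s': %s\n",
              x$hemisphere, x$task,
              paste(names(x$n_per_class), x$n_per_class, sep = "=",
                    collapse = " vs ")))
  cat(sprintf("  LOO accuracy %.1f%% (C = %g), p = %.4g (%s, %d labelings)\n",
              100 * x$loo_accuracy, x$selected_C, x$p_value,
              if (x$exhaustive) "exhaustive" else "Monte-Carlo",
              x$n_permutations))
  invisible(x)
}
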