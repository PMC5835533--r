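# Single-trial amplitude statistics: pointwise t-tests and the
# cluster-based permutation test over time.

# Row-wise two-sample t statistics. D: trials x samples; G: labelings x
# trials 0/1 indicator of group A membership (all rows share the group
# sizes). Returns list(t, df): t is labelings x samples; df is a scalar
# (pooled) or labelings x samples matrix (Welch).
t_stat_rows <- function(D, G, welch = FALSE) {
  n <- ncol(G); n1 <- sum(G[1, ]); n2 <- n - n1
  H <- 1 - G
  S1 <- G %*% D; S2 <- H %*% D
  Q1 <- G %*% (D^2); Q2 <- H %*% (D^2)
  m1 <- S1 / n1; m2 <- S2 / n2
  v1 <- (Q1 - n1 * m1^2) / (n1 - 1)
  v2 <- (Q2 - n2 * m2^2) / (n2 - 1)
  v1[v1 < 0] <- 0; v2[v2 < 0] <- 0   # rounding guard
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
    list(t = (m1 - m2) / sqrt(se2), df = df)
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    list(t = (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2)), df = n1 + n2 - 2)
  }
}

# Trials x samples matrix for one electrode restricted to two conditions,
# non-rejected trials only.
electrode_trials <- function(epochs, electrode, cond_a, cond_b) {
  ids <- dimnames(epochs$data)[[2]]
  e <- if (is.character(electrode)) match(electrode, ids) else as.integer(electrode)
  if (is.na(e) || e < 1 || e > length(ids))
    stop_input("unknown electrode: ", electrode)
  keep <- epochs$condition %in% c(cond_a, cond_b) & !epochs$rejected
  lab <- epochs$condition[keep]
  if (sum(lab == cond_a) < 2 || sum(lab == cond_b) < 2)
    stop_input("need at least 2 non-rejected trials per condition")
  D <- epochs$data[keep, e, , drop = TRUE]
  if (is.null(dim(D))) D <- matrix(D, nrow = sum(keep))
  list(D = D, labels = lab, electrode_id = ids[e])
}

#' Pointwise two-sample t-test across time
#'
#' Independent two-sample t statistic at every time sample between the
#' single-trial amplitudes of two conditions at one electrode, with the
#' uncorrected two-tailed p < `alpha` mask. Pooled-variance t
#' (df = n_a + n_b - 2) by default; Welch by flag.
#'
#' @param epochs an [epoch_set()].
#' @param electrode electrode id or index.
#' @param cond_a,cond_b condition labels to compare.
#' @param alpha two-tailed uncorrected level, default 0.05.
#' @param welch use Welch's unequal-variance t.
#' @return list: `t_series`, `df`, `crit` (critical |t|), `mask` (logical),
#'   `times`, `n_a`, `n_b`, `electrode_id`.
#' @export
pointwise_t <- function(epochs, electrode, cond_a, cond_b, alpha = 0.05,
                        welch = FALSE) {
  et <- electrode_trials(epochs, electrode, cond_a, cond_b)
  G <- matrix(as.numeric(et$labels == cond_a), 1)
  ts <- t_stat_rows(et$D, G, welch)
  tt <- drop(ts$t); df <- if (welch) drop(ts$df) else ts$df
  crit <- stats::qt(1 - alpha / 2, df)
  list(t_series = tt, df = df, crit = crit, mask = abs(tt) > crit,
       times = epochs$times, n_a = sum(et$labels == cond_a),
       n_b = sum(et$labels == cond_b), electrode_id = et$electrode_id)
}

#' Find suprathreshold clusters in a t series
#'
#' Maximal runs of contiguous samples whose t statistic exceeds the
#' two-tailed critical value at level `alpha`, found separately for
#' positive and negative excursions. The cluster mass is the sum of t over
#' the run.
#'
#' @param t_series numeric t statistic per time sample.
#' @param times time axis in ms.
#' @param df degrees of freedom (scalar, or per-sample vector for Welch).
#' @param alpha threshold level, default 0.05.
#' @return data.frame: `start_ms`, `end_ms`, `istart`, `iend`, `sign`,
#'   `mass`; zero rows when nothing is suprathreshold.
#' @export
find_clusters <- function(t_series, times, df, alpha = 0.05) {
  crit <- stats::qt(1 - alpha / 2, df)
  out <- list()
  for (sgn in c(1, -1)) {
    mask <- sgn * t_series > crit
    r <- rle(mask)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      i0 <- starts[k]; i1 <- ends[k]
      out[[length(out) + 1]] <- data.frame(
        start_ms = times[i0], end_ms = times[i1], istart = i0, iend = i1,
        sign = sgn, mass = sum(t_series[i0:i1]))
    }
  }
  if (!length(out))
    return(data.frame(start_ms = numeric(0), end_ms = numeric(0),
                      istart = integer(0), iend = integer(0),
                      sign = numeric(0), mass = numeric(0)))
  res <- do.call(rbind, out)
  res[order(res$istart), , drop = FALSE]
}

# Max |cluster mass| per row of a t matrix (0 when no cluster).
max_cluster_mass_rows <- function(tmat, df, alpha) {
  crit <- stats::qt(1 - alpha / 2, df)
  apply(tmat, 1, function(tt) {
    cr <- if (length(crit) > 1) crit else rep(crit, length(tt))
    best <- 0
    for (sgn in c(1, -1)) {
      mask <- sgn * tt > cr
      if (!any(mask)) next
      r <- rle(mask)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      for (k in which(r$values))
        best <- max(best, abs(sum(tt[starts[k]:ends[k]])))
    }
    best
  })
}

#' Cluster-based permutation test on single-trial amplitudes
#'
#' Family-wise error control over time samples by the randomization
#' cluster test: clusters are contiguous runs where the pointwise t
#' exceeds the two-tailed critical value at `alpha`; each cluster's mass
#' (sum of t) is referred to the permutation null distribution of the
#' maximum absolute cluster mass, obtained by randomly reassigning trial
#' condition labels (class sizes preserved) `n_perm` times. Cluster
#' p-values use the add-one convention (the observed statistic counts as
#' one permutation), so p >= 1/(n_perm + 1).
#'
#' @inheritParams pointwise_t
#' @param n_perm number of random label permutations, default 1000.
#' @param seed RNG seed; required for reproducibility of the null.
#' @param alpha cluster-forming and decision level, default 0.05.
#' @return object of class `cluster_result`: `electrode_id`, `t_series`,
#'   `df`, `uncorrected_mask`, `clusters` (with `p_cluster`), `null_max`,
#'   `n_permutations`, `alpha`, `significant`.
#' @export
cluster_test <- function(epochs, electrode, cond_a, cond_b, n_perm = 1000,
                         seed = NULL, alpha = 0.05, welch = FALSE) {
  if (!is.numeric(n_perm) || n_perm < 1)
    stop_input("n_perm must be a positive count")
  et <- electrode_trials(epochs, electrode, cond_a, cond_b)
  n <- nrow(et$D); n1 <- sum(et$labels == cond_a)

  obs <- t_stat_rows(et$D, matrix(as.numeric(et$labels == cond_a), 1), welch)
  t_obs <- drop(obs$t); df_obs <- if (welch) drop(obs$df) else obs$df
  clusters <- find_clusters(t_obs, epochs$times, df_obs, alpha)

  G <- local_seed(seed %||% stop_input("cluster_test requires a seed"), {
    m <- matrix(0, n_perm, n)
    for (p in seq_len(n_perm)) m[p, sample.int(n, n1)] <- 1
    m
  })
  perm <- t_stat_rows(et$D, G, welch)
  null_max <- max_cluster_mass_rows(perm$t, if (welch) perm$df else perm$df,
                                    alpha)

  if (nrow(clusters)) {
    clusters$p_cluster <- vapply(abs(clusters$mass), function(m)
      (1 + sum(null_max >= m)) / (n_perm + 1), numeric(1))
  } else {
    clusters$p_cluster <- numeric(0)
  }
  crit <- stats::qt(1 - alpha / 2, df_obs)
  structure(list(
    electrode_id = et$electrode_id, t_series = t_obs, df = df_obs,
    uncorrected_mask = abs(t_obs) > crit, times = epochs$times,
    clusters = clusters, null_max = null_max, n_permutations = n_perm,
    alpha = alpha,
    significant = nrow(clusters) > 0 && any(clusters$p_cluster < alpha)
  ), class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> electrode %s: %d cluster(s), %d permutations\n",
              x$electrode_id, nrow(x$clusters), x$n_permutations))
  if (nrow(x$clusters))
    print(x$clusters[, c("start_ms", "end_ms", "sign", "mass", "p_cluster")],
          row.names = FALSE)
  cat(if (x$significant) "  significant at alpha\n" else
        "  no significant cluster\n")
  invisible(x)
}
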