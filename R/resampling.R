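#' Point-wise paired bootstrap test
#'
#' For each time point, builds the bootstrap distribution (default 20,000
#' iterations) of the mean paired difference between two conditions by
#' resampling participants with replacement, and computes a two-sided
#' p-value as 2 x min(tail proportions) with the (count + 1)/(n_boot + 1)
#' small-sample correction so p is never exactly 0. The resampling unit is
#' the participant: rows of both matrices must be the same participants in
#' the same order.
#'
#' @param cond_a,cond_b Numeric matrices, participants x time, same shape.
#' @param n_boot Number of bootstrap iterations (>= 1000).
#' @param seed Integer seed, or NULL to use the current RNG state.
#' @return List of class `pointwise_boot` with `mean_diff`, `p_raw` (per time
#'   point), `boot` (n_boot x time matrix of bootstrap means), `n_boot`, `n`.
#' @export
pointwise_bootstrap <- function(cond_a, cond_b, n_boot = 20000, seed = NULL) {
  cond_a <- as.matrix(cond_a); cond_b <- as.matrix(cond_b)
  if (!all(dim(cond_a) == dim(cond_b)))
    stop("condition matrices must have identical shape")
  if (n_boot < 1000) stop("n_boot must be >= 1000")
  n <- nrow(cond_a)
  if (n < 5) warning("fewer than 5 participants; bootstrap p-values are coarse")
  if (!is.null(seed)) set.seed(seed)
  d <- cond_a - cond_b
  dimnames(d) <- NULL
  idx <- sample.int(n, n_boot * n, replace = TRUE)
  # multiplicity of each participant in each bootstrap draw
  counts <- matrix(tabulate(rep(seq_len(n_boot) - 1L, each = n) * n + idx,
                            nbins = n_boot * n),
                   n_boot, n, byrow = TRUE)
  boot <- (counts %*% d) / n
  n_le <- colSums(boot <= 0)
  n_ge <- colSums(boot >= 0)
  p <- pmin(1, 2 * pmin((n_le + 1) / (n_boot + 1), (n_ge + 1) / (n_boot + 1)))
  structure(
    list(mean_diff = colMeans(d), p_raw = p, boot = boot,
         n_boot = n_boot, n = n),
    class = "pointwise_boot"
  )
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjusted p-values across the supplied set of tests.
#'
#' @param p_raw Numeric vector of p-values in [0, 1]; must be non-empty.
#' @return Vector of BH-adjusted p-values.
#' @export
fdr_correct <- function(p_raw) {
  if (length(p_raw) == 0) stop("empty p-value vector")
  if (any(p_raw < 0 | p_raw > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_raw, method = "BH")
}

#' Temporal-persistence filter
#'
#' Keeps only runs of consecutive significant time points of at least
#' `min_run` samples (4 samples = 16 ms at 250 Hz); shorter runs are set to
#' FALSE. Never adds TRUE values.
#'
#' @param sig Logical vector.
#' @param min_run Minimum run length (>= 1).
#' @return Logical vector of the same length.
#' @export
persistence_filter <- function(sig, min_run = 4) {
  stopifnot(min_run >= 1)
  if (length(sig) == 0) return(sig)
  r <- rle(sig)
  r$values <- r$values & r$lengths >= min_run
  inverse.rle(r)
}

#' Full point-wise contrast between two conditions
#'
#' Cluster-averages each participant's ERP, restricts to post-stimulus time
#' points (from stimulus onset to the end of the epoch), runs the point-wise
#' paired bootstrap, applies BH-FDR across those time points and then the
#' temporal-persistence filter.
#'
#' @param erps Named list of [erp_stack()] objects (one per condition, same
#'   participants in the same order).
#' @param pair Character vector of two condition names; the difference is
#'   `pair[1] - pair[2]`.
#' @param cluster Channel names to average before testing.
#' @param n_boot Bootstrap iterations.
#' @param alpha Significance level applied to the FDR-adjusted p-values.
#' @param min_run Persistence threshold, samples.
#' @param seed Integer seed for the bootstrap.
#' @return List of class `pointwise_result` with `time_ms`, `mean_diff`,
#'   `p_raw`, `p_fdr`, `sig_mask`, plus the test parameters.
#' @export
contrast_conditions <- function(erps, pair, cluster, n_boot = 20000,
                                alpha = 0.05, min_run = 4, seed = NULL) {
  missing_cond <- setdiff(pair, names(erps))
  if (length(missing_cond))
    stop("missing condition(s): ", paste(missing_cond, collapse = ", "))
  a <- stack_cluster_matrix(erps[[pair[1]]], cluster)
  b <- stack_cluster_matrix(erps[[pair[2]]], cluster)
  time_ms <- erps[[pair[1]]]$time_ms
  post <- which(time_ms >= 0)
  bt <- pointwise_bootstrap(a[, post, drop = FALSE], b[, post, drop = FALSE],
                            n_boot = n_boot, seed = seed)
  p_fdr <- fdr_correct(bt$p_raw)
  sig <- persistence_filter(p_fdr < alpha, min_run)
  structure(
    list(time_ms = time_ms[post], mean_diff = bt$mean_diff,
         p_raw = bt$p_raw, p_fdr = p_fdr, sig_mask = sig,
         n_boot = n_boot, min_run = min_run, alpha = alpha,
         pair = pair, cluster = cluster, n = bt$n),
    class = "pointwise_result"
  )
}

#' @export
print.pointwise_result <- function(x, ...) {
  cat(sprintf("<pointwise_result> %s - %s, %d participants, %d boot\n",
              x$pair[1], x$pair[2], x$n, x$n_boot))
  w <- significant_windows(x)
  if (nrow(w) == 0) cat("  no significant windows\n")
  else for (i in seq_len(nrow(w)))
    cat(sprintf("  significant %g..%g ms\n", w$start_ms[i], w$end_ms[i]))
  invisible(x)
}

#' Significant time windows of a point-wise result
#'
#' @param result A `pointwise_result`.
#' @return data.frame with columns `start_ms`, `end_ms` (one row per maximal
#'   significant run).
#' @export
significant_windows <- function(result) {
  r <- rle(result$sig_mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  data.frame(start_ms = result$time_ms[starts[keep]],
             end_ms = result$time_ms[ends[keep]])
}

#' Mean amplitude in a time window
#'
#' Mean over the window samples of the cluster-averaged waveform — the scalar
#' summary used for the mid-latency component analyses (default window
#' 200-250 ms).
#'
#' @param erp An `erp_waveform` (returns one value) or an `erp_stack`
#'   (returns one value per participant).
#' @param window Window (start, end), ms; must lie inside the epoch.
#'   Half-open: samples with start <= t < end.
#' @param cluster Channel names to average.
#' @return Numeric scalar (waveform) or vector (stack), microvolts.
#' @export
window_amplitude <- function(erp, window = c(200, 250), cluster) {
  if (window[1] >= window[2]) stop("window start must precede end")
  time_ms <- erp$time_ms
  if (window[1] < min(time_ms) || window[2] > max(time_ms) + 1e-9 + diff(time_ms[1:2]))
    stop("window lies outside the epoch")
  sel <- which(time_ms >= window[1] & time_ms < window[2])
  if (length(sel) == 0) stop("window contains no samples")
  if (inherits(erp, "erp_stack")) {
    m <- stack_cluster_matrix(erp, cluster)
    return(rowMeans(m[, sel, drop = FALSE]))
  }
  mean(cluster_average(erp, cluster)[sel])
}

#' Bootstrap distribution of a window-amplitude difference
#'
#' Bootstrap (participant resampling) distribution of the mean paired
#' difference of window amplitudes between two conditions, with the central
#' 95% percentile interval and a flag for whether 0 falls outside it.
#'
#' @param amp_a,amp_b Paired per-participant amplitudes (same length/order).
#' @param n_boot Bootstrap iterations.
#' @param seed Integer seed.
#' @param conf Central interval coverage.
#' @return List with `boot` (vector of bootstrap means), `mean_diff`, `ci`
#'   (interval endpoints), `null_excluded` (logical).
#' @export
window_bootstrap_distribution <- function(amp_a, amp_b, n_boot = 20000,
                                          seed = NULL, conf = 0.95) {
  if (length(amp_a) != length(amp_b)) stop("amplitudes must be paired")
  bt <- pointwise_bootstrap(matrix(amp_a, ncol = 1), matrix(amp_b, ncol = 1),
                            n_boot = n_boot, seed = seed)
  boot <- as.numeric(bt$boot)
  ci <- stats::quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        type = 7, names = FALSE)
  list(boot = boot, mean_diff = mean(amp_a - amp_b), ci = ci,
       null_excluded = 0 < ci[1] || 0 > ci[2])
}

#' Correlation between behavioral and electrophysiological adaptation effects
#'
#' Spearman rank correlation between per-participant behavioral differences
#' (e.g. Neutral - Adaptation estimates, dots) and ERP differences (e.g.
#' Neutral - Adaptation P2p window amplitude, microvolts), with the exact or
#' t-approximation p-value that `cor.test` selects by sample size.
#'
#' @param behavior_diff,eeg_diff Numeric vectors, equal length >= 5.
#' @return List with `rho` and `p`.
#' @export
brain_behavior_correlation <- function(behavior_diff, eeg_diff) {
  if (length(behavior_diff) != length(eeg_diff)) stop("lengths differ")
  if (length(behavior_diff) < 5) stop("need at least 5 participants")
  if (stats::sd(behavior_diff) == 0 || stats::sd(eeg_diff) == 0)
    stop("rank correlation undefined for a constant vector")
  ct <- suppressWarnings(
    stats::cor.test(behavior_diff, eeg_diff, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Per-channel topography of a condition difference
#'
#' Grand-average (over participants) per-channel mean difference between two
#' conditions within one or more time windows — the quantity rendered as
#' scalp difference maps.
#'
#' @param erps Named list of `erp_stack` objects.
#' @param pair Two condition names; difference is `pair[1] - pair[2]`.
#' @param windows List of (start, end) windows, ms (half-open).
#' @return Matrix channels x windows; row names are channel names, column
#'   names "start-end".
#' @export
topography_difference <- function(erps, pair, windows = list(c(200, 250))) {
  missing_cond <- setdiff(pair, names(erps))
  if (length(missing_cond))
    stop("missing condition(s): ", paste(missing_cond, collapse = ", "))
  a <- erps[[pair[1]]]; b <- erps[[pair[2]]]
  time_ms <- a$time_ms
  d <- apply(a$data - b$data, c(2, 3), mean)  # channels x time grand diff
  out <- sapply(windows, function(w) {
    if (w[1] < min(time_ms) || w[2] > max(time_ms) + diff(time_ms[1:2]))
      stop("window ", w[1], "-", w[2], " lies outside the epoch")
    sel <- which(time_ms >= w[1] & time_ms < w[2])
    rowMeans(d[, sel, drop = FALSE])
  })
  out <- matrix(out, nrow = length(a$channel_names))
  rownames(out) <- a$channel_names
  colnames(out) <- vapply(windows, function(w) paste0(w[1], "-", w[2]), "")
  out
}
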