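#' Quartile-based pruning of numerosity estimates
#'
#' Discards estimates lying above twice the upper quartile or below half the
#' lower quartile of the response distribution — the rule used to remove
#' response-dialing errors from verbal estimates. Quartiles use the type-7
#' (linear interpolation) convention.
#'
#' @param values Numeric vector of estimates; at least 4 values are required
#'   for the quartiles to be defined.
#' @return A list of class `pruned_estimates` with elements `kept`,
#'   `removed_fraction` (percent) and `bounds_used` (lower, upper).
#' @examples
#' prune_estimates(c(10, 28, 29, 30, 31, 32, 100))$bounds_used
#' @export
prune_estimates <- function(values) {
  if (length(values) < 4) stop("need at least 4 values to define quartiles")
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  bounds <- c(lower = q[1] / 2, upper = 2 * q[2])
  keep <- values >= bounds[1] & values <= bounds[2]
  structure(
    list(kept = values[keep],
         removed_fraction = 100 * mean(!keep),
         bounds_used = bounds),
    class = "pruned_estimates"
  )
}

#' Apply pruning within participant x condition cells
#'
#' Convenience wrapper applying [prune_estimates()] to every participant x
#' condition (x numerosity) cell of an estimate table.
#'
#' @param table Estimate table (columns `participant`, `condition`,
#'   `numerosity`, `estimate`).
#' @return The table with pruned rows removed; the overall removed percentage
#'   is attached as attribute `removed_fraction`.
#' @export
prune_table <- function(table) {
  key <- interaction(table$participant, table$condition, table$numerosity, drop = TRUE)
  keep <- unlist(lapply(split(seq_len(nrow(table)), key), function(idx) {
    v <- table$estimate[idx]
    if (length(v) < 4) return(idx)
    q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    idx[v >= q[1] / 2 & v <= 2 * q[2]]
  }), use.names = FALSE)
  out <- table[sort(keep), , drop = FALSE]
  attr(out, "removed_fraction") <- 100 * (1 - nrow(out) / nrow(table))
  out
}

participant_condition_means <- function(table) {
  stats::aggregate(estimate ~ participant + condition, data = table, FUN = mean)
}

#' One-way repeated-measures ANOVA on condition means
#'
#' Aggregates the estimate table to participant x condition means and runs
#' the within-subject one-way ANOVA with factor Condition, returning F, dfs
#' (k-1, (k-1)(n-1)), p, eta-squared (both SS_effect/SS_total and partial)
#' and Tukey-Kramer pairwise adjusted p-values computed on the studentized
#' range with the repeated-measures error term.
#'
#' @param table Estimate table with columns `participant`, `condition`,
#'   `estimate` (filter to one numerosity first if required).
#' @return A list of class `rm_anova` with elements `F`, `df`, `p`,
#'   `eta_squared`, `partial_eta_squared`, `means`, `posthoc` (data.frame
#'   with columns `pair`, `diff`, `p_adj`), `ms_error`.
#' @export
rm_anova_oneway <- function(table) {
  m <- participant_condition_means(table)
  conds <- sort(unique(m$condition))
  parts <- sort(unique(m$participant))
  k <- length(conds); n <- length(parts)
  if (k < 2) stop("need at least 2 conditions")
  wide <- matrix(NA_real_, n, k, dimnames = list(parts, conds))
  wide[cbind(match(m$participant, parts), match(m$condition, conds))] <- m$estimate
  if (anyNA(wide)) {
    miss <- which(is.na(wide), arr.ind = TRUE)
    stop("missing cell: participant ", parts[miss[1, 1]],
         ", condition ", conds[miss[1, 2]])
  }
  grand <- mean(wide)
  ss_cond <- n * sum((colMeans(wide) - grand)^2)
  ss_part <- k * sum((rowMeans(wide) - grand)^2)
  ss_tot  <- sum((wide - grand)^2)
  ss_err  <- max(0, ss_tot - ss_cond - ss_part)
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  ms_err <- ss_err / df2
  # degenerate inputs: no error variance (e.g. identical values everywhere)
  Fval <- if (ms_err <= 0) { if (ss_cond <= 0) 0 else Inf }
          else (ss_cond / df1) / ms_err
  p <- stats::pf(Fval, df1, df2, lower.tail = FALSE)
  cm <- colMeans(wide)
  pairs <- utils::combn(conds, 2)
  posthoc <- data.frame(
    pair = apply(pairs, 2, paste, collapse = " vs "),
    diff = apply(pairs, 2, function(pr) cm[pr[1]] - cm[pr[2]]),
    p_adj = apply(pairs, 2, function(pr) {
      q <- abs(cm[pr[1]] - cm[pr[2]]) / sqrt(ms_err / n)
      stats::ptukey(q, nmeans = k, df = df2, lower.tail = FALSE)
    }),
    row.names = NULL
  )
  structure(
    list(F = Fval, df = c(df1, df2), p = p,
         eta_squared = ss_cond / ss_tot,
         partial_eta_squared = ss_cond / (ss_cond + ss_err),
         means = cm, posthoc = posthoc, ms_error = ms_err, n = n),
    class = "rm_anova"
  )
}

#' @export
print.rm_anova <- function(x, ...) {
  if (!is.null(x$terms)) {
    for (tm in names(x$terms)) {
      t <- x$terms[[tm]]
      cat(sprintf("%s: F(%g,%g) = %.3f, p = %.4g, eta^2 = %.3f\n",
                  tm, t$df[1], t$df[2], t$F, t$p, t$eta_squared))
    }
  } else {
    cat(sprintf("RM-ANOVA: F(%g,%g) = %.2f, p = %.4g, eta^2 = %.3f (partial %.3f)\n",
                x$df[1], x$df[2], x$F, x$p, x$eta_squared, x$partial_eta_squared))
    if (!is.null(x$posthoc)) {
      cat("Tukey-Kramer post-hoc:\n")
      print(x$posthoc, digits = 3)
    }
  }
  invisible(x)
}

#' Two-way repeated-measures ANOVA (Condition x Numerosity)
#'
#' Within-subject two-way ANOVA on participant x condition x numerosity cell
#' means, as used to check that Baseline and Neutral estimates agree across
#' the filling numerosities. Each effect is tested against its own
#' effect-by-participant interaction (the standard univariate RM error term).
#'
#' @param table Estimate table with columns `participant`, `condition`,
#'   `numerosity`, `estimate`; restrict `condition` to the two levels of
#'   interest (e.g. Baseline, Neutral) before calling.
#' @return A list of class `rm_anova` with a `terms` element: for each of
#'   `condition`, `numerosity` and `condition:numerosity`, F, dfs, p and
#'   eta-squared (SS_effect over total SS across all strata).
#' @export
rm_anova_twoway <- function(table) {
  cells <- stats::aggregate(estimate ~ participant + condition + numerosity,
                            data = table, FUN = mean)
  parts <- sort(unique(cells$participant))
  conds <- sort(unique(cells$condition))
  nums  <- sort(unique(cells$numerosity))
  n <- length(parts); a <- length(conds); b <- length(nums)
  if (a < 2 || b < 2) stop("need at least 2 levels per factor")
  arr <- array(NA_real_, dim = c(n, a, b))
  arr[cbind(match(cells$participant, parts),
            match(cells$condition, conds),
            match(cells$numerosity, nums))] <- cells$estimate
  if (anyNA(arr)) stop("incomplete participant x condition x numerosity design")
  grand <- mean(arr)
  mp  <- apply(arr, 1, mean); ma <- apply(arr, 2, mean); mb <- apply(arr, 3, mean)
  mpa <- apply(arr, c(1, 2), mean); mpb <- apply(arr, c(1, 3), mean)
  mab <- apply(arr, c(2, 3), mean)
  ss <- function(x) sum((x - grand)^2)
  ss_p <- a * b * ss(mp); ss_a <- n * b * ss(ma); ss_b <- n * a * ss(mb)
  ss_ab <- n * sum((mab - outer(ma, mb, "+") + grand)^2)
  ss_pa <- b * sum((mpa - outer(mp, ma, "+") + grand)^2)
  ss_pb <- a * sum((mpb - outer(mp, mb, "+") + grand)^2)
  ss_tot <- sum((arr - grand)^2)
  ss_pab <- ss_tot - ss_p - ss_a - ss_b - ss_ab - ss_pa - ss_pb
  term <- function(ss_eff, df1, ss_err, df2) {
    Fv <- if (ss_err <= 0) { if (ss_eff <= 0) 0 else Inf }
          else (ss_eff / df1) / (ss_err / df2)
    list(F = Fv, df = c(df1, df2),
         p = stats::pf(Fv, df1, df2, lower.tail = FALSE),
         eta_squared = ss_eff / ss_tot)
  }
  structure(
    list(terms = list(
      condition = term(ss_a, a - 1, ss_pa, (a - 1) * (n - 1)),
      numerosity = term(ss_b, b - 1, ss_pb, (b - 1) * (n - 1)),
      `condition:numerosity` =
        term(ss_ab, (a - 1) * (b - 1), ss_pab, (a - 1) * (b - 1) * (n - 1))
    )),
    class = "rm_anova"
  )
}

#' Per-participant adaptation magnitude
#'
#' The difference between each participant's Neutral and Adaptation mean
#' estimates, and the corresponding percent change
#' 100 x (Neutral - Adaptation) / Neutral. Positive values indicate
#' underestimation under adaptation.
#'
#' @param table Estimate table containing at least the Adaptation and Neutral
#'   conditions (filter to one numerosity first if required).
#' @return data.frame with columns `participant`, `neutral_mean`,
#'   `adaptation_mean`, `difference` (dots), `percent`.
#' @export
adaptation_magnitude <- function(table) {
  m <- participant_condition_means(table)
  need <- c("Adaptation", "Neutral")
  if (!all(need %in% m$condition))
    stop("table must contain Adaptation and Neutral conditions")
  neu <- m[m$condition == "Neutral", ]
  ada <- m[m$condition == "Adaptation", ]
  parts <- intersect(neu$participant, ada$participant)
  nv <- neu$estimate[match(parts, neu$participant)]
  av <- ada$estimate[match(parts, ada$participant)]
  if (any(nv == 0)) stop("zero Neutral mean for participant ",
                         parts[which(nv == 0)[1]])
  data.frame(participant = parts, neutral_mean = nv, adaptation_mean = av,
             difference = nv - av, percent = 100 * (nv - av) / nv)
}

#' Power of the within-factor repeated-measures ANOVA F-test
#'
#' Noncentral-F power with noncentrality lambda = f^2 * n * m / (1 - rho) and
#' degrees of freedom df1 = (m - 1) * eps, df2 = (n - 1) * (m - 1) * eps —
#' the convention standard power-analysis software uses for a design with
#' one within factor.
#'
#' @param n Number of participants.
#' @param f Cohen's f effect size (> 0).
#' @param alpha Significance level.
#' @param n_measurements Number of repeated measurements m.
#' @param corr_rep_measures Correlation among repeated measures, rho in [0,1).
#' @param nonsphericity Nonsphericity correction epsilon in (0, 1].
#' @return Power (probability), a single number.
#' @export
rm_anova_power <- function(n, f, alpha = 0.05, n_measurements = 3,
                           corr_rep_measures = 0.5, nonsphericity = 1) {
  m <- n_measurements
  lambda <- f^2 * n * m / (1 - corr_rep_measures)
  df1 <- (m - 1) * nonsphericity
  df2 <- (n - 1) * (m - 1) * nonsphericity
  if (df2 < 1) return(0)
  crit <- stats::qf(1 - alpha, df1, df2)
  stats::pf(crit, df1, df2, ncp = lambda, lower.tail = FALSE)
}

#' A-priori sample size for the repeated-measures ANOVA
#'
#' Smallest n such that [rm_anova_power()] reaches the target power.
#'
#' @inheritParams rm_anova_power
#' @param power Target power in (0, 1).
#' @param n_max Search bound; an error is thrown if the target power is not
#'   reached by `n_max` participants.
#' @return Required number of participants (integer).
#' @examples
#' required_sample_size(f = 0.30, alpha = 0.05, power = 0.90,
#'                      n_measurements = 3)  # 25
#' @export
required_sample_size <- function(f, alpha = 0.05, power = 0.90,
                                 n_measurements = 3, corr_rep_measures = 0.5,
                                 nonsphericity = 1, n_max = 10000) {
  if (f <= 0) stop("f must be > 0")
  if (power <= 0 || power >= 1) stop("power must be in (0, 1)")
  for (n in 3:n_max) {
    if (rm_anova_power(n, f, alpha, n_measurements, corr_rep_measures,
                       nonsphericity) >= power)
      return(as.integer(n))
  }
  stop("target power not reachable with n <= ", n_max)
}
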