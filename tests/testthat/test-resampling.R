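test_that("identical conditions give zero difference and p = 1 everywhere", {
  set.seed(1)
  a <- matrix(rnorm(25 * 10), 25, 10)
  bt <- pointwise_bootstrap(a, a, n_boot = 1000, seed = 2)
  expect_equal(bt$mean_diff, rep(0, 10))
  expect_equal(bt$p_raw, rep(1, 10))
})

test_that("bootstrap p matches exhaustive resample enumeration at n = 5", {
  d <- c(0.3, -0.1, 0.4, 0.2, -0.2)
  a <- cbind(d, d); b <- matrix(0, 5, 2)
  # brute-force oracle: all 5^5 equally likely participant resamples. The
  # resample mean has an atom at exactly 0, which floating-point summation
  # order can place on either side of the threshold, so the exact p is
  # bracketed with strict and non-strict tail counts.
  grid <- as.matrix(expand.grid(1:5, 1:5, 1:5, 1:5, 1:5))
  means <- rowMeans(matrix(d[grid], nrow(grid), 5))
  eps <- 1e-12
  p_lo <- 2 * min(mean(means <= -eps), mean(means >= eps))
  p_hi <- 2 * min(mean(means <= eps), mean(means >= -eps))
  suppressWarnings(bt <- pointwise_bootstrap(a, b, n_boot = 20000, seed = 3))
  mc_tol <- 2 * sqrt(p_hi * (1 - p_hi) / 20000) + 2 / 20001
  expect_gt(bt$p_raw[1], p_lo - mc_tol)
  expect_lt(bt$p_raw[1], p_hi + mc_tol)
  expect_gt(bt$p_raw[2], p_lo - mc_tol)
  expect_lt(bt$p_raw[2], p_hi + mc_tol)
  expect_equal(bt$mean_diff, c(mean(d), mean(d)))
})

test_that("bootstrap is reproducible and validates its inputs", {
  a <- matrix(rnorm(50), 10, 5); b <- matrix(rnorm(50), 10, 5)
  b1 <- pointwise_bootstrap(a, b, n_boot = 1000, seed = 7)
  b2 <- pointwise_bootstrap(a, b, n_boot = 1000, seed = 7)
  expect_identical(b1$boot, b2$boot)
  expect_error(pointwise_bootstrap(a, b[1:9, ]), "identical shape")
  expect_error(pointwise_bootstrap(a, b, n_boot = 10), "1000")
  expect_warning(pointwise_bootstrap(a[1:4, ], b[1:4, ], n_boot = 1000),
                 "fewer than 5")
})

test_that("BH adjustment matches hand computation and its tie behavior", {
  expect_equal(fdr_correct(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_correct(rep(0.02, 6)), rep(0.02, 6))
  set.seed(5)
  p <- runif(50)
  expect_true(all(fdr_correct(p) >= p))
  expect_error(fdr_correct(numeric(0)), "empty")
  expect_error(fdr_correct(c(0.5, 1.2)), "0, 1")
})

test_that("persistence filter keeps only runs of at least min_run points", {
  expect_equal(persistence_filter(c(F, T, T, T, F, F), 4), rep(FALSE, 6))
  expect_equal(persistence_filter(c(F, T, T, T, T, F), 4),
               c(F, T, T, T, T, F))
  set.seed(9)
  for (i in 1:20) {
    m <- runif(40) < 0.4
    out <- persistence_filter(m, sample(2:5, 1))
    expect_true(all(!out | m))  # never adds a TRUE
  }
  expect_equal(persistence_filter(logical(0), 4), logical(0))
})

test_that("window amplitude summarizes cluster waveforms", {
  tm <- seq(-200, 596, by = 4)
  flat <- erp_waveform(matrix(5, 2, length(tm)), tm, c("PO7", "PO8"))
  expect_equal(window_amplitude(flat, c(200, 250), c("PO7", "PO8")), 5)
  ramp <- erp_waveform(rbind(tm, tm), tm, c("PO7", "PO8"))
  # mean of a linear ramp = midpoint of the sampled window
  sel <- tm >= 200 & tm < 250
  expect_equal(window_amplitude(ramp, c(200, 250), "PO7"), mean(tm[sel]))
  expect_error(window_amplitude(flat, c(590, 900), "PO7"), "outside")
  expect_error(window_amplitude(flat, c(250, 200), "PO7"), "precede")

  # noiseless forward model vs the analytic Gaussian-kernel window mean
  erp <- average_erp(generate_epochs(noiseless_p2p_spec(n_trials = 1), "Neutral"))
  got <- window_amplitude(erp, c(200, 250), c("PO7", "O1"))
  gauss_int <- function(lo, hi) {
    # (1/(hi-lo)) * integral of exp(-(t-220)^2 / (2*20^2)) dt
    20 * sqrt(2 * pi) / (hi - lo) *
      (pnorm((hi - 220) / 20) - pnorm((lo - 220) / 20))
  }
  # continuous-time integral over the sampled half-open window [200, 250)
  expected <- 3 * mean(c(1, 0.8)) * gauss_int(198, 250)
  expect_equal(got, expected, tolerance = 0.01)
})

test_that("window bootstrap interval matches a sort-based percentile oracle", {
  set.seed(13)
  a <- rnorm(25, 1); b <- rnorm(25)
  wb <- window_bootstrap_distribution(a, b, n_boot = 2000, seed = 17)
  # independent sort-based type-7 percentile computation
  pct <- function(x, prob) {
    s <- sort(x); n <- length(s); h <- (n - 1) * prob + 1
    lo <- floor(h); s[lo] + (h - lo) * (s[min(lo + 1, n)] - s[lo])
  }
  expect_equal(wb$ci[1], pct(wb$boot, 0.025))
  expect_equal(wb$ci[2], pct(wb$boot, 0.975))
  expect_equal(wb$mean_diff, mean(a - b))
  # identical inputs: zero lies inside the interval
  wb0 <- window_bootstrap_distribution(b, b, n_boot = 2000, seed = 19)
  expect_false(wb0$null_excluded)
})

test_that("scenario P2p window bootstrap separates left from right cluster", {
  sim <- simulate_experiment(default_adaptation_scenario(), seed = 3)
  cl <- electrode_clusters()
  amp <- function(cond, cluster)
    window_amplitude(sim$erps[[cond]], c(200, 250), cluster)
  wl <- window_bootstrap_distribution(amp("Neutral", cl$left),
                                      amp("Adaptation", cl$left),
                                      n_boot = 2000, seed = 29)
  wr <- window_bootstrap_distribution(amp("Neutral", cl$right),
                                      amp("Adaptation", cl$right),
                                      n_boot = 2000, seed = 31)
  expect_true(wl$null_excluded)
  expect_false(wr$null_excluded)
  expect_gt(wl$mean_diff, 0)  # Neutral larger than Adaptation
})

test_that("contrast pipeline flags the P2p window on the left cluster only", {
  sim <- simulate_experiment(default_adaptation_scenario(), seed = 4)
  cl <- electrode_clusters()
  left <- contrast_conditions(sim$erps, c("Adaptation", "Neutral"), cl$left,
                              n_boot = 2000, seed = 37)
  right <- contrast_conditions(sim$erps, c("Adaptation", "Neutral"), cl$right,
                               n_boot = 2000, seed = 41)
  expect_true(any_sig_in_window(left, c(200, 250)))
  expect_false(any_sig_in_window(left, c(0, 150)))
  expect_false(any_sig_in_window(right, c(200, 250)))
  # direction: Adaptation below Neutral in the window
  sel <- left$time_ms >= 200 & left$time_ms < 250
  expect_lt(mean(left$mean_diff[sel]), 0)
  # post-stimulus samples only
  expect_true(all(left$time_ms >= 0))
  expect_error(contrast_conditions(sim$erps, c("Adaptation", "Sleep"), cl$left),
               "missing condition")
})

test_that("Spearman correlation behaves as a rank statistic", {
  x <- c(1, 3, 2, 5, 4, 7, 6, 9, 8, 10)
  y <- exp(x)
  r <- brain_behavior_correlation(x, y)
  expect_equal(r$rho, 1)
  # invariance under strictly monotone transforms
  r2 <- brain_behavior_correlation(log(x), y^3)
  set.seed(43)
  xx <- rnorm(20); yy <- xx + rnorm(20)
  expect_equal(brain_behavior_correlation(xx, yy)$rho,
               brain_behavior_correlation(exp(xx), yy)$rho)
  expect_error(brain_behavior_correlation(rep(1, 6), rnorm(6)), "constant")
  expect_error(brain_behavior_correlation(rnorm(4), rnorm(4)), "at least 5")
})

test_that("coupled scenario recovers a positive brain-behavior correlation", {
  # at n = 25 a single experiment replicates a rho ~ 0.3-0.4 association
  # only part of the time, so recovery is asserted on evidence pooled over
  # simulated experiments rather than per-experiment significance
  sc <- default_adaptation_scenario(coupling = 0.6)
  cl <- electrode_clusters()
  n_seeds <- 20
  rhos <- numeric(n_seeds)
  for (i in seq_len(n_seeds)) {
    sim <- simulate_experiment(sc, seed = 400 + i)
    mag <- adaptation_magnitude(sim$behavior[sim$behavior$numerosity == 30, ])
    ed <- window_amplitude(sim$erps$Neutral, c(200, 250), cl$left) -
      window_amplitude(sim$erps$Adaptation, c(200, 250), cl$left)
    rhos[i] <- brain_behavior_correlation(mag$difference, ed)$rho
  }
  expect_gte(sum(rhos > 0), 15)
  expect_gt(mean(rhos), 0.1)
  expect_lt(t.test(rhos)$p.value, 0.01)  # pooled evidence of association

  # permutation oracle for the p-value on one dataset
  sim <- simulate_experiment(sc, seed = 400 + 1)
  mag <- adaptation_magnitude(sim$behavior[sim$behavior$numerosity == 30, ])
  ed <- window_amplitude(sim$erps$Neutral, c(200, 250), cl$left) -
    window_amplitude(sim$erps$Adaptation, c(200, 250), cl$left)
  obs <- brain_behavior_correlation(mag$difference, ed)
  set.seed(47)
  perm <- replicate(10000,
    abs(cor(mag$difference, sample(ed), method = "spearman")))
  p_perm <- mean(perm >= abs(obs$rho) - 1e-12)
  expect_lt(abs(obs$p - p_perm), 0.02)
})

test_that("topography differences localize the effects", {
  sim <- simulate_experiment(default_adaptation_scenario(), seed = 6)
  cl <- electrode_clusters()
  # identical condition with itself: all zeros
  z <- topography_difference(list(A = sim$erps$Neutral, B = sim$erps$Neutral),
                             c("A", "B"))
  expect_equal(max(abs(z)), 0)
  # Neutral - Adaptation, 200-250 ms: peak over the left posterior cluster
  topo <- topography_difference(sim$erps, c("Neutral", "Adaptation"),
                                windows = list(c(200, 250)))
  expect_true(rownames(topo)[which.max(abs(topo[, 1]))] %in% cl$left)

  # physical numerosity: HighNum - LowNum peaks over the right cluster
  simn <- simulate_experiment(default_adaptation_scenario(), seed = 7,
                              conditions = c("LowNum", "HighNum"))
  topon <- topography_difference(simn$erps, c("HighNum", "LowNum"),
                                 windows = list(c(200, 250)))
  expect_true(rownames(topon)[which.max(abs(topon[, 1]))] %in% cl$right)
  expect_error(topography_difference(sim$erps, c("Neutral", "Adaptation"),
                                     windows = list(c(500, 900))), "outside")
})
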