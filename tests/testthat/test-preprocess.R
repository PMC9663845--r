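test_that("band-pass filter preserves the passband and rejects drift/EMG", {
  fs <- 500
  t <- seq(0, 10, by = 1 / fs)
  mid <- 1500:3500
  y10 <- bandpass_filter(sin(2 * pi * 10 * t), fs)
  expect_lt(abs(max(abs(y10[mid])) - 1), 0.01)  # passband identity

  h <- fir_bandpass_design(fs)
  resp_db <- function(f) 20 * log10(Mod(fir_response(h, f, fs)))
  expect_lt(resp_db(0.1), -20)   # slow drift
  expect_lt(resp_db(45), -20)    # beyond the upper edge
  expect_gt(resp_db(10), -0.2)
  expect_lt(resp_db(0), -20)     # DC suppressed
  # band edges sit in the -6 dB neighborhood
  expect_true(Mod(fir_response(h, 0.5, fs)) > 0.3 &&
                Mod(fir_response(h, 0.5, fs)) < 0.7)
  expect_true(Mod(fir_response(h, 40.5, fs)) > 0.25 &&
                Mod(fir_response(h, 40.5, fs)) < 0.7)
  # time-domain confirmation of stopband attenuation
  yd <- bandpass_filter(sin(2 * pi * 0.1 * t), fs)
  expect_lt(max(abs(yd[mid])), 10^(-20 / 20))
  expect_error(bandpass_filter(t, fs = 60), "too low")
})

test_that("downsampling keeps spectra and handles edge cases", {
  fs <- 500
  t <- seq(0, 10, by = 1 / fs)
  # constant stays constant
  d <- downsample_signal(rep(3, length(t)), fs, 250)
  expect_equal(d$fs, 250)
  expect_equal(d$data[100:1000], rep(3, 901), tolerance = 1e-6)
  # 10 Hz tone: spectral peak preserved at 10 Hz after 500 -> 250
  d <- downsample_signal(sin(2 * pi * 10 * t), fs, 250)
  n <- 2000
  sp <- Mod(fft(d$data[201 + seq_len(n)]))[seq_len(n / 2)]
  expect_equal((which.max(sp) - 1) * 250 / n, 10)
  # identity and error cases
  same <- downsample_signal(t, fs, fs)
  expect_identical(same$data, t)
  expect_error(downsample_signal(t, 250, 500), "exceed")
  expect_error(downsample_signal(t, 500, 300), "integer multiple")
})

test_that("spherical-spline interpolation solves the spline system", {
  m <- standard_montage()
  pos <- as.matrix(m[, c("x", "y", "z")])
  bad <- c("Pz")
  ib <- match(bad, m$name); ig <- setdiff(seq_len(30), ib)
  M <- spline_interp_matrix(pos[ig, ], pos[ib, , drop = FALSE])
  # weights sum to 1 (constant fields reproduced exactly)
  expect_equal(rowSums(M), rep(1, length(ib)), tolerance = 1e-9)

  # independent oracle: solve the augmented spline system directly per value
  g_of <- function(ca) {
    x <- as.numeric(ca); P0 <- rep(1, length(x)); P1 <- x
    g <- 3 / 2^4 * P1
    for (nn in 2:50) {
      P2 <- ((2 * nn - 1) * x * P1 - (nn - 1) * P0) / nn
      g <- g + (2 * nn + 1) / (nn * (nn + 1))^4 * P2
      P0 <- P1; P1 <- P2
    }
    g / (4 * pi)
  }
  v <- pos[, 3]^2 + 0.5 * pos[, 2]       # smooth potential over the scalp
  ng <- length(ig)
  G <- matrix(g_of(pos[ig, ] %*% t(pos[ig, ])), ng, ng)
  A <- rbind(cbind(G + 1e-5 * diag(ng), 1), c(rep(1, ng), 0))
  sol <- solve(A, c(v[ig], 0))
  gt <- g_of(pos[ib, , drop = FALSE] %*% t(pos[ig, ]))
  oracle <- sum(gt * sol[1:ng]) + sol[ng + 1]
  expect_equal(as.numeric(M %*% v[ig]), oracle, tolerance = 1e-9)
  # reconstruction of a smooth field is accurate
  expect_lt(abs(oracle - v[ib]), 0.05 * diff(range(v)))

  # applied to an epoch_set: empty bad list is the identity
  spec <- default_adaptation_scenario()$eeg_specs$Neutral
  spec$n_trials_per_condition <- 3L
  spec$artifact_rate <- 0
  spec$seed <- 2L
  ep <- generate_epochs(spec, "Neutral")
  expect_identical(interpolate_bad_channels(ep, character(0))$data, ep$data)
  ipz <- match("Pz", ep$channel_names)
  ep2 <- interpolate_bad_channels(ep, "Pz")
  expect_equal(dim(ep2$data), dim(ep$data))
  expect_false(identical(ep2$data[1, ipz, ], ep$data[1, ipz, ]))
  expect_identical(ep2$data[, -ipz, ], ep$data[, -ipz, ])
  # four-channel set cannot spare a channel
  ep4 <- generate_epochs(noisy_small_spec(n_trials = 2, seed = 3), "Neutral")
  expect_error(interpolate_bad_channels(ep4, "PO3"), "at least 4 good")
})

test_that("average reference zeroes the channel mean and keeps contrasts", {
  ep <- generate_epochs(noisy_small_spec(n_trials = 4, seed = 6), "Neutral")
  rr <- rereference_average(ep)
  mu <- apply(rr$data, c(1, 3), mean)
  expect_lt(max(abs(mu)), 1e-12)
  # idempotent
  expect_equal(rereference_average(rr)$data, rr$data, tolerance = 1e-12)
  # difference between two channels unchanged
  expect_equal(rr$data[1, 1, ] - rr$data[1, 2, ],
               ep$data[1, 1, ] - ep$data[1, 2, ])
})

test_that("epoching trims, baseline-corrects and follows the sample convention", {
  fs <- 250
  nch <- 4
  n <- 3000
  x <- matrix(0, nch, n)
  onsets <- c(800, 1600)
  for (o in onsets) x[, o:n] <- x[, o:n] + 5   # step of 5 uV at onset
  cont <- list(data = x, fs = fs, channel_names = c("P3", "P4", "O1", "O2"))
  ev <- data.frame(sample = onsets, condition = "Test")
  ep <- epoch_and_trim(cont, ev)
  # half-open convention: -200..600 ms at 250 Hz = 200 samples
  expect_equal(dim(ep$data), c(2, nch, 200))
  expect_equal(ep$time_ms[1], -200)
  expect_equal(diff(ep$time_ms)[1], 4)
  # baseline mean is zero, step preserved
  bl <- ep$time_ms < 0
  expect_lt(max(abs(apply(ep$data[, , bl], c(1, 2), mean))), 1e-9)
  expect_equal(ep$data[1, 1, ep$time_ms >= 0], rep(5, 150))
  # identical events give identical epochs
  expect_equal(ep$data[1, , ], ep$data[2, , ])
  # event too close to the edge is dropped with a message
  ev2 <- data.frame(sample = c(50, 800), condition = "Test")
  expect_message(ep2 <- epoch_and_trim(cont, ev2), "dropped")
  expect_equal(dim(ep2$data)[1], 1)
})

test_that("epoch rejection removes exactly the artifact trials", {
  spec <- noisy_small_spec(n_trials = 20, seed = 44)
  ep <- generate_epochs(spec, "Neutral")
  r <- reject_epochs(ep, threshold = 500)
  expect_equal(r$removed_fraction, 0)
  # inject a 500 uV spike into trial 7
  ep$data[7, 2, 90] <- ep$data[7, 2, 90] + 500
  r <- reject_epochs(ep, threshold = 150)
  expect_equal(dim(r$epochs$data)[1], 19)
  expect_equal(r$removed_fraction, 5)
  expect_error(reject_epochs(ep, threshold = 1e-9), "raise the threshold")
})

test_that("scenario artifact rate matches the expected rejection fraction", {
  sc <- default_adaptation_scenario()
  spec <- sc$eeg_specs$Adaptation
  spec$seed <- 55
  ep <- generate_epochs(spec, "Adaptation")
  r <- reject_epochs(ep, threshold = 150)
  # generator injects bursts on ~5% of trials (binomial spread over 240)
  expect_gt(r$removed_fraction, 2)
  expect_lt(r$removed_fraction, 9)
})

test_that("trial averaging and cluster averaging are arithmetic means", {
  spec <- noiseless_p2p_spec(n_trials = 1)
  ep <- generate_epochs(spec, "Neutral")
  erp <- average_erp(ep)
  expect_equal(erp$data, ep$data[1, , ])
  expect_equal(erp$n_trials, 1L)

  # posterior cluster = mean of left and right cluster averages (5 + 5)
  sim <- simulate_experiment(default_adaptation_scenario(), seed = 23)
  s <- sim$erps$Neutral
  erp1 <- erp_waveform(s$data[1, , ], s$time_ms, s$channel_names)
  cl <- electrode_clusters()
  expect_equal(cluster_average(erp1, cl$posterior),
               (cluster_average(erp1, cl$left) + cluster_average(erp1, cl$right)) / 2)
  expect_error(cluster_average(erp1, character(0)), "empty")
  expect_error(cluster_average(erp1, "XX9"), "not in montage")

  # noiseless forward model: cluster average equals the analytic kernel
  epn <- generate_epochs(noiseless_p2p_spec(n_trials = 2), "Adaptation")
  erpn <- average_erp(epn)
  ca <- cluster_average(erpn, c("PO7", "PO3", "O1"))
  kern <- exp(-((erpn$time_ms - 220)^2) / (2 * 20^2))
  expect_equal(ca, 2 * mean(c(1, 0.6, 0.8)) * kern)
})

test_that("artifact hook is identity when unset and validates its output", {
  ep <- generate_epochs(noiseless_p2p_spec(), "Neutral")
  expect_identical(artifact_removal_hook(ep), ep)
  scaled <- artifact_removal_hook(ep, function(e) { e$data <- e$data * 0; e })
  expect_equal(max(abs(scaled$data)), 0)
  expect_error(artifact_removal_hook(ep, function(e) 42), "epoch_set")
})

test_that("the preprocessing chain is deterministic", {
  cont <- synthetic_continuous()
  run <- function() {
    f <- bandpass_filter(cont$data, cont$fs)
    ep <- epoch_and_trim(list(data = f, fs = cont$fs,
                              channel_names = cont$channel_names),
                         data.frame(sample = c(1500, 2500), condition = "T"))
    rereference_average(ep)$data
  }
  expect_identical(run(), run())
})
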