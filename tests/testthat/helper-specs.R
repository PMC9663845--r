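# Shared fixtures, all built in code.

# minimal 4-channel noiseless spec with one P2p-like component
noiseless_p2p_spec <- function(amp_adapt = 2, amp_neutral = 3, seed = 1L,
                               n_trials = 5L) {
  ch <- c("PO7", "PO3", "O1", "PO8")
  eeg_gen_spec(
    components = list(erp_component_spec(
      "P2p", latency_ms = 220, width_ms = 20,
      channel_weights = c(PO7 = 1, PO3 = 0.6, O1 = 0.8),
      amplitude_by_condition = c(Adaptation = amp_adapt, Neutral = amp_neutral)
    )),
    channels = ch, n_trials_per_condition = n_trials,
    noise_scale = 0, alpha_amp = 0, white_scale = 0,
    trial_amplitude_jitter_sd = 0, seed = seed
  )
}

# small noisy spec for Monte-Carlo checks
noisy_small_spec <- function(n_trials = 200L, seed = 2L) {
  sp <- noiseless_p2p_spec(n_trials = n_trials, seed = seed)
  sp$noise_scale <- 8; sp$alpha_amp <- 3; sp$white_scale <- 2
  sp$trial_amplitude_jitter_sd <- 0.5
  sp
}

# does a pointwise_result have any significant sample inside [w1, w2) ms?
any_sig_in_window <- function(result, window) {
  sel <- result$time_ms >= window[1] & result$time_ms < window[2]
  any(result$sig_mask[sel])
}

# build an erp_stack of pure-noise participant ERPs from one generator spec
null_erp_stack <- function(spec, n_participants = 25, condition = "Neutral") {
  a <- NULL
  time_ms <- NULL
  for (p in seq_len(n_participants)) {
    w <- generate_erp(spec, condition)
    if (is.null(a)) {
      a <- array(0, dim = c(n_participants, nrow(w$data), ncol(w$data)))
      time_ms <- w$time_ms
    }
    a[p, , ] <- w$data
  }
  erp_stack(a, time_ms, spec$channels, condition)
}

# continuous recording with a known deterministic pattern per channel
synthetic_continuous <- function(n_channels = 4, n_samples = 5000, fs = 250) {
  t <- (seq_len(n_samples) - 1) / fs
  data <- t(sapply(seq_len(n_channels), function(i) sin(2 * pi * (4 + i) * t)))
  list(data = data, fs = fs,
       channel_names = c("P3", "P4", "O1", "O2")[seq_len(n_channels)])
}
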