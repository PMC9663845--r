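#' Specification of the behavioral estimate generator
#'
#' Parameterizes the generative model for verbal numerosity estimates in the
#' three conditions Baseline, Adaptation and Neutral. Each participant carries
#' an additive response bias; adaptation multiplies the perceived numerosity
#' by (1 - underestimation_fraction) in the Adaptation condition only, so the
#' expected per-participant mean is
#' `true_numerosity * (1 - u[Adaptation]) + bias` and Baseline and Neutral
#' share the same expectation.
#'
#' @param n_participants Number of participants.
#' @param true_numerosity Dot count(s) of the test stimulus. May be a vector
#'   (e.g. the full test set 22, 26, 30, 35, 41); `trials_per_condition` is
#'   then recycled or matched per numerosity.
#' @param underestimation_fraction Fractional underestimation applied in the
#'   Adaptation condition only, in [0, 1).
#' @param participant_bias_sd SD of the per-participant additive bias (dots).
#' @param trial_noise_sd SD of single-trial response noise (dots); must be > 0.
#' @param trials_per_condition Reported trials per participant, condition and
#'   numerosity (verbal reports are requested on a subset of trials, so this
#'   is the reported-trial count).
#' @param seed Integer seed, or NULL to use the current RNG state.
#' @return Object of class `behavioral_gen_spec`.
#' @export
behavioral_gen_spec <- function(n_participants = 25,
                                true_numerosity = 30,
                                underestimation_fraction = 0.20,
                                participant_bias_sd = 1.5,
                                trial_noise_sd = 4,
                                trials_per_condition = 80,
                                seed = 1L) {
  if (underestimation_fraction < 0 || underestimation_fraction >= 1)
    stop("underestimation_fraction must be in [0, 1)")
  if (any(trial_noise_sd <= 0))
    stop("trial_noise_sd must be > 0")
  if (n_participants < 1 || any(true_numerosity < 1))
    stop("n_participants and true_numerosity must be positive")
  trials_per_condition <- rep_len(trials_per_condition, length(true_numerosity))
  structure(
    list(n_participants = as.integer(n_participants),
         true_numerosity = true_numerosity,
         underestimation_fraction = underestimation_fraction,
         participant_bias_sd = participant_bias_sd,
         trial_noise_sd = trial_noise_sd,
         trials_per_condition = as.integer(trials_per_condition),
         seed = seed),
    class = "behavioral_gen_spec"
  )
}

#' Generate a behavioral estimate table
#'
#' Draws a trial-level table of verbal numerosity estimates under the model in
#' [behavioral_gen_spec()]. Estimates are rounded to whole dots (verbal
#' reports are integers) and truncated at 1 dot. Hemifield is balanced within
#' each participant x condition x numerosity cell and adaptation trials are
#' spread over 10 blocks (baseline over 5), mirroring the block structure of
#' the adaptation paradigm.
#'
#' @param spec A `behavioral_gen_spec`.
#' @param underestimation_by_participant Optional numeric vector (length
#'   `n_participants`) of per-participant adaptation fractions, overriding the
#'   shared `underestimation_fraction` (used to couple behavioral and EEG
#'   effects through a shared latent).
#' @return A data.frame with columns `participant`, `block`, `condition`,
#'   `numerosity`, `hemifield`, `estimate`.
#' @export
generate_behavior <- function(spec, underestimation_by_participant = NULL) {
  stopifnot(inherits(spec, "behavioral_gen_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_participants
  u <- underestimation_by_participant
  if (is.null(u)) u <- rep(spec$underestimation_fraction, n)
  if (length(u) != n) stop("underestimation_by_participant must have length n_participants")
  u <- pmin(pmax(u, 0), 0.9)
  bias <- stats::rnorm(n, 0, spec$participant_bias_sd)
  conds <- c("Baseline", "Adaptation", "Neutral")
  out <- vector("list", n * 3 * length(spec$true_numerosity))
  k <- 0L
  for (p in seq_len(n)) {
    for (j in seq_along(spec$true_numerosity)) {
      num <- spec$true_numerosity[j]
      nt <- spec$trials_per_condition[j]
      for (cond in conds) {
        mu <- num * (1 - if (cond == "Adaptation") u[p] else 0) + bias[p]
        est <- pmax(1, round(mu + stats::rnorm(nt, 0, spec$trial_noise_sd)))
        nb <- if (cond == "Baseline") 5L else 10L
        k <- k + 1L
        out[[k]] <- data.frame(
          participant = p,
          block = rep_len(seq_len(nb), nt),
          condition = cond,
          numerosity = num,
          hemifield = rep_len(c("left", "right"), nt),
          estimate = est
        )
      }
    }
  }
  do.call(rbind, out)
}

#' Specification of one parametric ERP component
#'
#' A component is a Gaussian temporal kernel at a fixed latency with a fixed
#' scalp topography; its amplitude depends on the experimental condition.
#'
#' @param name Component label (e.g. "P1", "N1", "P2p", "P3").
#' @param latency_ms Peak latency, ms post stimulus onset.
#' @param width_ms SD of the Gaussian temporal kernel, ms; must be > 0.
#' @param channel_weights Named numeric vector mapping channel name to
#'   topography weight (channels absent from the map get weight 0).
#' @param amplitude_by_condition Named numeric vector mapping condition label
#'   to peak amplitude in microvolts.
#' @return Object of class `erp_component_spec`.
#' @export
erp_component_spec <- function(name, latency_ms, width_ms, channel_weights,
                               amplitude_by_condition) {
  if (width_ms <= 0) stop("width_ms must be > 0")
  stopifnot(!is.null(names(channel_weights)), !is.null(names(amplitude_by_condition)))
  structure(
    list(name = name, latency_ms = latency_ms, width_ms = width_ms,
         channel_weights = channel_weights,
         amplitude_by_condition = amplitude_by_condition),
    class = "erp_component_spec"
  )
}

#' Specification of the epoched-EEG generator
#'
#' The forward model is a sum over components of
#' amplitude(condition) x channel weight x Gaussian(time; latency, width),
#' plus 1/f noise (spectrally shaped white noise), an alpha-band sinusoid
#' with random phase per trial and channel, and white noise. Component
#' amplitudes additionally receive zero-mean Gaussian jitter per trial.
#' Optionally, a fraction of trials receives a large zero-mean amplitude
#' burst, emulating blink/muscle artifacts at the rate at which epochs were
#' discarded in the recordings this generator mimics (4-6%).
#'
#' @param components List of [erp_component_spec()] objects.
#' @param channels Montage channel names; every channel referenced by a
#'   component must be in this list.
#' @param fs Sampling rate, Hz.
#' @param epoch_window_ms Epoch window (start, end) in ms; start < 0 < end.
#'   Samples follow the half-open convention [start, end).
#' @param n_trials_per_condition Trials per condition.
#' @param noise_1f_exponent Spectral exponent of the 1/f noise.
#' @param noise_scale RMS of the 1/f noise per trial and channel, microvolts.
#' @param alpha_amp Amplitude of the alpha sinusoid, microvolts.
#' @param alpha_freq Alpha frequency, Hz.
#' @param white_scale SD of additive white noise, microvolts.
#' @param trial_amplitude_jitter_sd SD of per-trial component-amplitude
#'   jitter, microvolts.
#' @param artifact_rate Fraction of trials receiving an artifact burst.
#' @param artifact_amp Peak amplitude of the artifact burst, microvolts
#'   (random sign, so artifacts are zero-mean across trials).
#' @param seed Integer seed, or NULL to use the current RNG state.
#' @return Object of class `eeg_gen_spec`.
#' @export
eeg_gen_spec <- function(components,
                         channels = standard_montage()$name,
                         fs = 250,
                         epoch_window_ms = c(-200, 600),
                         n_trials_per_condition = 240,
                         noise_1f_exponent = 1,
                         noise_scale = 8,
                         alpha_amp = 3,
                         alpha_freq = 10,
                         white_scale = 2,
                         trial_amplitude_jitter_sd = 0.5,
                         artifact_rate = 0,
                         artifact_amp = 300,
                         seed = 1L) {
  if (fs <= 0) stop("fs must be > 0")
  if (!(epoch_window_ms[1] < 0 && 0 < epoch_window_ms[2]))
    stop("epoch window must straddle stimulus onset: start < 0 < end")
  if (n_trials_per_condition < 1) stop("n_trials_per_condition must be >= 1")
  for (cmp in components) {
    stopifnot(inherits(cmp, "erp_component_spec"))
    bad <- setdiff(names(cmp$channel_weights), channels)
    if (length(bad))
      stop("component ", cmp$name, " references channels not in the montage: ",
           paste(bad, collapse = ", "))
  }
  structure(
    list(components = components, channels = channels, fs = fs,
         epoch_window_ms = epoch_window_ms,
         n_trials_per_condition = as.integer(n_trials_per_condition),
         noise_1f_exponent = noise_1f_exponent, noise_scale = noise_scale,
         alpha_amp = alpha_amp, alpha_freq = alpha_freq,
         white_scale = white_scale,
         trial_amplitude_jitter_sd = trial_amplitude_jitter_sd,
         artifact_rate = artifact_rate, artifact_amp = artifact_amp,
         seed = seed),
    class = "eeg_gen_spec"
  )
}

#' Spectrally shaped 1/f^a Gaussian noise
#'
#' Synthesizes columns of stationary Gaussian noise whose power spectrum
#' falls off as 1/f^exponent, by shaping complex white noise in the frequency
#' domain. Columns are scaled to unit RMS in expectation.
#'
#' @param n_time Samples per column.
#' @param n_series Number of columns.
#' @param exponent Spectral exponent a (0 = white).
#' @param fs Sampling rate, Hz (sets the frequency grid only).
#' @return Matrix n_time x n_series.
#' @export
noise_1f <- function(n_time, n_series, exponent = 1, fs = 250) {
  if (exponent == 0)
    return(matrix(stats::rnorm(n_time * n_series), n_time, n_series))
  k <- seq_len(n_time) - 1
  fk <- pmin(k, n_time - k) * fs / n_time
  amp <- c(0, fk[-1]^(-exponent / 2))  # zero DC
  z <- matrix(stats::rnorm(n_time * n_series), n_time, n_series) +
    1i * matrix(stats::rnorm(n_time * n_series), n_time, n_series)
  x <- Re(stats::mvfft(z * amp, inverse = TRUE)) / n_time
  # Var(x_j) = sum(amp^2) / n^2 per sample; rescale to unit RMS
  x * (n_time / sqrt(sum(amp^2)))
}

epoch_time_axis <- function(spec) {
  n_time <- round((spec$epoch_window_ms[2] - spec$epoch_window_ms[1]) * spec$fs / 1000)
  spec$epoch_window_ms[1] + (seq_len(n_time) - 1) * 1000 / spec$fs
}

component_amplitude <- function(cmp, condition) {
  if (!condition %in% names(cmp$amplitude_by_condition))
    stop("unknown condition '", condition, "' for component ", cmp$name,
         "; known: ", paste(names(cmp$amplitude_by_condition), collapse = ", "))
  unname(cmp$amplitude_by_condition[[condition]])
}

# channels x time deterministic forward model for unit component amplitudes:
# list of per-component matrices W_k %o% kernel_k
component_fields <- function(spec, time_ms) {
  lapply(spec$components, function(cmp) {
    w <- stats::setNames(numeric(length(spec$channels)), spec$channels)
    w[names(cmp$channel_weights)] <- cmp$channel_weights
    kern <- exp(-((time_ms - cmp$latency_ms)^2) / (2 * cmp$width_ms^2))
    outer(unname(w), kern)
  })
}

cond_seed_offset <- function(condition) sum(utf8ToInt(condition)) %% 1000L

#' Generate epoched EEG for one condition
#'
#' Draws an [epoch_set()] of single trials from the forward model described
#' in [eeg_gen_spec()]. Bit-identical under a fixed `spec$seed` (the seed is
#' combined with a stable offset derived from the condition label, so each
#' condition has its own reproducible stream).
#'
#' @param spec An `eeg_gen_spec`.
#' @param condition Condition label; must be present in every component's
#'   `amplitude_by_condition`.
#' @param participant Participant identifier stored in the result.
#' @return An `epoch_set` (trials x channels x time).
#' @export
generate_epochs <- function(spec, condition, participant = NA) {
  stopifnot(inherits(spec, "eeg_gen_spec"))
  amps <- vapply(spec$components, component_amplitude, numeric(1), condition = condition)
  if (!is.null(spec$seed)) set.seed(spec$seed + cond_seed_offset(condition))
  time_ms <- epoch_time_axis(spec)
  nt <- length(time_ms)
  nc <- length(spec$channels)
  ntr <- spec$n_trials_per_condition
  fields <- component_fields(spec, time_ms)

  data <- array(0, dim = c(ntr, nc, nt))
  # deterministic components with per-trial amplitude jitter
  for (k in seq_along(fields)) {
    a_k <- amps[k] + stats::rnorm(ntr, 0, spec$trial_amplitude_jitter_sd)
    data <- data + outer(a_k, fields[[k]])
  }
  # 1/f noise, independent per trial and channel
  if (spec$noise_scale > 0) {
    nf <- spec$noise_scale *
      noise_1f(nt, ntr * nc, spec$noise_1f_exponent, spec$fs)
    data <- data + aperm(array(nf, dim = c(nt, ntr, nc)), c(2, 3, 1))
  }
  # alpha sinusoid, random phase per trial and channel
  if (spec$alpha_amp > 0) {
    theta <- 2 * pi * spec$alpha_freq * time_ms / 1000
    phi <- matrix(stats::runif(ntr * nc, 0, 2 * pi), ntr, nc)
    data <- data + spec$alpha_amp *
      (outer(sin(phi), cos(theta)) + outer(cos(phi), sin(theta)))
  }
  if (spec$white_scale > 0)
    data <- data + array(stats::rnorm(ntr * nc * nt, 0, spec$white_scale),
                         dim = c(ntr, nc, nt))
  # optional zero-mean artifact bursts (~100 ms half-sine on a channel subset)
  if (spec$artifact_rate > 0) {
    hit <- which(stats::runif(ntr) < spec$artifact_rate)
    for (tr in hit) {
      len <- max(2L, round(0.1 * spec$fs))
      start <- sample.int(nt - len + 1L, 1L)
      chs <- sample.int(nc, max(1L, round(nc / 3)))
      burst <- sample(c(-1, 1), 1) * spec$artifact_amp * sin(pi * seq_len(len) / len)
      data[tr, chs, start:(start + len - 1L)] <-
        data[tr, chs, start:(start + len - 1L)] +
        matrix(burst, length(chs), len, byrow = TRUE)
    }
  }
  epoch_set(data, spec$fs, time_ms, spec$channels,
            condition = condition, participant = participant)
}

#' Sample a participant ERP directly from the trial-average distribution
#'
#' Draws a channels x time ERP from the exact sampling distribution of the
#' mean of `n_trials` epochs under the generative model of [eeg_gen_spec()]:
#' Gaussian noise components average to Gaussian noise with SD scaled by
#' 1/sqrt(n), amplitude jitter averages likewise, and the mean of n
#' random-phase alpha sinusoids is a sinusoid with Gaussian quadrature
#' coefficients of variance alpha_amp^2/(2n) (asymptotically exact; n of a
#' few dozen suffices). This makes simulating hundreds of experiments at the
#' full trial counts cheap without changing their statistics. Artifact bursts
#' are not included: the ERP models the average of artifact-free (accepted)
#' trials.
#'
#' @inheritParams generate_epochs
#' @param n_trials Number of trials entering the average.
#' @return An `erp_waveform`.
#' @export
generate_erp <- function(spec, condition, n_trials = spec$n_trials_per_condition,
                         participant = NA) {
  stopifnot(inherits(spec, "eeg_gen_spec"), n_trials >= 1)
  amps <- vapply(spec$components, component_amplitude, numeric(1), condition = condition)
  if (!is.null(spec$seed)) set.seed(spec$seed + cond_seed_offset(condition))
  time_ms <- epoch_time_axis(spec)
  nt <- length(time_ms)
  nc <- length(spec$channels)
  fields <- component_fields(spec, time_ms)
  sq <- sqrt(n_trials)

  erp <- matrix(0, nc, nt)
  for (k in seq_along(fields)) {
    a_k <- amps[k] + stats::rnorm(1, 0, spec$trial_amplitude_jitter_sd / sq)
    erp <- erp + a_k * fields[[k]]
  }
  if (spec$noise_scale > 0) {
    nf <- (spec$noise_scale / sq) * noise_1f(nt, nc, spec$noise_1f_exponent, spec$fs)
    erp <- erp + t(nf)
  }
  if (spec$alpha_amp > 0) {
    theta <- 2 * pi * spec$alpha_freq * time_ms / 1000
    sd_q <- spec$alpha_amp / sqrt(2 * n_trials)
    erp <- erp + outer(stats::rnorm(nc, 0, sd_q), sin(theta)) +
      outer(stats::rnorm(nc, 0, sd_q), cos(theta))
  }
  if (spec$white_scale > 0)
    erp <- erp + matrix(stats::rnorm(nc * nt, 0, spec$white_scale / sq), nc, nt)
  erp_waveform(erp, time_ms, spec$channels, n_trials = n_trials,
               condition = condition, participant = participant)
}

#' The packaged adaptation-experiment scenario
#'
#' Returns the full parameterization of the default synthetic experiment:
#' about 20% behavioral underestimation under Adaptation only; a P1 component
#' elevated equally in Adaptation and Neutral relative to Baseline (an
#' aftereffect of the bright adaptor, not of numerosity); a left-posterior
#' P2p reduction in Adaptation only; and LowNum/HighNum variants in which N1
#' scales bilaterally and P2p scales over right-posterior channels with
#' physical numerosity. Component latencies are P1 = 100 ms, N1 = 170 ms,
#' P2p = 220 ms, P3 = 350 ms with Gaussian temporal kernels; topographies are
#' Gaussian fall-offs from peak electrodes (PO7/PO8 for the lateralized P2p
#' subcomponents).
#'
#' @param coupling Target correlation between the per-participant behavioral
#'   and electrophysiological adaptation effects (shared latent), in [0, 1].
#' @param participant_effect_sd Relative SD of per-participant effect
#'   magnitudes (both behavioral underestimation and P2p reduction).
#' @return A list with elements `behavior` (a `behavioral_gen_spec`),
#'   `eeg_specs` (named list mapping condition to `eeg_gen_spec`; Baseline,
#'   Adaptation and Neutral share one spec, LowNum and HighNum another),
#'   `p2p_reduction` (microvolts), `coupling`, `participant_effect_sd`,
#'   `clusters`.
#' @export
default_adaptation_scenario <- function(coupling = 0.6, participant_effect_sd = 0.25) {
  montage <- standard_montage()
  cmp <- list(
    erp_component_spec(
      "P1", latency_ms = 100, width_ms = 15,
      channel_weights = topo_weights("POz", 40, montage),
      amplitude_by_condition = c(Baseline = 2, Adaptation = 3, Neutral = 3,
                                 LowNum = 3, HighNum = 3)),
    erp_component_spec(
      "N1_left", latency_ms = 170, width_ms = 20,
      channel_weights = topo_weights("PO7", 30, montage),
      amplitude_by_condition = c(Baseline = -3, Adaptation = -3, Neutral = -3,
                                 LowNum = -3.4, HighNum = -2.4)),
    erp_component_spec(
      "N1_right", latency_ms = 170, width_ms = 20,
      channel_weights = topo_weights("PO8", 30, montage),
      amplitude_by_condition = c(Baseline = -3, Adaptation = -3, Neutral = -3,
                                 LowNum = -3.4, HighNum = -2.4)),
    erp_component_spec(
      "P2p_left", latency_ms = 220, width_ms = 20,
      channel_weights = topo_weights("PO7", 30, montage),
      amplitude_by_condition = c(Baseline = 3, Adaptation = 2, Neutral = 3,
                                 LowNum = 3, HighNum = 3)),
    erp_component_spec(
      "P2p_right", latency_ms = 220, width_ms = 20,
      channel_weights = topo_weights("PO8", 30, montage),
      amplitude_by_condition = c(Baseline = 3, Adaptation = 3, Neutral = 3,
                                 LowNum = 2.5, HighNum = 3.5)),
    erp_component_spec(
      "P3", latency_ms = 350, width_ms = 40,
      channel_weights = topo_weights("Pz", 45, montage),
      amplitude_by_condition = c(Baseline = 2, Adaptation = 2.5, Neutral = 2.5,
                                 LowNum = 2, HighNum = 2))
  )
  # artifact_rate emulates the ~4-6% of epochs discarded for blinks/muscle
  # activity in the recordings this scenario mimics
  adapt_spec <- eeg_gen_spec(cmp, n_trials_per_condition = 240, artifact_rate = 0.05)
  num_spec <- eeg_gen_spec(cmp, n_trials_per_condition = 96, artifact_rate = 0.05)
  list(
    behavior = behavioral_gen_spec(
      n_participants = 25,
      true_numerosity = c(22, 26, 30, 35, 41),
      underestimation_fraction = 0.20,
      trials_per_condition = c(8, 8, 80, 8, 8)),
    eeg_specs = list(Baseline = adapt_spec, Adaptation = adapt_spec,
                     Neutral = adapt_spec, LowNum = num_spec, HighNum = num_spec),
    p2p_reduction = 1,
    coupling = coupling,
    participant_effect_sd = participant_effect_sd,
    clusters = electrode_clusters()
  )
}

#' Simulate one complete experiment (behavior + participant ERPs)
#'
#' Draws per-participant behavioral tables and condition-wise ERPs under a
#' scenario from [default_adaptation_scenario()]. The per-participant behavioral
#' underestimation and left-posterior P2p reduction share a latent factor
#' with correlation `scenario$coupling`, so the brain-behavior association
#' the analysis looks for is present by construction. ERPs are drawn with
#' [generate_erp()] at the scenario's trial counts.
#'
#' @param scenario Scenario list, as from [default_adaptation_scenario()].
#' @param seed Integer seed for the whole experiment.
#' @param conditions Conditions to simulate EEG for.
#' @return List with `behavior` (estimate table), `erps` (named list of
#'   [erp_stack()] by condition), and `latents` (data.frame of the shared,
#'   behavioral and EEG latent draws per participant).
#' @export
simulate_experiment <- function(scenario = default_adaptation_scenario(),
                                seed = 1L,
                                conditions = c("Baseline", "Adaptation", "Neutral")) {
  set.seed(seed)
  n <- scenario$behavior$n_participants
  cc <- scenario$coupling
  z  <- stats::rnorm(n)
  zb <- sqrt(cc) * z + sqrt(1 - cc) * stats::rnorm(n)
  ze <- sqrt(cc) * z + sqrt(1 - cc) * stats::rnorm(n)
  rel <- scenario$participant_effect_sd

  beh_spec <- scenario$behavior
  beh_spec$seed <- NULL  # consume the experiment-level stream
  u <- scenario$behavior$underestimation_fraction * (1 + rel * zb)
  behavior <- generate_behavior(beh_spec, underestimation_by_participant = u)

  erps <- list()
  for (cond in conditions) {
    spec0 <- scenario$eeg_specs[[cond]]
    if (is.null(spec0))
      stop("scenario has no EEG spec for condition ", cond)
    first <- TRUE
    stack <- NULL
    for (p in seq_len(n)) {
      spec <- spec0
      spec$seed <- NULL
      if (cond == "Adaptation") {
        # participant-specific P2p reduction on the left subcomponent
        red <- scenario$p2p_reduction * (1 + rel * ze[p])
        for (k in seq_along(spec$components)) {
          if (spec$components[[k]]$name == "P2p_left") {
            base <- spec$components[[k]]$amplitude_by_condition[["Neutral"]]
            spec$components[[k]]$amplitude_by_condition[["Adaptation"]] <-
              max(0, base - red)
          }
        }
      }
      w <- generate_erp(spec, cond, participant = p)
      if (first) {
        stack <- array(0, dim = c(n, nrow(w$data), ncol(w$data)))
        time_ms <- w$time_ms
        first <- FALSE
      }
      stack[p, , ] <- w$data
    }
    erps[[cond]] <- erp_stack(stack, time_ms, spec0$channels, cond,
                              n_trials = spec0$n_trials_per_condition)
  }
  list(behavior = behavior, erps = erps,
       latents = data.frame(z = z, zb = zb, ze = ze))
}
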