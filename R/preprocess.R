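#' Design the band-pass FIR kernel
#'
#' Windowed-sinc (Hamming) linear-phase band-pass whose -6 dB points sit at
#' `low - transition/2` and `high + transition/2` Hz: with the default
#' 1-40 Hz band and 1 Hz transition width this puts the -6 dB points at 0.5
#' and 40.5 Hz. Order is chosen from the Hamming transition-width rule
#' (3.3 / transition) and rounded up to an even number so the kernel is
#' symmetric (type I).
#'
#' @param fs Sampling rate, Hz.
#' @param low,high Passband edges, Hz.
#' @param transition Transition width, Hz.
#' @return Numeric vector of filter coefficients (odd length).
#' @export
fir_bandpass_design <- function(fs, low = 1, high = 40, transition = 1) {
  if (fs <= 2 * high) stop("sampling rate too low for the requested passband")
  order <- 2 * ceiling(3.3 * fs / transition / 2)
  edges <- c(low - transition / 2, high + transition / 2)
  if (edges[1] <= 0) stop("transition band extends below 0 Hz")
  signal::fir1(order, edges / (fs / 2), type = "pass")
}

# zero-phase application of a symmetric odd-length FIR kernel to the rows of
# a matrix (channels x time), with reflection padding
apply_fir <- function(x, h) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  half <- (length(h) - 1) / 2
  n <- ncol(x)
  pad <- min(half, n - 1)
  out <- matrix(0, nrow(x), n)
  for (i in seq_len(nrow(x))) {
    v <- x[i, ]
    # reflect about the end points to limit edge transients
    left <- 2 * v[1] - v[seq(pad + 1, 2)]
    right <- 2 * v[n] - v[seq(n - 1, n - pad)]
    ext <- c(left, v, right)
    f <- stats::convolve(ext, rev(h), type = "open")
    out[i, ] <- f[(half + pad + 1):(half + pad + n)]
  }
  if (vec) drop(out) else out
}

#' Band-pass filter EEG
#'
#' Zero-phase FIR band-pass (see [fir_bandpass_design()]); with the defaults
#' the -6 dB points are at 0.5 and 40.5 Hz and DC is removed. Operates on a
#' numeric vector, a channels x time matrix, or the trials of an
#' [epoch_set()] (filtering continuous data before epoching is preferred;
#' epoch-wise filtering is provided for completeness).
#'
#' @param x Vector, channels x time matrix, or `epoch_set`.
#' @param fs Sampling rate, Hz (taken from the object for an `epoch_set`).
#' @param low,high,transition Passband edges and transition width, Hz.
#' @return Filtered object of the same shape/class.
#' @export
bandpass_filter <- function(x, fs = NULL, low = 1, high = 40, transition = 1) {
  if (inherits(x, "epoch_set")) {
    h <- fir_bandpass_design(x$fs, low, high, transition)
    for (tr in seq_len(dim(x$data)[1]))
      x$data[tr, , ] <- apply_fir(x$data[tr, , , drop = TRUE], h)
    return(x)
  }
  if (is.null(fs)) stop("fs is required for vector/matrix input")
  apply_fir(x, fir_bandpass_design(fs, low, high, transition))
}

#' Frequency response of an FIR kernel
#'
#' Evaluates H(f) = sum_k h_k exp(-2 pi i f k / fs) on a frequency grid;
#' used to verify passband/stopband behavior of designed filters.
#'
#' @param h FIR coefficients.
#' @param freq_hz Frequencies at which to evaluate, Hz.
#' @param fs Sampling rate, Hz.
#' @return Complex vector of the same length as `freq_hz`; take `Mod()` for
#'   the magnitude response.
#' @export
fir_response <- function(h, freq_hz, fs) {
  k <- seq_along(h) - 1
  vapply(freq_hz, function(f) sum(h * exp(-2i * pi * f * k / fs)),
         complex(1))
}

#' Downsample with anti-alias filtering
#'
#' Integer-factor decimation preceded by a zero-phase FIR anti-alias low-pass
#' with cutoff at 0.8 of the new Nyquist frequency. `fs_out == fs_in` is the
#' identity; `fs_out > fs_in` is an error.
#'
#' @param x Vector or channels x time matrix.
#' @param fs_in Input sampling rate, Hz.
#' @param fs_out Output sampling rate, Hz; must divide `fs_in`.
#' @return List with elements `data` (downsampled) and `fs` (= fs_out).
#' @export
downsample_signal <- function(x, fs_in, fs_out) {
  if (fs_out > fs_in) stop("fs_out must not exceed fs_in")
  if (fs_out == fs_in) return(list(data = x, fs = fs_out))
  k <- fs_in / fs_out
  if (abs(k - round(k)) > 1e-9)
    stop("fs_in must be an integer multiple of fs_out")
  k <- round(k)
  cutoff <- 0.8 * (fs_out / 2)
  order <- 2 * ceiling(3.3 * fs_in / (0.2 * fs_out) / 2)
  h <- signal::fir1(order, cutoff / (fs_in / 2), type = "low")
  h <- h / sum(h)  # unit DC gain
  y <- apply_fir(x, h)
  idx <- seq(1, if (is.null(dim(y))) length(y) else ncol(y), by = k)
  list(data = if (is.null(dim(y))) y[idx] else y[, idx, drop = FALSE],
       fs = fs_out)
}

# spherical-spline g function (stiffness m, nterms Legendre terms)
spline_g <- function(cosang, m = 4, nterms = 50) {
  x <- as.numeric(cosang)
  P_prev <- rep(1, length(x))  # P_0
  P_cur <- x                   # P_1
  g <- (2 * 1 + 1) / (1 * 2)^m * P_cur
  for (n in 2:nterms) {
    P_next <- ((2 * n - 1) * x * P_cur - (n - 1) * P_prev) / n
    g <- g + (2 * n + 1) / (n * (n + 1))^m * P_next
    P_prev <- P_cur
    P_cur <- P_next
  }
  matrix(g / (4 * pi), nrow = nrow(cosang))
}

#' Spherical-spline interpolation matrix
#'
#' Linear mapping from good-channel values to interpolated values at target
#' positions, following the spherical-spline formulation (stiffness 4, 50
#' Legendre terms, small diagonal regularization). Rows sum to 1, so constant
#' potentials are reproduced exactly.
#'
#' @param pos_good Good-channel positions, n_good x 3 unit vectors.
#' @param pos_bad Target positions, n_bad x 3 unit vectors.
#' @param stiffness Spline stiffness m.
#' @param nterms Number of Legendre terms.
#' @param reg Diagonal regularization added to the spline system.
#' @return Matrix n_bad x n_good of interpolation weights.
#' @export
spline_interp_matrix <- function(pos_good, pos_bad, stiffness = 4,
                                 nterms = 50, reg = 1e-5) {
  ng <- nrow(pos_good)
  G <- spline_g(angular_cosines(pos_good, pos_good), stiffness, nterms)
  Gt <- spline_g(angular_cosines(pos_bad, pos_good), stiffness, nterms)
  A <- rbind(cbind(G + reg * diag(ng), 1), c(rep(1, ng), 0))
  M <- cbind(Gt, 1) %*% solve(A)
  M[, seq_len(ng), drop = FALSE]
}

#' Interpolate bad channels by spherical splines
#'
#' Replaces the listed channels of an [epoch_set()] with spherical-spline
#' interpolations from the remaining channels.
#'
#' @param epochs An `epoch_set` with channel positions.
#' @param bad Character vector of bad channel names; empty input is the
#'   identity.
#' @return The `epoch_set` with bad channels replaced; interpolated channel
#'   names are recorded in attribute `interpolated`.
#' @export
interpolate_bad_channels <- function(epochs, bad) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (length(bad) == 0) return(epochs)
  if (is.null(epochs$channel_positions))
    stop("epoch_set has no channel positions")
  ib <- match(bad, epochs$channel_names)
  if (anyNA(ib)) stop("bad channels not in montage: ",
                      paste(bad[is.na(ib)], collapse = ", "))
  ig <- setdiff(seq_along(epochs$channel_names), ib)
  if (length(ig) < 4) stop("need at least 4 good channels to interpolate")
  M <- spline_interp_matrix(epochs$channel_positions[ig, , drop = FALSE],
                            epochs$channel_positions[ib, , drop = FALSE])
  for (tr in seq_len(dim(epochs$data)[1]))
    epochs$data[tr, ib, ] <- M %*% epochs$data[tr, ig, , drop = TRUE]
  attr(epochs, "interpolated") <- bad
  epochs
}

#' Re-reference to the channel average
#'
#' Subtracts, at every trial and time point, the mean over all channels, so
#' the channel mean is exactly zero afterwards. Idempotent; differences
#' between channels are unchanged.
#'
#' @param epochs An `epoch_set` (or `erp_waveform`).
#' @return Re-referenced object of the same class.
#' @export
rereference_average <- function(epochs) {
  if (inherits(epochs, "erp_waveform")) {
    epochs$data <- sweep(epochs$data, 2, colMeans(epochs$data))
    return(epochs)
  }
  stopifnot(inherits(epochs, "epoch_set"))
  mu <- apply(epochs$data, c(1, 3), mean)  # trials x time
  nc <- dim(epochs$data)[2]
  epochs$data <- epochs$data - aperm(array(mu, dim = c(dim(mu), nc)), c(1, 3, 2))
  epochs
}

#' Epoch continuous EEG, trim and baseline-correct
#'
#' Extracts epochs around event onsets from a continuous recording, trims
#' them to the analysis window, and subtracts the per-trial, per-channel mean
#' of the baseline window. Samples follow the half-open convention
#' [start, end), so -200..600 ms at 250 Hz yields exactly 200 samples, with
#' the stimulus-onset sample included. Events too close to the recording
#' edges for the extraction window are dropped with a message.
#'
#' @param continuous List with `data` (channels x samples), `fs`, and
#'   `channel_names` (as returned by [read_brainvision()] / [read_edf()]).
#' @param events data.frame with columns `sample` (1-based onset index) and
#'   `condition`.
#' @param window Extraction window (start, end), ms.
#' @param trim Analysis window kept after extraction, ms.
#' @param baseline Baseline window, ms.
#' @return An `epoch_set`; `condition` holds one label per trial.
#' @export
epoch_and_trim <- function(continuous, events, window = c(-500, 1000),
                           trim = c(-200, 600), baseline = c(-200, 0)) {
  stopifnot(all(c("data", "fs") %in% names(continuous)),
            all(c("sample", "condition") %in% names(events)))
  fs <- continuous$fs
  x <- continuous$data
  n <- ncol(x)
  w0 <- round(window[1] * fs / 1000); w1 <- round(window[2] * fs / 1000) - 1
  ok <- events$sample + w0 >= 1 & events$sample + w1 <= n
  if (any(!ok))
    message(sum(!ok), " event(s) too close to the recording edge; dropped")
  events <- events[ok, , drop = FALSE]
  if (nrow(events) == 0) stop("no events fall inside the recording")
  t0 <- round(trim[1] * fs / 1000); t1 <- round(trim[2] * fs / 1000) - 1
  nt <- t1 - t0 + 1
  nc <- nrow(x)
  data <- array(0, dim = c(nrow(events), nc, nt))
  for (i in seq_len(nrow(events)))
    data[i, , ] <- x[, (events$sample[i] + t0):(events$sample[i] + t1), drop = FALSE]
  time_ms <- (t0:t1) * 1000 / fs
  bl <- time_ms >= baseline[1] & time_ms < baseline[2]
  if (!any(bl)) stop("baseline window contains no samples")
  blmean <- apply(data[, , bl, drop = FALSE], c(1, 2), mean)
  data <- data - array(blmean, dim = dim(data))
  epoch_set(data, fs, time_ms,
            continuous$channel_names %||% paste0("ch", seq_len(nc)),
            condition = as.character(events$condition))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reject epochs on a peak-to-peak criterion
#'
#' Removes trials whose maximum peak-to-peak amplitude on any channel exceeds
#' a threshold — an automated stand-in for manual artifact inspection; the
#' threshold is configurable.
#'
#' @param epochs An `epoch_set`.
#' @param threshold Peak-to-peak threshold, microvolts (> 0).
#' @return List with `epochs` (trials kept) and `removed_fraction` (percent).
#' @export
reject_epochs <- function(epochs, threshold = 150) {
  stopifnot(inherits(epochs, "epoch_set"), threshold > 0)
  p2p <- apply(epochs$data, 1, function(tr) max(apply(tr, 1, function(v) diff(range(v)))))
  keep <- p2p <= threshold
  if (!any(keep))
    stop("all trials exceed the peak-to-peak threshold (", threshold,
         " uV); raise the threshold")
  epochs$data <- epochs$data[keep, , , drop = FALSE]
  if (length(epochs$condition) > 1) epochs$condition <- epochs$condition[keep]
  list(epochs = epochs, removed_fraction = 100 * mean(!keep))
}

#' Pluggable artifact-removal hook
#'
#' Independent-component-based ocular/muscle cleanup is deliberately outside
#' this package; this hook lets callers plug any epochs -> epochs cleaning
#' function into the preprocessing chain. With `fun = NULL` it is the
#' identity.
#'
#' @param epochs An `epoch_set`.
#' @param fun NULL, or a function(epoch_set) -> epoch_set.
#' @return The (possibly cleaned) `epoch_set`.
#' @export
artifact_removal_hook <- function(epochs, fun = NULL) {
  if (is.null(fun)) return(epochs)
  out <- fun(epochs)
  if (!inherits(out, "epoch_set")) stop("hook must return an epoch_set")
  out
}

#' Average epochs into an ERP
#'
#' @param epochs An `epoch_set` (optionally restricted with `condition`).
#' @param condition If given, average only trials with this condition label.
#' @return An `erp_waveform` (channels x time) with `n_trials` recorded.
#' @export
average_erp <- function(epochs, condition = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  sel <- seq_len(dim(epochs$data)[1])
  lab <- epochs$condition
  if (!is.null(condition)) {
    if (length(lab) == 1) {
      if (!identical(lab, condition)) stop("epochs are condition ", lab)
    } else {
      sel <- which(lab == condition)
      if (length(sel) == 0) stop("no trials with condition ", condition)
      lab <- condition
    }
  }
  m <- apply(epochs$data[sel, , , drop = FALSE], c(2, 3), mean)
  erp_waveform(m, epochs$time_ms, epochs$channel_names,
               n_trials = length(sel),
               condition = if (length(unique(lab)) == 1) unique(lab) else NA_character_,
               participant = epochs$participant)
}

#' Cluster-averaged waveform
#'
#' Arithmetic mean of an ERP over a set of cluster channels.
#'
#' @param erp An `erp_waveform`.
#' @param cluster Character vector of channel names (non-empty, all present).
#' @return Numeric vector over time (same axis as `erp$time_ms`).
#' @export
cluster_average <- function(erp, cluster) {
  stopifnot(inherits(erp, "erp_waveform"))
  if (length(cluster) == 0) stop("empty cluster")
  idx <- match(cluster, erp$channel_names)
  if (anyNA(idx))
    stop("cluster channels not in montage: ",
         paste(cluster[is.na(idx)], collapse = ", "))
  colMeans(erp$data[idx, , drop = FALSE])
}
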