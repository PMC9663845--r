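#' Epoched EEG container
#'
#' Constructs an `epoch_set`: a trials x channels x time array of epoched EEG
#' in microvolts, with its sampling rate, time axis and channel metadata.
#'
#' @param data Numeric array, trials x channels x time (microvolts).
#' @param fs Sampling rate, Hz.
#' @param time_ms Time axis in ms relative to stimulus onset; must be strictly
#'   increasing and uniformly spaced at 1000/fs.
#' @param channel_names Character vector, one unique name per channel.
#' @param channel_positions Optional matrix (channels x 3) of unit-sphere
#'   coordinates; defaults to the standard montage positions where names match.
#' @param condition Condition label (scalar, or one label per trial after
#'   epoching mixed-condition event tables).
#' @param participant Participant identifier.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, fs, time_ms, channel_names,
                      channel_positions = NULL, condition = NA_character_,
                      participant = NA) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (dim(data)[2] != length(channel_names))
    stop("channel axis length (", dim(data)[2], ") != number of channel names (",
         length(channel_names), ")")
  if (dim(data)[3] != length(time_ms))
    stop("time axis length mismatch")
  if (anyDuplicated(channel_names)) stop("channel names must be unique")
  dt <- diff(time_ms)
  if (any(dt <= 0) || max(abs(dt - 1000 / fs)) > 1e-6)
    stop("time axis must be strictly increasing and uniform at 1/fs")
  if (is.null(channel_positions)) {
    m <- standard_montage()
    idx <- match(channel_names, m$name)
    if (!anyNA(idx))
      channel_positions <- as.matrix(m[idx, c("x", "y", "z")])
  }
  structure(
    list(data = data, fs = fs, time_ms = time_ms,
         channel_names = channel_names,
         channel_positions = channel_positions,
         condition = condition, participant = participant),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples @ %g Hz, %g..%g ms\n",
              d[1], d[2], d[3], x$fs, min(x$time_ms), max(x$time_ms)))
  cat("  condition:", paste(unique(x$condition), collapse = ", "),
      " participant:", x$participant, "\n")
  invisible(x)
}

n_trials <- function(epochs) dim(epochs$data)[1]

#' ERP waveform container
#'
#' A channels x time trial-average (or grand average) with the number of
#' trials (or participants) that entered the average.
#'
#' @param data Numeric matrix, channels x time (microvolts).
#' @param time_ms Time axis, ms.
#' @param channel_names Channel names (length = nrow(data)).
#' @param n_trials Number of trials averaged.
#' @param condition Condition label.
#' @param participant Participant identifier.
#' @return Object of class `erp_waveform`.
#' @export
erp_waveform <- function(data, time_ms, channel_names, n_trials = 1L,
                         condition = NA_character_, participant = NA) {
  stopifnot(is.matrix(data), nrow(data) == length(channel_names),
            ncol(data) == length(time_ms), n_trials >= 1)
  structure(
    list(data = data, time_ms = time_ms, channel_names = channel_names,
         n_trials = as.integer(n_trials), condition = condition,
         participant = participant),
    class = "erp_waveform"
  )
}

#' @export
print.erp_waveform <- function(x, ...) {
  cat(sprintf("<erp_waveform> %d channels x %d samples (%g..%g ms), %d trials, condition %s\n",
              nrow(x$data), ncol(x$data), min(x$time_ms), max(x$time_ms),
              x$n_trials, x$condition))
  invisible(x)
}

#' Stack of participant ERPs for one condition
#'
#' @param data Numeric array, participants x channels x time.
#' @param time_ms Time axis, ms.
#' @param channel_names Channel names.
#' @param condition Condition label.
#' @param n_trials Trials per participant average.
#' @return Object of class `erp_stack`.
#' @export
erp_stack <- function(data, time_ms, channel_names, condition, n_trials = NA_integer_) {
  stopifnot(is.array(data), length(dim(data)) == 3,
            dim(data)[2] == length(channel_names),
            dim(data)[3] == length(time_ms))
  structure(
    list(data = data, time_ms = time_ms, channel_names = channel_names,
         condition = condition, n_trials = n_trials),
    class = "erp_stack"
  )
}

#' @export
print.erp_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<erp_stack> %d participants x %d channels x %d samples, condition %s\n",
              d[1], d[2], d[3], x$condition))
  invisible(x)
}

#' Per-participant cluster-averaged waveforms
#'
#' Averages an [erp_stack()] over a set of cluster channels, yielding a
#' participants x time matrix — the unit on which the point-wise bootstrap
#' statistics operate.
#'
#' @param stack An `erp_stack`.
#' @param cluster Character vector of channel names.
#' @return Numeric matrix, participants x time.
#' @export
stack_cluster_matrix <- function(stack, cluster) {
  idx <- match(cluster, stack$channel_names)
  if (anyNA(idx))
    stop("cluster channels not in data: ",
         paste(cluster[is.na(idx)], collapse = ", "))
  if (length(idx) == 1L) return(stack$data[, idx, , drop = TRUE])
  apply(stack$data[, idx, , drop = FALSE], c(1, 3), mean)
}
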