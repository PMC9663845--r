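ESTIMATE_COLUMNS <- c("participant", "block", "condition", "numerosity",
                      "hemifield", "estimate")

#' Read / write behavioral estimate tables
#'
#' Estimate tables are plain CSV with header
#' `participant,block,condition,numerosity,hemifield,estimate`.
#'
#' @param path File path.
#' @param table Estimate data.frame (for writing).
#' @return `read_estimates` returns the data.frame; `write_estimates` returns
#'   `path` invisibly.
#' @export
read_estimates <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(ESTIMATE_COLUMNS, names(tab))
  if (length(missing_cols))
    stop("estimate table lacks column(s): ", paste(missing_cols, collapse = ", "))
  tab
}

#' @rdname read_estimates
#' @export
write_estimates <- function(table, path) {
  missing_cols <- setdiff(ESTIMATE_COLUMNS, names(table))
  if (length(missing_cols))
    stop("estimate table lacks column(s): ", paste(missing_cols, collapse = ", "))
  utils::write.csv(table[, ESTIMATE_COLUMNS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

EPO_MAGIC <- "NAEPO1"

#' Write / read the epochs container
#'
#' A self-describing single-file container for epoched EEG: a magic string,
#' a 4-byte little-endian header length, a JSON header (dimensions, sampling
#' rate, time axis, channel names and positions, condition, participant) and
#' the data payload as little-endian float64 in trials-fastest order. This is
#' the on-disk form of an [epoch_set()].
#'
#' @param epochs An `epoch_set`.
#' @param path File path (conventional extension `.epo`).
#' @return `write_epochs` returns `path` invisibly; `read_epochs` returns the
#'   `epoch_set`.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  header <- list(
    dims = dim(epochs$data), fs = epochs$fs, time_ms = epochs$time_ms,
    channel_names = epochs$channel_names,
    channel_positions = epochs$channel_positions,
    condition = epochs$condition, participant = epochs$participant
  )
  hj <- charToRaw(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA, null = "null"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(EPO_MAGIC), con)
  writeBin(length(hj), con, size = 4, endian = "little")
  writeBin(hj, con)
  writeBin(as.numeric(epochs$data), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", nchar(EPO_MAGIC)))
  if (!identical(magic, EPO_MAGIC))
    stop(path, " is not an epochs container (bad magic)")
  hlen <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (length(hlen) == 0 || hlen <= 0) stop("truncated epochs container header")
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", hlen)))
  nvals <- prod(header$dims)
  vals <- readBin(con, "numeric", nvals, size = 8, endian = "little")
  if (length(vals) < nvals)
    stop("truncated epochs container: expected ", nvals, " values, got ",
         length(vals))
  pos <- header$channel_positions
  if (!is.null(pos)) pos <- matrix(unlist(pos), ncol = 3)
  epoch_set(array(vals, dim = header$dims), header$fs, header$time_ms,
            header$channel_names, channel_positions = pos,
            condition = header$condition,
            participant = header$participant %||% NA)
}

#' Validate an epochs container file
#'
#' Checks the structural invariants of the on-disk [epoch_set()]: readable
#' header, consistent axis lengths, uniform time axis at 1/fs, unique channel
#' names, and channel names resolvable against the standard montage.
#'
#' @param path Path to an `.epo` file.
#' @return List with `ok` (logical) and `violations` (character vector;
#'   empty when ok).
#' @export
validate_container <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  violations <- character(0)
  ep <- tryCatch(read_epochs(path), error = function(e) e)
  if (inherits(ep, "error"))
    return(list(ok = FALSE, violations = paste("read failure:", conditionMessage(ep))))
  d <- dim(ep$data)
  if (d[2] != length(ep$channel_names))
    violations <- c(violations, "channel axis length != number of channel names")
  if (d[3] != length(ep$time_ms))
    violations <- c(violations, "time axis length mismatch")
  if (anyDuplicated(ep$channel_names))
    violations <- c(violations, "duplicate channel names")
  dt <- diff(ep$time_ms)
  if (any(dt <= 0) || max(abs(dt - 1000 / ep$fs)) > 1e-6)
    violations <- c(violations, "time axis not uniform at 1/fs")
  unknown <- setdiff(ep$channel_names, standard_montage()$name)
  if (length(unknown))
    violations <- c(violations,
                    paste("channels not in the standard montage:",
                          paste(unknown, collapse = ", ")))
  list(ok = length(violations) == 0, violations = violations)
}

parse_ini <- function(lines) {
  sec <- NULL
  out <- list()
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[.*\\]$", ln)) {
      sec <- gsub("^\\[|\\]$", "", ln)
      out[[sec]] <- list()
    } else if (grepl("=", ln) && !is.null(sec)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      out[[sec]][[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = "="))
    }
  }
  out
}

#' Read a BrainVision recording
#'
#' Reads the `.vhdr`/`.vmrk`/data triplet. Supported data formats: binary
#' IEEE_FLOAT_32 and INT_16 (multiplexed or vectorized) and ASCII. Channel
#' resolutions are applied so the result is in microvolts. Stimulus markers
#' are returned as an event table.
#'
#' @param vhdr_path Path to the `.vhdr` header file.
#' @return List with `data` (channels x samples, microvolts), `fs`,
#'   `channel_names`, and `events` (data.frame `sample`, `condition` from
#'   stimulus markers; empty if no marker file).
#' @export
read_brainvision <- function(vhdr_path) {
  if (!file.exists(vhdr_path)) stop("no such file: ", vhdr_path)
  ini <- parse_ini(readLines(vhdr_path, warn = FALSE))
  ci <- ini[["Common Infos"]]
  if (is.null(ci)) stop("not a BrainVision header: missing [Common Infos]")
  dir <- dirname(vhdr_path)
  data_file <- file.path(dir, ci$DataFile)
  fs <- 1e6 / as.numeric(ci$SamplingInterval)  # interval is in microseconds
  nch <- as.integer(ci$NumberOfChannels)
  chan <- ini[["Channel Infos"]]
  ch_names <- character(nch); resolution <- rep(1, nch)
  for (i in seq_len(nch)) {
    parts <- strsplit(chan[[sprintf("Ch%d", i)]], ",")[[1]]
    ch_names[i] <- trimws(parts[1])
    if (length(parts) >= 3 && nzchar(trimws(parts[3])))
      resolution[i] <- as.numeric(parts[3])
  }
  fmt <- toupper(ci$DataFormat %||% "BINARY")
  orientation <- toupper(ci$DataOrientation %||% "MULTIPLEXED")
  if (fmt == "BINARY") {
    bin <- toupper(ini[["Binary Infos"]]$BinaryFormat %||% "IEEE_FLOAT_32")
    sz <- file.size(data_file)
    if (bin == "IEEE_FLOAT_32") {
      vals <- readBin(data_file, "numeric", n = sz / 4, size = 4, endian = "little")
    } else if (bin == "INT_16") {
      vals <- readBin(data_file, "integer", n = sz / 2, size = 2, endian = "little")
    } else stop("unsupported BinaryFormat: ", bin)
  } else if (fmt == "ASCII") {
    tab <- utils::read.table(data_file, header = FALSE)
    # ASCII data are written vectorized (one line per channel) by convention
    vals <- as.numeric(t(as.matrix(tab)))
    orientation <- "VECTORIZED"
  } else stop("unsupported DataFormat: ", fmt)
  ns <- length(vals) %/% nch
  x <- if (orientation == "MULTIPLEXED") {
    matrix(vals[seq_len(ns * nch)], nrow = nch)          # channel-fastest
  } else {
    t(matrix(vals[seq_len(ns * nch)], nrow = ns))        # sample-fastest
  }
  x <- x * resolution
  events <- data.frame(sample = integer(0), condition = character(0))
  if (!is.null(ci$MarkerFile)) {
    mrk_path <- file.path(dir, ci$MarkerFile)
    if (file.exists(mrk_path)) {
      mrk <- parse_ini(readLines(mrk_path, warn = FALSE))[["Marker Infos"]]
      rows <- lapply(mrk, function(v) strsplit(v, ",")[[1]])
      keep <- vapply(rows, function(r) trimws(r[1]) == "Stimulus", logical(1))
      rows <- rows[keep]
      if (length(rows))
        events <- data.frame(
          sample = vapply(rows, function(r) as.integer(r[3]), integer(1)),
          condition = vapply(rows, function(r) trimws(r[2]), character(1))
        )
    }
  }
  list(data = x, fs = fs, channel_names = ch_names, events = events)
}

#' Read an EDF/EDF+ recording
#'
#' Minimal reader for continuous EDF recordings with a uniform sampling rate
#' across ordinary signals: parses the fixed-layout header, reads the 16-bit
#' data records and rescales to physical units (microvolts for EEG channels).
#' Annotation channels ("EDF Annotations") are dropped.
#'
#' @param path Path to the `.edf` file.
#' @return List with `data` (channels x samples), `fs`, `channel_names`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd_str <- function(nbytes) trimws(rawToChar(readBin(con, "raw", nbytes)))
  rd_num <- function(nbytes) as.numeric(rd_str(nbytes))
  version <- rd_str(8)
  if (version != "0") stop("not an EDF file (version field '", version, "')")
  invisible(rd_str(80 + 80 + 8 + 8))       # patient, recording, date, time
  header_bytes <- rd_num(8)
  invisible(rd_str(44))                    # reserved
  n_records <- rd_num(8)
  record_dur <- rd_num(8)
  ns <- as.integer(rd_num(4))
  labels <- vapply(seq_len(ns), function(i) rd_str(16), "")
  invisible(rd_str(80 * ns + 8 * ns))      # transducer, physical dimension
  phys_min <- vapply(seq_len(ns), function(i) rd_num(8), 0)
  phys_max <- vapply(seq_len(ns), function(i) rd_num(8), 0)
  dig_min <- vapply(seq_len(ns), function(i) rd_num(8), 0)
  dig_max <- vapply(seq_len(ns), function(i) rd_num(8), 0)
  invisible(rd_str(80 * ns))               # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(rd_num(8)), 0L)
  invisible(rd_str(32 * ns))               # reserved
  seek(con, header_bytes)
  keep <- labels != "EDF Annotations"
  if (!any(keep)) stop("EDF file contains no ordinary signals")
  if (length(unique(spr[keep])) != 1)
    stop("mixed sampling rates across signals are not supported")
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  offset <- phys_min - gain * dig_min
  total_per_rec <- sum(spr)
  raw <- readBin(con, "integer", n = n_records * total_per_rec,
                 size = 2, endian = "little", signed = TRUE)
  if (length(raw) < n_records * total_per_rec)
    stop("truncated EDF file")
  starts <- cumsum(c(0, spr))[seq_len(ns)]
  nk <- spr[keep][1]
  out <- matrix(0, sum(keep), n_records * nk)
  ki <- 0L
  for (i in seq_len(ns)) {
    if (!keep[i]) next
    ki <- ki + 1L
    idx <- as.vector(outer(seq_len(spr[i]), (seq_len(n_records) - 1) * total_per_rec,
                           "+") + starts[i])
    out[ki, ] <- raw[idx] * gain[i] + offset[i]
  }
  ch <- sub("^EEG ", "", labels[keep])
  list(data = out, fs = nk / record_dur, channel_names = ch)
}
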