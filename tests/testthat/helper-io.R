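# Fixture writers for the external EEG formats, built in code at test time.

write_brainvision_fixture <- function(dir, data, fs, channel_names,
                                      events = NULL,
                                      format = c("float32", "int16", "ascii")) {
  format <- match.arg(format)
  base <- "fixture"
  data_ext <- if (format == "ascii") "dat" else "eeg"
  vhdr <- file.path(dir, paste0(base, ".vhdr"))
  nch <- nrow(data)
  resolution <- if (format == "int16") 0.1 else 1
  lines <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", base, ".", data_ext),
    if (!is.null(events)) paste0("MarkerFile=", base, ".vmrk"),
    paste0("DataFormat=", if (format == "ascii") "ASCII" else "BINARY"),
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nch),
    paste0("SamplingInterval=", format(1e6 / fs, scientific = FALSE)),
    if (format != "ascii") c("[Binary Infos]",
      paste0("BinaryFormat=",
             if (format == "float32") "IEEE_FLOAT_32" else "INT_16")),
    "[Channel Infos]",
    sprintf("Ch%d=%s,,%s", seq_len(nch), channel_names, resolution)
  )
  writeLines(lines, vhdr)
  dpath <- file.path(dir, paste0(base, ".", data_ext))
  if (format == "ascii") {
    # vectorized: one line per channel
    con <- file(dpath, "w")
    for (i in seq_len(nch))
      writeLines(paste(format(data[i, ], scientific = FALSE), collapse = " "), con)
    close(con)
  } else {
    con <- file(dpath, "wb")
    v <- as.numeric(data) / resolution          # multiplexed: channel-fastest
    if (format == "float32") writeBin(v, con, size = 4, endian = "little")
    else writeBin(as.integer(round(v)), con, size = 2, endian = "little")
    close(con)
  }
  if (!is.null(events)) {
    ml <- c("Brain Vision Data Exchange Marker File, Version 1.0",
            "[Marker Infos]",
            sprintf("Mk%d=Stimulus,%s,%d,1,0", seq_len(nrow(events)),
                    events$condition, events$sample))
    writeLines(ml, file.path(dir, paste0(base, ".vmrk")))
  }
  vhdr
}

write_edf_fixture <- function(path, data, fs, channel_names,
                              phys_range = c(-500, 500)) {
  nch <- nrow(data)
  spr <- as.integer(fs)                 # 1-second records
  n_rec <- ncol(data) %/% spr
  pad <- function(s, w) formatC(as.character(s), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeBin(charToRaw(pad(s, w)), con)
  wr("0", 8); wr("test patient", 80); wr("test recording", 80)
  wr("01.01.20", 8); wr("00.00.00", 8)
  wr(256 + 256 * nch, 8); wr("", 44); wr(n_rec, 8); wr("1", 8); wr(nch, 4)
  for (ch in channel_names) wr(paste("EEG", ch), 16)
  for (i in seq_len(nch)) wr("AgAgCl electrode", 80)
  for (i in seq_len(nch)) wr("uV", 8)
  for (i in seq_len(nch)) wr(phys_range[1], 8)
  for (i in seq_len(nch)) wr(phys_range[2], 8)
  for (i in seq_len(nch)) wr(-32768, 8)
  for (i in seq_len(nch)) wr(32767, 8)
  for (i in seq_len(nch)) wr("", 80)
  for (i in seq_len(nch)) wr(spr, 8)
  for (i in seq_len(nch)) wr("", 32)
  gain <- (phys_range[2] - phys_range[1]) / (32767 - (-32768))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(nch)) {
      seg <- data[i, ((r - 1) * spr + 1):(r * spr)]
      dig <- as.integer(round((seg - phys_range[1]) / gain + (-32768)))
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  path
}
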