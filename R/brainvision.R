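# BrainVision triplet (.vhdr/.vmrk/.eeg) writer and reader for the dialect
# subset used here: binary multiplexed IEEE_FLOAT_32 (write/read) and INT_16
# with per-channel resolution scaling (read).

#' Write an EEG recording as a BrainVision triplet
#'
#' Produces `<basename>.vhdr` (INI-style header), `<basename>.eeg`
#' (little-endian float32, channel-multiplexed) and `<basename>.vmrk`
#' (markers with 1-based sample positions). At 250 Hz the header's sampling
#' interval is 4000 microseconds.
#'
#' @param recording an [eeg_recording()].
#' @param basename output path without extension.
#' @return `basename`, invisibly.
#' @export
write_brainvision <- function(recording, basename) {
  stopifnot(inherits(recording, "efp_eeg"))
  base <- basename(basename)
  k <- nrow(recording$data)
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "; Written by efpnf",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", k),
    paste0("SamplingInterval=", format(1e6 / recording$rate,
                                       scientific = FALSE)),
    "",
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(k), recording$channel_labels))
  con <- file(paste0(basename, ".vhdr"), open = "wb")
  writeLines(hdr, con, useBytes = TRUE)
  close(con)

  mk <- recording$markers
  mk_lines <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", base, ".eeg"),
    "",
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0,00000000000000000000")
  if (nrow(mk)) {
    pos <- pmax(1L, round((mk$time - recording$t0) * recording$rate) + 1L)
    mk_lines <- c(mk_lines,
                  sprintf("Mk%d=Stimulus,%s,%d,1,0",
                          seq_len(nrow(mk)) + 1L, mk$label, pos))
  }
  con <- file(paste0(basename, ".vmrk"), open = "wb")
  writeLines(mk_lines, con, useBytes = TRUE)
  close(con)

  con <- file(paste0(basename, ".eeg"), open = "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.vector(recording$data), con, size = 4, endian = "little")
  invisible(basename)
}

parse_vhdr_fields <- function(lines) {
  kv <- grep("^[A-Za-z0-9]+=", lines, value = TRUE)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  stats::setNames(as.list(vals), keys)
}

#' Read a BrainVision triplet
#'
#' Inverse of [write_brainvision()] for the supported dialect subset:
#' binary, multiplexed, IEEE_FLOAT_32 or INT_16 (integer data are scaled by
#' the per-channel resolution field). Vectorized/ASCII encodings and other
#' binary formats are rejected with a clear error. Marker positions are
#' 1-based sample indices.
#'
#' @param basename path without extension (a `.vhdr` path is also accepted).
#' @return an [eeg_recording()].
#' @export
read_brainvision <- function(basename) {
  basename <- sub("\\.vhdr$", "", basename)
  vhdr <- paste0(basename, ".vhdr")
  if (!file.exists(vhdr)) stop_param("header not found: ", vhdr)
  lines <- readLines(vhdr, warn = FALSE, encoding = "UTF-8")
  fields <- parse_vhdr_fields(lines)
  if (!identical(fields$DataFormat, "BINARY"))
    stop_param("unsupported DataFormat: ", fields$DataFormat)
  if (!identical(fields$DataOrientation, "MULTIPLEXED"))
    stop_param("unsupported DataOrientation: ", fields$DataOrientation)
  fmt <- fields$BinaryFormat
  if (!fmt %in% c("IEEE_FLOAT_32", "INT_16"))
    stop_param("unsupported BinaryFormat: ", fmt)
  k <- as.integer(fields$NumberOfChannels)
  rate <- 1e6 / as.numeric(fields$SamplingInterval)
  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  ch_parts <- strsplit(sub("^Ch[0-9]+=", "", ch_lines), ",")
  ch_names <- vapply(ch_parts, `[`, character(1), 1)
  resolution <- vapply(ch_parts, function(p) {
    r <- suppressWarnings(as.numeric(p[3]))
    if (is.na(r)) 1 else r
  }, numeric(1))
  if (length(ch_names) != k)
    stop_param("header NumberOfChannels (", k, ") does not match the ",
               length(ch_names), " Ch<n> entries")

  eeg_path <- file.path(dirname(basename),
                        if (!is.null(fields$DataFile)) fields$DataFile
                        else paste0(basename(basename), ".eeg"))
  if (!file.exists(eeg_path)) stop_param("data file not found: ", eeg_path)
  bytes_per <- if (fmt == "IEEE_FLOAT_32") 4L else 2L
  fsize <- file.info(eeg_path)$size
  if (fsize %% (bytes_per * k) != 0)
    stop_param("truncated data file: ", fsize, " bytes is not a whole ",
               "number of ", k, "-channel frames (", bytes_per * k,
               " bytes each)")
  n <- fsize / (bytes_per * k)
  con <- file(eeg_path, open = "rb")
  raw_vals <- if (fmt == "IEEE_FLOAT_32")
    readBin(con, "numeric", n = n * k, size = 4, endian = "little")
  else
    readBin(con, "integer", n = n * k, size = 2, endian = "little",
            signed = TRUE)
  close(con)
  if (length(raw_vals) != n * k)
    stop_param("truncated data file: expected ", n * k, " samples, found ",
               length(raw_vals))
  data <- matrix(raw_vals, nrow = k)
  if (fmt == "INT_16") data <- data * resolution

  vmrk <- paste0(basename, ".vmrk")
  markers <- data.frame(time = numeric(0), label = character(0))
  if (file.exists(vmrk)) {
    ml <- grep("^Mk[0-9]+=", readLines(vmrk, warn = FALSE), value = TRUE)
    parts <- strsplit(sub("^Mk[0-9]+=", "", ml), ",")
    keep <- vapply(parts, function(p) p[1] != "New Segment", logical(1))
    parts <- parts[keep]
    if (length(parts)) {
      markers <- data.frame(
        time = (vapply(parts, function(p) as.numeric(p[3]),
                       numeric(1)) - 1) / rate,
        label = vapply(parts, `[`, character(1), 2),
        stringsAsFactors = FALSE)
    }
  }
  eeg_recording(data, rate = rate, channel_labels = ch_names,
                markers = markers)
}
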