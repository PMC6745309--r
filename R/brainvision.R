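#' @title BrainVision and EDF containers
#' @description
#' Readers and writers for the BrainVision `.vhdr`/`.vmrk`/`.eeg` triplet
#' (16-bit signed integer, multiplexed) and a minimal continuous EDF reader.
#' Stimulation metadata travel in the BrainVision marker description using
#' the convention `S<intensity>/<frequency>/B<block>` with marker type
#' `Stimulus` (or `Sham` for sham pulses), e.g. `S35/0.5/B2` for a pulse at
#' 35% maximal stimulator output inside a 0.5 Hz block. Third-party data
#' using a different scheme must be re-encoded to this convention.
#' @name brainvision
NULL

# Amplifier measurement span: +/- 16.384 mV. One 16-bit LSB = 0.5 uV.
BV_RANGE_UV <- 16384
BV_RESOLUTION_UV <- 2 * BV_RANGE_UV / 65536

stop_format <- function(...) {
  stop(structure(class = c("tepnet_format_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Write a recording as a BrainVision triplet
#'
#' Data are quantized to 16-bit integers at 0.5 uV per bit (the +/-16.384 mV
#' amplifier span), multiplexed, little-endian.
#'
#' @param rec a `tep_recording`.
#' @param header_path output `.vhdr` path; companion `.vmrk` and `.eeg`
#'   files are written next to it.
#' @return `header_path`, invisibly.
#' @export
write_brainvision <- function(rec, header_path) {
  stopifnot(inherits(rec, "tep_recording"))
  base <- sub("\\.vhdr$", "", header_path)
  data_file <- paste0(basename(base), ".eeg")
  marker_file <- paste0(basename(base), ".vmrk")

  nch <- nrow(rec$data)
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", data_file),
    paste0("MarkerFile=", marker_file),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nch),
    paste0("SamplingInterval=", format(1e6 / rec$sampling_rate_hz, digits = 12)),
    "[Binary Infos]",
    "BinaryFormat=INT_16",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,%s,uV", seq_len(nch), rownames(rec$data),
            format(BV_RESOLUTION_UV, digits = 12)))
  writeLines(hdr, header_path)

  ev <- rec$events
  mk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", data_file),
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0,00000000000000000000")
  if (nrow(ev)) {
    pos <- round(ev$onset_time * rec$sampling_rate_hz) + 1
    desc <- sprintf("S%g/%g/B%d", ev$intensity_pct, ev$train_frequency_hz,
                    ev$block_id)
    type <- ifelse(ev$sham, "Sham", "Stimulus")
    mk <- c(mk, sprintf("Mk%d=%s,%s,%d,1,0", seq_len(nrow(ev)) + 1L,
                        type, desc, pos))
  }
  writeLines(mk, paste0(base, ".vmrk"))

  counts <- pmin(pmax(round(rec$data / BV_RESOLUTION_UV), -32768), 32767)
  con <- file(paste0(base, ".eeg"), "wb")
  on.exit(close(con))
  writeBin(as.integer(counts[]), con, size = 2, endian = "little")
  invisible(header_path)
}

# internal: parse "Key=Value" lines of an INI-ish BrainVision section file
bv_parse_ini <- function(lines) {
  kv <- lines[grepl("=", lines, fixed = TRUE) & !grepl("^;", lines)]
  eq <- regexpr("=", kv, fixed = TRUE)
  stats::setNames(substring(kv, eq + 1L), substring(kv, 1L, eq - 1L))
}

#' Read a BrainVision triplet into a [tep_recording()]
#'
#' Voltages are converted to microvolts using each channel's declared
#' resolution; channels are restricted and re-ordered to the montage order.
#' Markers of type `Stimulus`/`Sham` are parsed with the
#' `S<intensity>/<frequency>/B<block>` description convention.
#'
#' @param header_path path to the `.vhdr` header.
#' @param montage `sensor_montage` defining channel selection/order.
#' @param subject_id subject identifier attached to the recording.
#' @return a `tep_recording`.
#' @export
read_brainvision <- function(header_path, montage = default_montage(),
                             subject_id = "subject") {
  if (!file.exists(header_path))
    stop_format("header file not found: ", header_path)
  lines <- readLines(header_path, warn = FALSE)
  kv <- bv_parse_ini(lines)
  dir <- dirname(header_path)
  data_path <- file.path(dir, kv[["DataFile"]])
  marker_path <- file.path(dir, kv[["MarkerFile"]])
  if (!file.exists(data_path))
    stop_format("missing companion data file: ", data_path)
  if (!file.exists(marker_path))
    stop_format("missing companion marker file: ", marker_path)
  if (toupper(kv[["BinaryFormat"]]) != "INT_16")
    stop_format("unsupported binary format: ", kv[["BinaryFormat"]])
  if (toupper(kv[["DataOrientation"]]) != "MULTIPLEXED")
    stop_format("unsupported data orientation")
  nch <- as.integer(kv[["NumberOfChannels"]])
  fs <- 1e6 / as.numeric(kv[["SamplingInterval"]])

  ch_lines <- kv[grepl("^Ch[0-9]+$", names(kv))]
  ch_lines <- ch_lines[order(as.integer(sub("^Ch", "", names(ch_lines))))]
  parts <- strsplit(ch_lines, ",", fixed = TRUE)
  ch_names <- vapply(parts, `[`, "", 1L)
  ch_res <- vapply(parts, function(p)
    if (length(p) >= 3 && nzchar(p[3])) as.numeric(p[3]) else 1, numeric(1))

  nbytes <- file.info(data_path)$size
  n_samp <- as.integer(nbytes / 2 / nch)
  if (n_samp < 1) stop_format("truncated or empty data file: ", data_path)
  con <- file(data_path, "rb")
  raw_counts <- readBin(con, integer(), n = n_samp * nch, size = 2,
                        endian = "little", signed = TRUE)
  close(con)
  if (length(raw_counts) < n_samp * nch)
    stop_format("truncated data file: ", data_path)
  mat <- matrix(raw_counts, nrow = nch) * ch_res
  rownames(mat) <- ch_names

  keep <- match(montage$electrodes, ch_names)
  if (anyNA(keep))
    stop_format("montage electrodes absent from file: ",
                paste(montage$electrodes[is.na(keep)], collapse = ", "))
  mat <- mat[keep, , drop = FALSE]

  events <- bv_read_markers(marker_path, fs)
  if (!nrow(events))
    warning("no stimulation markers found in ", marker_path)
  tep_recording(mat, fs, events, montage, subject_id = subject_id)
}

# internal: parse .vmrk markers into the event table
bv_read_markers <- function(marker_path, fs) {
  lines <- readLines(marker_path, warn = FALSE)
  mk <- lines[grepl("^Mk[0-9]+=", lines)]
  out <- empty_events()
  for (i in seq_along(mk)) {
    body <- sub("^Mk[0-9]+=", "", mk[i])
    p <- strsplit(body, ",", fixed = TRUE)[[1]]
    type <- p[1]
    if (!type %in% c("Stimulus", "Sham")) next
    m <- regmatches(p[2], regexec(
      "^S([0-9.]+)/([0-9.]+)(?:/B([0-9]+))?$", p[2]))[[1]]
    if (length(m) == 0)
      stop_format("marker ", i, " has unparsable description: ", p[2])
    out <- rbind(out, data.frame(
      onset_time = (as.numeric(p[3]) - 1) / fs,
      intensity_pct = as.numeric(m[2]),
      train_frequency_hz = as.numeric(m[3]),
      block_id = if (nzchar(m[4])) as.integer(m[4]) else 1L,
      sham = type == "Sham"))
  }
  out
}

#' Read a continuous EDF file (secondary reader)
#'
#' Minimal EDF support: continuous 16-bit records, physical units taken from
#' the per-signal calibration fields. EDF carries no stimulation metadata,
#' so the event table is empty unless supplied.
#'
#' @param path EDF file path.
#' @param montage `sensor_montage` for channel selection and ordering.
#' @param events optional event data.frame (see [tep_recording()]).
#' @param subject_id subject identifier.
#' @return a `tep_recording`.
#' @export
read_edf <- function(path, montage = default_montage(), events = NULL,
                     subject_id = "subject") {
  if (!file.exists(path)) stop_format("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(rawToChar(readBin(con, raw(), n)))
  version <- rd(8)
  if (version != "0") stop_format("not an EDF file (bad version field)")
  rd(80); rd(80); rd(8); rd(8)           # patient, recording, date, time
  rd(8)                                  # header bytes
  rd(44)                                 # reserved
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  field <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- field(16)
  field(80); field(8)                    # transducer, unit
  pmin_ <- as.numeric(field(8)); pmax_ <- as.numeric(field(8))
  dmin_ <- as.numeric(field(8)); dmax_ <- as.numeric(field(8))
  field(80)                              # prefilter
  spr <- as.integer(field(8))
  field(32)                              # reserved
  if (length(unique(spr)) != 1)
    stop_format("EDF signals with differing sampling rates are unsupported")
  fs <- spr[1] / rec_dur
  gain <- (pmax_ - pmin_) / (dmax_ - dmin_)
  offset <- pmin_ - gain * dmin_
  mat <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    block <- readBin(con, integer(), n = ns * spr[1], size = 2,
                     endian = "little", signed = TRUE)
    if (length(block) < ns * spr[1]) stop_format("truncated EDF record ", r)
    block <- matrix(block, nrow = spr[1])  # one column per signal
    cols <- ((r - 1) * spr[1] + 1):(r * spr[1])
    mat[, cols] <- t(block * rep(gain, each = spr[1]) +
                       rep(offset, each = spr[1]))
  }
  rownames(mat) <- labels
  keep <- match(montage$electrodes, labels)
  if (anyNA(keep))
    stop_format("montage electrodes absent from EDF: ",
                paste(montage$electrodes[is.na(keep)], collapse = ", "))
  mat <- mat[keep, , drop = FALSE]
  if (is.null(events)) events <- empty_events()
  tep_recording(mat, fs, events, montage, subject_id = subject_id)
}

#' Write a recording as a minimal continuous EDF file
#'
#' Export convenience (1-second records, 16-bit). Stimulation events are not
#' representable in plain EDF and are dropped with a warning.
#'
#' @inheritParams write_brainvision
#' @param path output `.edf` path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "tep_recording"))
  if (nrow(rec$events))
    warning("EDF export drops stimulation events; use write_brainvision ",
            "to preserve them")
  fs <- rec$sampling_rate_hz
  if (fs != round(fs)) stop("EDF export requires an integer sampling rate")
  ns <- nrow(rec$data)
  n_rec <- floor(ncol(rec$data) / fs)
  if (n_rec < 1) stop("recording shorter than one EDF record (1 s)")
  pmin_ <- -BV_RANGE_UV; pmax_ <- BV_RANGE_UV
  dmin_ <- -32768; dmax_ <- 32767
  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x) writeChar(x, con, eos = NULL)
  wr(pad("0", 8)); wr(pad("X", 80)); wr(pad("X", 80))
  wr(pad("01.01.00", 8)); wr(pad("00.00.00", 8))
  wr(pad(256 * (1 + ns), 8)); wr(pad("", 44))
  wr(pad(n_rec, 8)); wr(pad("1", 8)); wr(pad(ns, 4))
  wr(paste0(vapply(rownames(rec$data), pad, "", w = 16), collapse = ""))
  wr(strrep(" ", 80 * ns)); wr(paste0(rep(pad("uV", 8), ns), collapse = ""))
  wr(paste0(rep(pad(pmin_, 8), ns), collapse = ""))
  wr(paste0(rep(pad(pmax_, 8), ns), collapse = ""))
  wr(paste0(rep(pad(dmin_, 8), ns), collapse = ""))
  wr(paste0(rep(pad(dmax_, 8), ns), collapse = ""))
  wr(strrep(" ", 80 * ns)); wr(paste0(rep(pad(fs, 8), ns), collapse = ""))
  wr(strrep(" ", 32 * ns))
  gain <- (pmax_ - pmin_) / (dmax_ - dmin_)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    counts <- pmin(pmax(round(t(rec$data[, cols]) / gain), dmin_), dmax_)
    writeBin(as.integer(counts), con, size = 2, endian = "little")
  }
  invisible(path)
}
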