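#' Sensor montage for TEP analysis
#'
#' A `sensor_montage` names the analysis electrodes, their schematic 2-D
#' positions (unit-disk head, x toward the right ear, y toward the nasion),
#' the grouping of electrodes into cortical regions split by hemisphere role
#' relative to the stimulation site, and the stimulated hub electrode.
#'
#' @param electrodes character vector of channel labels.
#' @param positions numeric matrix (n x 2) of planar coordinates, rows named
#'   by electrode.
#' @param groups named list mapping `"<region>.<role>"` (role one of
#'   `"ipsilateral"`, `"contralateral"`) to character vectors of electrodes.
#' @param stim_site label of the stimulated hub electrode.
#' @return An object of class `sensor_montage`.
#' @export
sensor_montage <- function(electrodes, positions, groups, stim_site) {
  stopifnot(is.character(electrodes), !anyDuplicated(electrodes))
  positions <- as.matrix(positions)
  if (nrow(positions) != length(electrodes))
    stop("positions must have one row per electrode")
  rownames(positions) <- electrodes
  missing <- setdiff(unlist(groups), electrodes)
  if (length(missing))
    stop("region group members not in electrode list: ",
         paste(missing, collapse = ", "))
  if (!stim_site %in% electrodes)
    stop("stim_site must be one of the montage electrodes")
  structure(
    list(electrodes = electrodes, positions = positions,
         groups = groups, stim_site = stim_site),
    class = "sensor_montage")
}

#' Fixed ordering of the eight region-role groups
#' @param montage optional `sensor_montage`; defaults to the group names of
#'   [default_montage()].
#' @return character vector of `"<region>.<role>"` keys in canonical order.
#' @export
region_roles <- function(montage = NULL) {
  if (!is.null(montage)) return(names(montage$groups))
  as.vector(outer(c("frontal", "parietal", "temporal", "occipital"),
                  c("ipsilateral", "contralateral"),
                  function(r, h) paste(r, h, sep = ".")))
}

#' Default 20-electrode analysis montage
#'
#' Twenty 10-10 electrodes grouped into frontal, parietal, temporal and
#' occipital regions, each split into ipsilateral and contralateral subsets
#' relative to left-M1 stimulation (hub electrode C3). The temporal
#' ipsilateral list uses FC5 (mirroring contralateral FC6).
#'
#' @return A `sensor_montage` with 20 electrodes and 8 region-role groups.
#' @export
default_montage <- function() {
  path <- system.file("extdata", "montage_1010.tsv", package = "tepnet",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  groups <- lapply(region_roles(), function(key) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    tab$electrode[tab$region == parts[1] & tab$role == parts[2]]
  })
  names(groups) <- region_roles()
  sensor_montage(
    electrodes = tab$electrode,
    positions  = cbind(x = tab$x, y = tab$y),
    groups     = groups,
    stim_site  = "C3")
}

#' @export
print.sensor_montage <- function(x, ...) {
  cat("<sensor_montage>", length(x$electrodes), "electrodes,",
      length(x$groups), "region-role groups, stim site", x$stim_site, "\n")
  invisible(x)
}

#' Average per-channel values over each region-role group
#'
#' Region-role aggregates are defined as the arithmetic mean of the member
#' electrodes' feature values (not the feature of the mean waveform).
#'
#' @param values named numeric vector (names = electrode labels).
#' @param montage a `sensor_montage`.
#' @param na_rm drop missing electrode values before averaging.
#' @return named numeric vector over `region_roles(montage)`.
#' @export
aggregate_by_region <- function(values, montage, na_rm = TRUE) {
  vapply(montage$groups, function(g) {
    v <- values[g]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = na_rm)
  }, numeric(1))
}

# internal: validate stimulation event data.frame
validate_events <- function(events) {
  req <- c("onset_time", "intensity_pct", "train_frequency_hz",
           "block_id", "sham")
  miss <- setdiff(req, names(events))
  if (length(miss))
    stop("events missing columns: ", paste(miss, collapse = ", "))
  if (nrow(events)) {
    if (any(events$intensity_pct < 0 | events$intensity_pct > 100))
      stop("intensity_pct must lie in [0, 100]")
    if (any(events$train_frequency_hz < 0))
      stop("train_frequency_hz must be >= 0")
    if (is.unsorted(events$onset_time, strictly = TRUE))
      stop("event onset times must be strictly increasing")
  }
  events
}

#' Construct a raw TEP recording
#'
#' @param data channels x samples matrix of voltages in microvolts, rows
#'   named by electrode in montage order.
#' @param sampling_rate_hz sampling rate in Hz.
#' @param events data.frame with columns `onset_time` (s), `intensity_pct`
#'   (% of maximal stimulator output), `train_frequency_hz`, `block_id`,
#'   `sham`.
#' @param montage a `sensor_montage`.
#' @param subject_id subject identifier string.
#' @return object of class `tep_recording`.
#' @export
tep_recording <- function(data, sampling_rate_hz, events, montage,
                          subject_id = "subject") {
  stopifnot(is.matrix(data), sampling_rate_hz > 0)
  if (nrow(data) != length(montage$electrodes))
    stop("channel count must equal montage electrode count")
  rownames(data) <- montage$electrodes
  events <- validate_events(events)
  dur <- ncol(data) / sampling_rate_hz
  if (nrow(events) && any(events$onset_time >= dur))
    stop("event onsets must fall before the end of the recording")
  structure(
    list(data = data, sampling_rate_hz = sampling_rate_hz,
         events = events, montage = montage, subject_id = subject_id),
    class = "tep_recording")
}

#' @export
print.tep_recording <- function(x, ...) {
  cat(sprintf("<tep_recording> %s: %d ch x %d samples @ %g Hz, %d events\n",
              x$subject_id, nrow(x$data), ncol(x$data),
              x$sampling_rate_hz, nrow(x$events)))
  invisible(x)
}

# internal: empty event table
empty_events <- function() {
  data.frame(onset_time = numeric(0), intensity_pct = numeric(0),
             train_frequency_hz = numeric(0), block_id = integer(0),
             sham = logical(0))
}
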