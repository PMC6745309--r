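#' @title Subject network profile, classifier and region maps
#' @description
#' Orchestration of preprocessing, feature extraction, connectivity and
#' plasticity into one subject-level physiological network profile; a
#' demonstration sign-rule classifier; and pseudo-color region map
#' rendering.
#' @name profile_map
NULL

#' Default analysis configuration
#'
#' All pipeline parameters with their defaults. Units: ms for windows,
#' Hz for rates and bands, uV for thresholds, % MSO for intensities.
#'
#' @return nested named list of configuration values.
#' @export
default_config <- function() {
  list(
    artifact_window_ms = c(-2, 10),
    band_hz = c(1, 80),
    notch_hz = 50,
    resample_hz = 1000,
    epoch_window_ms = c(-500, 500),
    baseline_ms = c(-300, -50),
    reject = list(amp_uv = 150, flat_uv = 0.1),
    peak_windows = default_peak_windows(),
    q_window_ms = c(15, 300),
    freq_classes = default_freq_classes(),
    stp_baseline_intensity = c(45, 55),
    io_feature = "q",
    min_trials_kept_fraction = 0.5,
    classifier = list(min_regions = 4, threshold = 0))
}

# internal: deep-merge overrides into defaults, rejecting unknown keys
merge_config <- function(defaults, overrides, path = "") {
  if (is.null(overrides)) return(defaults)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "))
  for (k in names(overrides)) {
    if (is.list(defaults[[k]]) && is.list(overrides[[k]]) &&
        !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(defaults[[k]], overrides[[k]],
                                    paste0(path, k, "."))
    } else {
      v <- overrides[[k]]
      defaults[[k]] <- if (is.list(v)) unlist(v) else v
    }
  }
  defaults
}

#' Load an analysis configuration from YAML
#'
#' Values omitted from the file keep their defaults; unknown keys are
#' rejected.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  merge_config(cfg, yaml::read_yaml(path))
}

# internal: FNV-1a hash of the serialized config, for provenance
config_hash <- function(config) {
  bytes <- as.integer(charToRaw(jsonlite::toJSON(config, auto_unbox = TRUE,
                                                 digits = NA)))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Assemble the subject-level physiological network profile
#'
#' Runs artifact removal, filtering, epoching, trial rejection, evoked
#' averaging, peak/slope/charge-transfer extraction, the intensity
#' input/output fit, evoked connectivity and short-term plasticity with
#' the given configuration. Deterministic for identical input and config.
#'
#' @param rec a `tep_recording`.
#' @param config configuration list, see [default_config()].
#' @param group_label optional group label carried into the profile.
#' @return a `tep_profile`: `features` (long data.frame region x role x
#'   feature), `qc` report, `peaks`, `io_curve`, `connectivity` (electrode
#'   and region matrices), `stp`, provenance fields.
#' @export
assemble_profile <- function(rec, config = default_config(),
                             group_label = NA_character_) {
  stopifnot(inherits(rec, "tep_recording"))
  rec <- remove_pulse_artifact(rec, config$artifact_window_ms)
  rec <- filter_recording(rec, config$band_hz, config$notch_hz,
                          config$resample_hz)
  ep <- epoch_and_baseline(rec, config$epoch_window_ms[1],
                           config$epoch_window_ms[2], config$baseline_ms)
  rj <- reject_trials(ep, config$reject[["amp_uv"]],
                      config$reject[["flat_uv"]],
                      config$artifact_window_ms)
  ep <- rj$epochs
  qc <- rj$report
  if (qc$n_trials_kept < config$min_trials_kept_fraction * qc$n_trials_in)
    stop_qc(sprintf("QC failure: only %d/%d trials kept",
                    qc$n_trials_kept, qc$n_trials_in), report = qc)

  fc <- config$freq_classes
  ev_single <- average_evoked(ep, class = "baseline", freq_classes = fc)
  ev_base_matched <- average_evoked(
    ep, class = "baseline", intensity_range = config$stp_baseline_intensity,
    freq_classes = fc)
  has_inhib <- length(select_trials(ep, class = "inhibitory",
                                    freq_classes = fc)) > 0

  peaks <- detect_peaks(ev_single, config$peak_windows)
  slopes <- compute_slopes(peaks, montage = rec$montage)
  q <- compute_charge_transfer(ev_single, config$q_window_ms)
  io <- fit_io_curve(ep, feature = config$io_feature,
                     window_ms = config$q_window_ms, freq_classes = fc)
  conn_e <- evoked_connectivity(ev_single, config$q_window_ms)
  conn_r <- region_aggregate(conn_e, rec$montage)

  stp <- NULL
  if (has_inhib) {
    ev_inhib <- average_evoked(ep, class = "inhibitory", freq_classes = fc)
    stp <- compute_stp(ev_base_matched, ev_inhib, config$q_window_ms,
                       config$peak_windows)
  }

  keys <- region_roles(rec$montage)
  by_region <- attr(slopes, "by_region")
  q_region <- aggregate_by_region(
    stats::setNames(q$q_uv_ms, q$channel), rec$montage)
  feat <- data.frame(
    region = rep(sub("\\..*$", "", keys), times = 7),
    role = rep(sub("^.*\\.", "", keys), times = 7),
    feature = rep(c("early_slope", "late_slope", "slope_ratio", "q",
                    "stp_q", "stp_slope_late", "stp_ratio"),
                  each = length(keys)),
    value = c(by_region[, "early_slope"], by_region[, "late_slope"],
              by_region[, "slope_ratio"], q_region,
              if (is.null(stp)) rep(NA_real_, 3 * length(keys)) else
                c(stp$by_region[, "stp_q"],
                  stp$by_region[, "stp_slope_late"],
                  stp$by_region[, "stp_ratio"])))
  feat$flag <- ifelse(is.na(feat$value),
                      if (is.null(stp)) "no inhibitory trials"
                      else "not computable", "")

  structure(
    list(subject_id = rec$subject_id, group_label = group_label,
         features = feat, qc = qc, peaks = peaks, io_curve = io,
         connectivity = list(electrode = conn_e, region = conn_r),
         stp = stp, config_hash = config_hash(config),
         version = as.character(utils::packageVersion("tepnet"))),
    class = "tep_profile")
}

#' @export
print.tep_profile <- function(x, ...) {
  cat(sprintf("<tep_profile> %s: %d feature values, QC %d/%d trials\n",
              x$subject_id, nrow(x$features), x$qc$n_trials_kept,
              x$qc$n_trials_in))
  invisible(x)
}

#' Demonstration sign-rule classifier
#'
#' Labels a profile `"abnormal"` iff the median over region-roles of the
#' late-slope STP sign exceeds the threshold (positive late-slope STP,
#' i.e. the modulation reversal). A minimal formalization of a binary
#' step-function observation — a demonstration rule, not a clinical
#' device.
#'
#' @param p a `tep_profile`.
#' @param min_regions minimum region-roles with a defined sign.
#' @param threshold median-sign threshold, default 0.
#' @return list with `label` (`"normal"`, `"abnormal"`, or
#'   `"indeterminate"`), `median_sign` and per-region `evidence`.
#' @export
classify_profile <- function(p, min_regions = 4, threshold = 0) {
  stopifnot(inherits(p, "tep_profile"))
  f <- p$features
  v <- f$value[f$feature == "stp_slope_late"]
  names(v) <- paste(f$region, f$role, sep = ".")[f$feature ==
                                                   "stp_slope_late"]
  s <- sign(v)
  s[!is.na(v) & abs(v) < 1e-6] <- 0
  n_ok <- sum(!is.na(s))
  if (n_ok < min_regions)
    return(list(label = "indeterminate", median_sign = NA_real_,
                evidence = s))
  med <- stats::median(s, na.rm = TRUE)
  list(label = if (med > threshold) "abnormal" else "normal",
       median_sign = med, evidence = s)
}

#' Colormap lookup table
#'
#' Fixed diverging table: low values map to red, high values to blue
#' (the connectivity-map orientation).
#'
#' @param name colormap name; only `"red-blue"` is defined.
#' @param n number of entries.
#' @return character vector of hex colors.
#' @export
colormap_table <- function(name = "red-blue", n = 256) {
  if (name != "red-blue") stop("unknown colormap: ", name)
  grDevices::colorRampPalette(c("#B2182B", "#F7F7F7", "#2166AC"))(n)
}

#' Region-value map for one profile feature
#'
#' @param p a `tep_profile`.
#' @param feature feature name present in the profile.
#' @param scale `(min, max)` color scale; defaults to a fixed per-feature
#'   scale so images are comparable across subjects.
#' @return a `region_value_map` list (`values`, `scale`, `colormap`,
#'   `title`, `clipped` flags).
#' @export
region_value_map <- function(p, feature = "slope_ratio", scale = NULL) {
  f <- p$features[p$features$feature == feature, ]
  if (!nrow(f)) stop("feature not present in profile: ", feature)
  values <- stats::setNames(f$value, paste(f$region, f$role, sep = "."))
  fixed <- list(slope_ratio = c(-2, 0), stp_ratio = c(-3, 3),
                q = c(0, 800), stp_q = c(0, 2), stp_slope_late = c(-2, 2),
                early_slope = c(-0.5, 0), late_slope = c(0, 0.5))
  scale <- scale %||% fixed[[feature]] %||% range(values, na.rm = TRUE)
  clipped <- !is.na(values) & (values < scale[1] | values > scale[2])
  structure(list(values = values, scale = scale, colormap = "red-blue",
                 title = paste(p$subject_id, feature),
                 clipped = clipped),
            class = "region_value_map")
}

#' Render a region-value map as a pseudo-color PNG
#'
#' Writes a schematic head (unit disk) with one filled patch per
#' region-role, colored by linear lookup of the value in the fixed
#' colormap; deterministic bytes for fixed input. A sidecar JSON
#' (`<path>.json`) records the value-to-color assignment.
#'
#' @param m a `region_value_map`.
#' @param out_path output PNG path.
#' @param montage a `sensor_montage` giving patch positions.
#' @param size image size in pixels.
#' @return `out_path`, invisibly.
#' @export
render_region_map <- function(m, out_path, montage = default_montage(),
                              size = 256) {
  stopifnot(inherits(m, "region_value_map"))
  cmap <- colormap_table(m$colormap)
  lookup_index <- function(v) {
    if (is.na(v)) return(NA_integer_)
    u <- (v - m$scale[1]) / (m$scale[2] - m$scale[1])
    u <- min(1, max(0, u))
    as.integer(round(u * (length(cmap) - 1))) + 1L
  }
  idx <- vapply(m$values, lookup_index, integer(1))
  colors <- ifelse(is.na(idx), "#BBBBBB", cmap[idx])

  # raster canvas: white background, grey head outline, region patches
  img <- array(1, dim = c(size, size, 3))
  xs <- (col(matrix(0, size, size)) - size / 2) / (size / 2 * 0.95)
  ys <- -(row(matrix(0, size, size)) - size / 2) / (size / 2 * 0.95)
  rim <- abs(sqrt(xs^2 + ys^2) - 1) < 0.02
  for (k in 1:3) img[, , k][rim] <- 0.4

  centers <- t(vapply(montage$groups, function(g)
    colMeans(montage$positions[g, , drop = FALSE]), numeric(2)))
  radius <- 0.16
  for (i in seq_along(m$values)) {
    rgbv <- grDevices::col2rgb(colors[i]) / 255
    inside <- (xs - centers[i, 1])^2 + (ys - centers[i, 2])^2 < radius^2
    for (k in 1:3) img[, , k][inside] <- rgbv[k]
  }
  png::writePNG(img, out_path)
  sidecar <- list(title = m$title, colormap = m$colormap,
                  scale = m$scale,
                  values = as.list(m$values),
                  colors = as.list(stats::setNames(colors,
                                                   names(m$values))),
                  clipped = as.list(m$clipped))
  jsonlite::write_json(sidecar, paste0(out_path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_path)
}

#' Write profiles as one tidy feature table
#'
#' One row per subject x region x hemisphere-role x feature, columns
#' `(subject_id, group_label, region, role, feature, value)`. Values are
#' printed with 17 significant digits so a read-back reproduces them
#' exactly.
#'
#' @param profiles list of `tep_profile` objects sharing a feature schema.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(profiles, path) {
  header <- "subject_id,group_label,region,role,feature,value"
  if (!length(profiles)) {
    writeLines(header, path)
    return(invisible(path))
  }
  schema <- function(p) paste(p$features$region, p$features$role,
                              p$features$feature, collapse = ";")
  ref <- schema(profiles[[1]])
  for (p in profiles)
    if (!identical(schema(p), ref))
      stop("inconsistent feature schema for subject ", p$subject_id)
  rows <- lapply(profiles, function(p) {
    f <- p$features
    sprintf("%s,%s,%s,%s,%s,%s", p$subject_id,
            ifelse(is.na(p$group_label), "", p$group_label),
            f$region, f$role, f$feature,
            ifelse(is.na(f$value), "NA", sprintf("%.17g", f$value)))
  })
  writeLines(c(header, unlist(rows)), path)
  invisible(path)
}

#' Read back a feature table written by [write_feature_table()]
#' @param path CSV path.
#' @return data.frame with a numeric `value` column.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(value = "character"))
  df$value <- as.numeric(df$value)
  df
}

#' Serialize a profile to JSON (with peak provenance)
#' @param p a `tep_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile_json <- function(p, path) {
  out <- list(
    schema_version = 1L,
    subject_id = p$subject_id, group_label = p$group_label,
    version = p$version, config_hash = p$config_hash,
    features = p$features,
    peaks = p$peaks,
    io_curve = if (p$io_curve$fitted)
      c(as.list(p$io_curve$params),
        list(residual_rms = p$io_curve$residual_rms)) else NULL,
    qc = unclass(p$qc))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}
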