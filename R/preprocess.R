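#' @title Preprocessing: artifact removal, filtering, epoching, rejection
#' @description
#' Cleaning of raw TEP recordings: replacement of the TMS pulse transient by
#' cubic interpolation, zero-phase band-pass/notch filtering with
#' resampling, epoching around pulses with baseline correction, and
#' amplitude/flatline trial rejection. All windows use the millisecond time
#' convention with the pulse at 0 and half-open intervals `[start, end)`.
#' @name preprocess
NULL

stop_qc <- function(msg, report = NULL) {
  stop(structure(class = c("tepnet_qc_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), report = report)))
}

#' Replace the TMS pulse transient by cubic interpolation
#'
#' Samples inside `window_ms` around every stimulation event are replaced by
#' a natural cubic spline fitted through short flanking segments; samples
#' outside all windows are untouched. Windows whose inter-pulse interval is
#' shorter than the window length are merged with a warning.
#'
#' @param rec a `tep_recording`.
#' @param window_ms `(pre, post)` window in ms relative to the pulse;
#'   must contain 0. Default `c(-2, 10)`.
#' @param n_flank number of anchor samples on each side of the window.
#' @return the recording with interpolated pulse windows.
#' @export
remove_pulse_artifact <- function(rec, window_ms = c(-2, 10), n_flank = 5L) {
  stopifnot(inherits(rec, "tep_recording"),
            window_ms[1] <= 0, window_ms[2] >= 0)
  if (!nrow(rec$events)) return(rec)
  fs <- rec$sampling_rate_hz
  n <- ncol(rec$data)
  onset <- round(rec$events$onset_time * fs) + 1L
  lo <- pmax(onset + floor(window_ms[1] / 1000 * fs), 1L)
  hi <- pmin(onset + ceiling(window_ms[2] / 1000 * fs), n)

  # merge overlapping windows
  ord <- order(lo)
  lo <- lo[ord]; hi <- hi[ord]
  m_lo <- lo[1]; m_hi <- hi[1]; merged <- FALSE
  out_lo <- integer(0); out_hi <- integer(0)
  for (i in seq_along(lo)[-1]) {
    if (lo[i] <= m_hi + 1L) {
      m_hi <- max(m_hi, hi[i]); merged <- TRUE
    } else {
      out_lo <- c(out_lo, m_lo); out_hi <- c(out_hi, m_hi)
      m_lo <- lo[i]; m_hi <- hi[i]
    }
  }
  out_lo <- c(out_lo, m_lo); out_hi <- c(out_hi, m_hi)
  if (merged)
    warning("overlapping pulse-artifact windows merged ",
            "(inter-pulse interval shorter than window)")

  dat <- rec$data
  for (w in seq_along(out_lo)) {
    inside <- out_lo[w]:out_hi[w]
    left <- max(out_lo[w] - n_flank, 1L):max(out_lo[w] - 1L, 1L)
    right <- min(out_hi[w] + 1L, n):min(out_hi[w] + n_flank, n)
    anchors <- unique(setdiff(c(left, right), inside))
    if (length(anchors) < 2) next
    for (ch in seq_len(nrow(dat))) {
      dat[ch, inside] <- stats::spline(anchors, dat[ch, anchors],
                                       xout = inside,
                                       method = "natural")$y
    }
  }
  rec$data <- dat
  rec
}

#' Zero-phase band-pass + notch filtering with resampling
#'
#' Applies a zero-phase (forward-backward Butterworth) low-pass at the band
#' top, resamples, then applies zero-phase high-pass and band-stop notch at
#' the target rate. Event onsets are carried in seconds and therefore remap
#' automatically.
#'
#' @param rec a `tep_recording`.
#' @param band_hz `(low, high)` pass band in Hz; default `c(1, 80)`.
#' @param notch_hz line frequency to suppress (Hz), `NULL` to skip;
#'   default 50.
#' @param resample_hz target sampling rate; default 1000.
#' @param notch_halfwidth_hz half width of the band-stop notch.
#' @return filtered, resampled `tep_recording`.
#' @export
filter_recording <- function(rec, band_hz = c(1, 80), notch_hz = 50,
                             resample_hz = 1000, notch_halfwidth_hz = 2) {
  stopifnot(inherits(rec, "tep_recording"))
  fs <- rec$sampling_rate_hz
  if (!(band_hz[1] > 0 && band_hz[1] < band_hz[2]))
    stop("band_hz must satisfy 0 < low < high")
  if (band_hz[2] >= resample_hz / 2)
    stop("band top must lie below the Nyquist frequency of the ",
         "resampled rate")

  apply_filtfilt <- function(mat, flt) {
    t(apply(mat, 1, function(x) signal::filtfilt(flt, x)))
  }

  dat <- rec$data
  lp <- signal::butter(4, band_hz[2] / (fs / 2), type = "low")
  dat <- apply_filtfilt(dat, lp)

  if (resample_hz != fs) {
    if (fs %% resample_hz == 0) {
      k <- fs / resample_hz
      dat <- dat[, seq(1, ncol(dat), by = k), drop = FALSE]
    } else {
      if (fs != round(fs) || resample_hz != round(resample_hz))
        stop("non-integer sampling rates are only supported when the ",
             "original rate is an integer multiple of the target rate")
      g <- function(a, b) if (b == 0) a else g(b, a %% b)
      d <- g(as.integer(resample_hz), as.integer(fs))
      dat <- t(apply(dat, 1, function(x)
        signal::resample(x, resample_hz / d, fs / d)))
    }
    fs <- resample_hz
  }

  hp <- signal::butter(2, band_hz[1] / (fs / 2), type = "high")
  dat <- apply_filtfilt(dat, hp)
  if (!is.null(notch_hz) && notch_hz < fs / 2) {
    bs <- signal::butter(2, c(notch_hz - notch_halfwidth_hz,
                              notch_hz + notch_halfwidth_hz) / (fs / 2),
                         type = "stop")
    dat <- apply_filtfilt(dat, bs)
  }
  rownames(dat) <- rownames(rec$data)
  rec$data <- dat
  rec$sampling_rate_hz <- fs
  rec
}

#' Sample index of each stimulation event
#'
#' @param rec a `tep_recording`.
#' @param one_based return 1-based R indices (default) or 0-based.
#' @return integer vector of sample indices at the recording's rate.
#' @export
event_sample_index <- function(rec, one_based = TRUE) {
  idx <- round(rec$events$onset_time * rec$sampling_rate_hz)
  as.integer(idx + as.integer(one_based))
}

#' Epoch a recording around stimulation pulses with baseline correction
#'
#' One trial per event; per-trial, per-channel mean over the baseline window
#' is subtracted. Events whose epoch would cross a recording edge are
#' dropped and recorded in the `dropped_events` field.
#'
#' @param rec a `tep_recording`.
#' @param tmin_ms,tmax_ms epoch window in ms relative to the pulse
#'   (half-open `[tmin, tmax)`).
#' @param baseline_ms baseline window `(start, end)` in ms.
#' @return a `tep_epochs` object: `data` is a trials x channels x time
#'   array (uV), `times_ms` the epoch time axis, `trial_meta` the per-trial
#'   event metadata.
#' @export
epoch_and_baseline <- function(rec, tmin_ms = -500, tmax_ms = 500,
                               baseline_ms = c(-300, -50)) {
  stopifnot(inherits(rec, "tep_recording"), tmin_ms < 0, tmax_ms > 0)
  fs <- rec$sampling_rate_hz
  n <- ncol(rec$data)
  n_pre <- round(-tmin_ms / 1000 * fs)
  n_post <- round(tmax_ms / 1000 * fs)
  times_ms <- (seq_len(n_pre + n_post) - 1 - n_pre) * 1000 / fs

  onset <- round(rec$events$onset_time * fs) + 1L
  first <- onset - n_pre
  last <- onset + n_post - 1L
  ok <- first >= 1L & last <= n
  dropped <- which(!ok)
  keep <- which(ok)
  if (!length(keep)) stop_qc("no event epoch fits inside the recording")

  nch <- nrow(rec$data)
  ntime <- n_pre + n_post
  arr <- array(0, dim = c(length(keep), nch, ntime))
  for (i in seq_along(keep)) {
    arr[i, , ] <- rec$data[, first[keep[i]]:last[keep[i]]]
  }
  ep <- structure(
    list(data = arr, times_ms = times_ms,
         trial_meta = rec$events[keep, , drop = FALSE],
         baseline_ms = baseline_ms, montage = rec$montage,
         dropped_events = dropped, subject_id = rec$subject_id),
    class = "tep_epochs")
  baseline_correct(ep)
}

# internal: subtract per-trial per-channel baseline mean
baseline_correct <- function(ep) {
  bl <- ep$times_ms >= ep$baseline_ms[1] & ep$times_ms < ep$baseline_ms[2]
  if (!any(bl)) stop("baseline window contains no samples")
  mu <- apply(ep$data[, , bl, drop = FALSE], c(1, 2), mean)
  ep$data <- ep$data - as.vector(mu)  # recycles over the time dimension
  ep
}

#' @export
print.tep_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<tep_epochs> %d trials x %d ch x %d samples (%g..%g ms)\n",
              d[1], d[2], d[3], min(x$times_ms), max(x$times_ms)))
  invisible(x)
}

#' Reject trials by amplitude and flatline criteria
#'
#' A trial is rejected if any sample outside the pulse-artifact window
#' exceeds `amp_thresh_uv` in absolute value, or if any channel's
#' peak-to-peak amplitude falls below `flat_thresh_uv`.
#'
#' @param ep a `tep_epochs` object.
#' @param amp_thresh_uv absolute amplitude threshold (uV), default 150.
#' @param flat_thresh_uv minimum peak-to-peak amplitude (uV), default 0.1.
#' @param artifact_window_ms window excluded from the amplitude check.
#' @return `list(epochs =, report =)` with the cleaned `tep_epochs` and a
#'   `qc_report` (fields `n_trials_in`, `n_trials_kept`, `rejected_indices`,
#'   `channel_noise_rms_uv`, `flags`).
#' @export
reject_trials <- function(ep, amp_thresh_uv = 150, flat_thresh_uv = 0.1,
                          artifact_window_ms = c(-2, 10)) {
  stopifnot(inherits(ep, "tep_epochs"),
            amp_thresh_uv > 0, flat_thresh_uv > 0)
  tt <- ep$times_ms
  mask <- tt < artifact_window_ms[1] | tt >= artifact_window_ms[2]
  n_in <- dim(ep$data)[1]
  bad <- logical(n_in)
  for (i in seq_len(n_in)) {
    x <- ep$data[i, , mask, drop = TRUE]
    ptp <- apply(x, 1, function(v) diff(range(v)))
    bad[i] <- any(abs(x) > amp_thresh_uv) || any(ptp < flat_thresh_uv)
  }
  if (all(bad))
    stop_qc(paste0("all ", n_in, " trials rejected; review the amplitude/",
                   "flatline thresholds"))
  keep <- which(!bad)
  kept <- ep
  kept$data <- ep$data[keep, , , drop = FALSE]
  kept$trial_meta <- ep$trial_meta[keep, , drop = FALSE]

  bl <- tt >= ep$baseline_ms[1] & tt < ep$baseline_ms[2]
  noise <- apply(kept$data[, , bl, drop = FALSE], 2,
                 function(x) sqrt(mean(x^2)))
  names(noise) <- ep$montage$electrodes
  flags <- character(0)
  if (length(ep$dropped_events))
    flags <- c(flags, sprintf("%d event(s) dropped at recording edges",
                              length(ep$dropped_events)))
  if (any(bad))
    flags <- c(flags, sprintf("%d trial(s) rejected", sum(bad)))
  report <- structure(
    list(n_trials_in = n_in, n_trials_kept = length(keep),
         rejected_indices = which(bad), channel_noise_rms_uv = noise,
         flags = flags),
    class = "qc_report")
  list(epochs = kept, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d/%d trials kept", x$n_trials_kept,
              x$n_trials_in))
  if (length(x$flags)) cat("; ", paste(x$flags, collapse = "; "), sep = "")
  cat("\n")
  invisible(x)
}

#' Serialize a QC report to JSON
#' @param report a `qc_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Select trials by protocol class, intensity and sham status
#'
#' @param ep a `tep_epochs` object.
#' @param class protocol class (`"baseline"`, `"inhibitory"`,
#'   `"excitatory"`) or `NULL` for all.
#' @param intensity_range `(lo, hi)` % MSO closed interval or `NULL`.
#' @param sham logical filter or `NULL`.
#' @param freq_classes frequency class boundaries, see
#'   [classify_trials_by_protocol()].
#' @return integer vector of trial indices.
#' @export
select_trials <- function(ep, class = NULL, intensity_range = NULL,
                          sham = NULL, freq_classes = default_freq_classes()) {
  meta <- ep$trial_meta
  keep <- rep(TRUE, nrow(meta))
  if (!is.null(class)) {
    cls <- classify_trials_by_protocol(ep, freq_classes)$class
    keep <- keep & cls == class
  }
  if (!is.null(intensity_range))
    keep <- keep & meta$intensity_pct >= intensity_range[1] &
      meta$intensity_pct <= intensity_range[2]
  if (!is.null(sham)) keep <- keep & meta$sham == sham
  which(keep)
}

#' Average selected trials into an evoked response
#'
#' @inheritParams select_trials
#' @return a `tep_evoked` object (`data`: channels x time uV matrix,
#'   `times_ms`, `n_trials`, `condition`).
#' @export
average_evoked <- function(ep, class = NULL, intensity_range = NULL,
                           sham = NULL,
                           freq_classes = default_freq_classes()) {
  idx <- select_trials(ep, class, intensity_range, sham, freq_classes)
  if (!length(idx))
    stop("no trials match selector (class=", class %||% "any",
         ", intensity=", paste(intensity_range %||% "any", collapse = "-"),
         ")")
  dat <- ep$data[idx, , , drop = FALSE]
  m <- apply(dat, c(2, 3), mean)
  rownames(m) <- ep$montage$electrodes
  structure(
    list(data = m, times_ms = ep$times_ms, n_trials = length(idx),
         condition = list(class = class, intensity_range = intensity_range,
                          sham = sham),
         montage = ep$montage, subject_id = ep$subject_id),
    class = "tep_evoked")
}

#' @export
print.tep_evoked <- function(x, ...) {
  cat(sprintf("<tep_evoked> %d ch x %d samples, n_trials=%d (%s)\n",
              nrow(x$data), ncol(x$data), x$n_trials,
              x$condition$class %||% "all"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
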