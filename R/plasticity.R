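#' @title Short-term plasticity (frequency-dependent modulation)
#' @description
#' History dependence of the evoked response: ratios of charge transfer and
#' late (N100-P180) slope between a frequency-patterned stimulation
#' protocol and the single-pulse baseline. A value of 1 means no
#' modulation; negative late-slope ratios indicate a reversal of the late
#' segment under the protocol.
#' @name plasticity
NULL

#' Default frequency class boundaries (Hz)
#'
#' Baseline (single pulse): `[0, 0.5]`; inhibitory trains: `[1, 5]`;
#' excitatory trains: `[20, Inf)`. Closed intervals; a 0.5 Hz trial is
#' baseline. Trials outside all classes are labelled `"other"`.
#'
#' @return named list of `(lo, hi)` frequency intervals.
#' @export
default_freq_classes <- function() {
  list(baseline = c(0, 0.5), inhibitory = c(1, 5), excitatory = c(20, Inf))
}

#' Partition trials into protocol classes by train frequency
#'
#' @param ep a `tep_epochs` object (or its `trial_meta` data.frame).
#' @param freq_classes class boundaries, see [default_freq_classes()].
#' @return list with `class` (character per trial), `counts` (per class)
#'   and `n_other` (trials in no class, excluded from analysis).
#' @export
classify_trials_by_protocol <- function(ep,
                                        freq_classes =
                                          default_freq_classes()) {
  meta <- if (inherits(ep, "tep_epochs")) ep$trial_meta else ep
  f <- meta$train_frequency_hz
  cls <- rep("other", length(f))
  for (name in names(freq_classes)) {
    b <- freq_classes[[name]]
    cls[cls == "other" & f >= b[1] & f <= b[2]] <- name
  }
  counts <- table(factor(cls, levels = c(names(freq_classes), "other")))
  list(class = cls, counts = counts, n_other = sum(cls == "other"))
}

#' Short-term plasticity ratios between protocol and baseline evoked
#'
#' Per channel: `stp_q` = Q_protocol / Q_baseline, `stp_slope_late` =
#' late-slope_protocol / late-slope_baseline, and `stp_ratio` =
#' `stp_q / stp_slope_late`. The protocol response's peaks are located
#' sign-agnostically (largest-magnitude local extremum per window, see
#' [detect_peaks()]), because a modulated protocol response can genuinely
#' reverse the late segment's polarity — that reversal is the feature of
#' interest, not a detection failure. Channels whose baseline Q or late
#' slope is zero are reported missing.
#'
#' @param baseline_ev single-pulse baseline `tep_evoked`.
#' @param protocol_ev protocol-class `tep_evoked` (same time axis and
#'   montage).
#' @param window_ms charge-transfer window, default `c(15, 300)` ms.
#' @param peak_windows component search windows.
#' @param allow_unfound use window extrema for unfound components when
#'   computing the late slope (default `TRUE`, see Details).
#' @return an `stp_profile`: `by_channel` data.frame (`channel`, `stp_q`,
#'   `stp_slope_late`, `stp_ratio`), `by_region` matrix over region-roles,
#'   and `protocol_class`.
#' @export
compute_stp <- function(baseline_ev, protocol_ev, window_ms = c(15, 300),
                        peak_windows = default_peak_windows(),
                        allow_unfound = TRUE) {
  stopifnot(inherits(baseline_ev, "tep_evoked"),
            inherits(protocol_ev, "tep_evoked"))
  if (!isTRUE(all.equal(baseline_ev$times_ms, protocol_ev$times_ms)))
    stop("baseline and protocol evoked responses must share a time axis")
  if (!identical(rownames(baseline_ev$data), rownames(protocol_ev$data)))
    stop("baseline and protocol evoked responses must share channels")

  q_b <- compute_charge_transfer(baseline_ev, window_ms)
  q_p <- compute_charge_transfer(protocol_ev, window_ms)
  pol <- if (allow_unfound) "agnostic" else "signed"
  sl_b <- compute_slopes(detect_peaks(baseline_ev, peak_windows),
                         allow_unfound = allow_unfound)
  sl_p <- compute_slopes(detect_peaks(protocol_ev, peak_windows,
                                      polarity = pol),
                         allow_unfound = allow_unfound)

  stp_q <- ifelse(q_b$q_uv_ms > 0, q_p$q_uv_ms / q_b$q_uv_ms, NA)
  stp_slope <- ifelse(!is.na(sl_b$late_slope) & sl_b$late_slope != 0 &
                        !is.na(sl_p$late_slope),
                      sl_p$late_slope / sl_b$late_slope, NA)
  stp_ratio <- ifelse(!is.na(stp_slope) & abs(stp_slope) > 0,
                      stp_q / stp_slope, NA)
  by_channel <- data.frame(channel = q_b$channel, stp_q = stp_q,
                           stp_slope_late = stp_slope,
                           stp_ratio = stp_ratio)
  montage <- baseline_ev$montage
  by_region <- vapply(
    c("stp_q", "stp_slope_late", "stp_ratio"),
    function(f) aggregate_by_region(
      stats::setNames(by_channel[[f]], by_channel$channel), montage),
    numeric(length(montage$groups)))
  structure(
    list(by_channel = by_channel, by_region = by_region,
         protocol_class = protocol_ev$condition$class %||% "protocol",
         n_trials = c(baseline = baseline_ev$n_trials,
                      protocol = protocol_ev$n_trials)),
    class = "stp_profile")
}

#' @export
print.stp_profile <- function(x, ...) {
  cat(sprintf("<stp_profile> protocol=%s, median stp_q=%.3f, median stp_slope_late=%.3f\n",
              x$protocol_class,
              stats::median(x$by_channel$stp_q, na.rm = TRUE),
              stats::median(x$by_channel$stp_slope_late, na.rm = TRUE)))
  invisible(x)
}

#' Sign of the late-slope STP ratio per region-role
#'
#' @param profile an `stp_profile`.
#' @param tol magnitudes below `tol` map to 0.
#' @return named integer vector in `{-1, 0, +1}` (NA propagates).
#' @export
stp_sign_feature <- function(profile, tol = 1e-6) {
  v <- profile$by_region[, "stp_slope_late"]
  s <- sign(v)
  s[!is.na(v) & abs(v) < tol] <- 0
  s
}
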