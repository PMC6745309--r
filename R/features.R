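#' @title Single-pulse evoked features
#' @description
#' Extraction of the canonical TEP components (N45, P60, N100, P180), the
#' early (P60-N100) and late (N100-P180) slopes and their ratio, the
#' charge transfer Q (rectified area of the evoked response), and the
#' stimulation-intensity input/output recruitment curve.
#' @name evoked_features
NULL

#' Default TEP component search windows (ms)
#' @return named list of `(start, end)` windows, half-open.
#' @export
default_peak_windows <- function() {
  list(N45 = c(30, 57), P60 = c(50, 80), N100 = c(80, 140),
       P180 = c(140, 250))
}

# internal: component polarity from its name (N = negative, P = positive)
component_sign <- function(component) {
  ifelse(substr(component, 1, 1) == "N", -1, 1)
}

#' Detect TEP component peaks on an evoked response
#'
#' Per channel and component, the sign-constrained local extremum of
#' largest magnitude inside the component's search window. When no
#' sign-consistent local extremum exists, `found` is `FALSE` and the
#' reported value is the window extremum in the component's direction.
#' A detected extremum must additionally exceed `snr_threshold` times the
#' channel's pre-stimulus RMS (when the time axis contains pre-stimulus
#' samples) to count as found, so near-floor responses (e.g. sham) are
#' flagged rather than mistaken for components.
#'
#' @param ev a `tep_evoked` object.
#' @param windows named list of search windows in ms (half-open); see
#'   [default_peak_windows()].
#' @param polarity `"signed"` (default) constrains each component to its
#'   canonical polarity; `"agnostic"` takes the local extremum of largest
#'   magnitude regardless of sign — used for protocol responses whose
#'   components may genuinely reverse polarity under modulation.
#' @param snr_threshold multiple of the pre-stimulus RMS an extremum must
#'   exceed to be `found`; default 3.
#' @return a `peak_set` data.frame with columns `channel`, `component`,
#'   `latency_ms`, `amplitude_uv`, `found`, `window_lo`, `window_hi`.
#' @export
detect_peaks <- function(ev, windows = default_peak_windows(),
                         polarity = c("signed", "agnostic"),
                         snr_threshold = 3) {
  polarity <- match.arg(polarity)
  stopifnot(inherits(ev, "tep_evoked"))
  tt <- ev$times_ms
  for (w in windows)
    if (w[1] < min(tt) || w[2] > max(tt) + 1e-9)
      stop("peak window [", w[1], ", ", w[2],
           ") lies outside the evoked time axis")
  channels <- rownames(ev$data)
  pre <- tt < 0
  rows <- vector("list", length(channels) * length(windows))
  k <- 0
  for (ch in seq_along(channels)) {
    y <- ev$data[ch, ]
    floor_uv <- if (any(pre)) snr_threshold * sqrt(mean(y[pre]^2)) else 0
    for (comp in names(windows)) {
      w <- windows[[comp]]
      s <- component_sign(comp)
      idx <- which(tt >= w[1] & tt < w[2])
      ys <- s * y  # flip so we always search for a maximum
      # local extrema of the trace, evaluated against full-axis
      # neighbours so window-edge samples are treated fairly
      loc_max <- function(v) {
        prev <- ifelse(idx - 1 >= 1, v[pmax(idx - 1, 1)], -Inf)
        nxt <- ifelse(idx + 1 <= length(v),
                      v[pmin(idx + 1, length(v))], -Inf)
        v[idx] >= prev & v[idx] >= nxt & v[idx] > 0
      }
      if (polarity == "agnostic") {
        is_max <- loc_max(ys) | loc_max(-ys)
        ys <- abs(ys)
      } else {
        is_max <- loc_max(ys)
      }
      is_max <- is_max & ys[idx] > floor_uv
      k <- k + 1
      if (any(is_max)) {
        cand <- idx[is_max]
        best <- cand[which.max(ys[cand])]
        rows[[k]] <- data.frame(
          channel = channels[ch], component = comp,
          latency_ms = tt[best], amplitude_uv = y[best], found = TRUE,
          window_lo = w[1], window_hi = w[2])
      } else {
        best <- idx[which.max(ys[idx])]
        rows[[k]] <- data.frame(
          channel = channels[ch], component = comp,
          latency_ms = tt[best], amplitude_uv = y[best], found = FALSE,
          window_lo = w[1], window_hi = w[2])
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("peak_set", "data.frame")
  out
}

# internal: fetch one component row per channel from a peak_set
peak_lookup <- function(peaks, comp) {
  p <- peaks[peaks$component == comp, , drop = FALSE]
  p[match(unique(peaks$channel), p$channel), , drop = FALSE]
}

#' Early/late slope features from detected peaks
#'
#' Early slope = (A_N100 - A_P60) / (t_N100 - t_P60); late slope =
#' (A_P180 - A_N100) / (t_P180 - t_N100); `slope_ratio` = late / early.
#' Finite differences of the peak coordinates, no smoothing.
#'
#' @param peaks a `peak_set`.
#' @param montage optional `sensor_montage`; when given, region-role
#'   aggregates (mean over member electrodes) are attached as attribute
#'   `"by_region"`.
#' @param allow_unfound use window-extremum values for components whose
#'   sign-consistency flag is `FALSE` instead of reporting `NA`.
#' @return data.frame with columns `channel`, `early_slope`, `late_slope`,
#'   `slope_ratio` (uV/ms; ratio dimensionless).
#' @export
compute_slopes <- function(peaks, montage = NULL, allow_unfound = FALSE) {
  p60 <- peak_lookup(peaks, "P60")
  n100 <- peak_lookup(peaks, "N100")
  p180 <- peak_lookup(peaks, "P180")
  usable <- function(p) p$found | allow_unfound
  ok_e <- usable(p60) & usable(n100)
  ok_l <- usable(n100) & usable(p180)
  dt_e <- n100$latency_ms - p60$latency_ms
  dt_l <- p180$latency_ms - n100$latency_ms
  if (any(ok_e & dt_e == 0) || any(ok_l & dt_l == 0))
    stop("degenerate peaks: zero latency difference between components")
  early <- ifelse(ok_e, (n100$amplitude_uv - p60$amplitude_uv) / dt_e, NA)
  late <- ifelse(ok_l, (p180$amplitude_uv - n100$amplitude_uv) / dt_l, NA)
  ratio <- ifelse(!is.na(early) & !is.na(late) & abs(early) > 0,
                  late / early, NA)
  out <- data.frame(channel = p60$channel, early_slope = early,
                    late_slope = late, slope_ratio = ratio)
  if (!is.null(montage)) {
    attr(out, "by_region") <- vapply(
      c("early_slope", "late_slope", "slope_ratio"),
      function(f) aggregate_by_region(
        stats::setNames(out[[f]], out$channel), montage),
      numeric(length(montage$groups)))
  }
  out
}

#' Charge transfer Q: rectified area of the evoked response
#'
#' Trapezoidal integral of `|V(t)|` over the analysis window, per channel.
#' The window is closed for integration so that Q is additive over a
#' partition of the window.
#'
#' @param ev a `tep_evoked` object.
#' @param window_ms integration window, default `c(15, 300)` ms (the lower
#'   edge excludes pulse-artifact-interpolated samples).
#' @return data.frame with columns `channel`, `q_uv_ms`; the window is
#'   attached as attribute `"window_ms"`.
#' @export
compute_charge_transfer <- function(ev, window_ms = c(15, 300)) {
  stopifnot(inherits(ev, "tep_evoked"))
  tt <- ev$times_ms
  idx <- which(tt >= window_ms[1] & tt <= window_ms[2])
  if (length(idx) < 2)
    stop("charge-transfer window contains fewer than two samples")
  x <- tt[idx]
  q <- apply(ev$data[, idx, drop = FALSE], 1, function(v) {
    av <- abs(v)
    sum(diff(x) * (av[-1] + av[-length(av)]) / 2)
  })
  out <- data.frame(channel = rownames(ev$data), q_uv_ms = unname(q))
  attr(out, "window_ms") <- window_ms
  out
}

#' Fit the stimulation-intensity input/output recruitment curve
#'
#' Per distinct single-pulse intensity level, the evoked response is
#' averaged and the chosen feature extracted; a Boltzmann sigmoid
#' `floor + span / (1 + exp(-(I - i50) / k))` is then least-squares fitted
#' by an exhaustive grid over `(i50, k)` (with `floor`/`span` solved
#' linearly at each grid point) followed by Nelder-Mead refinement.
#'
#' @param ep a `tep_epochs` object containing single-pulse trials.
#' @param feature `"q"` (charge transfer) or `"p2p"` (peak-to-peak).
#' @param channel electrode whose feature is tracked; defaults to the
#'   montage stimulation site.
#' @param window_ms analysis window for the feature.
#' @param freq_classes frequency class boundaries used to select
#'   single-pulse trials.
#' @param intensity_round rounding step identifying intensity levels.
#' @return an `io_curve`: `intensity` and `value` grids, `params`
#'   (`floor`, `span`, `i50`, `k`), `residual_rms`, `fitted` flag,
#'   `converged` flag.
#' @export
fit_io_curve <- function(ep, feature = c("q", "p2p"), channel = NULL,
                         window_ms = c(15, 300),
                         freq_classes = default_freq_classes(),
                         intensity_round = 1) {
  feature <- match.arg(feature)
  stopifnot(inherits(ep, "tep_epochs"))
  channel <- channel %||% ep$montage$stim_site
  idx <- select_trials(ep, class = "baseline", freq_classes = freq_classes)
  if (!length(idx)) stop("no single-pulse trials available")
  lev_all <- round(ep$trial_meta$intensity_pct[idx] / intensity_round) *
    intensity_round
  levels <- sort(unique(lev_all))
  value <- vapply(levels, function(l) {
    ev <- average_evoked(ep, class = "baseline",
                         intensity_range = c(l - intensity_round / 2,
                                             l + intensity_round / 2),
                         freq_classes = freq_classes)
    v <- ev$data[channel, ]
    tt <- ev$times_ms
    w <- tt >= window_ms[1] & tt <= window_ms[2]
    if (feature == "q") {
      x <- tt[w]; av <- abs(v[w])
      sum(diff(x) * (av[-1] + av[-length(av)]) / 2)
    } else {
      diff(range(v[w]))
    }
  }, numeric(1))

  out <- list(intensity = levels, value = value, feature = feature,
              channel = channel, params = NULL,
              residual_rms = NA_real_, fitted = FALSE, converged = FALSE)
  class(out) <- "io_curve"
  if (length(levels) < 4) {
    out$flag <- "fewer than 4 intensity levels; sigmoid fit skipped"
    return(out)
  }

  boltz <- function(I, p) p[1] + p[2] / (1 + exp(-(I - p[3]) / abs(p[4])))
  sse <- function(p) {
    s <- sum((value - boltz(levels, p))^2)
    if (is.finite(s)) s else Inf
  }
  # grid over (i50, k); floor/span solved by linear least squares
  # (rank-deficient grid points, e.g. a saturated sigmoid, are skipped)
  best <- NULL
  for (i50 in seq(min(levels) - 5, max(levels) + 5, by = 2.5)) {
    for (k in c(0.5, 1, 2, 3, 5, 8, 12, 20)) {
      g <- 1 / (1 + exp(-(levels - i50) / k))
      fit <- stats::lm.fit(cbind(1, g), value)
      p <- c(fit$coefficients, i50, k)
      if (anyNA(p)) next
      s <- sse(p)
      if (is.null(best) || s < best$s) best <- list(p = p, s = s)
    }
  }
  if (is.null(best)) best <- list(p = c(mean(value), 0, mean(levels), 5))
  opt <- stats::optim(best$p, sse, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  p <- opt$par
  p[4] <- abs(p[4])
  # a feature flat across intensities is reported as a flat curve
  # (zero span) rather than a saturated sigmoid of arbitrary span
  flat_sse <- sum((value - mean(value))^2)
  if (flat_sse <= opt$value + 1e-9 * (1 + flat_sse)) {
    p <- c(mean(value), 0, mean(levels), p[4])
    opt$value <- flat_sse
  }
  out$params <- stats::setNames(p, c("floor", "span", "i50", "k"))
  out$residual_rms <- sqrt(opt$value / length(levels))
  out$fitted <- TRUE
  out$converged <- opt$convergence == 0
  out
}

#' @export
print.io_curve <- function(x, ...) {
  cat(sprintf("<io_curve> feature=%s channel=%s, %d levels", x$feature,
              x$channel, length(x$intensity)))
  if (x$fitted)
    cat(sprintf("; i50=%.2f%% MSO, k=%.2f, span=%.1f (rms %.3g)",
                x$params["i50"], x$params["k"], x$params["span"],
                x$residual_rms))
  cat("\n")
  invisible(x)
}
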