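#' @title Synthetic TEP cohort simulator
#' @description
#' Seeded generator of raw TMS-EEG recordings with known ground truth:
#' Gaussian TEP components (N45/P60/N100/P180) with sigmoidal intensity
#' recruitment, distance-based spatial attenuation from the stimulated hub,
#' interhemispheric waveform mixing controlled by a coherence parameter,
#' frequency-class short-term-plasticity modulation (with the late-segment
#' reversal that separates healthy from MD phenotypes), pulse artifact,
#' 1/f + line + white noise, sham, and protocol scheduling.
#' @name synth_tep
NULL

#' Default TEP component specification
#'
#' Four Gaussian components at the canonical latencies with fixed signs
#' (-, +, -, +). Amplitudes are the values at the stimulated hub for a
#' phenotype of amplitude scale 1 at full recruitment.
#'
#' @return data.frame with columns `component`, `center_ms`, `width_ms`,
#'   `amplitude_uv`.
#' @export
default_components <- function() {
  data.frame(component = c("N45", "P60", "N100", "P180"),
             center_ms = c(45, 60, 100, 180),
             width_ms = c(8, 8, 15, 25),
             amplitude_uv = c(-3, 4, -8, 5))
}

#' Subject phenotype parameters
#'
#' Group-level defaults are qualitative-direction calibration constants
#' (the underlying study reports directions of effects, not effect sizes):
#' amplitude and coherence decline with age, MD carries the late-slope
#' modulation sign reversal (`stp_m_slope > 0`).
#'
#' @param label one of `"young"`, `"adult"`, `"elderly"`, `"md"`.
#' @param ... overrides for individual fields (`amplitude_scale`,
#'   `coherence`, `slope_drift`, `stp_m_q`, `stp_m_slope`,
#'   `noise_sigma_uv`, `i50`, `k`).
#' @return a `subject_phenotype` list.
#' @export
subject_phenotype <- function(label = c("young", "adult", "elderly", "md"),
                              ...) {
  label <- match.arg(label)
  defaults <- list(
    young   = list(amplitude_scale = 1.00, coherence = 0.85,
                   slope_drift = 1.00, stp_m_q = 0.75, stp_m_slope = -0.75,
                   noise_sigma_uv = 2, i50 = 40, k = 5),
    adult   = list(amplitude_scale = 0.85, coherence = 0.70,
                   slope_drift = 0.90, stp_m_q = 0.80, stp_m_slope = -0.70,
                   noise_sigma_uv = 2, i50 = 42, k = 5),
    elderly = list(amplitude_scale = 0.70, coherence = 0.55,
                   slope_drift = 0.80, stp_m_q = 0.85, stp_m_slope = -0.60,
                   noise_sigma_uv = 2, i50 = 44, k = 5),
    md      = list(amplitude_scale = 0.65, coherence = 0.35,
                   slope_drift = 0.75, stp_m_q = 0.85, stp_m_slope = 0.60,
                   noise_sigma_uv = 2, i50 = 46, k = 5))[[label]]
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) stop("unknown phenotype fields: ",
                        paste(bad, collapse = ", "))
  defaults[names(over)] <- over
  if (defaults$coherence < 0 || defaults$coherence > 1)
    stop("coherence must lie in [0, 1]")
  structure(c(list(label = label), defaults,
              list(stp_reversal = defaults$stp_m_slope > 0)),
            class = "subject_phenotype")
}

# internal: deterministic "private" hemisphere shape used when coherence
# is below 1 and no subject-specific shape is supplied
default_private_components <- function(components) {
  components$center_ms <- components$center_ms + c(12, -10, 15, -18)
  components$amplitude_uv <- components$amplitude_uv * c(0.7, 1.3, 0.6, 1.2)
  components
}

#' Jittered subject-specific private hemisphere shape
#' @param components component spec to perturb.
#' @param seed integer seed.
#' @return perturbed component spec.
#' @export
make_private_components <- function(components = default_components(),
                                    seed = 1L) {
  withr_seed(seed + 77L, {
    components$center_ms <- components$center_ms +
      stats::runif(4, -15, 15)
    components$amplitude_uv <- components$amplitude_uv *
      stats::runif(4, 0.6, 1.4)
  })
  components
}

# internal: evaluate a sum-of-Gaussians component waveform at times (ms)
component_waveform <- function(times_ms, components, factors = 1) {
  amps <- components$amplitude_uv * factors
  w <- numeric(length(times_ms))
  pos <- times_ms > 0
  for (i in seq_len(nrow(components))) {
    w[pos] <- w[pos] + amps[i] *
      exp(-0.5 * ((times_ms[pos] - components$center_ms[i]) /
                    components$width_ms[i])^2)
  }
  w
}

# internal: run expr with a local RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed %% .Machine$integer.max))
  eval.parent(substitute(expr))
}

# internal: per-electrode gain and ipsi/contra assignment
electrode_gains <- function(montage, lambda = 0.8, contra_transfer = 0.7) {
  pos <- montage$positions
  stim <- pos[montage$stim_site, ]
  ipsi <- sign(pos[, 1]) == sign(stim[1]) | pos[, 1] == 0
  mirror <- c(-stim[1], stim[2])
  d <- ifelse(ipsi,
              sqrt(rowSums((pos - matrix(stim, nrow(pos), 2,
                                         byrow = TRUE))^2)),
              sqrt(rowSums((pos - matrix(mirror, nrow(pos), 2,
                                         byrow = TRUE))^2)))
  gain <- exp(-d / lambda) * ifelse(ipsi, 1, contra_transfer)
  list(gain = stats::setNames(gain, rownames(pos)),
       ipsi = stats::setNames(ipsi, rownames(pos)))
}

#' Noiseless evoked waveform for a phenotype and condition
#'
#' Sum of four Gaussian components scaled by sigmoidal recruitment at the
#' given intensity and by the phenotype's protocol-class modulation
#' (inhibitory: N45/P60 scaled by `stp_m_q`, N100/P180 by the signed
#' `stp_m_slope`; excitatory: uniform `1/stp_m_q`). Ipsilateral electrodes
#' receive distance-attenuated copies of the hub waveform; contralateral
#' electrodes receive the coherence-weighted mix of the hub waveform and
#' the private hemisphere shape. Deterministic (no RNG).
#'
#' @param phenotype a `subject_phenotype`.
#' @param intensity_pct stimulation intensity (% MSO).
#' @param protocol_class `"baseline"`, `"inhibitory"`, or `"excitatory"`.
#' @param montage a `sensor_montage`.
#' @param times_ms time axis in ms (pulse at 0).
#' @param components component spec, see [default_components()].
#' @param private private hemisphere shape (component spec) or `NULL` for
#'   the deterministic default.
#' @param sham_scale evoked amplitude multiplier for sham (1 = real).
#' @return channels x time matrix (uV), rows in montage order.
#' @export
simulate_evoked <- function(phenotype, intensity_pct = 50,
                            protocol_class = "baseline",
                            montage = default_montage(),
                            times_ms = seq(-500, 499.9, by = 1),
                            components = default_components(),
                            private = NULL, sham_scale = 1) {
  stopifnot(inherits(phenotype, "subject_phenotype"))
  g <- stats::plogis((intensity_pct - phenotype$i50) / phenotype$k)
  factors <- switch(protocol_class,
    baseline = rep(1, 4),
    inhibitory = c(phenotype$stp_m_q, phenotype$stp_m_q,
                   phenotype$stp_m_slope, phenotype$stp_m_slope),
    excitatory = rep(1 / phenotype$stp_m_q, 4),
    stop("unknown protocol class: ", protocol_class))
  drift <- c(1, 1, phenotype$slope_drift, phenotype$slope_drift)
  scale <- phenotype$amplitude_scale * g * sham_scale
  w_hub <- component_waveform(times_ms, components, factors * drift) * scale
  if (is.null(private)) private <- default_private_components(components)
  w_priv <- component_waveform(times_ms, private, factors * drift) * scale

  eg <- electrode_gains(montage)
  out <- matrix(0, length(montage$electrodes), length(times_ms),
                dimnames = list(montage$electrodes, NULL))
  cc <- phenotype$coherence
  for (e in montage$electrodes) {
    w <- if (eg$ipsi[e]) w_hub else cc * w_hub + (1 - cc) * w_priv
    out[e, ] <- eg$gain[e] * w
  }
  out
}

# internal: seeded colored noise: 1/f^alpha + white mixture scaled to
# sigma, optional line component. Vector of length n.
colored_noise <- function(n, fs, sigma, alpha = 1, pink_weight = 0.6,
                          line_hz = NULL, line_amp_uv = 0) {
  white <- stats::rnorm(n)
  m <- 2 * ceiling(n / 2)
  spec <- stats::rnorm(m / 2 - 1) + 1i * stats::rnorm(m / 2 - 1)
  freqs <- (1:(m / 2 - 1)) * fs / m
  spec <- spec * freqs^(-alpha / 2)
  full <- c(0, spec, 0, Conj(rev(spec)))
  pink <- Re(stats::fft(full, inverse = TRUE))[1:n]
  pink <- pink / stats::sd(pink)
  x <- pink_weight * pink + (1 - pink_weight) * white
  x <- sigma * x / stats::sd(x)
  if (!is.null(line_hz) && line_amp_uv > 0) {
    phase <- stats::runif(1, 0, 2 * pi)
    x <- x + line_amp_uv * sin(2 * pi * line_hz * (0:(n - 1)) / fs + phase)
  }
  x
}

#' Default 420-pulse stimulation protocol
#'
#' Eight intensity levels (25-60% MSO in 5% steps) x 25 single pulses at
#' 0.5 Hz, one 110-pulse inhibitory train at 2 Hz and 50% MSO, one
#' 110-pulse excitatory train at 20 Hz and 50% MSO; 5 s between blocks.
#'
#' @param n_per_intensity single pulses per intensity level.
#' @param train_n pulses per train block.
#' @param train_intensity train intensity (% MSO).
#' @param single_freq_hz nominal single-pulse rate (Hz).
#' @param inhibitory_freq_hz,excitatory_freq_hz train rates (Hz).
#' @param gap_s silence between blocks (s).
#' @return a `stim_protocol` list.
#' @export
default_protocol <- function(n_per_intensity = 25, train_n = 110,
                             train_intensity = 50, single_freq_hz = 0.5,
                             inhibitory_freq_hz = 2,
                             excitatory_freq_hz = 20, gap_s = 5) {
  structure(list(intensities = seq(25, 60, by = 5),
                 n_per_intensity = n_per_intensity, train_n = train_n,
                 train_intensity = train_intensity,
                 single_freq_hz = single_freq_hz,
                 inhibitory_freq_hz = inhibitory_freq_hz,
                 excitatory_freq_hz = excitatory_freq_hz, gap_s = gap_s,
                 lead_s = 2, tail_s = 2),
            class = "stim_protocol")
}

# internal: build the event schedule for a protocol
build_schedule <- function(protocol) {
  t <- protocol$lead_s
  rows <- list()
  block <- 0L
  for (I in protocol$intensities) {
    block <- block + 1L
    isi <- 1 / protocol$single_freq_hz
    onsets <- t + (0:(protocol$n_per_intensity - 1)) * isi
    rows[[length(rows) + 1]] <- data.frame(
      onset_time = onsets, intensity_pct = I,
      train_frequency_hz = protocol$single_freq_hz, block_id = block,
      sham = FALSE)
    t <- max(onsets) + isi + protocol$gap_s
  }
  for (freq in c(protocol$inhibitory_freq_hz, protocol$excitatory_freq_hz)) {
    block <- block + 1L
    isi <- 1 / freq
    onsets <- t + (0:(protocol$train_n - 1)) * isi
    rows[[length(rows) + 1]] <- data.frame(
      onset_time = onsets, intensity_pct = protocol$train_intensity,
      train_frequency_hz = freq, block_id = block, sham = FALSE)
    t <- max(onsets) + isi + protocol$gap_s
  }
  list(events = do.call(rbind, rows),
       duration_s = t - protocol$gap_s + protocol$tail_s)
}

#' Simulate a raw TMS-EEG recording
#'
#' Schedules the protocol, then inserts per-pulse evoked responses (with
#' lognormal trial-to-trial amplitude jitter), a decaying-exponential pulse
#' artifact over the first 5 ms, and per-channel 1/f + 50 Hz line + white
#' noise. Fully determined by `seed`.
#'
#' @param phenotype a `subject_phenotype`.
#' @param protocol a `stim_protocol`, see [default_protocol()].
#' @param seed integer seed.
#' @param fs sampling rate in Hz (the reference acquisition rate is
#'   5000 Hz; 1000 Hz keeps cohort-scale simulation light).
#' @param montage a `sensor_montage`.
#' @param components component spec.
#' @param subject_id identifier stored in the recording.
#' @param sham simulate sham stimulation (evoked scaled to
#'   `sham_scale`, identical noise stream for the same seed).
#' @param sham_scale evoked multiplier under sham, default 0.03.
#' @param artifact_amp_uv pulse-artifact peak amplitude.
#' @param noise_alpha 1/f exponent of the background noise.
#' @param line_amp_uv 50 Hz line-noise amplitude.
#' @param amp_jitter_sd lognormal sd of trial-to-trial amplitude jitter.
#' @return a `tep_recording`.
#' @export
simulate_recording <- function(phenotype, protocol = default_protocol(),
                               seed = 1L, fs = 5000,
                               montage = default_montage(),
                               components = default_components(),
                               subject_id = paste0("sim-", seed),
                               sham = FALSE, sham_scale = 0.03,
                               artifact_amp_uv = 4000, noise_alpha = 1,
                               line_amp_uv = 1.5, amp_jitter_sd = 0.1) {
  stopifnot(inherits(phenotype, "subject_phenotype"))
  sched <- build_schedule(protocol)
  events <- sched$events
  events$sham <- sham
  n <- ceiling(sched$duration_s * fs)
  nch <- length(montage$electrodes)

  withr_seed(seed, {
    private <- make_private_components(components, seed)
    dat <- matrix(0, nch, n, dimnames = list(montage$electrodes, NULL))
    for (ch in seq_len(nch)) {
      dat[ch, ] <- colored_noise(n, fs, phenotype$noise_sigma_uv,
                                 alpha = noise_alpha, line_hz = 50,
                                 line_amp_uv = line_amp_uv)
    }
    jitter <- exp(stats::rnorm(nrow(events), 0, amp_jitter_sd))

    ev_times <- seq(0, 400, by = 1000 / fs)
    art <- artifact_amp_uv * exp(-(seq(0, 5, by = 1000 / fs)) / 1)
    combos <- unique(events[, c("intensity_pct", "train_frequency_hz")])
    cls <- classify_trials_by_protocol(events)$class
    cache <- list()
    for (i in seq_len(nrow(combos))) {
      key <- paste(combos$intensity_pct[i], combos$train_frequency_hz[i])
      row1 <- which(events$intensity_pct == combos$intensity_pct[i] &
                      events$train_frequency_hz ==
                      combos$train_frequency_hz[i])[1]
      cache[[key]] <- simulate_evoked(
        phenotype, combos$intensity_pct[i], cls[row1], montage,
        times_ms = ev_times, components = components, private = private,
        sham_scale = if (sham) sham_scale else 1)
    }
    for (i in seq_len(nrow(events))) {
      s0 <- round(events$onset_time[i] * fs) + 1L
      key <- paste(events$intensity_pct[i], events$train_frequency_hz[i])
      w <- cache[[key]]
      idx <- s0:(s0 + ncol(w) - 1L)
      ok <- idx <= n
      dat[, idx[ok]] <- dat[, idx[ok]] + jitter[i] * w[, ok, drop = FALSE]
      aidx <- s0:(s0 + length(art) - 1L)
      ok <- aidx <= n
      dat[, aidx[ok]] <- dat[, aidx[ok]] +
        rep(art[ok], each = nch)
    }
  })
  tep_recording(dat, fs, events, montage, subject_id = subject_id)
}

#' Simulate a sham recording
#'
#' Identical schedule, noise and artifact stream as
#' [simulate_recording()] with the same seed; evoked component amplitudes
#' scaled to a small fraction of the real response.
#'
#' @inheritParams simulate_recording
#' @return a `tep_recording` with `sham = TRUE` on every event.
#' @export
simulate_sham <- function(phenotype, protocol = default_protocol(),
                          seed = 1L, fs = 5000,
                          montage = default_montage(), ...) {
  simulate_recording(phenotype, protocol, seed, fs, montage,
                     sham = TRUE, ...)
}

#' Simulate epoched trials directly (no continuous recording)
#'
#' Builds a `tep_epochs` object of noisy single-condition trials around
#' the phenotype's evoked waveform: the light-weight path for parameter-
#' recovery studies where scheduling and filtering are irrelevant.
#'
#' @inheritParams simulate_recording
#' @param n_trials number of trials.
#' @param intensity_pct stimulation intensity (% MSO).
#' @param protocol_class condition class of all trials.
#' @param epoch_ms epoch window, default `c(-500, 500)`.
#' @param baseline_ms baseline window for correction.
#' @param noise_sigma_uv overrides the phenotype's noise sd when not NULL.
#' @param private subject-specific private shape (or NULL for default).
#' @return a `tep_epochs` object (baseline-corrected).
#' @export
simulate_epochs <- function(phenotype, n_trials = 40, intensity_pct = 50,
                            protocol_class = "baseline", seed = 1L,
                            fs = 1000, montage = default_montage(),
                            components = default_components(),
                            epoch_ms = c(-500, 500),
                            baseline_ms = c(-300, -50),
                            noise_sigma_uv = NULL, amp_jitter_sd = 0.1,
                            noise_alpha = 1, private = NULL) {
  times_ms <- seq(epoch_ms[1], epoch_ms[2] - 1000 / fs, by = 1000 / fs)
  w <- simulate_evoked(phenotype, intensity_pct, protocol_class, montage,
                       times_ms, components, private = private)
  sigma <- noise_sigma_uv %||% phenotype$noise_sigma_uv
  nch <- nrow(w); nt <- length(times_ms)
  freq <- switch(protocol_class, baseline = 0.5, inhibitory = 2,
                 excitatory = 20, 0)
  arr <- array(0, dim = c(n_trials, nch, nt))
  withr_seed(seed, {
    jitter <- exp(stats::rnorm(n_trials, 0, amp_jitter_sd))
    for (i in seq_len(n_trials)) {
      noise <- t(vapply(seq_len(nch), function(ch)
        colored_noise(nt, fs, sigma, alpha = noise_alpha),
        numeric(nt)))
      arr[i, , ] <- jitter[i] * w + noise
    }
  })
  meta <- data.frame(onset_time = seq_len(n_trials),
                     intensity_pct = intensity_pct,
                     train_frequency_hz = freq, block_id = 1L,
                     sham = FALSE)
  ep <- structure(
    list(data = arr, times_ms = times_ms, trial_meta = meta,
         baseline_ms = baseline_ms, montage = montage,
         dropped_events = integer(0),
         subject_id = paste0(phenotype$label, "-", seed)),
    class = "tep_epochs")
  baseline_correct(ep)
}

#' Cohort specification
#'
#' @param group_sizes named integer vector, names are phenotype labels
#'   (`young`, `adult`, `elderly`, `md`).
#' @param protocol a `stim_protocol`.
#' @param fs sampling rate for the simulated recordings.
#' @param seed master seed; fully determines the cohort.
#' @param param_jitter_sd relative sd of between-subject phenotype
#'   parameter variation.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(group_sizes = c(young = 5, adult = 5, elderly = 5,
                                        md = 5),
                        protocol = default_protocol(), fs = 1000,
                        seed = 1L, param_jitter_sd = 0.05) {
  stopifnot(all(group_sizes >= 1),
            all(names(group_sizes) %in% c("young", "adult", "elderly",
                                          "md")))
  structure(list(group_sizes = group_sizes, protocol = protocol, fs = fs,
                 seed = as.integer(seed),
                 param_jitter_sd = param_jitter_sd),
            class = "cohort_spec")
}

# internal: derive a per-subject seed that stays inside 32-bit range
subject_seed <- function(master, index) {
  as.integer((as.numeric(master) %% 1e6) * 1000 + index)
}

# internal: draw a subject's phenotype around the group defaults
draw_phenotype <- function(label, seed, jitter_sd) {
  base <- subject_phenotype(label)
  withr_seed(seed + 31L, {
    mul <- exp(stats::rnorm(5, 0, jitter_sd))
    pars <- list(
      amplitude_scale = base$amplitude_scale * mul[1],
      coherence = min(1, max(0, base$coherence * mul[2])),
      slope_drift = base$slope_drift * mul[3],
      stp_m_q = base$stp_m_q * mul[4],
      stp_m_slope = base$stp_m_slope * mul[5],
      noise_sigma_uv = base$noise_sigma_uv,
      i50 = base$i50, k = base$k)
  })
  do.call(subject_phenotype, c(list(label = label), pars))
}

#' Simulate a full cohort with ground truth
#'
#' Per-subject phenotype parameters are drawn around the group defaults
#' (lognormal multiplicative jitter); every injected parameter is stored in
#' the subject's ground-truth record for recovery tests.
#'
#' @param spec a `cohort_spec`.
#' @param out_dir when given, each recording is written as a BrainVision
#'   triplet under `out_dir` and dropped from memory; the returned
#'   `recording` entries are then file paths.
#' @return list of per-subject lists with `subject_id`, `group`,
#'   `recording` (a `tep_recording`, or a `.vhdr` path when `out_dir` is
#'   used) and `truth` (the injected phenotype parameters and seed).
#' @export
simulate_cohort <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  out <- list()
  idx <- 0L
  for (g in names(spec$group_sizes)) {
    for (i in seq_len(spec$group_sizes[[g]])) {
      idx <- idx + 1L
      sid <- sprintf("%s-%02d", g, i)
      seed_i <- subject_seed(spec$seed, idx)
      ph <- draw_phenotype(g, seed_i, spec$param_jitter_sd)
      rec <- simulate_recording(ph, spec$protocol, seed = seed_i,
                                fs = spec$fs, subject_id = sid)
      truth <- c(ph[setdiff(names(ph), "label")],
                 list(label = g, seed = seed_i))
      entry <- list(subject_id = sid, group = g, truth = truth)
      if (is.null(out_dir)) {
        entry$recording <- rec
      } else {
        path <- file.path(out_dir, paste0(sid, ".vhdr"))
        write_brainvision(rec, path)
        jsonlite::write_json(truth, file.path(out_dir,
                                              paste0(sid, "-truth.json")),
                             auto_unbox = TRUE, digits = NA)
        entry$recording <- path
      }
      out[[sid]] <- entry
    }
  }
  out
}
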