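# Shared fixtures built in code: Gaussian TEP composites, evoked/epoch
# constructors, and a tiny stimulation protocol for fast pipeline tests.

# sum-of-Gaussians composite evaluated at times (ms); canonical TEP signs
gauss_composite <- function(t, centers = c(45, 60, 100, 180),
                            widths = c(8, 8, 15, 25),
                            amps = c(-3, 4, -8, 5)) {
  out <- numeric(length(t))
  for (i in seq_along(centers))
    out <- out + amps[i] * exp(-0.5 * ((t - centers[i]) / widths[i])^2)
  out
}

# random canonical composite parameters: each component stays inside its
# default search window with signs fixed, and components stay separated
# enough that each remains a local extremum of the composite
rand_composite_params <- function() {
  list(centers = c(runif(1, 38, 46), runif(1, 60, 70), runif(1, 95, 120),
                   runif(1, 160, 225)),
       widths = c(runif(1, 4, 7), runif(1, 4, 7), runif(1, 10, 14),
                  runif(1, 15, 25)),
       amps = c(-runif(1, 2.5, 5), runif(1, 4, 6), -runif(1, 5, 10),
                runif(1, 3, 8)))
}

# wrap a channels x time matrix as a tep_evoked
as_evoked <- function(data, times_ms, montage = default_montage(),
                      n_trials = 1, class = "baseline") {
  if (is.null(dim(data)))
    data <- matrix(data, nrow = length(montage$electrodes),
                   ncol = length(data), byrow = TRUE)
  rownames(data) <- montage$electrodes
  structure(list(data = data, times_ms = times_ms, n_trials = n_trials,
                 condition = list(class = class), montage = montage,
                 subject_id = "fixture"),
            class = "tep_evoked")
}

# wrap a trials x channels x time array as (uncorrected) tep_epochs
as_epochs <- function(arr, times_ms, meta, montage = default_montage(),
                      baseline_ms = c(-300, -50)) {
  structure(list(data = arr, times_ms = times_ms, trial_meta = meta,
                 baseline_ms = baseline_ms, montage = montage,
                 dropped_events = integer(0), subject_id = "fixture"),
            class = "tep_epochs")
}

trial_meta_row <- function(n, intensity = 50, freq = 0.5, sham = FALSE) {
  data.frame(onset_time = seq_len(n), intensity_pct = intensity,
             train_frequency_hz = freq, block_id = 1L, sham = sham)
}

# epochs pooling several intensity levels (zero-noise unless sigma > 0)
epochs_multi_intensity <- function(phenotype, intensities, n_per = 3,
                                   fs = 1000, sigma = 0, seed = 1) {
  montage <- default_montage()
  times_ms <- seq(-500, 499, by = 1000 / fs)
  arrs <- list(); metas <- list()
  set.seed(seed)
  for (I in intensities) {
    w <- simulate_evoked(phenotype, I, "baseline", montage, times_ms)
    arr <- array(0, dim = c(n_per, nrow(w), ncol(w)))
    for (i in seq_len(n_per)) {
      noise <- if (sigma > 0)
        matrix(rnorm(length(w), 0, sigma), nrow(w)) else 0
      arr[i, , ] <- w + noise
    }
    arrs[[length(arrs) + 1]] <- arr
    metas[[length(metas) + 1]] <- trial_meta_row(n_per, intensity = I)
  }
  full <- array(0, dim = c(n_per * length(intensities),
                           dim(arrs[[1]])[2], dim(arrs[[1]])[3]))
  for (k in seq_along(arrs))
    full[((k - 1) * n_per + 1):(k * n_per), , ] <- arrs[[k]]
  as_epochs(full, times_ms, do.call(rbind, metas), montage)
}

# tiny protocol for fast end-to-end pipeline tests (52 pulses, ~95 s)
tiny_protocol <- function() {
  default_protocol(n_per_intensity = 4, train_n = 10, gap_s = 2)
}
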