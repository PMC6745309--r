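flat_rec <- function(background, n_events = 3, fs = 1000, dur_s = 10,
                     first_s = 2, isi_s = 2) {
  m <- default_montage()
  dat <- matrix(rep(background, each = 20), nrow = 20)
  ev <- data.frame(onset_time = first_s + (0:(n_events - 1)) * isi_s,
                   intensity_pct = 50, train_frequency_hz = 0.5,
                   block_id = 1L, sham = FALSE)
  tep_recording(dat[, 1:(fs * dur_s)], fs, ev, m)
}

test_that("pulse-artifact interpolation flattens impulses and preserves the rest", {
  rec <- flat_rec(rep(0, 10000))
  spike_at <- round(rec$events$onset_time * 1000) + 1
  rec$data[, spike_at] <- 5000
  out <- remove_pulse_artifact(rec)
  # inside windows: interpolation of flat flanks is flat
  expect_lt(max(abs(out$data[, spike_at])), 1e-6)
  # outside all windows: bit-exact
  tt <- (seq_len(ncol(rec$data)) - 1) / 1000
  outside <- rep(TRUE, ncol(rec$data))
  for (on in rec$events$onset_time)
    outside[tt >= on - 0.004 & tt <= on + 0.012] <- FALSE
  expect_identical(out$data[, outside], rec$data[, outside])
})

test_that("interpolation through a linear ramp reproduces the ramp", {
  ramp <- seq(0, 100, length.out = 10000)
  rec <- flat_rec(ramp)
  truth <- rec$data
  spike_at <- round(rec$events$onset_time * 1000) + 1
  rec$data[, spike_at] <- 5000
  out <- remove_pulse_artifact(rec)
  expect_lt(max(abs(out$data - truth)), 1e-6)
})

test_that("artifact removal is idempotent and merges overlapping windows", {
  set.seed(4)
  rec <- flat_rec(rnorm(10000, 0, 10))
  once <- remove_pulse_artifact(rec)
  twice <- remove_pulse_artifact(once)
  expect_identical(once$data, twice$data)

  close_ev <- flat_rec(rnorm(10000, 0, 10), n_events = 3, isi_s = 0.005)
  expect_warning(remove_pulse_artifact(close_ev), "merged")
})

test_that("filtering attenuates the notch frequency and DC", {
  m <- default_montage()
  fs <- 5000; n <- 20000
  sine <- matrix(rep(100 * sin(2 * pi * 50 * (0:(n - 1)) / fs), each = 20),
                 nrow = 20)
  rec <- tep_recording(sine, fs, tepnet:::empty_events(), m)
  out <- filter_recording(rec)
  expect_equal(out$sampling_rate_hz, 1000)
  mid <- 500:3500  # avoid forward-backward edge transients
  expect_lt(stats::sd(out$data[1, mid]), 0.05 * stats::sd(sine[1, ]))

  dc <- tep_recording(matrix(100, 20, n), fs, tepnet:::empty_events(), m)
  out_dc <- filter_recording(dc)
  expect_lt(mean(abs(out_dc$data[1, mid])), 1)

  expect_error(filter_recording(rec, band_hz = c(1, 600)), "Nyquist")
})

test_that("event sample indices remap through resampling", {
  m <- default_montage()
  ev <- data.frame(onset_time = 1.0, intensity_pct = 50,
                   train_frequency_hz = 0.5, block_id = 1L, sham = FALSE)
  rec <- tep_recording(matrix(0, 20, 15000), 5000, ev, m)
  expect_equal(event_sample_index(rec, one_based = FALSE), 5000L)
  out <- filter_recording(rec)
  expect_equal(event_sample_index(out, one_based = FALSE), 1000L)
  expect_equal(event_sample_index(out), 1001L)
})

test_that("epoching copies metadata, drops edge events, and zeroes baselines", {
  rec <- flat_rec(rep(7, 10000), n_events = 4, first_s = 2, isi_s = 2)
  # last event 100 ms before the end: epoch cannot fit
  rec$events$onset_time[4] <- 9.9
  ep <- epoch_and_baseline(rec)
  expect_equal(dim(ep$data)[1], 3)
  expect_equal(ep$dropped_events, 4L)
  expect_true(0 %in% ep$times_ms)
  expect_false(is.unsorted(ep$times_ms, strictly = TRUE))
  # constant channel: zero after baseline subtraction
  expect_lt(max(abs(ep$data)), 1e-9)
  expect_equal(ep$trial_meta$intensity_pct, rep(50, 3))
})

test_that("baseline correction is shift invariant post-stimulus", {
  set.seed(11)
  rec <- flat_rec(rnorm(10000, 0, 5), n_events = 2)
  ep1 <- epoch_and_baseline(rec)
  rec$data <- rec$data + 42  # constant offset
  ep2 <- epoch_and_baseline(rec)
  expect_equal(ep1$data, ep2$data, tolerance = 1e-12)
})

test_that("trial rejection drops amplitude excursions and flat channels", {
  m <- default_montage()
  tt <- seq(-500, 499, by = 1)
  arr <- array(rnorm(40 * 20 * 1000, 0, 5), dim = c(40, 20, 1000))
  arr[17, 3, which(tt == 200)] <- 400
  ep <- as_epochs(arr, tt, trial_meta_row(40), m)
  res <- reject_trials(ep)
  expect_equal(res$report$n_trials_in, 40)
  expect_equal(res$report$n_trials_kept, 39)
  expect_equal(res$report$rejected_indices, 17L)
  expect_equal(res$report$n_trials_kept +
                 length(res$report$rejected_indices), 40)

  clean <- as_epochs(array(rnorm(10 * 20 * 1000, 0, 5),
                           dim = c(10, 20, 1000)), tt,
                     trial_meta_row(10), m)
  res2 <- reject_trials(clean)
  expect_equal(res2$report$n_trials_kept, 10)

  dead <- as_epochs(array(0, dim = c(4, 20, 1000)), tt,
                    trial_meta_row(4), m)
  expect_error(reject_trials(dead), "all 4 trials",
               class = "tepnet_qc_error")
})

test_that("rejection rate tracks an injected contamination rate", {
  m <- default_montage()
  tt <- seq(-500, 499, by = 1)
  blink <- 200 * exp(-0.5 * ((tt - 100) / 80)^2)  # low-frequency, 200 uV
  fracs <- vapply(1:50, function(s) {
    set.seed(s)
    n <- 40
    arr <- array(rnorm(n * 20 * 1000, 0, 5), dim = c(n, 20, 1000))
    hit <- runif(n) < 0.10
    for (i in which(hit)) arr[i, 1, ] <- arr[i, 1, ] + blink
    ep <- as_epochs(arr, tt, trial_meta_row(n), m)
    length(reject_trials(ep)$report$rejected_indices) / n
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.10), 0.03)
})

test_that("evoked averaging obeys the mean, selector and 1/sqrt(N) laws", {
  m <- default_montage()
  tt <- seq(-500, 499, by = 1)
  arr <- array(0, dim = c(2, 20, 1000))
  arr[1, , ] <- 1; arr[2, , ] <- -1
  ep <- as_epochs(arr, tt, trial_meta_row(2), m)
  ev <- average_evoked(ep)
  expect_equal(max(abs(ev$data)), 0)
  expect_equal(ev$n_trials, 2)

  # mixed-frequency epochs: the baseline selector counts <= 0.5 Hz trials
  meta <- trial_meta_row(9, freq = rep(c(0.1, 2, 20), each = 3))
  mixed <- as_epochs(array(rnorm(9 * 20 * 1000), dim = c(9, 20, 1000)),
                     tt, meta, m)
  expect_equal(average_evoked(mixed, class = "baseline")$n_trials, 3)
  expect_error(average_evoked(mixed, class = "baseline",
                              intensity_range = c(90, 100)),
               "no trials match")

  # identical trials average to the trial exactly
  one <- array(rep(rnorm(20 * 1000), each = 4), dim = c(4, 20, 1000))
  epi <- as_epochs(one, tt, trial_meta_row(4), m)
  expect_equal(average_evoked(epi)$data[], epi$data[1, , ],
               ignore_attr = TRUE)

  # evoked noise scales as sigma / sqrt(N)
  for (N in c(4, 16, 64)) {
    rmss <- vapply(1:20, function(s) {
      set.seed(N * 100 + s)
      arr <- array(rnorm(N * 20 * 200, 0, 10), dim = c(N, 20, 200))
      epn <- as_epochs(arr, seq(-100, 99, by = 1), trial_meta_row(N), m)
      sqrt(mean(average_evoked(epn)$data^2))
    }, numeric(1))
    expect_lt(abs(mean(rmss) - 10 / sqrt(N)), 0.2 * 10 / sqrt(N))
  }
})
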