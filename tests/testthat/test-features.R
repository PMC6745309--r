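test_that("peak detection matches a dense-grid argmax oracle on noiseless composites", {
  tt <- seq(-500, 499, by = 1)
  windows <- default_peak_windows()
  set.seed(101)
  for (rep in 1:20) {
    p <- rand_composite_params()
    f <- function(t) gauss_composite(t, p$centers, p$widths, p$amps)
    ev <- as_evoked(f(tt), tt)
    peaks <- detect_peaks(ev)
    one <- peaks[peaks$channel == "C3", ]
    for (comp in names(windows)) {
      w <- windows[[comp]]
      dense <- seq(w[1], w[2] - 1e-9, by = 0.05)
      s <- if (substr(comp, 1, 1) == "N") -1 else 1
      oracle_lat <- dense[which.max(s * f(dense))]
      got <- one[one$component == comp, ]
      expect_true(got$found)
      expect_lt(abs(got$latency_ms - oracle_lat), 1 + 1e-9)
      expect_equal(sign(got$amplitude_uv), s)
    }
  }
})

test_that("all-zero evoked yields no found peaks; latencies stay ordered", {
  tt <- seq(-500, 499, by = 1)
  zero <- as_evoked(rep(0, length(tt)), tt)
  pk <- detect_peaks(zero)
  expect_false(any(pk$found))

  ev <- as_evoked(gauss_composite(tt), tt)
  one <- detect_peaks(ev)
  one <- one[one$channel == "C3", ]
  expect_true(all(one$found))
  lat <- one$latency_ms[match(c("N45", "P60", "N100", "P180"),
                              one$component)]
  expect_false(is.unsorted(lat, strictly = TRUE))
  expect_error(detect_peaks(ev, windows = list(N45 = c(400, 600))),
               "outside")
})

test_that("noisy 40-trial averages recover the N100 within tolerance", {
  tt <- seq(-500, 499, by = 1)
  truth <- gauss_composite(tt)
  w <- default_peak_windows()$N100
  dense_idx <- which(tt >= w[1] & tt < w[2])
  oracle_lat <- tt[dense_idx][which.min(truth[dense_idx])]
  oracle_amp <- min(truth[dense_idx])
  hits <- vapply(1:200, function(s) {
    set.seed(1000 + s)
    ev_data <- truth + rnorm(length(tt), 0, 1 / sqrt(40))
    pk <- detect_peaks(as_evoked(ev_data, tt))
    n100 <- pk[pk$channel == "C3" & pk$component == "N100", ]
    n100$found && abs(n100$latency_ms - oracle_lat) <= 3 &&
      abs(n100$amplitude_uv - oracle_amp) <= 0.1 * abs(oracle_amp)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("slope arithmetic matches the finite-difference definition", {
  mk_peaks <- function(a60, a100, a180) {
    data.frame(channel = "C3",
               component = c("N45", "P60", "N100", "P180"),
               latency_ms = c(45, 60, 100, 180),
               amplitude_uv = c(-2, a60, a100, a180),
               found = TRUE, window_lo = 0, window_hi = 0)
  }
  sl <- compute_slopes(mk_peaks(4, -6, 2))
  expect_equal(sl$early_slope, (-6 - 4) / 40)   # -0.25 uV/ms
  expect_equal(sl$late_slope, (2 - (-6)) / 80)  # 0.1 uV/ms
  expect_equal(sl$slope_ratio, 0.1 / -0.25)     # -0.4

  # homogeneity: amplitudes x2 -> slopes x2, ratio unchanged
  sl2 <- compute_slopes(mk_peaks(8, -12, 4))
  expect_equal(sl2$early_slope, 2 * sl$early_slope)
  expect_equal(sl2$late_slope, 2 * sl$late_slope)
  expect_equal(sl2$slope_ratio, sl$slope_ratio)

  # unfound components propagate NA unless allow_unfound
  p <- mk_peaks(4, -6, 2); p$found[p$component == "P180"] <- FALSE
  expect_true(is.na(compute_slopes(p)$late_slope))
  expect_equal(compute_slopes(p, allow_unfound = TRUE)$late_slope, 0.1)

  bad <- mk_peaks(4, -6, 2)
  bad$latency_ms[bad$component == "N100"] <- 60
  expect_error(compute_slopes(bad), "degenerate")
})

test_that("charge transfer integrates the rectified waveform", {
  tt <- seq(-500, 499, by = 1)
  const <- as_evoked(ifelse(tt >= 0, 2, 0), tt)
  q <- compute_charge_transfer(const)
  expect_equal(q$q_uv_ms[1], 2 * 285)  # 2 uV over [15, 300] ms

  g <- function(t) 10 * exp(-0.5 * ((t - 100) / 10)^2)
  ev <- as_evoked(g(tt), tt)
  qg <- compute_charge_transfer(ev)$q_uv_ms[1]
  oracle <- stats::integrate(function(t) abs(g(t)), 15, 300,
                             rel.tol = 1e-10)$value
  expect_lt(abs(qg - oracle) / oracle, 1e-3)
  expect_lt(abs(oracle - 10 * 10 * sqrt(2 * pi)) / oracle, 1e-6)

  flipped <- as_evoked(-g(tt), tt)
  expect_equal(compute_charge_transfer(flipped)$q_uv_ms[1], qg)
  expect_error(compute_charge_transfer(ev, window_ms = c(600, 700)),
               "fewer than two")
})

test_that("Q is additive over a partition of the window", {
  tt <- seq(-500, 499, by = 1)
  set.seed(7)
  ev <- as_evoked(gauss_composite(tt) + rnorm(length(tt), 0, 1), tt)
  q_full <- compute_charge_transfer(ev, c(15, 300))$q_uv_ms
  q_a <- compute_charge_transfer(ev, c(15, 150))$q_uv_ms
  q_b <- compute_charge_transfer(ev, c(150, 300))$q_uv_ms
  expect_lt(max(abs(q_full - (q_a + q_b)) / q_full), 1e-9)
})

test_that("scaling the evoked scales Q and slopes, fixes latencies and ratio", {
  tt <- seq(-500, 499, by = 1)
  ev1 <- as_evoked(gauss_composite(tt), tt)
  ev3 <- as_evoked(3 * gauss_composite(tt), tt)
  q1 <- compute_charge_transfer(ev1)$q_uv_ms
  q3 <- compute_charge_transfer(ev3)$q_uv_ms
  expect_equal(q3, 3 * q1, tolerance = 1e-12)
  p1 <- detect_peaks(ev1); p3 <- detect_peaks(ev3)
  expect_equal(p1$latency_ms, p3$latency_ms)
  s1 <- compute_slopes(p1); s3 <- compute_slopes(p3)
  expect_equal(s3$early_slope, 3 * s1$early_slope)
  expect_equal(s3$late_slope, 3 * s1$late_slope)
  expect_equal(s3$slope_ratio, s1$slope_ratio)
})

test_that("input/output fit recovers injected recruitment parameters", {
  ph <- subject_phenotype("young")  # i50 = 40, k = 5
  ep <- epochs_multi_intensity(ph, seq(25, 60, 5), n_per = 2)
  io <- fit_io_curve(ep)
  expect_length(io$intensity, 8)
  expect_true(io$fitted)
  expect_lt(abs(io$params[["i50"]] - 40), 2)
  expect_lt(abs(io$params[["k"]] - 5) / 5, 0.2)
  expect_true(all(diff(io$value) > 0))  # recruitment is monotone here
})

test_that("degenerate input/output grids are handled gracefully", {
  ph <- subject_phenotype("young")
  ep3 <- epochs_multi_intensity(ph, c(30, 40, 50), n_per = 2)
  io3 <- fit_io_curve(ep3)
  expect_false(io3$fitted)
  expect_length(io3$value, 3)

  # constant feature across intensities -> flat fit with zero span
  m <- default_montage()
  tt <- seq(-500, 499, by = 1)
  w <- simulate_evoked(ph, 50, "baseline", m, tt)
  levels <- seq(25, 60, 5)
  arr <- array(0, dim = c(length(levels), 20, 1000))
  for (i in seq_along(levels)) arr[i, , ] <- w
  epf <- as_epochs(arr, tt, trial_meta_row(length(levels),
                                           intensity = levels), m)
  iof <- fit_io_curve(epf)
  expect_true(iof$fitted)
  expect_equal(unname(iof$params[["span"]]), 0)
  expect_lt(iof$residual_rms, 1e-9 * mean(iof$value))
})
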