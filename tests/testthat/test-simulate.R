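test_that("AR change-point simulation matches stationary theory", {
  sim <- simulate_ar_changepoint(model1_spec(seed = 61))
  expect_length(sim$signal, 4000)
  expect_equal(sim$changepoints, 2001L)
  v1 <- var(sim$signal[1:2000])
  expect_equal(v1, ar2_stationary_var(0.6, -0.2), tolerance = 0.05 *
                 ar2_stationary_var(0.6, -0.2))

  # variance-change study: fourfold variance jump across the change point
  sim2 <- simulate_ar_changepoint(model2_spec(seed = 62))
  ratio <- var(sim2$signal[2001:4000]) / var(sim2$signal[1:2000])
  expect_equal(ratio, 4, tolerance = 0.6)
})

test_that("generators are bit-reproducible and validate stationarity", {
  a <- simulate_ar_changepoint(model1_spec(seed = 7))
  b <- simulate_ar_changepoint(model1_spec(seed = 7))
  expect_identical(a$signal, b$signal)
  expect_error(ar_change_spec(list(list(coef = c(1.1), sd = 1, n = 100))),
               "non-stationary")

  r1 <- simulate_spindle_eeg(spindle_sim_spec(snr = 2, seed = 9))
  r2 <- simulate_spindle_eeg(spindle_sim_spec(snr = 2, seed = 9))
  expect_identical(r1$data, r2$data)
})

test_that("noise-free segments decay deterministically via lag carry-over", {
  spec <- ar_change_spec(list(list(coef = c(0.6, -0.2), sd = 1, n = 200L),
                              list(coef = c(0.6, -0.2), sd = 0, n = 60L)),
                         seed = 63)
  sim <- simulate_ar_changepoint(spec)
  seg2 <- sim$signal[201:260]
  # homogeneous recursion from the carried state, written out directly
  x1 <- sim$signal[200]; x2 <- sim$signal[199]
  for (k in seq_len(60)) {
    xt <- 0.6 * x1 - 0.2 * x2
    expect_equal(seg2[k], xt, tolerance = 1e-12)
    x2 <- x1; x1 <- xt
  }
  expect_lt(abs(seg2[60]), abs(sim$signal[200]) + 1e-6)
})

test_that("spindle simulation follows the burst schedule", {
  spec <- spindle_sim_spec(snr = 3, seed = 64)
  rec <- simulate_spindle_eeg(spec)
  truth <- attr(rec, "truth")
  expect_equal(nrow(truth), 20L)
  expect_equal(truth$onset, seq(10, 105, by = 5))
  expect_equal(truth$offset - truth$onset, rep(0.5, 20))
  expect_equal(nrow(rec$data), 33L)
  expect_equal(rec$fs, 300)
  expect_true(all(c("PO7", "POz", "O1", "O2", "Pz") %in%
                    rec$channel_labels))
  # posterior channels carry the strongest burst
  gains <- spec$channel_gains
  expect_equal(max(gains), 1)
  expect_true(all(gains[spec$channel_labels %in% c("O1", "O2", "POz")] == 1))
  expect_lt(gains[spec$channel_labels == "Fz"], 0.1)
})

test_that("burst amplitude matches the requested SNR on max-gain channels", {
  spec <- spindle_sim_spec(snr = 3, seed = 65)
  rec <- simulate_spindle_eeg(spec)
  truth <- attr(rec, "truth")
  fs <- rec$fs
  i_o1 <- which(rec$channel_labels == "O1")
  # project the burst core (taper ramps excluded) onto the 10 Hz quadrature
  amps <- vapply(seq_len(nrow(truth)), function(k) {
    idx <- (round((truth$onset[k] + 0.05) * fs) + 1):
           (round((truth$offset[k] - 0.05) * fs))
    tt <- (idx - 1) / fs
    y <- rec$data[i_o1, idx]
    2 * sqrt(mean(y * sin(2 * pi * 10 * tt))^2 +
             mean(y * cos(2 * pi * 10 * tt))^2)
  }, numeric(1))
  expect_equal(mean(amps), spec$snr * spec$noise_rms_uv,
               tolerance = 0.1 * spec$snr * spec$noise_rms_uv)
  # burst windows have visibly higher RMS than background on O1
  in_rms <- sd(rec$data[i_o1, (10 * fs + 1):(10.5 * fs)])
  out_rms <- sd(rec$data[i_o1, (12 * fs + 1):(14 * fs)])
  expect_gt(in_rms, out_rms * 1.3)
})

test_that("preprocessing attenuates out-of-band tones and passes alpha", {
  fs_in <- 300; fs_out <- 128
  tt <- (0:(20 * fs_in - 1)) / fs_in
  x3 <- sin(2 * pi * 3 * tt)
  x10 <- sin(2 * pi * 10 * tt)
  y3 <- preprocess(x3, fs_in = fs_in, fs_out = fs_out)
  y10 <- preprocess(x10, fs_in = fs_in, fs_out = fs_out)
  core <- (5 * fs_out):(15 * fs_out)      # avoid filter edge transients
  att3 <- 20 * log10(sd(y3[core]) / sd(x3))
  att10 <- 20 * log10(sd(y10[core]) / sd(x10))
  expect_lt(att3, -40)
  expect_gt(att10, -1)
  expect_lt(att10, 1)
  # zero in, zero out; band edge validation
  y0 <- preprocess(numeric(3000), fs_in = fs_in)
  expect_equal(length(y0), floor(3000 * 128 / 300))
  expect_true(all(abs(y0) < 1e-9))
  expect_error(preprocess(x3, fs_in = fs_in, band = c(6, 70)),
               "fs_out/2")
})
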