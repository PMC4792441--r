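test_that("noiseless single-pixel recovery is exact to optimizer tolerance", {
  p0 <- acquisition_protocol(noise_sigma = 0)
  ti <- p0$inversion_times
  sig <- abs(3.29 * (1 - 2 * exp(-0.557e-3 * ti)))
  f <- fit_ir_pixel(sig, p0)
  expect_true(f$fit_ok)
  expect_lt(abs(f$s0 - 3.29) / 3.29, 1e-6)
  expect_lt(abs(f$inv_eff - 2) / 2, 1e-6)
  expect_lt(abs(f$r1 - 0.557) / 0.557, 1e-6)
  expect_lt(f$residual, 1e-12)
})

test_that("R1 comes back in s^-1 whether TIs are in ms or s", {
  p_ms <- acquisition_protocol(noise_sigma = 0)
  p_s <- acquisition_protocol(inversion_times = p_ms$inversion_times / 1000,
                              echo_time = 0.0005, ti_unit = "s",
                              noise_sigma = 0)
  sig <- abs(1.7 * (1 - 1.9 * exp(-0.8e-3 * p_ms$inversion_times)))
  f_ms <- fit_ir_pixel(sig, p_ms)
  f_s <- fit_ir_pixel(sig, p_s)
  expect_equal(f_ms$r1, 0.8, tolerance = 1e-6)
  expect_equal(f_s$r1, 0.8, tolerance = 1e-6)
  expect_equal(f_ms$s0, f_s$s0, tolerance = 1e-6)
})

test_that("a coarse parameter grid is recovered within 1e-4 relative error", {
  p0 <- acquisition_protocol(noise_sigma = 0)
  ti <- p0$inversion_times
  for (s0 in c(1, 3.29, 8)) {
    for (b in c(1.2, 1.9, 2.05)) {
      for (r1 in c(0.2, 0.557, 2)) {
        sig <- abs(s0 * (1 - b * exp(-r1 / 1000 * ti)))
        f <- fit_ir_pixel(sig, p0)
        expect_true(f$fit_ok)
        expect_lt(max(abs(f$s0 - s0) / s0, abs(f$inv_eff - b) / b,
                      abs(f$r1 - r1) / r1), 1e-4)
      }
    }
  }
})

test_that("degenerate or malformed signals are rejected or flagged", {
  p0 <- acquisition_protocol(noise_sigma = 0)
  f <- fit_ir_pixel(rep(0, 7), p0)
  expect_false(f$fit_ok)
  expect_true(is.na(f$r1))
  expect_error(fit_ir_pixel(c(1, 2, 3), p0), "length")
  expect_error(fit_ir_pixel(c(-1, 1, 1, 1, 1, 1, 1), p0), "nonnegative")
  expect_error(fit_ir_pixel(c(NA, 1, 1, 1, 1, 1, 1), p0), "nonnegative|finite")
})

test_that("noiseless maps fit everywhere; out-of-mask pixels carry no values", {
  gt <- make_phantom(quick_spec("control", seed = 5))
  p0 <- acquisition_protocol(noise_sigma = 0)
  mp <- fit_maps(simulate_signal(gt, p0, seed = 1))
  m <- gt$mask
  expect_gte(mean(mp$valid[m]), 0.999)
  expect_true(all(is.na(mp$r1$air[!m])))
  expect_true(all(is.na(mp$delta_r1[!m])))
  expect_false(any(mp$fit_ok$air[!m]))
  # recovered maps match the generating truth
  expect_lt(max(abs(mp$r1$air[mp$valid] - gt$r1_air[mp$valid])), 1e-4)
  expect_lt(max(abs(mp$delta_r1[mp$valid] - gt$delta_r1[mp$valid])), 1e-4)
})

test_that("noisy maps recover R1_air with small error at default SNR", {
  gt <- make_phantom(phantom_spec("control", seed = 3,
                                  nx = 40, ny = 40, n_pixels_target = 400))
  mp <- fit_maps(simulate_signal(gt, acquisition_protocol(), seed = 11))
  v <- mp$valid
  expect_gt(mean(v[gt$mask]), 0.5)
  rmse <- sqrt(mean((mp$r1$air[v] - gt$r1_air[v])^2))
  expect_lt(rmse, 0.06)
})

test_that("delta_r1 arithmetic matches the group-mean identities", {
  expect_equal(delta_r1(0.581, 0.557), 0.024, tolerance = 1e-12)
  expect_equal(delta_r1(0.574, 0.549), 0.025, tolerance = 1e-12)
  a <- matrix(1:4 / 10, 2)
  expect_true(all(delta_r1(a, a) == 0))
  expect_error(delta_r1(matrix(0, 2, 2), matrix(0, 3, 3)), "grid")
})

test_that("delta_r2star inverts the simulator attenuation and flags edge cases", {
  expect_equal(as.numeric(delta_r2star(1, 1, 0.5)), 0)
  expect_equal(as.numeric(delta_r2star(1, 0.98, 0.5)), log(1 / 0.98) / 0.5,
               tolerance = 1e-12)
  expect_equal(as.numeric(delta_r2star(1, exp(-0.045), 0.5)), 0.090,
               tolerance = 1e-12)
  # negative outputs permitted but flagged
  d <- delta_r2star(c(1, 1), c(0.9, 1.2), 0.5)
  expect_identical(attr(d, "negative"), c(FALSE, TRUE))
  # nonpositive S0 marks the pixel invalid without aborting
  d2 <- delta_r2star(c(1, -1), c(1, 1), 0.5)
  expect_true(is.na(d2[2]))
  expect_identical(attr(d2, "invalid"), c(FALSE, TRUE))
  expect_error(delta_r2star(1, 1, 0), "echo_time")
})

test_that("group-mean delta-R1 bias is below 10% at default SNR, n = 9", {
  spec <- study_spec(n_control = 9, n_challenged = 0, master_seed = 42)
  st <- make_study(spec)
  per_animal <- vapply(st, function(a) {
    mp <- fit_maps(a$series)
    c(bias = mean((mp$delta_r1 - a$ground_truth$delta_r1)[mp$valid]),
      truth = mean(a$ground_truth$delta_r1[a$ground_truth$mask]))
  }, c(bias = 0, truth = 0))
  bias <- mean(per_animal["bias", ])
  gen_mean <- mean(per_animal["truth", ])
  expect_lt(abs(bias), 0.10 * abs(gen_mean))
})
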