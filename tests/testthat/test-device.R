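test_that("time normalization matches the printed floor formula", {
  expect_equal(normalize_time(0.65, 0.65, 60), 0)
  expect_equal(normalize_time(5.70, 0.65, 60), 0.05, tolerance = 1e-12)
  expect_equal(normalize_time(0.30, 0.65, 60), 0.65, tolerance = 1e-12)
  # always lands in [0, 60/hr)
  set.seed(7)
  for (hr in c(60, 72, 95)) {
    tn <- normalize_time(stats::runif(200, 0, 30), 0.4, hr)
    expect_true(all(tn >= 0 & tn < 60 / hr))
  }
})

test_that("the gain surface evaluates and clamps as specified", {
  expect_equal(gain(80, 9, rep(0, 5)), 0)
  expect_equal(gain(80, 9, c(0, 0, 0, 0.5, 0)), 0.5)
  expect_equal(gain(100, 10, c(0, -0.001, 0.05, 0.5, 0)), 0.9)
  expect_equal(gain(100, 10, c(0, -0.05, 0, 0.5, 0), clamp = TRUE), 0)
  expect_lt(gain(100, 10, c(0, 0.05, 0, 0.5, 0), clamp = TRUE), 1)
})

test_that("gain-surface fitting is an exact round trip on noiseless grids", {
  grid <- synth_bench_data(seed = 3, noise_sd = 0)
  fit <- fit_gain_surface(grid)
  expect_equal(unname(fit$coeffs), unname(hemopulse:::bench_true_coeffs),
               tolerance = 1e-8)
  expect_lt(fit$rmse, 1e-10)
  # refitting the model's own predictions returns the same coefficients
  grid2 <- grid
  grid2$g_exp <- gain(grid$p_aorta_mmHg, grid$p_act_psi, fit$coeffs)
  expect_equal(fit_gain_surface(grid2)$coeffs, fit$coeffs, tolerance = 1e-10)

  const <- grid
  const$g_exp <- 0.4
  cf <- fit_gain_surface(const)$coeffs
  expect_equal(unname(cf[4]), 0.4, tolerance = 1e-8)
  expect_equal(unname(cf[-4]), rep(0, 4), tolerance = 1e-8)

  expect_error(fit_gain_surface(grid[1:4, ]), "degenerate")
  one_pa <- grid[grid$p_aorta_mmHg == 80, ]
  expect_error(fit_gain_surface(one_pa), "degenerate")
})

test_that("the pressure source is continuous with a zero tail", {
  dev <- device_params(p_act = 10, dt_act = 0.65, t_on = 0.3, t_off = 0.5,
                       gain_coeffs = c(0, 0, 0, 0.3, 0), correction = 1)
  # hand-solved continuity system at g_act = 0.3, p_aorta = 100
  p_on <- source_pressure(0.3, 100, dev)
  expect_equal(p_on, 30 * (1 - exp(-13.04 * 0.3)), tolerance = 1e-12)
  expect_equal(p_on, 29.40, tolerance = 1e-3)
  expect_equal(source_pressure(0.3 + 1e-12, 100, dev), p_on, tolerance = 1e-6)
  expect_equal(source_pressure(0.5, 100, dev), 0, tolerance = 1e-9)
  expect_equal(source_pressure(0.7, 100, dev), 0)
  # zero gain means a silent source
  dev0 <- device_params(p_act = 10, dt_act = 0, gain_coeffs = rep(0, 5))
  expect_equal(source_pressure(seq(0, 0.9, 0.01), 100, dev0), rep(0, 91))
})

test_that("peak source pressure rises with actuation pressure and falls with loop pressure", {
  grid <- synth_bench_data(seed = 5, noise_sd = 0)
  for (pa in unique(grid$p_aorta_mmHg)) {
    g <- grid$g_exp[grid$p_aorta_mmHg == pa]
    expect_true(all(diff(g) > 0)) # increasing in p_act
  }
  for (pc in unique(grid$p_act_psi)) {
    g <- grid$g_exp[grid$p_act_psi == pc]
    expect_true(all(diff(g) < 0)) # decreasing in p_aorta
  }
  fit <- fit_gain_surface(grid)
  peak <- function(p_act) {
    dev <- device_params(p_act = p_act, dt_act = 0, gain_coeffs = fit$coeffs)
    max(source_pressure(seq(0, 0.5, 1e-3), 95, dev))
  }
  expect_true(all(diff(vapply(6:12, peak, numeric(1))) > 0))
})

test_that("device flow is the scaled rate of the source pressure", {
  dev <- device_params(p_act = 10, dt_act = 0, C_sr = 0.05, correction = 1)
  expect_equal(device_flow(100, dev), 5) # +100 mmHg/s ramp -> +5 mL/s
  expect_equal(device_flow(0, dev), 0)
  dev2 <- device_params(p_act = 10, dt_act = 0, C_sr = 0.05, correction = 3)
  expect_equal(device_flow(100, dev2), 15)
})

test_that("timing lookup interpolates the bench grid with edge clamping", {
  grid <- synth_bench_data(seed = 2, noise_sd = 0)
  # exact grid point
  at <- timing_lookup(9, 100, grid)
  row <- grid[grid$p_act_psi == 9 & grid$p_aorta_mmHg == 100, ]
  expect_equal(at$t_on, row$t_on_s)
  expect_equal(at$t_off, row$t_off_s)
  # between neighbors
  mid <- timing_lookup(9.5, 100, grid)
  lo <- timing_lookup(9, 100, grid)$t_on
  hi <- timing_lookup(10, 100, grid)$t_on
  expect_true(mid$t_on >= min(lo, hi) && mid$t_on <= max(lo, hi))
  # clamped outside the measured range
  expect_equal(timing_lookup(20, 400, grid)$t_off,
               timing_lookup(12, 150, grid)$t_off)
  expect_error(timing_lookup(9, 100, grid[0, ]), "empty")
})

test_that("the synthetic bench generator is reproducible", {
  expect_identical(synth_bench_data(seed = 11, noise_sd = 0.02),
                   synth_bench_data(seed = 11, noise_sd = 0.02))
  g <- synth_bench_data(seed = 11, noise_sd = 0.02)
  expect_equal(nrow(g), 8 * 7)
  expect_true(all(g$g_exp > 0 & g$g_exp < 1))
  expect_true(all(g$t_on_s < g$t_off_s))
})

test_that("the correction factor is the linear displacement ratio", {
  dev <- device_params(p_act = 10, dt_act = 0, C_sr = 0.05,
                       gain_coeffs = c(0, 0, 0, 0.3, 0))
  tn <- seq(0, dev$t_off, length.out = 2001)
  disp <- dev$C_sr * max(source_pressure(tn, 100, dev))
  expect_equal(calibrate_correction(disp, dev), 1, tolerance = 1e-6)
  expect_equal(calibrate_correction(2 * disp, dev), 2, tolerance = 1e-6)
  expect_equal(calibrate_correction(0, dev), 0)
  expect_error(calibrate_correction(-1, dev), "negative")
  dev0 <- device_params(p_act = 10, dt_act = 0, gain_coeffs = rep(0, 5))
  expect_error(calibrate_correction(5, dev0), "zero gain")
})
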