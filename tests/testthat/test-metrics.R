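test_that("cycle metrics reproduce closed-form values on synthetic loops", {
  tt <- seq(0, 1, by = 1e-3)
  # constant aortic flow of 86.17 mL/s is a cardiac output of 5.17 L/min
  flat <- synthetic_trajectory(data.frame(time = tt, Q_AV = 86.17,
                                          V_LV = 100, P_LV = 50, P_ao = 90,
                                          s_MV = 0, s_AV = 1))
  expect_equal(summarize_cycle(flat)$co, 5.1702, tolerance = 1e-6)

  # rectangular PV loop 34..119 mL x 10..110 mmHg: 8500 mmHg.mL = 1.133 J
  n4 <- 250
  V <- c(rep(119, n4), seq(119, 34, length.out = n4),
         rep(34, n4), seq(34, 119, length.out = n4 + 1))
  P <- c(seq(10, 110, length.out = n4), rep(110, n4),
         seq(110, 10, length.out = n4), rep(10, n4 + 1))
  rect <- synthetic_trajectory(data.frame(time = tt, V_LV = V, P_LV = P,
                                          Q_AV = 0, s_MV = 0, s_AV = 0))
  s <- summarize_cycle(rect)
  expect_equal(s$stroke_work, 8500, tolerance = 1e-2)
  expect_equal(s$stroke_work_J, 1.133, tolerance = 1e-3)
  expect_equal(s$edv, 119)
  expect_equal(s$esv, 34)

  # a degenerate loop with no enclosed area does no work
  line <- synthetic_trajectory(data.frame(time = tt,
                                          V_LV = 100 + 10 * sin(2 * pi * tt),
                                          P_LV = 20, Q_AV = 0,
                                          s_MV = 0, s_AV = 0))
  expect_equal(summarize_cycle(line)$stroke_work, 0, tolerance = 1e-9)
})

test_that("summary metrics of the calibrated cycle are internally consistent", {
  cal <- cached_calibration()
  s <- cal$summary
  expect_gt(s$peak_systolic, s$diastolic)
  expect_gt(s$edv, s$esv)
  expect_gte(s$co, 0)
  expect_equal(s$ea, s$esp / s$co, tolerance = 1e-12)
  splits <- as.numeric(s[grep("^split_", names(s))])
  expect_equal(sum(splits), 100, tolerance = 1e-6)
  expect_equal(s$upper_split, 100 - s$split_descending_aorta, tolerance = 1e-9)
})

test_that("waveform RMSE handles resampling, offsets, and disjoint supports", {
  tt <- seq(0, 1, by = 1e-3)
  a <- data.frame(time = tt, flow = 100 * sin(2 * pi * tt))
  expect_equal(waveform_rmse(a, a), 0)
  b <- a
  b$flow <- b$flow + 5
  expect_equal(waveform_rmse(a, b), 5, tolerance = 1e-12)
  # against a flat reference the RMSE is the RMS of the sine: amp / sqrt(2)
  z <- data.frame(time = tt, flow = 0)
  expect_equal(waveform_rmse(a, z), 100 / sqrt(2), tolerance = 1e-3)
  # reference on its own (coarser, shifted) grid is interpolated
  b2 <- data.frame(time = seq(-0.004, 1.004, by = 0.017))
  b2$flow <- 100 * sin(2 * pi * b2$time) + 5
  expect_equal(waveform_rmse(a, b2), 5, tolerance = 0.05)
  far <- data.frame(time = tt + 10, flow = 0)
  expect_error(waveform_rmse(a, far), "non-overlapping")
})

test_that("sweeps with the actuator at zero pressure reproduce the baseline", {
  m <- device_model()
  sw <- delay_sweep(m, delays_ms = c(100, 650), p_act = 0, n_cycles = 3)
  base <- dplyr::filter(sw, baseline)
  pts <- dplyr::filter(sw, !baseline)
  for (i in seq_len(nrow(pts))) {
    expect_equal(pts$peak_systolic[i], base$peak_systolic, tolerance = 1e-12)
    expect_equal(pts$co[i], base$co, tolerance = 1e-12)
  }
})

test_that("sweep reports are complete, normalized, and byte-stable", {
  m <- device_model()
  sw <- delay_sweep(m, delays_ms = c(450, 650), n_cycles = 3)
  expect_equal(nrow(sw), 3) # baseline + 2 points
  expect_equal(sum(sw$baseline), 1)

  dir <- withr::local_tempdir()
  paths <- report_sweep(sw, dir)
  tab <- readr::read_csv(paths[1], show_col_types = FALSE)
  expect_equal(nrow(tab), 3)
  splits <- readr::read_csv(paths[2], show_col_types = FALSE)
  expect_equal(colSums(splits[, -1]), rep(100, 3), tolerance = 0.1,
               ignore_attr = TRUE)
  h1 <- tools::md5sum(paths[1])
  report_sweep(sw, dir)
  expect_identical(tools::md5sum(paths[1]), h1)
})

test_that("a full delay sweep has nineteen points plus the baseline", {
  skip_if(Sys.getenv("HEMOPULSE_FULL_SWEEP") == "never") # documentation only
  m <- device_model()
  sw <- delay_sweep(m, n_cycles = 4, dt = 2e-4)
  expect_equal(nrow(sw), 20)
  expect_equal(sum(!sw$baseline), 19)
  expect_true(all(!sw$failed))
})
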