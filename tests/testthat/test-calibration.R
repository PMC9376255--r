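test_that("patient targets are validated on construction", {
  expect_s3_class(patient_targets(), "patient_targets")
  expect_error(patient_targets(esv = 120), "edv > esv")
  expect_error(patient_targets(dbp = 160), "sbp > dbp")
  expect_error(patient_targets(upper_split = 0), "upper_split")
})

test_that("the MAP estimate and Ohmic resistance target are exact", {
  expect_equal(map_estimate(68, 150), 95 + 1 / 3, tolerance = 1e-12)
  t1 <- patient_targets()
  t2 <- patient_targets(co = 2 * t1$co)
  expect_equal(target_total_resistance(t1) / target_total_resistance(t2), 2,
               tolerance = 1e-12)
})

test_that("the resistance stage hits the Ohmic total and branch budget", {
  m <- cv_model(build_network(hemopulse_geometry()))
  t <- patient_targets()
  st <- stage_total_resistance(m, t, refine = FALSE)
  expect_equal(total_systemic_resistance(st$model), target_total_resistance(t),
               tolerance = 1e-10)
  # an impossible venous resistance is a stage failure
  m2 <- m
  m2$R_ven <- 2
  expect_error(stage_total_resistance(m2, t, refine = FALSE), "stage failure")
})

test_that("branch fractions must sum to 100", {
  m <- cv_model(build_network(hemopulse_geometry()))
  bad <- default_branch_fractions() * 0.9
  expect_error(stage_flow_splits(m, patient_targets(), bad), "sum to 100")
  expect_equal(sum(default_branch_fractions()), 100, tolerance = 0.5)
})

test_that("raising every terminal capacitance lowers the pulse pressure", {
  cal <- cached_calibration()
  m <- cal$model
  pp_of <- function(scale) {
    m2 <- m
    m2$network$terminals$C <- m$network$terminals$C * scale
    s <- summarize_cycle(simulate_model(m2, n_cycles = 4, dt = 2e-4), -1)
    s$peak_systolic - s$diastolic
  }
  pps <- vapply(c(0.7, 1, 1.5), pp_of, numeric(1))
  expect_true(all(diff(pps) < 0))
})

test_that("raising peak elastance at fixed load lowers the end-systolic volume", {
  cal <- cached_calibration()
  m <- cal$model
  esv_of <- function(e) {
    m2 <- m
    m2$lv$E_act_max <- e
    summarize_cycle(simulate_model(m2, n_cycles = 4, dt = 2e-4), -1)$esv
  }
  esvs <- vapply(c(4, 5.5, 7), esv_of, numeric(1))
  expect_true(all(diff(esvs) < 0))
})

test_that("calibration is deterministic for a fixed seed and configuration", {
  cal1 <- cached_calibration()
  cal2 <- calibrate(seed = 0)
  expect_equal(cal1$report, cal2$report, tolerance = 1e-12)
  expect_equal(cal1$state0, cal2$state0, tolerance = 1e-12)
})

test_that("tidy and glance expose the comparison table and fit summary", {
  cal <- cached_calibration()
  td <- tidy(cal)
  expect_setequal(td$quantity, c("hr", "dbp", "sbp", "peak_flow", "co",
                                 "flow_split", "edv", "esv", "edp"))
  expect_named(td, c("quantity", "patient", "model", "delta_abs", "delta_pct"))
  gl <- glance(cal)
  expect_equal(nrow(gl), 1)
  expect_true(gl$envelope_ok)

  dir <- withr::local_tempdir()
  paths <- report_calibration(cal, dir)
  expect_true(all(file.exists(paths)))
  expect_equal(nrow(readr::read_csv(paths[1], show_col_types = FALSE)), 9)
})
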