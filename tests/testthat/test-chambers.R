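test_that("activation is a normalized bump confined to its window", {
  p <- chamber_params(E_act_max = 2, V0 = 10, A_pas = 0.5, B_pas = 0.04,
                      t_onset = 0.1, t_sys = 0.3)
  expect_equal(activation(0.1, p, 1), 0)
  expect_equal(activation(0.1 + 0.15, p, 1), 1)
  expect_equal(activation(0.6, p, 1), 0)
  expect_equal(activation(0.05, p, 1), 0)
  # periodic wrap: one full cycle later is identical
  ts <- seq(0, 0.999, by = 1e-3)
  expect_equal(activation(ts, p, 1), activation(ts + 3, p, 1))
  expect_true(all(activation(ts, p, 1) >= 0 & activation(ts, p, 1) <= 1))

  # asymmetric shape peaks at rise_frac * t_sys, still normalized
  pa <- chamber_params(E_act_max = 2, V0 = 10, A_pas = 0.5, B_pas = 0.04,
                       t_onset = 0, t_sys = 0.5, rise_frac = 0.8)
  expect_equal(activation(0.4, pa, 1), 1)
  expect_equal(max(activation(ts, pa, 1)), 1, tolerance = 1e-6)
  expect_equal(activation(0.55, pa, 1), 0)
})

test_that("passive pressure is the pinned exponential through V0", {
  p <- chamber_params(E_act_max = 2, V0 = 0, A_pas = 0.8, B_pas = 0.04,
                      t_onset = 0, t_sys = 0.3)
  expect_equal(passive_pressure(0, p), 0)
  expect_equal(passive_pressure(50, p), 0.8 * (exp(2) - 1), tolerance = 1e-12)
  expect_equal(passive_pressure(50, p), 5.113, tolerance = 1e-3)
  vols <- seq(1, 150, by = 7)
  expect_true(all(diff(passive_pressure(vols, p)) > 0))
})

test_that("total chamber pressure superposes passive and active parts", {
  p <- chamber_params(E_act_max = 2, V0 = 0, A_pas = 0.8, B_pas = 0.04,
                      t_onset = 0, t_sys = 0.4)
  # e = 0 outside the window: purely passive
  expect_equal(chamber_pressure(50, 0.7, p, 1), passive_pressure(50, p))
  # e = 1, no passive component: linear ESPVR through V0 with slope E_act_max
  p0 <- chamber_params(E_act_max = 2, V0 = 0, A_pas = 1e-12, B_pas = 0.04,
                       t_onset = 0, t_sys = 0.4)
  expect_equal(chamber_pressure(60, 0.2, p0, 1), 120, tolerance = 1e-6)
})

test_that("a stiffer passive curve yields a smaller volume at fixed filling pressure", {
  vol_at <- function(B) {
    p <- chamber_params(E_act_max = 2, V0 = 10, A_pas = 0.8, B_pas = B,
                        t_onset = 0, t_sys = 0.3)
    uniroot(function(v) passive_pressure(v, p) - 16, c(10.01, 500))$root
  }
  bs <- c(0.02, 0.04, 0.06, 0.09)
  expect_true(all(diff(vapply(bs, vol_at, numeric(1))) < 0))
})

test_that("end-diastolic pinning solves the passive scale exactly", {
  A <- hemopulse:::pin_passive_A(116, 16, 0.05, 10)
  p <- chamber_params(E_act_max = 2, V0 = 10, A_pas = A, B_pas = 0.05,
                      t_onset = 0, t_sys = 0.3)
  expect_equal(passive_pressure(116, p), 16, tolerance = 1e-12)
  expect_error(hemopulse:::pin_passive_A(5, 16, 0.05, 10), "exceed")
})
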