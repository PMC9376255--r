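test_that("the compiled derivative matches the independent reference algebra", {
  net <- build_network(hemopulse_geometry())
  # inertial aortic valve (flow is a state)
  m1 <- cv_model(net)
  # inertance-free variant: closed-form quadratic vs the oracle's uniroot
  m2 <- cv_model(net, av = valve_params(bernoulli_coeff = 1e-4,
                                        inertance_coeff = 0))
  set.seed(1)
  for (m in list(m1, m2)) {
    f_pkg <- cv_derivative(m)
    f_ref <- oracle_derivative(m)
    for (rep in 1:20) {
      st <- literature_state(m)
      st["V_LA"] <- stats::runif(1, 40, 160)
      st["V_LV"] <- stats::runif(1, 40, 160)
      st["s_MV"] <- stats::runif(1)
      st["s_AV"] <- stats::runif(1)
      st[grep("P_term", names(st))] <- stats::runif(6, 40, 120)
      if ("Q_AV_state" %in% names(st)) st["Q_AV_state"] <- stats::runif(1, -50, 300)
      t <- stats::runif(1, 0, 1)
      d_pkg <- f_pkg(st, t)
      d_ref <- f_ref(st, t)
      expect_equal(d_pkg$dstate, unname(d_ref$dstate), tolerance = 1e-8)
      expect_equal(d_pkg$P_ao, d_ref$P_ao, tolerance = 1e-8)
      expect_equal(d_pkg$Q_AV, d_ref$Q_AV, tolerance = 1e-8)
    }
  }
})

test_that("the compiled integrator reproduces a reference RK4 trajectory", {
  m <- cv_model(build_network(hemopulse_geometry()))
  st <- literature_state(m)
  n_steps <- 40
  dt <- 5e-4 # coarse step keeps the reference cheap; same scheme both sides
  ref <- oracle_rk4(m, st, dt, n_steps)
  traj <- simulate_model(m, n_cycles = 1, dt = dt, record_dt = dt, state0 = st)
  got <- as.numeric(traj[n_steps + 1, hemopulse:::state_columns(traj)])
  expect_equal(got, unname(ref), tolerance = 1e-9)
})

test_that("a pressure-balanced state with shut valves is an equilibrium", {
  m <- cv_model(build_network(hemopulse_geometry()))
  # choose chamber volumes whose passive pressures equal the vascular 80 mmHg
  v_la <- uniroot(function(v) passive_pressure(v, m$la) - 80, c(11, 2000),
                  tol = 1e-12)$root
  v_lv <- uniroot(function(v) passive_pressure(v, m$lv) - 80, c(11, 2000),
                  tol = 1e-12)$root
  st <- literature_state(m)
  st["V_LA"] <- v_la; st["V_LV"] <- v_lv
  st["s_MV"] <- 0; st["s_AV"] <- 0
  st[grep("P_term", names(st))] <- 80
  if ("Q_AV_state" %in% names(st)) st["Q_AV_state"] <- 0
  # at an instant with no active elastance in either chamber
  d <- cv_derivative(m)(st, t = 0.7)
  expect_lt(max(abs(d$dstate)), 1e-6)
})

test_that("Kirchhoff holds at every recorded sample", {
  cal <- cached_calibration()
  traj <- cal$trajectory
  q_br <- as.matrix(traj[, paste0("Q_br_", attr(traj, "terminals"))])
  imbalance <- traj$Q_AV + traj$Q_dev - rowSums(q_br)
  expect_lt(max(abs(imbalance)), 1e-8)
})

test_that("total blood volume is conserved through the closed loop", {
  cal <- cached_calibration()
  tv <- total_volume(cal$trajectory)
  expect_lt((max(tv) - min(tv)) / tv[1], 1e-6)
})

test_that("a short run is the exact prefix of a longer one", {
  m <- cv_model(build_network(hemopulse_geometry()))
  t1 <- simulate_model(m, n_cycles = 1, dt = 2e-4)
  t3 <- simulate_model(m, n_cycles = 3, dt = 2e-4)
  expect_equal(as.data.frame(t1), as.data.frame(t3[seq_len(nrow(t1)), ]),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("divergence is reported with the failure time", {
  m <- cv_model(build_network(hemopulse_geometry()))
  st <- literature_state(m)
  st["V_LV"] <- 5000 # absurd overfilling blows up the exponential chamber
  expect_error(simulate_model(m, n_cycles = 2, state0 = st, dt = 2e-3,
                              record_dt = 2e-3),
               "diverged.*t = ")
})

test_that("initial-condition search is a fixed point at the periodic state", {
  cal <- cached_calibration()
  st <- estimate_initial_conditions(cal$model, state0 = cal$state0)
  expect_true(attr(st, "converged"))
  expect_equal(attr(st, "iterations"), 1)
  expect_equal(unname(st[1:2]), unname(cal$state0[1:2]), tolerance = 5e-3)
})

test_that("initial conditions from the literature guess converge within five cycles", {
  cal <- cached_calibration()
  st <- estimate_initial_conditions(cal$model,
                                    state0 = literature_state(cal$model))
  expect_true(attr(st, "converged"))
  expect_lte(attr(st, "iterations"), 5)
})

test_that("non-convergence raises a warning with the best-found state", {
  cal <- cached_calibration()
  expect_warning(
    st <- estimate_initial_conditions(cal$model,
                                      state0 = literature_state(cal$model),
                                      tol = 1e-12, max_iter = 2),
    "not periodic"
  )
  expect_false(attr(st, "converged"))
})

test_that("periodicity detection finds the first repeating cycle", {
  cal <- cached_calibration()
  expect_lte(detect_periodicity(cal$trajectory), 5)

  # an exactly repeating synthetic trajectory is periodic from cycle 1
  tt <- seq(0, 3, by = 1e-2)
  rep3 <- synthetic_trajectory(
    data.frame(time = tt, V_LV = 100 + 10 * sin(2 * pi * tt)),
    n_cycles = 3
  )
  expect_equal(detect_periodicity(rep3), 1)

  # a monotonically drifting trajectory never repeats
  drift <- synthetic_trajectory(
    data.frame(time = tt, V_LV = 100 + 20 * tt),
    n_cycles = 3
  )
  expect_error(detect_periodicity(drift), "periodic")
  expect_error(detect_periodicity(synthetic_trajectory(
    data.frame(time = c(0, 0.5), V_LV = c(1, 1)), n_cycles = 1)), "2 complete")
})
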