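#' Assemble the closed-loop cardiovascular model
#'
#' Connects the left atrium, mitral valve, left ventricle, aortic valve,
#' arterial network, RCR terminals, and venous return (every terminal's
#' distal resistor drains into a common venous node that feeds the atrium
#' through a single venous resistance) into one closed loop, optionally with
#' the counterpulsation device injecting flow at its insertion node.
#'
#' The state vector is `(V_LA, V_LV, s_MV, s_AV, P_term_1..P_term_nt)`:
#' chamber volumes, valve opening states, and terminal capacitor pressures.
#' Rigid aortic segments store no volume, so all node pressures and branch
#' flows are solved algebraically from the resistive tree at every
#' evaluation.
#'
#' @param network A [build_network()] object.
#' @param hr Heart rate (bpm).
#' @param lv,la [chamber_params()] for the ventricle and atrium; defaults
#'   are an HFpEF-like stiff ventricle at 60 bpm.
#' @param mv,av [valve_params()] for the mitral and aortic valves.
#' @param device A [device_params()] object, or `NULL` for no device. A
#'   device with `p_act = 0` is equivalent to no device.
#' @param R_ven Venous return resistance (mmHg.s/mL).
#' @param zc_frac Fraction of each terminal's resistance placed proximally
#'   (the lumped characteristic impedance of the branch; calibration tunes
#'   it against the measured peak flow).
#' @param state0 Optional initial state (named numeric); defaults to a
#'   literature guess via [literature_state()].
#' @return An object of class `cv_model`.
#' @export
cv_model <- function(network, hr = 60,
                     lv = NULL, la = NULL,
                     mv = valve_params(bernoulli_coeff = 1.5e-5),
                     av = valve_params(bernoulli_coeff = 1e-4,
                                       inertance_coeff = 1e-3),
                     device = NULL, R_ven = 0.02, zc_frac = 0.08,
                     state0 = NULL) {
  stopifnot(inherits(network, "cv_network"), hr > 0, R_ven > 0)
  T_cyc <- 60 / hr
  if (is.null(lv)) {
    lv <- chamber_params(E_act_max = 2.0, V0 = 10,
                         A_pas = pin_passive_A(116, 16, 0.05, 10), B_pas = 0.05,
                         t_onset = 0, t_sys = 0.5 * T_cyc, rise_frac = 0.6,
                         label = "LV")
  }
  if (is.null(la)) {
    # the atrial chamber stands for the LA plus pulmonary venous pool, so
    # its passive curve is reservoir-like (~6 mL/mmHg near 11 mmHg) and the
    # kick adds a few mmHg in late diastole
    la <- chamber_params(E_act_max = 0.12, V0 = 10, A_pas = 6, B_pas = 0.01,
                         t_onset = 0.80 * T_cyc, t_sys = 0.12 * T_cyc,
                         label = "LA")
  }
  m <- structure(
    list(network = network, hr = hr, lv = lv, la = la, mv = mv, av = av,
         device = device, R_ven = R_ven, zc_frac = zc_frac),
    class = "cv_model"
  )
  m$state0 <- state0 %||% literature_state(m)
  m
}

#' Literature-based initial state
#'
#' The starting point for the periodic-state search: a filled ventricle
#' (120 mL), a moderately filled atrium (60 mL), an open mitral and closed
#' aortic valve, and all terminal capacitors at 80 mmHg.
#'
#' @param model A `cv_model`.
#' @return A named state vector.
#' @export
literature_state <- function(model) {
  nt <- nrow(model$network$terminals)
  st <- stats::setNames(
    c(110, 120, 1, 0, rep(80, nt)),
    c("V_LA", "V_LV", "s_MV", "s_AV",
      paste0("P_term_", model$network$terminals$name))
  )
  if (model$av$inertance_coeff > 0) st <- c(st, Q_AV_state = 0)
  st
}

#' @export
print.cv_model <- function(x, ...) {
  cat("<cv_model> HR ", x$hr, " bpm, ", nrow(x$network$segments),
      " segments, ", nrow(x$network$terminals), " terminals, device ",
      if (is.null(x$device) || x$device$p_act == 0) "off" else
        sprintf("on (%.1f psi, delay %.0f ms)", x$device$p_act,
                1000 * x$device$dt_act),
      "\n", sep = "")
  invisible(x)
}

device_is_active <- function(model) {
  !is.null(model$device) && model$device$p_act > 0
}

# ---- packing for the compiled core -----------------------------------------

pack_network <- function(model) {
  net <- model$network
  G <- network_conductance(net)
  list(
    Ginv = solve(G),
    term_node = as.integer(net$terminals$node - 1L),
    Rp = net$terminals$R_proximal,
    C = net$terminals$C,
    Rd = net$terminals$R_distal,
    R_ven = model$R_ven,
    device_node = as.integer(net$device_node - 1L)
  )
}

pack_chambers <- function(model) {
  as_vec <- function(ch) c(ch$E_act_max, ch$V0, ch$A_pas, ch$B_pas,
                           ch$t_onset, ch$t_sys, ch$rise_frac %||% 0.5)
  list(la = as_vec(model$la), lv = as_vec(model$lv))
}

pack_valves <- function(model) {
  as_vec <- function(v) c(v$K_open, v$K_close, v$bernoulli_coeff,
                          v$inertance_coeff)
  list(mv = as_vec(model$mv), av = as_vec(model$av))
}

pack_device <- function(model, pa_ref0) {
  if (!device_is_active(model)) return(list(active = FALSE))
  d <- model$device
  list(active = TRUE, lambda = d$correction, C_sr = d$C_sr, k1 = d$k1,
       k2 = d$k2, t_on = d$t_on, t_off = d$t_off, dt_act = d$dt_act,
       p_act = d$p_act, coeffs = d$gain_coeffs, pa_ref0 = pa_ref0)
}

#' Derivative function of the assembled model
#'
#' Returns a closure mapping `(state, t)` to the state time-derivative plus
#' the algebraically derived quantities (chamber and node pressures, valve
#' and branch flows). This is the single-evaluation surface of the same
#' physics the compiled integrator steps.
#'
#' @param model A `cv_model`.
#' @param pa_ref Reference aortic pressure used for the device gain (mmHg).
#' @return `function(state, t)` returning a list with `dstate` and the
#'   derived quantities.
#' @export
cv_derivative <- function(model, pa_ref = 95) {
  net <- pack_network(model)
  ch <- pack_chambers(model)
  vv <- pack_valves(model)
  dev <- pack_device(model, pa_ref)
  g_act <- if (device_is_active(model)) {
    gain(pa_ref, model$device$p_act, model$device$gain_coeffs, clamp = TRUE)
  } else 0
  function(state, t = 0) {
    sim_deriv(net, ch, vv, dev, unname(state), t, model$hr, g_act, pa_ref)
  }
}
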