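#' Integrate the closed-loop model
#'
#' Fixed-step explicit RK4 integration at the model's native 0.1 ms step
#' over a whole number of cardiac cycles, recording a uniformly sampled
#' trajectory of every state variable plus the derived node pressures and
#' branch flows.
#'
#' @param model A [cv_model()].
#' @param n_cycles Number of cardiac cycles to integrate (default 10).
#' @param dt Integration step in seconds (default 1e-4).
#' @param record_dt Sampling interval of the returned trajectory (s); must
#'   be an integer multiple of `dt`. Default 1e-3.
#' @param state0 Initial state; defaults to the model's stored state.
#' @param pa_ref0 Aortic reference pressure (mmHg) for the device gain in
#'   the first cycle; later cycles use the running mean root pressure of the
#'   previous completed cycle. Defaults to the mean initial terminal
#'   pressure.
#' @return A `cv_trajectory`: a tibble with one row per sample and columns
#'   `time`, the state variables, `P_LA`, `P_LV`, `P_ao` (aortic root
#'   pressure), `Q_MV`, `Q_AV` (transvalvular flows), `P_ven`, per-branch
#'   flows `Q_br_*` and pressures `P_br_*` at the junction between the last
#'   vessel element and its terminal's proximal resistor, and the device
#'   quantities `p_sr`, `Q_dev`, `V_dev`.
#' @export
simulate_model <- function(model, n_cycles = 10, dt = 1e-4, record_dt = 1e-3,
                           state0 = NULL, pa_ref0 = NULL) {
  stopifnot(inherits(model, "cv_model"), n_cycles >= 1, dt > 0)
  stride <- round(record_dt / dt)
  if (abs(stride * dt - record_dt) > 1e-12) {
    stop("record_dt must be an integer multiple of dt", call. = FALSE)
  }
  state0 <- state0 %||% model$state0
  pa_ref0 <- pa_ref0 %||% mean(state0[-(1:4)])

  net <- pack_network(model)
  mat <- sim_core(net, pack_chambers(model), pack_valves(model),
                  pack_device(model, pa_ref0), unname(state0), model$hr, dt,
                  as.integer(n_cycles), as.integer(stride))

  tnames <- model$network$terminals$name
  qav_state <- if (model$av$inertance_coeff > 0) "Q_AV_state" else NULL
  colnames(mat) <- c(
    "time", "V_LA", "V_LV", "s_MV", "s_AV", paste0("P_term_", tnames),
    qav_state,
    "P_LA", "P_LV", "P_ao", "Q_MV", "Q_AV", "P_ven",
    paste0("Q_br_", tnames), paste0("P_br_", tnames),
    "p_sr", "Q_dev", "V_dev", "e_LA", "e_LV"
  )
  traj <- tibble::as_tibble(as.data.frame(mat))
  attr(traj, "hr") <- model$hr
  attr(traj, "dt") <- dt
  attr(traj, "record_dt") <- record_dt
  attr(traj, "n_cycles") <- n_cycles
  attr(traj, "terminals") <- tnames
  attr(traj, "has_qav") <- model$av$inertance_coeff > 0
  attr(traj, "capacitances") <- model$network$terminals$C
  class(traj) <- c("cv_trajectory", class(traj))
  traj
}

state_columns <- function(traj) {
  c("V_LA", "V_LV", "s_MV", "s_AV",
    paste0("P_term_", attr(traj, "terminals")),
    if (isTRUE(attr(traj, "has_qav"))) "Q_AV_state")
}

# rows closest to the start of each cycle (1-based cycle index)
cycle_start_rows <- function(traj) {
  T_cyc <- 60 / attr(traj, "hr")
  n <- attr(traj, "n_cycles")
  starts <- (seq_len(n + 1) - 1) * T_cyc
  vapply(starts, function(s) which.min(abs(traj$time - s)), integer(1))
}

#' Extract one cardiac cycle from a trajectory
#'
#' @param traj A `cv_trajectory`.
#' @param cycle Cycle index (1-based); negative counts from the end, so the
#'   default `-1` is the final cycle.
#' @return The rows of `traj` spanning the requested cycle (both boundary
#'   samples included).
#' @export
trajectory_cycle <- function(traj, cycle = -1) {
  n <- attr(traj, "n_cycles")
  if (cycle < 0) cycle <- n + 1 + cycle
  if (cycle < 1 || cycle > n) stop("no complete cycle at that index", call. = FALSE)
  rows <- cycle_start_rows(traj)
  out <- traj[rows[cycle]:rows[cycle + 1], ]
  attributes(out)[c("hr", "terminals", "capacitances", "record_dt")] <-
    attributes(traj)[c("hr", "terminals", "capacitances", "record_dt")]
  out
}

#' Estimate periodic initial conditions
#'
#' Starting from a literature-based guess, repeatedly simulates single
#' cycles and minimizes the squared mismatch between cycle-start and
#' cycle-end states by fixed-point refinement (the next guess is the
#' cycle-end state), stopping when the normalized squared mismatch falls
#' below `tol`.
#'
#' @param model A [cv_model()].
#' @param state0 Starting guess; defaults to [literature_state()].
#' @param tol Convergence threshold on the normalized squared mismatch
#'   (mean over states of the squared relative change; default 1e-4).
#' @param max_iter Maximum single-cycle iterations (default 20).
#' @param dt Integration step (s).
#' @return The refined state, with attributes `iterations`, `converged`,
#'   and `mismatch`. Warns and returns the best-found state if the fixed
#'   point is not reached within `max_iter`.
#' @export
estimate_initial_conditions <- function(model, state0 = NULL, tol = 1e-4,
                                        max_iter = 20, dt = 1e-4) {
  state <- state0 %||% literature_state(model)
  mism <- Inf
  for (it in seq_len(max_iter)) {
    traj <- simulate_model(model, n_cycles = 1, dt = dt, state0 = state)
    endr <- traj[nrow(traj), state_columns(traj)]
    new_state <- stats::setNames(as.numeric(endr), names(state))
    scale <- pmax(abs(state), 0.05)
    mism <- mean(((new_state - state) / scale)^2)
    state <- new_state
    if (!all(is.finite(state))) {
      warning("initial-condition search diverged; returning last finite guess")
      break
    }
    if (mism < tol) {
      attr(state, "iterations") <- it
      attr(state, "converged") <- TRUE
      attr(state, "mismatch") <- mism
      return(state)
    }
  }
  warning(sprintf(
    "initial conditions not periodic after %d iterations (mismatch %.3g)",
    max_iter, mism))
  attr(state, "iterations") <- max_iter
  attr(state, "converged") <- FALSE
  attr(state, "mismatch") <- mism
  state
}

#' Detect the first periodic cycle of a trajectory
#'
#' Finds the smallest cycle index `k` such that every state variable's
#' cycle-start value changes by less than `tol` (relative, with magnitudes
#' floored at 0.05 so near-zero valve states do not dominate) between
#' cycles `k` and `k + 1`.
#'
#' @param traj A `cv_trajectory` covering at least 2 complete cycles.
#' @param tol Relative tolerance (default 0.01).
#' @return The first periodic cycle index (1-based).
#' @export
detect_periodicity <- function(traj, tol = 0.01) {
  n <- attr(traj, "n_cycles")
  if (n < 2) stop("need at least 2 complete cycles", call. = FALSE)
  rows <- cycle_start_rows(traj)
  sc <- state_columns(traj)
  X <- as.matrix(traj[rows, sc])
  floor_scale <- pmax(0.02 * apply(abs(X), 2, max), 0.05)
  for (k in seq_len(n - 1)) {
    rel <- abs(X[k + 1, ] - X[k, ]) / pmax(abs(X[k, ]), floor_scale)
    if (all(rel < tol)) return(k)
  }
  stop("trajectory never reaches a periodic state within tolerance",
       call. = FALSE)
}

#' Total stored blood volume along a trajectory
#'
#' Chamber volumes plus terminal capacitor stored volumes (`C * P`) plus
#' the device stored volume. In the rigid-vessel closed loop this total is
#' conserved by construction; its drift is a numerical-soundness check.
#'
#' @param traj A `cv_trajectory`.
#' @return Numeric vector of total volume (mL) per sample.
#' @export
total_volume <- function(traj) {
  Cc <- attr(traj, "capacitances")
  P <- as.matrix(traj[, paste0("P_term_", attr(traj, "terminals"))])
  traj$V_LA + traj$V_LV + as.numeric(P %*% Cc) + traj$V_dev
}
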