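#' Patient hemodynamic targets
#'
#' The target table for calibration. The defaults are the HFpEF study
#' patient: heart rate 60 bpm, aortic root pressures 68/150 mmHg, peak
#' aortic flow 266 mL/s, cardiac output 5.17 L/min, upper-body flow
#' fraction 29% (coronaries included), LV volumes 116/36 mL, and an
#' echo-estimated end-diastolic pressure of 16 mmHg.
#'
#' @param hr Heart rate (bpm).
#' @param dbp,sbp Diastolic and systolic aortic root pressure (mmHg).
#' @param peak_flow Peak aortic root flow (mL/s).
#' @param co Cardiac output (L/min).
#' @param upper_split Upper-body flow percentage, coronaries included.
#' @param edv,esv End-diastolic and end-systolic LV volume (mL).
#' @param edp End-diastolic LV pressure (mmHg).
#' @return A `patient_targets` list.
#' @export
patient_targets <- function(hr = 60, dbp = 68, sbp = 150, peak_flow = 266,
                            co = 5.17, upper_split = 29, edv = 116, esv = 36,
                            edp = 16) {
  if (!(sbp > dbp && dbp > 0)) {
    stop("invalid targets: need sbp > dbp > 0", call. = FALSE)
  }
  if (!(edv > esv && esv > 0)) {
    stop("invalid targets: need edv > esv > 0", call. = FALSE)
  }
  if (!(upper_split > 0 && upper_split < 100)) {
    stop("invalid targets: upper_split must be in (0, 100)", call. = FALSE)
  }
  stopifnot(hr > 0, peak_flow > 0, co > 0, edp > 0)
  structure(list(hr = hr, dbp = dbp, sbp = sbp, peak_flow = peak_flow,
                 co = co, upper_split = upper_split, edv = edv, esv = esv,
                 edp = edp),
            class = "patient_targets")
}

#' Default per-branch flow fractions
#'
#' Mean-flow percentages per branch used by the flow-split stage:
#' descending aorta 70.27, coronaries 3.00, right subclavian 7.45, right
#' carotid 9.18, left subclavian 5.25, left carotid 4.86 (the actuator-off
#' split table; upper body including coronaries sums to 29.73%, matching
#' the patient's 29/71 split within one percentage point).
#'
#' @return Named numeric vector of percentages.
#' @export
default_branch_fractions <- function() {
  c(descending_aorta = 70.27, coronaries = 3.00, right_subclavian = 7.45,
    right_carotid = 9.18, left_subclavian = 5.25, left_carotid = 4.86)
}

#' Mean arterial pressure estimate from cuff pressures
#'
#' The standard cuff convention `MAP = DBP + (SBP - DBP) / 3`.
#'
#' @param dbp,sbp Diastolic and systolic pressure (mmHg).
#' @return MAP in mmHg.
#' @export
map_estimate <- function(dbp, sbp) dbp + (sbp - dbp) / 3

#' Target total systemic resistance
#'
#' The Ohmic estimate `MAP / CO` used to initialize the resistance stage.
#'
#' @param targets A [patient_targets()].
#' @return Resistance in mmHg.s/mL.
#' @export
target_total_resistance <- function(targets) {
  map_estimate(targets$dbp, targets$sbp) / (targets$co * 1000 / 60)
}

# path resistance from the aortic root to a terminal's attachment node
path_resistance <- function(network, terminal_name) {
  seg <- network$segments
  ter <- network$terminals
  nd <- ter$node[ter$name == terminal_name]
  r <- 0
  repeat {
    i <- which(seg$to_node == nd)
    if (!length(i)) break
    r <- r + seg$resistance[i]
    nd <- seg$from_node[i]
    if (nd == network$root_node) break
  }
  r
}

#' Total effective systemic resistance of a model
#'
#' Parallel combination of the per-branch path resistances (segments plus
#' terminal proximal and distal resistors) plus the venous return
#' resistance: the DC resistance from the aortic root back to the atrium.
#'
#' @param model A `cv_model`.
#' @return Resistance in mmHg.s/mL.
#' @export
total_systemic_resistance <- function(model) {
  ter <- model$network$terminals
  rp <- vapply(ter$name, function(nm) path_resistance(model$network, nm),
               numeric(1))
  rtot <- rp + ter$R_proximal + ter$R_distal
  1 / sum(1 / rtot) + model$R_ven
}

# quick warm-started run -> summary + end state
run_probe <- function(model, state, n_cycles = 5, dt = 2e-4) {
  traj <- simulate_model(model, n_cycles = n_cycles, dt = dt, state0 = state)
  endr <- traj[nrow(traj), state_columns(traj)]
  list(summary = summarize_cycle(traj, -1),
       state = stats::setNames(as.numeric(endr), names(state)),
       traj = traj)
}

# bounded damped secant on a scalar knob; f must return the measured metric
secant_drive <- function(f, x0, step, target, tol, lower = -Inf,
                         upper = Inf, max_iter = 6) {
  fs <- function(x) tryCatch(f(x), error = function(e) NA_real_)
  x1 <- min(max(x0 + step, lower), upper)
  y0 <- fs(x0)
  if (!is.finite(y0)) return(x0)
  if (abs(y0 - target) <= tol * max(abs(target), 1)) return(x0)
  y1 <- fs(x1)
  if (!is.finite(y1)) return(x0)
  for (i in seq_len(max_iter)) {
    if (abs(y1 - target) <= tol * max(abs(target), 1)) return(x1)
    slope <- (y1 - y0) / (x1 - x0)
    if (!is.finite(slope) || slope == 0) break
    x2 <- x1 + (target - y1) / slope
    x2 <- min(max(x2, lower), upper)
    if (x2 == x1) break
    y0 <- y1; x0 <- x1
    x1 <- x2; y1 <- fs(x1)
    if (!is.finite(y1)) return(x0)
  }
  x1
}

# ---- calibration stages ----------------------------------------------------

#' Stage 1: set the total systemic resistance
#'
#' Assigns terminal distal resistances so the total effective systemic
#' resistance equals the Ohmic target `MAP / CO`, distributing branch path
#' resistances inversely to the requested flow fractions (Windkessel time
#' constants stay uniform across beds), then optionally trims the overall
#' scale by short simulations so the simulated mean root pressure hits the
#' MAP target.
#'
#' @param model A `cv_model`.
#' @param targets A [patient_targets()].
#' @param fractions Named branch percentages (default
#'   [default_branch_fractions()]).
#' @param state Warm-start state (default the model's).
#' @param refine Run the simulation-based trim (default TRUE).
#' @param map_target Override for the trimmed mean-pressure target (mmHg).
#' @return List with the updated `model` and `state`.
#' @export
stage_total_resistance <- function(model, targets,
                                   fractions = default_branch_fractions(),
                                   state = NULL, refine = TRUE,
                                   map_target = NULL) {
  state <- state %||% model$state0
  f <- fractions[model$network$terminals$name]
  f <- f / sum(f)
  r_target <- target_total_resistance(targets)
  r_arterial <- r_target - model$R_ven
  if (r_arterial <= 0) stop("stage failure: venous resistance exceeds MAP/CO",
                            call. = FALSE)
  # per-branch total path resistance inversely proportional to fraction
  ter <- model$network$terminals
  r_path <- r_arterial / f
  r_seg <- vapply(ter$name, function(nm) path_resistance(model$network, nm),
                  numeric(1))
  r_term <- r_path - r_seg
  if (any(r_term <= 0)) stop("stage failure: segment resistance exceeds branch budget",
                             call. = FALSE)
  zc <- model$zc_frac %||% 0.08
  ter$R_proximal <- zc * r_term
  ter$R_distal <- (1 - zc) * r_term
  ter$C <- sum(ter$C) * f / sum(f)
  model$network$terminals <- ter

  if (refine) {
    map_t <- map_target %||% map_estimate(targets$dbp, targets$sbp)
    env <- environment()
    meas <- function(scale) {
      m2 <- env$model
      m2$network$terminals$R_distal <- ter$R_distal * scale
      pr <- run_probe(m2, env$state)
      env$state <- pr$state
      env$last <- m2
      # trapezoidal mean of root pressure over the final cycle
      cy <- trajectory_cycle(pr$traj, -1)
      mean(cy$P_ao)
    }
    sc <- secant_drive(meas, 1, 0.1, map_t, tol = 0.004,
                       lower = 0.3, upper = 3)
    model$network$terminals$R_distal <- ter$R_distal * sc
  }
  list(model = model, state = state)
}

#' Stage 2: match the per-branch flow splits
#'
#' Iteratively rescales each branch's terminal resistance by the ratio of
#' its measured to requested mean-flow fraction, renormalizing after each
#' pass so the total effective resistance is preserved, until every branch
#' fraction is within half a percentage point of its request.
#'
#' @inheritParams stage_total_resistance
#' @param max_iter Maximum refinement passes.
#' @return List with the updated `model`, `state`, and the final measured
#'   `fractions`.
#' @export
stage_flow_splits <- function(model, targets,
                              fractions = default_branch_fractions(),
                              state = NULL, max_iter = 4) {
  state <- state %||% model$state0
  if (abs(sum(fractions) - 100) > 0.5) {
    stop("input error: branch fractions must sum to 100 +/- 0.5", call. = FALSE)
  }
  f_req <- fractions[model$network$terminals$name] / 100
  r_total0 <- total_systemic_resistance(model)
  meas <- NULL
  for (it in seq_len(max_iter)) {
    pr <- run_probe(model, state)
    state <- pr$state
    meas <- as.numeric(pr$summary[paste0("split_", model$network$terminals$name)]) / 100
    if (max(abs(meas - f_req)) < 0.002) break
    ter <- model$network$terminals
    zc <- model$zc_frac %||% 0.08
    r_term <- ter$R_proximal + ter$R_distal
    r_term <- r_term * (meas / f_req)
    ter$R_proximal <- zc * r_term
    ter$R_distal <- (1 - zc) * r_term
    model$network$terminals <- ter
    # restore the total within 1%
    drift <- total_systemic_resistance(model) / r_total0
    model$network$terminals$R_distal <- model$network$terminals$R_distal / drift
  }
  list(model = model, state = state,
       fractions = stats::setNames(100 * meas, model$network$terminals$name))
}

#' Stage 3: match the aortic pulse pressure
#'
#' Uniformly scales the terminal capacitances (bounded secant search) until
#' the simulated aortic root pulse pressure matches the target
#' `SBP - DBP`.
#'
#' @inheritParams stage_total_resistance
#' @param pp_target Override for the pulse-pressure target (mmHg).
#' @return List with the updated `model` and `state`.
#' @export
stage_compliance <- function(model, targets, state = NULL, pp_target = NULL) {
  state <- state %||% model$state0
  pp_t <- pp_target %||% (targets$sbp - targets$dbp)
  C0 <- model$network$terminals$C
  env <- environment()
  meas <- function(scale) {
    m2 <- env$model
    m2$network$terminals$C <- C0 * scale
    pr <- run_probe(m2, env$state)
    env$state <- pr$state
    pr$summary$peak_systolic - pr$summary$diastolic
  }
  sc <- secant_drive(meas, 1, -0.2, pp_t, tol = 0.01, lower = 0.1, upper = 10)
  model$network$terminals$C <- C0 * sc
  list(model = model, state = state)
}

# distribute an SV surplus between raising EDV and lowering ESV, keeping
# each within its printed error headroom; any unallocatable remainder
# shifts the CO aim (within a fraction of a percent).
allocate_volumes <- function(targets, extra_sv = 0) {
  sv_star <- targets$co * 1000 / targets$hr + extra_sv
  sv_t <- targets$edv - targets$esv
  d <- sv_star - sv_t
  if (abs(d) / sv_star < 0.005) {
    return(list(edv = targets$edv, esv = targets$esv, co = targets$co))
  }
  cap_e <- 0.024 * targets$edv
  cap_s <- 0.079 * targets$esv
  x <- sign(d) * min(abs(d) * cap_e / (cap_e + cap_s), cap_e)
  y <- sign(d) * min(abs(d) - abs(x), cap_s)
  resid <- d - x - y
  co_shift <- max(min(resid * targets$hr / 1000, 0.004 * targets$co),
                  -0.004 * targets$co)
  list(edv = targets$edv + x, esv = targets$esv - y,
       co = targets$co - co_shift)
}

#' Stage 4: tune the heart
#'
#' Pins the passive (diastolic) LV curve so the end-diastolic
#' pressure--volume point is met exactly, then alternates bounded secant
#' searches on the three cardiac knobs: total stressed blood volume (added
#' to the initial atrial volume) drives cardiac output, peak active
#' elastance drives end-systolic volume, and systolic duration drives peak
#' aortic flow. Where the printed volume targets are not exactly consistent
#' with the printed cardiac output (`EDV - ESV` vs `CO / HR`), the surplus
#' is split between the volumes within their printed error headroom.
#'
#' @inheritParams stage_total_resistance
#' @param rounds Alternation rounds (default 3).
#' @return List with the updated `model` and `state`.
#' @export
stage_heart <- function(model, targets, state = NULL, rounds = 3) {
  state <- state %||% model$state0
  env <- environment()
  env$extra_sv <- 0

  probe <- function() {
    pr <- run_probe(env$model, env$state)
    env$state <- pr$state
    pr
  }

  for (r in seq_len(rounds)) {
    alloc <- allocate_volumes(targets, env$extra_sv)
    # pin the passive curve at the allocated end-diastolic point
    lv <- env$model$lv
    lv$A_pas <- pin_passive_A(alloc$edv, targets$edp, lv$B_pas, lv$V0)
    env$model$lv <- lv

    # total stressed volume -> cardiac output (the shift is applied from a
    # fixed reference state; once simulated, the added volume persists in
    # the conserved closed loop)
    state_ref <- env$state
    co_meas <- function(dv) {
      st <- state_ref
      st["V_LA"] <- max(st["V_LA"] + dv, 5)
      pr <- run_probe(env$model, st)
      env$state <- pr$state
      pr$summary$co
    }
    secant_drive(co_meas, 0, 8, alloc$co, tol = 0.002, lower = -40, upper = 40)

    # peak active elastance -> end-systolic volume
    esv_meas <- function(emax) {
      env$model$lv$E_act_max <- emax
      probe()$summary$esv
    }
    e0 <- env$model$lv$E_act_max
    env$model$lv$E_act_max <- secant_drive(esv_meas, e0, 0.3, alloc$esv,
                                           tol = 0.004, lower = 0.5, upper = 10)

    # systolic duration -> peak aortic flow
    pf_meas <- function(tsys) {
      env$model$lv$t_sys <- tsys
      probe()$summary$peak_flow
    }
    t0 <- env$model$lv$t_sys
    T_cyc <- 60 / env$model$hr
    env$model$lv$t_sys <- secant_drive(pf_meas, t0, 0.04, targets$peak_flow,
                                       tol = 0.003, lower = 0.25 * T_cyc,
                                       upper = 0.72 * T_cyc)

    # measure the valve back-leak and the realized ED point for the next round
    pr <- probe()
    env$extra_sv <- (pr$summary$edv - pr$summary$esv) -
      pr$summary$co * 1000 / targets$hr
    # re-pin the passive curve at the realized cycle-start volume so the
    # measured EDP lands on the target
    v_start <- trajectory_cycle(pr$traj, -1)$V_LV[1]
    env$model$lv$A_pas <- pin_passive_A(v_start, targets$edp,
                                        env$model$lv$B_pas, env$model$lv$V0)
  }
  list(model = env$model, state = env$state)
}

# ---- full calibration ------------------------------------------------------

envelope_spec <- function() {
  tibble::tibble(
    quantity = c("hr", "sbp", "peak_flow", "co", "flow_split", "edv", "edp",
                 "dbp", "esv"),
    bound_pct = c(5, 5, 5, 5, 5, 5, 5, 7, 8),
    signed = c(rep(FALSE, 7), TRUE, FALSE)
  )
}

#' Calibrate the closed-loop model to patient targets
#'
#' Runs the four tuning stages (total resistance, flow splits, compliance,
#' heart) inside up to `n_outer` refinement loops, with the internal mean-
#' and pulse-pressure aims nudged each loop by the residual systolic and
#' diastolic errors. The calibrated model is then integrated to periodic
#' steady state (10 cycles at the 0.1 ms step) and compared to every
#' target.
#'
#' The accepted error envelope mirrors the study's printed agreement:
#' relative errors of at most 5% on heart rate, systolic pressure, peak
#' flow, cardiac output, flow split, EDV, and EDP; at most +7% (signed) on
#' diastolic pressure; and within 8% on ESV.
#'
#' @param targets A [patient_targets()].
#' @param geometry Geometry description or path (default the shipped
#'   synthetic aortic tree).
#' @param fractions Branch flow percentages (default
#'   [default_branch_fractions()], rescaled so the upper-body sum matches
#'   `targets$upper_split` when they disagree by more than 1 point).
#' @param model Optionally, a pre-built `cv_model` to start from.
#' @param n_outer Maximum outer refinement loops (default 5).
#' @param seed Integer seed (the search is deterministic; the seed is
#'   recorded for provenance).
#' @param dt Final-run integration step (s).
#' @param strict Error (rather than warn) when the envelope is not met.
#' @param verbose Print per-loop residuals.
#' @return A `cv_calibration`: list with the tuned `model`, periodic
#'   `state0`, final `trajectory`, `summary`, tidy `report` and `splits`
#'   tables, `envelope_ok`, and `periodic_cycle`.
#' @export
calibrate <- function(targets = patient_targets(),
                      geometry = hemopulse_geometry(),
                      fractions = default_branch_fractions(),
                      model = NULL, n_outer = 5, seed = 0, dt = 1e-4,
                      strict = FALSE, verbose = FALSE) {
  stopifnot(inherits(targets, "patient_targets"))
  set.seed(seed)
  if (is.null(model)) {
    network <- build_network(geometry)
    model <- cv_model(network, hr = targets$hr)
  }

  # reconcile requested branch fractions with the patient's upper split
  up <- sum(fractions) - fractions[["descending_aorta"]]
  if (abs(up - targets$upper_split) > 1) {
    scale_up <- targets$upper_split / up
    fractions[names(fractions) != "descending_aorta"] <-
      fractions[names(fractions) != "descending_aorta"] * scale_up
    fractions[["descending_aorta"]] <- 100 - targets$upper_split
  }

  state <- estimate_initial_conditions(model, tol = 1e-3, max_iter = 6,
                                       dt = 2e-4)

  # coarse placement by the four stages
  st <- stage_total_resistance(model, targets, fractions, state,
                               refine = FALSE)
  model <- st$model; state <- st$state
  st <- stage_flow_splits(model, targets, fractions, state, max_iter = 3)
  model <- st$model; state <- st$state
  st <- stage_compliance(model, targets, state)
  model <- st$model; state <- st$state
  st <- stage_heart(model, targets, state, rounds = 1)
  model <- st$model; state <- st$state

  # joint damped refinement: every knob is nudged from one probe per pass,
  # which tolerates the strong coupling between afterload, preload, and
  # contractility far better than sequential line searches
  refine_pass <- function(dt, n_cycles, damp, n_iter, tol_mult = 1) {
    map_t <- map_estimate(targets$dbp, targets$sbp)
    pp_t <- targets$sbp - targets$dbp
    for (it in seq_len(n_iter)) {
      pr <- run_probe(model, state, n_cycles = n_cycles, dt = dt)
      state <<- pr$state
      s <- pr$summary
      leak <- (s$edv - s$esv) - s$co * 1000 / targets$hr
      alloc <- allocate_volumes(targets, extra_sv = max(min(leak, 3), 0))

      err <- c(sbp = (s$peak_systolic - targets$sbp) / targets$sbp,
               dbp = (s$diastolic - targets$dbp) / targets$dbp,
               co = (s$co - alloc$co) / alloc$co,
               esv = (s$esv - alloc$esv) / alloc$esv,
               pf = (s$peak_flow - targets$peak_flow) / targets$peak_flow,
               edp = (s$edp - targets$edp) / targets$edp)
      if (verbose) {
        message(sprintf(
          "  refine %2d: sbp %+5.3f dbp %+5.3f co %+5.3f esv %+5.3f pf %+5.3f edp %+5.3f",
          it, err[["sbp"]], err[["dbp"]], err[["co"]], err[["esv"]],
          err[["pf"]], err[["edp"]]))
      }
      tol <- c(sbp = 0.005, dbp = 0.01, co = 0.002, esv = 0.006,
               pf = 0.005, edp = 0.005) * tol_mult
      if (all(abs(err) < tol)) break

      map_sim <- map_estimate(s$diastolic, s$peak_systolic)
      pp_sim <- s$peak_systolic - s$diastolic
      # anchor the arterial resistance on the systemic vascular resistance
      # implied by a mean LA pressure of 0.7 * EDP (the Frank-Starling
      # operating point); a weak secondary factor trims residual MAP error
      lap_t <- 0.7 * targets$edp
      svr_t <- (map_t - lap_t) / (targets$co * 1000 / 60)
      svr_sim <- (map_sim - s$mean_lap) / (s$co * 1000 / 60)
      # the SVR term is a guardrail with a deadband: it only acts when the
      # operating point drifts far from the physiological resistance, so
      # near equilibrium the mean pressure is pinned exactly
      svr_dev <- svr_t / svr_sim
      svr_excess <- svr_dev / min(max(svr_dev, 0.8), 1.25)
      r_fac <- (map_t / map_sim)^damp * svr_excess^(0.5 * damp)
      c_fac <- (pp_sim / pp_t)^damp
      ter <- model$network$terminals
      ter$R_proximal <- ter$R_proximal * r_fac
      ter$R_distal <- ter$R_distal * r_fac
      ter$C <- ter$C * c_fac
      model$network$terminals <<- ter

      # contractility and timing
      model$lv$E_act_max <<- min(max(
        model$lv$E_act_max * (s$esv / alloc$esv)^damp, 0.3), 12)
      T_cyc <- 60 / model$hr
      model$lv$t_sys <<- min(max(
        model$lv$t_sys * (s$peak_flow / targets$peak_flow)^(0.4 * damp),
        0.15 * T_cyc), 0.72 * T_cyc)
      # a slower elastance upstroke spreads ejection over a longer window
      # and lowers the flow peak; the rise fraction and activation duration
      # are the honest knobs for the CMR-measured peak flow
      model$lv$rise_frac <<- min(max(
        model$lv$rise_frac * (s$peak_flow / targets$peak_flow)^(0.5 * damp),
        0.3), 0.88)
      # a mildly restrictive effective orifice takes up what the activation
      # shape cannot, at a clinically mild transvalvular gradient
      model$av$bernoulli_coeff <<- min(max(
        model$av$bernoulli_coeff * (s$peak_flow / targets$peak_flow)^(0.8 * damp),
        8e-5), 1e-3)

      # total stressed volume -> cardiac output
      dsv <- (alloc$co - s$co) * 1000 / 60
      state["V_LA"] <<- max(state[["V_LA"]] + max(min(2 * dsv, 25), -25), 5)

      # re-pin the passive curve at the realized cycle-start volume
      v_start <- trajectory_cycle(pr$traj, -1)$V_LV[1]
      dsv_pred <- alloc$edv - s$edv  # anticipated filling shift
      model$lv$A_pas <<- pin_passive_A(v_start + 0.5 * dsv_pred,
                                       targets$edp, model$lv$B_pas,
                                       model$lv$V0)

      # keep the branch splits pinned (ratio update, total preserved)
      if (it %% 4 == 0) {
        f_req <- fractions[ter$name] / 100
        meas <- as.numeric(s[paste0("split_", ter$name)]) / 100
        r_tot0 <- total_systemic_resistance(model)
        r_term <- (ter$R_proximal + ter$R_distal) * (meas / f_req)^0.8
        ter$R_proximal <- model$zc_frac * r_term
        ter$R_distal <- (1 - model$zc_frac) * r_term
        model$network$terminals <<- ter
        drift <- total_systemic_resistance(model) / r_tot0
        model$network$terminals$R_distal <<-
          model$network$terminals$R_distal / drift
      }
    }
    invisible(NULL)
  }

  for (loop in seq_len(n_outer)) {
    refine_pass(dt = 2e-4, n_cycles = 5, damp = 0.7, n_iter = 25)
    st <- stage_flow_splits(model, targets, fractions, state, max_iter = 2)
    model <- st$model; state <- st$state
    refine_pass(dt = dt, n_cycles = 6, damp = 0.5, n_iter = 10)
    # verification probe at the native step
    pr <- run_probe(model, state, n_cycles = 6, dt = dt)
    state <- pr$state
    s <- pr$summary
    ok <- abs(s$peak_systolic - targets$sbp) < 0.008 * targets$sbp &&
      abs(s$diastolic - targets$dbp) < 0.02 * targets$dbp &&
      abs(s$co - targets$co) < 0.004 * targets$co &&
      abs(s$peak_flow - targets$peak_flow) < 0.008 * targets$peak_flow
    if (ok) break
  }

  # final run at the native step from refined periodic initial conditions
  state0 <- estimate_initial_conditions(model, state0 = state, tol = 1e-6,
                                        max_iter = 10, dt = dt)
  model$state0 <- stats::setNames(as.numeric(state0), names(state))
  traj <- simulate_model(model, n_cycles = 10, dt = dt)
  summary <- summarize_cycle(traj, -1)
  periodic_cycle <- detect_periodicity(traj)

  report <- calibration_report(summary, targets)
  splits <- tibble::tibble(
    vessel = model$network$terminals$name,
    requested_pct = as.numeric(fractions[model$network$terminals$name]),
    model_pct = as.numeric(summary[paste0("split_",
                                          model$network$terminals$name)])
  )

  env <- envelope_spec()
  err <- report$delta_pct[match(env$quantity, report$quantity)]
  env$ok <- ifelse(env$signed, err <= env$bound_pct, abs(err) <= env$bound_pct)
  if (!all(env$ok)) {
    offenders <- paste(env$quantity[!env$ok], collapse = ", ")
    msg <- sprintf("calibration envelope not met for: %s", offenders)
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }

  structure(
    list(model = model, state0 = model$state0, targets = targets,
         trajectory = traj, summary = summary, report = report,
         splits = splits, envelope = env, envelope_ok = all(env$ok),
         periodic_cycle = periodic_cycle, seed = seed),
    class = "cv_calibration"
  )
}

calibration_report <- function(summary, targets) {
  model_vals <- c(
    hr = summary$hr, dbp = summary$diastolic, sbp = summary$peak_systolic,
    peak_flow = summary$peak_flow, co = summary$co,
    flow_split = summary$upper_split, edv = summary$edv, esv = summary$esv,
    edp = summary$edp
  )
  patient_vals <- c(
    hr = targets$hr, dbp = targets$dbp, sbp = targets$sbp,
    peak_flow = targets$peak_flow, co = targets$co,
    flow_split = targets$upper_split, edv = targets$edv, esv = targets$esv,
    edp = targets$edp
  )
  delta <- model_vals - patient_vals
  # the flow split is compared in percentage points, as printed
  delta_pct <- ifelse(names(model_vals) == "flow_split", delta,
                      100 * delta / patient_vals)
  tibble::tibble(
    quantity = names(model_vals),
    patient = unname(patient_vals),
    model = unname(model_vals),
    delta_abs = unname(delta),
    delta_pct = unname(delta_pct)
  )
}

#' @export
print.cv_calibration <- function(x, ...) {
  cat("<cv_calibration> envelope ",
      if (x$envelope_ok) "met" else "NOT met",
      ", periodic by cycle ", x$periodic_cycle, "\n", sep = "")
  print(x$report)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a calibration: the per-target comparison table
#'
#' @param x A `cv_calibration`.
#' @param ... Unused.
#' @return A tibble with columns `quantity`, `patient`, `model`,
#'   `delta_abs`, `delta_pct`.
#' @method tidy cv_calibration
#' @export
tidy.cv_calibration <- function(x, ...) x$report

#' Glance at a calibration: one-row fit summary
#'
#' @param x A `cv_calibration`.
#' @param ... Unused.
#' @return A one-row tibble with the maximum absolute relative error, the
#'   envelope flag, and the first periodic cycle.
#' @method glance cv_calibration
#' @export
glance.cv_calibration <- function(x, ...) {
  tibble::tibble(
    max_abs_err_pct = max(abs(x$report$delta_pct)),
    envelope_ok = x$envelope_ok,
    periodic_cycle = x$periodic_cycle,
    seed = x$seed
  )
}

#' Write a calibration report to CSV
#'
#' Writes the target comparison table (patient, model, absolute and
#' relative differences) and the branch flow-split table.
#'
#' @param calibration A `cv_calibration`.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
report_calibration <- function(calibration, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "targets.csv")
  p2 <- file.path(dir, "splits.csv")
  readr::write_csv(calibration$report, p1)
  readr::write_csv(calibration$splits, p2)
  invisible(c(p1, p2))
}
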