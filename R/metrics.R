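#' Hemodynamic summary of one cardiac cycle
#'
#' Computes the standard hemodynamic metrics from one (ideally periodic)
#' cycle of a trajectory: cardiac output as mean aortic root flow converted
#' to L/min, peak systolic and minimum diastolic aortic root pressure, peak
#' aortic root flow, end-diastolic volume (LV volume at mitral valve
#' closure), end-systolic volume (minimum LV volume), end-diastolic
#' pressure (LV pressure at cycle start, the R-wave instant), stroke work
#' as the area of the LV pressure--volume loop (in mmHg.mL and in joules),
#' arterial elastance `EA = ESP/CO` with ESP the LV pressure at aortic
#' valve closure (state first below 0.05 after peak ejection) and CO in
#' L/min, mean left atrial pressure, mean coronary flow, and per-branch
#' mean-flow percentages.
#'
#' @param traj A `cv_trajectory`.
#' @param cycle Cycle index passed to [trajectory_cycle()]; default the
#'   final cycle.
#' @return A one-row tibble (`hemo_summary`).
#' @export
summarize_cycle <- function(traj, cycle = -1) {
  cy <- trajectory_cycle(traj, cycle)
  tnames <- attr(traj, "terminals")
  hr <- attr(traj, "hr")

  tt <- cy$time
  wmean <- function(x) { # trapezoid time average
    sum(diff(tt) * (utils::head(x, -1) + utils::tail(x, -1)) / 2) / diff(range(tt))
  }

  co <- wmean(cy$Q_AV) * 0.06 # mL/s -> L/min

  # EDV at mitral valve closure (opening state first drops below 0.05)
  i_mvc <- which(cy$s_MV < 0.05)
  edv <- if (length(i_mvc)) cy$V_LV[min(i_mvc)] else max(cy$V_LV)
  esv <- min(cy$V_LV)
  edp <- cy$P_LV[1]

  # PV-loop area; the ejection loop is traversed so that the time integral
  # of P dV is minus the enclosed area
  sw_mmhg_ml <- -sum(diff(cy$V_LV) * (utils::head(cy$P_LV, -1) +
                                        utils::tail(cy$P_LV, -1)) / 2)

  # end-systolic pressure: LV pressure at aortic valve closure
  i_pk <- which.max(cy$Q_AV)
  i_avc <- which(cy$s_AV < 0.05 & seq_along(cy$s_AV) > i_pk)
  esp <- if (length(i_avc) && max(cy$s_AV) >= 0.05) cy$P_LV[min(i_avc)] else NA_real_

  branch_means <- vapply(tnames, function(nm) wmean(cy[[paste0("Q_br_", nm)]]),
                         numeric(1))
  splits <- 100 * branch_means / sum(branch_means)

  out <- tibble::tibble(
    hr = hr,
    co = co,
    peak_systolic = max(cy$P_ao),
    diastolic = min(cy$P_ao),
    peak_flow = max(cy$Q_AV),
    edv = edv, esv = esv, edp = edp,
    stroke_work = sw_mmhg_ml,
    stroke_work_J = sw_mmhg_ml * 1.33322e-4,
    ea = esp / co,
    esp = esp,
    mean_lap = wmean(cy$P_LA),
    coronary_flow = 0.06 * branch_means[["coronaries"]],
    upper_split = 100 - splits[["descending_aorta"]]
  )
  for (nm in tnames) out[[paste0("split_", nm)]] <- splits[[nm]]
  class(out) <- c("hemo_summary", class(out))
  out
}

#' Root-mean-square error between two flow waveforms
#'
#' The reference series is resampled onto the model timing by linear
#' interpolation; the RMSE is taken over the overlapping time support.
#'
#' @param model_flow,reference_flow Data frames with columns `time` (s) and
#'   `flow` (mL/s), each covering one cycle.
#' @return RMSE in mL/s.
#' @export
waveform_rmse <- function(model_flow, reference_flow) {
  lo <- max(min(model_flow$time), min(reference_flow$time))
  hi <- min(max(model_flow$time), max(reference_flow$time))
  keep <- model_flow$time >= lo & model_flow$time <= hi
  if (hi <= lo || sum(keep) < 2) {
    stop("non-overlapping time supports", call. = FALSE)
  }
  ref <- stats::approx(reference_flow$time, reference_flow$flow,
                       xout = model_flow$time[keep])$y
  sqrt(mean((model_flow$flow[keep] - ref)^2))
}

sweep_point <- function(model, n_cycles, dt) {
  traj <- simulate_model(model, n_cycles = n_cycles, dt = dt)
  s <- summarize_cycle(traj, -1)
  s$periodic_cycle <- tryCatch(detect_periodicity(traj), error = function(e) NA_integer_)
  s
}

#' Configure the mounted device on a model
#'
#' Returns the model with its device set to the given actuation pressure and
#' delay; when a bench grid is supplied, the measured contraction timings
#' `t_on`/`t_off` are interpolated from it at the reference loop pressure.
#'
#' @param model A `cv_model` whose `device` field is a [device_params()]
#'   template.
#' @param p_act Actuation pressure (psi); 0 disables the device.
#' @param dt_act Actuation delay from the R wave (s).
#' @param bench Optional bench grid for [timing_lookup()].
#' @param pa_ref Reference loop pressure (mmHg) for the timing lookup.
#' @return The updated `cv_model`.
#' @export
apply_device <- function(model, p_act, dt_act, bench = NULL, pa_ref = NULL) {
  stopifnot(!is.null(model$device))
  d <- model$device
  d$p_act <- p_act
  d$dt_act <- dt_act
  if (!is.null(bench) && p_act > 0) {
    pa_ref <- pa_ref %||% 95
    tim <- timing_lookup(p_act, pa_ref, bench)
    d$t_on <- tim$t_on
    d$t_off <- tim$t_off
  }
  model$device <- d
  model
}

#' Sweep the actuation delay
#'
#' Runs the coupled model at each actuation delay (the device template,
#' gain surface, and actuation pressure come from `model$device`), plus the
#' actuator-off baseline, and summarizes the periodic steady state of each
#' run.
#'
#' @param model A calibrated `cv_model` with a configured device.
#' @param delays_ms Actuation delays in ms (default 50 to 950 by 50).
#' @param p_act Actuation pressure in psi (default the device's).
#' @param bench Optional bench grid for per-point `t_on`/`t_off` lookup.
#' @param n_cycles,dt Simulation length and step per point.
#' @return A `cv_sweep` tibble: the baseline row (`baseline = TRUE`,
#'   `delay_ms = NA`) followed by one row per delay. Points whose run fails
#'   carry `failed = TRUE` and NA metrics.
#' @export
delay_sweep <- function(model, delays_ms = seq(50, 950, by = 50),
                        p_act = NULL, bench = NULL, n_cycles = 10, dt = 1e-4) {
  p_act <- p_act %||% model$device$p_act
  base_model <- model
  base_model$device <- NULL
  base <- sweep_point(base_model, n_cycles, dt)
  rows <- purrr::map(delays_ms, function(d_ms) {
    m <- apply_device(model, p_act, d_ms / 1000, bench)
    tryCatch(
      dplyr::mutate(sweep_point(m, n_cycles, dt), failed = FALSE),
      error = function(e) tibble::tibble(failed = TRUE)
    )
  })
  out <- dplyr::bind_rows(
    dplyr::mutate(base, baseline = TRUE, delay_ms = NA_real_,
                  p_act_psi = 0, failed = FALSE),
    dplyr::mutate(dplyr::bind_rows(rows), baseline = FALSE,
                  delay_ms = delays_ms, p_act_psi = p_act)
  )
  structure(out, class = c("cv_sweep", class(tibble::tibble())),
            sweep_mode = "delay")
}

#' Sweep the actuation pressure
#'
#' As [delay_sweep()], but varying the actuator pressure at a fixed delay.
#'
#' @inheritParams delay_sweep
#' @param p_acts Actuation pressures in psi (default 6, 8, 10, 12).
#' @param delay_ms Fixed actuation delay in ms (default 650).
#' @return A `cv_sweep` tibble with a `p_act_psi` axis.
#' @export
pressure_sweep <- function(model, p_acts = c(6, 8, 10, 12), delay_ms = 650,
                           bench = NULL, n_cycles = 10, dt = 1e-4) {
  base_model <- model
  base_model$device <- NULL
  base <- sweep_point(base_model, n_cycles, dt)
  rows <- purrr::map(p_acts, function(pa) {
    m <- apply_device(model, pa, delay_ms / 1000, bench)
    tryCatch(
      dplyr::mutate(sweep_point(m, n_cycles, dt), failed = FALSE),
      error = function(e) tibble::tibble(failed = TRUE)
    )
  })
  out <- dplyr::bind_rows(
    dplyr::mutate(base, baseline = TRUE, delay_ms = NA_real_,
                  p_act_psi = 0, failed = FALSE),
    dplyr::mutate(dplyr::bind_rows(rows), baseline = FALSE,
                  delay_ms = delay_ms, p_act_psi = p_acts)
  )
  structure(out, class = c("cv_sweep", class(tibble::tibble())),
            sweep_mode = "pressure")
}

#' Write sweep results to CSV tables
#'
#' Writes `sweep.csv` (one row per sweep point, baseline first, all summary
#' metrics) and `splits.csv` (per-branch flow percentages in the layout of
#' a flow-split table: one row per branch, one column per sweep point).
#'
#' @param sweep A `cv_sweep`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
report_sweep <- function(sweep, dir) {
  if (!nrow(sweep)) stop("empty sweep", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  main <- file.path(dir, "sweep.csv")
  readr::write_csv(as.data.frame(sweep), main)

  split_cols <- grep("^split_", names(sweep), value = TRUE)
  axis_label <- if (attr(sweep, "sweep_mode") == "delay") {
    paste0("delay_", sweep$delay_ms, "ms")
  } else {
    paste0("p_act_", sweep$p_act_psi, "psi")
  }
  label <- ifelse(sweep$baseline, "baseline", axis_label)
  splits <- tibble::tibble(vessel = sub("^split_", "", split_cols))
  for (i in seq_len(nrow(sweep))) {
    splits[[label[i]]] <- as.numeric(sweep[i, split_cols])
  }
  spath <- file.path(dir, "splits.csv")
  readr::write_csv(splits, spath)
  invisible(c(main, spath))
}

#' Count diastolic augmentation peaks
#'
#' Counts the local maxima (above a prominence threshold) of the aortic
#' root pressure and of every branch pressure over one cycle.
#' Counterpulsation timed in diastole adds a second pressure peak in every
#' branch; a baseline cycle has exactly one.
#'
#' @param traj A `cv_trajectory`.
#' @param cycle Cycle index (default final).
#' @param prominence Minimum peak prominence in mmHg (default 1).
#' @return Named integer vector of peak counts (`P_ao` plus one entry per
#'   branch).
#' @export
augmentation_peaks <- function(traj, cycle = -1, prominence = 1) {
  cy <- trajectory_cycle(traj, cycle)
  sigs <- c("P_ao", paste0("P_br_", attr(traj, "terminals")))
  vapply(sigs, function(nm) {
    x <- cy[[nm]]
    # periodic padding so a peak at the cycle boundary is counted once
    pk <- pracma::findpeaks(x, minpeakdistance = 5)
    if (is.null(pk)) return(0L)
    # prominence relative to the lower neighboring trough
    sum(apply(pk, 1, function(row) {
      lo <- min(x[row[3]:row[4]])
      (row[1] - lo) >= prominence
    }))
  }, integer(1))
}
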