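#' Build a model from a YAML run configuration
#'
#' The configuration mirrors the model structure: top-level `hr` and
#' `geometry` (path, default the shipped synthetic tree), optional
#' `chambers` blocks (`LA`, `LV`) with [chamber_params()] fields, optional
#' `valves` blocks (`MV`, `AV`) with [valve_params()] fields, an optional
#' `venous` block with `R_ven`, and an optional `device` block with
#' `p_act_psi`, `delay_ms`, `t_act_ms`, `t_on_ms`, `t_off_ms`, `C_sr`,
#' `correction`, and either `gain_coeffs` (a1..a5) or `bench_csv` (a bench
#' grid to fit with [fit_gain_surface()] and interrogate with
#' [timing_lookup()]).
#'
#' @param path Path to a YAML file, or a pre-parsed list.
#' @return A `cv_model`.
#' @export
read_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  geometry <- cfg$geometry %||% hemopulse_geometry()
  hr <- cfg$hr %||% 60
  network <- build_network(geometry)
  T_cyc <- 60 / hr

  mk_chamber <- function(block, label, defaults) {
    if (is.null(block)) return(defaults)
    chamber_params(
      E_act_max = block$E_act_max %||% defaults$E_act_max,
      V0 = block$V0 %||% defaults$V0,
      A_pas = block$A_pas %||% defaults$A_pas,
      B_pas = block$B_pas %||% defaults$B_pas,
      t_onset = block$t_onset %||% defaults$t_onset,
      t_sys = block$t_sys %||% defaults$t_sys,
      label = label
    )
  }
  mk_valve <- function(block, defaults) {
    if (is.null(block)) return(defaults)
    valve_params(
      K_open = block$K_open %||% defaults$K_open,
      K_close = block$K_close %||% defaults$K_close,
      A_eff_max = block$A_eff_max %||% defaults$A_eff_max,
      bernoulli_coeff = block$bernoulli_coeff %||% defaults$bernoulli_coeff
    )
  }

  base <- cv_model(network, hr = hr)
  lv <- mk_chamber(cfg$chambers$LV, "LV", base$lv)
  la <- mk_chamber(cfg$chambers$LA, "LA", base$la)
  mv <- mk_valve(cfg$valves$MV, base$mv)
  av <- mk_valve(cfg$valves$AV, base$av)

  device <- NULL
  if (!is.null(cfg$device)) {
    d <- cfg$device
    coeffs <- d$gain_coeffs
    t_on <- (d$t_on_ms %||% 300) / 1000
    t_off <- (d$t_off_ms %||% 500) / 1000
    if (is.null(coeffs) && !is.null(d$bench_csv)) {
      path <- d$bench_csv
      if (!file.exists(path)) {
        path <- system.file("extdata", d$bench_csv, package = "hemopulse")
      }
      bench <- readr::read_csv(path, show_col_types = FALSE)
      coeffs <- fit_gain_surface(bench)$coeffs
      tim <- timing_lookup(d$p_act_psi %||% 12, 95, bench)
      t_on <- tim$t_on
      t_off <- tim$t_off
    }
    device <- device_params(
      p_act = d$p_act_psi %||% 12,
      dt_act = (d$delay_ms %||% 650) / 1000,
      t_act = (d$t_act_ms %||% 300) / 1000,
      t_on = t_on, t_off = t_off,
      gain_coeffs = coeffs %||% formals(device_params)$gain_coeffs |> eval(),
      C_sr = d$C_sr %||% 0.05,
      correction = d$correction %||% 6
    )
  }

  m <- cv_model(network, hr = hr, lv = lv, la = la, mv = mv, av = av,
                device = device,
                R_ven = cfg$venous$R_ven %||% 0.02)
  m
}

#' Write a trajectory and its run metadata
#'
#' Writes the trajectory as CSV plus a sidecar JSON with the integration
#' settings (heart rate, step, cycle count, sampling interval).
#'
#' @param traj A `cv_trajectory`.
#' @param path Output CSV path; the sidecar is `<path>.meta.json`.
#' @return Invisibly, the CSV path.
#' @export
write_trajectory <- function(traj, path) {
  readr::write_csv(as.data.frame(traj), path)
  meta <- list(hr = attr(traj, "hr"), dt = attr(traj, "dt"),
               record_dt = attr(traj, "record_dt"),
               n_cycles = attr(traj, "n_cycles"),
               terminals = attr(traj, "terminals"))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
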