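#' Time-varying elastance chamber parameters
#'
#' Describes the left atrium or left ventricle as a time-varying elastance
#' chamber: pressure is the sum of a passive exponential component (the
#' diastolic pressure--volume relation) and an active component driven by a
#' normalized activation waveform.
#'
#' @param E_act_max Peak active elastance (mmHg/mL).
#' @param V0 Unstressed volume (mL): the volume at which both passive and
#'   active pressures vanish.
#' @param A_pas Passive stiffness scale (mmHg).
#' @param B_pas Passive stiffness exponent (1/mL); larger values give the
#'   stiffer diastolic curve characteristic of HFpEF.
#' @param t_onset Activation onset within the cycle (s); the cycle starts at
#'   the R wave, so the ventricle uses `t_onset = 0`.
#' @param t_sys Activation duration (s).
#' @param rise_frac Fraction of `t_sys` at which activation peaks (default
#'   0.5, the symmetric half-cosine bump). Smaller values model fast
#'   contraction with slow relaxation.
#' @param label `"LA"` or `"LV"`.
#' @return A `chamber_params` list.
#' @export
chamber_params <- function(E_act_max, V0, A_pas, B_pas, t_onset, t_sys,
                           rise_frac = 0.5, label = c("LV", "LA")) {
  label <- match.arg(label)
  stopifnot(E_act_max > 0, A_pas >= 0, B_pas > 0, t_onset >= 0, t_sys > 0,
            rise_frac > 0, rise_frac < 1)
  structure(
    list(E_act_max = E_act_max, V0 = V0, A_pas = A_pas, B_pas = B_pas,
         t_onset = t_onset, t_sys = t_sys, rise_frac = rise_frac,
         label = label),
    class = "chamber_params"
  )
}

#' Normalized activation waveform
#'
#' A raised-cosine bump: zero outside the activation window
#' `[t_onset, t_onset + t_sys]`, rising smoothly to exactly 1 at
#' `rise_frac * t_sys` into the window (the midpoint for the default
#' symmetric shape) and returning smoothly to zero. C1 everywhere and
#' periodic in the cycle length.
#'
#' @param t_cycle Time within the cycle (s), in `[0, cycle_length)`.
#' @param params A [chamber_params()] object.
#' @param cycle_length Cardiac cycle length (s).
#' @return Activation in `[0, 1]` (vectorized over `t_cycle`).
#' @export
activation <- function(t_cycle, params, cycle_length) {
  x <- (t_cycle - params$t_onset) %% cycle_length
  r <- params$rise_frac %||% 0.5
  xr <- r * params$t_sys
  ifelse(x >= 0 & x <= params$t_sys,
         ifelse(x <= xr,
                0.5 * (1 - cos(pi * x / xr)),
                0.5 * (1 + cos(pi * (x - xr) / (params$t_sys - xr)))),
         0)
}

#' Passive (diastolic) chamber pressure
#'
#' `P_pas = A_pas * (exp(B_pas * (V - V0)) - 1)`: zero at the unstressed
#' volume and strictly increasing in volume.
#'
#' @param volume Chamber volume (mL).
#' @inheritParams activation
#' @return Pressure in mmHg (vectorized over `volume`).
#' @export
passive_pressure <- function(volume, params) {
  params$A_pas * (exp(params$B_pas * (volume - params$V0)) - 1)
}

#' Total chamber pressure
#'
#' Sum of the passive exponential and the active linear elastance component:
#' `P = P_pas(V) + e(t) * E_act_max * (V - V0)`.
#'
#' @inheritParams activation
#' @inheritParams passive_pressure
#' @return Pressure in mmHg.
#' @export
chamber_pressure <- function(volume, t_cycle, params, cycle_length) {
  e <- activation(t_cycle, params, cycle_length)
  passive_pressure(volume, params) + e * params$E_act_max * (volume - params$V0)
}

# Solve A_pas from the end-diastolic pinning condition
# passive_pressure(edv) == edp given B_pas and V0.
pin_passive_A <- function(edv, edp, B_pas, V0) {
  denom <- exp(B_pas * (edv - V0)) - 1
  if (denom <= 0) stop("EDV must exceed V0 to pin the passive curve", call. = FALSE)
  edp / denom
}
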