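#' Pressure-actuated valve parameters
#'
#' The valve carries a continuous opening state `s` in `[0, 1]` (0 fully
#' closed) whose rate depends on the transvalvular pressure difference, and
#' a Bernoulli pressure--flow law gated by `s`.
#'
#' @param K_open Opening rate constant (1/(mmHg.s)). The default 40 gives
#'   10--30 ms opening at physiological gradients of a few mmHg.
#' @param K_close Closing rate constant (1/(mmHg.s)); the default closes
#'   within tens of ms of the pressure reversal, bounding the regurgitant
#'   back-leak to a small fraction of forward volume.
#' @param A_eff_max Maximal effective orifice area (cm^2); descriptive.
#' @param bernoulli_coeff Bernoulli coefficient at full opening
#'   (mmHg.s^2/mL^2): `dp = (bernoulli_coeff / s^2) * Q * |Q|`.
#' @param inertance_coeff Optional valve inertance (mmHg.s^2/mL); default 0
#'   keeps the system an ODE in volumes, terminal pressures, and valve
#'   states.
#' @return A `valve_params` list.
#' @export
valve_params <- function(K_open = 40, K_close = 80, A_eff_max = 4,
                         bernoulli_coeff = 1e-4, inertance_coeff = 0) {
  stopifnot(K_open > 0, K_close > 0, A_eff_max > 0, bernoulli_coeff > 0,
            inertance_coeff >= 0)
  structure(
    list(K_open = K_open, K_close = K_close, A_eff_max = A_eff_max,
         bernoulli_coeff = bernoulli_coeff, inertance_coeff = inertance_coeff),
    class = "valve_params"
  )
}

#' Rate of change of the valve opening state
#'
#' `ds/dt = (1 - s) * K_open * dp` for a positive (opening) pressure
#' difference and `ds/dt = s * K_close * dp` for a non-positive one. The
#' `(1 - s)` and `s` factors guarantee the state can never leave `[0, 1]`.
#'
#' @param s Opening state in `[0, 1]`.
#' @param dp Inlet-minus-outlet pressure difference (mmHg).
#' @param params A [valve_params()] object.
#' @return `ds/dt` in 1/s.
#' @export
valve_state_rate <- function(s, dp, params) {
  stopifnot(all(s >= 0 & s <= 1))
  ifelse(dp > 0, (1 - s) * params$K_open * dp, s * params$K_close * dp)
}

#' Transvalvular flow
#'
#' Solves the gated Bernoulli law `dp = (bernoulli_coeff / s^2) * Q * |Q|`
#' for the flow: `Q = sign(dp) * s * sqrt(|dp| / bernoulli_coeff)`. The flow
#' is hard-zeroed for `s` below 1e-6, honoring the fully closed state.
#'
#' @inheritParams valve_state_rate
#' @return Flow in mL/s.
#' @export
valve_flow <- function(dp, s, params) {
  stopifnot(all(s >= 0 & s <= 1))
  ifelse(s <= 1e-6, 0, sign(dp) * s * sqrt(abs(dp) / params$bernoulli_coeff))
}
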