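#' Soft-robot counterpulsation device parameters
#'
#' The extra-aortic McKibben actuator is represented by an equivalent
#' pressure source `p_sr` coupled into the ascending aorta through a
#' capacitance. The source is a contraction exponential (rate `k1`) followed
#' by a relaxation exponential (rate `k2`) whose continuity constants pin
#' `p_sr` to be continuous at `t_on` and zero at `t_off`. Its amplitude is
#' `g_act * p_aorta`, where the dimensionless gain `g_act` comes from the
#' bench-fitted quadratic surface in actuation and loop pressure.
#'
#' @param p_act Actuator pressure (psi, bench range 6--12). `p_act = 0`
#'   disables the device.
#' @param dt_act Actuation delay from the R wave (s).
#' @param t_act Commanded contraction duration (s); the prototype always
#'   uses 0.3 s.
#' @param t_on Measured contraction duration (s).
#' @param t_off Duration of the full actuation cycle including relaxation (s).
#' @param k1,k2 Contraction and relaxation rate constants (1/s); the bench
#'   characterization of the prototype gives 13.04 and 34.66.
#' @param gain_coeffs Numeric vector `(a1..a5)` of the gain surface
#'   `g_act = a1*pa^2 + a2*pa + a3*p_act + a4 + a5*pa*p_act`.
#' @param C_sr Device coupling capacitance (mL/mmHg).
#' @param correction Dimensionless in-vivo scaling factor `lambda`
#'   multiplying `p_sr` (see [calibrate_correction()]).
#' @return A `device_params` list.
#' @export
device_params <- function(p_act, dt_act, t_act = 0.3, t_on = 0.3, t_off = 0.5,
                          k1 = 13.04, k2 = 34.66,
                          gain_coeffs = c(0, -0.002, 0.03, 0.25, 0),
                          C_sr = 0.05, correction = 6) {
  if (t_off <= t_on) stop("t_off must exceed t_on", call. = FALSE)
  stopifnot(p_act >= 0, dt_act >= 0, t_on > 0, k1 > 0, k2 > 0, C_sr > 0,
            correction >= 0, length(gain_coeffs) == 5)
  structure(
    list(p_act = p_act, dt_act = dt_act, t_act = t_act, t_on = t_on,
         t_off = t_off, k1 = k1, k2 = k2, gain_coeffs = as.numeric(gain_coeffs),
         C_sr = C_sr, correction = correction),
    class = "device_params"
  )
}

#' Normalize time with respect to the cycle and actuation delay
#'
#' `t_norm = t - floor((t - dt_act) * HR/60) * 60/HR - dt_act`, mapping
#' absolute time into `[0, 60/HR)` measured from the most recent actuation
#' onset.
#'
#' @param t Absolute time (s); vectorized.
#' @param dt_act Actuation delay from the R wave (s).
#' @param hr Heart rate (bpm).
#' @return Normalized time in seconds.
#' @export
normalize_time <- function(t, dt_act, hr) {
  stopifnot(hr > 0)
  t - floor((t - dt_act) * hr / 60) * 60 / hr - dt_act
}

#' Device gain surface
#'
#' Quadratic bench-characterization surface
#' `g_act = a1*pa^2 + a2*pa + a3*p_act + a4 + a5*pa*p_act`, optionally
#' clamped to `[0, 1)` as used inside the pressure source (the device
#' augments but cannot exceed the loop pressure).
#'
#' @param p_aorta Loop (aortic) pressure in mmHg; vectorized.
#' @param p_act Actuator pressure in psi.
#' @param coeffs Numeric vector `(a1..a5)`.
#' @param clamp Clamp the result to `[0, 1)`? Default `FALSE` (the raw
#'   surface, as fitted).
#' @return Dimensionless gain.
#' @export
gain <- function(p_aorta, p_act, coeffs, clamp = FALSE) {
  stopifnot(length(coeffs) == 5)
  g <- coeffs[1] * p_aorta^2 + coeffs[2] * p_aorta + coeffs[3] * p_act +
    coeffs[4] + coeffs[5] * p_aorta * p_act
  if (clamp) g <- pmin(pmax(g, 0), 1 - 1e-9)
  g
}

#' Fit the gain surface to bench data
#'
#' Least-squares fit of the quadratic gain surface to measured gains on the
#' bench grid, minimizing the root-mean-square error.
#'
#' @param grid A bench grid tibble with columns `p_aorta_mmHg`, `p_act_psi`,
#'   and `g_exp` (see [synth_bench_data()]).
#' @return A list with `coeffs` (named a1..a5) and the achieved `rmse`.
#' @export
fit_gain_surface <- function(grid) {
  pts <- unique(grid[, c("p_aorta_mmHg", "p_act_psi")])
  if (nrow(pts) < 5) {
    stop("degenerate fit: need at least 5 distinct (p_aorta, p_act) points",
         call. = FALSE)
  }
  X <- cbind(grid$p_aorta_mmHg^2, grid$p_aorta_mmHg, grid$p_act_psi, 1,
             grid$p_aorta_mmHg * grid$p_act_psi)
  if (qr(X)$rank < 5) {
    stop("degenerate fit: rank-deficient design (vary both pressures)",
         call. = FALSE)
  }
  fit <- stats::lm.fit(X, grid$g_exp)
  coeffs <- stats::setNames(as.numeric(fit$coefficients), paste0("a", 1:5))
  rmse <- sqrt(mean(fit$residuals^2))
  list(coeffs = coeffs, rmse = rmse)
}

#' Device pressure source waveform
#'
#' Piecewise source: a saturating contraction
#' `p_sr = g_act * p_aorta * (1 - exp(-k1 * t_norm))` for
#' `0 <= t_norm <= t_on`, a relaxation
#' `p_sr = c * exp(-k2 * (t_norm - t_on)) + d` for `t_on < t_norm <= t_off`
#' with `(c, d)` solving the two continuity conditions
#' `p_sr(t_on+) = p_sr(t_on-)` and `p_sr(t_off) = 0`, and zero elsewhere.
#'
#' @param t_norm Normalized time (s) in `[0, cycle_length)`; vectorized.
#' @param p_aorta Reference aortic pressure (mmHg).
#' @param dev A [device_params()] object.
#' @return `p_sr` in mmHg.
#' @export
source_pressure <- function(t_norm, p_aorta, dev) {
  if (dev$t_off <= dev$t_on) stop("t_off must exceed t_on", call. = FALSE)
  g <- gain(p_aorta, dev$p_act, dev$gain_coeffs, clamp = TRUE)
  amp <- g * p_aorta
  P_on <- amp * (1 - exp(-dev$k1 * dev$t_on))
  E <- exp(-dev$k2 * (dev$t_off - dev$t_on))
  cc <- P_on / (1 - E)
  dd <- -P_on * E / (1 - E)
  out <- numeric(length(t_norm))
  contr <- t_norm >= 0 & t_norm <= dev$t_on
  relax <- t_norm > dev$t_on & t_norm <= dev$t_off
  out[contr] <- amp * (1 - exp(-dev$k1 * t_norm[contr]))
  out[relax] <- cc * exp(-dev$k2 * (t_norm[relax] - dev$t_on)) + dd
  out
}

#' Device flow into the aortic node
#'
#' The coupling element behaves as a capacitance `C_sr` driven by the
#' externally imposed pressure `lambda * p_sr`: the squeeze displaces the
#' stored volume `V_dev = -lambda * C_sr * p_sr` (relative to rest) into the
#' circulation, so the flow injected at the insertion node is
#' `lambda * C_sr * dp_sr/dt`. Over a periodic cycle the net injected volume
#' is exactly zero.
#'
#' @param dpsr_dt Time derivative of the source pressure (mmHg/s); vectorized.
#' @param dev A [device_params()] object.
#' @return Flow into the node in mL/s.
#' @export
device_flow <- function(dpsr_dt, dev) {
  dev$correction * dev$C_sr * dpsr_dt
}

#' Interpolate measured actuation timings from the bench grid
#'
#' Bilinear interpolation of the experimentally determined contraction
#' duration `t_on` and actuation-cycle duration `t_off` over the
#' (loop pressure, actuator pressure) bench grid, clamped at the grid edges.
#'
#' @param p_act Actuator pressure (psi).
#' @param p_aorta Loop pressure (mmHg).
#' @param grid A bench grid tibble with columns `p_aorta_mmHg`, `p_act_psi`,
#'   `t_on_s`, `t_off_s`.
#' @return A list with `t_on` and `t_off` in seconds.
#' @export
timing_lookup <- function(p_act, p_aorta, grid) {
  if (!nrow(grid)) stop("empty bench grid", call. = FALSE)
  pa_vals <- sort(unique(grid$p_aorta_mmHg))
  pc_vals <- sort(unique(grid$p_act_psi))
  interp1 <- function(col) {
    # values on the full grid, matrix [pa, pc]
    M <- matrix(NA_real_, length(pa_vals), length(pc_vals))
    idx <- cbind(match(grid$p_aorta_mmHg, pa_vals), match(grid$p_act_psi, pc_vals))
    M[idx] <- grid[[col]]
    bilinear_clamped(pa_vals, pc_vals, M, p_aorta, p_act)
  }
  list(t_on = interp1("t_on_s"), t_off = interp1("t_off_s"))
}

bilinear_clamped <- function(xs, ys, M, x, y) {
  x <- min(max(x, xs[1]), xs[length(xs)])
  y <- min(max(y, ys[1]), ys[length(ys)])
  i <- findInterval(x, xs, rightmost.closed = TRUE)
  j <- findInterval(y, ys, rightmost.closed = TRUE)
  i <- min(max(i, 1), length(xs) - 1)
  j <- min(max(j, 1), length(ys) - 1)
  if (length(xs) == 1) i <- 1
  if (length(ys) == 1) j <- 1
  tx <- if (xs[i + 1] > xs[i]) (x - xs[i]) / (xs[i + 1] - xs[i]) else 0
  ty <- if (ys[j + 1] > ys[j]) (y - ys[j]) / (ys[j + 1] - ys[j]) else 0
  (1 - tx) * (1 - ty) * M[i, j] + tx * (1 - ty) * M[i + 1, j] +
    (1 - tx) * ty * M[i, j + 1] + tx * ty * M[i + 1, j + 1]
}

# Hidden surface used by the synthetic bench generator: gently decreasing in
# loop pressure, increasing in actuation pressure, within (0, 1) over the
# bench ranges (50-150 mmHg, 6-12 psi).
bench_true_coeffs <- c(a1 = 2e-6, a2 = -2.6e-3, a3 = 3.2e-2, a4 = 0.22,
                       a5 = -4e-5)

#' Generate a synthetic bench characterization grid
#'
#' Emulates the silicone-loop bench experiment: the full factorial grid of
#' loop pressures \{50, 60, 70, 80, 90, 100, 125, 150\} mmHg and actuator
#' pressures \{6..12\} psi, with measured gains drawn from a hidden quadratic
#' surface of the same form as the fitted gain model (so a noiseless grid is
#' an exact round trip) plus Gaussian noise, and measured timings `t_on`
#' near 0.3 s and `t_off` near 0.5 s with a mild dependence on actuator
#' pressure.
#'
#' @param seed Integer seed; the grid is reproducible for a fixed seed.
#' @param noise_sd Standard deviation of the Gaussian noise added to the
#'   gains (dimensionless, default 0).
#' @return A tibble with columns `p_aorta_mmHg`, `p_act_psi`, `g_exp`,
#'   `t_on_s`, `t_off_s`.
#' @export
synth_bench_data <- function(seed = 1, noise_sd = 0) {
  stopifnot(noise_sd >= 0)
  grid <- tidyr::expand_grid(
    p_aorta_mmHg = c(50, 60, 70, 80, 90, 100, 125, 150),
    p_act_psi = 6:12
  )
  g <- gain(grid$p_aorta_mmHg, grid$p_act_psi, unname(bench_true_coeffs))
  noise <- withr::with_seed(seed, stats::rnorm(nrow(grid), 0, noise_sd))
  dplyr::mutate(
    grid,
    g_exp = pmin(pmax(g + noise, 1e-3), 0.999),
    t_on_s = 0.30 + 0.004 * (.data$p_act_psi - 9),
    t_off_s = 0.50 + 0.008 * (.data$p_act_psi - 9)
  )
}

#' Calibrate the in-vivo correction factor
#'
#' The bench loop and the patient aorta differ in local resistance and
#' capacitance, so the source pressure is scaled by a correction factor
#' `lambda` chosen such that the in-model peak device volume displacement at
#' a reference aortic pressure of 100 mmHg matches the bench-measured peak
#' displacement. Because the coupling is linear in `lambda`, the factor is
#' the ratio of target to uncorrected displacement.
#'
#' @param bench_peak_displacement Bench-measured peak volume displacement
#'   (mL) at a loop pressure of 100 mmHg.
#' @param dev A [device_params()] object (its `correction` is ignored).
#' @param p_aorta_ref Reference aortic pressure (mmHg, default 100 as in the
#'   bench determination).
#' @return The correction factor `lambda`.
#' @export
calibrate_correction <- function(bench_peak_displacement, dev,
                                 p_aorta_ref = 100) {
  if (bench_peak_displacement < 0) {
    stop("calibration failure: negative target displacement", call. = FALSE)
  }
  tn <- seq(0, dev$t_off, length.out = 2001)
  peak_uncorrected <- dev$C_sr * max(source_pressure(tn, p_aorta_ref, dev))
  if (bench_peak_displacement == 0) return(0)
  if (peak_uncorrected <= 0) {
    stop("calibration failure: device displaces no volume (zero gain?)",
         call. = FALSE)
  }
  bench_peak_displacement / peak_uncorrected
}
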