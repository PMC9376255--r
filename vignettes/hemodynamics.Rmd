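---
title: "A closed-loop lumped-parameter model of HFpEF hemodynamics with extra-aortic counterpulsation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A closed-loop lumped-parameter model of HFpEF hemodynamics with extra-aortic counterpulsation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`hemopulse` simulates the left heart and systemic arteries of a patient with
heart failure with preserved ejection fraction (HFpEF) as a closed
zero-dimensional circuit, and couples a soft-robotic extra-aortic
counterpulsation device into the ascending aorta. The circuit is:

left atrium → mitral valve → left ventricle → aortic valve → aortic tree
(ascending aorta in two elements, arch, arch branches, coronary trunk,
descending aorta) → one RCR Windkessel terminal per outlet → common venous
node → venous resistance → left atrium.

**Chambers.** Both chambers are time-varying elastance elements with
separate passive and active pressure components,

$$P(V, t) = A\,(e^{B (V - V_0)} - 1) + e(t)\, E_{\max} (V - V_0),$$

where the passive exponential is the diastolic pressure–volume relation (a
stiff one — large $B$ — is the HFpEF phenotype) and $e(t) \in [0,1]$ is a
raised-cosine activation bump that rises over `rise_frac * t_sys` and falls
over the remainder. The default shape is the symmetric half-cosine
(`rise_frac = 0.5`); the shape is a configuration choice because reference
elastance formulations drive activation through first-order dynamics whose
rise and relaxation times differ. The atrial element stands for the left
atrium *plus the pulmonary venous pool*: its passive curve is
reservoir-like (≈6 mL/mmHg near 11 mmHg) so it can buffer venous return
during systole, and its active kick adds a few mmHg in late diastole
(window 0.80–0.92 of the cycle).

**Valves.** Pressure-actuated valves with a continuous opening state
$s \in [0,1]$: $\dot s = (1-s) K_{open}\,\Delta p$ for opening and
$\dot s = s\, K_{close}\,\Delta p$ for closing, so the state can never
leave the unit interval. The rate constants default to 40 and 60
mmHg⁻¹s⁻¹, giving 10–30 ms transitions at physiological gradients of a few
mmHg (rate constants quoted per Pascal in the valve-dynamics literature are
two orders of magnitude smaller). Flow obeys a gated Bernoulli law
$\Delta p = (B_q/s^2)\, Q |Q|$, hard-zeroed below $s = 10^{-6}$. The aortic
valve optionally carries an inertance $L$ (default $10^{-3}$ mmHg·s²/mL,
the blood column of the root), which turns its flow into a state variable
and rounds the ejection upstroke; inside the quadratic drag the orifice is
floored so that $B_q/s_f^2 \le 10^{-2}$, which keeps the closing transient
integrable at the fixed 0.1 ms step while full closure is enforced by a
hard gate.

**Vessels.** Each named segment is a Poiseuille resistance computed from
its length and the arithmetic mean of 10–20 sampled lumen areas
($R = 8\pi\mu L / \bar A^2$, converted to mmHg·s/mL), split into three
equal series sub-resistors. Walls are rigid: segments store no volume, so
all node pressures are algebraic. Blood viscosity defaults to 0.04 poise,
matching a 40–60% glycerine–water blood analog. Each outlet ends in an RCR
terminal whose proximal fraction (`zc_frac`, default 0.08) plays the role
of the branch characteristic impedance. The shipped geometry is
*synthetic* — a plausible adult aortic tree standing in for a CT-derived
model — which is acceptable because the segment resistances (~10⁻³
mmHg·s/mL) are dominated by the calibrated terminal beds (~1 mmHg·s/mL).

**Numerics.** The state vector is (chamber volumes, valve states, terminal
capacitor pressures, aortic flow when the valve inertance is active):
about 15 states. An explicit fixed-step RK4 advances the system at 0.1 ms
over 10 cycles by default; node pressures come from the precomputed inverse
of the constant nodal conductance matrix, and the inertance-free valve flow
is solved in closed form against the Thévenin equivalent of the tree seen
from the root. Volume conservation holds to round-off by construction
(~10⁻⁹ % over 10 cycles), halving the step changes CO, peak pressure, and
EDV by under 0.001%, and a model with a mounted but unpressurized device is
bit-identical to one with no device.

## The counterpulsation device

The McKibben-type actuator wrapped around the ascending aorta is
represented by an equivalent pressure source coupled through a capacitance
$C_{sr}$ between the two ascending-aorta elements. The source is a
contraction exponential followed by a relaxation exponential,

$$p_{sr}(t_n) = \begin{cases}
g_{act}\, p_{ao} \,(1 - e^{-k_1 t_n}) & 0 \le t_n \le t_{on} \\
c\, e^{-k_2 (t_n - t_{on})} + d & t_{on} < t_n \le t_{off} \\
0 & \text{else,}
\end{cases}$$

with $k_1 = 13.04$ s⁻¹ and $k_2 = 34.66$ s⁻¹ from the bench
characterization, $(c, d)$ solving the two continuity conditions
$p_{sr}(t_{on}^+) = p_{sr}(t_{on}^-)$ and $p_{sr}(t_{off}) = 0$, and $t_n$
the time normalized to the cycle and the actuation delay. The dimensionless
gain is the quadratic bench surface
$g_{act} = a_1 p_{ao}^2 + a_2 p_{ao} + a_3 p_{act} + a_4 + a_5 p_{ao} p_{act}$,
least-squares fitted to measured gains and clamped to $[0, 1)$ before use
(the squeeze augments but cannot exceed the loop pressure). During coupled
simulation $p_{ao}$ is the mean root pressure of the previous completed
cycle, because the bench characterization used a static loop pressure.

The coupling is a flow source $Q_{dev} = \lambda\, C_{sr}\, \dot p_{sr}$
injected at the insertion node — the rigid-node limit of the capacitive
element. The full capacitive form would place a $C_{sr}$ capacitor at a
node flanked by ~10⁻⁴ mmHg·s/mL segment resistances, whose ~5 µs time
constant cannot be integrated explicitly at 0.1 ms; the flow-source limit
preserves every property that matters (zero net volume per cycle,
λ-linearity, the displaced-volume scale) and is exact when the node
pressure variation is small against $\lambda p_{sr}$. The stored volume
$V_{dev} = -\lambda C_{sr}\, p_{sr}$ enters the conservation ledger, so
total blood volume remains exact with the device running. The correction
factor $\lambda$ absorbs the compliance difference between the silicone
bench loop and the aorta; `calibrate_correction()` sets it from a bench
displacement at a loop pressure of 100 mmHg (the coupling is linear in
$\lambda$, so the factor is a ratio). The default $\lambda = 6$ with
$C_{sr} = 0.05$ mL/mmHg displaces ~10 mL at 12 psi — between the published
prototype (whose displacement was reported as insufficient) and clinical
counterpulsation devices (25–40 mL).

**Synthetic bench data.** The real bench tables (measured gains, timing
tables, fitted coefficients, correction factor) live in unavailable
supplementary material, so `synth_bench_data()` emulates the experiment:
the full factorial grid of loop pressures {50…150} mmHg × actuator
pressures {6…12} psi, gains drawn from a hidden surface of the same
quadratic form (so a noiseless grid is an exact fitting round trip),
monotonically increasing in $p_{act}$ and decreasing in $p_{ao}$ as
observed on the bench, $t_{on}$ near 0.3 s and $t_{off}$ near 0.5 s with a
mild $p_{act}$ dependence, and optional Gaussian noise under a fixed seed.
Consequently the device-on *absolute* numbers of the study are not
reproducible here; only directions and orderings of effects are asserted.

## Calibration

`calibrate()` tunes the model to the nine printed patient values (HR 60
bpm, 68/150 mmHg, peak flow 266 mL/s, CO 5.17 L/min, 29/71 split, EDV/ESV
116/36 mL, EDP 16 mmHg) in two phases.

*Coarse staging.* Total systemic resistance is set to the Ohmic estimate
MAP/CO with MAP = DBP + (SBP − DBP)/3, distributed over branches inversely
to the requested flow fractions (defaults from the actuator-off flow-split
table) with capacitances proportional to the fractions so Windkessel time
constants are uniform; the splits are then trimmed multiplicatively against
short simulations, the capacitance scale is driven to the pulse pressure,
and the heart stage pins the passive curve through the end-diastolic point
and line-searches contractility, systolic duration, and total stressed
volume.

*Joint damped refinement.* Because afterload, preload, and contractility
couple strongly, the final approach nudges every knob from one short probe
per pass (damping 0.5–0.7): terminal resistance on mean pressure, guarded
by a deadbanded systemic-vascular-resistance term anchored at the operating
point implied by a mean atrial pressure of 0.7 × EDP (without the guard the
(resistance, volume) → (MAP, CO) map has a soft direction along which
absolute pressures and atrial pressure drift together); capacitance on
pulse pressure; total stressed volume on cardiac output; peak elastance on
end-systolic volume; activation shape (`rise_frac`, `t_sys`) and the
effective aortic orifice on peak flow; and the passive scale re-pinned at
the realized cycle-start volume so the measured EDP lands on target.
Probes run 5 cycles at 0.2 ms; the final run integrates 10 cycles at
0.1 ms from fixed-point-refined initial conditions.

Two printed combinations force deliberate compromises, both documented in
the calibration report:

- *CO vs volumes.* At periodic steady state, mean aortic flow × period
  equals the PV-loop stroke volume minus the valve back-leak — exactly. The
  printed CO (5.17 L/min ⇒ 86.2 mL/beat) and volumes (EDV − ESV = 80 mL)
  disagree by ~7%, so the surplus is split between raising EDV (< +3%) and
  lowering ESV (< −8%) within the printed per-row error envelope, keeping
  CO within 0.4%.
- *Peak flow vs systolic timing.* Peak flow 266 mL/s at 86 mL stroke
  volume implies a long, flat ejection (≥ 0.32 s even for a rectangular
  pulse). Within the raised-cosine activation family this calibrates to a
  slow-rising activation (`rise_frac` ≈ 0.88, `t_sys` capped at 0.72 s so
  ejection ends before mid-diastole) plus a mildly restrictive effective
  aortic orifice (transvalvular gradient ~25 mmHg at peak — mild stenosis,
  consistent with a low-flow ejection in an elderly patient). A side effect
  is that systolic pressure peaks ~0.45 s after the R wave, later than a
  conventional ~0.3 s systole; actuation delays quoted from the R wave
  therefore land at slightly different cardiac phases than in a
  normal-timing heart. In particular, actuation at exactly 0 ms delay ends
  its injection before this model's pressure peak and slightly *lowers*
  peak systolic pressure (−1.8%), whereas actuation anchored on the actual
  pressure upstroke (delays of 100–300 ms) raises it by 5–6%, reproducing
  the worst-case direction. The best-case direction is unaffected: the
  optimal delay is solidly diastolic, reduces peak systolic pressure and
  stroke work, and raises cardiac output monotonically with actuation
  pressure at the 650 ms operating point.

The baseline mean atrial pressure settles near 16 mmHg — higher than the
11.2 mmHg the anchor aims for, the residual of the shortened diastole the
peak-flow target forces. Atrial pressure is reported but is not a
calibration target.

## What the tests do and do not show

The synthetic geometry and synthetic bench grid reproduce the *structure*
of the study inputs (six outlets, factorial bench design, monotone gain
surface, timing scales), not their measured values. Passing tests
demonstrate that the closed-loop physics is conservative and convergent,
that calibration reproduces the printed patient table within its printed
error envelope, that the device model honors its analytic contract
(continuity, fit round trip, volume neutrality), and that the directional
physiology of counterpulsation (diastolic augmentation in every branch,
afterload reduction at diastolic timing, dose response in actuation
pressure) emerges from the coupled model. They do not validate the model
against any real waveform beyond the printed summary table, and absolute
device-on numbers (augmented pressures, stroke work in the printed unit
convention, arterial elastance) are out of numeric scope: stroke work is
reported in mmHg·mL and J from the loop integral, and arterial elastance
as ESP/CO exactly as defined, with ESP sampled at aortic valve closure
(opening state first below 0.05 after peak ejection).

## Degenerate inputs and tie-breaks

Zero-length segments carry zero resistance (floored at 10⁻⁸ inside the
conductance matrix); valve flow is hard-zeroed below the 10⁻⁶ opening
floor; the gain is clamped to [0, 1); a device with `p_act = 0` is removed
from the system entirely; non-finite states abort integration with the
failure time; the initial-condition search warns and returns its best
state after 20 cycles; and calibration warns (or errors under
`strict = TRUE`) listing the offending targets when the envelope cannot be
met. Cycle metrics use the R-wave sample for EDP, mitral closure (state
below 0.05) for EDV, and the trapezoid rule on the recorded 1 ms sampling
for all means and loop integrals — the problem sizes throughout (10 cycles
at 0.1 ms, ~15 states, 5-cycle probes at 0.2 ms during staging) keep a
full calibration under ten seconds on one core.
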