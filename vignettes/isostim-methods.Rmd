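---
title: "Amplitude-field based closed-loop stimulation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Amplitude-field based closed-loop stimulation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`isostim` simulates a two-dimensional stochastic Wilson-Cowan neural mass
model of essential tremor. An excitatory population (activity $E$, standing
for the ventral intermediate thalamic nucleus, the clinical stimulation
target) and an inhibitory population (activity $I$, the reticular nucleus)
interact through a logistic response function
$f(x) = 1/(1 + e^{-\beta(x-1)})$:

$$
dE = \tfrac{1}{\nu}\left(-E + f(\eta_E + w_{EE}E - w_{IE}I)\right)dt
     + \zeta\, dW_E, \qquad
dI = \tfrac{1}{\nu}\left(-I + f(\eta_I + w_{EI}E)\right)dt
     + \zeta\, dW_I.
$$

$\nu$ is a shared time constant (seconds), $\eta_P$ are constant inputs,
$w_{PR}$ connection weights, and $\zeta$ the SD of independent Gaussian
white noise on both populations. As printed, the noise coefficient sits
*outside* the $1/\nu$ factor; `integrate_sde(noise_inside_nu = TRUE)`
exposes the alternative reading. The deterministic part has a stable focus
$X^* = (E^*, I^*)$: the Jacobian there has eigenvalues
$\sigma \pm i\omega$ with $\sigma < 0$, $\omega > 0$, so tremor appears as
noise-sustained rotation around $X^*$ at frequency $\omega/2\pi$ (4-6 Hz).
$E$ models the tremor signal. A stimulation pulse instantaneously increments
the excitatory activity: $\delta X = (\delta E, 0)$.

Integration uses fixed-step Euler or adaptive Dormand-Prince RK45
(rtol $10^{-8}$, atol $10^{-10}$) for deterministic work and Euler-Maruyama
at $dt = 1$ ms for stochastic work; all randomness flows through R's seeded
RNG, so every run is reproducible bit for bit.

# Isostable amplitude

Isostables of a stable focus are sets of states that converge to $X^*$
synchronously; the isostable amplitude $r(X)$ labels them and obeys
$r(\Phi_t X) = e^{\sigma t} r(X)$ along the deterministic flow $\Phi_t$.
Near $X^*$, $r$ equals $2\lvert c_1\rvert$ where $c_1$ is the coordinate of
$X - X^*$ on the leading eigenvector $v_1 = a - ib$ — the package uses this
closed form as an independent oracle in its tests.

$r$ is estimated with a map-based formula: flow the state for $n$ linear
periods $T = 2\pi/\omega$, evaluate the linear observables
$g_1 = \langle X - X^*, (b_2, -b_1)\rangle$,
$g_2 = \langle X - X^*, (a_2, -a_1)\rangle$ at the endpoint, and rescale:

$$
r(X) \approx e^{-\sigma n T}
\frac{\sqrt{g_1(\Phi_{nT}X)^2 + g_2(\Phi_{nT}X)^2}}
     {\lvert b_2 a_1 - b_1 a_2 \rvert}.
$$

The eigenvector is fixed deterministically (unit norm, first component
rotated onto the positive real axis), which makes $g_1, g_2$ and hence the
fields platform-independent; $r$ itself is invariant to the eigenvector
phase.

## Numerical choices that matter

* **Deviation coordinates.** The map is integrated in $y = X - X^*$ with
  the floating-point drift residual at $X^*$ subtracted, and the RK45 error
  is controlled *relative to* $\lvert y\rvert$ (`atol = 0`). In absolute
  coordinates the observables decay like $e^{\sigma n T}$ (often $10^{-4}$
  of the state scale) and drown in the integrator's absolute error; in
  deviation form the oracle agreement near $X^*$ is $\sim 10^{-4}$ relative.
* **Choice of $n$.** $n$ must be large enough that the nonlinear transient
  has decayed, yet $e^{\sigma n T}$ must stay well above the $\sim 10^{-16}$
  relative floor of double precision. The default picks
  $n \approx 10 / (\lvert\sigma\rvert T)$ (target decay $e^{-10}$), capped
  at a decay of $e^{-25}$, and at least 20. This is also why the synthetic
  patient generator restricts damping to $\sigma \in [-3, -0.5]$ s$^{-1}$:
  strongly damped foci make the long-horizon map numerically meaningless
  for any admissible $n$.
* **Presets.** The *full* preset uses RK45; the *quick* preset relaxes the
  convergence requirement ($n \to \max(10, n/6)$) and integrates with Euler
  at 1 ms. Quick fields preserve the shape (rank correlation with full
  fields $> 0.95$) but sit on a different scale — the relaxed horizon
  leaves a phase-dependent bias factor — which is why cross-preset
  comparisons in the tests are scale-aware (below).

# Hilbert amplitude fields

The clinical control goal is phrased in terms of the Hilbert amplitude of
the tremor signal: the modulus of the analytic signal
$\tilde E + i\mathcal{H}(\tilde E)$ of the centered activity $\tilde E$.
Fields are estimated by ensemble averaging: draw initial positions
uniformly over the region of interest (2000 trajectories of 1000 periods at
the full preset), simulate the stochastic model, compute each trajectory's
amplitude series, clip 0.5% of samples at both ends (Hilbert edge
effects), smooth trajectories and amplitude series with a centered 4-sample
moving average, and average samples within 0.001-unit phase-space bins
(0.0002 in $I$ for narrow-$I$ models). Bins never visited stay missing —
unlike isostable fields, Hilbert fields cannot cover the whole basin.
Centering is per-trajectory mean (`hilbert-mean`) or $E^*$ (`hilbert-fp`).

# Response fields and the stimulation controller

Given an amplitude field $\Omega$, the instantaneous amplitude response
field is $\Gamma_0(X) = \Omega(X + \delta X) - \Omega(X)$ with nearest-bin
lookup (no interpolation — the controller operates in discretized space, and
interpolation would change the discrete decision trace). Negative values
mark states where a pulse shrinks the oscillation. For fair strategy
comparisons, bins missing in a Hilbert field are *emptied* (set to 0,
non-actionable) in the isostable response field (`harmonize_support()`),
and all remaining missing bins are zero-filled before use.

The augmented field $\Gamma(i, j, k)$ embeds $\Gamma_0$ along the
deterministic trajectory from each bin over one period ($t_1 = 0$ to
$t_u = T$, $u = \mathrm{round}(T/dt) + 1$): at each step the visited bin's
$\Gamma_0$ is stored if it is negative and at least as beneficial as the
start bin's, else 0. Trajectory points leaving the grid contribute 0
(conservative: no advice outside the known field).

At every integration step the controller decides pulse/no-pulse:

1. eligibility: at least $N_{\mathrm{lim}}$ steps since the last pulse
   (10 Hz cap, roughly twice the tremor frequency) and no pulse yet in the
   current period;
2. the current bin's immediate benefit $\Gamma(p, q, 1)$ must be negative;
3. stimulate if the predicted period end has already passed, or if the
   immediate benefit beats every discounted future benefit
   $\alpha_{i,k}\,\Gamma(p,q,k)$.

Future benefits are predictions from noiseless trajectories while the model
is stochastic, so they are discounted:

$$
\alpha_{i,k} =
\frac{(t_{i+k-1}-t_{n_0})^{-b} - (t_{n_1}-t_{n_0})^{-b}}
     {(t_{i}-t_{n_0})^{-b} - (t_{n_1}-t_{n_0})^{-b}},
$$

equal to 1 at the present step and 0 at the predicted period end $n_1$;
larger $b$ discounts the future more heavily. Two removable singularities
are defined by their limits: $b = 0$ uses the log form, and $t_i = t_{n_0}$
with $b > 0$ gives $\alpha = 0$.

Phase is tracked online by zero crossings: the phase resets to 0 at
positive zero-crossings of the centered $E$ signal and advances linearly at
$2\pi$ over the previous period's duration (bootstrap: the linear period
$T$ until two crossings have been seen). The centering reference is a
causal 2 s running mean of $E$ (with $E^*$ as fallback before 2 s have
elapsed) — an online-implementable choice where a global mean would not be.

# Baselines and evaluation

*Phase-locked stimulation* uses the same tracker and delivers one pulse per
period at the first step where the phase reaches a target; if a crossing
arrives first, the phase was underestimated and the pulse fires right then.
The target phase is calibrated per model and magnitude over twelve phase
bins, picking the bin with the lowest oscillatory power (ties: lowest bin).

*High-frequency (HF) stimulation* is open loop at 130 Hz (quantized to 8
steps = 125 Hz at $dt = 1$ ms). To compare energy at equal clinical effect,
`match_hf_magnitude()` finds the pulse magnitude whose mean power matches a
target within ±1%, by derivative-free pattern search. In our synthetic
models HF power is *non-monotone* in magnitude — a small continuous-like
drive first amplifies the oscillation before quenching it — so the search
is seeded by a geometric bracketing sweep; for some models the HF power
floor lies above the closed-loop efficacy and no match exists, which the
function reports as a classed error carrying the closest candidate.

*Efficacy* is the integral of the Welch power spectral density of $E$
(Hann window, 10 s segments, 50% overlap, per-segment mean detrend) over
the full band; by Parseval this tracks the variance of the tremor proxy and
is robust to estimator details. The reference protocol is 30 trials of
5000 s; the test suite uses a desk-scale 6 × 300 s preset with paired
seeds, which it documents as such. *Energy* per pulse is
$\delta E^{\,2}$ by default (pulse energy scales with amplitude squared at
fixed pulse shape); the exponent-1 convention is available, and energy
ratios are reported per convention.

# The synthetic world

No clinical parameters ship with the package. `generate_focus_model()`
rejection-samples Wilson-Cowan shape parameters ($\beta \in [2,8]$, weights
$\in [0,6]$, inputs $\in [0,2]$) until the model has a stable focus with
its fixed point inside the unit square, then exploits the fact that the
fixed point is independent of $\nu$ while eigenvalues scale as $1/\nu$:
$\nu$ is set to place the frequency at a seeded draw inside the tremor band
(5 ± 0.5 Hz, so distinct seeds yield distinct frequencies), accepting the
candidate if the damping lands in $[-3, -0.5]$ s$^{-1}$ and
$\nu \in [5, 40]$ ms. The noise SD is calibrated so the stationary SD of
$E$ is 0.02 activity units (a linearized Lyapunov solution refined on a
200 s run) — a direct parametrization chosen because, for the linearized
focus, band-power *ratios* are $\zeta$-invariant and cannot identify
$\zeta$. The reference pulse magnitude is 10% of the RMS orbit radius.
Three frozen "patients" (seeds 1-3) ship as JSON with their stored focus
metadata and occupancy grids (tightest rectangle holding 99.5% of a 500 s
calibration trajectory, snapped to 0.001-unit bins).

What the generator emulates: heterogeneous weakly-damped 4-6 Hz foci with
activities confined to $(0,1)$ and noise-sustained tremor-like
oscillations. What it does not: fitted responses of real patients, bursting
dynamics, peripheral reflex loops, measurement noise, or the specific
response-curve shapes of clinical datasets. A green test therefore
establishes the *mechanisms* (field similarity, controller correctness,
power suppression, energy efficiency direction) on plausible models, not
clinical effect sizes.

Two consequences of this stated world are worth flagging. First,
closed-loop stimulation at $\delta E_0$ is very effective here (power
ratios of 0.15-0.6 versus no stimulation), stronger than typical published
bar charts. Second, on one frozen fixture the HF power floor lies strictly
above the closed-loop efficacy, so the ±1% efficacy match is unsatisfiable
and the corresponding acceptance check is left honestly red for that
fixture; at HF's own best operating point it still delivers orders of
magnitude more energy.

## Scale-aware degradation comparison

Quick-versus-full degradation of response fields is measured as the
residual SD after an optimal scalar rescaling of the quick field onto the
full one, relative to the rescaled field's SD. A raw residual SD would be
dominated, for the isostable kind, by the documented scale shift of quick
isostable fields rather than by noise — the mechanism under test is the
*noisiness* of quick Hilbert estimates (relative residuals 1.1-1.9 versus
0.10-0.25 for isostable on the frozen fixtures).

# Known limitations

* Two-dimensional stable-focus dynamics only: no limit-cycle isostables,
  no higher dimensions, no model fitting to recordings.
* The discretized controller is tied to the simulation grid; nearest-bin
  lookup means field resolution bounds decision resolution.
* Phase tracking assumes a dominant oscillation; for crossing-free signals
  it free-runs on the bootstrap period (by design, with the 10 Hz cap as
  the safety net).
* Mixed-effects significance testing of strategy differences is exported
  as tidy data (`compare_strategies(long = TRUE)`) rather than fitted
  in-package.
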