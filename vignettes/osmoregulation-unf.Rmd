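---
title: "Ultrasensitive negative feedback and the yeast osmoshock response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ultrasensitive negative feedback and the yeast osmoshock response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(osmounf)
library(dplyr)
```

## The model

When budding yeast is hit by a hyperosmotic step (NaCl added to the
medium), water leaves the cell, and volume and turgor pressure drop. The
cell restores both by accumulating glycerol, through two parallel feedback
branches that both read the same error signal, the turgor deviation
$e = P_t(0) - P_t$: the membrane channel Fps1 closes (retaining glycerol)
and the Hog1 MAPK cascade activates glycerol production. `osmounf`
implements this closed loop as a small ODE system and asks a
model-selection question: what kind of control law on each branch —
proportional, integral, finite-window integral, or ultrasensitive
(Hill-type) — best reproduces step-shock volume and Hog1 trajectories?

### Biophysics

Volume follows the water flux across the membrane,
$\dot V = k_{p1}(P_i - P_e - P_t)$, with the intracellular osmotic
pressure given by van't Hoff's law over the osmotically active volume,
$P_i = (s + Gly)/(V - V_b)$, the extracellular pressure
$P_e = P_e^{equil} + u(t)$ stepped by the shock, and turgor linear in
volume, $P_t = P_t(0)\,(V - V^{P_t=0})/(V(0) - V^{P_t=0})$, floored at
zero below the turgor-loss volume. An equivalent form uses the volumetric
elastic modulus $\epsilon = P_t(0) V(0)/(V(0) - V^{P_t=0})$; the package
stores $V^{P_t=0}$ (the quantity the fits optimize) and derives
$\epsilon$ (`elastic_modulus()`).

### Controllers

The Fps1 branch outputs a glycerol permeability
$$u_{Fps1}(e) = k_{Fps1} - \mathrm{sgn}(e)\,
  \frac{k_{Fps1}\,|e|^{n_{Fps1}}}{\beta_{Fps1}|e|^{n_{Fps1}} + K_{Fps1}},$$
clamped below at zero. The Hog1 branch first low-pass filters the error,
$\dot u_{HOG} = b_{HOG} e - a_{HOG} u_{HOG}$, then produces glycerol at
$$v_{HOG}(u) = \frac{k_{HOG}\,u^{n_{HOG}}}{\beta_{HOG} u^{n_{HOG}} +
  K_{HOG}} \quad (u > 0; \text{ zero otherwise}),$$
or, in the integral variants, at $v_{HOG}(t) = k_i \int_{t-T_m}^t
u_{HOG}\,d\tau$ (ideal integrator for $T_m = \infty$). The dependent
constants $\beta = 1 - e^{k_e(1-n)}$ and $K$ (with $K_{Fps1}$ scaled by
$P_t(0)$, $K_{HOG}$ dimensionless) make the Hill exponent the single
knob that morphs each branch from proportional ($n = 1$, where $\beta =
0$ exactly) to ultrasensitive ($n > 1$). Glycerol exchanges across Fps1
by Fick diffusion, $u_{Diff} = u_{Fps1}(Gly/(V - V_b) - Gly_e/V_e)$, and
the two glycerol pools obey $\dot{Gly} = v_{HOG} - u_{Diff}$,
$\dot{Gly_e} = u_{Diff}$, so total glycerol changes only through
production — an identity the tests verify along every trajectory.

Six schemes pair the branch laws: `PNF-PNF`, `PNF-INF`, `PNF-FINF`,
`UNF-INF`, `UNF-FINF` and `UNF-UNF` (`scheme_names()`).

```{r}
traj <- simulate_osmo(scheme_config("UNF-UNF"), shock_input(0.4))
traj %>% filter(time %in% c(0, 6, 10, 30, 60)) %>%
  select(time, V, uHOG, e, uFps1, vHOG)
```

The ultrasensitive pairing shows the signature behaviour: the channel
shuts almost completely after the shock and stays shut until the error
falls below the Hill threshold, production surges immediately, and volume
recovers with a small residual error. With both branches proportional the
loop settles far from the set-point; with an ideal integrator it adapts
perfectly but can overshoot.

## The generic loop and sliding mode control

To explain *why* ultrasensitivity adapts so well, `simulate_loop()`
closes a first-order process ($x' = -ax + b(v_0 + u)$, measured output
$y = x + u_d$, error $e = r - y$) around a single controller. The
ultrasensitive law $u = \mathrm{sgn}(e)\,k_p|e|^n/(|e|^n + K^n)$ is a
smooth approximation of the ideal sliding-mode law $k_p\,\mathrm{sgn}(e)$
(its $K \to 0$ limit) and of the saturation law $k_p\,\mathrm{sat}(me)$
with slope $m = n/(4K)$. Instead of confining the error to the manifold
$e = 0$, it confines it to the boundary layer
$$|e| < \frac{4K}{n},$$
which is the package's design rule (`boundary_layer()`): Hill constants
chosen by the designer bound the closed-loop steady error. For the ideal
sliding-mode law, a gain strictly above the disturbance amplitude
suffices for complete rejection when the loop starts on the set-point
(`smc_gain_condition()`).

```{r}
ss <- steady_state_error(generic_controller("UNF", kp = 1, K = 0.01, n = 2),
                         feedback_loop(), a_ud = 0.2)
c(steady_error = ss, bound = boundary_layer(0.01, 2))
```

**Disturbance injection and the nominal bias.** The block diagram behind
the loop is not fully specified by a steady-state picture alone, so the
package fixes it as follows: the disturbance adds at the measured output,
and the controller side carries the nominal bias $v_0 = a y_0 / b$ that
sustains the pre-disturbance equilibrium at $y_0$. Steady states then
solve $a(r - e - a_{ud}) = b(v_0 + g(e))$. With $y_0 = 0$ the bias
vanishes and the textbook intersection geometry is recovered (a
proportional gain of 1 against a 0.2-step on a unit loop leaves an error
of 0.4); with $y_0 = r$ the sliding-mode gain condition $k_p > |a_{ud}|$
and the boundary-layer bound hold across the whole disturbance range.
Both regimes are exercised by the tests; `steady_state_error()` and
`simulate_loop()` are consistent with each other by construction and are
held to within $10^{-4}$ of each other in the acceptance suite.

**A note on the saturation approximation.** The ultrasensitive and
saturation maps both rescale with $e/K$, so the sup-norm distance between
them is invariant in $K$ (it is always attained near $|e| \approx 2K$ and
is about $0.2\,k_p$ for $n = 2$). What does vanish as $K$ shrinks is the
distance outside the (shrinking) boundary layer, and the distance between
the closed-loop responses; the tests assert those forms rather than the
raw sup-norm.

## Fitting and model selection

`osmo_cost()` scores a scheme against per-shock datasets by the unweighted
sum of squared volume and Hog1 residuals over all shocks and sampling
times. Because the model has no growth mechanism, observed volume above
the normalized initial value is uninformative: `clip_volume()` sets
samples above 1 to exactly 1 before fitting (data only; model output is
never clipped). Model Hog1 enters as the activation state directly, with
no rescaling — the synthetic data are generated in the same units, and
any affine mismatch would be absorbed into `bHOG`.

`fit_scheme()` minimizes the cost with a hybrid strategy: a real-coded
genetic algorithm (tournament selection, blend crossover, Gaussian
mutation, elitism) followed by a bounded derivative-free refinement
(Nelder–Mead on a sigmoid reparameterization of the box; golden-section
search for one free parameter), restarted five times by default with
seeds derived from the master seed, keeping the best restart. Schemes are
compared by the residual cost $J$ and by Gaussian least-squares
information criteria,
$$AIC = N\ln(J/N) + 2p, \qquad BIC = N\ln(J/N) + p\ln N, \qquad
  FPE = \frac{J}{N}\cdot\frac{N+p}{N-p},$$
where $N$ counts volume and Hog1 samples jointly ($2\times$ rows) and $p$
is the number of free parameters. The criteria are named but not written
out in the literature this model family comes from; these standard forms
are the package's choice, so only the induced *ordering* of schemes is
treated as a checkable claim, never criterion values themselves.
`rank_schemes()` breaks exact ties by fewer free parameters, then scheme
name.

The full model has 20 constants, 16 free and 4 dependent (the two
$\beta$/$K$ pairs; `param_registry()`). Fits free the controller
constants plus the two biophysical parameters the response is most
sensitive to, $V^{P_t=0}$ and $k_{p1}$. Hill exponents are real-valued
with default search range $[1, 8]$.

## Synthetic data: what it does and does not emulate

No quantitative single-cell osmoshock dataset ships with the package, so
`generate_shock_data()` stands in for one: it simulates a chosen scheme
under the three standard step amplitudes (0.2, 0.4, 0.6 M NaCl), samples
volume and Hog1 on a 0–60 min grid at 2-min spacing, and adds independent
Gaussian measurement noise per sample (defaults $\sigma_v = 0.01$,
$\sigma_h = 0.02$ — small, consistent with the low noise levels reported
for this pathway; harness defaults, not literature values). This
reproduces the *structure* the fitting stage assumes — normalized volume
equal to 1 at $t = 0$, clipping after recovery, per-shock series — but
none of the artifacts of real microscopy (segmentation error,
photobleaching, cell-to-cell parameter variability, non-Gaussian
outliers). Passing tests therefore demonstrate that the estimation and
ranking machinery recovers truth under the model's own assumptions, not
that the biological conclusions transfer to any particular dataset.

Process noise is a separate facility: `simulate_noisy()` perturbs the two
controller *outputs* during integration (per step, scaled by
$1/\sqrt{h}$ so the integrated variance is step-size consistent), and the
tests verify that the deterministic solution is the ensemble mean to
within Monte-Carlo error.

## Parameter defaults and units

Volumes are fractions of the initial volume ($V_0 = 1$); pressures are in
osmolarity-equivalent units (van't Hoff with $RT$ absorbed); time is in
minutes. Shock molarities convert to pressure via `c_osm` (default 2
osmotic units per M NaCl, i.e. full dissociation) — exposed as a units
convention because the source literature states concentrations, not
pressures. The remaining defaults are package choices tuned once, before
any fitting, to give physiological dip-and-recover dynamics: non-osmotic
fraction $V_b = 0.368$, turgor-loss volume $V^{P_t=0} = 0.9$, resting
turgor 0.5 and medium osmolarity 0.24 (so $P_i(0) = 0.74$), extracellular
volume $V_e = 10$ cell volumes, water permeability $k_{p1} = 0.2$
(volume dip completes within ~2–3 min of a shock), Hog1 filter rates
$b_{HOG} = a_{HOG} = 0.5\,\mathrm{min}^{-1}$ (activation lag ≈ 2 min and
unit steady-state gain, satisfying the similar-values constraint the
activation stage is built on), branch gains $k_{Fps1} = 0.5$, $k_{HOG} =
0.2$, and ultrasensitive shape $k_e = 6$, $n = 2$ on both branches, which
places the Hill thresholds (error ≈ 0.1, activation ≈ 0.05) inside the
post-shock operating range so that the ultrasensitive pairing genuinely
adapts (residual error 0.02–0.05 across 0.2–0.6 M) while the proportional
pairing visibly does not (residual ≈ 0.25 at 0.4 M). Integral-branch
defaults are $k_i = 0.02$, $T_m = 10$ min.

## Numerical choices

* **Integrators.** Smooth schemes (Hill or ideal-integral Hog branch) use
  the adaptive stiff-capable `lsoda` via a compiled right-hand side, with
  the integration restarted at the shock onset so the step discontinuity
  is never stepped across. The finite-window integral branch needs a
  lagged state, and the noise study needs per-step perturbations; both
  use a compiled fixed-step RK4 (default $h = 0.01$ min) with a full
  per-step history buffer for the lag.
* **Step inputs in fixed-step integration** are evaluated at the step
  start and held across Runge–Kutta stages, so an onset on a grid point
  is handled exactly piecewise; adaptive and fixed-step volume
  trajectories agree to ~$10^{-8}$.
* **Loop step sizes.** Discontinuous laws (sliding mode, saturation) use
  $h = 10^{-3}$ so chattering is resolved (band amplitude scales with
  $h\,k_p$); ultrasensitive laws shrink $h$ automatically with $K$
  because their local slope near the manifold grows as $k_p n/K$ and
  would destabilize an explicit method at a fixed step.
* **Bookkeeping states.** The solver carries $z = \int u_{HOG}$ (drives
  the integral branches; the finite window evaluates $z(t) - z(t-T_m)$ by
  linear interpolation of the step history) and $Q = \int v_{HOG}$, which
  makes the glycerol-conservation identity checkable to solver precision
  instead of quadrature precision.
* **Degenerate inputs.** Glycerol pools are floored at zero inside the
  right-hand side (a coarse step could transiently overdraw the Fick
  flux); `sgn(0) = 0` for the sliding-mode law so the manifold is an
  equilibrium; zero cost aborts the information criteria (their
  log-likelihood forms require $J > 0$) and such fits report $-\infty$
  criteria explicitly; a failed simulation inside the optimizer returns
  an infinite cost rather than an error.
* **Steady states** are found by bracketed root finding on the
  monotone steady-state residual; the sliding-mode law is handled
  set-valued at $e = 0$ (the manifold equilibrium exists whenever the
  required holding control is within $\pm k_p$).

## Problem sizes

The test and acceptance suites run at desk scale, chosen to finish in a
few minutes while leaving the conclusions unambiguous: parameter recovery
fits 4 free constants on 3 noiseless shocks (31 samples each) with a
population of 40 for 60 generations and 5 restarts; the scheme-ranking
comparison uses noisy data ($\sigma_v = \sigma_h = 0.01$) with a
population of 24 for 30 generations and 2 restarts; the noise-mean check
uses 200 replicates; the boundary-layer sweep covers four values of $K$
against a 21-point disturbance grid.

## Known limitations

The model deliberately omits growth (hence the clipping rule), all
osmolytes other than glycerol, mechanistic origins of ultrasensitivity
(MAPK cascade structure, scaffolding), and spatial or single-molecule
detail; noise enters only additively on controller outputs. The
finite-window integral is resolved only to the fixed step size. The
Lyapunov machinery behind the sliding-mode conditions is not reproduced —
only its conclusions (the gain condition with the reaching term exposed
as an optional user-supplied constant, and the boundary-layer bound) are
implemented as testable checks, and the reaching case with the output far
from the set-point is reported as indeterminate unless that constant is
supplied.
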