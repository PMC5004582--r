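# osmounf

Feedback-control analysis of the yeast osmoshock response, built around
one idea: **ultrasensitive negative feedback (U_NF)** — a Hill-type,
sigmoidal control law inside a negative feedback loop — behaves as a
*quasi sliding mode controller* and is enough to explain near-perfect
adaptation of cell volume and turgor pressure after a hyperosmotic step.

The package is for systems/synthetic biologists and control engineers who
want to (i) simulate the yeast high-osmolarity glycerol (HOG) closed loop
under alternative controller hypotheses, (ii) fit those hypotheses to
step-shock volume/Hog1 time series and rank them by information criteria,
and (iii) reuse the generic design rule linking Hill constants to
closed-loop precision.

## The model

A biophysical core

```
dV/dt  = kp1 (Pi − Pe − Pt)          water flux
Pi     = (s + Gly)/(V − Vb)          van't Hoff
Pe     = Pe_equil + u(t)             step osmoshock
Pt     = Pt0 (V − V^{Pt=0})/(V0 − V^{Pt=0}),  floored at 0
```

is closed by two feedback branches reading the turgor error
`e = Pt0 − Pt`: the Fps1 glycerol channel,

```
uFps1(e) = kFps1 − sgn(e) · kFps1 |e|^n / (βFps1 |e|^n + KFps1)
```

and Hog1-mediated glycerol production, `u̇HOG = bHOG e − aHOG uHOG`
feeding either a Hill law `vHOG = kHOG uHOG^n / (βHOG uHOG^n + KHOG)`
(for `uHOG > 0`) or a (finite-window) integrator
`vHOG = ki ∫_{t−Tm}^{t} uHOG dτ`. Glycerol moves across Fps1 by Fick
diffusion. At Hill exponent `n = 1` the dependent constants collapse
(`β = 0`) and each branch becomes a plain proportional controller, so six
schemes span the hypothesis space: `PNF-PNF`, `PNF-INF`, `PNF-FINF`,
`UNF-INF`, `UNF-FINF`, `UNF-UNF`.

On a generic first-order loop the U_NF law
`u = sgn(e) kp |e|^n/(|e|^n + K^n)` approximates ideal sliding mode
control `kp·sgn(e)`; instead of holding the error on the manifold
`e = 0` it confines it to the **boundary layer `|e| < 4K/n`**, the
package's design rule. Fitting uses the least-squares cost over all
shocks and both channels, a hybrid genetic algorithm with simplex
refinement and restarts, and AIC/BIC/FPE for scheme ranking.

## Worked example

Simulate the double-ultrasensitive scheme under a 0.4 M NaCl step applied
at t = 5 min:

```r
library(osmounf)
traj <- simulate_osmo(scheme_config("UNF-UNF"), shock_input(0.4))
traj[traj$time %in% c(0, 6, 10, 30, 60), c("time", "V", "uHOG", "e", "uFps1")]
#> # A tibble: 5 × 5
#>    time     V   uHOG      e   uFps1
#>   <dbl> <dbl>  <dbl>  <dbl>   <dbl>
#> 1     0 1     0      0      0.5
#> 2     6 0.915 0.112  0.425  0.00218
#> 3    10 0.992 0.124  0.0407 0.214
#> 4    30 0.991 0.0463 0.0456 0.186
#> 5    60 0.993 0.0356 0.0349 0.252
```

One minute after the shock the volume has dipped ~8.5% and the Fps1
channel is essentially shut (`uFps1` fell from 0.5 to 0.002); by 10 min
glycerol production has restored the volume to within 1% and the channel
reopens only partially — the error stays inside the ultrasensitive
threshold band instead of returning to zero exactly. Compare
`scheme_config("PNF-PNF")`, which settles with a persistent error ≈ 0.25.

Fit a scheme to synthetic noisy data and inspect it broom-style:

```r
sch <- scheme_config("UNF-UNF")
d <- generate_shock_data(sch, sigma_v = 0.01, sigma_h = 0.01, seed = 42)
fit <- fit_scheme(d, sch, free = c("kHOG", "nHOG"), n_restart = 2, seed = 1,
                  ga_control = list(pop_size = 20, generations = 15))
glance(fit)
#> # A tibble: 1 × 8
#>   scheme       J n_free     N    AIC    BIC       FPE n_restart
#>   <chr>    <dbl>  <int> <int>  <dbl>  <dbl>     <dbl>     <int>
#> 1 UNF-UNF 0.0149      2   186 -1751. -1744. 0.0000817         2
tidy(fit)
#> # A tibble: 2 × 4
#>   term  estimate lower upper
#>   <chr>    <dbl> <dbl> <dbl>
#> 1 kHOG     0.199  0.01     1
#> 2 nHOG     2.04   1        8
```

The generating values (`kHOG = 0.2`, `nHOG = 2`) are recovered to within
2% from noisy data. `rank_schemes()` collects several such fits into a
J/AIC/BIC/FPE ranking table; `autoplot()` works on trajectories, loop
responses and fits.

The design rule on the generic loop:

```r
boundary_layer(K = 0.01, n = 2)
#> [1] 0.02
steady_state_error(generic_controller("UNF", kp = 1, K = 0.01, n = 2),
                   feedback_loop(), a_ud = 0.2)
#> [1] -0.004923
```

A unit-gain ultrasensitive controller holds the steady error of a
0.2-step disturbance at 0.005 — inside the guaranteed `4K/n = 0.02` band
— where a proportional controller with the same gain would leave an error
two orders of magnitude larger.

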