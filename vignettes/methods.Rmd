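---
title: "Delayed dual-feedback models of NF-kB: derivation, calibration and findings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delayed dual-feedback models of NF-kB: derivation, calibration and findings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nfkbdde)
```

This vignette records how the models shipped in `nfkbdde` are derived, how the
reference configuration was calibrated, the numerical choices behind the
solvers, and the structural findings of the analysis — including two places
where the reduced model genuinely refuses to behave the way the folklore about
this architecture says it should.

## 1. Model derivation

The module is a transcriptional negative feedback loop: nuclear NF-kB
activates synthesis of its inhibitors IkBa (and, in the dual model, IkBe),
which sequester NF-kB; the input is the IkB kinase activity $K(t)$, which
degrades IkB and frees NF-kB. Writing mass-action kinetics for the nine
elementary reactions of the single loop (promoter binding/unbinding, complex
association/dissociation, constitutive and induced synthesis with
transcription/translation lag, constitutive and IKK-mediated degradation) and
assuming the two binding reactions fast (quasi-equilibrium), the system
reduces to one delay-differential equation for total IkBa $y(t)$:

$$\dot y = c_0\,p_f(x_{\tau_1}) + c_1\,p_b(x_{\tau_1})
 - d_a\,y_f - r\,K\,(y_f + \rho\,y_b),$$

where $x$ is free nuclear NF-kB, $p_b(x) = x/(k_p + x)$ and
$p_f = 1 - p_b$ are the bound/free promoter probabilities, and
$(y_f, y_b)$ is the free/NF-kB-bound partition of $y$ at complex
quasi-equilibrium with dissociation constant $k_c$. Free NF-kB follows from
conservation of the total $n$:

$$x^2 + (k_c + y_a + y_e - n)\,x - n\,k_c = 0,$$

taking the positive root (promoter-bound NF-kB, at most a couple of copies,
is neglected in this bookkeeping — a point that returns in Section 6). The
dual model adds the same equation for IkBe with its own delay $\tau_2$,
constitutive rate $c_{0e}$, degradation $d_e$, and an overall loop-strength
scale $\varepsilon$ multiplying both synthesis terms; $\varepsilon = 0$
reduces the dual model exactly to the single one. The implementation
(`rhs_single()`, `rhs_dual()`, `solve_free_nfkb()`, `partition_ikb()`) is
verified in the test suite against an independent full mass-action ODE oracle
with explicit binding kinetics.

## 2. Linear stability

With tight binding ($k_c \to 0$) and under constant stimulation, the
linearization about the fixed point $y^*$ collapses to the scalar prototype
$\dot{\delta y} = -a\,\delta y - b\,\delta y(t - \tau_1)$ with
$a = \rho r K$ and $b = c_1 k_p/(k_p + n - y^*)^2$, whose dominant eigenvalue
is

$$\lambda = -a + \frac{1}{\tau_1} W\!\left(-b\,\tau_1 e^{a \tau_1}\right)$$

in terms of the principal branch of the Lambert function. `lambert_w()`
implements complex $W$ by Halley iteration (no installed package provides
complex branches) and is verified against the defining equation and a
brute-force spectral Newton oracle. Two properties matter downstream:

* **The period is delay-dominated.** $\mathrm{Im}\,W$ varies weakly over the
  relevant argument range, so the period $2\pi/\mathrm{Im}\,\lambda$ scales
  with $\tau_1$ and shifts by only a few percent when the input is
  quadrupled (`period_sensitivity()`).
* **The decay rate is only weakly input-sensitive.** Although $a = \rho r K$
  grows linearly in $K$, the argument of $W$ contains $e^{a\tau_1}$, so
  $\mathrm{Re}\,W/\tau_1 \approx a + \log(b\tau_1)/\tau_1 + \dots$ cancels
  most of that growth; the net decay rate increases monotonically but
  sublinearly (log-like) in $K$. A linear fit over any input window gives
  $R^2 \approx 0.96$, not $0.99$; the model simply is not linear in $K$ here.

## 3. Calibration of the reference configuration

`reference_params()` was produced once, before any acceptance outcome was
inspected, by anchoring literature-scale biochemical constants to three
printed observables: a ~90-minute oscillation period of the single loop under
persistent stimulation, a peak IkBa : IkBe ratio of 3.9 when
$\varepsilon = 1$, and a ~60-minute response duration (time above a 50 nM
free-NF-kB threshold) for a 15-minute input pulse. The structural findings of
that calibration:

* **Period**: with the measured synthesis delay $\tau_1 = 45$ min the
  linear period lands at ~2$\tau_1$; the nonlinear inter-peak interval of the
  full model is 90.5 min.
* **Peak ratio**: under stimulation both isoform totals track the
  quasi-steady level $c_1 p_b/(\rho r K)$, so the observable peak ratio is
  controlled by the *basal* IkBa level (which holds nearly all NF-kB) against
  the IkBe peak; $c_{0e}$, $d_e$ and $k_p$ set it. The shipped configuration
  gives 3.64 at $\varepsilon = 1$.
* **Duration**: the 50 nM threshold must sit well below the stimulated free
  pool for threshold crossing to be sharp, which fixes the NF-kB scale
  $n = 250$ nM; the response outlasts a short pulse by roughly one synthesis
  delay (in-flight synthesis keeps arriving), giving ~53 min for a 15-min
  pulse.
* **Loop strength**: $\varepsilon = 0.7$ maps the measured relative isoform
  abundance (a factor ~5.3) through the model's peak-ratio curve, mirroring
  the abundance-scaling procedure used to motivate $\varepsilon$ in the first
  place.

The calibrated single loop is *damped* (decay rate $+0.033$/min): the
oscillation rides on a high fixed point $x^* \approx 196$ nM with two to
three resolvable peaks. That regime is forced by the joint anchors — pushing
the loop into a limit cycle while keeping the period, ratio and duration
anchors was not achievable in an extensive constrained search.

## 4. The secondary delay does not damp at half the period

The central claim usually attached to this architecture is that the second
feedback loop, with its delay near 45 min, *damps* late-phase oscillations.
The reduced model says otherwise, and the reason is elementary. With tight
binding the two inhibitors sequester from the same NF-kB pool, so the
linearized dual system collapses to a scalar **two-delay** equation in the
summed inhibitor:

$$\dot{\delta s} = -a\,\delta s - b_1\,\delta s(t - \tau_1)
 - b_2\,\delta s(t - \tau_2), \qquad b_2 \propto \varepsilon.$$

Perturbing the single-loop root $\lambda = \sigma + i\omega$ to first order
in $b_2$ gives $\partial \sigma / \partial b_2 \propto -\cos(\omega \tau_2)$
(up to a positive factor). The single loop oscillates with period
$P = 2\pi/\omega \approx 90$ min, so:

* $\tau_2 \lesssim P/4$ (under ~22 min): $\cos \omega\tau_2 > 0$, the
  $\varepsilon$ term **damps** — the scan minimum sits at $\tau_2 = 0$ on the
  reference grid (metric $4.4\times10^{-4}$ nM vs the single loop's
  $9.1\times10^{-4}$ nM);
* $\tau_2 = P/2 = 45$ min: $\cos \omega\tau_2 = -1$, the $\varepsilon$ term
  is **maximally destabilizing** — the scan metric at
  ($\tau_2 = 45, \varepsilon = 1$) is three orders of magnitude above the
  single loop.

`damping_scan()` (analysis script `03`) confirms this over the full
$(\tau_2, \varepsilon)$ surface, and nonlinear simulations agree. The
consequences propagate:

* the scan argmin is 0, not 45 (release criterion on the optimal delay is
  red, by design of honest reporting);
* at the reference $\tau_2 = 45$ the dual network's **late-phase stochastic
  CV is larger** than the single network's (0.131 vs 0.091 at $n = 1000$,
  200 runs) — the noise-suppression ordering is inverted for the same
  structural reason;
* the quantized-vs-graded duration contrast (next section) loses its
  mechanism.

We report these as findings of the reduced model, implemented exactly as
specified, rather than adjusting metrics until they agree with expectation.

## 5. Duration encoding: graded, quantized, and when each occurs

`duration_response()` maps input-pulse duration to the total time free NF-kB
spends above a threshold. Three regimes:

* **No feedback** (constitutive synthesis only): activation is fast but
  deactivation takes hours — the response saturates at the observation
  window regardless of pulse length. Feedback is what turns the output off.
* **Damped feedback (the calibrated regime)**: the stimulated trajectory
  settles far above the 50 nM threshold, so the response tracks the input
  with unit slope — *graded* for single and dual alike. Short pulses outlast
  the input by roughly one synthesis delay (in-flight synthesis must arrive
  before the output can shut off), while long pulses shut off within minutes
  of input removal.
* **Limit-cycle feedback with the threshold inside the oscillation band**:
  each cycle contributes a fixed above-threshold quantum, so the response is
  a staircase — many different input durations share one output plateau
  (`analysis/04`, plateaus spanning 80–90 min of inputs). This is the
  quantization mechanism, and it is real; but it appears in *any*
  persistently oscillating loop here, dual included, because the second loop
  does not damp the first (Section 4). The single-quantized/dual-graded
  contrast therefore does not emerge from this reduced model.

## 6. Exact stochastic simulation with delays

`build_network()` translates the rate constants into discrete propensities
via $\Omega = n_{\text{copies}}/n$, with explicit association/dissociation
(dissociation rates `k_off_complex`, `k_off_promoter` set the
quasi-equilibration speed; association follows from $k_c$, $k_p$), one
binary promoter per gene, and delayed synthesis channels whose stoichiometry
is applied only when the delay elapses (delayed-update SSA with a pending
completion queue; piecewise-constant $K(t)$ handled by propensity barrier
events; implemented in C++ on R's RNG so seeds are bit-reproducible).

Two consistency points were needed to make the ensemble mean agree with the
deterministic solution to within statistical resolution (3 standard errors
at 20 checkpoints, 200 runs, $n = 1000$):

* **Observable mapping.** The reduced model's $x$ folds the neglected
  promoter-bound NF-kB into the free pool. In the depleted-IkB plateau the
  ensemble SD is ~0.5 copies while the mean promoter occupancy is ~0.3
  copies, so comparing raw free copies fails by ~7 SE for bookkeeping
  reasons alone. The faithful discrete observable is the NF-kB pool *not
  sequestered by IkB*: `species = c("N", "Pb")` (plus `"Qb"` for dual).
* **Queue prewarming.** A cold delayed queue at $t = 0$ is inconsistent with
  the deterministic solver's constant pre-stimulus history: basal syntheses
  initiated during $[-\tau, 0)$ are missing, about half a copy of IkB influx
  during the first delay, which biases the first descent by several SE.
  `ssa_simulate(prewarm = TRUE)` seeds Poisson in-flight completions at the
  basal propensities — the stochastic analogue of the constant history.

With both in place the worst checkpoint deviation is ~2.2 SE for single and
dual networks.

For noise metrics, `cv_peak_and_late()` reports the ensemble CV at the mean
trajectory's first peak and averaged over the late phase;
`damping_metrics()` contrasts the mean of per-cell late-phase amplitudes
(`a_single`) with the amplitude of the population-mean trajectory
(`a_population`) — dephasing guarantees
$a_{\text{population}} \le a_{\text{single}}$, and the gap measures how much
apparent damping is an averaging artifact. The auto-repressor contrast
network (signal-activated delayed self-repressor, four reactions) is scaled
so its ensemble-mean peak matches the NF-kB networks' (~1000 copies at
$n = 1000$); its slow promoter kinetics make its first peak ~50× noisier
than the NF-kB networks' (CV 0.028 vs 0.0006), whose sequestration topology
pins the early response.

## 7. Numerical choices

* DDE integration: `deSolve::dede` (method-of-steps lsoda) behind
  `integrate_dde()`; default `rel_tol = 1e-8`, `abs_tol = 1e-10`,
  `max_step = 1` min so input switch times are never stepped over; dense
  output every 0.25 min for peak detection.
* Fixed points: 1-D `uniroot` on the conservation residual; the simplified
  large-input fixed point has a closed quadratic form used by the stability
  module.
* Threshold crossings: bracketed linear interpolation on the dense grid
  (`time_above_threshold()`), exact for the piecewise-linear interpolant.
* Calibration: bounded Brent (one free parameter) or Nelder-Mead on a
  logistic box transform (`calibrate_parameters()`).

## 8. Surrogate data and delay estimation

`gen_mrna_course()` generates logistic induction time courses crossing
half-maximum at the true synthesis delay, with lognormal (mean-corrected) or
Gaussian noise; `estimate_half_max_delay()` applies the half-maximal
induction rule (normalize to the observed maximum, first linear-interpolated
50% crossing). Because the rule normalizes to the noisy maximum, it carries
a small positive bias (~2 min at CV 0.1 with 3-min sampling), which is why
recovery is quoted at the 30–45-min delay scale where it is well within 10%.

## 9. Limitations

The reduction has no nuclear/cytoplasmic shuttling, no upstream kinase
cascade, and absorbs mRNA dynamics into pure delays; promoter-bound NF-kB is
neglected deterministically (but represented stochastically); extrinsic
noise is modeled as static parameter scatter, not slow fluctuation. The
findings of Sections 4–5 are statements about this reduced model class —
they say that the damping-at-45-min narrative cannot be rescued *within*
the reduction, not that richer models with compartments or mRNA dynamics
behave the same way.
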