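# nfkbdde

Reduced delay-differential models of the IkBa/IkBe–NF-kB negative feedback
module, with Lambert-W linear stability analysis, damping optimization of the
secondary feedback loop, duration-encoding analysis of pulsed stimulation,
and exact stochastic simulation of the discrete reaction networks with
delayed synthesis (Gillespie algorithm with delayed-update reactions).

Nuclear NF-kB activates transcription of its own inhibitors; synthesis
arrives after a transcription/translation delay, sequesters NF-kB, and the
input kinase activity K(t) degrades the inhibitors to free it again. The
package reduces the mass-action network to one delay equation per inhibitor
(quasi-equilibrium binding), analyses the oscillatory response analytically
(dominant eigenvalue via the complex Lambert function), and simulates the
matching discrete stochastic networks exactly. The methods vignette
(`vignettes/methods.Rmd`) derives the equations, documents the calibration of
the shipped reference configuration, and reports two structural findings: in
this reduced model a secondary loop delayed by half the primary period
*destabilizes* rather than damps the late response, and the
quantized-vs-graded duration contrast between the single and dual loops has
no mechanism without that damping.

## Worked example

```r
library(nfkbdde)
p <- reference_params()

# deterministic response to persistent stimulation, oscillation measurement
tr <- integrate_dde("single", p, input_signal(amplitude = reference_K()),
                    t_end = 480)
osc <- measure_oscillations(tr, t_cut = 0)
osc$period_estimate
#> [1] 90.5

# analytic period/decay from the Lambert-W dominant eigenvalue
lin <- dominant_eigenvalue(p, reference_K())
round(c(period = lin$period, decay = lin$decay_rate), 4)
#> period  decay
#> 97.923  0.033

# dual model: isoform peak ratio at full secondary-loop strength
peak_ratio(p, eps = 1, K = reference_K())
#> [1] 3.639582

# duration encoding: total time free NF-kB exceeds 50 nM after a 15-min pulse
dc <- duration_response("dual", p, K = reference_K(), pulse_durations = 15,
                        threshold = 50, t_end = 480)
dc$response_duration_min
#> [1] 53.42572

# exact delayed-SSA ensemble of the discrete single-loop network
net <- build_network("single", p, n_nfkb_total = 1000)
ens <- ssa_ensemble(net, n_runs = 20, input_signal(amplitude = reference_K()),
                    t_end = 120, dt = 1, seed = 1)
round(ens[ens$time_min %in% c(30, 45, 60, 90), ], 3)
#>    time_min   mean     sd    cv
#> 31       30 999.65  0.489 0.000
#> 46       45 999.65  0.489 0.000
#> 61       60 737.15 70.731 0.096
#> 91       90 768.45 71.707 0.093
```

## Repository layout

- `R/`, `src/` — package code: model core, DDE engine (`deSolve::dede`),
  stability (complex Lambert W), delayed SSA (Rcpp), pipelines
  (damping scan, duration response, extrinsic noise), surrogate-data
  generators, config/trajectory IO.
- `analysis/01`–`06` — numbered study drivers (deterministic response,
  stability, damping scan, duration encoding, stochastic noise, delay
  estimation); each writes CSV/JSON under `results/`.
- `tests/testthat/` — unit oracles plus `test-acceptance.R`, one block per
  release criterion. Two checks encode published expectations the reduced
  model demonstrably does not satisfy (the 45-min damping optimum and the
  dual-vs-single late-phase noise ordering); they are left red deliberately —
  see the vignette, Section 4.
- `scripts/acceptance.R` — headline quantitative targets.

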