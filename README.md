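# klepsydra

Analysis of **duration reproduction** experiments with the **dual klepsydra
model** (DKM), for researchers in time perception and computational
psychophysics who want to separate *stimulus-induced* changes of perceived
duration (e.g. by emotionally arousing sounds) from the general
*progressive shortening* of reproduced intervals.

## The model

A "klepsydra" is a water clock: an integrator that leaks while it fills.
The DKM represents each interval of a reproduction trial by the state of a
lossy integrator, dx/dt = F − κx. One unit fills at inflow η during the
encoding phase (duration *s*), leaks through the pause *w* and the
reproduction phase; a second fills at unit inflow from reproduction onset.
The response ends when the states are equal, giving the reproduction
function

    r = κ⁻¹ · log{ 1 + η · e^(−κw) · (1 − e^(−κs)) }

* **κ** (s⁻¹): leakage/outflow rate — a tonic individual trait producing
  the decrease of r/s with increasing s (Vierordt-type shortening).
* **η**: encoding/reproduction inflow ratio — the locus of phasic,
  stimulus-induced effects; η > 1 lengthens reproductions.

Per subject, the pipeline estimates κ from all 45 trials (least squares,
formally η = 1), then η per valence condition (P = positive, N = negative,
E = neutral), then the net inflow ratios η_PE = η_P/η_E and η_NE = η_N/η_E
(null expectation 1). In parallel, the model-free aggregate ratio index
a_v = ⅓ Σᵢ r̄_{v,i}/r̄_{E,i} is computed from the 3 × 3 cell means. Group
inference uses one-sample and paired t-tests, repeated-measures ANOVA with
Greenhouse–Geisser correction, Pearson correlations, and fixed-bandwidth
(σ = 0.04) Gaussian KDEs. A seeded generator provides synthetic cohorts
with the reference design (31 subjects × 45 trials; κ lognormal, median
0.03 s⁻¹, clipped to [0.003, 0.096]; true ratios 1.08/1.04; multiplicative
lognormal noise, σ_log = 0.10) plus injectable over-reproducers and
non-responders. See `vignettes/dkm-methods.Rmd` for assumptions, defaults
and limitations.

## Worked example

```r
library(klepsydra)
coh <- simulate_cohort(cohort_spec(n_subjects = 31, n_over_reproducers = 4,
                                   n_non_responders = 1, seed = 1))
report <- run_analysis(coh$trials)
print(report)
```

```
DKM analysis report (31 subjects, 5 excluded)
-- full cohort (n = 31)
   mean a_P = 1.0616 (t = 6.690, df = 30, p = 2.065e-07)
   mean a_N = 1.0301 (t = 4.536, df = 30, p = 8.596e-05)
   ...
-- cleaned cohort (n = 26)
   mean a_P = 1.0736 (t = 8.730, df = 25, p = 4.615e-09)
   mean a_N = 1.0334 (t = 4.618, df = 25, p = 0.0001002)
   mean eta_pe = 1.0714 (t = 6.947, df = 25, p = 2.787e-07)
   mean eta_ne = 1.0351 (t = 3.667, df = 25, p = 0.001158)
   ANOVA valence: F = 39.882, GG df = (1.83, 45.64), p = 2.637e-10
   ANOVA duration: F = 857.008, GG df = (1.13, 28.34), p = 2.379e-23
   ANOVA valence:duration: F = 1.850, GG df = (3.05, 76.21), p = 0.1444
   r(a_N, eta_ne) = 0.740 (df = 24, p = 1.563e-05)
   r(a_P, eta_pe) = 0.842 (df = 24, p = 6.846e-08)
   ...
```

Reading this: the 4 injected over-reproducers stop the κ fit at its 0
boundary and the injected flat responder trips the slope rule, cleaning the
cohort to n = 26. On the cleaned sample both the model-free index a_P and
the model-based inflow ratio η_PE sit ≈ 7% above their null value 1
(positive sounds are reproduced longer than neutral ones), the negative
condition shows a smaller ≈ 3–4% effect, the valence main effect is highly
significant while the duration effect (progressive shortening itself)
dominates, and the model-free and model-based measures correlate strongly
(r ≈ 0.74–0.84) — they measure almost the same thing, with the inflow
ratios cleanly separated from κ.

`write_report(report, "out/")` writes `report.json` (full precision,
byte-stable), `subjects.csv`, `kde_curves.csv` and `summary.txt`. The same
pipeline runs from the shell:

```sh
Rscript exec/dkm simulate --out sim --n-subjects 31 --seed 1
Rscript exec/dkm analyze  --input sim/trials.csv --out results
```

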