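# taguchiomega

Quality-improvement analysis for dialyzer solidification in hemodialysis:
a Taguchi L9(3⁴) orthogonal-array experiment over four process factors,
attribute-data (good/defective) accumulation analysis with
smaller-the-better level selection, defect-rate prediction through the
omega (logit-decibel) transformation, and a from-scratch back-propagation
network used as a stability check on the selected combination.  A
synthetic-data generator (Bernoulli run outcomes, categorical patient
covariates) makes every stage testable without external data.

## Who this is for

Quality engineers and biostatisticians analysing binary (count-value)
outcomes from fractional-factorial experiments — here, whether a dialyzer
ends a hemodialysis session with ≥20% of its fiber volume clotted
("defective") as a function of anticoagulation dose (500/1000/1500 units),
blood-flow velocity (200/250/300 ml/min), dehydration volume
(1.5/2.5/3.5 kg) and vascular access type.

## The method in brief

For factor *F* at level *ℓ*, the accumulated defect rate is the defective
count summed over the design rows with *F = ℓ*, divided by the dialyzers
observed there (90 per factor-level in the 9 × 30 reference experiment).
Each factor's best level minimises this rate.  Because rates are not
additive across factors, the selected combination's rate is predicted on
the decibel scale:

    Ω = 10·log₁₀((1 − P)/P)
    Ω(comb) = Σᵢ Ω(level_i) − (m − 1)·Ω(overall),    P = 1/(1 + 10^(Ω/10))

A 4-5-1 sigmoid network trained with the online delta rule plus momentum
(η = 0.1, α = 0.1, 500 cycles, 80/10/10 split) checks that the condition →
defect-rate map is learnable and stable; analytic gradients are verified
against central finite differences.

## Worked example

```r
library(taguchiomega)
rep <- run_pipeline(confirmation = load_fixture("table10"), seed = 1)
print(rep)
```

```
== Dialyzer solidification analysis ==
[effect_analysis] 9 conditions, 270 runs; baseline defect rate 86/270 = 32%
[selection] A1B3C2D2
[omega] paper rounding: 8.19 dB -> 13.17%; full precision: 8.2056 dB -> 13.13%
[bpn] final training MSE 0.00751; converged at epoch 2
[confirmation] 35/270 defective = 12.9%
```

Reading this: the packaged 270-run experiment has a 32% baseline defect
rate; the accumulation analysis selects 500 units anticoagulation (A1),
300 ml/min blood flow (B3), 2.5 kg dehydration (C2) and autologous access
(D2); the omega chain predicts a 13.17% defect rate for that combination
(8.19 dB on the decibel scale, using 2-decimal hand-calculation rounding;
13.13% at full precision); the network fits the per-condition rates to a
mean squared error of 0.0075; and the 270-run confirmation experiment at
the selected settings observed 35 defective dialyzers, i.e. 12.9% —
close to the prediction and far below baseline.

The numbered scripts under `analysis/` run the same stages one at a time
and write their tables under `results/` (design, effect table, omega
predictions in both rounding modes, convergence curves, confirmation
arithmetic, and a Monte-Carlo study of how reliably simulated data recover
the true best combination).

## Package layout

- `R/` — design construction and validation, accumulation analysis, omega
  transformation, the back-propagation network, synthetic-data generation,
  pipeline orchestration.
- `inst/extdata/` — the reference experiment's tables as plain CSV
  (factors, L9 array, per-condition counts, cohort covariates,
  confirmation counts), loaded via `load_fixture()`.
- `analysis/` — numbered narrative drivers for each stage.
- `tests/testthat/` — unit, property and end-to-end tests.
- `vignettes/dialyzer-solidification-workflow.Rmd` — the methods account:
  model assumptions, rounding modes, network design choices, what the
  generator does and does not emulate, limitations.
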