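# isrfit

Model-based inference of the **insulin secretion rate (ISR)** and
**c-peptide secretion rate (CSR)** from sparse oral glucose tolerance test
(OGTT) measurements.

## The problem

An OGTT samples plasma glucose, insulin, and c-peptide at a handful of times
over ~3 hours. The quantity of clinical interest — how much insulin the
beta cells secrete *as a function of glucose* — is not measured directly and
must be inferred through a model of hormone accumulation and clearance.
`isrfit` is for researchers and modelers who want a *parametric* secretion
functional per subject, with uncertainty, from exactly such sparse records.

The secretion functional is a glucose-dependent sigmoid

```
u(g) = Km / (1 + exp(alpha * (C0 - g)))
```

with maximum rate `Km`, glucose midpoint `C0`, and inverse width `alpha`.
Plasma insulin (or c-peptide) follows first-order clearance

```
dx/dt = u(g(t)) - x / tau_p
```

(optionally a two-compartment plasma/interstitium variant). Glucose enters
as a cubic-spline interpolation of the measured values; the system is
propagated by the exact discretization `Phi = exp(A*Ts)`,
`Gamma = A^-1 (Phi - I) B` at `Ts = 0.1` min. The unknowns
`(tau_p, Km, C0, alpha)` are estimated by multi-start bounded nonlinear
least squares (Levenberg–Marquardt descents from many random starts inside
physiological bounds; solutions that end on a bound are excluded), and the
surviving ensemble yields mean ± SD parameters and trajectories.

Insulin and c-peptide are fitted independently; since they are co-secreted
at a 1:1 molar ratio (0.056 ng/µU in the working units), the slope of the
fitted CSR~ISR relation validates the pair of fits and estimates first-pass
hepatic insulin extraction `alpha_h = 1 - 0.056/slope`. A
leave-one-timepoint-out screen identifies suspect measurements whose
removal improves all goodness-of-fit metrics.

## Worked example

Simulate a synthetic OGTT subject (5% assay-level noise) and fit it:

```r
library(isrfit)

spec <- synthetic_spec(noise_fraction = 0.05)
subj <- generate_subject(spec, seed = 42)
rec  <- subj$record
rec
#> <ogtt_record> synthetic-seed42: 10 samples over [-10, 180] min, glucose in mg/L
#>   insulin measured at 10 times, c-peptide at 10

fits <- fit_subject(rec, bounds = validation_bounds(), n_starts = 100, seed = 1)
fits$insulin
#> <fit_ensemble> synthetic-seed42 / insulin (single model)
#>   accepted 21 of 100 starts (seed 1)
#>   parameter      mean        sd     ci_lo     ci_hi
#> 1     tau_p 1.482e+01 8.157e-07 1.482e+01 1.482e+01
#> 2        Km 6.349e-01 1.615e-08 6.349e-01 6.349e-01
#> 3        C0 1.073e+03 1.715e-05 1.073e+03 1.073e+03
#> 4     alpha 8.158e-03 8.151e-10 8.158e-03 8.158e-03

fit_report(rec, fits$insulin, fits$cpeptide)
#> <fit_report> synthetic-seed42
#>   RMS insulin 0.1394 | c-peptide 0.1473 | CSR~ISR 0.2063
#>   CSR~ISR slope 0.0711 ng/uU (molar expectation 0.056), alpha_h 0.212
#>   ISR at 140 mg/dl: 0.5937 +- 3.011e-08
```

Reading the output: the generating subject had `tau_p = 15` min,
`Km = 0.6`, `C0 = 1000` mg/L, `alpha = 0.01` per mg/L. The 100-start
ensemble converged to a single optimum (21 accepted interior solutions,
negligible spread) recovering the degradation time within ~1%; the secretion
parameters carry more noise-induced error, which the normalized RMS errors
(~0.14 per trajectory) and the CSR~ISR slope (0.071 vs the molar 0.056)
quantify. At zero noise the same pipeline recovers every parameter to
~1e-13 relative.

Screen a suspect timepoint (e.g. a spuriously low 60-minute glucose draw):

```r
bad <- generate_subject(synthetic_spec(noise_fraction = 0.05,
         corruption = list(time = 60, factor = 0.5)), seed = 3)
screen_timepoint(bad$record, 60, n_starts = 40, seed = 81)
#> <screen_result> timepoint 60 min: all three metrics improve on removal (suspect)
```

Clinical-style CSV records (`time_min, glucose, insulin, cpeptide`) are read
with `read_ogtt()`; a thin command-line wrapper ships in `inst/exec/isrfit`
(`simulate`, `fit`, `screen` subcommands).

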