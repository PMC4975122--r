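# ageadapt

Model-based analysis of facial **age adaptation aftereffects**: does
adaptation renormalize perceived age, or locally repel it?

After staring at old (or young) faces for a while, the faces you see next
look a little younger (or older). Two standard accounts of face coding make
different predictions about the *pattern* of these aftereffects across test
ages:

- **Norm-based renormalization.** Faces are coded relative to a prototype.
  Adapting drags the norm toward the adaptor, so *all* test ages shift by a
  similar amount in one direction; adapting to the norm itself does nothing.
  The predicted aftereffect is constant in test age,

  `a(t) = k (t_norm − t_adapt)`,

  with a single gain parameter `k`.

- **Multichannel local repulsion.** Faces are coded by channels tuned to
  absolute ages. Test ages on either side of the adaptor are pushed *away*
  from it, with a null at the adapting age. The standard descriptive form is
  a Gaussian derivative (GD),

  `a(t) = A √e · u · exp(−u²/2)`, `u = (t − μ)/σ`,

  parameterised so the extrema are exactly `±A` at `μ ± σ`, with the
  zero-crossing `μ` pinned to the adapting age.

`ageadapt` is aimed at visual psychophysicists who want to fit and compare
these accounts on per-face pre/post age-rating data. It provides:

- the two prediction functions and a three-condition study design
  (adapt ≈ 35 / 57 / 65 years, test range 18–89);
- least-squares fits: the 1-parameter renormalization model (closed form),
  the 2-parameter constrained repulsion model (GD with the null forced to
  each adapting age, amplitude and bandwidth shared across conditions), and
  the 3-parameter *unconstrained* per-condition GD whose pathologies
  (zero-crossings at impossible ages, wildly inconsistent bandwidths)
  motivate the constrained comparison;
- model comparison by RMS error against a no-model baseline, with a
  Wilcoxon signed-rank test on paired per-point absolute residuals (exact
  enumeration for ≤ 12 pairs, tie- and continuity-corrected normal
  approximation otherwise);
- the intercept-curve regression analysis: OLS lines fit to GD aftereffect
  curves always have *negative* intercepts, whereas uniform renormalization
  shifts the intercept by `+A` (young), `0` (middle), `−A` (old) — opposite
  signs for young vs old adaptors, the discriminating signature;
- a synthetic multi-observer rating generator for power, type-I-error and
  parameter-recovery studies, plus CSV/JSON I/O and an end-to-end pipeline.

## Worked example

Simulate a renormalization-truth experiment (24 faces per condition, rating
noise 3 years per observer, 20 observers averaged), fit both models, and
compare:

```r
library(ageadapt)

design <- study_design()
dat <- generate_dataset(simulation_config(truth_model = "normalization",
                                          seed = 42))
fit_n <- fit_normalization(dat, design)
fit_r <- fit_constrained_repulsion(dat, design)
fit_n
#> Fit: normalization
#>   k = 0.09564 (norm age 57 y)
#>   SSE = 31.292 over 72 points; RMS = 0.6593 y
fit_r
#> Fit: constrained_repulsion
#>   A = 1.656 y, sigma = 100 y
#>   SSE = 122.56 over 72 points; RMS = 1.305 y

compare_models(dat, fit_n, fit_r)
#> Model comparison: renormalization vs constrained repulsion
#> (winner declared at two-sided alpha = 0.05)
#>
#>     scope  n rms_normalization rms_repulsion rms_no_model wilcoxon_z wilcoxon_p
#>     young 24             0.628         1.760        2.140      -3.84   1.22e-04
#>    middle 24             0.711         0.844        0.711      -1.07   2.84e-01
#>       old 24             0.635         1.140        1.120      -3.01   2.58e-03
#>  combined 72             0.659         1.300        1.450      -4.91   8.97e-07
#>  n_pairs  better_model
#>       24 normalization
#>       24           tie
#>       24 normalization
#>       72 normalization
```

Reading the table: the true gain 0.1 is recovered as `k = 0.096` (a constant
shift of `+2.1` years after adapting young, `−0.8` after adapting old). Both
fitted models beat the no-model baseline, but normalization has the smaller
RMS error, and the signed-rank test on the paired absolute residuals makes
the combined difference decisive (negative `z`: the first model's errors are
smaller). In the middle condition normalization predicts exactly zero
aftereffect, so its RMS *equals* the baseline there and the two models are
statistically tied — itself a hallmark of norm-based coding.

The intercept analysis shows why a repulsion account cannot mimic opposite
intercept shifts for young vs old adaptors:

```r
intercept_curve(design, "young")
#> Intercepts of OLS lines fit to GD aftereffect curves (young condition)
#> Uniform-renormalization reference intercept: +2.4 y
#>  sigma intercept
#>      2  -0.06825
#>      5  -0.42330
#>     10  -0.98960
#>     20  -1.31600
#>     30  -1.84000
#>     40  -1.99400
#>     48  -1.95000
#>     50  -1.92800
#>     80  -1.49700
```

Every GD bandwidth yields a *negative* intercept, while a uniform
renormalization of the same peak size shifts the intercept by `+2.4` years.

The whole analysis is also available as one call
(`run_pipeline(run_config(...))`, writing `ratings.csv`, `report.json` and
`fitted_curves.csv`), and as shell subcommands
(`Rscript inst/scripts/ageadapt-cli.R run --seed 3 --out out/`).

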