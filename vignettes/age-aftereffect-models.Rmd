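---
title: "Renormalization versus repulsion: methods behind ageadapt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Renormalization versus repulsion: methods behind ageadapt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ageadapt)
```

## The scientific question

Perceived facial age is one of the few face dimensions observers can report
on a ratio scale, which makes it a rare testbed for a long-standing question
in face perception: are faces coded **relative to a norm** (a prototype,
with adaptation shifting the norm) or by **channels tuned to absolute
levels** (with adaptation locally desensitising channels near the adaptor)?
The two accounts predict qualitatively different aftereffect patterns when
observers rate the same faces before and after adapting to young,
middle-aged, or old faces:

* *Renormalization*: aftereffects of similar size and direction at every
  test age, scaling with the adaptor's distance from the norm, and no
  aftereffect when adapting to the norm itself. Adapting young and adapting
  old shift ratings in opposite directions.
* *Local repulsion*: aftereffects in opposite directions on either side of
  the adapting age, a null at the adaptor, and the same local pattern at
  every adapting level.

`ageadapt` implements both accounts as explicit prediction functions, fits
them to per-face aftereffect data, and compares them in a way that does not
reward the repulsion model for its extra parameter.

## Models and their parameterisation

**Renormalization** (`normalization_aftereffect`) predicts a constant
aftereffect per condition,

$$ a(t) = k\,(t_{\mathrm{norm}} - t_{\mathrm{adapt}}), $$

with one dimensionless gain $k$. The norm age defaults to the middle
adapting age (57 years), the age observers treat as age-neutral; it is a
configurable field of `study_design()` because nothing in the model forces
the two to coincide.

**Repulsion** (`gd_aftereffect`) uses the field's standard descriptive
shape, the first derivative of a Gaussian,

$$ a(t) = A \sqrt{e}\; u\, e^{-u^2/2}, \qquad u = (t - \mu)/\sigma . $$

We parameterise by the *peak* aftereffect $A$ rather than a derivative
scale: the extrema are exactly $\pm A$ at $\mu \pm \sigma$, which is how
aftereffect magnitudes are quoted in practice and what makes amplitudes
comparable across bandwidths in the intercept analysis. Positive
aftereffects mean "perceived as older" throughout, so $A > 0$ pushes test
ages above the null older, as repulsion requires. All predictions are
functions of the *preadapt perceived age*, not the physical stimulus age:
the preadapt rating is the only age scale the data themselves provide.

The **constrained repulsion model** (`fit_constrained_repulsion`) is the GD
with its zero-crossing pinned to each condition's adapting age and a single
$(A, \sigma)$ shared by all conditions — the two assumptions that make it a
viable mechanism rather than a curve family. The **unconstrained GD**
(`fit_unconstrained_gd`) frees $(A, \sigma, \mu)$ per condition. It is
included deliberately: with wide bounds ($\mu \in [-50, 150]$ years) it
happily places the null at impossible ages while approximating a
near-linear trend over the measured range, which is precisely the pathology
that motivates constraining the model before comparing accounts.

## Fitting

The renormalization gain is linear in the residuals, so its pooled
least-squares solution is closed form, $k = \sum y_i d_i / \sum d_i^2$ with
$d_i$ the norm-to-adaptor distance of point $i$; points adapted at the norm
have $d_i = 0$ and contribute residuals against a zero prediction.

GD fits are genuinely multimodal in $\sigma$ (and $\mu$), so both GD fits
are multi-start: bandwidth restarts at $\{2, 5, 10, 20, 40, 80\}$ years
(joined by a $\mu$ grid in 10-year steps for the unconstrained fit), each
refined by bounded quasi-Newton iterations (`optim` L-BFGS-B, relative SSE
tolerance $10^{-8}$, $A \in [-20, 20]$, $\sigma \in [1, 100]$ years). The
amplitude enters the SSE quadratically at fixed $\sigma$, so each restart is
initialised at the clamped closed-form amplitude. Best-of-restarts is by
SSE with a deterministic tie-break (smallest $\sigma$, then smallest
$|A|$); non-convergence of every restart raises an error rather than
returning silently. On 30-point datasets the tests require the optimizer to
match a dense $(A, \sigma)$ grid evaluation of the same SSE surface to
within 0.1%.

Degenerate inputs are reported, not guessed at: all-zero aftereffects give
$A = 0$ with the bandwidth at its first initialisation and an
`identifiable = FALSE` flag, since $\sigma$ is then meaningless.

## Model comparison

Each model is scored by RMS error per condition and pooled, against the
no-model baseline (RMS of the raw aftereffects). Because both parameter
spaces contain the zero model, a fitted model can never lose to the
baseline on its own training data — a useful invariant check, not a
finding.

The models are compared by a **Wilcoxon signed-rank test on paired
per-point absolute residuals**, which makes minimal distributional
assumptions and does not penalise the repulsion model for having one more
parameter. "Relative errors" admits more than one reading; we pair
$|y_i - \hat y_i^{\mathrm{norm}}|$ with $|y_i - \hat y_i^{\mathrm{rep}}|$
— the most common convention — and include the middle condition's points in
the combined test. Zero differences are dropped and tied absolute
differences get midranks. For $n \le 12$ usable pairs the null distribution
of the positive-rank sum is enumerated exactly over all $2^n$ sign
assignments; for larger $n$ a normal approximation with tie correction and
a 0.5 continuity correction is used. The reported $z$ is signed so that
positive values mean the first model's errors are larger. A winner is
declared only when the two-sided $p$ falls below $\alpha$ (default 0.05);
otherwise the scope is a tie, which is the expected outcome both under a
no-effect truth and in the middle condition, where renormalization predicts
exactly zero aftereffect and so coincides with the baseline.

## The intercept-curve analysis

The regression analysis asks what adaptation does to the line relating
rated age to test age. A uniform renormalization shift of $s$ changes the
intercept by exactly $s$ and the slope not at all — so young and old
adaptors produce intercept shifts of opposite sign ($+A$, $0$, $-A$ for a
peak-matched shift). Repulsion instead steepens the line and, for every
bandwidth in the default grid $\{2, 5, 10, 20, 30, 40, 48, 50, 80\}$ years
and every adapting age, drives the intercept *negative*:

```{r intercepts}
intercept_curves_all(study_design(), sigma_grid = c(5, 20, 48))
```

Curves are sampled at integer ages 18–89 (72 points, unweighted OLS) —
integer years are the natural sampling unit and the choice affects
intercepts only in the third decimal. Intercepts are the conventional OLS
value at age 0, extrapolated below the test range; evaluating at age 18
instead would shift all curves by 18 times the slope without changing any
sign conclusion. `slope_intercept_change()` applies the same logic to
pre/post rating vectors directly.

## What the synthetic data emulate — and what they do not

No raw per-face ratings from the original study are publicly available, so
the package ships a generator (`generate_dataset`) that emulates the study
*design*: three adapting conditions, per-face preadapt ages spread evenly
(with jitter of at most 30% of the grid spacing) over 18–89 years, and
per-face aftereffects built as post-minus-pre rating means.

Noise enters each observer's pre and post rating independently (both are
behavioural judgments), so per-face aftereffects carry noise of standard
deviation $\sqrt{\sigma_{\mathrm{pre}}^2 + \sigma_{\mathrm{post}}^2} /
\sqrt{n_{\mathrm{obs}}}$ — the formula the calibration test checks. The
default condition is 24 faces per condition, post-rating noise of 3 years
per observer, no pre-rating noise, and 20 observers averaged: individual
age judgments scatter by a few years, and averaging across a typical
observer panel leaves a per-face standard error near 0.7 years, small
enough that aftereffects of around 2 years are reliably measurable. Truth
models default to a gain of 0.1 (a +2.2-year shift after adapting young) or
a GD with $A = 2.4$, $\sigma = 20$ years, the aftereffect scale typical of
age adaptation. The preadapt perceived age is used as the regressor without
measurement-error correction, mirroring the analysis the package
implements.

Passing tests on these data show that the pipeline recovers known
parameters and selects the generating model under realistic noise; they do
not show that real observers satisfy the generator's assumptions. In
particular the generator has no lapses, no scale compression at extreme
ages, no observer-specific biases, and no correlation between a face's
rating errors across the pre and post phases beyond the shared latent age.
Real data may also leave both models significantly worse than their fits
here; the per-face scatter of averaged human ratings around *any* smooth
model can be ~3 years, at which scale 24 faces per condition would not
reliably separate the models — discrimination at the default design relies
on the observer averaging described above.

## Problem sizes and numerical choices

The validation studies run at sizes chosen to estimate rates stably while
keeping the full suite quick: 200 replicate datasets for parameter recovery
(mean recovered $A$ within 0.2 years of 2.4, mean $k$ within 0.01 of 0.1),
200 replicates per truth model for selection rates, 20 datasets of 30
points for the optimizer-versus-grid check, and exact-versus-approximate
signed-rank comparisons at $n = 5$–$12$. Reproducibility is strict: every
simulation is seeded, the generator restores the caller's RNG state, and
two pipeline runs with the same configuration and seed produce
byte-identical JSON reports (datasets with different seeds share their
structure — conditions, face ids, grid — and differ only in the stochastic
draws).

## Known limitations

* The models are descriptive response functions, not mechanistic channel
  populations; no tuning curves or gain-control dynamics are simulated.
* Residuals are computed on per-face mean aftereffects; per-observer
  weighting (and hence heteroscedasticity across faces) is out of scope.
* Parameter uncertainty is not quantified (no confidence intervals or
  information criteria); the comparison is deliberately a paired rank test.
* The unconstrained GD fit reports the printed parameters of a replication
  procedure; on data without a true GD structure its optima can sit at the
  bandwidth bound, which is the behaviour under critique, not a defect of
  the optimizer.
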