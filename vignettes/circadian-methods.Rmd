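---
title: "Methods: rhythmicity testing and damped cosinor fitting in circapanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rhythmicity testing and damped cosinor fitting in circapanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circapanel)
```

## The model and its assumptions

`circapanel` analyzes replicated expression time courses from
serum-shock-synchronized cell cultures. Its central model is a damped (or
growing) cosine on a linear baseline,

$$y(t) = A\,e^{-\lambda t}\cos\!\Big(\frac{2\pi (t-\theta)}{\tau}\Big) + m t + b,$$

with six parameters:

| parameter | meaning | units | default bounds |
|---|---|---|---|
| $A$ | amplitude | relative expression | $\ge 0$ (sign absorbed into $\theta$) |
| $\lambda$ | damping rate; $>0$ damps, $<0$ grows | 1/h | $[-0.05, 0.05]$ |
| $\theta$ | phase; peak falls at $\theta \bmod \tau$ | h | canonical $[0, \tau)$ |
| $\tau$ | intrinsic period | h | $[18, 48]$ free fit; $[24, 32]$ bounded-period test |
| $m$ | baseline slope | 1/h | free |
| $b$ | y-intercept | relative expression | free |

Assumptions: replicates are exchangeable observations of a common
deterministic trajectory plus independent noise with a time-point-specific
variance; the oscillation is a single harmonic whose envelope changes
exponentially; slow non-circadian drift is linear. Desynchronization of
individual cells after a serum shock is what the envelope term absorbs;
the model does not distinguish damping of single-cell oscillators from
population dephasing.

The free-fit period window $[18, 48]$ h is wider than the "circadian"
range on purpose: published fits of this kind of panel report periods up
to ~36 h with confidence intervals reaching 42 h, and a bound that clips
the estimate would silently bias both the point estimate and its CI. The
bounded-period rhythm test, by contrast, deliberately restricts
$\tau \in [24, 32]$ h so that "rhythmic" means "rhythmic in the circadian
window".

## Quantification (2^−ΔΔCt) and normalization

For each (time, replicate): $\Delta C_t = C_t^{target} - C_t^{ref}$,
$\Delta\Delta C_t = \Delta C_t - \Delta C_t^{cal}$, relative expression
$= 2^{-\Delta\Delta C_t}$. The calibrator is replicate-matched and
defaults to the $t = 0$ sample (the one taken immediately after
synchronization), with the replicate's temporal mean as the alternative.
The choice only rescales each replicate by a constant, and the subsequent
per-replicate mean normalization (each series divided by its mean over
its present time points) removes exactly that scale — so the analyzed
series is insensitive to the calibrator rule. Technical replicates are
assumed pre-averaged; `collapse_technical_replicates()` does this by
median when a `tech_replicate` column is present.

## The rhythmicity battery

All tests consume every present (time, value) point individually —
replicates are never averaged before testing — and all permutation tests
shuffle values across slots with times held fixed, using the add-one
convention $p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + N)$, so $p$
can never fall below $1/(N+1)$.

* **Lomb–Scargle permutation test.** Classical normalized periodogram on
  a frequency grid spanning periods 6–50 h, spaced $1/(4 \cdot
  \text{span})$ (oversampling 4). Statistic: max power. Handles
  missingness trivially since each point enters on its own.
* **JTK-style template test.** Tie-corrected Kendall $\tau$ between the
  data and cosine templates over a period grid (default 20/24/28 h —
  the scan the original tool is typically run with is not standardized,
  so the grid is exposed as configuration) crossed with phases on the
  sampling-interval grid. Statistic: max $\tau$.
* **RAIN-style umbrella test.** Times folded modulo the test period
  (default 24 h); for each candidate peak position a Mack–Wolfe umbrella
  statistic is built from pairwise Mann–Whitney counts (rises up the
  rising arm, falls down the falling arm; the edge positions give the
  monotone alternatives). Rank-based, hence invariant under strictly
  increasing transforms, and waveform-agnostic. This is a reimplementation
  in spirit, not line-by-line: longitudinal vs independent sampling modes
  are collapsed to independent sampling.
* **Bounded-period fit test.** Linear detrend, then the damped-cosine fit
  with $\tau \in [24, 32]$ h and uniform weights; $p$ from an F-test of
  the 6-parameter fit against the baseline-only (slope + intercept)
  model with $(4, n-6)$ degrees of freedom.

**Multiplicity and calibration.** For the two template/grid tests the
p-value comes from the permutation null of the *maximum* statistic over
the grid, not from a per-template p-value with a Bonferroni factor. The
max-null absorbs the grid multiplicity exactly (the permutation test of
the maximum is exact by construction), whereas Bonferroni over strongly
correlated templates is conservative. This is the one place the package
deviates from the classical description of these tests, and it is why the
measured type-I error of all three permutation tests sits inside the
exact binomial band around the nominal level.

**A known limitation: the fit test's F reference.** Because $\tau$ and
$\lambda$ are optimized inside narrow boxes, the oscillation does not
realize 4 full degrees of freedom under the null; the $(4, n-6)$ F-test
is therefore mildly conservative (empirical type-I ≈ 0.036 at
$\alpha$ = 0.05 over 1000 white-noise series with the standard design —
inside the exact binomial 99% band around 0.05, but near its lower
edge). Its null p-values are not exactly uniform and no fixed-df F
reference can make them so under this selection structure; the test is
valid (never exceeds its nominal level) but blunter than the permutation
members.

Rank tests applied to strongly trended series lose power (the trend
dominates the ranks); the battery leaves the Lomb–Scargle and rank tests
untrended by design (only the fit test and the differential test
detrend), so a trending arrhythmic series can be flagged by the
Lomb–Scargle test on the trend alone. That is a property of the test, not
a defect; compare members of the battery rather than trusting one.

## Differential rhythmicity

Both series are linearly detrended (ordinary least squares over all
present points), then each is fit by harmonic regression at a shared
period (default 24 h, configurable; a sweep helper reruns the test over a
period grid): $y \approx M + \beta_c \cos(2\pi t/T) + \beta_s \sin(2\pi
t/T)$, robustly (Huber M-estimation) by default. The statistic is the
Wald quadratic form on $\Delta(\beta_c, \beta_s)$ with the summed
coefficient covariances, referred to $\chi^2_2$, or — for exact finite-
sample calibration — to a null built by shuffling condition labels within
time points. The analytic route is used for the pipeline's pairwise
scans; the permutation route exists because the $\chi^2$ reference relies
on the coefficient covariances being well estimated from 5–6 replicates
per time point.

## The weighted cosinor fit

Numerical strategy: **variable projection**. For fixed $(\lambda, \tau)$
the model is linear in $(A\cos, A\sin, m, b)$ via
$A e^{-\lambda t}\cos(2\pi(t-\theta)/\tau) = e^{-\lambda t}(a_c \cos
\omega t + a_s \sin \omega t)$, so the inner problem is a weighted linear
solve and only $(\lambda, \tau)$ need nonlinear optimization (L-BFGS-B
inside the bounds, multistart over $\tau \in \{20, 24, 28, 32, 40\}$ and
$\lambda \in \{-0.04, 0, 0.04\}$, then a high-precision polish). This is
strictly stronger than multistarting over phases: the phase is profiled
out exactly, which removes the worst multimodality of the objective.
Amplitude and phase are recovered as $A = \sqrt{a_c^2 + a_s^2}$,
$\theta = \tau \,\mathrm{atan2}(a_s, a_c)/2\pi \bmod \tau$ (canonical in
$[0, \tau)$; a negative amplitude is absorbed as a half-period phase
shift).

Weights are the inverse of the per-time-point sample variance. Zero or
undefined variances (exact ties, or a single replicate) are replaced by
the median positive variance across time points — weights must stay
finite, and the cap keeps such points at a typical, not dominant,
influence. With no positive variance anywhere (noiseless data) weights
are uniform.

Uncertainty: standard errors from the Gauss–Newton curvature
$\sigma^2 (J^\top W J)^{-1}$ at the optimum (numerical Jacobian over all
six reported parameters), 95% CIs as Wald t-intervals with $n - 6$ df.
These are curvature (not profile) intervals; profile-t intervals, which
the classical `nls`-based workflow produces, are somewhat wider for the
period, and the measured coverage of the Wald period CI at the study
design with 10% noise is ≈ 0.90 — slightly below nominal, above the 0.88
floor the test suite asserts.

$R^2 = 1 - SS_{res}/SS_{tot}$ is computed **unweighted against the grand
mean over all replicate points** and may be negative — a fit worse than a
flat line, which is exactly how a lack of fit is flagged (per-time-point
medians are exposed as an alternative basis). The parameter table masks a
row to NA when the fit fails, is degenerate, or converges with $R^2 < 0$,
mirroring how such series are reported in practice.

Peak times ignore the envelope and baseline: peaks are those of the
cosine factor, at $\theta \bmod \tau$ and every $\tau$ thereafter. The
derived metrics are baseline change $= m \times 48$ h and growth rate
$= -\lambda$ when $\lambda < 0$ (zero otherwise, with the damping rate
$|\lambda|$ carried separately). The phase relationship between two genes
is the circular distance between first peaks on a circle of circumference
$\bar\tau$ (the mean period), with "anti-phase" declared within 20% of
$\bar\tau/2$ — wide enough to catch the biological claim, narrow enough
to exclude the ~8 h offsets seen in the dysregulated lines.

## The synthetic-data generator

The generator emulates the study design that the analysis assumes:
samples at 0–48 h every 4 h (13 time points), 6 exchangeable replicates
(3 biological × 2 experiments; the experiment label is carried for
bookkeeping but no batch effect is simulated), additive Gaussian noise
with constant sd by default (matching the inverse-variance weighting
assumption), lognormal noise as the positive-valued alternative. Preset
truths for three cell lines × two genes use published parameter columns;
the metastatic line's BMAL1 series — for which no sinusoidal parameters
exist because the fit failed on the real data — is generated as the null
model (linear trend + noise) with that line's PER2 trend, and the
metastatic presets drop one replicate at 4 of 13 time points (n = 5
there). The default preset noise, `noise_sd = 0.05` relative-expression
units, was chosen once as a realistic qPCR replicate scatter (~5–15% of
the normalized signal, consistent with the spread visible in published
figures of this kind); the magnitude of the real data's noise is not
published, so presets expose it as a parameter rather than asserting it.

Ct-level simulation inverts the 2^−ΔΔCt mapping with amplification
efficiency exactly 2 (configurable base), a constant reference-gene Ct
(optional jitter), and a constant calibrator offset; round-tripping
through quantification recovers the truth up to the calibrator
normalization (to 1e−9 relative, asserted).

What a green test does **not** establish: the generator draws i.i.d.
noise around a parametric truth, so it cannot reveal misbehavior under
heteroscedastic amplification noise, replicate-correlated batch effects,
non-sinusoidal waveforms, or reference-gene instability. Tests against it
validate the machinery, not the biology.

## Numerical choices and degenerate inputs

* Relative-error recovery sweeps draw $|\lambda| \ge 0.005$ and
  $|m| \ge 0.003$ (within the observed magnitudes of published fits):
  relative error at a truth of zero is ill-conditioned, while the fits
  themselves are accurate to ~1e−6 absolute there.
* "Optimum no worse than truth" on noiseless data is asserted with
  numerical slack (objective < 1e−6 · Σy²), since the truth's objective
  is exactly 0 and L-BFGS-B stops near 1e−9.
* Constant series: periodogram powers are defined as 0, the template test
  returns p = 1 with a `constant_series` flag (τ undefined), the umbrella
  test returns p = 1, the fit flags `degenerate`.
* Permutation seeds: every stochastic routine takes a seed; the pipeline
  derives per-stage seeds from the master seed with a fixed LCG step, so
  a run is reproducible end to end (byte-identical output files).

## Known limitations

* The bounded-period fit test is conservative (above); use the
  permutation members of the battery when calibrated error rates matter.
* Wald CIs undercover slightly relative to profile intervals.
* The differential test assumes both series share a time grid;
  resampling mismatched grids is out of scope.
* No multi-harmonic waveforms, no Bayesian fitting, no cross-gene FDR
  (designed for two-gene panels; within-test grid multiplicity is handled
  by the max-statistic permutation null).
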