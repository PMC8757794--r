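---
title: "Braided flow-diverter mesh geometry and aneurysm occlusion: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Braided flow-diverter mesh geometry and aneurysm occlusion: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdbraid)
```

## What the package models

Braided flow diverters (FDs) are dense wire-mesh stents placed across the
neck of a cerebral aneurysm to starve it of flow until it thromboses. Two
linked questions drive treatment planning: how the *local* mesh of the
deployed device — porosity, braiding angle, expansion — depends on the
vessel it lands in, and whether that mesh morphology predicts occlusion
and the time-to-occlusion (TTO) seen at angiographic follow-up. `fdbraid`
implements this chain end to end: closed-form unit-cell geometry, virtual
deployment along a centerline, a principal-component morphology index
(MAAI), an occlusion logit model, a TTO ANCOVA with sequential covariate
correction, and a synthetic cohort generator with fully known ground
truth for verifying all of the above.

## Unit-cell geometry

The braid's repeating element is a rhombic pore bounded by four struts of
length $S$ and width $\omega$ crossing at angle $2\alpha$, where $\alpha$
is the half-angle against the device's longitudinal axis. The cell area
is $S^2 \sin 2\alpha$; the two wires cover $2S\omega$ minus the crossing
overlap $\omega^2/\sin 2\alpha$ (the parallelogram where two
$\omega$-wide strips at included angle $2\alpha$ intersect), so the metal
fraction is

$$f(\alpha) = \frac{2S\omega - \omega^2/\sin 2\alpha}{S^2 \sin 2\alpha},
  \qquad \text{porosity} = 1 - f.$$

Algebraically $f - 1 = -(S\sin 2\alpha - \omega)^2 / (S \sin 2\alpha)^2
\le 0$: the formula never exceeds full coverage, and touches $f = 1$
exactly at the closure angle $\sin 2\alpha = \omega / S$. We therefore
define the *valid angle range* as $\sin 2\alpha \ge \omega/S$; outside
it the braid is geometrically closed and requests are rejected (row
placement) or clamped (curvature modulation, see below). Coverage is
minimal — porosity maximal — at $\alpha = 45^\circ$. In all reporting the
"mesh angle" is $2\alpha$ on the 0–180° scale (0 = crimped, 180 = fully
open); internal computation uses $\alpha$ in radians. The closed form is
cross-checked in the test suite against an independent Monte-Carlo
rasterisation oracle that pixel-counts the two wire-strip families over
the cell (agreement to $2\times10^{-3}$ over 200 random designs).

When the device is constrained to diameter $d$ below its nominal
$\phi_{nom}$, the crossings per circumference and the strut length are
fixed, so the circumferential cell span scales with both $d$ and
$\sin\alpha$, giving the parameter-free calibration
$\alpha(d) = \arcsin(\sin\alpha_{nom}\, d/\phi_{nom})$, exact at nominal.
Rows of cells each span $2S\cos\alpha$ longitudinally and the row count
$M = \mathrm{round}(L_{nom}/(2S\cos\alpha_{nom}))$ is conserved across
deployments (a wire-length conservation surrogate) — this is what makes
under-expanded braids lengthen (foreshortening in reverse).

## Deployment

`deploy()` anchors the device distally and marches rows proximally. Row
lengths depend on the local diameter at the row centers, which depend on
the row placement; the coupled system is solved by fixed-point iteration
(convergence $10^{-10}$ mm, at most 100 sweeps — in practice a handful).
The local diameter is capped at $\phi_{nom}$: a braid cannot expand past
its nominal diameter, so expansion $= 100\, d/\phi_{nom} \le 100\%$.

On a bent vessel the inner wall is longitudinally compressed and the
outer wall stretched. Each circumferential sample at angle $\theta$
(measured from the curvature normal; $\theta = 0$ is the inner wall)
carries strain $\varepsilon(\theta) = -\kappa (d/2)\cos\theta$, clamped
to $|\varepsilon| \le 0.5$, and the modulated half-angle solves
$\cos\alpha(\theta) = \cos(\alpha_{row})(1 + \varepsilon(\theta))$,
clamped to the valid angle range. On straight vessels the field is
circumferentially constant to machine precision. For open braids
($\alpha_{row} > 45^\circ$) this closes the mesh on the inner wall —
porosity(inner) $\le$ porosity(outer); the ordering holds whenever
$2\cos^2(\alpha_{row})(1 + (\kappa d/2)^2) \le 1$ and can reverse in a
thin sliver just above $45^\circ$ under strong curvature, a property of
the closed form worth knowing when interpreting per-row fields. The
ordering flips below $45^\circ$.

Defaults: 16 circumferential samples per row; region summaries
(`region_summary()`) average all samples of rows whose centers fall in
the half-open neck interval, unweighted, and report means with
*population* SDs. Curvature is estimated from second differences of the
sampled centerline (non-uniform-grid formulas, one-sided at the ends);
straight segments (below $10^{-8}$/mm) get a fixed reference normal
(global $z$ projected orthogonal to the tangent, falling back to $y$) so
runs are reproducible.

## Brand presets

Wire counts, strut lengths and widths of commercial devices are not
public at this level of detail; the four bundled presets (Derivo, P64,
Pipeline, Surpass) are *illustrative*. Wire counts and nominal angles are
plausible for each family; strut length follows from braid closure around
the nominal circumference, $S = \pi\phi_{nom}/(n_{wires}
\sin\alpha_{nom})$; and strut widths (29–50 µm) were chosen once so that
nominal porosities sit in the 0.65–0.80 band and the deployed porosity at
the cohort's mean expansion (87%) averages near the reported cohort mean
of 72%. They should not be mistaken for manufacturer specifications.

## MAAI

Aneurysm size descriptors (maximum/minimum neck diameter, depth, width;
optionally volume) are strongly correlated, so they are reduced to one
composite by PCA of the *correlation* matrix — correlation, not
covariance, because the variables mix mm and mm³ scales and the source
analysis does not state its scaling. The first eigenvector (unit norm,
sign anchored so the maximum-diameter loading is non-negative) gives the
loadings; its eigenvalue share is the explained fraction. For an
equicorrelated 4-variable correlation matrix the first eigenvalue is
$1 + 3\rho$, so $\rho = 0.92$ gives an explained share of exactly
$(1 + 3 \times 0.92)/4 = 0.94$ — the generator's default, matching the
reported 94%. The default descriptor set is the four-variable one; the
five-variable set is a documented configuration because the source
listing is ambiguous about which produced the 94% figure.

## Outcome models

*Occlusion* is modelled with a logistic regression of the 0/1 occlusion
state on porosity, mesh angle and expansion means over the neck region,
MAAI, and brand (dummy-coded, alphabetical reference by default). The
three mesh covariates are all monotone functions of the local diameter,
hence strongly collinear; their individual coefficients carry wide
confidence intervals, which is faithful to the scientific situation (the
fits flag separation and non-convergence rather than failing silently).

*TTO* (months, occluded cases with TTO ≤ 12 only) is modelled by ANCOVA:
brand and an age factor, then the continuous covariates entered in a
user-chosen order, with the sequential (Type I) sum-of-squares
decomposition reported alongside marginal drop-one tests. Entry order
changes the decomposition table, never the fitted values or $R^2$ — the
pair of facts that underpins "correction power" comparisons between
covariate orders. No multiple-testing correction is applied, stated in
the output metadata.

Age needs care: one level per year is unidentifiable at cohort sizes
near 50, and the age pattern is non-linear (young and old occlude faster
than mid-age). The default bins age at the sample tertiles; explicit
breaks, a linear term, and an orthogonal quadratic are configurable.
When analysing the package's own synthetic cohorts the generating breaks
are known and should be supplied (`age_handling = "breaks"`); sample
tertiles are a pragmatic default for real cohorts where the grouping is
unknown, at the price of some attenuation from boundary
misclassification.

Diagnostics follow standard practice: Shapiro–Wilk on residuals and
median-centred Levene (Brown–Forsythe) across a factor's groups; both
are calibrated at their nominal 5% level in the test suite.

## The synthetic cohort generator

`generate_cohort()` is the package's verification instrument: it runs
the *full* forward pipeline per case (morphology → vessel → deployment →
region summary → outcomes) with every parameter recorded. Defaults
emulate the motivating study's conditions:

* brand mix 8/8/26/22 over Derivo/P64/Pipeline/Surpass; follow-ups in
  6–12 months; ages uniform 30–75;
* log-normal, equicorrelated ($\rho = 0.92$ on the log scale) morphology
  with medians near 3–4 mm;
* target expansion truncated-normal around 87% (SD 5%), mild taper and
  bends up to 0.08/mm;
* occlusion from a logistic model with MAAI slope $-0.25$ and zero mesh
  and brand effects (they were not significant for occlusion); the
  intercept carries a logit-normal correction,
  $\mathrm{logit}(51/64)\sqrt{1 + 0.346\,(0.25\,\sigma_{MAAI})^2}$, so
  that the *marginal* occlusion rate matches the reported 51-of-64
  despite the MAAI dispersion (Jensen's inequality would otherwise pull
  it below the anchored rate);
* TTO from a linear model anchored at a mean of 6.92 months: age-group
  offsets (0, 3.6, 0.3) months on breaks at 45 and 60 years — the
  population tertiles of the age distribution, sized so the realised TTO
  SD is about 1.7 months, i.e. an SE near 0.24 at $n \approx 51$ — plus
  8 months per porosity fraction and $-0.035$ months per degree of mesh
  angle; expansion, MAAI and brand contribute nothing.

The residual SD is derived per dataset from the realised linear-predictor
spread so the generating $R^2$ is exactly 0.92. TTO is the follow-up
time at which occlusion is observed, so the generator rejects TTO draws
outside (0, 12] and then draws the follow-up at or after the occlusion
within the 6–12 month window — guaranteeing TTO ≤ follow-up without
biasing the mean, which an unconditional truncation at an independent
follow-up would. Mesh covariates enter both models centred at their
realised means, and the truth attribute stores the uncentred coefficient
vectors in the fitted models' parameterisation, the residual SD and the
latent linear predictors, so recovery tests compare like with like.

What the generator does *not* emulate: imaging and segmentation noise,
real aneurysm sac geometry (the neck is an arc-length interval, not a
surface patch), malapposition, telescoped devices, antiplatelet regimes,
and any coagulation biology. Passing recovery tests therefore shows that
the estimators recover the truth of *this* generative family at these
sizes — not that the models are correctly specified for any real cohort.

The phantom-validation emulation adds i.i.d. Gaussian noise (default SD
0.02, clipped to [0, 1]) to the simulated porosity field and scores the
fraction of samples with relative error below 10% ("good estimates"),
contrasting the spatially resolved prediction with the constant
manufacturer-tag porosity. Relative error is the default reading of the
10% criterion; absolute is available. With a clean noise model the
resolved prediction scores near 100% — the informative quantity is the
*gap* to the tag baseline, which mirrors the reported 91%-vs-58%
contrast qualitatively, not its absolute levels, because real phantom
measurements carry segmentation error we do not model.

## Numerical choices and problem sizes

Degrees at every interface, radians internally; lengths in mm, TTO and
follow-up in months. The valid-angle bounds are located by `uniroot` to
$10^{-12}$; deployment fixed-point tolerance is $10^{-10}$ mm; straight
segments are those with curvature below $10^{-8}$/mm. Logit confidence
intervals are Wald-based; ANCOVA intervals are exact t intervals.
Exports are deterministic (row-major, ascending $\theta$) so repeated
runs are byte-identical; every output file carries the seed and a config
hash.

The verification suite runs at sizes chosen to keep Monte-Carlo error
well below the margins being asserted: 200 random designs against the
rasterisation oracle at $2048^2$ pixels; null calibration of all
reported tests with 500 replicates (rejection within 5% ± 2%); and
parameter recovery with 300 replicates of $n = 500$ cohorts, pooling CI
coverage over each model's coefficient vector (a per-coefficient
threshold at these replicate counts would fail by chance alone a
substantial fraction of the time even at exactly nominal coverage).

## Limitations

The deployment model is kinematic, not mechanical: no wire contact or
friction, no flared ends, no apposition modelling, and the sub-row
diameter variation is ignored (row-center lookup). The angle–diameter
law is the simplest calibration consistent with fixed strut length and
crossing count; real braids deviate near their crimped limit. The
statistical models treat TTO as the observed follow-up time of occluded
cases — not a censored event time — mirroring the source design; a
survival treatment is out of scope. And the brand presets are
illustrative stand-ins, so cross-brand contrasts computed from them
describe the presets, not the commercial devices.
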