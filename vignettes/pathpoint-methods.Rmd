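---
title: "Circular analysis of pointing-to-origin responses: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circular analysis of pointing-to-origin responses: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathpoint)
```

## The task and its geometry

A navigator walks a path of four legs `L1..L4` (meters) joined by three
90-degree turns, all in the same direction, then points back to where they
started. Depending only on the leg lengths, the first and fourth legs either
cross (`L3 < L1` and `L4 > L2`) or do not; the uncrossed family splits into
paths whose fourth leg stops short of the first leg's line (`L4 < L2`) and
paths whose third leg overshoots it (`L3 > L1`, `L4 > L2`). `pathpoint`
works in a canonical frame: start at the origin, first leg along +y,
left-turn chirality, and all pointing angles expressed relative to the final
heading at the end point E, positive clockwise, wrapped to (-180, 180]. In
that frame the landmark points used by the analysis have closed forms — the
walked intersection I, the virtual intersection I' of the extended fourth
leg with the first leg's line, the false-intersection point F2 where the
fourth leg crosses that line, the hypothesized extended endpoint E', and
E'_far, which shares E's x-coordinate and the first turn's y-coordinate.
Mirrored (right-turn) paths are the exact reflection, and every bearing
flips sign.

Boundary topologies (`L3 = L1` or `L4 = L2`) put the intersection exactly at
a path endpoint and are rejected rather than silently classified, as is the
corner `L3 > L1` with `L4 < L2`, for which no hypothesis landmark exists.
All geometric equalities are held to 1e-9 (meters and degrees). Leg lengths
above the 3.4 m arena bound of real walking stimuli produce a warning, not
an error: hypothetical geometries (used in worked examples and tests) may
exceed the bound, while the shipped path generator never does.

One rendered landmark has no analytic role: the false-intersection gate on
the first leg (F1). No hypothesis boundary references it, so it is placed at
the midpoint of leg 1 purely for completeness of the landmark table.

## Hypothesis intervals

Each of nine representational hypotheses describes a family of remembered
path shapes — legs shortened or extended, the crossing kept, deleted, or
invented — and predicts a clockwise arc of pointing directions bounded by
landmark bearings. For a crossed path, for example, keeping the crossing
while allowing both outer legs to shrink (CtoC) predicts the arc from
`bearing(I, S) = 90` to `bearing(E, I) = 180` degrees; deleting the crossing
by shortening the first leg (CtoN1) predicts the arc from 180 to
`bearing(E, T1)`. Within each admissible set the arcs have pairwise disjoint
interiors (shared endpoints only), which is what makes the later
overlap-ratio comparison diagnostic. Interval boundaries count as inside
(closed arcs), and all interval arithmetic is wrap-safe across the +/-180
cut.

Two choices here were genuinely open:

* **The NtoN1 sweep for long-third-leg paths.** The hypothesis lets the
  remembered first leg be extended or shortened by noise; the interval is
  the set of bearings from E to the remembered start S' as the represented
  leg-1 length runs from maximal shortening (S' at the first turn) up to a
  cap. We cap the represented length at `min(arena bound, L3)`: extending
  past `L3` would place S' beyond the fourth leg's line and create a
  crossing, contradicting the no-cross topology this hypothesis asserts, and
  it would also overlap the NtoC2 arc, destroying disjointness. With the cap
  the two arcs meet exactly at the straight-back direction (180 degrees)
  and remain disjoint.
* **The NtoC1 boundary order.** The meaningful arc runs clockwise from
  `bearing(I', S) = 90` to `bearing(E', S)` (always between 90 and 180 for
  short-fourth-leg paths); the complementary arc would cover 326+ degrees
  and overlap every other hypothesis.

The mean prediction of an interval is the circular mean of 1000 uniform
draws on the arc (`range_mean()`), which converges to the arc midpoint; the
package exposes both.

## Preprocessing

Raw responses arrive in [0, 360) with 0 at the facing direction and are
mapped to (-180, 180] (180 maps to +180). Mirror-image paths produce
mirror-image response distributions, so trials whose chirality differs from
the canonical chirality of their path have their sign flipped before
pooling; the canonical chirality defaults to left for every path but can be
declared per path, which reproduces designs where the left-turn versions of
some paths are the mirrored ones. Per participant and path, responses are
circularly averaged across trials (direction of the vector sum); a cell with
a numerically zero resultant — two antipodal trials, say — has no defined
mean and is flagged and excluded downstream with a warning rather than
assigned an arbitrary direction. The signed angular error AE_G is the
wrapped difference between the cell mean and the geometrically correct
bearing from E to S. When landing coordinates accompany a trial they
supply the pointing angle for trials missing an explicit one; if both exist
and disagree by more than 0.1 degrees the explicit angle wins with a
warning. Distances yield a proportional error, `(correct - response) /
correct`, positive for underestimation.

## Circular statistics

Descriptives are the textbook quantities: mean direction, mean resultant
length `r`, and the maximum-likelihood von Mises concentration `kappa`
obtained by inverting `A1(kappa) = r` (Best-Fisher piecewise starting value,
Newton refinement to 1e-10) with the standard small-sample bias correction
below n = 16. The 95% CI of the mean direction uses the large-sample
circular-dispersion method. Uniformity is tested with the Rayleigh statistic
`z = n r^2` and its standard series p-value; two independent samples are
compared with the Mardia-Watson-Wheeler uniform-scores test (chi-square, 2
df; midranks on ties, with a warning); paired conditions are compared by
embedding each angle as a unit vector and applying Hotelling's T-squared to
the paired component differences, referred to F(2, n-2). All tests are
two-tailed at alpha = .05 and invariant to a common rotation of the data.
A note on degrees of freedom: published analyses of this design sometimes
print F(1, n-2) for the paired test; the bivariate form implemented here has
2 numerator df, and we do not emulate the printed convention.

## Outlier detection

The discordancy measure for observation i is the C-statistic
`(r_-i - r) / r`: how much the resultant improves when i is left out. Its
null distribution depends on the concentration, so the cutoff is calibrated
by simulation: 1000 von Mises samples at the candidate concentration, the
maximum C of each, and the 90% quantile of those maxima. Because observed
concentration is deflated by the very outliers being sought, candidates run
from the observed kappa upward in steps of 0.05 (to +3.00); a candidate is
accepted when (a) its kappa minus the post-exclusion kappa is below 1.5,
(b) the post-exclusion kappa improves on the original, and (c) fewer than
10% of observations are excluded. The first acceptable candidate — the
smallest inflation — wins; if none qualifies the sample is returned intact
with a flag. Exclusion is single-pass (no iterative re-detection), and the
simulated sample size is an explicit parameter so that analyses that round
it up (e.g. to a round 120 or 150) remain reproducible. Outliers are
detected on the signed errors AE_G pooled across paths within a condition,
since different paths can have different correct directions.

A limitation worth stating: a contaminant drawn uniformly on the circle
lands inside the clean distribution's bulk about half the time. Such points
are not discordant in any sense, so no discordancy test — this one included
— can recover a majority of uniform contaminants while honoring a 10%
exclusion cap. The procedure's guarantees are about what it excludes (only
high-C points, never more than the cap, never without improving kappa), not
about recovering all contamination.

## The projected-normal mixed model

Pointing angles are analysed on the component scale: each angle is the
direction of a latent bivariate normal vector with identity covariance,

```
r_i u_i ~ N2(mu_i, I),   u_i = (cos theta_i, sin theta_i),  r_i > 0,
mu_i = beta[cell_i] + b[subject_i]        (each a 2-vector),
```

with flat priors on the cell coefficients (Components I and II) and
subject random intercepts per component with inverse-gamma(0.001, 0.001)
variances. The Gibbs sampler updates cell coefficients and random effects
from their conjugate normals, the random-effect variances from their
inverse-gamma conditionals, and each latent length from its known
univariate conditional `f(r) proportional to r * phi(r - t_i)` with
`t_i = mu_i . u_i`. That conditional's CDF has the closed form
`phi(t) - phi(r - t) + t (Phi(r - t) - Phi(-t))`, so lengths are drawn
exactly by inverting it with 30 steps of vectorized bisection on
`[0, max(t, 0) + 8]` — no tuning, no rejection. Defaults are 1000
iterations with a burn-in of 200 (the sampler mixes quickly; a split-half
diagnostic above 1.1 on any cell's direction draws triggers a warning).
Posterior mean directions per cell are the angles of the sampled cell
coefficient vectors, making the whole fit rotation-equivariant.

The published formula for this analysis, "pointing angle ~ hypothesis +
subject", is ambiguous as a design matrix — the data do not vary by
hypothesis. We implement the surrogate that reproduces the reported
outputs: path-level fixed cells plus subject random intercepts fitted once
per condition, with every admissible hypothesis then scored against the
same per-path posteriors. The per-participant variant fits path cells with
no random effects to one participant's raw trials, without outlier
exclusion.

The 95% HPD interval of a cell's posterior direction is the shortest arc
containing 95% of the draws, found by a sliding window over draws unwrapped
around their circular mean; it requires at least 100 concentrated draws
(resultant above 0.1 — a circular HPD is ill-defined for dispersed
posteriors). The overlap ratio of an HPD interval with a predicted range is
the intersection arc length divided by the *HPD* width: 1 exactly when the
posterior's credible arc lies wholly inside the prediction, which is the
only convention under which a well-fitting hypothesis can reach a ratio of
1 (predicted ranges are much wider than concentrated posteriors). The best
hypothesis is the one with the largest mean ratio across paths; top ratios
within 1e-6 of each other are reported as ambiguous.

## The synthetic generator

`make_experiment_paths()` builds the two path families analysed here. The
Experiment-1 family pairs four crossed paths with four short-fourth-leg
uncrossed paths; the Experiment-2/3 family pairs each crossed path with a
long-third-leg partner matched in total length and end-to-start distance,
whose mirrored version has the same correct pointing angle. The matching is
solved in closed form: the uncrossed endpoint is the reflection of the
crossed endpoint across the heading axis, and the first two legs are
rebalanced to preserve the total. All legs respect the 3.4 m arena bound.

`generate_dataset()` layers, per subject and condition, a von Mises angular
offset (concentration `kappa_subject`, default 8, about a 21-degree SD —
moderate subject heterogeneity) on top of trial-level von Mises noise
(`kappa_trial`, default 4) around the generating hypothesis's predicted
direction, contaminates a small fraction of responses (default 5%, matching
the outlier proportions such experiments report) with uniform draws, and
underestimates pointing distance by a truncated-normal proportion (mean
0.29, SD 0.20). Half of each shape's trials use the mirrored path, and raw
responses are emitted in the pre-flip 0-360 convention of each trial's own
chirality, so the generator exercises the full preprocessing path. Subject
heterogeneity enters as an additive angular offset — a good approximation
to projected-normal random intercepts at moderate concentration, but an
approximation. The generator emulates the noise *structure* of walking
experiments, not walking itself: no trajectory dynamics, no optic flow, no
cue-competition model, no history effects between trials. Recovery results
on synthetic data therefore validate the estimation machinery, not the
psychology.

Default problem sizes follow the study design the generator emulates: 32
subjects, 4 shapes per condition, 4 trials per shape. At those sizes a full
condition fit (1000 iterations on 128 cell means) takes about a second, and
the package's end-to-end recovery property — data generated under any
admissible hypothesis of any condition is assigned that hypothesis as best
fit — holds in at least 18 of 20 seeded replicates per cell.

## Worked example

```{r, eval = FALSE}
specs <- make_experiment_paths(2)
cfg <- synth_config(specs,
                    c("FI-NC" = "NtoC3", "NI-NC" = "NtoN1"),
                    seed = 2026)
trials <- generate_dataset(cfg)
res <- analyze_experiment(trials, specs, experiment = 2, seed = 2026)
print(res)
```

## Known limitations

* The F(1, n-2) convention some published paired-Hotelling results print is
  not reproduced (see above); statistics and p-values use the bivariate
  F(2, n-2) form.
* The overlap-ratio scale depends on the HPD width: very concentrated
  posteriors make ratios nearly 0/1 indicators, so mean ratios are best
  compared within a fit, not across sample sizes.
* Uniform contamination is only partially recoverable in principle; see the
  outlier section.
* The latent-length bisection resolves r to ~1e-8 of its bracket; this is
  far below the Monte-Carlo error of a 1000-iteration chain but is not an
  unbiased floating-point-exact inverse-CDF draw.
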