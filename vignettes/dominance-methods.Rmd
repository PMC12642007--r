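---
title: "Methods: from gaze streams to dwell dominance and design actions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from gaze streams to dwell dominance and design actions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazedominion)
```

This vignette documents the models, conventions, and numerical choices
behind `gazedominion`, in the spirit of a methods appendix: what is
computed, under which assumptions, which knobs matter, and what the test
suite does and does not demonstrate.

## The analysis unit

Everything downstream of preprocessing operates on a long-form table with
one row per participant × ad × AOI, holding three standard metrics:

* **TTFF** (ms): latency from stimulus onset to the first fixation inside
  the AOI — early capture. Time zero is stimulus onset. When an AOI is
  never fixated during the exposure, TTFF is right-censored at the censor
  value (default 10,000 ms, equal to the exposure) and the row is flagged
  `censored`.
* **FC**: number of fixations in the AOI — revisiting. Zero when censored.
* **FD** (ms): summed fixation time in the AOI — depth of processing.
  Zero when censored.

Censored rows stay in the table deliberately: latency summaries *include*
censored TTFF at the censor value (so rarely-seen AOIs show honestly
inflated medians, with `n_censored` reported alongside), while first-hit
determination and dwell comparisons treat censoring as "not observed".

## Preprocessing model

Fixations are identified with a velocity-threshold (I-VT) scheme.
Point-to-point angular velocity is a two-point backward difference between
consecutive valid samples, converted to degrees via the screen geometry:
one degree subtends `2·d·tan(0.5°)` cm at viewing distance `d`, i.e.
about 1.05 cm ≈ 38 px on the default 1920 px / 53 cm display at 60 cm.
No velocity smoothing is applied before thresholding — at 60 Hz the
two-point estimate is already an average over ~17 ms. A sample with no
valid backward neighbour opens a run when its forward velocity is below
threshold; invalid samples (blinks, tracking loss) always break runs.
Runs shorter than the minimum fixation duration are discarded; a run's
duration is last-sample time minus first-sample time.

Tunable parameters (all on `ivt_params()`):

| parameter | default | unit | rationale |
|---|---|---|---|
| `velocity_threshold_deg_s` | 30 | °/s | conventional I-VT threshold for static stimuli |
| `min_fixation_ms` | 60 | ms | low end of the conventional 60–80 ms band; exposed because the band, not a point, is conventional |
| `merge_max_gap_ms` | 75 | ms | merge window for adjacent fixations |
| `merge_max_dist_deg` | 0.5 | ° | merge distance for adjacent fixations |

Merging is applied left-to-right until stable; the merged fixation spans
first onset to last offset and its centroid is duration-weighted, which
preserves dwell mass. Trial-level quality control excludes trials with
under 70% valid samples, with externally supplied calibration drift above
1°, or with no valid samples at all ("disengaged"). Drift is an input,
not an estimate: it comes from validation screens, which are outside the
stimulus stream.

## AOI geometry

AOIs are simple polygons (convexity is not assumed). Containment uses
even-odd ray casting with an explicit edge test, and the boundary counts
as *inside* — AOIs are closed polygons, so a fixation exactly on an edge
belongs to the AOI. Overlaps resolve by a fixed category priority
(`Website/CTA > Logo > Symbol > Source/Authority > Text > Image/Visual`):
the most actionable object wins the boundary fixation. Equal-priority
overlaps break deterministically by smaller pixel area (a specific element
beats a large backdrop), then lexicographic AOI id. A fixation is assigned
by its centroid only; dwell is never split across AOIs. Layout covariates
are the shoelace polygon area (px²) and the centroid-to-screen-centre
distance (px).

## Pairwise dwell dominance

For each ad and each unordered AOI pair (i, j), restricted to participants
with uncensored dwell on both, the win probability is

$$P_{ij} = \frac{\#\{FD_i > FD_j\} + \tfrac12\,\#\{FD_i = FD_j\}}{N_{ij}},$$

with `P_ii = 0.5` and `P_ij + P_ji = 1` by construction. Ties are exact
equality — dwell values are millisecond-scale sums and no epsilon is
applied. Pairs with no joint observer are *undefined* (`NA`), which is a
different state from display masking: masking (support below 5 by
default) affects figures only and never the algebra. The dominance score

$$s_i = 2\,(\bar P_i - 0.5), \qquad
\bar P_i = \operatorname{mean}_{j \ne i,\ \text{defined}} P_{ij},$$

lies in [−1, 1]; the mean excludes the diagonal (including the fixed 0.5
self-entry would shrink every score toward zero and break the ±1 range for
small matrices) and skips undefined pairs, with isolated keys reported as
`NA` with a warning. When every pair is defined the scores sum to zero,
since each unordered pair contributes exactly 1 to the off-diagonal total.

Category-level dominance first sums dwell within category per participant
(a participant observes a category if at least one of its AOIs was
fixated), then applies the same construction. Precedence matrices replace
"more dwell" with "earlier TTFF": with both keys uncensored the smaller
TTFF wins (equal values count half); with exactly one censored, the
uncensored key wins; participants censored on both carry no information
and leave the support. The censoring rule is this package's convention —
"earlier is a win" alone does not decide it — and is stated here rather
than hidden.

`verify_axioms()` checks `max |P_ij + P_ji − 1|` and `max |P_ii − 0.5|`
against a tolerance of 1e−12. These are identities of the construction,
so the check is a tripwire for post-hoc tampering or transcription errors,
not a numerical-stability allowance. As an external robustness check,
`concordance()` correlates dominance scores with benchmark median dwell
(Pearson and Spearman); stochastically ordered dwell should and does give
positive coefficients.

## First hits, subgroups, quadrants

The first hit of a trial is the AOI with minimum uncensored TTFF. Exact
ties — possible with discretised clocks — break by category priority,
then AOI id, so output is deterministic. Trials where every AOI is
censored are excluded from first-hit denominators and counted separately
(`n_no_hit`). Distribution percentages are kept at full precision (they
sum to exactly 100 within an ad); rounding to one decimal is a display
concern.

Subgroup deltas are `subgroup − overall` in percentage points, per
category and stratum level; each level's deltas cancel to zero because
both distributions sum to 100%. The sign convention is stored in the
output so no reader has to guess it.

The early-vs-sticky map crosses each AOI's first-hit share with its
dominance score. "Early" is a share at or above the within-ad median of
first-hit percentages, computed over *all* ranked AOIs with never-hit
AOIs at 0%; "sticky" is strictly `s > 0`. The reference lines define four
actions: early∧sticky → *protect*; late∧sticky → *promote* (move it
earlier); early∧¬sticky → *unclutter* (strengthen the payoff);
neither → *reconsider*. The boundary memberships (≥ median is early,
`s = 0` is not sticky) are explicit because reference lines alone do not
decide them.

## The synthetic generator

No public gaze dataset accompanies this kind of panel study, so the
package ships a generator whose defaults emulate the study conditions the
pipeline targets: 30 participants, 6 static ads with 41 AOIs over the six
semantic categories, 10 s exposures sampled at 60 Hz, and quota strata
(four age bands 30/16.7/23.3/30%, four household types 63.3/16.7/10/10%,
four education levels 13.3/43.3/23.3/20%).

The generative model, chosen once and documented here:

* **Entry**: the first-hit AOI is drawn from per-AOI salience weights
  (multiplied by subgroup entry modifiers) and is always fixated; other
  AOIs are skipped independently with per-AOI probability `p_skip`
  (the censoring mechanism), and their entry order follows log-normal
  latency draws. Consequently the ground-truth first-hit distribution is
  exactly the normalized (mixture-averaged) entry weights.
* **Dwell**: per-AOI gamma distributions — positive and right-skewed, as
  empirical dwell is. Dwell splits across an AOI's revisit fixations by a
  symmetric Dirichlet; revisit counts are 1 + Poisson(dwell/350 ms).
* **Scanpath**: first fixations of fixated AOIs in entry order, revisits
  shuffled after, 80 ms saccade gaps (above the 75 ms merge window, so
  distinct fixations stay distinct), fixation points uniform inside the
  AOI polygon, plus background fixations outside every AOI that fill the
  remaining exposure. Raw 60 Hz samples carry sub-threshold jitter inside
  fixations, linear interpolation during saccades, and invalid samples
  outside the scanpath.
* **Feasibility**: configs whose expected dwell mass exceeds 75% of the
  exposure are rejected; individual trials whose *drawn* dwell overruns
  the budget are scaled down uniformly. Uniform scaling preserves every
  within-trial dwell comparison, so ground-truth win probabilities are
  unaffected — this is why the trick is safe.
* **Determinism**: participant p uses seed `root + p`, so enlarging the
  panel never perturbs existing participants.

Analytic ground truth comes with the config: first-hit shares in closed
form; pairwise win probabilities by the beta identity
`Pr(X > Y) = pbeta(0.5, a_y, a_x)` for equal-scale gammas and by
quadrature otherwise, averaged over the stratum mixture when dwell
modifiers apply; category orderings by expected within-category dwell
(valid when the configured distributions are stochastically ordered, as
the defaults are).

What passing tests on synthetic data do **not** show: the generator has
no scanpath realism beyond AOI-level structure (no saliency-driven
spatial correlations, no smooth pursuit, no pupil or blink dynamics, no
drift), its skip decisions are independent across AOIs, and its subgroup
effects are clean multiplicative shifts. Recovery results demonstrate the
*estimators*, not properties of any real population.

## Heatmaps and rendering

Attention heatmaps splat fixation centroids (duration-weighted by
default) on a grid — down-sampled ×4 by default for speed, recorded in
the object — convolve with an isotropic Gaussian of σ = 1.0° (the low end
of the conventional 1–1.5° band, exposed as a parameter), and normalize
the maximum to 1; empty input gives an all-zero grid rather than an
error. Rendering never alters numbers: every atlas figure is written next
to the exact table it draws, and masked dominance cells are greyed with
their support printed, backed by a companion support-N heatmap.

## Problem sizes and numerical notes

The shipped tests run the full pipeline at study scale (30 × 6 ads, 41
AOIs) and use 200 participants for win-probability recovery (tolerance 3
binomial standard errors), 1000 for first-hit recovery (3 percentage
points), and 10⁶ Monte-Carlo draws to cross-check the quadrature
(tolerance 0.005) — sizes chosen so sampling error, not the
implementation, sets the tolerance, while the whole suite stays fast.
Degenerate inputs have defined behaviour throughout: zero-area polygons,
single-key matrices, all-censored trials, empty strata levels, and empty
fixation sets each raise a classed error, a warning, or a documented
neutral value rather than propagating NaN.

Known limitations: no survival-analysis treatment of censored TTFF (plain
right-censoring only, matching the descriptive aims), no parametric
paired-comparison model fitting (the dominance matrix is the estimator),
no dynamic or time-varying AOIs, and no inferential subgroup testing —
deltas are descriptive by design.
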