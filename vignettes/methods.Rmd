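---
title: "Along-tract abnormality analysis: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Along-tract abnormality analysis: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epitract)
```

`epitract` analyses along-tract diffusion metrics in epilepsy-surgery
cohorts: 100-node tract profiles of FA, MD and Vol plus a whole-tract fiber
count, compared between patient groups and controls cell by cell, and
condensed into a rule-based abnormality taxonomy. This vignette explains
the models behind each stage, the parameters that matter, what the
synthetic cohort generator does and does not emulate, and the choices made
where the underlying methodology left the design open.

## Tract profiles

A streamline is resampled at `n_nodes = 100` points of equal arc length
along its piecewise-linear geometry (`resample_fiber()`), endpoints
preserved exactly. We deliberately use the piecewise-linear interpolant
rather than a spline: it is deterministic, cheap, and directly checkable
against a brute-force dense resampler, and nothing downstream is sensitive
to sub-voxel smoothing of the path. Scalars sampled along the fiber (FA,
MD) are interpolated on the same arc-length parameterisation.

At each node, `profile_bundle()` aggregates fibers by the unweighted mean.
Tractometry implementations sometimes weight fibers by their Mahalanobis
distance from the bundle core; we use the plain mean as the simplest
defensible contract and document it here — with synthetic bundles whose
fibers are exchangeable the two coincide in expectation.

Volume is defined node-wise: the number of distinct voxel cells (edge
`voxel_size`, default 2 mm, a typical DWI slice thickness) containing any
fiber's k-th node, times the voxel volume. This makes *segmental* volume
well-defined, which a single whole-tract volume would not be. A bundle
with fewer than `min_fibers = 5` streamlines is flagged invalid rather
than erroring — the concrete version of the rule that tracts whose
variables cannot be measured are discarded; invalid instances propagate as
explicitly `skipped` comparison cells, never as silent absence.

Profiles are summarised into 5 segments of 20 consecutive nodes (segment 1
= nodes 1–20, 1-based, through segment 5 = nodes 81–100). The global mean
is computed as the mean of the five segment means; with equal segment
sizes this is mathematically the all-node mean, and computing it this way
makes the aggregation identity hold bit-for-bit when recomputed. Fib has
no segmental scope. Node 1's anatomical end is taken as given by the input
and must be consistent within a tract across subjects; no automatic
reorientation is attempted.

## Laterality and the control arm

Patients' tract sides are recoded relative to the ictal onset zone (IOZ):
same side → `ipsi`, opposite → `contra`; the commissural CFMe stays
`midline`. Controls have no IOZ, and the source methodology states only
that their left and right characteristics were "combined". Both readings
are implemented: `pool` (default) enters each control hemisphere as its own
observation, `subject-mean` averages the two sides per subject. Pooling
doubles the control observation count (n = 38 from 19 controls) and treats
hemispheres as exchangeable; the subject-mean policy is more conservative
about within-subject correlation. The choice is a config switch
(`control_policy`) carried in every output's fingerprint.

## The comparison grid

Each tract instance (5 bilateral families × {ipsi, contra} + CFMe = 11)
contributes 19 cells: 4 variables at global scope and FA/MD/Vol at each of
5 segments — 209 rows per group pair. Each cell is a univariate general
linear model with Fisher LSD contrasts:

* `diagnosis`: a 3-level one-way model (control, FLE, TLE); the reported
  patient-vs-control p-values are the LSD pairwise t statistics built on
  the pooled error mean square of the 3-level fit. When a single diagnosis
  group is analysed independently, a 2-level model is used (`combined`
  grouping for all patients vs controls).
* `outcome`: operated patients only, Engel Class I (seizure freedom)
  versus Classes II–IV (recurrence).

Tests are two-sided at `alpha = 0.05` with no multiplicity correction by
default, matching the raw-P reporting convention of LSD-based clinical
analyses; Benjamini–Hochberg adjustment within each group pair is
available (`multiplicity = "BH"`). The direction of every contrast
(sign of patient mean minus control mean) is reported separately rather
than folded into one-sided tests. ANCOVA covariates (age, sex) can be
entered linearly; the original analysis names a covariance model without
stating its covariates, so the default is none and the option is explicit.
The multivariate (MANOVA) layer is intentionally not implemented as an
omnibus gate: results are reported per variable, so each variable is
tested univariately.

Two numerical contracts are worth stating. First, `lsd_anova()` declares
data with zero within-group variance in *every* group degenerate; the
check is range-based with a 1e-12 relative tolerance because group means
of bit-identical values computed by grouped summation can differ by one
ulp, which would otherwise manufacture an F statistic out of rounding
noise. Second, `comparison_grid()` resolves such degenerate cells by the
exact limit rule — p = 1 if the group means coincide (to 1e-8 relative),
p = 0 if they differ — so that noise-free simulations run the entire
pipeline deterministically instead of crashing; user-facing `lsd_anova()`
still raises the degenerate-variance error.

Kruskal–Wallis (tie-corrected, chi-square reference) is used for the
demographic comparisons, where small group sizes and skewed distributions
make rank tests appropriate.

## The abnormality taxonomy

Against the control reference, for one tract instance:

* **consistent-global** — 3 or 4 of the 4 variables significant at global
  scope.
* **consistent-segmental** — a segment is abnormal when ≥ 2 of its 3
  segmental variables are significant; the label fires when 1–4 of the 5
  segments are abnormal. The "2 or 3 variables" condition is evaluated
  per segment (co-significance within a segment), not cumulatively across
  different segments: a segment-level reading keeps "consistent" spatially
  coherent. A tract abnormal in all 5 segments is not segment-confined;
  it is reported under the distinct `whole-length-segmental` flag.
* **de-novo-global / de-novo-segmental** — the same rules applied after
  surgery, restricted to variables (or variable-segment pairs) that were
  *not* significant before surgery. Because Fib is global-only, a de novo
  global label may rest on Fib plus two node-wise variables.
* **reinforced-global / reinforced-segmental** — variables (pairs)
  significant at both timepoints with the same direction; persistence
  requires direction agreement, de novo does not (a new finding is new
  whatever its sign). A tract may carry de novo and reinforced labels
  simultaneously on disjoint variable sets; pre-only significance
  (resolution) is deliberately untracked.

Tract instances with skipped cells at a timepoint are excluded from that
timepoint's labels and from longitudinal labels, and are listed in the
`not_evaluable` attribute — missingness is never treated as absence of
abnormality. The classifiers are verified against independent brute-force
rule evaluators over all 2⁴ global and 2¹⁵ segmental significance
patterns.

## The synthetic cohort generator

No DWI data of this kind are publicly deposited, so the generator is a
first-class module, not a fixture. For each subject, tract instance and
node-wise variable it draws

curve = m(tract, variable) + b + ε,

where m is a smooth tract-specific mean curve (baseline plus a low-order
sinusoid, so first differences are bounded), b ~ N(0, between_subject_sd²)
is a whole-tract subject shift, and ε is Gaussian node noise with
exponential autocorrelation exp(−Δ/L) over the node index (L = 10 nodes by
default — AFQ profiles are smooth, and i.i.d. node noise would be
unrealistic). Fib is negative-binomial (mean 80, size 20), since fiber
counts are overdispersed; `fib_size = Inf` gives the deterministic
expected count for noise-free checks. Planted effects are additive shifts
on the mean curve of matching subjects — whole-tract or confined to one
20-node segment — with the sign convention that positive places patients
above controls; the directions observed in this population are increased
MD with decreased FA, Vol and Fib.

Defaults encode the study design: 19 controls, 8 FLE (7 operated, 1/7
seizure free), 12 TLE (10 operated, 6/10 seizure free); ages ~N(22, 5²)
for FLE and N(33.6, 13.8²) for TLE; epilepsy durations ~N(13.4, 8.3²) and
N(17.6, 9.7²) years. Controls are measured once and serve as the reference
arm at both timepoints; operated patients have pre and post measurements.
Baselines (FA 0.45, MD 0.80 × 10⁻³ mm²/s, Vol 15 mm³/node, Fib 80) are
plausible white-matter magnitudes chosen once — the source reports no
within-group variance figures, so noise magnitudes (sd 0.02/0.03/1.5 for
FA/MD/Vol at both the subject and node level) are free parameters of the
emulation, not estimates. Consequently the suite verifies *calibration and
recovery* — type-I control at α and majority recovery of planted effects
by the correct taxonomy category — and cannot, even in principle,
reproduce the study's specific patient-derived anomaly counts. That is
also what passing tests mean for real data: the machinery is correct and
calibrated under a plausible noise model, not that any particular clinical
finding recurs.

The generator does not emulate raw DWI volumes, tensor fitting, motion or
eddy artifacts, tractography failure modes beyond a configurable per-tract
dropout probability, hemispheric asymmetries of the mean curves, or
age/sex effects on the metrics. In streamline-bundle output mode, FA and
MD are carried on the fibers while Vol and Fib emerge from voxel occupancy
and fiber count, so planted Vol effects apply only in profile output mode.

Randomness is reproducible by construction: one global seed feeds a fixed
per-subject, per-timepoint substream scheme
(`substream_seed(seed, i, tp)`), so a subject's data do not depend on how
many other subjects were generated, and equal specs give byte-identical
cohorts.

## Monte-Carlo design of the calibration checks

The null-calibration test simulates 500 no-effect cohorts at the study's
group sizes and requires the mean per-contrast rejection rate of the full
pipeline to sit within a 99% interval around α = 0.05. Contrasts within a
cohort are positively correlated by construction — a tract's global mean
is the average of its segment means, and the subject-level shift b spans
all scopes of a variable — so the interval uses the replicate-level
(cluster-level) standard error, not a naive binomial n = cohorts × cells,
which would be anti-conservative. Planted-effect recovery uses effects of
2× the node noise sd at n = 19 controls vs 12 patients over 200
replicates (majority recovery required), plus exact noise-free runs in
which the wrong category must never fire; problem sizes throughout the
suite (500 and 200 replicates, 30-observation oracle instances) are the
package's chosen verification scale.

## Known limitations

* The LSD contrasts assume normal within-cell errors; Fib cells are
  negative-binomial and rely on t robustness at these group sizes.
* No mixed-effects, permutation or cluster-based along-tract inference;
  the 19-cell grid treats cells as separate univariate models, exactly as
  the original analysis reports them.
* The whole-length-segmental flag, the per-segment reading of the
  co-significance rule, and the 1–4 segment band are documented
  interpretations of a verbally stated rule set; alternatives (cumulative
  variable counting, 5/5 as segmental) would change label counts on real
  data.
* `recode_laterality()` requires a lateralised IOZ; cohorts with midline
  or unknown onset need relabelling upstream.
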