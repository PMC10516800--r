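---
title: "Cross-subject metabolic connectivity: model, design choices, and what the synthetic tests show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-subject metabolic connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaconn)
```

## The statistical model

Metabolic connectivity treats each subject (animal) as one observation of a
176-dimensional vector of regional uptake. Within a group, the coupling of
two regions is the Pearson correlation of their uptake values across the
n subjects. This is a cross-sectional quantity: it measures whether animals
with unusually high activity in one region also show unusually high (or
low) activity in the other, and it says nothing about within-subject
dynamics. The analysis therefore assumes:

* subject vectors are independent draws from a common multivariate
  distribution within each group;
* that distribution is close enough to multivariate normal for the Pearson
  correlation, the t-based p-value with n − 2 degrees of freedom, and the
  Fisher z machinery (variance 1/(n − 3)) to be calibrated;
* global uptake differences between animals are nuisance gain, removed by
  proportional scaling of every subject row to a common mean (default 100,
  an arbitrary positive constant — only ratios matter).

With n = 10 subjects these are strong assumptions, and single-edge tests at
n = 10 are weak (the two-sided 5% critical value is |r| ≈ 0.63). The
jackknife criteria below are what make the edge lists usable at this sample
size.

## Reliability by jackknife

Thousands of simultaneous edge tests at α = 0.05 would produce hundreds of
false edges. Instead of a multiplicity correction on p-values, reliability
is enforced by leave-one-out stability:

* **Within a group** (n iterations): an edge is kept only if its
  correlation is significant (p < α) in every one of the n recomputations
  with one subject removed, with the same sign each time.
* **Between groups** (2n iterations): the Fisher Z matrix comparing the two
  groups is recomputed dropping one subject from either group (the other
  group stays at full n, so each iteration compares n and n − 1 subjects);
  a difference is kept only if significant with a consistent Z sign in all
  2n iterations.

Both procedures are strictly harder to pass than the corresponding
full-sample test at the same α, so the per-edge false-positive rate is
bounded by α; empirically (see the acceptance script) it sits near 1% at
the design size. Two deliberate interpretive choices:

* **Sign consistency always binds.** An edge whose leave-one-out
  correlations flip sign cannot be booked as reliably positive or negative,
  so it is excluded even when every iteration is nominally "significant".
  The practical consequence appears only at large α: at α = 1 the procedure
  returns the sign-consistent pairs, not all pairs. At conventional α the
  clause is almost never the binding one.
* **Full-sample significance is not additionally required** — the
  all-iterations criterion is the definition of reliability. A
  `strict_full_sample` flag adds the full-sample requirement for users who
  want both.

Degenerate inputs are errors, not silent repairs: constant ROI columns
(Pearson undefined), n < 5 (a jackknife iteration would drop below 4
subjects), and n ≤ 3 in the Fisher Z denominator all stop with a message
naming the offender. Perfect correlations (|r| = 1) get p = 0 in the
t-test; inside the Fisher Z statistic they are clamped to 1 − 10⁻¹⁵ so that
two equal perfect correlations compare as equal (Z = 0) instead of NaN.

## The parcellation and connectivity density

Connectivity density is the count of reliable edges of one sign between two
structures divided by the number of ROI pairs for that structure pair —
k(k−1)/2 within a structure of k ROIs, k_a·k_b between two structures. The
shipped registry fixes the denominators: 176 ROIs with 66 in the
caudoputamen and 21 in the thalamus, giving 2,145 within-CP and 1,386
CP–thalamus pairs. The remaining structure sizes (SNr 25, GPe 27, motor
cortex 18, PFC 19) are pinned by the density arithmetic itself: they are
the only integer counts for which published within-structure densities such
as +32.48% (GPe) and +8.77% (PFC) correspond to whole edge counts
(114/351, 15/171). The per-bregma grouping of ROIs inside each structure,
by contrast, is a declared synthetic layout — plausible coronal levels in
the atlas ranges, one ROI per domain per level, hemisphere-agnostic — and
nothing downstream depends on it beyond ordering.

Hubs are the top 10% of nodes by degree. The count is made exact,
⌈0.1·N⌉ (= 18 at N = 176), by breaking ties at the cutoff deterministically
in registry order; degrees count positive and negative edges identically.
The Kamada-Kawai layout is computed per connected component (a single pass
over a disconnected graph need not separate components), each component
normalised to unit RMS radius and spread on a circle; isolated nodes sit on
an outer ring. The layout is deterministic for a fixed seed and treats
edges as unsigned and unweighted — sign is a rendering attribute.

## The synthetic generator

`simulate_study()` emulates the study design: two groups of 10 subjects,
176 ROIs, multivariate-normal uptake with mean 100 and subject-level
standard deviation 5 (a 5% between-animal spread, typical of proportionally
scaled uptake data). Correlation structure is block-compound-symmetric
within each structure, with block correlations (CP 0.55, SNr 0.80, GPe
0.85, motor 0.75, PFC 0.70, TH 0.80) chosen once so that, at n = 10, each
structure retains a partial, structure-dependent share of jackknife-
surviving edges — high enough to form clusters, low enough that the
jackknife prunes — mirroring the qualitative ordering of published
within-structure densities (caudoputamen sparsest, pallidal/nigral and
thalamic blocks densest). Ground truth for the group comparison is seven
planted edge differences: four caudoputamen–motor couplings (0 vs 0.95)
present only in the exercise group and three thalamus–prefrontal couplings
(0.95 vs 0) present only in the control group, the pattern of the published
exercise effects.

Two generator details matter for interpretation:

* **Feasibility and PSD repair.** A requested correlation matrix
  (blocks + planted overrides) need not be positive semi-definite. It is
  repaired by clipping negative eigenvalues at zero and re-normalising to
  unit diagonal; if the repair moves any entry by more than a tolerance
  (default 0.05) the request is rejected as infeasible rather than silently
  distorted. This is why the planted-difference endpoints are decoupled
  from their structure's block in the covariance spec: a 0.95 coupling to
  an outside region is geometrically incompatible with simultaneously
  strong within-block coupling. Substantively this models a region rewired
  away from its home structure, which is the phenomenon the comparison is
  meant to detect.
* **What the generator does not emulate:** film response and digitisation
  noise, spatial autocorrelation between neighbouring ROIs beyond the block
  structure, heavy-tailed or skewed uptake distributions, and any
  systematic global-uptake differences (data are generated post-scaling).
  Passing tests therefore certify the statistical machinery under the
  model's own assumptions, not robustness to violations of them.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 0.05 | per-iteration significance level in both jackknives |
| `hub_fraction` | 0.10 | top-degree fraction flagged as hubs (⌈fraction·N⌉ exact) |
| `target_mean` | 100 | common subject mean after proportional scaling (units arbitrary) |
| `strict_full_sample` | `FALSE` | additionally require full-sample significance |
| PSD repair `tol` | 0.05 | max entry change tolerated when repairing a target matrix |
| `layout_seed` | 1 | seed for the deterministic Kamada-Kawai layout |

## Problem sizes used in the test suite

The suite checks oracle equivalence of both jackknife procedures against
explicit brute-force leave-one-out loops on 8-ROI instances at n = 6–10
(50 seeds), type-I control on 20-ROI null instances at n = 10/group
(200 seeds), and recovery of planted effects (r = 0.95 within-group;
0 vs 0.95 between groups) over 100 replicates — sizes at which the
brute-force oracles are exact and fast while the statistics are at the
study's design sample size. The acceptance script re-runs the same
measurements from scratch at comparable sizes.

## Known limitations

* Correlation-based coupling cannot distinguish direct from indirect
  (common-input) coupling, and cross-subject correlation conflates stable
  trait covariance with state covariance.
* The jackknife bounds the per-edge error rate but is not a family-wise or
  FDR guarantee over the 15,400-pair matrix.
* Equal group sizes are the design assumption; unequal sizes are supported
  (n₁ + n₂ drop-one iterations) with a warning, but the 2n-iteration
  calibration claims are only exercised at n₁ = n₂.
* Density comparisons between groups are descriptive — no standard error is
  attached to a density, matching the original reporting.
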