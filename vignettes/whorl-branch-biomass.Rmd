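---
title: "Estimating whorl-level branch attributes and biomass from TLS stem geometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating whorl-level branch attributes and biomass from TLS stem geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(whorltls)
```

## The problem

Terrestrial laser scanning (TLS) reconstructs conifer stems well, but
individual branches poorly: needles, branch overlap and the growing
beam footprint occlude the upper crown, so cylinder-model
reconstructions miss many branches outright and mis-size others. For
Scots pine and other whorl-forming conifers there is, however, strong
structural regularity to exploit: branches insert in annual whorls, and
pipe model theory ties the branch cross-sectional area carried above
any stem height to the stem's own cross-sectional area at that height.
`whorltls` uses the part of the TLS signal that is reliable — the stem
taper and the heights of detected trunk-attached ("0") branches — and
lets structure models predict what TLS cannot see: per-whorl branch
numbers, individual branch basal areas and diameters, and branch dry
biomass.

## The model chain

For a tree with height $H$ (m), breast-height diameter $D$ (cm) and
crown length $H_C$ (m), the pipeline is:

1. **Taper curve.** Refined stem-slice diameters plus the two known
   anchors $(1.3\,\mathrm{m}, D)$ and $(H, 0)$ are interpolated into a
   queryable taper $d(h)$; stem area is $A(h) = \pi d(h)^2/4$.
2. **Whorls.** Detected "0"-branch heights are clustered: consecutive
   sorted heights at most 3 cm apart belong to one whorl (single-linkage
   chaining), and whorl height is the mean of its members. Where the
   topmost whorl sits more than 0.5 m below the treetop — the signature
   of upper-crown occlusion — *fake whorls* are inserted every 25 cm,
   stepping upward from the topmost whorl, until the gap closes.
3. **Branch count.** For whorl $i$ with height increment
   $\Delta h_i$ (cm) to the whorl above and relative crown depth
   $h_r = (H - h_i)/H_C$,
   $N_{bi} = b_0 + b_1 \ln \Delta h_i + b_2 (H - 1.3)/D + b_3 h_r$,
   rounded half-up and clamped to $\ge 1$.
4. **Whorl basal area.** Pipe model theory:
   $\sum_{j \le i} B_j = \eta A_i$ (areas in cm²), so each whorl's
   share is the increment $B_i = \eta (A_i - A_{i-1})$ with $A_0 = 0$.
5. **Individual branches.** The largest and smallest branch relative to
   the whorl mean follow log-linear / logit-linear models in $N_{bi}$,
   $(1.1 - h_r)$, $\ln(1.1 - h_r)$ and tree dimensions. Relative sizes
   are drawn uniformly between those extremes and rescaled so the whorl
   total is conserved exactly; a single-branch whorl receives $B_i$
   whole. Diameter follows from basal area.
6. **Dry mass.** $\ln w = b_0 + b_1 (\ln d)^{0.22}$ with $d$ in mm and
   $w$ in g (fixed part only); the tree total is the sum over living
   branches, reported in kg.

All regression coefficients default to fixed-part estimates from a
destructive database of 122 Scots pines (about 14 000 branches); the
random effects of the original mixed models are never applied in
prediction. Three standard TLS-based comparison estimators are
included: cylinder volume × wood density ($\rho_b = 400$ kg m⁻³),
a stump-diameter/height allometry
($\ln W_b = a + b\, d_S/(d_S+6) + c\, H/(H+1)$), and a crown-base
pipe-model allometry ($W_b = \rho_b \varphi_b (\eta_s/\eta_b) A_c$).

```{r worked}
tm <- tree_metrics(25, 30, 15, tree_id = "demo")
slices <- data.frame(height_m = c(0.3, 2, 5, 8, 11, 14, 18, 22))
slices$diameter_cm <- 30 * sqrt((25 - slices$height_m) / 23.7)
detections <- c(24.7, 24.2, 24.21, 23.6, 22.9, 22.91, 22.93, 21.8, 20.7,
                19.4, 18.1, 16.9, 15.6)
est <- estimate_tree(tm, slices, detections, run_config(seed = 42))
est
head(est$prediction$whorls[c("whorl_height_m", "is_fake", "basal_area_cm2",
                             "n_branches")])
```

## Numerical and design choices

**Taper interpolant.** The curve is an exact cubic spline fitted on the
squared-diameter (area) scale, sampled on a 1-cm grid above breast
height, forced non-increasing by a pool-adjacent-violators (isotonic)
correction, and re-pinned to the anchors. The squared scale was chosen
because the two analytic stem forms used in validation — the cone and
the quadratic paraboloid — are then represented exactly, and because it
guarantees non-negative areas, which the pipe-model step divides into
branch basal area. Below breast height the diameter is held at DBH
unless butt slices are provided (butt swell is irrelevant to crown
whorls). Monotonicity enforcement protects the downstream invariant
$B_i \ge 0$.

**Clustering semantics.** The 3-cm rule is applied to *consecutive*
sorted heights (inclusive comparison), so a chain of close detections
can form a whorl spanning more than 3 cm in total; this matches the
pairwise statement of the rule. Ties in sorting are stable. Dead
branches below the crown base are excluded before clustering whenever a
crown base is supplied.

**Fake-whorl anchoring.** Insertion steps upward from the current
topmost whorl rather than downward from the treetop, preserving spacing
relative to the detected crown; the operation is idempotent. The 25-cm
interval and the 0.5-m trigger are configurable (`run_config()`).

**Pipe-model increment.** The increment form of the whorl basal area is
implemented *with* the proportionality coefficient,
$B_i = \eta (A_i - A_{i-1})$: only this variant is consistent with the
telescoping cumulative relation $\sum_{j\le i} B_j = \eta A_i$ that
defines the theory. The coefficient-free variant is available behind
`structure_params(eta_in_eq3 = FALSE)` for sensitivity analysis.

**Rounding and guards.** Branch counts are rounded half-up and clamped
to 1; $\Delta h$ of the topmost whorl is the distance to the treetop,
floored at 1 cm so the logarithm stays defined; negative area
increments (impossible after isotonic correction, but guarded anyway)
yield zero-branch whorls. Uniform branch sizes are rescaled
multiplicatively to conserve $B_i$, which can push individual sizes
slightly outside $[R_{min}, R_{max}]$ — accepted, since exact
conservation is the invariant the biomass step relies on.

**Units.** Heights m, stem and branch diameters cm (branch diameters
reported in mm), areas cm², branch mass g, tree totals kg. The dry-mass
model's mm/g convention is inherited from the branch-biomass literature
the coefficients come from and yields plausible masses (about 0.64 kg
for a 30-mm branch); it is exposed in `biomass_params()`.

## The synthetic generator

Because destructive whorl-level reference data are not publicly
deposited, the package ships a generator
(`synthetic_config()`, `generate_tree()`) that emulates the study
conditions: mature Scots pines (H 20-31 m, DBH 22-41 cm, crown ratios
0.25-0.5), annual whorl spacing N(0.30 m, 0.05 m) truncated to
[0.05, 0.5] m, and an analytic stem form. The default form is the
quadratic paraboloid, which reproduces the crown-base diameters of old
pines far better than a cone. Branch structure is produced by the same
pipe-model chain the estimator uses, so generated trees satisfy the
pipe-model identity exactly and closed-loop recovery is a meaningful
test: with perfect detections and noise-free slices the estimator must
reproduce the generative truth to numerical precision (it does, to
below 10⁻⁶ kg).

TLS defects are simulated as logistic height-dependent retention
(defaults give roughly 60 % omission in the upper crown and 20 % in the
lower crown, matching the qualitative occlusion pattern of real scans),
Gaussian attachment-height jitter (sd 1 cm), and optional slice noise.
Branch-mass noise is log-normal with sd 0.43 — the residual spread of
the dry-mass model — and is mean-corrected so that expected mass equals
the fixed-part prediction.

What the generator does *not* emulate: real crowns are shaped by
competition and shading, so true branch counts deviate from the count
model in ways the generator cannot show; detection omission in real
scans is spatially correlated (whole occluded sectors), not
independent per branch; and stem forms are neither exact cones nor
paraboloids. Passing closed-loop tests therefore demonstrates internal
consistency and robustness to the modelled defects, not field accuracy.

## Evaluation suite

`evaluate_tree()` formalizes the comparison against destructive
reference measurements: whorls are paired one-to-one by greedy
nearest stem cross-sectional area (no distance cap), branches within
paired whorls by count, and metrics are reported per crown layer —
upper ($h_r < 0.3$), middle ($0.3 \le h_r < 0.7$), lower
($h_r \ge 0.7$), with half-open boundaries so the layers partition the
crown. Accuracy, commission error $E_c$ and omission error $E_o$ share
the denominator $N_p + N_c + N_o$ and always sum to 100 %. Paired
whorls contribute to the stratum of their *reference* whorl;
commissions to the stratum of the estimated whorl — so stratum counts
add up to the whole-tree counts exactly. Agreement measures are RMSE,
CV-RMSE (percent of reference mean), Lin's concordance correlation
coefficient (population moments), and the two-sample
Kolmogorov-Smirnov statistic (asymptotic p-values; the samples involved
are tens of branches). Branch diameters are compared rank-matched
(largest to largest) within paired whorls.

The package also ships the published six-tree detection-count table
(`detection_count_table()`); recomputing the percentage columns from
the counts reproduces the published values — except in two rows whose
printed percentages are internally inconsistent with their own counts
(they do not sum to 100); the counts are treated as authoritative.

## Problem sizes and reproducibility

The validation suite works at desk scale by choice: eight slices per
taper (the canonical destructive measurement points), trees of 25-45
whorls, 50-replicate closed-loop batches, and 1000-branch parameter
recovery; these sizes keep every property estimate stable without
inflating runtimes. Every stochastic step takes an explicit integer
seed, and all pipeline randomness flows through one seeded generator
recorded in the run manifest, so `run_pipeline()` outputs are
byte-identical under a fixed configuration.

## Known limitations

Coefficients are for Scots pine in southern Finland; applying them to
other species or climates requires refitting (only the dry-mass
fixed-part refit, `fit_branch_biomass_fixed()`, is included). The
25-cm fake-whorl interval was calibrated against destructive data in
the source study; other stands may need a different value. Individual
branch diameters are known to be biased low even when whorl totals are
unbiased — the whorl total is the quantity pipe model theory actually
constrains. Dead branches, branch angles and lengths, and foliage
biomass are out of scope.
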