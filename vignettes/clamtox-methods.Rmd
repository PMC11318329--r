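---
title: "Methods: multi-biomarker toxicity assessment in bivalves"
author: "clamtox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-biomarker toxicity assessment in bivalves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

clamtox implements the statistical chain of a chronic water-borne exposure
experiment on a marine clam: three concentration groups (0 "control", 1 and
5 µg/L of bisphenol A), five replicate aquaria of eight animals per group,
21 days, with survival checked daily and, at the end of exposure,
biochemical biomarkers (n = 3 animals/group), comet-assay DNA damage and
digestive-gland histopathology (n = 5 animals/group). This vignette is the
package's own account of the models, the generator calibration, and the
numerical choices; it states no empirical result beyond what the test suite
and `scripts/acceptance.R` compute.

## Survival: product-limit estimation and the log-rank test

Death is the event; animals alive at day 21 are censored there. Because
daily inspection yields integer event days, ties within a day are routine.
`km_estimate()` computes the Kaplan–Meier step function: at each distinct
event time $t$ with $d$ deaths among $n$ at risk, $\hat S$ multiplies by
$(1 - d/n)$. `logrank_test()` accumulates, at each event time, the observed
deaths per group against the conditional expectation
$E_{gj} = d_j n_{gj}/N_j$ and the tied-data hypergeometric covariance with
the $d_j (N_j - d_j)/(N_j - 1)$ factor, then forms the quadratic form of
$O - E$ over $k - 1$ groups against $\chi^2_{k-1}$. No continuity
correction is applied, matching mainstream survival software; the test
suite cross-checks the statistic against `survival::survdiff()` on both the
scripted reconstruction and random data.

Individuals are pooled across replicate aquaria: a three-aquarium-level
frailty cannot be estimated from four events, and the pooled analysis is
the one the published χ² (8.3 on 2 df) corresponds to. Aquarium identity is
still carried in every record so a clustered reanalysis remains possible on
richer data.

The generator's **scripted** survival mode hard-codes the published event
history — one death on day 17, two on day 19, one on day 20, all in the
high-dose group — making the printed log-rank χ² an exact, reproducible
target. The aquaria of the four dead clams are not identifiable from the
published account; scripted mode assigns them to the first individuals of
the group, an explicitly arbitrary bookkeeping choice with no effect on the
pooled analysis. The **hazard** mode is the general stochastic path: each
animal's death day is geometric with the group's daily hazard. Its default
high-dose hazard, 0.005/day, was chosen so the expected death count over 21
days, $40(1 - 0.995^{21}) \approx 4.0$, matches the scripted outcome.

## Biomarkers and the generator calibration

Biomarker values are strictly positive concentrations/activities, so noise
is multiplicative log-normal: a draw is
`control_mean × multiplier × LN(−σ²/2, σ)` with
`σ = sqrt(log(1 + CV²))`, which makes the factor's mean exactly 1 and
avoids the negative values an additive model would produce at any CV. The
default CV is 5 %, consistent with the within-group mean squares of the
published one-way tables at these means.

The group multipliers are the published percent changes read as ratios —
MDA ×{1, 2.35, 2.97}, GSH ×{1, 3.90, 5.98}, CAT ×{1, 0.5975, 0.3758}, AChE
×{1, 0.48, 0.20}. Control means are not published directly; the defaults
(MDA 7.95 nmol/mg, GSH 0.42 µg/mg, CAT 31.4 U/mg, AChE 0.00172 nmol/min/mg
protein) are back-solved from the published between-group sums of squares
under those multipliers with n = 3 per group, so the generator's ANOVA
tables land near the published decompositions. `percent_change()` is the
signed effect size `(treatment − control)/control × 100`;
`percent_change_label()` renders the conventional "80% reduction" wording.

## Comet assay: a one-dimensional representation

The package does not segment micrographs (a non-goal); a comet cell is the
one-dimensional object the endpoints are actually functions of: binned
intensity along the electrophoresis axis with a head/tail boundary. The
generator builds each cell with total intensity 100 over a 10-µm head (1-µm
bins, positions recorded at the bin's trailing edge); a tailed cell
(Bernoulli with the group's tailed probability) appends a tail whose length
is gamma-distributed (shape 4 — positive, right-skewed, as comet tails are)
and whose DNA share is beta-distributed (concentration 20). Gamma and beta
are free modelling choices on the correct supports; nothing in the study
constrains the families.

Measurement (`comet_cell_metrics()`): tail intensity is the
above-background intensity beyond the boundary; tail DNA % is tail/total ×
100; tail length is the distance from the measurement origin to the
farthest above-background tail bin; tail moment is the **extent** moment,
tail length × tail-DNA fraction. Commercial comet software does not always
document its variant — the Olive moment (distance between intensity
centroids) is deliberately out of scope, and the tail-length origin
(boundary edge vs head centre) is exposed as an option because conventions
differ. A cell counts as *tailed* when its tail DNA reaches 5 %, also
configurable since no standard cutoff exists. Note the interplay with the
control calibration: control tails carry a beta(mean 0.05) DNA share, so
roughly half of generated control tails fall below the 5 % cutoff and the
*measured* control tailed percentage sits well under the configured 4 %
tail probability — conservative in the right direction for a control group
described as just under 5 % damaged nuclei.

Calibration across groups: tailed probabilities 0.04/0.08/0.20 (the
published ~2× and ~5× control), tail-length means 2/4.5/9 µm and tail-DNA
means 0.05/0.12/0.25, giving group separations of the order of the
published comet ANOVA decompositions. Tail-moment magnitudes are *not*
matched to the published table — its arbitrary units are instrument
specific — only their ordering is meaningful here.

## Histopathology

`condition_index()` computes $I_h = \sum_j w_j a_{jh} / \sum_j M_j$ with
the seven-category weight table (denominator 78). The published class
bands — low 0.00–0.30, moderate 0.31–0.60, high 0.61–1.0 — leave the open
intervals (0.30, 0.31) and (0.60, 0.61) unassigned for continuous values;
the classifier uses the half-open partition [0, 0.30], (0.30, 0.60],
(0.60, 1], which covers [0, 1], assigns boundaries to the lower class, and
preserves the class of every published group value (0.02 low, 0.53
moderate, 0.71 high). "Fused tubules", described qualitatively in the
source results but absent from its weight table, are not scored: the index
is defined only over the weighted categories. One score set per individual
is assumed (whether the original scoring averaged multiple fields of view
per section is unstated).

Lesion-score distributions per group were chosen to put the expected index
near the published group means: with a shared per-category distribution the
expectation is $E[I_h] = E[a]/6$, giving control $P(0,2,4,6) =
(0.94, 0.06, 0, 0)$ (E[I] ≈ 0.02), low dose $(0.12, 0.34, 0.37, 0.17)$
(≈ 0.53) and high dose $(0.03, 0.15, 0.48, 0.34)$ (≈ 0.71).

Morphometry: relative lumen and wall areas are percentages of total tubule
area, averaged over each animal's five tubules. Wall area is accepted as a
*measurement* and cross-checked against total − lumen at 1 % relative
tolerance (a consistency warning, never a silent fix), since all three
areas are measured quantities in the field workflow. The generator draws
the lumen fraction normally (SD 0.04, redrawn while outside (0, 1) with
bounded retries) around group means 0.28/0.42/0.50 — rising with dose, the
atrophy direction, and sized to the published between-group variance of the
relative areas.

## ANOVA, Tukey HSD and the studentized range

`anova_oneway()` is the textbook fixed-effects decomposition; a zero
within-group mean square reports F as explicitly undefined rather than
infinite. `anova_table_from_ss()` audits any printed one-way table from its
own SS and df — useful because printed mean squares occasionally carry
typesetting errors while SS/df remain self-consistent. Assumption checks
(Shapiro–Wilk, Fligner–Killeen) are intentionally delegated to base R's
`shapiro.test()`/`fligner.test()` by the user; the package does not wrap
them.

`studentized_range_sf()` evaluates $P(Q_{k,\nu} > q)$ by nested quadrature:
the normal-range CDF $k \int \phi(z)\,[\Phi(z) - \Phi(z - r)]^{k-1} dz$
integrated against the density of $\chi_\nu/\sqrt{\nu}$, each with
`stats::integrate()` at relative tolerances 1e-10/1e-9. At $k = 2$ it
collapses to the two-sided t probability $P(|T_\nu| > q/\sqrt 2)$, which
the tests verify to better than four decimals; across a (q, k, df) grid it
agrees with `stats::ptukey()` to ~1e-6 absolute (the residual is ptukey's
own approximation error at small df, where the quadrature matches the
exact t-reduction to machine precision).

`tukey_hsd()` uses the Tukey–Kramer standard error
$\sqrt{MS_w/2\,(1/n_i + 1/n_j)}$ so unbalanced groups degrade gracefully;
with equal n it is the classic HSD. Adjusted p-values come from the
studentized-range tail at (k, df within). Welch ANOVA is deliberately not
offered — the target design is balanced and the original analysis used the
classic test. `compact_letters()` implements insert-and-absorb: two groups
share a letter exactly when they are not significantly different, the
representation used in the figures of this literature.

## Pipeline determinism and I/O

Every generator seeds its own RNG stream from the master seed, so each
stream is reproducible in isolation and `report.json` is a pure function of
(config, seed, input files) — the determinism contract is tested by
byte-comparing reports from two runs. Wall-clock timestamps therefore live
in a sidecar `pipeline.log`, while the report's provenance block carries
the seed and an MD5 hash of the canonical-JSON config. Input CSVs are
validated against fixed schemas with row-level diagnostics (e.g. a lesion
score of 3 names its row); unknown columns warn, missing mandatory columns
fail fast, and an empty file with a valid header is an empty record set.

## What the generator does and does not emulate

It reproduces the *design* (group sizes, subsampling depths, daily event
grid) and the *published effect sizes* under simple parametric noise. It
does not emulate inter-aquarium variance components, correlations between
endpoints within an animal (oxidative damage and DNA damage are generated
independently), assay-level artefacts (protein normalisation,
plate effects), or 2-D comet morphology. Green tests on synthetic data
therefore demonstrate that the *computational chain* is correct and
recovers known inputs — not that the biological conclusions would replicate
on new animals.

## Problem sizes and tolerances in the test suite

The suite runs the full design (120 survival records, 1500 comet cells)
where a single replicate suffices, and scales Monte-Carlo checks to their
purpose: 200 seed replicates for biomarker effect-size recovery, 400 for
the geometric-survival closed form, 25 for the control comet calibration,
and 2000 null replicates for the ANOVA type-I error, each asserted within
three Monte-Carlo standard errors of its target. Stochastic assertions use
fixed seeds; analytic identities (SS conservation, tail-moment identity,
KM monotonicity) are asserted at numerical tolerance.
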