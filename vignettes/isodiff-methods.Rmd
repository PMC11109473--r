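---
title: "Differential analysis of isotope tracing data with isodiff: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential analysis of isotope tracing data with isodiff: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isodiff)
```

## The data model

In a stable isotope-resolved metabolomics (SIRM) experiment, cells or
organisms are fed a labeled substrate (typically ¹³C₆-glucose) and the
incorporation of heavy atoms into downstream metabolites is quantified by
mass spectrometry. After upstream correction for natural isotope abundance
(IsoCor, PolyMID — out of scope here), each metabolite with $n$ carbons is
described by its isotopologue intensities $(M_0, \dots, M_n)$, where $M_i$
is the abundance of the variant carrying $i$ heavy carbons.

Three derived quantities drive all downstream analysis:

* **Isotopologue proportions** (the mass distribution vector, MDV):
  $c_i = M_i / \sum_{j=0}^{n} M_j$, so each metabolite–sample cell lies on
  the simplex, $\sum_i c_i = 1$.
* **Total abundance**: $m = \sum_{j=0}^{n} M_j$.
* **Fractional contribution** (mean enrichment):
  $\varphi = \sum_{j=0}^{n} (c_j \cdot j) / n \in [0, 1]$, the
  carbon-weighted mean of the MDV; 0 when all mass is unlabeled ($c_0$),
  1 when fully labeled ($c_n$). An increase in $\varphi$ between
  conditions indicates faster label incorporation.

`harmonize_inputs()` derives whichever of the three a user did not supply
from the corrected isotopologues, aligns everything to the sample sheet,
and validates the MDV algebra. User-supplied tables always take precedence
over derived ones; when both are available they are compared, and cells
differing by more than $10^{-6}$ relative are logged — surfacing upstream
inconsistencies rather than hiding them.

### Numerical and validation choices

* **Normalization tolerance** $\varepsilon$ for proportion sums defaults
  to 0.02: upstream correction tools commonly leave percent-level
  residuals on MDV sums. It is configurable everywhere it is used.
* Proportion input whose per-cell sums fall in $[98, 102]$ is treated as
  percentages and rescaled by $1/100$ (both conventions circulate);
  the rescaling is logged. Slightly off unit sums are *validated but not
  rescaled* — silently renormalizing would mask upstream problems.
* A zero total ($\sum_j M_j = 0$) makes the proportions a 0/0; the cell is
  recorded as missing, never fabricated, and missing values are removed
  pairwise per feature in every test.
* Negative corrected isotopologues (a known artifact of over-correction)
  are flagged by validation, not clipped.
* Carbon counts are inferred from the isotopologue rows
  ($n = \#\text{rows} - 1$); an explicitly supplied count that disagrees
  is an error rather than a warning, because every enrichment value
  depends on it.
* Tables are written with full `%.17g` precision, period decimal
  separator, UTF-8 and Unix newlines, so a write/read round trip is exact
  and output tables can be compared byte for byte.

## Univariate differential testing

Tracer datasets are small (triplicates are the norm) and rarely Gaussian,
so the engine's emphasis is nonparametric: Student's *t* (pooled
variance, the convention of this tool family), Mann–Whitney / Wilcoxon
rank-sum (two names for the same unpaired rank test), Wilcoxon signed
rank (paired), Kruskal–Wallis (the nonparametric one-way ANOVA used for
all multi-group comparisons), and a permutation test. Statistics are
oriented so that positive means the first (test) group lies above the
second (reference). All p-values are two-sided.

**Small-sample exactness.** Rank tests use their exact null distribution
whenever both groups have ≤ 25 observations and no ties occur, and the
normal approximation with continuity and tie correction otherwise;
midranks are used everywhere ties arise.

**The permutation test** permutes group labels. With
$\binom{n_A+n_B}{n_A} \le$ `n_permutations` (default 10 000) every
labeling is enumerated and the p-value is exact; otherwise
`n_permutations` random labelings are drawn and the add-one rule
$p = (1 + \#\{|T^\ast| \ge |T_{obs}|\})/(1 + B)$ guarantees $p > 0$. The
default statistic is the difference of group means; a rank-sum variant
(centered at its null mean, so the two-sided $|T|$ criterion is
symmetric) and an absolute-difference variant are available. The
Monte-Carlo kernel is compiled code driven by R's RNG, so results are
reproducible under a seed.

**A consequence worth knowing at triplicate scale.** Exact two-sided
tests on 3 vs 3 samples have a hard p-value floor: the 20 labelings of a
3+3 permutation (or rank-sum) test cannot produce $p < 2/20 = 0.1$, and
the 8 sign patterns of a 3-pair signed-rank test cannot go below 0.25.
No metabolite can therefore pass $\alpha = 0.05$ after (or before) FDR
adjustment with these tests at $n = 3$ — their realized type-I error at
0.05 is exactly zero, i.e. they are conservative, not broken. Detection
at triplicate scale requires either the *t*-test (exact under normality
at any $n$) or more replicates; the package's tests document this
behaviour rather than papering over it, and the time-course recovery
checks consequently use the *t*-test.

**Effect sizes.** Abundances are strictly positive and heavy-tailed, so
the effect is the log2 ratio of group geometric means. Fractional
contributions and isotopologue proportions are bounded in $[0,1]$, where
ratios are misleading; their effect is the difference of group means.

**Multiple testing.** p-values are adjusted with Benjamini–Hochberg by
default (any `p.adjust` step-up/step-down method can be named through one
registry). One family is one (comparison × quantity type): abundance
results are never co-adjusted with isotopologue results, so adding or
removing one quantity type cannot change another's calls. A feature with
$p_{adj} \le \alpha$ is a differentially abundant/labeled metabolite
(DAM). Isotopologues of one metabolite are treated as independent
features within their family.

**Determinism.** One top-level seed governs a run; per-feature sub-seeds
are derived by hashing the feature label (`derive_seed()`), so feature
order, subsetting, or parallel evaluation can never change a feature's
result.

## Time-course analysis

For a series $t_1 < \dots < t_T$ (hours, numeric spacing), the engine
automatically builds the $T-1$ families $t_{i+1}$ vs $t_i$ (later time
point as the test group) and tests every feature in each, with FDR
applied within (family × quantity type). A feature is *time-responsive*
when it is significant in at least one consecutive comparison. Trajectory
modelling (splines, mixed models) is deliberately out of scope — the
consecutive-pair design answers "when does it change", not "what is the
curve".

## Bivariate MDV comparison

Whole labeling profiles are compared by Spearman rank correlation of the
two groups' **mean** MDVs (condition-level profiles, not pooled
replicates — the profile is the group's labeling pattern, and replicate
pooling would mix replicate noise into the rank structure). Exact
p-values are used for profiles of up to 8 isotopologues without ties, the
t-approximation otherwise; metabolites with fewer than 3 isotopologues
are excluded with a logged reason (rank correlation of 2 points is
degenerate), as are constant profiles (undefined rank variance).
Correlations are collected per comparison and FDR-adjusted together.

## PCA overview

`pca_overview()` runs a standard PCA of samples on total abundances or
fractional contributions. Defaults: unit-variance scaling for abundances
(metabolite scales span orders of magnitude), none for fractional
contributions (already bounded); an optional $\log_{10}(x + \delta)$
transform for abundances uses $\delta$ = half the minimum positive value.
Zero-variance features are dropped and reported. Component signs are
fixed by making each component's largest-magnitude loading positive, so
results are fully deterministic. PCA is global by default; per-timepoint
or per-condition views are obtained by filtering the input table.

## Metabolograms and network projection

A metabologram juxtaposes, for one biological comparison and one pathway,
the differential values of member metabolites (inner ring) and genes
(outer ring, from an externally computed differential-expression table
that this package consumes, never produces). Conventions, chosen where
the rendering itself fixes none: rings ordered metabolites-inner /
genes-outer, members alphabetical within a ring; members missing from the
results appear as neutral segments flagged "not measured"; the color
domain is the symmetric interval $[-M, M]$ with $M$ the largest absolute
effect over both omics in the pathway, and each omics side is
additionally normalized to $[-1, 1]$ on its own per-pathway scale so one
omics' dynamic range cannot swamp the other. The diverging palette is
odd-symmetric: negating every effect mirrors the colors exactly. Whether
metabolite segments show abundance or enrichment effects is a
configuration choice; both are supported.

`project_subnetwork()` annotates a user-supplied reaction graph
(metabolite nodes as ovals, gene nodes as rectangles) and styles an edge
as a **hypothesized slow flux** when its product metabolite shows a
significantly decreased fractional contribution while its total abundance
is non-decreasing — the signature of a pool that keeps its size while
incorporating label more slowly, compatible with either a slower
producing flux or dilution from an unlabeled source. This rule is an
interpretive aid, and is labeled as such in the result metadata; it is
deliberately conservative (abundance-only changes never trigger it).

## The synthetic-data generator

`generate_dataset()` emulates the two study designs the package is
exercised on, with known ground truth:

* `"ldh_ko_48h"`: two conditions (control vs a lactate-dehydrogenase
  double-knockout analog) × 3 replicates at 48 h, ten TCA-cycle and
  amino-acid metabolites including 5-carbon α-ketoglutarate and glutamate
  analogs; injected effects: AKG abundance up and Lactate down / Malate
  up (2σ on the log scale), AKG and glutamate enrichment down.
* `"timecourse_p3"`: one condition × 6 time points (0, 1, 2, 4, 6, 24 h)
  × 3 replicates, no injected effects.

Per sample, a total abundance is drawn log-normally around the condition
mean (default CV 0.2, a typical targeted-LC-MS replicate spread) and an
MDV is drawn from a Dirichlet centered on the condition/timepoint mean
MDV with concentration 150 (replicate proportions stay on the simplex —
the natural noise model for compositional replicates; concentration 150
gives roughly percent-level jitter on major isotopologues). Absolute
isotopologues are their product. Abundance effect magnitudes are in units
of the log-scale SD; enrichment effects are mixing weights pulling the
steady MDV toward fully labeled or unlabeled. Time courses start
unlabeled (all mass at $m+0$, so $\varphi = 0$ at $t = 0$ — structurally,
via zero Dirichlet mass) and relax as $1 - e^{-kt}$ toward a
steady-state MDV with per-metabolite rates around 0.25 h⁻¹, emulating
pre-steady-state labeling kinetics; at late times MDVs become
time-invariant. Generation is byte-deterministic for a fixed seed and
leaves the caller's RNG state untouched.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: instrument drift and batch effects, missing
values from detection limits, correlated noise across metabolites sharing
pathways, natural-abundance correction artifacts (including negative
values), and realistic inter-metabolite covariance of labeling. The
companion `generate_deg_table()` is likewise a truth-assignment device:
non-configured genes are non-significant *by construction*, not a
calibrated null.

## Problem sizes used in the checks

The automated checks run at deliberately desk-scale sizes: type-I error
grids at 10 000 replicates per (test × group size), effect recovery on
the `ldh_ko_48h` preset over 200 regenerations, time-course recovery over
100 regenerations, BH agreement on 1000 random vectors, and exhaustive
permutation enumeration up to 4+4. Where a check involves a discrete
test at triplicate scale, the p-value floor discussed above applies and
is reported as measured: recovery power at $\alpha = 0.05$ with the
exact 3v3 permutation test is structurally zero, and the monotone
time-course recovery therefore demonstrates the contract with the
*t*-test. For null features, "not flagged" is asserted as a rate bound
$\le 1 - (1-\alpha)^{T-1}$ plus sampling slack — with per-family FDR
control and $T-1$ families, a null feature is flagged at most at the
multiple-family error rate, and an absolute "never" is statistically
impossible for any $\alpha > 0$.

## Known limitations

* No flux estimation, no natural-abundance correction, no spectral
  parsing, no metabolite identification — upstream and downstream tools
  own those.
* The exact-test p-value floors above mean that with the nonparametric
  defaults and triplicates, no single feature can reach $\alpha = 0.05$;
  this is a property of exact small-sample inference, not of the
  implementation.
* The consecutive-pair time-course design does not borrow strength
  across time points; slowly drifting features with small per-step
  changes can escape it.
* Pathway definitions and reaction graphs are user-supplied; there is no
  automatic retrieval from KEGG/Reactome, and no pathway enrichment
  statistic.
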