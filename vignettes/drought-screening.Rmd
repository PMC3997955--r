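---
title: "Methods: drought-tolerance screening of cultivar panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drought-tolerance screening of cultivar panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(droughtscreen)
```

`droughtscreen` evaluates the drought tolerance of a cultivar panel from
four kinds of plant-level records: growth traits (taproot length, shoot
length, root and shoot dry matter) per stage and watering condition,
fresh/turgid/dry weight triples, per-cultivar wilting and recovery time
courses, and soil moisture monitoring. This vignette describes the models
and procedures behind each stage, the tunable parameters and their
defaults, what the synthetic generator does and does not emulate, and the
numerical and design choices that were genuinely open.

## Relative water content

For a sample with fresh weight FW, fully turgid weight TW (after overnight
soaking) and oven-dry weight DW, tissue hydration is

$$\mathrm{RWC}\,(\%) = 100 \cdot \frac{FW - DW}{TW - DW}.$$

The ratio is scale-free: multiplying all three weights by a constant
leaves it unchanged, so the unit of the balance does not matter. Two edge
cases need a policy:

* $TW \le DW$ makes the denominator non-positive; no physical sample can
  do this, so `rwc()` treats it as a hard error naming the offending
  plant.
* $FW > TW$ or $FW < DW$ can genuinely arise from wiping and weighing
  variance. The computed value then falls outside $[0, 100]$; it is
  **returned with a warning, not clipped**, because clipping would bias
  cell means upward or downward in exactly the noisy cells where accuracy
  matters.

## The drought-tolerant index

The wilting/recovery experiment observes, on the odd days 1, 3, ..., 15 of
a drought treatment, the percentage $D_n$ of plants not yet withered, and
on the odd days of the subsequent re-irrigation the percentage $R_n$ of
plants that have recovered. The sixteen values, interleaved
$D_1, R_1, D_3, R_3, \ldots, D_{15}, R_{15}$, are laid out as the axes of
a radar chart with equal inner angle $\alpha = 360^\circ/16 = 22.5^\circ$,
and the drought-tolerant index is the area of the polygon they span:

$$\mathrm{DTI} = \tfrac{1}{2}\sin\alpha\,
  (D_1R_1 + R_1D_3 + D_3R_3 + \cdots + D_{15}R_{15} + R_{15}D_1),$$

the final term closing the polygon. The formula is the triangle-fan
decomposition of the polygon area, so it is algebraically identical to the
shoelace formula applied to the vertices at polar coordinates
(axis value, axis index $\times\ \alpha$). `radar_polygon_area()`
implements that shoelace route independently and the test suite holds the
two to $10^{-9}$ relative agreement on random axis vectors — a cheap,
complete check of the implementation.

Properties that follow from the formula, all tested: the area is zero iff
no two circularly adjacent axes are both positive; scaling all axes by $c$
scales the area by $c^2$; with percentage axes the maximum is
$8\sin(22.5^\circ)\cdot 10^4 \approx 3.06\times 10^4$, attained by the
regular 16-gon at radius 100. `compute_dti()` also reports the area
divided by that maximum (`dti_norm`), a dimensionless tolerance score in
$[0,1]$ that is comparable across charts with different day grids; the
raw area remains the primary output.

Two deliberate permissivenesses: the computation does **not** require
$D_n$ to be non-increasing or $R_n$ non-decreasing (real counts can
violate monotonicity through observer error, and the area is well defined
regardless), and the angle is always taken as $360/n_{\mathrm{axes}}$
degrees converted to radians — the only reading under which the radar-area
derivation is consistent.

Published screenings report DTI values of order $10\times 10^4$ to
$70\times 10^4$, above the $3.06\times 10^4$ ceiling for 0–100% axes; the
underlying percentages and their scale are generally not published with
such tables. This package computes the literal formula above, so its
values are internally consistent and bounded, but absolute magnitudes
should not be compared against such reports — rankings, which are scale
invariant, can be.

## ANOVA and Duncan's multiple range test

Cultivar comparisons use a fixed-effects one-way analysis of variance per
trait × stage × condition cell, computed directly from sums of squares
(`anova_oneway()`). The error mean square MSE and its degrees of freedom
feed Duncan's multiple range test (`duncan_mrt()`):

* means are sorted in descending order, ties broken by group label so
  letters are reproducible;
* a range covering $p$ ordered means is tested against the least
  significant range $LSR_p = r_p\sqrt{MSE/\tilde n}$, where
  $r_p = q_{\mathrm{tukey}}\!\big((1-\alpha)^{p-1},\,p,\,df_e\big)$ is the
  studentized-range quantile at Duncan's protection level and $\tilde n$
  is the harmonic mean of the group sizes (equal to $n$ in balanced
  designs; the harmonic-mean convention matches the major statistical
  packages for unbalanced ones);
* the scan runs from the widest span downward with **containment
  protection**: a range inside a range already found non-significant is
  never declared significant. Without this rule the grouping can be
  inconsistent (an inner pair "significant" inside a homogeneous block).

Quantiles come from `stats::qtukey()` rather than printed tables; the
tests verify them against classical Duncan table values at
$\alpha = 0.05$, 20 error df, spans 2–5 (2.950, 3.097, 3.190, 3.255) to
table precision. With $MSE = 0$ every LSR collapses to zero and all
distinct means separate — the natural limit. With two groups the
procedure reduces exactly to Fisher's LSD, since
$r_2 = \sqrt{2}\,t_{1-\alpha/2}$.

The letters (`assign_letters()`) are the compact letter display: each
maximal run of consecutive, mutually non-separated means gets one letter,
absorbed runs are dropped, and two groups share a letter exactly when the
procedure does not separate them. Because the protected range procedure
always produces interval-structured non-separation along the sorted means,
this insert-and-absorb construction is exact, and the suite verifies the
round trip (letters $\leftrightarrow$ separation relation) on random
interval-structured patterns and on 500 simulated panels against an
exhaustive range-scan oracle.

Duncan's procedure is intentionally liberal: its familywise error under
the complete null exceeds the nominal $\alpha$ by design (the protection
level is $(1-\alpha)^{p-1}$, not $1-\alpha$). The per-cell ANOVA itself is
calibrated — the suite checks an empirical type-I error of $0.05 \pm 0.01$
over 5,000 null panels of 5 groups × 10 plants.

Letters are computed **within one treatment** (one condition), one test
per trait × stage × condition cell, mirroring how phenotyping figures
annotate bars within a watering regime.

## Threshold classification

Cultivar trait means (not individual plants) are binned against published
cut-offs: e.g. seedling taproots short $<19$ cm, medium 19–22 cm, long
$>22$ cm; V3 shoot dry matter low $<0.4$ g, medium 0.4–0.5 g, high
$>0.5$ g. Eight threshold pairs (four traits × two stages) ship as
`builtin_thresholds()`; a user table with the same columns can replace
them. The published descriptions use strict inequalities for the outer
bins, which forces the boundary convention: a value exactly on a cut
belongs to the **closed medium interval**. That convention is documented
rather than inferable from data, since no published mean sits exactly on a
cut.

## The synthetic panel generator

No raw plant-level data accompany published screenings of this design, so
the package ships a generator whose draws have the statistical structure
the analysis assumes, with a known ground truth. Each cultivar carries a
latent tolerance $t \in [0,1]$ that drives everything jointly:

* **Traits**: noise-free cell mean $= b\,(1 + s\,t)$ under well-watered
  conditions, further multiplied by $1 - e\,(1-t)$ under drought
  (`drought_effect` $e = 0.4$ by default, so a fully sensitive cultivar
  loses 40% of its growth). Baselines $b$ and spans $s$
  (`trait_baselines()`) are set so panels cover the published
  classification bins — seedling taproots run from 18 cm ($t=0$) to
  30.6 cm ($t=1$), V3 taproots from 36 to 59 cm, and so on. Plant noise
  is multiplicative log-normal with coefficient of variation
  `noise_sd_frac` (default 0.1): traits are positive and their dispersion
  scales with the mean, and log-normal noise avoids the truncation bias
  additive noise would create in small dry-matter values.
* **Water content**: turgid weight first (mean 2.5 g), dry weight a fixed
  fraction (0.22) of it, fresh weight placed so the implied RWC hits
  $74 + 10t$ percent, lowered by $8(1-t)$ under drought — by
  construction $DW < FW \le TW$ on every draw.
* **Time courses** are modelled per plant as latent event days, then
  counted: median wilting day $4 + 10t$ after withholding, recovery
  probability $0.15 + 0.8t$, median recovery day $12 - 9t$, plant spread
  1.5 days at the default noise level. Counting (rather than drawing
  percentages directly) guarantees non-increasing survival curves,
  non-decreasing cumulative recovery, and percentages in multiples of 4
  with the default 25 plants. Whether recovery counts should be
  cumulative is ambiguous in most experimental descriptions; the
  generator emits cumulative curves, and deliberately nothing downstream
  depends on that choice. Plants that never wilt within the 15-day window
  count as recovered from day 1.
* **Soil moisture** fluctuates around 35% when watered and decays
  exponentially (rate 0.15/day) toward a 6% residual after withholding
  begins at day 12, sampled every 5 days — a descriptive drydown curve,
  not a water-balance model.

Default cell sizes are 30 plants for traits, 15 for water content and 25
for time courses, the sizes typical of tube-system screenings. Randomness
is split per cultivar by a stable hash of the cultivar name combined with
the global seed, so adding a cultivar to a panel never changes the other
cultivars' draws, and identical configurations reproduce byte-identical
tables.

What the generator does **not** emulate: correlated traits beyond the
shared latent tolerance (real panels show taproot length and dry matter
only weakly correlated), stage-to-stage within-plant correlation,
block/tray effects, censoring or death during recovery, and measurement
rounding. Tests passing on synthetic panels therefore demonstrate the
*procedures* are correct and the pipeline recovers a known ordering under
realistic noise — not that any particular real panel will separate
cleanly.

## Validation design

The package's own acceptance checks (in `tests/testthat/` and
`scripts/acceptance.R`) are property-based, sized to run in minutes on one
CPU: 1,000-vector DTI/shoelace agreement; the DTI closed forms and scale
law; RWC identities on random triples; Duncan letters against the
exhaustive oracle on 500 panels plus the df = 20 table check; ANOVA
type-I calibration over 5,000 null panels; the published classification
spot checks (30.5 cm → long and 18 cm → short at seedling, 59.3 → long
and 36.2 → short at V3); ranking recovery over 200 simulated 14-cultivar
panels; and byte-level determinism of a full run.

Ranking recovery is measured two ways. With tolerances spread evenly over
$[0.1, 0.9]$, adjacent cultivars differ by only 0.06 in tolerance —
about 0.6 days of median wilting time against a 1.5-day plant spread — so
the check there is the mean Spearman correlation between latent tolerance
and DTI ($\ge 0.8$; observed $\approx 0.98$). Identifying the single most
tolerant *and* most sensitive cultivar simultaneously is a stricter event
that is only a fair ask when the extremes stand apart from the field;
that recovery rate ($\ge 90\%$) is therefore measured on panels with the
same span but the middle twelve cultivars bunched in $[0.35, 0.65]$,
leaving a 0.25 tolerance gap at each end.

## Known limitations

* DTI magnitudes are only comparable between analyses using the same axis
  scale and day grid; see the scale note above.
* Duncan's MRT is kept for fidelity to common phenotyping practice; users
  wanting familywise control should prefer a single-step procedure (not
  provided here — out of scope by design, apart from the LSD reduction
  used in testing).
* The classification thresholds are declarative, not estimated; they are
  specific to the crop, stages and tube system they were published for.
* The evaluation treats cells independently; there is no mixed model for
  repeated measures across stages.
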