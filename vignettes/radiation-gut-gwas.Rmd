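---
title: "Mapping dose-dependent genetic effects on radiation-induced gut permeability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping dose-dependent genetic effects on radiation-induced gut permeability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radgut)
```

## The problem

Ionizing radiation damages the adult *Drosophila* intestine: permeability of
the gut barrier (scored by the Smurf dye assay as the proportion of flies
with dye visible outside the intestine) rises after a 100 Gy exposure, and
survival falls. Sensitivity to this damage varies widely across fully inbred
lines of a reference panel such as the DGRP, which makes it mappable: lines
are genotyped once, phenotyped in paired unirradiated/irradiated conditions,
and each biallelic marker is asked whether carrying the minor allele shifts
the *dose-dependent* part of the phenotype.

`radgut` implements that screen — per-marker interaction regression with a
minor-allele-frequency filter and a permutation-based empirical false
discovery rate — together with the companion analyses such a study uses: a
Musashi-binding-element scan of candidate 3'UTRs, Smurf-proportion
summaries, Kaplan–Meier survival with the log-rank test, and qPCR
$2^{-\Delta\Delta C_t}$ fold changes. A seeded synthetic-data generator with
planted effects makes every stage testable without any external data.

## The model

For each marker, the per-line Smurf response $y_{ld}$ (line $l$, dose
condition $d$) is fitted by ordinary least squares to

$$ y_{ld} = \beta_0 + \beta_1 G_l + \beta_2 D_d + \beta_3 G_l D_d +
\varepsilon_{ld}, $$

where $G_l \in \{0, 1\}$ is the line's homozygous call (inbred lines carry
no heterozygotes) and $D_d$ is the irradiation indicator. The interaction
$\beta_3$ carries the dose-dependent portion of the genetic effect and its
two-sided t-test p-value (residual degrees of freedom $n - 4$) is the
scan's tested quantity by default; `tested_term` can select $\beta_1$ or
$\beta_2$ instead. No kinship or covariate correction is applied — this is
the model as published, and it is a documented limitation (see below).

With binary genotype and binary dose the design is a saturated $2 \times 2$
cell-means model, so the OLS solution is the cell-mean contrast
$\hat\beta_3 = \bar y_{11} - \bar y_{10} - \bar y_{01} + \bar y_{00}$ with
$\mathrm{Var}(\hat\beta_3) = \sigma^2 \sum_{gd} 1/n_{gd}$. `gxe_scan()`
exploits this closed form, vectorised across all markers at once (a
2000-marker, 156-line scan takes ~40 ms); the general QR path used by
`fit_marker_model()` handles raw-Gy dose coding and is the reference
implementation — the test suite asserts exact agreement between the two.

### Filtering, orientation and degeneracy

* **MAF filter.** Markers are retained when the minor-allele frequency
  among non-missing calls is *strictly* above `maf_min` (default 0.25,
  i.e. "> 25%"). Missing calls never enter a denominator; lines with a
  missing call are dropped per marker at fit time, not globally. The filter
  depends on genotypes only, so it is permutation-invariant and applied
  once to the observed panel.
* **Orientation.** Genotype files sometimes disagree with the analysed
  subset about which allele is minor, so the scan verifies the empirical
  frequency of allele 1 and flips markers above 0.5 with a warning. A flip
  negates $\beta_1$ and $\beta_3$ and leaves every p-value unchanged;
  flipped markers are flagged.
* **Degenerate fits.** A marker is flagged degenerate — coefficients
  reported where computable, p undefined, excluded from ranking — when the
  design is rank-deficient, the residual variance is zero, or any
  genotype-by-dose cell holds fewer than `min_lines_per_cell` (default 3)
  observations. A finite p additionally requires at least 5 usable
  observations ($df \ge 1$).

### Response scale

The default response is the raw per-line Smurf proportion with vials pooled
(`sum(n_smurf)/sum(n_total)` per line and condition), matching the linear
model above; `pool_vials = FALSE` keeps vials as replicates. An optional
logit response applies the Haldane–Anscombe correction (0.5 added to both
counts) so vials at 0% or 100% remain finite.

## Permutation-based empirical FDR

Analytic p-values rank markers, but panel-wide significance is judged
empirically: phenotypes are permuted and the full scan re-run $B$ times
under the identical configuration. The **permutation unit is the line as a
whole block** — each line's complete all-dose, all-vial record set is
reassigned to another line id. This breaks genotype–phenotype linkage while
preserving the within-line dose pairing and the dose main effect, which is
what keeps the null honest for the *interaction* test; permuting individual
records would destroy the pairing and misrepresent the null.

For observed p-value $p_i$,

$$ \widehat{\mathrm{FDR}}(p_i) = \frac{\frac{1}{B} \sum_b \#\{p^{(b)} \le
p_i\}}{\max(1, \#\{p_j \le p_i\})}, $$

pooling null p-values across markers within each permutation (one
panel-wide null, matching a single FDR percentage per marker). The reported
q is the running minimum of the raw FDR from least to most significant,
capped at 1, so q is non-decreasing in p and behaves as a step-up quantity.
The `max(1, \cdot)` guard avoids 0/0 at the most extreme threshold.

Two cutoff presets are documented because the source screen states both:
27% (the validation cutoff, the default) and 25% (the candidate-table
legend). Neither is silently preferred; `fdr_cutoff_percent` selects one.
The default $B = 100$ suits interactive work; FDR percentages quoted to 1%
resolution want $B \ge 1000$.

Candidate tables are sorted by ascending p with ties broken by
(chromosome, position) for stable ranking, and can be annotated from a GFF3
feature index; the innermost containing interval wins within the class
priority exon > intron > non-coding > intergenic.

## The synthetic-data generator

`simulate_smurf_study()` emulates the screen's study conditions: 156 inbred
lines, ~100 flies per line phenotyped in paired 0 Gy / 100 Gy conditions.
Marker MAFs are drawn uniformly from `maf_range`; each line's call is an
independent Bernoulli draw (fully inbred, so one 0/1 call per line). The
latent phenotype of line $l$ at dose $d$ mirrors the fitted model:

$$ \eta_{ld} = p_0 + \delta D_d + \textstyle\sum_{c} (b_{G,c} G_{lc} +
b_{G \times D,c} G_{lc} D_d) + a_l, \qquad a_l \sim N(0, \sigma_\ell^2), $$

mapped to a probability and observed as $n_{\mathrm{smurf}} \sim
\mathrm{Binomial}(n_{\mathrm{flies}}, \pi_{ld})$ per record (per vial when a
vial size is set — 25 flies per vial is the assay's usual layout).

Default parameter choices, and why:

| parameter | default | rationale |
|---|---|---|
| `baseline_p` | 0.10 | unirradiated Smurf incidence is low (order 10%) |
| `dose_effect` | 0.15 | irradiation raises incidence severalfold at 100 Gy |
| `line_sd` | 0.05 | loose visual calibration to the published between-line spread; a calibration, not a fit |
| `maf_range` | (0.05, 0.5) | a generic panel spectrum; calibration fixtures narrow it above the 0.25 filter |
| `scale` | proportion | the published model regresses the raw proportion; logit available |

The default generative scale is the raw proportion (identity link), with
values outside $[0,1]$ **clamped** and counted (attribute `"n_clamped"`,
plus a warning); clamping rather than resampling keeps the generator simple
and its distortions visible. The logit scale avoids clamping at the cost of
effects becoming log-odds increments. One RNG stream is used, explicitly
seeded, with per-stage sub-streams derived deterministically so panel,
phenotypes, survival and UTR fixtures are independently reproducible.

What the generator does *not* emulate — and therefore what passing tests do
not establish about real panels: linkage disequilibrium between markers,
inversion and endosymbiont covariates, population structure, batch and
block effects in phenotyping, and any non-binomial overdispersion beyond
the Gaussian line effect. The screen's published model ignores these too,
but on real data they widen nulls and can confound candidates.

## Statistical behaviour, measured

Two properties of the scan are worth stating precisely because the test
suite relies on them.

**Dependence across markers.** Within one scan, every marker is tested
against the *same* phenotype draw, so per-marker p-values are dependent:
conditional on the phenotypes, the interaction t is a two-sample
randomization statistic on the fixed per-line dose differences, and an
unusual line (an outlier dose response) shifts the whole scan's p
distribution. Measured at the null study conditions, the per-replicate
type-I rate at $\alpha = 0.05$ has standard deviation ≈ 0.0085 across
replicates, 1.7× the binomial value. Calibration checks therefore treat the
replicate, not the marker, as the Monte-Carlo unit.

**Mild anti-conservatism.** The pooled-variance t assumes homoskedastic
residuals, but binomial noise is larger in the irradiated condition
($p(1-p)/n$ at 0.25 vs 0.10). With dose-balanced cells the variance
estimate stays unbiased, and the remaining distortion is small but real: an
isolated 20 000-draw Monte Carlo of the cell-means t at typical cell sizes
gives a type-I rate of 0.052 at $\alpha = 0.05$ (0.012 at 0.01), i.e. the
marginal p distribution sits within about 1% of uniform in the CDF. This is
a property of the published model on proportion data, not an
implementation artifact; the logit response reduces it.

## Problem sizes used by the checks

The packaged tests and `scripts/acceptance.R` run entirely on synthetic
data at sizes chosen to give the assertions real power while staying quick
on one CPU: 100 random small datasets for oracle equivalence of the OLS
core (coefficients to $10^{-6}$, p to $10^{-8}$; observed agreement is at
machine precision); 20 replicates of a 156-line × 2000-marker null panel
for scan calibration; the same design with $B = 50$ permutations for FDR
calibration; 200 replicates of a 156-line × 1000-marker panel with five
planted interaction effects for recovery and power; exhaustive permutation
enumeration at 3–4 lines; and rejection-verified UTR fixtures for motif
counts 0–6.

For the planted-effect study, the effect size was chosen by a variance
budget *before* freezing the conditions: with five equal planted effects
the other four act as polygenic background, so the per-marker noncentrality
saturates as effects grow. Five pure interaction effects of 0.14 on the
proportion scale keep every latent probability inside $[0,1]$ (the tests
assert a clamp count of zero) and give per-marker $t \approx 5.8$, i.e.
per-marker power well above 0.9 at the observed panel-minimum p — verified
by simulation before the recovery and shortlist assertions were fixed.

## The MBE scan

Musashi represses translation through Musashi Binding Elements in target
3'UTRs. The scanner's default motif is the literature consensus
`(G/A)U(1-3)AGU`, expressed as the configurable pattern `[GA]U{1,3}AGU` on
the RNA alphabet; DNA input is normalised T→U, `N` never matches, and
sequences are scanned on the sense strand only (3'UTRs are sense-strand by
contract — reverse complements are never taken implicitly). Counting is
greedy and non-overlapping by default, since "repeats" of an element are
distinct sites; an all-overlapping mode reports every start offset and
always counts at least as many. Genes with ≥ 4 sites are shortlisted. The
proprietary position-specific scoring model of the RBPmap web service is
deliberately not cloned; users who have a PWM can supply one, and scanning
is then routed through `Biostrings::matchPWM()`. Reports use 1-based closed
intervals; BED export converts to 0-based half-open.

## Phenotype statistics

The **vial** is the replication unit for Smurf dispersion and t-tests
(error bars in this kind of assay summarise replicate vials, not flies).
The two-sample test defaults to Welch's unequal-variance form — a bare
"t-test" on proportions rarely justifies pooling — with pooled variance as
an option; tests are run on raw proportions by default, with the logit
transform available upstream. Survival uses the product-limit estimator
(`survival::survfit` behind `km_estimate()`): censored flies leave the risk
set without a step, the median is the first time $S(t) \le 0.5$ and is
undefined if never reached; group comparison is the one-degree-of-freedom
log-rank test. qPCR fold changes are $2^{-\Delta\Delta C_t}$ with the
target normalised to a reference gene in each condition, which makes the
fold invariant to any constant shift in cycle thresholds.

## Known limitations

* No relatedness, inversion, symbiont or structure correction in the scan;
  q-values are panel-wide and share one null across markers.
* The proportion-scale generator clamps; heavy planted effects should use
  the logit scale.
* The consensus MBE pattern is a documented stand-in for a trained scoring
  model; site counts, not binding affinities, are the output.
* The t reference distribution is approximate for binomial proportions
  (quantified above).
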