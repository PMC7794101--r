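---
title: "Methods: plate QC, normalization and matched-pair association for newborn DBS metabolomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plate QC, normalization and matched-pair association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbsmetab)
```

## Scope

`dbsmetab` implements the analysis pipeline for a matched case–control
metabolomics study of newborns from dried blood spots (DBS): plate-level
data cleaning and normalization of a targeted kit panel, a
metabolome-wide matched-pair mixed-model scan with era stratification,
diagnosis-code co-occurrence testing, and SNP–metabolite models. Because
registry-linked DBS data cannot be shared, the package also contains a
first-class synthetic-data module that generates cohorts and raw plate
tables with the statistical structure the analysis assumes, together with
a ground-truth sidecar, so that the pipeline's operating characteristics
(effect recovery, type-I error, filter behaviour) are testable.

## The panel

The panel model mirrors a lipid-centric targeted kit quantifying 408
metabolites: 55 acylcarnitines, 21 amino acids, 21 biogenic amines, 196
glycerophospholipids (24 LPC + 172 PC), 40 sphingolipids (31 SM + 9 Cer),
one summed hexose measure, 14 cholesterol esters and 60 glycerides
(18 DG + 42 TG). Lipids are named `CLASS(X:Y)` with `X` acyl carbons and
`Y` double bonds; ether-linked PC/LPC species carry `-O`
(`PC-O(36:4)`), hydroxylated and dicarboxyl acylcarnitines carry `-OH` /
`-DC` inside the parentheses. The parser and formatter are exact
inverses, which the tests enforce over the whole bundled panel.

Two components of the bundled panel are synthetic by necessity and
documented as such: the per-class species lists are systematic
placeholders spanning realistic carbon/double-bond ranges (vendors do not
publish the full list, and any real kit export can be loaded with
`read_panel()`), and the QC2 target values `TV_m` are deterministic
class-typical concentrations, since real target values are vendor
database content. Hexoses are modelled as a single summed entry, the way
the kit reports them.

## Data cleaning and normalization

All cleaning operates on the long-format plate table (plate, well, well
role, metabolite, raw µM). The stages run in a fixed order, and the order
is pinned by a regression test because it is observable: a metabolite
failing both the LOD and CV criteria must be reported as an LOD failure.

1. **Per-plate LOD.** `LOD_{m,p}` is the median of the plate's paper
   blanks (triplicate by design; even counts use the midpoint median).
   Blanks are never normalized.
2. **LOD filter.** The fraction of sample wells with raw value ≤
   `LOD_{m,plate(sample)}` is computed separately in cases and controls.
   The default keeps a metabolite when at least one group has ≤ 20 % of
   measurements at or below LOD (equivalently ≥ 80 % above). A stricter
   both-groups rule is exposed as `lod_rule = "both"`; the two readings
   differ and both are legitimate, so the choice is a config knob rather
   than a hard-wired assumption. The comparison is non-strict (`≤ LOD`
   counts as below) while QC2 wells entering the correction must be
   strictly above LOD.
3. **Plate correction.** `A_{m,p}` is the median of the five QC2
   reference wells strictly above LOD; `C_{m,p} = A_{m,p} / TV_m`. A
   metabolite with no usable QC2 well on some plate cannot be normalized
   there and is dropped entirely (conservative; the verdict records the
   reason). Normalization is `Norm = Raw / C`, applied to every well.
   Algebraically the above-LOD QC2 median of each plate then equals
   `TV_m` exactly, normalization is idempotent (a second pass yields
   `C = 1`), and rescaling an entire plate by any factor is absorbed by
   `C` — all three properties are asserted to near machine precision in
   the tests.
4. **CV filter.** `CV_m` is the n−1 sample SD over the pooled normalized
   QC2 wells of all plates (40 observations at the default layout)
   divided by their mean; metabolites above 25 % are dropped. All QC2
   replicates enter the CV (the pooled count is part of the design), not
   only the above-LOD subset used for the correction medians.

Sample values at or below LOD that survive the metabolite-level filter
are kept as measured; no imputation is performed. Thresholds (0.20, 0.25)
are config-exposed with the study's values as defaults. QC1/QC3 wells are
parsed and simulated but take no part in normalization.

## Transformation and the matched-pair model

Metabolite concentrations from DBS are right-skewed and heavy-tailed, so
each metabolite is mapped to normal scores before modelling: the value at
rank `r` of `n` maps to `Φ⁻¹((r − ½)/n)`, with average ranks for ties
(a Blom offset `(r − 3/8)/(n + ¼)` is available). The transform is
undefined on a constant vector and errors there. Effects are therefore
reported in SD units of the transformed scale.

The association model per metabolite is a linear mixed model fit by REML
with `lme4::lmer()`:

```
z ~ case + sex + factor(year of birth) + parity + gestational age + (1 | pair)
```

The random intercept per matched pair carries the matching; sex and year
of birth are between-pair by construction (pairs are matched on sex and
day of birth). Implementation details that matter:

* Pairs with any missing outcome or covariate are dropped pairwise,
  mirroring how incomplete pairs were excluded in the emulated design.
* Year-of-birth levels supported by fewer than two pairs are merged into
  the nearest calendar year; without this, small cohorts produce singular
  designs. This is an estimability device, not a scientific claim.
* After factor expansion, fixed-effect columns that are constant or
  collinear are pruned (with an error only if case status itself is
  confounded), so an all-male or single-year subset fits cleanly.
* The default p-value is a Wald test of the case coefficient against the
  normal reference; with 267 pairs the normal and Satterthwaite-t
  references agree closely, and `use_t = TRUE` switches to the latter
  (via `lmerTest`) when exact small-sample behaviour matters.
* In the balanced case-only model the estimator reduces exactly to the
  mean within-pair difference (and its SE to the paired-t SE in interior
  fits); the tests assert this identity at 1e−8, which is the package's
  main guard against a silently misspecified random-effects structure.

A metabolome-wide scan shares one fixed-effect design across metabolites,
so after the first full fit every further metabolite is refit on the same
model structure (`lme4::refit`), which is exact and an order of magnitude
faster; the tests verify refit results equal fresh full fits.
Significance uses Bonferroni at `α / n_tested` with the number of
metabolites actually tested — e.g. a threshold of 0.05/148 when 148 of
408 survive QC.

Era-stratified scans split pairs at the screening-policy change year
(default 2009; sampling medians of 6 vs 2 days of age). By default each
stratum is re-transformed to normal scores on its own samples — ranks are
relative, and reusing global scores inside a stratum would leave a
non-normal margin; the global-transform alternative is exposed as
`retransform = FALSE` since the choice is not forced by the design.

Pairwise Pearson correlations of the significant hits use
pairwise-complete observations and the t-test
`t = r√(n−2)/√(1−r²)`; cells with fewer than three complete pairs or
zero variance are reported `NA` rather than guessed.

## Diagnosis codes and genetics

Co-occurrence of a diagnosis code (the motivating example is P92.5,
neonatal difficulty in feeding at breast) with case status is tested by
Fisher's exact test on the 2×2 carriage table. The point estimate is the
conditional maximum-likelihood odds ratio under the noncentral
hypergeometric model and the interval is the exact central 95 % CI from
inverting one-sided conditional tests at 2.5 % per side — the convention
of `stats::fisher.test`, which performs the computation; the test suite
checks the p-value against full enumeration of tables with fixed margins
and checks the CI endpoints by direct evaluation of the noncentral
hypergeometric tails. Other exact-CI conventions exist (e.g. exact
mid-p); the central interval is used because it reproduces the reference
implementation's output.

The code-timing model restricts to code carriers and regresses a
transformed metabolite on an indicator of day-of-birth assignment,
adjusted for sex, year of birth (continuous here), parity, gestational
age and case status, by OLS. SNP models regress a transformed trait on
additive allele dosage (0/1/2) adjusted for case status, sex, year of
birth (as factor, sparse levels merged), parity and gestational age, with
optional era stratification and a Bonferroni-corrected sweep over all
metabolites. Metabolite ratios such as PC(38:4)/PC(38:3) are formed on
the normalized concentration scale before transformation (the ratio then
cancels any common per-sample scaling; forming it after a rank transform
would not); elements with non-positive denominators are flagged missing.

## The synthetic study design

`sim_config()` fixes the generator to the emulated study's design facts:
267 case–control pairs (534 samples) matched on sex and exact day of
birth, laid out on eight 96-well plates with matched pairs always sharing
a plate; per plate three paper blanks, five QC2 replicates and one
QC1/QC3 well each; birth years 1997–2014 with 98/267 of pairs before the
2009 policy change (era drawn first, date uniform within era, matching
the published stratum split and the year-of-birth mean of ~2008);
sampling age 6 ± small integer jitter days before 2009 and 2 afterwards;
87.3 % male pairs; gestational age ~N(39.9, 1.5) weeks; parity ~1.7 ± 0.9;
maternal age ~30 ± 5.

Concentrations are generated multiplicatively:
`log C = log(TV_m) + σ·z` with biological log-SD σ = 0.35, so the raw
values are right-skewed the way real concentrations are — which is what
motivates the rank transform. The latent structure in `z`:

* a **bottle-feeding exposure** drawn per newborn (P = 0.5 cases, 0.2
  controls — bottle-feeding is a known disease risk factor, so the
  imbalance is by design) whose effect on seven designated metabolites
  (five PCs including PC(38:4), AC(2:0), histidine) is
  `feeding_effect_per_day × age_days`, default −0.4 SD/day. Newborn milk
  intake ramps up over the first week, so the exposure's metabolic
  footprint grows with age at sampling; this single mechanism produces
  the design's signature pattern (strong pre-2009 association, weak
  post-2009). The value −0.4 is calibrated so the simulated case–control
  betas (~−0.34 overall, ~−0.58 pre-2009, ~−0.19 post-2009 after
  rank-transform shrinkage) sit near the magnitudes the emulated study
  reports; no real per-day feeding effect is published, so this is a
  synthetic working value, documented as such.
* a **shared latent factor** (loading 0.5) across the seven affected
  metabolites, making them positively correlated as observed.
* a **biallelic variant** (MAF 0.3) adding +0.35 SD per allele to the
  precursor PC(38:3) and nothing to disease status, so the
  product/precursor ratio PC(38:4)/PC(38:3) is strongly genotype-
  associated while the disease is not — the dissociation the genetics
  module is designed to exhibit.
* a **feeding-difficulty code** assigned mostly to bottle-fed newborns
  (P = 0.126 cases / 0.067 controls given bottle-feeding, 0.002
  otherwise; marginals ~6.4 % vs ~1.5 %), with day-of-birth assignment
  more likely for bottle-fed carriers (0.5 vs 0.15), so day-0 codes tag
  the latent exposure.
* **plate batch factors** `C_{m,p} = exp(N(0, 0.15))`, blank signal at
  2 % of `TV_m` (lognormal CV 0.2), QC2 noise at CV 0.05. Metabolites
  can be designed to fail QC: LOD failures have their baseline pushed
  below the blank level, CV failures get QC noise of CV 0.4; the
  ground-truth sidecar records each designed failure with its intended
  reason, and `run_qc()` must recover exactly that verdict set.

All randomness flows from the single config seed; identical configs give
byte-identical study files. Setting every effect to zero makes cases and
controls exchangeable, which is how the type-I-error tests are built.

What the generator does **not** emulate: mass-spectral acquisition
(peak shapes, carryover, calibration curves), real registry covariate
distributions beyond the published moments, linkage disequilibrium or
any genetic architecture beyond one additive variant, and real feeding
behaviour (a binary latent exposure stands in for it). Passing tests
therefore demonstrate that the pipeline's algebra, filters and models
behave correctly under the assumed structure — not that the assumed
structure captures every property of real DBS data.

## Verification problem sizes

The test suite's Monte-Carlo checks use sizes chosen to give tight
binomial/Monte-Carlo bounds while staying desk-scale: effect recovery
(δ = −0.4 on one metabolite, 267 pairs) over 200 replicates with 95 % CI
coverage required in [0.92, 0.97]; family-wise error of the
148-metabolite Bonferroni scan over 200 null replicates, required inside
the central 95 % binomial band around 0.05; the era-gradient pattern
(larger pre-2009 |beta| on affected metabolites) over 100 replicates with
a 90 % success requirement; exact-test enumeration exhaustively over all
2×2 tables with total n ≤ 14 plus 300 random tables with margins ≤ 30.

## Known limitations

* The LOD rule has two published readings ("in cases and controls" vs
  "in cases or controls separately"); the default follows the
  at-least-one-group reading and the other is a flag. Neither is asserted
  to be the original intent.
* Whether the emulated study's p-values used a Wald z, likelihood ratio
  or Satterthwaite t is unknown; the default Wald-z is one defensible
  choice and the t option quantifies the (small) difference.
* The conditional-MLE odds ratio is undefined in degenerate tables; zero
  cells produce one-sided infinite CI bounds, which are flagged rather
  than truncated.
* Bundled target values and species names are synthetic placeholders;
  analyses of real kit exports should load the vendor's panel definition.
* The mixed model assumes one case and one control per pair; other
  matching ratios are out of scope.
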