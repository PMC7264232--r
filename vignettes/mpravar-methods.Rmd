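---
title: "Design and allelic analysis of MPRA experiments with mpravar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design and allelic analysis of MPRA experiments with mpravar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpravar)
```

## The measurement and the model

A massively parallel reporter assay (MPRA) asks, for thousands of short DNA
elements at once, whether an element drives transcription and whether its two
alleles drive it differently. Each 145-nt test sequence — carrying a variant's
risk allele, its protective allele, or a scrambled version of the 21-nt core
around the variant — is synthesised in both orientations and linked to ten
distinct 10-nt barcodes inside a fixed 200-nt oligo skeleton. After cloning
into reporter constructs and transfection, the transcriptional output of every
element is read out as the abundance of its barcodes in RNA relative to the
input DNA.

The unit of analysis is the per-tag, per-transfection normalised activity

$$y_{kt} = \log_2 \frac{\mathrm{TPM}^{RNA}_{kt}}{\mathrm{TPM}^{DNA}_{k}},$$

where TPM is the tag count divided by the sample's total matched count over
one million. Each retained tag-by-transfection value is treated as an
experimental replicate. For one variant, activity is modelled by ordinary
least squares:

$$y = \beta_0 + \beta_a\,\mathrm{allele} + \beta_s\,\mathrm{strand}
      + \sum_t \gamma_t\,\mathrm{transfection}_t + \varepsilon,$$

with allele coded risk = 1, strand reverse = 1, and transfection as a
categorical covariate absorbing cell line, promoter type, library, and
between-transfection variation. Because per-tag measurement error is visibly
heteroskedastic (low-abundance tags are noisier), inference on $\beta_a$ uses
the heteroskedasticity-consistent sandwich covariance

$$\widehat V = (X'X)^{-1} X' \,\mathrm{diag}\!\left(\frac{e_i^2}{(1-h_{ii})^2}\right) X (X'X)^{-1},$$

the HC3 flavour, which simulation literature recommends for moderate sample
sizes; HC0–HC2 are available through `hc_type`. The Wald statistic
$\beta_a/\sqrt{\widehat V_{aa}}$ is referred to the standard normal — at the
typical replication of hundreds of observations per variant a t reference
would be indistinguishable.

Two further regressions per variant replace the allele indicator with an
indicator of each allele against the variant's own scrambled control,
measuring signed departure from a sequence-matched null. A variant is called
**significant** only when, in both the melanoma-line-only scope and the
combined scope, the allelic-difference FDR and the FDR of at least one
allele's null departure fall below $\alpha = 0.01$ (Benjamini–Hochberg,
adjusted per scope: allelic p-values across variants, null-departure p-values
across all variant-by-allele tests). Significant variants are classified as
activators, repressors, or both from the signs of their significant null
departures.

## Design decisions where the procedure was open

Several choices are not forced by the assay definition; the package fixes
them as follows and exposes each as an argument.

* **Variant placement.** The variant's first base sits at position 73 of the
  145-nt window, i.e. centred for a SNV, giving symmetric sequence context.
  For indels the window is sized on the insertion allele and the deletion
  allele's segment is left correspondingly shorter.
* **Scrambled class.** One scrambled control per variant, built from the
  reference-allele sequence, even when the reference equals the risk allele.
* **Barcode constraints in context.** Homopolymer (> 3) and KpnI/XbaI/SfiI
  checks span the junctions between a barcode or scrambled core and the
  fixed skeleton, because the synthesised construct is contiguous and a site
  can straddle a boundary. The skeleton's own intentional KpnI/XbaI cloning
  sites are ignored; only matches touching variable bases count. Test
  segments that carry a cloning site from genomic sequence are flagged, not
  excluded.
* **Tag assignment.** One global barcode pool, one unique barcode per oligo;
  a variant synthesised in two libraries keeps the same barcode-to-sequence
  assignment in both, and `dedupe_repeated_variants()` later drops one
  library's observations for such variants.
* **Count filters.** The "ten counts or fewer" exclusion is applied to both
  the DNA input and each RNA sample (a tag failing either is dropped for
  that transfection) — the conservative reading, which also removes
  zero-count tags before the log transform. The TPM < 6 filter applies to
  the DNA input only, since its purpose is to keep low input abundance from
  dominating the ratio. Both thresholds are arguments of
  `mpra_observations()`.
* **Exact matching.** A read is assigned only when bases 1–10 equal a known
  barcode and bases 11–30 equal the fixed downstream context, with no
  indel- or quality-aware rescue; unassigned reads are reported but excluded
  from TPM denominators.
* **Rank deficiency.** Collinear design columns are pruned greedily in
  column order, so among interchangeable dummies the lexicographically first
  level survives; dropped columns are recorded on the fit. Leverages are
  capped at $1-10^{-10}$ before HC2/HC3 weighting so exactly-fit points
  cannot produce infinite weights.
* **Coordinates.** Variant positions are 1-based; annotation intervals are
  BED-style 0-based half-open; the conversion lives in one place
  (`select_candidate_variants()`).
* **Wilcoxon details.** The allele-specific-expression test is run on log
  ratios against zero by default (`scale = "linear"` is available); the
  exact signed-rank distribution is used up to n = 50 when magnitudes are
  distinct, otherwise a normal approximation with continuity correction and
  Pratt handling of exact zeros.
* **Quartile convention.** Mass-spec outlier fences use type-7 quantiles
  (the most common default); the convention and the IQR multiplier
  (default 1.5) are arguments, and the fences are attached to the output.

## What the generator emulates — and what it does not

`simulate_mpra()` draws data from exactly the structure the analysis
assumes, so estimator calibration is checkable: DNA tag abundances
$p \sim \mathrm{Dirichlet}(\alpha)$ sequenced multinomially; per tag $k$ of
class $c$ in transfection $t$ a latent activity
$r_{kt} = \mu_c + \beta\,\mathrm{risk} + \delta\,\mathrm{reverse} + \gamma_t + \eta_{kt}$
with $\eta_{kt} \sim N(0, \sigma^2_{tag})$ drawn independently per
tag-by-transfection cell; RNA proportions $\propto p_k 2^{r_{kt}}$ sequenced
with Dirichlet-multinomial overdispersion. Reads are emitted as
barcode + fixed 20-nt context + random filler with optional uniform
substitution errors.

Defaults are fixed at study-scale conditions: allelic folds uniform on
1.13–3.49 for the ~5% of variants with true effects, active elements one
log2 unit from the scrambled baseline (activator : neutral : repressor
probabilities 0.5 : 0.3 : 0.2), strand effect 0.2, transfection offsets
$N(0, 0.3)$, per-tag noise sd 0.3, Dirichlet concentration 50, per-tag RNA
overdispersion shape 100, and a sequencing depth of $5 \times 10^4$ reads
per tag scaled by a single `scale` factor. The default transfection layout
is two cell lines × two promoter types × two replicates plus one extra
melanoma-line replicate per library — nine levels per library, eighteen for
a two-library design.

The generator does **not** emulate PCR jackpotting, synthesis errors,
sequence-dependent cloning bias, flow-cell artefacts, or barcode collisions
from sequencing indels. Passing calibration and recovery tests on generated
data therefore demonstrates that the estimator is correct *for the model the
assay intends*, not that any particular real library is free of those
artefacts.

## Problem sizes used by the test suite

The packaged checks run at desk scale: a `scale` of 0.05 (2,500 reads per
tag) for the calibration study of 2,100 variants — 2,000 of them true nulls
— and for the recovery study of 200 variants at each true fold in
{1.2, 1.5, 3.1}; a `scale` of 0.002–0.0065 for FASTQ round trips (tens of
thousands of reads); 400 replicates for the allele-specific-expression
level check. At these sizes each allelic fit sees roughly 10 tags × 2
strands × 2 alleles × 9 transfections ≈ 360 observations, matching the
replication structure of a full-scale experiment.

## Known limitations

* The allelic model is a fixed-effects OLS on log ratios; count-level
  alternatives (negative binomial, mixed effects over tags) are out of
  scope by design.
* Zero-count tags are removed by the count filter rather than imputed, so
  elements silencing transcription to zero lose tags and power
  asymmetrically.
* Exact barcode matching discards all reads with any error in the first 30
  bases; with substitution rate $\epsilon$ the expected assignment rate is
  $(1-\epsilon)^{30}$, a pure sensitivity (not bias) loss.
* LD values, eQTL summary statistics, and mass-spec ratios are consumed as
  given; their upstream estimation is outside the package.
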