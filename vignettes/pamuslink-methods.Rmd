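---
title: "pamuslink: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pamuslink: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pamuslink)
```

This vignette is the package's own account of the statistics it
implements: the quantification model, the tests and their null
distributions, the three correlation analyses, what the synthetic-data
generator does and does not emulate, and the places where the design was
genuinely open and a choice had to be made.

## 1. emPAI/PAMUS quantification

TMT reporter-ion intensities are only semi-quantitative across proteins:
peptides differ in ionisation efficiency, so summed intensity cannot be
compared between proteins. The package therefore separates two questions:

* **How much of a protein is in the multiplexed mixture?** Answered by the
  protein abundance index, `PAI = n_observed / n_observable`, where
  `n_observable` counts the distinct fully tryptic peptides (cleavage
  after K/R except before P) whose monoisotopic mass falls in the
  instrument's effective scan range, and `n_observed` counts distinct
  identified peptide sequences. The exponential modification
  `emPAI = 10^PAI − 1` is approximately proportional to the protein's
  molar amount.
* **How does that amount split across the ten samples?** Answered by
  partitioning emPAI over channels in proportion to the protein's summed
  (impurity-corrected) reporter intensities. Because a peptide's response
  factor multiplies all ten of its channels equally, response factors
  cancel in the channel shares — the share vector, not the absolute
  intensity, carries the per-sample signal. Channel shares are then
  renormalised over proteins to **Mol%**, which sums to 100 in every
  sample by construction (enforced to 1e-9 in the test suite).

Parameter defaults, all configurable:

| parameter | default | rationale |
|---|---|---|
| observable-peptide mass window | 500–5000 Da | typical Orbitrap MS2 acquisition range; emPAI counts peptides "within the scan range" |
| missed cleavages (observable model) | 0 | fully tryptic counting; the upstream search's setting is unknowable from a PSM table |
| protein / peptide FDR | 0.03 / 0.03 | common Scaffold-style identification filter |
| minimum unique peptides | 2 | removes one-hit wonders before quantification |
| PSM-to-protein aggregation | sum | `mean` exposed as an alternative |

Shared peptides (a PSM listing several accessions, `;`-separated) are
assigned to the accession with the most unique peptides, ties broken
lexicographically — a cheap stand-in for parsimony-based protein
inference, chosen because the generator produces unambiguous mappings and
real inference engines (Protein Prophet) are out of scope. Isotope
impurity correction solves `impurity %*% corrected = raw` per PSM;
negative solutions (possible under noise) are clamped to zero with a
warning rather than propagated.

## 2. Permutation tests and the pooled null

The differential test statistic is the absolute difference of group means
of log2 abundances — two-sided by construction, and the simplest statistic
consistent with fold-change-oriented reporting. When the number of
distinct group-label assignments is at most 10,000 the permutation
distribution is enumerated exactly (C(8,4) = 70 for 4 vs 4; C(6,2) = 15
for 2 vs 4); otherwise assignments are sampled with a caller-provided
seed. The add-one estimator `p = (1 + #{perm ≥ obs}) / (1 + #perm)` keeps
p strictly positive so BH adjustment is well defined.

**Why a pooled null is the default for DE calling.** Per-feature
enumeration at 4 vs 4 can never produce a p-value below 3/71 ≈ 0.042
(the observed assignment and its complement always tie the observed
statistic). Consequently no feature could ever survive BH control at
0.05, at any effect size — the per-feature test is structurally sterile
for this design, and the test suite asserts exactly that property.
`protein_de()` and `transcript_de()` therefore compare each feature's
observed statistic against the permutation statistics pooled across *all*
features, refining the resolution to roughly `1/(m × 70)` for `m`
features. This is the classic pooled-null trick of SAM-style analyses; it
assumes features share a common null scale (approximately true for log
abundances with comparable noise), and it is mildly conservative when
strong true effects inflate the pooled tail. Under a global null the
average rejection rate at 0.05 is calibrated by construction — the
observed statistics are themselves draws from the pooled distribution —
which the suite verifies to ±0.02 (and ±0.01 for the transcript path)
over 2000 features. The per-feature mode remains available as
`null = "per_feature"`.

The 2-vs-4 contrast is genuinely under-powered (15 assignments per
feature); the package warns whenever the per-feature resolution floor
exceeds 0.05. `corrected_raw_threshold()` expresses the BH rejection
boundary on the raw-p scale — the number a volcano plot draws — and is
tested for exact agreement with the BH-adjusted calls.

Transcript DE uses median-of-ratios size factors (geometric-mean
reference over genes with all-positive counts), the normalisation family
of negative-binomial DE tools, then the same permutation machinery on
log2(normalised + 1). A gene is DE when `p_adj < 0.05` *and*
`|L2fc| > 1`; the fold-change criterion is interpreted as absolute
(both volcano tails), since a signed reading would discard all
downregulation.

## 3. The three correlation analyses

1. **Fold-change correlation:** OLS on gene-matched (protein L2fc,
   transcript L2fc) pairs; unmatched features are dropped and counted.
2. **Pooled mixed model:** `log(RPKM) ~ log(Mol%)` with
   `~ 1 + log(Mol%) | replicate`, natural logs on both axes, REML via
   `nlme`. Pairs with transcript abundance below 2.0 RPKM are excluded
   (very low counts make log-RPKM unstable), as are zero Mol% values —
   excluded rather than pseudocounted, with counts reported, because a
   pseudocount on a molar percentage has no natural scale. Fewer than two
   replicates is an error advising pooled OLS. The pooled Pearson R² is
   computed on the same filtered pairs (raw pairs, not model-fitted
   values).
3. **Per-gene regressions:** one OLS per gene across matched samples
   (≥ 3 points; constant-axis genes excluded with reason codes), with the
   same orientation as the pooled model — transcript on protein — so the
   two report comparable slopes. R² is orientation-invariant; slope
   *sign*, the quantity the census summarises, is orientation-invariant
   too.

Protein samples are matched to transcript samples by shared experimental
unit (group × replicate culture) at the proteome's sampling day; with ten
TMT channels against twelve cultures, the two unpaired transcript
replicates are excluded from analyses (2) and (3). Log bases: natural log
for abundance models, log2 for all fold changes.

## 4. What the generator emulates — and what it does not

`sim_config()` defaults describe a paired nutrient-deprivation study:
10 proteome channels (4 control / 4 N-deprived / 2 P-deprived, day 3,
mirroring a 10-label limit over 12 cultures) against 12 transcriptome
cultures sampled at days 3 and 5; a strong broad N contrast
(`frac_affected_N = 0.45`, log2 effect scale 1.0) against a weak sparse P
contrast (0.03, 0.5); day-5 effects scaled by 1.6 in the same direction
(monotone escalation of stress); a coupling mixture of 55% positively
coupled, 15% negatively coupled, 30% uncoupled genes (protein response =
κ × mRNA response + noise on the log2 scale — additive coupling chosen as
the simplest structure that reproduces fold-change-correlation geometry);
a cross-gene baseline relation `log2 mRNA = 0.5 + 0.8 × log2 protein + ε`
that the pooled mixed model estimates; a plastid-specific protein shift
of −0.42 log2 units under N deprivation; lognormal reporter noise
(CV 0.1) mixed by a banded isotope-impurity matrix (95% purity, 3%/2%
bleed into neighbouring channels); and negative-binomial counts
(dispersion 0.05, 2 × 10⁶ reads per sample). Peptide detection
probability rises with protein abundance, giving emPAI its abundance
signal; a configured 10% of proteins yield exactly one unique peptide so
the identification filter is exercised. A missingness knob exists but
defaults to complete observation.

Deliberately **not** emulated: spectrum-level structure (m/z peaks,
fragmentation, chimeric spectra), read-level FASTQ data, search-engine
score distributions, protein-inference ambiguity beyond simple shared
peptides, batch effects, and compositional artefacts of deeper real
designs. Passing tests on this generator therefore demonstrate that the
statistical machinery recovers known structure under the stated noise
model — not that any upstream identification pipeline is correct.

Because Mol% is a noisy, emPAI-mediated proxy of true protein abundance,
the pipeline-level pooled slope is attenuated relative to the configured
0.8 (regression dilution from error in the predictor) — visible in the
acceptance output. The dedicated slope-recovery check therefore uses
`simulate_paired_abundance()`, which generates the mixed model's own
geometry directly (random intercepts/slopes per replicate) and shows
≥ 80% CI coverage of the true slope over 20 seeded replicates.

## 5. Numerical choices and degenerate inputs

* Permutation tie tolerance: statistics within `1e-12 × (1 + |obs|)` of
  the observed value count as ≥, so exact ties (constant data) give p = 1.
* Top-table ties break by ascending p then lexicographic id, making
  output order deterministic.
* Logistic enrichment under complete separation: the Wald test collapses,
  so the term is reported with an infinite-LOR flag and a
  likelihood-ratio p-value instead of crashing.
* Set-level t test with zero-variance inputs reports t = 0, p = 1 in both
  directions. "More than five members" is enforced strictly (> 5); the
  logistic and Fisher tests prune at < 5.
* All seeds fix every downstream draw; reruns are byte-identical
  (asserted file-by-file in the suite). Sub-generators use fixed offsets
  of the configured seed.
* `lme` is run with `opt = "optim"` and raised iteration caps; exactly
  collinear input (zero residual variance) is a genuinely singular model
  and the suite perturbs such cases by 1e-6.

## 6. Problem sizes

The default pipeline study is 1000 genes (the acceptance script's size);
the frozen demo configuration uses 200; calibration checks use 2000
features/terms; recovery checks use 1200 genes (slope-sign census, where
the census is restricted to significantly regulated proteins because
uncoupled or unaffected genes have sign-random slope estimates) and
20 × 300 gene-replicates (mixed model). These sizes were chosen so each
statistical property is measured with binomial error small against its
tolerance.

## 7. Known limitations

* The pooled permutation null assumes exchangeable noise scales across
  features; heavily heteroscedastic real data would warrant per-feature
  standardisation first.
* emPAI is a coarse abundance estimate; PAMUS inherits its bias for
  proteins with few observable peptides.
* The 2-vs-4 phosphorus design has little power under any test; results
  for such contrasts should be read as descriptive.
* GO hierarchy propagation, KEGG topology, and protein-inference
  probabilities are out of scope; enrichment treats sets as flat.
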