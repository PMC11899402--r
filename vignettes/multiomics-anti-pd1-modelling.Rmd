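---
title: "Multi-omics modelling of anti-PD1 response: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-omics modelling of anti-PD1 response: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iciomics)
```

# The problem

Only a minority of melanoma patients respond to anti-PD1 checkpoint
blockade, and the single approved selection biomarker — nonsynonymous
tumor mutation burden (nsTMB), with its 10 mutations/Mb operating point —
is a weak predictor on its own. `iciomics` implements an analysis that
derives a broad panel of genomic and transcriptomic biomarkers from
upstream variant-, copy-number-, neoantigen-, HLA-, repertoire- and
expression-level calls, combines them in a cascade of L1-regularised
(LASSO) regression models, and explains the resulting per-patient
predictions with exact linear SHAP values.

Because the real meta-cohort behind this kind of analysis lives under
controlled access, the package ships a synthetic cohort generator with a
known sparse generative truth. Every stage — file ingestion, QC, feature
derivation, model training, evaluation, explanation — runs end-to-end on
generated data, and the tests score the pipeline against that truth.

# Biomarker layer

## Genomic features

The DNA side derives 38 per-sample values. Burden metrics count QC-passed
variants overlapping the meta-cohort target region, divided by the target
size in megabases:

* **nsTMB** counts missense, nonsense (stop gained/lost), start-lost,
  frameshift, in-frame indel and multi-amino-acid changes. Synonymous
  calls and pure splice-site calls are excluded. The literature never
  enumerates this set precisely; the class sets are exported
  (`ns_tmb_classes()`) so the choice is visible and editable.
* **Indel / fsIndel / in-frame / splice / missense / synonymous /
  multi-aa burdens** are the same construction over the obvious class
  subsets. Only splice *site* terms (donor/acceptor) count toward the
  splice burden; `splice_region_variant` maps to `other` — the coarser
  term describes bases outside the canonical dinucleotides and its
  functional impact is too heterogeneous to count as a splice defect.
* **Frameshift proportion** is frameshifts over protein-altering calls,
  0 when the denominator is empty. **dN/dS** is the pseudocount-stabilised
  count ratio (nonsynonymous SNVs + 1)/(synonymous SNVs + 1); only
  single-nucleotide substitutions enter either count.
* **CNV and deletion burden** are the fractions of target bases overlapped
  by QC-passed segments with copy number ≠ 2 (respectively < 2). The
  denominator is the target region, not the genome: burdens should be
  comparable across sub-cohorts with different capture designs, and the
  target region is the only interval set the pipeline can trust across
  all of them.
* **Neoantigen aggregates**: candidate burden per Mb; the strongest
  binding encoded as −log(Kd nM) so that larger = stronger; mean, median,
  maximum and upper-decile (90th percentile, linear interpolation) of the
  differential agretopicity index; and maxima of the precomputed
  recognition potential, HEX alignment score and dissimilarity. DAI is
  the natural log of the wildtype/mutant Kd ratio — the log symmetrises
  the ratio around 0 and makes the mean meaningful. Recognition
  potential, HEX and dissimilarity require epitope databases and aligners
  and are consumed as upstream inputs; only their aggregation is in
  scope. A sample without candidates carries `NA` aggregates, imputed
  with training-set medians at modelling time.
* **HED** (HLA evolutionary divergence): per class I locus, the mean
  Grantham distance between the two allele protein sequences over aligned
  positions, averaged over the A, B and C loci. The shipped Grantham
  matrix is computed from the published composition/polarity/volume
  formula (weights 1.833/0.1018/0.000399, scale 50.723) and rounded to
  integers.
* **HLA-B supertype flags** (B27/B44/B62) come from an editable membership
  table following the standard functional supertype classification;
  homozygosity is tested at 4-digit resolution.
* **Alteration flags** follow a shipped per-gene rules file:
  loss-of-function (frameshift/nonsense/start-lost/splice variant, or an
  overlapping deletion) for B2M, TP53, STK11 and PTEN; any nonsynonymous
  SNV for KRAS, CTNNB1, JAK1 and JAK2; amplification (copy number ≥ 4
  over the gene body) for MDM2, MDM4 and EGFR. The merged
  **response-pathway** flag fires on a qualifying JAK1/JAK2 or CTNNB1
  alteration or on a deletion overlapping chr6p21.3 (the HLA class
  I-containing locus, shipped as a GRCh38 BED interval).

A note on arithmetic: the biomarker panel is conventionally counted as 40
genomic features, with the three response mechanisms (JAK1/JAK2,
chr6p21.3 deletions, CTNNB1) tallied separately before they are merged
into the single response-pathway flag. The realised feature vector
therefore has 38 entries; `dna_feature_names()` is the authoritative
list.

## Transcriptomic features

Nine per-sample values, computed on batch-corrected expression:

* **TCR α, TCR β and IGH entropy** — Shannon entropy of clonotype
  read-count frequencies, in nats. The log base is a free choice (it
  rescales a feature that is z-transformed downstream); natural logs are
  used and documented. Zero or one clonotype gives 0.
* **Lymphocyte infiltration** — mean log2(TPM+1) over an editable
  lymphocyte marker list. The source analysis names the feature without
  printing a formula; a mean-log signature score is the minimal faithful
  reading.
* **IFNG-IMS ratio** — interferon-γ signature score over
  immunosuppression signature score, each guarded by ε = 1e-6.
* **In-frame fusion neoepitope count** — fusions called in frame;
  unknown-frame calls never count.
* **GEP of HLA class I, PD-L1 (CD274) and B2M** — log2(TPM+1) signature
  scores.

The signature gene lists ship as plain-text fixtures. They are
*placeholder* marker lists assembled from standard immunology usage, not
a reproduction of any publication's appendix; analyses of real data
should replace them with the intended published lists.

# Quality control and target regions

Sample-level WES QC requires mean tumor coverage ≥ 60×, normal coverage
≥ 20×, and a tumor–normal SNP genotype correlation ≥ 0.8 (guarding
against sample swaps). Variant-level QC keeps calls with tumor and
normal depth > 20, tumor VAF ≥ 5%, normal VAF < 0.17 × tumor VAF, and
≥ 3 supporting reads; each removal records the first rule it failed.
CNV segments need a caller log-likelihood ≥ 100. Strict versus
non-strict inequalities follow the stated thresholds exactly, and the
boundary cases are pinned by tests. When one patient has several
sequenced samples, the lexicographically greatest accession wins.

Per sub-cohort, a base enters the target region when it is covered
(≥ 20× upstream) in at least half the samples — implemented as
count ≥ ⌈n/2⌉, the only reading of "at least half" that is consistent
for odd n and inclusive at exact halves — intersected with exon
coordinates padded by ±2 bases. The meta-cohort target is the
intersection of the sub-cohort targets, so per-Mb burdens are computed
on bases every sub-cohort can see; this is the main guard against
coverage-driven batch effects on the DNA side.

Expression batch effects are removed with the parametric empirical-Bayes
location/scale model (ComBat, via `sva`), applied on log2(TPM+1) and
back-transformed with clamping at 0. The log scale is a documented
choice — the empirical-Bayes model assumes approximate normality, which
raw TPM violates badly. When the location/scale fit degenerates
(identical per-gene dispersions can make the scale-prior iteration
undefined), the adjustment falls back to location-only with a message.

# The model cascade

Sample availability is heterogeneous: some patients have only WES, some
only RNA-seq. To exploit all of it, three models are trained:

1. a **DNA model** on every WES training sample (38 features),
2. an **RNA model** on every RNA training sample (9 features),
3. a **multi-omics model** on the paired training subset, restricted to
   the features that survived gating in either single-omics model.

All models are LASSO fits of the 0/1 response by penalised least squares
— the continuous-response formulation, not logistic regression,
following the `LassoCV` convention common in this literature. Features
are z-transformed with training-set moments (population standard
deviation, the `StandardScaler` convention); the penalty is selected by
5-fold cross-validation over a geometric grid of 100 points spanning
[1e-4, 1] × the smallest penalty that zeroes every coefficient, with a
seeded fold assignment. Fitted values serve as response scores; they are
clipped to [0,1] only for display and never before AUC, since clipping
cannot improve a rank statistic and would discard information at the
mass points.

Feature gating uses **permutation importance**: the mean drop in
training ROC AUC over 30 seeded permutations of one feature's column.
Features with a zero coefficient are reported as exactly 0 — a permuted
column that never enters the linear predictor cannot change the score.
The gate keeps features with a non-zero coefficient and mean importance
strictly above 0.0055, in descending importance order with ties broken
by name. The metric (AUC) and repeat count are this package's own
defaults; the cited methodology names neither.

Classification thresholds maximise Youden's J = sensitivity +
specificity − 1 over the midpoints between adjacent sorted unique
training scores, ties broken toward the smaller threshold. Evaluation
reports the rank-statistic ROC AUC (midrank ties — identical to
trapezoidal integration), the confusion matrix at the stored threshold,
and the nsTMB baseline: raw burden as a continuous score, plus the
10 mutations/Mb operating point. For RNA-trained models the baseline is
computed on the subset of samples that also have WES.

The train/test split is stratified by response × (nsTMB ≥ 10), with
test candidates restricted to paired samples so a single test set serves
all three models; the default held-out fraction is 0.2. The test-set
size of any particular cohort is a property of that cohort, not of the
method.

# Explanation layer

For a linear model the Shapley decomposition under feature independence
has the closed form φ_ij = β_j (z_ij − mean(z_bg,j)) on the standardized
scale, with base value β₀ + Σ_j β_j mean(z_bg,j). This is exact — local
accuracy (base value + Σ φ = prediction) holds to machine precision and
is asserted at 1e-12 in the tests — and there is no reason to pay for a
sampling approximation. The background is the training matrix by
default, stated explicitly because the choice shifts every attribution
by a constant; the evaluation set is a configurable alternative.

Group analysis labels each explained sample TP/TN/FP/FN at the model's
threshold and compares per-feature mean SHAP values between TP and TN
with a two-sided Mann–Whitney U test — exact enumeration when both
groups have ≤ 8 samples without ties, midrank normal approximation with
continuity correction otherwise — Bonferroni-corrected over the tested
features. `force_decomposition()` produces the per-sample ordered
contribution table behind a force plot.

# The synthetic cohort generator

`generate_cohort()` emulates the structure the analysis assumes, not any
particular patient population:

* **Cohort structure.** 511 patients by default, split 203/62/246 into
  WES-only, RNA-only and paired, i.e. 449 WES and 308 RNA samples;
  eight batch-labelled sub-cohorts; responder fraction 192/449.
* **Immune axes.** Three correlated standard-normal latents: T-cell
  infiltration, a B-cell axis (correlation 0.4 with the T axis) and an
  interferon axis (0.5). TRA/TRB clonotype richness grows exponentially
  in the T axis (TRB through a partially independent replicate,
  correlation 0.7), IGH in the B axis; interferon-signature expression
  loads on the interferon axis. Tumor purity is moderately
  anti-correlated with the T axis (more immune infiltrate, less tumor
  cell fraction), which reproduces the purity–entropy correlation the
  analysis layer has to live with.
* **Mutational processes.** Per-sample nsTMB is log-normal
  (meanlog log 4, sdlog 1, truncated to [0.2, 60]/Mb — spanning roughly
  0.5–50/Mb). Consequence-class counts are Poisson draws around
  class-share rates with per-sample multiplicative jitter (sd 0.5 on the
  log scale): mutational-signature composition varies across tumors, so
  no class is a fixed multiple of the total load. Frameshift and
  in-frame indel counts run on their own log-normal rates. This partial
  decoupling matters: with a single shared load factor, nsTMB, missense
  burden and synonymous burden are exchangeable to the model and no
  selection procedure could be expected to recover the designated one.
* **Driver events.** BRAF V600E (28%), loss-of-function and
  nonsynonymous driver variants, amplifications and chr6p21.3 deletions
  are injected at their (approximate, GRCh38) gene coordinates with
  realistic prevalences, so the alteration flags vary.
* **Ancillary data.** Neoantigen candidate counts are Poisson around
  0.2 × the nonsynonymous count with lognormal jitter (sd 0.7) — the
  burden is a noisy proxy of nsTMB, as binding prediction makes it in
  practice. HLA genotypes are drawn from a small allele pool whose
  protein sequences are frozen synthetic stand-ins (labelled as such);
  expression adds per-sub-cohort per-gene batch shifts (sd 0.8 on log2)
  on top of the clean signal; a few percent of variants and samples are
  generated to fail QC so the filters have work to do.
* **Labels.** The realised values of eight designated signal biomarkers
  (nsTMB, fsIndel burden, response pathway, B2M alteration, HED, TCR α
  entropy, IFNG-IMS ratio, IGH entropy) are z-scored across the cohort
  and combined with sparse coefficients (0.8–0.9 in magnitude, negative
  for B2M); the intercept is calibrated so the mean sigmoid equals the
  configured responder fraction; labels are Bernoulli draws with 5%
  label noise. The generator's family (sigmoid-Bernoulli) deliberately
  differs from the fitted model's (L1 least squares): a generator should
  not be the model's own likelihood, and AUC-based checks are
  family-agnostic. Effect sizes are deliberately flat — with eight
  signals sharing the linear predictor, each feature's marginal
  correlation with the outcome scales as β_j over the predictor's
  standard deviation, and strongly unequal weights would make the weak
  ones undetectable at realistic cohort sizes.

The generator computes label-relevant biomarkers from the *clean*
expression signal (before batch shifts), so batch structure is a
nuisance, never a signal.

What the generator does **not** emulate: mutational signatures and
realistic positional clustering, linkage between HLA alleles, isoform
structure, read-level noise, FFPE artefacts, or the covariate shift
between real sub-cohorts. Passing tests therefore demonstrate that the
pipeline recovers a known sparse truth under its stated statistical
assumptions — not that any particular real-data AUC is reproducible.
The published performance numbers of this kind of analysis are computed
on controlled-access data and are out of reach by design.

A fully deterministic four-sample worked example
(`generate_worked_example()`) accompanies the generator; every one of
its biomarker values is verifiable by hand arithmetic, and the expected
matrices ship as fixtures the test suite compares bit-for-bit.

# Numerical choices and degenerate inputs

* Variants use 1-based coordinates (VCF convention), intervals 0-based
  half-open (BED); `GRanges` is the in-memory container. The
  majority-coverage vote and the per-sample interval arithmetic run as
  plain boundary sweeps validated against the `GenomicRanges`
  coverage/slice route.
* Zero-variance features standardize to 0 with scale 1 (logged);
  missing values impute to training medians; an empty candidate list
  yields `NA` aggregates, never 0, so absence is distinguishable from
  weak binding.
* Entropy of ≤ 1 clonotype is 0; dN/dS of an indel-only sample is 1
  (pseudocounts); a sample matching the SHAP background mean has all-zero
  attributions.
* Degenerate score vectors (single unique value) return that value as
  the Youden threshold with J = 0. The AUC of a constant score is 0.5 by
  the midrank convention — which is also the honest held-out value
  reported when the importance gate rejects every feature on a null
  cohort and the cascade degenerates to the intercept-only model.
* glmnet requires two columns; single-feature fits are padded with a
  dead column that is stripped from the result.

# Problem sizes used by the checks

The multi-seed simulation checks run 20 cohorts of n = 400 at default
effect sizes for selection recovery, five default-size cohorts (n = 511)
for the cascade-versus-nsTMB comparison, and 20 null cohorts (all
effects zero). The null cohorts are generated fully paired and evaluated
with a 0.5 held-out fraction: calibration of a chance-level AUC needs a
large evaluation set (the null AUC's standard deviation shrinks as
1/√n_test), and pairing every sample is the cheapest way to get one
without changing any modelling code. These sizes were chosen for
Monte-Carlo stability of the checked quantities.

# Known limitations

* The signature gene lists and the HLA supertype table are editable
  stand-ins; real-data use must substitute the published lists.
* Gene coordinates for the alteration rules are approximate gene bodies,
  adequate for overlap tests against megabase-scale CNV segments.
* The cascade assumes the paired training subset is representative of
  the full training set; nothing reweights for availability bias.
* Exact linear SHAP assumes feature independence (as does any linear
  attribution); correlated features share credit linearly, so
  attributions to near-collinear biomarkers (e.g. purity and TCR α
  entropy) must be read jointly.
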