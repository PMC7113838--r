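---
title: "Methods: rare-variant burden discovery and vasodilator response in IPAH"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rare-variant burden discovery and vasodilator response in IPAH}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pahburden)
```

# The analysis problem

Idiopathic pulmonary arterial hypertension (IPAH) is a rare disease
(diagnosed hemodynamically: mPAP ≥ 25 mm Hg, PAWP ≤ 15 mm Hg, PVR > 3 Wood
units at rest) with a strong but incompletely explained genetic component.
A common study design for finding new susceptibility genes is two-staged:
whole-genome sequence a small discovery arm of cases free of known-gene
variants, filter to rare deleterious heterozygous variants, prioritize
genes whose qualifying variants recur across unrelated cases and that are
expressed in the target tissue, then genotype the prioritized gene in a
larger replication arm and a control cohort and test the carrier burden.
`pahburden` implements that pipeline end to end, together with the
relatedness QC, the contingency statistics, the genotype-stratified
acute-vasodilator (iloprost) response comparison, and the splice-consequence
arithmetic needed to interpret donor-site variants.

Because subject-level data of this kind cannot be redistributed, the
package is organised around a synthetic cohort generator whose defaults
encode the study conditions of the motivating design, so every downstream
claim is testable by simulation with planted ground truth.

# The synthetic cohort generator

`simulation_config()` / `generate_cohort()` produce, from a single seed:

* **Arms.** 42 discovery cases, 188 replication cases, 968 controls
  (defaults). Ages are drawn per arm (discovery mean 23 SD 10; replication
  mean 37 SD 18, truncated to 2–75), giving a pediatric (< 18 y) fraction
  near one sixth of cases; case sex is ~71% female.
* **Causal gene.** Each case carries a heterozygous causal-gene variant
  with probability 0.061, each control with probability 0.008 (binomial
  planting; the realised carrier roster is stored as `truth`). Carriers are
  heterozygous at exactly one of three causal sites — one splice-donor site
  (restricted to cases, as splicing variants are typically case-private)
  and two recurrent missense sites. Homozygous rare genotypes are never
  planted: the design under study is strictly dominant and its carrier
  arithmetic counts heterozygotes.
* **Background rare variation.** Qualifying background hits are Poisson
  per discovery genome (rate 47.3) and scattered uniformly over a pool of
  7,600 genes. These two numbers were calibrated once, analytically, to the
  qualitative funnel the design assumes: with per-gene intensity
  λ ≈ 0.26, roughly 1,990 hits land in ~1,740 distinct genes of which
  ~87% are hit in a single case and ~15–20 reach three or more carriers.
  Background hits are planted in the *discovery* genomes only: replication
  and control arms are modelled as genotyped at the candidate gene alone,
  exactly as a Sanger-validation stage is. A second Poisson stream (rate
  40 per discovery genome) plants true negatives for the filter — variants
  that are too common in one panel, present in the Chinese reference
  subset, or not consensus-deleterious.
* **Expression labels.** The causal gene is always lung-expressed; each
  background gene is lung-expressed with probability 0.2, so the expression
  filter is discriminative but regularly lets background genes through
  (as in real data, where several shared genes are lung-expressed).
* **Kinship SNPs.** 10,000 common biallelic SNPs with MAF uniform on
  (0.05, 0.5), genotypes in Hardy–Weinberg equilibrium. Optional related
  pairs are constructed across the case/control boundary by explicit
  gamete sharing — duplicate (copy), parent–offspring (one transmitted
  gamete plus one population allele), second degree (two meioses) — giving
  expected KING kinship 0.5 / 0.25 / 0.125 without any allele-frequency
  assumptions.
* **Hemodynamics.** Baselines are normal draws per variable (defaults
  pooled across the two case arms: mPAP 61 (17) mm Hg, PAWP 8.4 (4.2),
  PVR 15.3 (8.5) WU, cardiac index 2.6 (1.1) L/min/m², RAP 7.6 (5.9),
  SvO2 63 (13)%), truncated to precapillary-PH-admissible ranges so every
  baseline satisfies the diagnostic rule. Post-iloprost values follow
  percent changes of the form *group mean + genotype effect +
  baseline-linked term + Gaussian noise*, on the percent-change scale —
  the same scale on which the analysis model operates. The true genotype
  effects default to −21.7 points (PVR) and +18.3 points (cardiac index);
  the residual SD defaults to 15 points, chosen so that a 12-vs-36
  comparison yields confidence intervals of roughly ±10 points, the
  precision a study of that size reports. Baseline slopes (−0.4 %/WU,
  −6 % per L/min/m²) are fixed generator internals that make the baseline
  adjustment non-trivial.

What the generator deliberately does **not** emulate: linkage
disequilibrium, population structure and admixture, sequencing error,
genotype missingness patterns, or any correlation between background
variation and phenotype. Tests passing on these cohorts therefore
demonstrate the correctness and calibration of the *statistical machinery*
under its stated assumptions, not robustness to the artefacts of real
sequencing data.

# Discovery filter

`filter_criteria()` fixes the rule set: every panel frequency strictly
below 0.5% (strict `<`, reading "less than 0.5%" literally), absence from
the Chinese reference subset, heterozygous genotype, and a deleteriousness
consensus over named predictor columns. Two points were genuinely open and
are resolved as package defaults:

* **Consensus rule.** Whether "predicted deleterious" requires unanimity
  or any-tool agreement is not specified in this class of design; the
  default is `all` (the strictest reading, minimising false candidates),
  with `majority` and `any` selectable.
* **Missing panel frequencies** are treated as 0 with a warning: absence
  from a reference panel is itself evidence of rarity, which matches the
  filter's intent; treating missing as disqualifying would silently bias
  against poorly covered sites.
* **Splice-class variants** pass the deleteriousness step by consequence
  class alone, since canonical ±1 donor variants carry no meaningful
  missense predictions yet are unambiguously damaging.

Gene aggregation counts *subjects*, not variant pairs: a subject with two
qualifying variants in one gene is one carrier. Prioritization keeps genes
with ≥ 3 carriers, orders by carrier count with alphabetical tie-break,
and flags lung expression.

A note on recovery probability: at a combined-cohort carrier frequency of
6.1%, the expected number of carriers among 42 discovery genomes is 2.6,
so the probability that the causal gene reaches the ≥ 3-carrier threshold
*within the discovery arm* is only ≈ 0.48 — the winner's-curse reality of
small discovery arms. The package's recovery property is therefore stated,
and tested, over the full case cohort (expected 14 carriers, recovery
probability ≈ 1), while `run_study()` honestly restricts its discovery
stage to the discovery arm and will sometimes surface a lung-expressed
background gene instead.

# Kinship QC

The between-family ("robust") KING estimator is used rather than the
homogeneous-population variant: it needs no allele-frequency estimates,
tolerates misspecification, and is the standard tool for case-control
relatedness screens; its 2nd-degree cutoff 0.0884 = 2^(−7/2) is the
conventional "unrelated" threshold. Sites missing in either member of a
pair are dropped pairwise (the cited tool's contract), never imputed. The
cohort summary reports the fraction of between-group pairs below the
threshold, the maximum kinship and the offending pairs; `run_study()`
aborts on any offending pair unless overridden, preserving partial
outputs. Dense cohorts are handled by an exact matrix-product formulation
of the same estimator (verified against the pairwise path in tests).

# Association statistics

All statistics operate on explicit 2×2 tables so that printed
contingency data can be re-analysed directly.

* The Wald z quantile is fixed at 1.959964 for determinism.
* **Zero-cell policy**: `NE` (not estimable), matching how such rows are
  reported; the Haldane–Anscombe +0.5 correction is available behind a
  flag for simulation work but never applied silently.
* **Yates truncation**: the continuity correction is `max(|O−E|−0.5, 0)`,
  truncated at zero. The truncation matters: a pediatric-vs-adult carrier
  table of (2/37 vs 12/193) has every |O−E| below 0.5, so the statistic is
  exactly 0 and p exactly 1 (reported "> .99") — an untruncated correction
  would manufacture a spurious positive statistic.
* **Logistic p-values** are Wald; on a saturated 2×2 the exponentiated
  slope equals the cross-product ratio to numerical precision (a tested
  invariant), and Wald reproduces the printed p-values of the motivating
  tables (e.g. 5 × 10⁻⁶ for 14/230 vs 8/968).
* **Fisher exact** is the package's own hypergeometric enumeration (sum of
  tables with probability ≤ observed, with the conventional 1 + 1e-7 tie
  guard); `stats::fisher.test` serves as an independent oracle in the test
  suite, keeping the dual computation routes separate.
* Reported rounding is 1 decimal for ORs, CIs and percentages; internal
  values keep full precision.

Gene-based score/burden tests (SKAT and relatives) are deliberately out of
scope: at these carrier counts the carrier-table statistics are the
appropriate tool.

# Vasodilator response model

"Difference in the least-square means" is implemented as the genotype
coefficient of the ANCOVA `percent change ~ genotype + baseline` — for a
two-group additive model this *is* the difference of model-adjusted means
at the common mean baseline, and it is the only reading consistent with a
model that has genotype and baseline as its predictors. The percent-change
scale (not the baseline-adjusted raw scale) is adopted as the outcome
scale throughout, matching the generator's truth. Confidence intervals use
t critical values at the residual degrees of freedom rather than normal
quantiles — at n = 48 the difference is within printed rounding, but the
t interval is the correct small-sample choice and is what the coverage
simulations validate (93–97% empirical coverage at nominal 95%).

The matching algorithm for the non-carrier comparison group is not
something this class of study reports; the package fixes a deterministic
choice — greedy nearest-age within sex, carriers in subject-id order, ties
to the smallest subject id, without replacement — and tests it against
exhaustive-optimal assignments on small instances (greedy mean age
discrepancy within 2 years of optimal).

# Splice-consequence arithmetic

The consequence module is pure integer arithmetic on a transcript model:
exon skipping deletes the exon's CDS contribution (frame decision by
mod 3; codon-aligned frame-preserving skips map to a residue interval by
arithmetic, non-aligned ones by protein diffing), and cryptic-donor
activation retains a prefix of the intron and scans the resulting frame
for the first stop codon. A premature termination codon is declared when
translation stops earlier than it would in the correspondingly lengthened
normal transcript — a rule that handles frame-preserving retained introns
without stops, frameshifts, and the zero-offset identity case uniformly.

The packaged fixture (`ptgis_transcript_model()`) is a *synthetic*
construction, not the reference PTGIS sequence: five exons contributing
180/120/78/144/981 CDS nucleotides (500 residues plus stop), threonine at
residue 127 and arginine at residue 174 bracketing the codon-aligned
144-nt exon 4, and an intron 4 beginning `GTA TAA …` so that any retained
prefix of length ≥ 6 introduces a stop immediately after the exon-4
product (PTC at codon 176). In the genomic transcript the exon 4 donor
sits one base inside codon 174 (the c.521+1 position); the fixture's
codon-aligned boundary is the clean abstraction under which the printed
residue interval 127–174 follows exactly, and the skip/donor operations
remain general for non-aligned models. One qualitative point is
under-determined by the motivating description — whether the cryptic
donor's stop arises immediately at the junction or further into the
retained intron; the fixture places it immediately after the junction and
the scan itself is generic.

# Numerical and testing choices

Problem sizes in the test suite are the package's own choices, selected so
properties are tested at full statistical strength where it matters and at
reduced bulk where it does not: carrier-frequency calibration uses 200
replicates at the default arm sizes (background and kinship sites removed
— they do not enter carrier planting); planted-gene recovery uses 100
seeds at the default frequencies, arm sizes and background rates with the
kinship SNP count reduced to 20 (kinship sites never enter discovery);
kinship degree recovery uses 30–40 replicate pairs at 10,000 SNPs; the
ANCOVA bias/coverage study uses 500 replicates of the 12-vs-36 design via
the exported hemodynamics simulator; Fisher type-I control uses 2,000 null
cohorts at equal 0.8% carrier frequency (empirical size ≤ 6% at nominal
5%, reflecting the test's conservatism). Brute-force oracles (double-loop
candidate discovery, exhaustive matched-assignment enumeration, naive
codon scanning, residualization regression) are kept in the test helpers,
structurally independent of the implementation paths they validate.

Degenerate inputs are rejected with classed errors (`config`, `data`,
`qc`), zero-carrier cohorts flow through to `NE` association rows rather
than crashing, and every random quantity in the package derives from the
configuration seed — two runs with the same configuration are
byte-identical, including written reports.

# Known limitations

* The generator's background variation is unlinked and uniform over genes;
  real mutation-rate heterogeneity would concentrate recurrent hits in
  long genes and raise the background false-positive rate of the
  shared-carrier filter.
* Kinship is simulated at independent SNPs; LD would reduce the effective
  marker count and widen the kinship sampling spread at a given SNP count.
* The vasoresponse generator draws baseline and response noise
  independently per variable; real hemodynamic variables co-vary.
* The two-stage pipeline validates a single gene chosen by carrier count
  and expression; it does not model the biological-pathway reasoning that
  a real study would add to choose among equally ranked genes.
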