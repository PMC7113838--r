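# pahburden

Two-stage rare-variant discovery and burden-association analysis for
idiopathic pulmonary arterial hypertension (IPAH), with genotype-stratified
acute-vasodilator response modelling. The package is aimed at statistical
geneticists and clinical researchers who want a tested, reproducible
implementation of the carrier-based (dominant-model) analysis used in
candidate-gene IPAH studies — and a seeded synthetic cohort generator so
that every stage can be exercised and validated without subject-level data.

## What it computes

**Discovery filter and gene prioritization.** Under a dominant model, a
variant qualifies as a candidate when it is heterozygous, has minor allele
frequency < 0.5% in every reference panel, is absent from the Chinese 1000
Genomes subset, and is predicted deleterious (consensus over predictor
flags; canonical splice variants qualify by consequence). Qualifying
(subject, site) pairs are aggregated per gene, counting each subject once;
genes carried by ≥ 3 individuals and abundantly expressed in lung are taken
forward. A 17-gene screen (BMPR2, EIF2AK4, TBX4, …, KCNA5) excludes
subjects with known PAH-gene variants.

**Kinship QC.** Pairwise relatedness via the KING-robust estimator

$$\hat\varphi = \frac{N_{het,het} - 2N_{opp.hom}}{N_{het}(i)+N_{het}(j)}$$

over shared non-missing biallelic sites, with the conventional degree
cutoffs (0.354 / 0.177 / 0.0884 / 0.0442). A cohort passes when
between-group kinship stays below the 2nd-degree threshold 0.0884
($2^{-7/2}$).

**Association statistics.** For a 2×2 carrier table $(a, b; c, d)$:
odds ratio $ad/bc$ with Wald CI
$\exp(\ln \text{OR} \pm z_{0.975}\sqrt{1/a+1/b+1/c+1/d})$, equivalent
single-predictor logistic regression, the continuity-adjusted chi-square
$\sum \max(|O-E|-0.5,\,0)^2/E$ (truncated, so near-balanced tables give
exactly 0), the two-sided Fisher exact test by hypergeometric enumeration,
and carrier percentages at printed precision. Tables with a zero cell are
reported not estimable (`NE`) unless the Haldane–Anscombe correction is
requested.

**Vasodilator response (ANCOVA).** Percent change from baseline is
regressed on genotype and the baseline measurement; the genotype
coefficient is the least-squares-mean difference (carrier − non-carrier),
with a t-based CI. Non-carrier comparison subjects are age- and sex-matched
(greedy nearest-age within sex, deterministic tie-breaks).

**Splice-consequence arithmetic.** For donor-site variants: exon-skip frame
analysis (a 144-nt codon-aligned exon 4 deletes residues 127–174,
`p.Thr127_Arg174del`), cryptic-donor intron retention with premature-stop
scanning, and HGVS-style protein deletion naming, on a packaged synthetic
transcript fixture.

## Worked example

```r
library(pahburden)

# a synthetic two-stage cohort: 42 discovery + 188 replication cases,
# 968 controls, causal-gene carriers at 6.1% / 0.8%
rep <- run_study(simulation_config(seed = 2), verbose = FALSE)
print(rep)
```

```
pahburden study report (seed 2)
  funnel: qualifying_variant_hits=2009, candidate_genes=1738, singleton_genes=1502, shared_genes=21, shared_expressed_genes=5
  validation gene: PTGIS
  combined burden: 16/230 cases vs 8/968 controls, OR 9.0 (3.8-21.2)
  vasoresponse PVR: LS-mean diff -23.5 (-31.7 to -15.4)
  vasoresponse cardiac_index: LS-mean diff +20.7 (12.3 to 29.1)
```

The funnel line is the discovery count trail: ~2000 filter-passing variant
hits over ~1700 candidate genes in the 42 discovery genomes, mostly
singletons; 21 genes shared by ≥ 3 carriers, 5 of them lung-expressed; the
planted causal gene tops the list with 6 discovery-arm carriers. The
combined burden row pools both case arms against controls (the planted
truth at this seed is 16 case and 8 control carriers), and the vasodilator
models recover the planted least-squares-mean effects (−21.7 and +18.3
percentage points) within their confidence intervals.

Published contingency data can be analysed directly:

```r
odds_ratio_wald(contingency_table(14, 216, 8, 960))
#> carrier [Wald odds ratio]: OR 7.8 (95% CI 3.2-18.8), p = 5.05e-06
yates_chi2(contingency_table(2, 40, 6, 182,
                             groups = c("discovery", "replication")))
#> $statistic 0.001328504; $p_value 0.9709246
```

A thin command-line wrapper ships in `inst/cli/pahburden.R`
(`simulate`, `run-all`, `assoc` subcommands).

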