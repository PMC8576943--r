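# clonescape

Multiregional tumor sequencing shows that a single biopsy is a poor witness
of a tumor's genome: mutations that look clonal in one region are often
subclonal in the patient ("clonal illusion"), and different regions of the
same tumor can follow different evolutionary modes. `clonescape` implements
a complete, tested analysis pipeline for this setting — built around the
multiregional study design used for gastric adenocarcinoma, but applicable
to any multi-sample somatic variant table — together with a simulator of
multiregional tumors with known clonal structure, so every stage can be
validated without access to controlled patient data.

It is aimed at cancer-genomics analysts working with per-patient,
multi-region somatic variant calls (multi-sample VCF with per-sample
DP/AD/AF), per-sample purity estimates and per-gene copy-number tables.

## What it computes

* **Variant filtering and cross-sample recovery** — retention rules on
  allele fraction (AF ≥ 5%), depth (≥ 10 in tumor or matched normal),
  alt reads (≥ 2), strand bias, blacklists, homopolymers (AF > 10%),
  population AF (< 1%) and cancer-gene annotations, followed by recovery of
  sub-threshold calls anchored by another sample of the same patient.
* **Intratumoral heterogeneity** — sharing spectra (variants present in
  exactly *k* of *n* regions), single-sample miss rates,
  primary-vs-metastasis set comparisons, multi-hit genes (parallel-evolution
  candidates), and copy-number heterogeneity (deletion: total CN = 0,
  amplification: total CN ≥ 6). TMB and MSI classification included.
* **Clonality via cancer cell fractions** — for each variant,
  CCF = VAF·(ρ·CN_t + (1−ρ)·CN_n)/(ρ·m) with Clopper-Pearson 95% intervals;
  a mutation is *subclonal* when the CI upper bound is below 0.95. Clonality
  is assessed per sample and per patient (all samples pooled into a single
  pseudo-sample), and discordances are reported as clonal illusions.
* **The 1/f neutrality test** — under neutral growth the cumulative
  mutation count follows M(f) = (μ/β)(1/f − 1/f_max). The package fits M(f)
  against 1/f through the origin inside a subclonal frequency window
  (default [0.1, 0.25]), reporting R² (neutral iff R² ≥ 0.98), the
  Kolmogorov distance between normalized empirical and theoretical
  cumulative curves, and a per-patient heterogeneity summary.
* **Sampling requirements** — the apparent-clonal curve C(n) (variants
  ubiquitous in random n-sample subsets) is fitted with
  C(n) = c∞ + (C(1) − c∞)·g^(n−1) to estimate the tumor's balance factor
  g; the number of samples needed for correct clonal identification solves
  P(n) = 1 − gⁿ ≥ p.
* **Region trees** — exact maximum-parsimony trees over regions (plus the
  normal outgroup) from binary SNV matrices via branch and bound, with
  Fitch/Hartigan scoring, per-branch mutation counts, newick output, and
  simplified CCF-based lineage ordering constraints.
* **Immunohistochemistry** — H-scores
  (0·pct₀ + 1·pct₁₊ + 2·pct₂₊ + 3·pct₃₊, range 0–300) and p53 quartile
  grouping (Q1/Q4: ≤ 15 or ≥ 189; Q2/Q3: 16–188).

## Worked example

```r
library(clonescape)

## a five-region tumor: 40 truncal mutations, two regional subclones,
## a neutral 1/f tail, 200x depth, purity 0.8
cfg <- simConfig(n_regions = 5, n_clonal = 40, depth_mean = 200, seed = 42)
vt  <- recoverVariants(applyFilters(simulateTumor(cfg)))
vt
#> VariantTable for patient 'sim_seed42': 283 variants x 6 samples (5 tumor)
#>   filtered: 185 variants present in >= 1 tumor sample

sharingSpectrum(vt)
#> SharingSpectrum over 5 samples, 135 variants
#>   1 sample(s): 0 (0.0%)
#>   2 sample(s): 25 (18.5%)
#>   3 sample(s): 25 (18.5%)
#>   4 sample(s): 0 (0.0%)
#>   5 sample(s): 85 (63.0%)

clonalityTally(perPatientClonality(vt)$status)$percent
#>         clonal      subclonal not_assessable
#>           14.1           85.9            0.0

set.seed(42)
fit <- fitBalanceFactor(apparentClonalCurve(vt))
fit
#> BalanceFit: g = 0.437, c_inf = 130.4 over 5 points (rss 0.979)
samplesNeeded(balanceG(fit), 0.90)
#> $n        [1] 3
#> $p_correct [1] 0.9167108

fitNeutralModel(prepareVafs(vt, "pooled"), sample = "pooled")
#> NeutralityResult [pooled]: non_neutral (n = 17 in window, R2 = 0.894,
#>   D = 0.264, mu/beta = 2.5)

maxParsimony(buildMatrix(vt))[[1]]
#> SampleTree (parsimony score 188): (((R3,R4),R5),(R1,R2),Normal);
```

Reading the output: the two 25-variant subclone branches sit in the 2- and
3-sample sharing bins while the trunk plus the high-frequency neutral tail
are ubiquitous (63%); pooling all regions demotes most ubiquitous-looking
calls, leaving 14% patient-level clonal; the fitted balance factor g = 0.44
implies three samples already give > 90% confidence in the clonal set; the
pooled VAF spectrum deviates from the 1/f neutral expectation (R² = 0.89
< 0.98) because the simulated subclones add a non-neutral peak; and the
parsimony tree recovers the two simulated clades (R1,R2) and (R3,R4,R5).

The same stages are scriptable through `runPipeline("simulate" | "filter" |
"het" | "clonality" | "neutrality" | "phylo" | "ihc" | "report", config,
out_dir, seed)`, which writes TSV/JSON artifacts with the seed and a config
digest embedded.

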