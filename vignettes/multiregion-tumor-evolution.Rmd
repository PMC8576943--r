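---
title: "Methods: multiregional tumor heterogeneity, clonality and neutrality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiregional tumor heterogeneity, clonality and neutrality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`clonescape` analyses per-patient, multi-region somatic variant tables. This
vignette explains the statistical models behind each stage, the parameters
that matter, the numerical choices made where the design was genuinely open,
and what the bundled simulator can and cannot stand in for. It states no
empirical result beyond what the package's tests and acceptance script
compute themselves.

## Data model

A `VariantTable` is a `SummarizedExperiment`: rows are somatic variants,
columns are the regional tumor samples plus the matched normal. Assays
`depth`, `alt` and `af` hold read support; per-sample purity and tissue type
(`primary`, `lymph_node`, `normal`) live in `colData`; the annotations the
filters consume (effect class, homopolymer/strand-bias/blacklist flags,
population allele frequency, known-somatic and cancer-census-gene flags) live
in `rowData`. Annotation flags are *inputs*: the upstream callers and
databases that produce them are out of scope, and the analysis starts at the
filtering logic.

## Filtering and cross-sample recovery

A call passes in a sample iff AF ≥ `min_af` (0.05), total depth ≥
`min_depth` (10) in the tumor *or* the matched normal, alt reads ≥
`min_alt_reads` (2), no strand bias, not blacklisted, AF strictly above
`homopolymer_min_af` (0.10) at homopolymer sites, population AF below
`max_population_af` (0.01), optionally non-synonymous, and optionally known
somatic or in a census gene. The `filter` assay records the first failing
rule in a fixed canonical order; the filter log plus the passing calls
always partition the input calls exactly (a tested conservation property).

Recovery then re-marks as present any call removed *solely* for AF <
`min_af` in a sample, provided the variant passes at AF ≥ `min_af` in
another sample of the same patient. Because a zero-alt call also fails the
alt-read rule, recovery can only rescue genuinely covered low-frequency
calls; the operation is idempotent and never removes calls. "Present" in
all downstream statistics means this post-recovery state; AF = 0 at
positive depth is "covered but absent", zero depth is "not assessable".

## Cancer cell fractions and clonality

For purity $\rho$, tumor copy number $CN_t$, normal copy number $CN_n$ and
multiplicity $m$,

$$\mathrm{CCF} = \mathrm{VAF}\,\frac{\rho\,CN_t + (1-\rho)\,CN_n}{\rho\, m}.$$

Open choices, decided as follows:

* **Multiplicity** is estimated by the nearest-integer rule
  $m = \mathrm{clamp}(\mathrm{round}(\mathrm{VAF}\,(\rho CN_t +
  (1-\rho)CN_n)/\rho),\,1,\,CN_t)$ — the simplest estimator consistent with
  the adjustment formula. A consequence worth knowing: the CCF point
  estimate is monotone in alt reads only within a fixed-$m$ regime; at an
  $m$ transition it re-scales by construction.
* **Confidence interval**: Clopper-Pearson exact binomial on alt/depth
  (via `qbeta`), transformed by the same linear map as the point estimate.
  The exact interval is conservative, which errs toward calling
  "subclonal" only on solid evidence — the safer direction for the
  clonal-illusion analysis. A mutation is *subclonal* iff the upper bound
  is below 0.95; zero depth gives `not_assessable` rather than an error.
  CCF and bounds are clamped to [0, 1.5] for reporting.
* **Per-patient pooling** sums read counts over all tumor samples (zeros
  included for covered-but-absent samples) and pools purity and copy number
  as depth-weighted means, then applies the same CCF machinery. Pooling
  *reads* rather than averaging per-sample CCFs keeps the binomial CI exact
  for the pooled pseudo-sample and reduces, for a single-sample patient, to
  the per-sample result.

The clonal-illusion report lists variants clonal in at least one sample but
subclonal in the pooled analysis, with the offending samples.

## Sampling requirements: the balance factor

The apparent-clonal curve $C(n)$ is the mean, over random size-$n$ subsets
of the patient's samples (exhaustive whenever at most 200 subsets exist), of
the number of variants present in every subset member. It is non-increasing
in $n$ and decays from $C(1)$ toward the count of mutations that are
ubiquitous no matter how many regions are examined. We summarize the decay
with the geometric model

$$C(n) = c_\infty + (C(1) - c_\infty)\,g^{\,n-1},\qquad 0 < g < 1,$$

fitted by least squares: for fixed $g$ the optimal $c_\infty$ is closed
form, so the fit is a 1-D `optimize` over $g$ (tolerance $10^{-12}$;
near-constant curves return $g$ at the lower boundary with
$c_\infty = C(1)$; fewer than 3 points is an error). The balance factor $g$
measures how evenly the phylogeny partitions the tumor mass: balanced
tumors (large $g$) need many samples before the apparent-clonal set stops
shrinking.

The probability that $n$ samples suffice for correct clonal identification
is modeled as $P(n) = 1 - g^n$, giving
$n = \lceil \ln(1-p)/\ln g \rceil$ samples for a target probability $p$.
This one-parameter model is a deliberate operationalization: it reproduces
the published probability bounds at the published balance factors
($g=0.56$: $P(5) = 94.5\% > 90\%$; $g=0.2,\ n=10$ and $g=0.01,\ n=4$: both
$> 98\%$). Note an honest wrinkle: under this model $g = 0.56$ already
reaches 90% at $n = 4$, whereas the source analysis states five samples;
the model is documented as such and the resampling estimator
(`apparentClonalCurve`) is the empirical cross-check.

## The 1/f neutrality test

Neutral tumor growth predicts that the cumulative number of subclonal
mutations with frequency at least $f$ grows as
$M(f) = \frac{\mu}{\beta}\left(\frac{1}{f} - \frac{1}{f_{max}}\right)$.
The test evaluates $M$ at the observed VAFs inside a window
$[f_{lower}, f_{upper}]$ (default $[0.1, 0.25]$ — below the diploid clonal
peak at $\sim 0.5\rho$, above the detection limit; the bounds are
configurable because the published analysis does not print its own),
regresses $M$ on $x(f) = 1/f - 1/f_{upper}$ **through the origin** (the
theoretical $M(f_{upper})$ is 0), and reports:

* the slope, an estimate of the effective mutation rate $\mu/\beta$
  (mutations per unit inverse frequency);
* $R^2$ computed about the mean of $M$, so the neutral/non-neutral
  threshold of 0.98 is on the conventional scale; negative values are
  floored at 0;
* the Kolmogorov distance between the empirical and theoretical cumulative
  curves, both normalized to 1 at $f_{lower}$ and evaluated only at the
  observed VAFs (no p-value: the distance is used descriptively, and its
  across-sample mean and SD summarize intra-patient heterogeneity).

Synonymous and non-synonymous passing variants are both included; variants
with estimated multiplicity ≥ 2 (gene doubling) are removed, because
doubling inflates frequency without clonal growth. No purity correction is
applied — purity scales all frequencies of a sample equally. The pooled
mode uses each variant's mean AF across all tumor samples, zeros included,
to dampen regional sampling bias. Fewer than 12 in-window mutations yields
the verdict `insufficient` rather than a silent "neutral"; hypermutant
samples whose clonal peak covers the window can be excluded from the panel
by name.

## Maximum parsimony over regions

The binary matrix has one row per distinct presence pattern (duplicates
collapsed with multiplicity weights, all-zero rows dropped) over the
samples plus an all-zero outgroup. The search enumerates unrooted binary
topologies by stepwise taxon addition with branch and bound: the Fitch
score of a partial tree never decreases when a taxon is added, so partial
trees scoring above the incumbent are pruned; a greedy addition pass seeds
the incumbent. Scoring uses Hartigan's generalization of Fitch, exact for
multifurcations, so the same routine scores user-supplied trees of any
shape. All co-optimal trees are returned; ties are ordered by canonical
newick (children sorted lexicographically, outgroup last) for
reproducibility. The exact-search cap is 12 samples; beyond that the
package refuses rather than silently switching to a heuristic.

Branch mutation counts come from a minimum-change labeling (root state
prefers the outgroup state 0, children keep the parent state when
admissible); they sum to the parsimony score. The CCF ordering check
implements the simplified lineage constraints — ancestry requires
$\mathrm{CCF}_X \ge \mathrm{CCF}_Y - \varepsilon$ in every sample,
siblinghood under $Z$ requires $\mathrm{CCF}_X + \mathrm{CCF}_Y \le
\mathrm{CCF}_Z + \varepsilon$ — with $\varepsilon = 0.1$ by default,
roughly the CCF uncertainty at a few-hundred-fold depth. Variants that fit
more than one branch are reported as unresolved, never forced.

## The simulator: what it emulates, and what it does not

`simConfig()` declares a founding clone carrying `n_clonal` truncal
mutations (cell fraction 1 everywhere), subclones with user-declared
per-region cell fractions (validated so siblings never exceed their
parent), and a neutral tail attached to the founding clone whose
intra-clone frequencies follow the truncated $1/f^2$ density on
`[f_min, f_max]` via inverse-CDF sampling, with a Poisson-distributed count
of mean $\mu_{eff}(1/f_{min} - 1/f_{max})$. Reads are drawn per region as
depth ~ Poisson(`depth_mean`) and alt reads ~ Binomial(depth, AF) with

$$\mathrm{AF} = \frac{f_{cell}\, m\, \rho}{\rho\, CN_t + (1-\rho)\,2},$$

where declared copy-number events set $CN_t$ and $m$ = major CN for the
variants placed inside them. The defaults — five regions, 40 truncal
mutations, two regional subclones at fractions 0.45/0.35, $\mu_{eff} = 10$
over [0.05, 0.4], 200× depth, purity 0.8 — describe a mid-size,
moderately impure surgical case of the kind multiregional studies sample.

Deliberate simplifications: no spatial growth model (clone fractions are
declared, not emergent), no selection dynamics, no sequencing artifacts
(strand bias, FFPE damage, mapping error — the corresponding flags exist
but the simulator leaves them benign), the neutral tail is
region-independent within its host clone (the test operates per sample, not
spatially), and a tail mutation is labeled truly clonal only if its
intra-clone frequency is 1. Passing tests on simulated tumors therefore
validate the *statistical logic* — filter algebra, CCF calibration, curve
fitting, tree recovery — not robustness to alignment- or chemistry-level
artifacts in real data.

## Problem sizes and reproducibility

The test-suite fixtures use 3–6 regions, tens to a few hundred variants,
and 20–25 seed replicates for stochastic properties; the acceptance script
uses 100 seeds of 1000-mutation VAF sets at depth 500 and exhaustive
parsimony checks on up to 6 samples. These sizes make every stochastic
criterion stable at desk scale while keeping a full run in minutes on one
CPU. Every entry point that draws random numbers either takes a seed
(`simConfig`, `runPipeline`) or documents that it uses the current RNG
stream; pipeline artifacts embed the package version, seed and a config
digest.

## Known limitations

* Purity and ploidy are inputs, not estimated; CNV segmentation and
  annotation databases are likewise upstream.
* The per-patient pooling and the $1-g^n$ sampling model are documented
  operationalizations of procedures whose published descriptions are
  qualitative; alternatives (CCF averaging, multi-parameter sampling
  models) would change numbers at the margins.
* Exact parsimony is limited to 12 regions; no bootstrap support values.
* The MSI score classification uses the closed interval [10, 30] for MSI-L
  — the published boundary sentence is internally inconsistent, and this
  partition is the package's resolution.
* The neutrality verdict is a threshold on $R^2$, inheriting that
  statistic's known insensitivity to small subclonal clusters near the
  window edges.
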