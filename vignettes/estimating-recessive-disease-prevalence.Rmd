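---
title: "Estimating carrier frequency and genetic prevalence of a recessive disorder from population allele frequencies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating carrier frequency and genetic prevalence of a recessive disorder from population allele frequencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carrierprev)
```

## The problem

For a rare autosomal recessive disorder, direct case counting
underestimates how common the disease really is: cases are missed,
misdiagnosed, or never genotyped. An alternative is *genetic*
prevalence — the proportion of conceptions expected to inherit two
pathogenic alleles — computed from the frequencies of the known
disease-causing alleles in a large reference cohort such as gnomAD.
carrierprev implements this estimator for population-stratified allele
frequency data, with iron-refractory iron deficiency anaemia (IRIDA) as
the worked case. IRIDA is caused by biallelic loss of *TMPRSS6*, the
chromosome-22 gene encoding matriptase-2, a serine protease that
downregulates hepcidin; the package ships the curated set of its
missense-class pathogenic variants observed in gnomAD v2.1.1.

## The model

Let $q_i$ be the population frequency of the $i$-th pathogenic allele,
treated as an independent biallelic site. Under Hardy–Weinberg
equilibrium with random mating:

* a haplotype carries *some* pathogenic allele with probability
  $1 - \prod_i (1 - q_i)$;
* the **genetic prevalence** (two pathogenic haplotypes) is
  $\left[1 - \prod_i (1 - q_i)\right]^2 \approx \left(\sum_i q_i\right)^2$;
* the **carrier frequency** (exactly one) is
  $2\left(1 - \sum_i q_i\right)\sum_i q_i \approx 2\sum_i q_i$,

where the approximations are first-order in the pooled frequency
$q = \sum_i q_i$ and are accurate to better than 2% relative error for
$q \le 10^{-2}$ (the error term is of order $q$ itself). Reports use the
first-order forms by default because at rare-disease scales the two are
numerically indistinguishable and the first-order forms make the
carrier/prevalence relationship exact on the reporting scales:
prevalence per million $= (\text{carrier per thousand}/2)^2$. The exact
forms are available via `method = "exact"`.

Each $q_i$ is estimated directly by the observed allele fraction
$AC_i/AN_i$ (allele count over allele number) in the reference cohort,
per population, falling back to the reported allele frequency when only
a frequency is published.

### Confidence intervals

The pooled allele count over the included variants is modelled as one
binomial draw, and its 95% interval is the **Wilson score interval** —
the inversion of the normal-approximation score test, which stays inside
$[0,1]$, always contains the observed proportion, and behaves well at
the extreme counts typical of rare alleles (lower bound exactly 0 at
zero successes). The critical value is the full-precision normal
quantile ($1.959964\ldots$ at 95%), not a rounded 1.96, so results are
bit-stable across platforms.

Both reporting scales inherit this single allele-scale interval by
**endpoint transformation**: the carrier transform $q \mapsto 2(1-q)q$
and the prevalence transform $q \mapsto q^2$ are monotone increasing on
$[0, \tfrac12]$, so mapping the endpoints propagates the interval
exactly. No delta-method approximation is involved, and the carrier and
prevalence intervals are automatically consistent with each other — the
consistency that the published stratified table exhibits.

### The effective allele number

When variants are pooled, each has its own $AN_i$, and no single
binomial sample size is canonically "the" denominator. This choice is
exposed as `an_strategy`:

* `"fixed:N"` — an externally known cohort size in alleles. For gnomAD
  v2.1.1 this is $2 \times 141{,}456 = 282{,}912$, the default whenever
  a `cohort_size` is passed to `report_config()`.
* `"mean"` (default otherwise), `"median"`, `"min"` — summaries of the
  observed per-variant $AN_i$; `"min"` is the conservative choice.

When some included variant carries only a frequency and no counts, the
pooled count is reconstructed as $\mathrm{round}(q \cdot AN)$ before the
interval is computed.

## Variant curation model

Classification labels (ACMG/AMP-style: pathogenic, likely pathogenic,
uncertain, likely benign, benign) are **inputs**, produced by human
curation; the package implements no evidence-code engine. Estimation
uses exactly the variants that are (a) classified pathogenic or likely
pathogenic and (b) free of the gnomAD quality flags
`low_confidence_pLoF`, `LCR`, and `not_LoF` — flagged putative
loss-of-function calls are of doubtful validity regardless of curated
classification, so the flag rule is applied unconditionally.
`filter_for_estimation()` is idempotent and order-preserving, and the
stratified report logs how many records each rule removed.

Records absent from a population contribute $q_i = 0$ there and are
tallied in a `n_missing` count rather than silently dropped —
subpopulation coverage in reference cohorts varies by variant.

Two conventions from the TMPRSS6 literature are handled explicitly:

* **Isoform numbering.** The MANE canonical transcript encodes an
  802-aa protein; much of the older literature numbers residues on an
  811-aa isoform translated from an upstream alternate start codon that
  prepends nine residues. `map_isoform_position()` converts between the
  numbering systems (canonical $i \leftrightarrow$ long $i+9$; long
  residues 1–9 have no canonical image). Ile203Thr in canonical
  numbering is the literature's I212T.
* **Initiator-codon substitutions.** The packaged table contains two
  Met1 substitutions. Ontologically they are `start_lost`, but the
  curated tabulation counts them with the missense set; the fixture
  records both facts (`consequence = "start_lost"`,
  `category_override = "missense"`), and `categorize_consequences()`
  counts by the override when present. This keeps the consequence
  vocabulary honest while reproducing the conventional 40-missense
  count.

## Minimum-sample gating

Populations with too few genotyped alleles produce intervals too wide to
be meaningful, and published analyses of this kind decline to report
them (for IRIDA, the Ashkenazi Jewish and Finnish strata) without
stating a numeric rule. The package makes the rule explicit and
configurable: a population whose effective allele number falls below
`gate_an` (default 10,000 alleles) — or that has no contributing data at
all — is reported with status `not_analysed` and carries no numbers,
never a spuriously precise zero.

## The synthetic cohort generator

`generate_cohort()` emulates the reference-cohort data structure with
known truth so the whole pipeline is testable without any download. Per
variant and population, the allele count is drawn
$\mathrm{Binomial}(AN_{\text{pop}}, q)$ at the configured true
frequency; the pooled `all` population aggregates counts and allele
numbers across populations. Defaults encode the study conditions:

* per-population allele numbers are twice the gnomAD v2.1.1 combined
  exome+genome individual counts (`gnomad_v2_an()`, 141,456 individuals
  in total);
* the consequence mix follows the curated TMPRSS6 spectrum
  (40 missense-class, 20 frameshift, 17 nonsense, 9 splice out of 86;
  the acceptor/donor split of the 9 splice variants is not published
  and is fixed at 5/4);
* decoy records — excluded classifications or disqualifying flags — can
  be appended to exercise the filter. Decoys are sampled *after* the
  causal records from a single seeded generator, so for a fixed seed the
  causal counts are identical with or without decoys, making
  "adding excluded records changes nothing" an exactly testable
  invariant rather than a statistical one.

What the generator deliberately does **not** emulate: linkage between
sites (haplotypes are independent-site draws), mutation–drift dynamics,
sampling correlation between variants genotyped on the same individuals,
classification error, and call-rate variation within a population
(every variant sees the full $AN$). Passing the recovery tests therefore
shows the estimator is correct *for the sampling model the field's
formulas assume*, not that real-cohort artefacts are absent.

Two independent stochastic oracles back the closed forms:
`simulate_genotype_prevalence()` assigns each individual two independent
haplotypes and observes the affected fraction (converging to the exact
prevalence), and `ci_coverage_study()` measures empirical Wilson
coverage against the nominal level.

## Numerical and reporting choices

* Display values are rounded half-even to 2 decimals on the reporting
  scales (per million for prevalence, per thousand for carriers), with
  full precision retained internally and in the JSON rendering; a
  published "1.6" appears here as "1.60".
* Wilson endpoints at the boundary counts ($AC = 0$, $AC = AN$) are set
  to exactly 0 and 1 — the score equation's boundary roots — rather than
  left to a final-ulp `sqrt()` wobble.
* Frequencies are recomputed from counts wherever both are present, so
  a stale frequency column can never disagree with its counts.
* All randomness flows through a single seeded generator per operation
  (`withr::with_seed`), and seeds are recorded in report metadata.

## Validation problem sizes

The shipped test suite validates at sizes chosen to make the statistical
assertions sharp while keeping a full run in well under a minute of CPU:
Wilson-vs-root-finder agreement to $10^{-10}$ on a grid up to
$AN = 282{,}912$; coverage studies with 2,000 replicates at
$q = 10^{-3}$, $AN = 282{,}912$ (nominal 95% coverage, observed within
$[0.93, 0.97]$); genotype-level simulation with $10^6$–$10^7$
individuals (the larger size where exact and first-order prevalence must
be distinguished — their gap at $\sum q = 0.03$ is $1.2\times10^{-5}$,
so the Monte-Carlo standard error must sit well below it); and pipeline
truth-recovery over 30–50 variants across the eight emulated
populations, asserted within three binomial standard errors.

## Known limitations

* Hardy–Weinberg with random mating only: no consanguinity,
  non-random mating, or X-linked inheritance.
* Genetic prevalence is a birth-incidence-style quantity; it equals
  observed disease prevalence only under full penetrance and no effect
  on survival, and it misses pathogenic alleles absent from the
  reference cohort — it is a lower bound in that respect.
* The pooled-binomial interval ignores between-variant sampling
  correlation (variants are genotyped on overlapping individuals).
* Classification quality is inherited from the curator; the filter can
  only be as good as its input labels.
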