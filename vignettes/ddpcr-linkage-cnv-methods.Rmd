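---
title: "Models and methods: droplet-level linkage and copy-number analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: droplet-level linkage and copy-number analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddpcrlink)
```

This vignette is the package's own account of the statistical models it
implements, the choices made where the design was genuinely open, and what
the simulation-based validation does and does not demonstrate.

## The Poisson partition model

A droplet digital PCR well partitions a reaction into roughly 20,000
nanoliter droplets. Molecules land in droplets independently and uniformly,
so the count per droplet is (in the many-droplet limit) Poisson with mean
$\lambda$, and the fraction of target-negative droplets estimates
$e^{-\lambda}$:

$$\hat\lambda = -\ln\frac{n_{neg}}{n_{total}}, \qquad
  \text{concentration} = \hat\lambda / V_{droplet}.$$

The droplet volume defaults to 1 nL; 0.85 nL is offered as an instrument
calibration preset. Every ratio statistic in the package (%L, copy number)
cancels the volume, so this choice only affects absolute copies/µL.

Uncertainty is propagated by the delta method from the binomial negative
fraction $p$: $\mathrm{se}(\hat\lambda) = \sqrt{(1-p)/(n_{total}\,p)}$,
with a symmetric normal interval clamped at zero. This is standard digital
PCR practice; no claim is made that it reproduces any particular vendor's
interval algorithm, which is not public. The suite verifies the interval
two ways: against a parametric bootstrap of the binomial count
($10^5$ resamples, widths within 5%) and by Monte-Carlo coverage (1,000
simulated wells of 20,000 droplets at $\lambda \in \{0.05, 0.5, 1.5\}$,
coverage required in 93–97%).

Two degenerate states are handled explicitly rather than numerically. A
well with **no negative droplets** is *saturated*: $\lambda$ is unbounded,
and the package raises a classed condition (scalar API) or sets a
`saturated` flag (data-frame API) — never a silent `Inf`. A well with all
droplets negative has $\lambda = 0$ exactly with a degenerate interval.
Wells under 8,000 accepted droplets are flagged by QC; the threshold is an
operational default (instrument runs routinely accept 10,000–17,000
droplets) and is configurable.

## Chance-corrected linkage

Two targets carried on one DNA fragment enter a droplet together. For a
duplex with per-channel means $\lambda_A, \lambda_B$ and double-negative
fraction $p_{nn}$, model the well as three independent Poisson molecule
species — A-only (rate $a$), B-only ($b$), linked AB ($\gamma$) — giving
$p_{nn} = e^{-(a+b+\gamma)}$, $p_{A-} = e^{-(a+\gamma)}$,
$p_{B-} = e^{-(b+\gamma)}$. Solving,

$$\hat\gamma = \hat\lambda_A + \hat\lambda_B - \hat\lambda_\cup
 = \ln\frac{p_{nn}}{p_{A-}\,p_{B-}},$$

which the suite confirms is exactly the maximum-likelihood estimate of the
linked rate under the full four-class multinomial likelihood (numeric
optimisation agrees to $10^{-6}$). Under independent loading
$E[\hat\gamma] = 0$; chance co-encapsulation is thereby corrected, not
merely thresholded. Negative point estimates are legitimate sampling noise
and are reported as-is (a zero-floored convenience column is included, but
all tests and summaries use the raw value, so that null averages center on
zero rather than being biased upward).

### Normalizing to %L

The linkage score is expressed as a percentage of a channel concentration.
The natural description — "the percentage of the partner gene's molecules
linked to the anchor" — divides by one named channel. But the quantitative
ceiling for a genotype with two anchor copies and a single linked partner
copy is 50%, which only holds when dividing by the **larger** of the two
channel means. The package therefore defaults to
`normalization = "max_channel"`, which respects copy-number ceilings in
all configurations, and provides `channel_a` / `channel_b` modes for the
partner-gene reading. The ceiling
$E[\%L] \le 100\,\min(\lambda_A,\lambda_B)/\max(\lambda_A,\lambda_B)$ is
property-tested on simulated genotypes.

The %L interval is a percentile bootstrap over multinomial resamples of
the four quadrant counts (default 2,000 resamples, seeded); resamples that
saturate are dropped and counted. A closed-form interval would require the
joint distribution of three correlated log-ratios; the bootstrap is
simpler, exact in the limit, and costs milliseconds.

### Digestion contrast and motif calls

A linkage signal is only believed when it can be destroyed: digestion with
a restriction enzyme cutting between the loci must collapse %L. A motif is
called **present** when the undigested score exceeds 1.0 %L *and* the
digested score is at most half of it. Both thresholds are operational
choices, exposed in the configuration: the presence threshold sits below
the weakest published long-range signal treated as evidence (%L = 2.9)
and above simulation noise at 20,000 droplets (null |mean %L| < 0.5);
the halving rule accepts the published partial abrogations (30→0,
2.9→0.9) while rejecting signals that digestion leaves untouched. Presence
calls under %L = 5 carry a `weak_evidence` flag — the signature of linkage
over unusually long range or from a minority of intact fragments — rather
than being suppressed.

## Copy number

With the target on one channel and the invariant reference *RPP30* (one
copy per haplotype, two per genome) on the other,
$\widehat{cn} = 2\hat\lambda_{target}/\hat\lambda_{ref}$. The interval is
a delta-method interval on the log-ratio treating the channels as
independent. They are not exactly independent — both are read from the
same droplets — but the dependence enters only through the shared
double-classification, and a multinomial bootstrap (provided as
`method = "bootstrap"`) agrees with the delta interval to a few percent on
realistic wells; the suite asserts that agreement.

### Mixture clustering

Raw estimates are clustered by a univariate Gaussian finite mixture fitted
with EM. Design choices, all of which were open:

* **Initialization** is by quantiles of the data, deterministically, so a
  fit is a pure function of the data and candidate `k`. Random restarts
  were rejected: ddPCR copy-number data are one-dimensional and strongly
  unimodal per cluster, and quantile starts recover the optimum in all
  tested scenarios while keeping results seed-independent.
* **Parameterizations:** equal-variance and free-variance models are both
  fitted and the winner chosen by BIC, since the truth varies (clusters
  widen with copy number when error is proportional, but archival cohorts
  often look homoskedastic).
* **Convergence:** absolute log-likelihood change below $10^{-8}$, at most
  1,000 iterations. The log-likelihood trace is stored on the fitted
  object and the suite asserts it is non-decreasing on every fit.
* **A floor of 0.05 copies on component standard deviations.** Zero-copy
  samples give *exactly* zero (no target molecules, no noise), and any
  point mass lets the likelihood diverge by shrinking a component onto it.
  The floor encodes that no real ddPCR measurement resolves copy number
  below ~0.05 and removes the singularity; it binds only from below.
* **Component→integer mapping:** each sorted component mean is rounded to
  the nearest integer; collisions are bumped upward to keep the mapping
  strictly increasing. This tolerates the systematic *downward* shift of
  whole cohorts (degraded archival DNA underestimates all copy numbers by
  a shared factor) without collapsing neighbouring bins — verified by
  shifting simulated cohorts by 0.85.

Assignment takes each sample to its maximum-posterior component (ties go
to the lower integer and are flagged). A call is flagged for **review**
when its posterior is below 0.95 or when the sample's own Poisson interval
excludes the assigned integer — the configuration where clustering and
per-well statistics disagree, which published experience shows is exactly
where human inspection catches misclassifications (a sample binned as
zero copies whose interval excludes zero is really a degraded one-copy
sample).

### Concordance

Cohen's kappa over the union of observed categories, unweighted (copy
numbers are treated as nominal; no published analysis of this kind uses
weighted kappa, and disagreements of one copy vs two copies are not
obviously "closer" in genotyping consequence). The interval uses the
large-sample standard error $\sqrt{p_o(1-p_o)/(n(1-p_e)^2)}$ clamped to
$[-1, 1]$. Perfect agreement inside a single category leaves chance
agreement at 1 and kappa undefined; that state is reported as degenerate
rather than as 1 or an error.

## Pedigree checking

A family's integer calls are Mendelian-consistent when one split of each
parent's total into two per-haplotype counts (each at most 2 for
*KIR2DL5*) lets every child's total be one maternal plus one paternal
haplotype count. The same parental splits must explain all siblings
jointly; de novo events are reported as violations, not explained away.
Unknown parents are quantified over all feasible totals. The implemented
search is exhaustive over splits and is itself verified against an
independent oracle that enumerates every per-child transmission
combination, exhaustively for all parent totals ≤ 4 and sibships up to 4
children.

The *KIR2DS3*/*KIR2DS5* co-segregation rules (absence of both implies no
*KIR2DL5*; presence of both implies at least two copies) are population
expectations from tight linkage disequilibrium, not laws; they are
reported as warnings for review.

## The simulator

The generator emulates the chain from genotype to quadrant counts:

1. **Genotype.** Two haplotypes, each one centromeric plus one telomeric
   motif from an editable library. The library places the genes this
   toolkit reasons about at the two published inter-locus distances
   (*KIR2DL2*→*KIR2DL5* 21.8 kb in cB01; *KIR3DS1*→*KIR2DL5* 19.9 kb in
   tB01); other positions are schematic. The inter-motif gap defaults to
   40 kb; it matters only for linkage across the motif boundary, which no
   default assay probes.
2. **Fragmentation.** Random breakage as a Poisson process along the
   molecule: a pair of loci $d$ kb apart stays joined with probability
   $e^{-d/\bar\ell}$, with $\bar\ell = 50$ kb by default to match
   column-extraction kits that prepare fragments up to ~50 kb. Restriction
   digestion adds fixed-position cut sites with per-site cut
   probabilities (1.0 = complete digestion). The exponential form is a
   one-parameter modelling choice; real fragment-length distributions of
   extraction protocols are not published beyond such summaries.
3. **Confinement.** Every molecule lands in a uniformly random droplet; a
   droplet is channel-positive when it holds at least one molecule
   bearing that target. Occupancy is deliberately not capped at one
   molecule — "zero or one target per droplet" is the dilute-limit
   idealization, and the uncapped multinomial reproduces Poisson
   statistics exactly at any loading. An optional per-channel
   misclassification rate ("rain") defaults to 0.

Default experiment sizes are 3,000 diploid genome equivalents (roughly
10–20 ng of human DNA, the assay's working range) in 20,000 droplets —
$\lambda$ per copy ≈ 0.15, inside the instrument's ideal quantification
window. Seeded runs are bit-reproducible and leave the global RNG stream
untouched.

**What passing these tests shows — and does not.** Parameter recovery on
the simulator validates the estimators against the model they assume:
Poisson confinement, exponential fragmentation, perfect classification.
Real wells add amplitude rain, gating error, droplet-volume variation and
PCR inhibition, none of which are modelled; the co-segregation rules are
population statistics that individual families can legitimately violate.
Agreement on simulated data is therefore necessary, not sufficient, for
field performance.

## Problem sizes used in validation

The shipped suite runs the coverage experiment at 1,000 replicate wells,
the null-%L calibration at 500 wells, the linkage benchmarks at 50
replicate wells of 20,000 droplets, mixture recovery over 40 seeded
cohorts, 300 simulated families plus 100 corruption probes, and the
exhaustive Mendelian cross-check over all 3,125 small family
configurations. These sizes give Monte-Carlo error comfortably below
every asserted tolerance while keeping the full suite around a minute.

## Known limitations

* The delta-method CI on $\lambda$ is a normal approximation; at very low
  positive counts (a handful of positive droplets) the bootstrap %L and
  copy-number intervals are the better-behaved choice.
* The CNV ratio interval ignores residual inter-channel dependence within
  shared droplets (checked to be small, not zero).
* The greedy nearest-distance pairing of target occurrences on a
  haplotype is exact for all genotypes expressible with the default
  library (at most two occurrences per target) but is heuristic for
  hypothetical arrangements with three or more copies of both targets on
  one haplotype.
* The mixture model assumes clusters are Gaussian on the raw-copy-number
  scale; heavy contamination or bimodal degradation within one true copy
  number would be split into spurious components rather than detected.
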