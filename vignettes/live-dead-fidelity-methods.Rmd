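---
title: "Live-dead compositional fidelity: models, parameters and design choices"
author: "taphofidelity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Live-dead compositional fidelity: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taphofidelity)
```

## The scientific problem

Death assemblages (DAs) — the accumulations of dead skeletal remains
sampled alongside living communities — are the raw material of
conservation paleobiology: if a DA faithfully records the composition
and diversity of the live assemblage (LA) it accumulated from, the
fossil record can stand in for long-term ecological monitoring.  That
fidelity has mostly been established for molluscs.  This package
implements a complete analysis for quantifying fidelity across
*multiple* higher taxa simultaneously (phyla and classes of benthic
marine invertebrates), where differential preservation — durable,
heavily biomineralized skeletons versus fragile or soft-bodied groups —
and time-averaging act very unevenly.

The package provides the full pipeline: ingestion and validation of
long-format occurrence tables, element correction, per-analysis sample
filtering, rarefaction standardization, the three fidelity statistics
with bootstrap confidence intervals, a randomization model of perfect
fidelity, diversity comparisons, a premortem/postmortem decomposition
of multivariate dispersion, and a forward taphonomic simulator so every
step is exercisable — and testable — without field data.

## Data model and preprocessing

Occurrence data are long (tidy): one record per site x taxon x
assemblage (x optional season), with the class and phylum travelling on
each record.  Counts are stored as reals because **element correction**
divides DA element counts (valves, plates, spines) by the number of
elements per live individual, giving fractional estimated individuals;
10 valves of a two-valved bivalve are 5 individuals, one spine of an
echinoid with 50 elements is 0.02.  The element catalog resolves taxon
> class > phylum > a global default of 1, so uncataloged taxa pass
through unchanged.  Inputs are assumed fragment-free: excluding
identifiable fragments is a data-collection rule, not something the
pipeline can detect after the fact.

Repeated seasonal visits to a locality are pooled into one site by
default (`poolSeasons = TRUE`), because locality-level fidelity
statistics are the target; a flag preserves visits as separate rows
for users who want within-site replication.  Whether repeat visits
should be replicates in locality-level statistics is genuinely open;
both modes are provided and the pooled mode is the default.

Where individual-level resampling needs integers, `integerize()`
converts fractional corrected counts.  The default `ceil_presence` mode
maps any value in (0, 1) up to 1 and otherwise rounds half-up: a taxon
that was observed in the field is never erased by numerical
convention.  Proportional metrics keep the fractional values.

Small samples make fidelity statistics unstable, so sites are filtered
by a minimum number of individuals.  The threshold is analysis-local:
50 for the correlation summaries, 20 for diversity and the
mollusc/non-mollusc splits, 30 for the dispersion analysis.  Whether
the threshold should apply to either assemblage, both, or their sum is
not settled; the default rule is `either` (a site falls if *either*
assemblage is too small), and the rule is a parameter.

## Sample standardization

DAs typically contain far more individuals than LAs, so live-dead
pairs are rarefied to the smaller of the two totals.  Richness uses
the analytic (Hurlbert) expectation

$$E[S_m] = \sum_i \left[ 1 - \binom{N - N_i}{m} \Big/ \binom{N}{m} \right],$$

computed with log-combinatorial arithmetic — deterministic and
replicate-free.  Compositional statistics (rank correlation, Pearson,
Bray-Curtis) have no closed form under subsampling, so they use
Monte-Carlo rarefaction: the larger assemblage is subsampled without
replacement (multivariate hypergeometric, drawn by a sequential
hypergeometric scheme that is O(species) per draw) and statistics are
averaged over replicates (default 1000; the mean, not the median, is
the aggregate).  One master seed drives everything; per-site and
per-replicate streams are derived by hashing the site id, so site
ordering can never change a result.

## Fidelity statistics

Three statistics, computed on proportional abundances over the union
taxon list of a pair:

* **Spearman's rho** of proportional rank abundance.  Taxa absent from
  one side receive tied minimum average ranks; ties use mean ranks
  throughout.  The two-sided p-value is exact by full permutation
  enumeration for n <= 9 (for six phyla in perfect rank agreement this
  gives p = 2/720 ~ 0.003) and t-approximate for larger n.
* **Pearson's r** on the same proportion vectors, p from the
  t-transform.  Weighted toward abundant taxa.
* **Bray-Curtis similarity**, `1 - sum|p_i - q_i| / sum(p_i + q_i)`.

Zero variance raises an error rather than returning a silent zero.
Within-taxon summaries (`taxonFidelitySummary()`) compute, per phylum
or class, the live-dead correlation of per-site abundance and per-site
richness across localities; groups with fewer than two species in
either assemblage are reported as missing, mirroring the dashes of
regional summary tables.  Cross-taxon correlations
(`crossTaxonCorrelations()`) operate on the regional table of per-taxon
abundance and richness.

One caveat found while validating against published regional tables:
live-assemblage abundance-vs-richness correlations reported in some
sources are not recoverable from the printed per-taxon columns (we
obtain r ~ 0.87 for phyla and ~ 0.80 for classes from the bundled
tables); the transformation behind such values is unstated, so the
package reports what the printed columns give.

## Bootstrap confidence intervals

Confidence intervals for locality-level correlations use the
accelerated bias-corrected (BCa) bootstrap: B resamples (default
1000) of the sampling units, bias term
$z_0 = \Phi^{-1}(\#\{\hat\theta^*_b < \hat\theta\}/B)$, acceleration
from the jackknife third-moment formula
$a = \sum(\bar\theta - \theta_{(i)})^3 / \{6[\sum(\bar\theta -
\theta_{(i)})^2]^{3/2}\}$, and adjusted percentile endpoints.  The
resampling unit is the **site**, with the live and dead members of a
pair resampled jointly, preserving the pairing structure.  Degenerate
bootstrap distributions collapse to a point interval with a warning;
replicates on which the statistic is undefined are redrawn (bounded
retries).

## The perfect-fidelity null

Fidelity statistics are biased away from their ideal values by finite
and unbalanced sampling alone — live samples are typically an order of
magnitude smaller than dead ones.  The randomization null asks what a
statistic would look like if fidelity were *perfect*: live and dead
counts are pooled into one species-abundance distribution, and each of
B replicates partitions the pooled specimens at random **without
replacement** into a pseudo-live sample of the original live size and
a pseudo-dead sample of the original dead size.  The resulting
distribution estimates the statistic under perfect fidelity at these
sample sizes; an observed value at or above the null's 2.5% quantile is
"explained by sampling" (boundary inclusive).  On enumerable pools the
replicate frequencies match the hypergeometric enumeration exactly,
and for exchangeable data the resulting p-values are uniform — both are
asserted in the test suite.

## Diversity comparisons

Per-site indices: richness S, Shannon's H (natural log), Simpson's D
and Pielou's J = H / ln S (undefined at S = 1 and reported missing).
"Simpson's D" is implemented as Gini-Simpson `1 - sum(p^2)` so that,
like H and J, larger means more diverse; the probability-of-identity
and inverse forms are available by flag since sources rarely say which
form they mean.  Site-level values (sample-standardized by default)
for the multi-taxic LA, the mollusc DA and the non-mollusc DA are
compared pairwise with tie-corrected Kruskal-Wallis tests and a
Bonferroni correction across the three pairs; a global test is also
emitted.  The degenerate all-tied case is mapped to H = 0, p = 1
(the tie correction otherwise divides by zero).

A structural point worth knowing: comparing a *taxonomic subset's* DA
against the *whole* LA only has "no difference" as its null when the
subset dominates the fauna.  In a community where molluscs are a
minority of species, the mollusc DA is systematically poorer than the
multi-taxic LA even with perfect preservation — a subset effect, not a
taphonomic one.  The package's effect-free property test therefore
uses a mollusc-dominated configuration (95% species share), matching
the real systems where mollusc surrogacy is proposed; with a
minority-mollusc fauna the comparison confounds subsetting with
taphonomy and should be interpreted accordingly.

## Dispersion decomposition (modified HMD)

To separate premortem (ecological) from postmortem (taphonomic)
variation, live and dead site points are embedded **jointly** by
principal coordinates analysis of Jaccard (presence-absence) or
Bray-Curtis (row-proportional abundance) dissimilarity.  The
embedding keeps axes with negative eigenvalues — both metrics are
semi-metric, so such axes are expected — as imaginary coordinates, and
distances combine the parts as
`sqrt(max(0, d_real^2 - d_imag^2))`, the standard correction.

*Premortem variation* is each LA's distance to the LA centroid;
*total live-dead variation* is each DA's distance to the **same** LA
centroid (the classical two-centroid variant is available by flag).
Overdispersion is the difference of the two means; its one-sided
p-value comes from permuting live/dead roles within site pairs
(default 999 permutations — the joint embedding is fixed under this
permutation, so only centroid and distances are recomputed).  The
premortem proportion uses means of distances; means of squared
distances are available by flag.  `classifySites()` labels sites
against the 1:1 line of good agreement with a user-supplied band
half-width: the compositional change expected from within-habitat
time-averaging alone is a reasonable choice of band, but its
derivation is model-dependent and deliberately left as a parameter.

## The taphonomic simulator

`taphonomicConfig()` defines a forward model whose defaults emulate a
multi-taxic shallow-shelf benthic survey: 52 localities, 157 species
in 11 classes across 6 phyla, about 170 live individuals per site
(~ 9 x 10^3 regionally), and a death assemblage totalling ~ 5 x 10^4
element counts — mollusc-dominated because mollusc groups preserve at
~ 0.95 while arthropod-like and soft-bodied groups preserve at
0.02–0.3.  The pieces:

* **Species pool** — species allocated to groups by largest remainder
  on the group shares; base relative abundances log-normal
  (sigma = 1.5, a typical marine SAD shape) within groups.
* **Site heterogeneity** — each site's latent composition is a
  Dirichlet draw with concentration `betaConc x base` (default 50:
  moderate between-site Bray-Curtis dissimilarity).
* **Time-averaging** — the composition drifts over `tSteps` (default
  10) by mixing with fresh Dirichlet perturbations at `turnoverRate`
  (default 0.1); the DA samples the *mean* of the history (uniform
  weights; exponential-decay weighting is a config option).  Live
  counts are a multinomial sample of the final step only.
* **Preservation** — each dead individual survives with its group's
  probability (binomial thinning at the individual level, so rare
  robust species can still appear); each survivor contributes its
  group's element count, and the output table reports elements so
  that `elementCorrect()` recovers individuals exactly.

What the simulator does *not* model: spatial transport (negligible in
shallow soft-bottom shelves), bioerosion as a stage distinct from the
survival probability, life-span effects, and sampling-effort variation
between sites (every simulated site has the same live n, so
site-filtering thresholds rarely bite on synthetic data).  Passing
tests on synthetic data therefore demonstrate the statistical
machinery and the direction of taphonomic effects, not the magnitudes
of any particular field system.

Two property-test conventions are worth stating.  Evenness inflation
by time-averaging is asserted on *sample-standardized* evenness (dead
subsampled to the live n): on raw counts the DA's inflated richness
raises the ln S denominator of J and masks the compositional effect.
And the effect-free diversity null uses the mollusc-dominated
configuration described above.

## Numerical choices and problem sizes

* Exact Spearman permutation enumeration up to n = 9 (362,880
  permutations, vectorized); t-approximation beyond.
* PCoA eigenvalue tolerance: |lambda| > max|lambda| x 1e-9 counts as
  real/imaginary; asymmetry beyond 1e-10 is rejected.
* Bootstrap and randomization defaults: B = 1000; HMD permutations =
  999.  The pipeline's locality stage uses 250 rarefaction replicates
  and 250 per-site null replicates by default, and the bundled
  acceptance script uses 100 replicates with 499 permutations — sizes
  chosen so a full default-scale synthetic study (52 sites, 157
  species, ~ 6 x 10^4 specimens) completes in well under a minute on
  one CPU while keeping Monte-Carlo error far below the effects of
  interest.  All replicate counts are parameters.
* Degenerate inputs fail loudly: zero-variance correlations,
  zero-total vectors, all-removed site sets and double element
  correction are errors, not silent values.

## Known limitations

* The analytic/Monte-Carlo split for standardization means richness
  fidelity is replicate-free while compositional fidelity carries
  Monte-Carlo error of order `1/sqrt(reps)`.
* BCa intervals with ~ 15 or fewer sites can be erratic for rank
  statistics (the jackknife acceleration is a third-moment estimate).
* The permutation p for overdispersion is one-sided by design;
  underdispersion (DAs *less* variable than LAs, e.g. strong
  homogenization) shows up in `classifySites()` but is not tested.
* Field point estimates from any particular deposited dataset are
  integration checks to run against that data, not properties of this
  package.
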