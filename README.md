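# taphofidelity

Live-dead compositional fidelity analysis for multi-taxic benthic
assemblages.

Death assemblages — the dead shells, tests and skeletal elements that
accumulate alongside living communities — are the closest thing ecology
has to a pre-industrial monitoring network, *if* they faithfully record
the live communities they came from.  That fidelity is well established
for molluscs; it is much less clear for whole faunas spanning durable
and fragile groups, where differential preservation and time-averaging
act unevenly across phyla and classes.  `taphofidelity` is for
paleoecologists and conservation paleobiologists who want to quantify
that fidelity from paired live-dead surveys, and to know how much of an
apparent mismatch is just sampling.

## What it computes

Given long-format occurrence tables (site, taxon, class, phylum,
live/dead, count) and a skeletal-element catalog:

* **Element correction** — dead element counts divided by elements per
  live individual (resolution taxon > class > phylum > 1).
* **Rarefaction standardization** of each live-dead pair to the smaller
  total: analytic Hurlbert expected richness
  `E[S_m] = Σᵢ [1 − C(N−Nᵢ, m)/C(N, m)]`, Monte-Carlo subsampling for
  compositional statistics.
* **Fidelity statistics** on proportional abundances over the union
  taxon list: Spearman's ρ of proportional rank abundance (exact
  permutation p for n ≤ 9), Pearson's r, Bray-Curtis similarity —
  regionally, per locality, and within each phylum/class — with BCa
  bootstrap confidence intervals (sites resampled as pairs).
* **Perfect-fidelity null** — pooled live+dead specimens partitioned at
  random without replacement at the original sample sizes; the
  distribution of a statistic under perfect fidelity, isolating
  sampling effects.
* **Diversity comparisons** — S, Shannon H, Simpson D, Pielou J per
  site; Kruskal-Wallis tests with Bonferroni correction across the
  multi-taxic LA / mollusc DA / non-mollusc DA pairs.
* **Modified HMD** — joint PCoA embedding (negative eigenvalues kept as
  imaginary axes), premortem variation (LA distances to the LA
  centroid) versus total live-dead variation (DA distances to the same
  centroid), overdispersion with a within-pair permutation test, and
  site classification against the line of good agreement.
* **A forward taphonomic simulator** — log-normal species abundances,
  Dirichlet site heterogeneity, time-averaged mixtures with turnover,
  per-group preservation probabilities and element counts — emitting
  pipeline-ready datasets with known ground truth.

## Worked example

Regional fidelity of higher taxa from a bundled live-dead summary of a
North Carolina shallow-shelf benthic survey (six phyla; columns are
live/dead specimen counts and species richness per phylum):

```r
library(taphofidelity)
ph <- read.csv(system.file("extdata", "onslow_phyla.csv",
                           package = "taphofidelity"))
crossTaxonCorrelations(ph)
#>                comparison   rho   p_rho     r      p_r
#> 1      richness_live_dead 1.000 0.00278 0.906 1.29e-02
#> 2     abundance_live_dead 0.657 0.17500 0.586 2.22e-01
#> 3 abundance_richness_live 0.943 0.01667 0.869 2.47e-02
#> 4 abundance_richness_dead 0.600 0.24167 0.994 4.97e-05
```

Phylum richness is in perfect rank agreement between live and dead
(ρ = 1, exact two-sided p = 2/720 ≈ 0.003; r = 0.91): phyla with many
live species also leave many species in the death assemblage.  Dead
abundance almost perfectly predicts dead richness (r = 0.99).

A complete synthetic study, from simulation to the sampling-effect
verdict:

```r
sim  <- generateStudy(taphonomicConfig(seed = 42), "demo_study")
occ  <- readOccurrences(sim$paths["occurrences"])
occ
#> OccurrenceTable: 5858 records, 52 sites, 155 taxa (8840 live / 53023 dead specimens)

live <- toMatrix(occ, "live")
dead <- integerize(elementCorrect(toMatrix(occ, "dead"),
          readElementCatalog(sim$paths["element_catalog"])))

pair <- makePairs(live, dead, "region")
fid  <- livedeadFidelity(pair, standardizationPlan(reps = 100, seed = 42))
null <- perfectFidelityNull(pair, "rho", B = 1000, seed = 42)
samplingEffectReport(fid, null)
#>   statistic observed null_mean  q025  q975 explained_by_sampling
#> 1       rho    0.495     0.975 0.968 0.981                 FALSE

livedeadDispersion(live, dead, "bray_curtis", permutations = 999, seed = 42)
#> DispersionResult [bray_curtis]: 52 sites, premortem = 0.298, total = 0.470
#>   overdispersion = 0.172 (p = 0.001), premortem proportion = 0.63
```

The simulator's default preservation bias (molluscs ~0.95, arthropods
~0.02) produces exactly the published pattern: observed regional rank
fidelity (ρ = 0.50) far below the perfect-fidelity expectation
(ρ ≈ 0.97), so the mismatch is taphonomic, not a sampling artifact; and
death assemblages significantly overdispersed around the live centroid
(overdispersion 0.17, p = 0.001), with premortem variation explaining
63% of total live-dead variation.

`runStudy()` chains every stage (summaries, locality fidelity with BCa
CIs, nulls, diversity tests, HMD for multi-taxic/mollusc/non-mollusc
subsets under Jaccard and Bray-Curtis) and writes the report tables
plus a JSON run manifest; reruns with the same manifest are
bit-identical.

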