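#' @import methods
NULL

OCC_COLUMNS <- c("site", "taxon", "class", "phylum", "assemblage",
                 "count", "season")

#' Long-format live-dead occurrence table
#'
#' Holds specimen counts keyed by site, taxon and assemblage (live or dead),
#' with the taxonomic hierarchy (class, phylum) travelling on every record
#' and an optional survey season.  Counts are stored as reals because
#' element correction of death-assemblage counts produces fractions.
#'
#' @slot records a `data.frame` with columns `site`, `taxon`, `class`,
#'   `phylum`, `assemblage` (`"live"` or `"dead"`), `count` (non-negative)
#'   and `season` (`NA` when a single survey).
#'
#' @details Validity enforces that each (site, taxon, assemblage, season)
#' key is unique, that every taxon maps to exactly one (class, phylum)
#' pair, that counts are non-negative and finite, and that each declared
#' assemblage carries at least one positive count.
#'
#' @seealso [readOccurrences()], [toMatrix()]
#' @export
setClass("OccurrenceTable", slots = c(records = "data.frame"))

setValidity("OccurrenceTable", function(object) {
  rec <- object@records
  missing_cols <- setdiff(OCC_COLUMNS, names(rec))
  if (length(missing_cols))
    return(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  if (!all(rec$assemblage %in% c("live", "dead")))
    return("assemblage must be 'live' or 'dead'")
  if (!is.numeric(rec$count) || any(!is.finite(rec$count)) ||
      any(rec$count < 0))
    return("counts must be finite and non-negative")
  key <- paste(rec$site, rec$taxon, rec$assemblage, rec$season, sep = "\r")
  if (anyDuplicated(key))
    return("duplicate (site, taxon, assemblage, season) keys")
  tax <- unique(rec[, c("taxon", "class", "phylum")])
  if (anyDuplicated(tax$taxon)) {
    bad <- tax$taxon[duplicated(tax$taxon)][1L]
    return(sprintf("taxon '%s' maps to more than one (class, phylum)", bad))
  }
  for (a in unique(rec$assemblage)) {
    if (!any(rec$count[rec$assemblage == a] > 0))
      return(sprintf("assemblage '%s' has no positive counts", a))
  }
  TRUE
})

#' Skeletal-element catalog
#'
#' Maps taxa (or higher groups) to the number of skeletal elements
#' estimated to be contained within a single live individual, used to
#' convert death-assemblage element counts to individuals.  Lookup
#' resolution order is taxon > class > phylum > global default (1).
#'
#' @slot byTaxon named numeric vector of per-taxon values (all >= 1).
#' @slot byClass named numeric vector of per-class values.
#' @slot byPhylum named numeric vector of per-phylum values.
#' @slot default numeric(1), the global fallback (1).
#'
#' @seealso [readElementCatalog()], [elementCorrect()]
#' @export
setClass("ElementCatalog",
         slots = c(byTaxon = "numeric", byClass = "numeric",
                   byPhylum = "numeric", default = "numeric"))

setValidity("ElementCatalog", function(object) {
  vals <- c(object@byTaxon, object@byClass, object@byPhylum,
            object@default)
  if (any(!is.finite(vals)) || any(vals < 1))
    return("all elements-per-individual values must be finite and >= 1")
  if (length(object@default) != 1L)
    return("default must be a single value")
  TRUE
})

#' Site-by-taxon community matrix for one assemblage
#'
#' A non-negative abundance grid (sites as rows, taxa as columns) for one
#' assemblage, together with the taxonomy map and a provenance stage flag
#' (`raw`, `element_corrected` or `standardized`).
#'
#' @slot abundance numeric matrix, sites x taxa, with dimnames.
#' @slot taxonomy `data.frame` with columns `taxon`, `class`, `phylum`,
#'   one row per column of `abundance`.
#' @slot assemblage `"live"` or `"dead"`.
#' @slot stage one of `"raw"`, `"element_corrected"`, `"standardized"`.
#' @slot flaggedSites character vector of sites whose row total dropped to
#'   zero during taxon subsetting (kept, not silently dropped).
#'
#' @seealso [toMatrix()], [elementCorrect()], [subsetTaxa()]
#' @export
setClass("CommunityMatrix",
         slots = c(abundance = "matrix", taxonomy = "data.frame",
                   assemblage = "character", stage = "character",
                   flaggedSites = "character"))

setValidity("CommunityMatrix", function(object) {
  ab <- object@abundance
  if (is.null(rownames(ab)) || is.null(colnames(ab)))
    return("abundance matrix needs site and taxon dimnames")
  if (!is.numeric(ab) || any(!is.finite(ab)))
    return("abundances must be finite numerics")
  if (any(ab < 0))
    return("abundances must be non-negative")
  if (!identical(sort(colnames(ab)), sort(object@taxonomy$taxon)))
    return("taxonomy must cover exactly the matrix columns")
  if (!object@assemblage %in% c("live", "dead"))
    return("assemblage must be 'live' or 'dead'")
  if (!object@stage %in% c("raw", "element_corrected", "standardized"))
    return("stage must be raw, element_corrected or standardized")
  TRUE
})

#' Aligned live and dead abundance vectors
#'
#' One live-dead comparison at site or regional scope: both vectors are
#' indexed by the union taxon list and carry positive totals.
#'
#' @slot scope `"site"` or `"region"`.
#' @slot siteId the site id (`NA` for regional scope).
#' @slot taxa union taxon list.
#' @slot live,dead non-negative abundance vectors over `taxa`.
#'
#' @seealso [makePairs()], [livedeadFidelity()]
#' @export
setClass("LiveDeadPair",
         slots = c(scope = "character", siteId = "character",
                   taxa = "character", live = "numeric", dead = "numeric"))

setValidity("LiveDeadPair", function(object) {
  if (!object@scope %in% c("site", "region"))
    return("scope must be 'site' or 'region'")
  n <- length(object@taxa)
  if (length(object@live) != n || length(object@dead) != n)
    return("live/dead vectors must match the taxon list length")
  if (any(object@live < 0) || any(object@dead < 0))
    return("abundances must be non-negative")
  if (sum(object@live) <= 0 || sum(object@dead) <= 0)
    return("both assemblages need a positive total")
  TRUE
})

#' Rarefaction standardization plan
#'
#' Describes how a live-dead pair is standardized by rarefaction: the
#' target sample size (the smaller of the two totals unless set), the
#' number of Monte-Carlo replicates, the master seed, and the mode.
#'
#' @slot targetN target number of individuals (`NA` means "use the
#'   smaller total of each pair").
#' @slot reps number of Monte-Carlo subsampling replicates (>= 1).
#' @slot seed integer master seed; per-site, per-replicate streams are
#'   derived from it so site order never changes results.
#' @slot mode `"monte_carlo"` (subsampling) or `"analytic_richness"`
#'   (Hurlbert expectation, replicate-free, richness only).
#'
#' @export
setClass("StandardizationPlan",
         slots = c(targetN = "numeric", reps = "numeric",
                   seed = "numeric", mode = "character"))

setValidity("StandardizationPlan", function(object) {
  if (object@reps < 1) return("reps must be >= 1")
  if (!object@mode %in% c("monte_carlo", "analytic_richness"))
    return("mode must be 'monte_carlo' or 'analytic_richness'")
  if (!is.na(object@targetN) && object@targetN < 1)
    return("targetN must be >= 1")
  TRUE
})

#' Fidelity statistics for one live-dead comparison
#'
#' The three fidelity statistics (Spearman rho of proportional rank
#' abundance, Pearson r, Bray-Curtis similarity), with sample sizes,
#' optional BCa bootstrap confidence intervals and p-values.
#'
#' @slot scope,group labels for the comparison.
#' @slot rho,r,brayCurtis the three statistics (replicate means when the
#'   pair was standardized by Monte-Carlo rarefaction).
#' @slot nLive,nDead totals entering the comparison.
#' @slot nTaxa number of union taxa present after standardization.
#' @slot ciRho,ciR,ciBC numeric(2) `(lo, hi)` intervals (`NA` when absent).
#' @slot pRho,pR two-sided p-values (`NA` when not computed).
#'
#' @export
setClass("FidelityResult",
         slots = c(scope = "character", group = "character",
                   rho = "numeric", r = "numeric", brayCurtis = "numeric",
                   nLive = "numeric", nDead = "numeric", nTaxa = "numeric",
                   ciRho = "numeric", ciR = "numeric", ciBC = "numeric",
                   pRho = "numeric", pR = "numeric"))

setValidity("FidelityResult", function(object) {
  chk <- function(v, lo, hi)
    length(v) == 1L && (is.na(v) || (v >= lo - 1e-9 && v <= hi + 1e-9))
  if (!chk(object@rho, -1, 1)) return("rho outside [-1, 1]")
  if (!chk(object@r, -1, 1)) return("r outside [-1, 1]")
  if (!chk(object@brayCurtis, 0, 1)) return("brayCurtis outside [0, 1]")
  for (ci in list(object@ciRho, object@ciR, object@ciBC)) {
    if (length(ci) != 2L) return("CIs must be length-2 (lo, hi)")
    if (!any(is.na(ci)) && ci[1] > ci[2] + 1e-12)
      return("CI endpoints must be ordered lo <= hi")
  }
  TRUE
})

#' Randomization null distribution of a fidelity statistic
#'
#' The distribution of a statistic under perfect fidelity: live and dead
#' samples drawn as a random partition of the pooled species-abundance
#' distribution at the original sample sizes.
#'
#' @slot statistic `"rho"`, `"r"` or `"bray_curtis"`.
#' @slot replicates the B replicate values.
#' @slot observed the observed statistic.
#' @slot quantiles named numeric for the 0.025, 0.5 and 0.975 quantiles.
#' @slot expectedMean mean of the replicates (the expected value of the
#'   statistic under perfect fidelity at these sample sizes).
#'
#' @seealso [perfectFidelityNull()], [samplingEffectReport()]
#' @export
setClass("NullDistribution",
         slots = c(statistic = "character", replicates = "numeric",
                   observed = "numeric", quantiles = "numeric",
                   expectedMean = "numeric"))

setValidity("NullDistribution", function(object) {
  q <- object@quantiles
  if (!all(c("2.5%", "50%", "97.5%") %in% names(q)))
    return("quantiles must be named 2.5%, 50%, 97.5%")
  if (is.unsorted(q[c("2.5%", "50%", "97.5%")]))
    return("quantiles must be ordered")
  TRUE
})

#' Premortem / postmortem multivariate dispersion decomposition
#'
#' Result of the modified homogeneity-of-multivariate-dispersions (HMD)
#' analysis: per-site live-assemblage distances to the live centroid
#' (premortem variation) and death-assemblage distances to the same live
#' centroid (total live-dead variation), the overdispersion magnitude,
#' its permutation p-value, and the premortem proportion.
#'
#' @slot metric `"jaccard"` or `"bray_curtis"`.
#' @slot perSite `data.frame` with columns `site`, `d_premortem`,
#'   `d_total`.
#' @slot meanPremortem,meanTotal,overdispersion,proportionPremortem
#'   summary statistics (overdispersion = meanTotal - meanPremortem;
#'   proportionPremortem = meanPremortem / meanTotal).
#' @slot pValue one-sided permutation p for overdispersion > 0.
#' @slot nSites number of paired sites.
#' @slot permutations number of label permutations used.
#'
#' @seealso [livedeadDispersion()], [classifySites()]
#' @export
setClass("DispersionResult",
         slots = c(metric = "character", perSite = "data.frame",
                   meanPremortem = "numeric", meanTotal = "numeric",
                   overdispersion = "numeric",
                   proportionPremortem = "numeric",
                   pValue = "numeric", nSites = "numeric",
                   permutations = "numeric"))

setValidity("DispersionResult", function(object) {
  ps <- object@perSite
  if (!all(c("site", "d_premortem", "d_total") %in% names(ps)))
    return("perSite needs columns site, d_premortem, d_total")
  if (any(ps$d_premortem < 0) || any(ps$d_total < 0))
    return("distances must be non-negative")
  TRUE
})

#' Configuration of the forward taphonomic simulator
#'
#' Defines a synthetic study: a species pool partitioned into higher-taxon
#' groups (each with a species share, a per-individual preservation
#' probability and a number of skeletal elements per individual), a
#' log-normal species-abundance distribution, site-to-site compositional
#' heterogeneity, a time-averaging window with compositional turnover,
#' and sampling intensities for the live and dead assemblages.
#'
#' @slot nSpecies number of species in the pool.
#' @slot groups `data.frame` with columns `group`, `phylum`, `class`,
#'   `share` (species shares summing to 1), `preservation` (per-individual
#'   survival probability in `[0, 1]`), `elements` (skeletal elements per
#'   individual, >= 1).
#' @slot sadShape log-normal sigma of the species-abundance distribution.
#' @slot nSites number of localities.
#' @slot liveNPerSite live individuals sampled per site.
#' @slot deadNMultiplier dead individuals drawn per site as a multiple of
#'   `liveNPerSite` (before preservation thinning).
#' @slot betaConc Dirichlet concentration controlling site-to-site
#'   compositional heterogeneity (larger = more homogeneous).
#' @slot tSteps length of the time-averaging window (>= 1).
#' @slot turnoverRate per-step compositional drift in `[0, 1]`.
#' @slot timeWeights `"uniform"` or `"exp_decay"` weighting of the
#'   time-averaged mixture.
#' @slot seed integer master seed.
#'
#' @seealso [taphonomicConfig()], [generateStudy()]
#' @export
setClass("TaphonomicConfig",
         slots = c(nSpecies = "numeric", groups = "data.frame",
                   sadShape = "numeric", nSites = "numeric",
                   liveNPerSite = "numeric", deadNMultiplier = "numeric",
                   betaConc = "numeric", tSteps = "numeric",
                   turnoverRate = "numeric", timeWeights = "character",
                   seed = "numeric"))

setValidity("TaphonomicConfig", function(object) {
  g <- object@groups
  need <- c("group", "phylum", "class", "share", "preservation", "elements")
  if (!all(need %in% names(g)))
    return(paste("groups needs columns", paste(need, collapse = ", ")))
  if (abs(sum(g$share) - 1) > 1e-8)
    return("group species shares must sum to 1")
  if (any(g$preservation < 0 | g$preservation > 1))
    return("preservation probabilities must lie in [0, 1]")
  if (any(g$elements < 1))
    return("elements per individual must be >= 1")
  if (object@nSpecies < nrow(g))
    return("nSpecies must be at least the number of groups")
  if (object@deadNMultiplier < 1) return("deadNMultiplier must be >= 1")
  if (object@betaConc <= 0) return("betaConc must be > 0")
  if (object@tSteps < 1) return("tSteps must be >= 1")
  if (object@turnoverRate < 0 || object@turnoverRate > 1)
    return("turnoverRate must lie in [0, 1]")
  if (!object@timeWeights %in% c("uniform", "exp_decay"))
    return("timeWeights must be 'uniform' or 'exp_decay'")
  TRUE
})

#' Ground truth of a synthetic study
#'
#' The latent state behind a simulated dataset: the configuration, the
#' species pool (group assignment and base relative abundances) and each
#' site's latent composition history (one row per time step, rows sum
#' to 1).
#'
#' @slot config the [TaphonomicConfig-class] used.
#' @slot pool `data.frame` with columns `taxon`, `group`, `class`,
#'   `phylum`, `base` (base relative abundance).
#' @slot compositions named list (one per site) of tSteps x nSpecies
#'   latent relative-abundance matrices.
#'
#' @export
setClass("SyntheticTruth",
         slots = c(config = "TaphonomicConfig", pool = "data.frame",
                   compositions = "list"))

setValidity("SyntheticTruth", function(object) {
  ok <- vapply(object@compositions, function(m)
    all(abs(rowSums(m) - 1) < 1e-6), logical(1))
  if (!all(ok)) return("latent composition rows must sum to 1")
  TRUE
})
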