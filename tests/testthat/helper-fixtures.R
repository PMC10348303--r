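# shared builders for small in-code fixtures

toyRecords <- function() {
  data.frame(
    site = c("S1", "S1", "S1", "S1", "S2", "S2", "S2"),
    taxon = c("a", "b", "a", "b", "b", "a", "b"),
    class = c("Bivalvia", "Gastropoda", "Bivalvia", "Gastropoda",
              "Gastropoda", "Bivalvia", "Gastropoda"),
    phylum = "Mollusca",
    assemblage = c("live", "live", "dead", "dead", "live", "dead",
                   "dead"),
    count = c(3, 1, 10, 2, 4, 6, 1),
    stringsAsFactors = FALSE)
}

toyMatrix <- function(ab, assemblage = "live", stage = "raw",
                      phylum = NULL, class = NULL) {
  taxa <- colnames(ab)
  if (is.null(phylum)) phylum <- rep("Mollusca", length(taxa))
  if (is.null(class)) class <- rep("Bivalvia", length(taxa))
  taxonomy <- data.frame(taxon = taxa, class = class, phylum = phylum,
                         stringsAsFactors = FALSE)
  taphofidelity:::newCommunityMatrix(ab, taxonomy, assemblage, stage)
}

# paired live/dead matrices over shared sites and taxa
toyPairedMatrices <- function(live_ab, dead_ab, ...) {
  list(live = toyMatrix(live_ab, "live", ...),
       dead = toyMatrix(dead_ab, "dead", ...))
}

regionalPhyla <- function()
  read.csv(system.file("extdata", "onslow_phyla.csv",
                       package = "taphofidelity"))

regionalClasses <- function()
  read.csv(system.file("extdata", "onslow_classes.csv",
                       package = "taphofidelity"))

# small simulator configuration for fast stochastic tests
smallConfig <- function(seed = 11, ...) {
  args <- list(nSpecies = 40, nSites = 12, liveNPerSite = 120,
               deadNMultiplier = 4, tSteps = 5, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(taphonomicConfig, args)
}

# effect-free setting for the mollusc-surrogacy diversity null: uniform
# perfect preservation, mild time-averaging, and a mollusc-dominated
# fauna (as in real shallow-shelf death assemblages) so the mollusc
# subset is not structurally poorer than the whole community
molluscDominatedConfig <- function(seed) {
  g <- defaultGroupSpec()
  g$share <- ifelse(g$phylum == "Mollusca", 0, g$share)
  g$share <- g$share / sum(g$share) * 0.05
  g$share[g$class == "Bivalvia"] <- 0.47
  g$share[g$class == "Gastropoda"] <- 0.47
  g$share[g$class == "Scaphopoda"] <- 0.01
  g$preservation <- 1
  taphonomicConfig(nSpecies = 40, groups = g, nSites = 12,
                   liveNPerSite = 120, deadNMultiplier = 4,
                   tSteps = 2, turnoverRate = 0.02, seed = seed)
}

# uniform-preservation variant: every group survives with probability p
uniformPreservation <- function(config, p = 1) {
  g <- config@groups
  g$preservation <- p
  taphonomicConfig(nSpecies = config@nSpecies, groups = g,
                   sadShape = config@sadShape, nSites = config@nSites,
                   liveNPerSite = config@liveNPerSite,
                   deadNMultiplier = config@deadNMultiplier,
                   betaConc = config@betaConc, tSteps = config@tSteps,
                   turnoverRate = config@turnoverRate,
                   timeWeights = config@timeWeights, seed = config@seed)
}

simulateTables <- function(config) {
  pool <- makeSpeciesPool(config)
  lv <- simulateLive(pool, config)
  dd <- simulateDeath(lv$truth, config)
  list(live_table = lv$table, dead_table = dd, truth = lv$truth,
       pool = pool)
}

# matrices (dead element-corrected + integerized) from a config
simulateMatrices <- function(config) {
  sim <- simulateTables(config)
  g <- config@groups
  catal <- elementCatalog(class = setNames(g$elements, g$class))
  live <- toMatrix(sim$live_table, "live")
  dead <- toMatrix(sim$dead_table, "dead")
  dead <- integerize(elementCorrect(dead, catal))
  list(live = live, dead = dead, truth = sim$truth)
}
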