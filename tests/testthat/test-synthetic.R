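test_that("species pool allocation and abundances behave", {
  g <- data.frame(group = c("g1", "g2"), phylum = c("P1", "P2"),
                  class = c("C1", "C2"), share = c(0.5, 0.5),
                  preservation = c(1, 1), elements = c(1, 1))
  cfg <- taphonomicConfig(nSpecies = 10, groups = g, seed = 1)
  pool <- makeSpeciesPool(cfg)
  expect_equal(as.integer(table(pool$group)[c("g1", "g2")]), c(5L, 5L))
  expect_equal(sum(pool$base), 1)
  # degenerate SAD: equal base abundances within group
  cfg0 <- taphonomicConfig(nSpecies = 10, groups = g, sadShape = 0,
                           seed = 1)
  pool0 <- makeSpeciesPool(cfg0)
  expect_equal(var(pool0$base[pool0$group == "g1"]), 0)
  # log-normal SAD: concave rank-abundance curve on log scale
  cfgL <- taphonomicConfig(seed = 2)
  poolL <- makeSpeciesPool(cfgL)
  lr <- log(sort(poolL$base, decreasing = TRUE))
  third <- floor(length(lr) / 3)
  slope_head <- (lr[third] - lr[1]) / (third - 1)
  slope_tail <- (lr[length(lr)] - lr[length(lr) - third + 1]) /
    (third - 1)
  expect_lt(slope_tail, slope_head)
  expect_error(taphonomicConfig(nSpecies = 1), "at least")
})

test_that("live simulation respects totals, determinism and limits", {
  cfg <- smallConfig(seed = 21)
  pool <- suppressWarnings(makeSpeciesPool(cfg))
  lv <- simulateLive(pool, cfg)
  rec <- occurrenceRecords(lv$table)
  expect_equal(sum(rec$count), cfg@nSites * cfg@liveNPerSite)
  expect_true(all(rec$assemblage == "live"))
  # determinism
  lv2 <- simulateLive(pool, cfg)
  expect_identical(occurrenceRecords(lv$table),
                   occurrenceRecords(lv2$table))
  # turnover 0: latent composition constant over time
  cfg0 <- smallConfig(seed = 22, turnoverRate = 0)
  t0 <- simulateLive(suppressWarnings(makeSpeciesPool(cfg0)), cfg0)$truth
  h <- t0@compositions[[1]]
  expect_equal(h[1, ], h[nrow(h), ])
  # concentration limit: sites converge to the base composition
  cfg_inf <- smallConfig(seed = 23, betaConc = 1e7, turnoverRate = 0)
  pool_inf <- suppressWarnings(makeSpeciesPool(cfg_inf))
  tr <- simulateLive(pool_inf, cfg_inf)$truth
  c1 <- tr@compositions[[1]][1, ]; c2 <- tr@compositions[[2]][1, ]
  expect_lt(sum(abs(c1 - c2)) / 2, 0.02)
})

test_that("death simulation thins, multiplies elements, conserves", {
  g <- data.frame(group = c("robust", "fragile"),
                  phylum = c("Mollusca", "Arthropoda"),
                  class = c("Bivalvia", "Malacostraca"),
                  share = c(0.5, 0.5), preservation = c(1, 0),
                  elements = c(2, 3))
  cfg <- taphonomicConfig(nSpecies = 20, groups = g, nSites = 4,
                          liveNPerSite = 200, deadNMultiplier = 3,
                          seed = 31)
  pool <- makeSpeciesPool(cfg)
  lv <- simulateLive(pool, cfg)
  dd <- simulateDeath(lv$truth, cfg)
  rec <- occurrenceRecords(dd)
  # zero-preservation group absent from every dead table
  expect_false(any(rec$phylum == "Arthropoda"))
  # elements are an exact multiple of thinned individuals
  expect_true(all(rec$count %% 2 == 0))
  # element correction recovers individual counts exactly
  dm <- toMatrix(dd, "dead")
  corr <- elementCorrect(dm, elementCatalog(class = c(Bivalvia = 2,
                                                      Malacostraca = 3)))
  expect_true(all(abs(abundances(corr) -
                        round(abundances(corr))) < 1e-9))
  expect_error(simulateDeath(lv$truth,
                             taphonomicConfig(nSpecies = 20,
                                              groups = transform(
                                                g,
                                                preservation = 0),
                                              nSites = 4, seed = 31)),
               "preservation")
})

test_that("generateStudy writes a deterministic pipeline-ready bundle", {
  cfg <- smallConfig(seed = 41)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  out1 <- suppressWarnings(generateStudy(cfg, d1))
  out2 <- suppressWarnings(generateStudy(cfg, d2))
  # byte-identical files under a fixed seed
  for (f in c("occurrences.csv", "element_catalog.csv", "truth.json"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  occ <- readOccurrences(file.path(d1, "occurrences.csv"))
  rec <- occurrenceRecords(occ)
  expect_true(all(unique(rec$phylum) %in% cfg@groups$phylum))
})

test_that("the default study configuration matches the target scale", {
  d <- withr::local_tempdir()
  generateStudy(taphonomicConfig(), d)
  rec <- occurrenceRecords(readOccurrences(file.path(d,
                                                     "occurrences.csv")))
  live_total <- sum(rec$count[rec$assemblage == "live"])
  dead_total <- sum(rec$count[rec$assemblage == "dead"])
  # live around 9e3 individuals, dead element counts several-fold larger
  expect_equal(live_total, 52 * 170)
  expect_gte(dead_total / live_total, 4)
  # all six configured phyla appear in the output table
  expect_equal(length(unique(rec$phylum)), 6)
  expect_equal(length(unique(rec$class)), 11)
})

test_that("live-dead rank fidelity degrades with preservation bias", {
  mean_rho <- vapply(c(0, 0.3, 0.6, 0.9), function(b) {
    rhos <- vapply(1:4, function(rep) {
      g <- defaultGroupSpec()
      g$preservation <- 1
      g$preservation[g$phylum != "Mollusca"] <- 1 - b
      cfg <- taphonomicConfig(nSpecies = 50, groups = g, nSites = 10,
                              liveNPerSite = 120, deadNMultiplier = 4,
                              tSteps = 3, seed = 500 + rep)
      mats <- suppressWarnings(simulateMatrices(cfg))
      pairs <- makePairs(mats$live, mats$dead, "site")
      plan <- standardizationPlan(reps = 10, seed = rep)
      mean(vapply(pairs, function(p)
        livedeadFidelity(p, plan)@rho, numeric(1)))
    }, numeric(1))
    mean(rhos)
  }, numeric(1))
  expect_true(all(diff(mean_rho) < 0))
})

test_that("time-averaging inflates death-assemblage evenness", {
  # pronounced turnover over a long window mixes successive community
  # states, evening out the time-averaged composition; compared at equal
  # sample size (dead subsampled to the live n) so that the dead
  # assemblage's richness inflation does not mask the effect through
  # the ln S denominator of Pielou's J
  higher <- 0L
  n_sim <- 15L
  for (i in seq_len(n_sim)) {
    cfg <- uniformPreservation(
      smallConfig(seed = 700 + i, tSteps = 15, turnoverRate = 0.5,
                  betaConc = 15),
      p = 1)
    mats <- suppressWarnings(simulateMatrices(cfg))
    j_live <- mean(apply(abundances(mats$live), 1, function(v)
      diversityIndices(v)$J), na.rm = TRUE)
    j_dead <- mean(vapply(siteNames(mats$dead), function(s) {
      v <- round(abundances(mats$dead)[s, ])
      m <- min(sum(v), cfg@liveNPerSite)
      diversityIndices(subsampleCounts(v, m, seed = i))$J
    }, numeric(1)), na.rm = TRUE)
    if (j_dead >= j_live) higher <- higher + 1L
  }
  expect_gte(higher / n_sim, 0.8)
})
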