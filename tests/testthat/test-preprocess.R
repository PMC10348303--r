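test_that("element correction divides by elements per individual", {
  ab <- matrix(c(10, 1, 7), 1, 3,
               dimnames = list("S1", c("valve_sp", "spine_sp",
                                       "plain_sp")))
  m <- toyMatrix(ab, "dead",
                 class = c("Bivalvia", "Echinoidea", "Gastropoda"))
  catal <- elementCatalog(class = c(Bivalvia = 2, Echinoidea = 50))
  corr <- elementCorrect(m, catal)
  expect_equal(unname(abundances(corr)[1, ]), c(5, 0.02, 7))
  expect_equal(analysisStage(corr), "element_corrected")
  # refuse double correction; live needs force
  expect_error(elementCorrect(corr, catal), "twice")
  lv <- toyMatrix(ab, "live", class = c("Bivalvia", "Echinoidea",
                                        "Gastropoda"))
  expect_error(elementCorrect(lv, catal), "force")
  expect_s4_class(elementCorrect(lv, catal, force = TRUE),
                  "CommunityMatrix")
  # multiplying back by the catalog values reproduces raw counts
  div <- c(2, 50, 1)
  expect_equal(sweep(abundances(corr), 2, div, "*"), ab)
})

test_that("integerize modes preserve or drop observed taxa as stated", {
  ab <- matrix(c(0.02, 5.4, 2.5), 1, 3,
               dimnames = list("S1", c("a", "b", "c")))
  m <- toyMatrix(ab, "dead", stage = "element_corrected")
  expect_equal(unname(abundances(integerize(m))[1, ]), c(1, 5, 3))
  expect_equal(unname(abundances(integerize(m, "round"))[1, ]),
               c(0, 5, 3))
  expect_message(fl <- integerize(m, "floor"), "dropped")
  expect_equal(unname(abundances(fl)[1, ]), c(0, 5, 2))
  raw <- toyMatrix(ab, "dead", stage = "raw")
  expect_error(integerize(raw), "element-corrected")
})

test_that("filterSites applies the either/both/combined rules", {
  # S1: live 40 / dead 900; S2: live 100 / dead 30; S3: live 100 / 900
  sites <- c("S1", "S2", "S3")
  lv2 <- toyMatrix(matrix(c(40, 100, 100), 3, 1,
                          dimnames = list(sites, "a")))
  dv2 <- toyMatrix(matrix(c(900, 30, 900), 3, 1,
                          dimnames = list(sites, "a")), "dead")
  either <- filterSites(lv2, dv2, minN = 50, rule = "either")
  expect_equal(either$report$removed, c(TRUE, TRUE, FALSE))
  expect_equal(siteNames(either$live), "S3")
  both <- filterSites(lv2, dv2, minN = 50, rule = "both")
  expect_equal(both$report$removed, c(FALSE, FALSE, FALSE))
  comb <- filterSites(lv2, dv2, minN = 50, rule = "combined")
  expect_equal(comb$report$removed, c(FALSE, FALSE, FALSE))
  none <- filterSites(lv2, dv2, minN = 1)
  expect_equal(sum(none$report$removed), 0)
  expect_error(filterSites(lv2, dv2, minN = 5000), "all sites")
})

test_that("filterSites is monotone in the threshold", {
  set.seed(42)
  ab_l <- matrix(rpois(60, 30), 10, 6,
                 dimnames = list(paste0("S", 1:10), paste0("t", 1:6)))
  ab_d <- matrix(rpois(60, 80), 10, 6,
                 dimnames = list(paste0("S", 1:10), paste0("t", 1:6)))
  lv <- toyMatrix(ab_l); dv <- toyMatrix(ab_d, "dead")
  prev <- siteNames(lv)
  for (n in c(50, 150, 200)) {
    kept <- tryCatch(
      siteNames(filterSites(lv, dv, minN = n)$live),
      error = function(e) character())
    expect_true(all(kept %in% prev))
    prev <- kept
  }
})

test_that("subsetTaxa splits molluscs and flags emptied sites", {
  ab <- matrix(c(3, 0, 1, 0, 0, 5), 2, 3,
               dimnames = list(c("S1", "S2"), c("m1", "m2", "crab")))
  m <- toyMatrix(ab, phylum = c("Mollusca", "Mollusca", "Arthropoda"),
                 class = c("Bivalvia", "Gastropoda", "Malacostraca"))
  mol <- subsetTaxa(m, "molluscs")
  expect_setequal(taxonNames(mol), c("m1", "m2"))
  expect_equal(mol@flaggedSites, "S2")
  non <- subsetTaxa(m, "non_molluscs")
  expect_setequal(taxonNames(non), "crab")
  expect_identical(abundances(subsetTaxa(m, "all")), ab)
  expect_error(subsetTaxa(m, "gastropods_only"), "unknown")
  pred <- subsetTaxa(m, function(tax) tax$class == "Gastropoda")
  expect_setequal(taxonNames(pred), "m2")
})

test_that("aggregateRank conserves abundance and bounds richness", {
  ab <- matrix(c(3, 1, 2, 0, 0, 4), 2, 3,
               dimnames = list(c("S1", "S2"), c("a", "b", "c")))
  m <- toyMatrix(ab, phylum = c("Mollusca", "Mollusca", "Annelida"),
                 class = c("Bivalvia", "Gastropoda", "Polychaeta"))
  byp <- aggregateRank(m, "phylum")
  expect_equal(sum(byp$abundance), sum(ab))
  expect_equal(unname(byp$abundance[, "Mollusca"]), c(5, 1))
  expect_equal(unname(byp$richness[, "Mollusca"]), c(2, 1))
  expect_true(all(rowSums(byp$richness) <= rowSums(ab > 0)))
  # single-species matrix: one higher taxon, richness 1
  single <- toyMatrix(matrix(5, 1, 1, dimnames = list("S1", "a")))
  agg <- aggregateRank(single, "class")
  expect_equal(dim(agg$richness), c(1, 1))
  expect_equal(unname(agg$richness[1, 1]), 1)
  # unresolved rank errors with the taxon name
  bad <- toyMatrix(ab, phylum = c("Mollusca", "", "Annelida"))
  expect_error(aggregateRank(bad, "phylum"), "b")
})

test_that("poolRegional returns column sums with order preserved", {
  ab <- matrix(c(3, 0, 1, 4, 0, 0), 2, 3,
               dimnames = list(c("S1", "S2"), c("a", "b", "z")))
  m <- toyMatrix(ab)
  expect_equal(poolRegional(m), c(a = 3, b = 5, z = 0))
  one <- toyMatrix(ab[1, , drop = FALSE])
  expect_equal(poolRegional(one), ab[1, ])
})
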