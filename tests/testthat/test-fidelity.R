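test_that("pearson correlation reproduces the regional richness values", {
  ph <- regionalPhyla()
  ld <- pearsonR(ph$live_s, ph$dead_s)
  expect_equal(ld$r, 0.91, tolerance = 0.005)
  expect_equal(ld$p, 0.01, tolerance = 0.5)
  nn <- pearsonR(ph$dead_n, ph$dead_s)
  expect_equal(nn$r, 0.99, tolerance = 0.005)
  # affine invariance and error cases
  x <- c(1, 4, 2, 7, 5)
  expect_equal(pearsonR(x, 2 * x + 3)$r, 1)
  expect_error(pearsonR(x, rep(1, 5)), "zero variance")
  expect_error(pearsonR(1:3, 1:4), "equal length")
})

test_that("spearman rho uses exact permutation p at small n", {
  ph <- regionalPhyla()
  sp <- spearmanRho(ph$live_s, ph$dead_s)
  expect_equal(sp$rho, 1)
  expect_equal(sp$p, 2 / 720)       # exact two-sided, n = 6
  expect_equal(spearmanRho(c(1, 2, 3), c(3, 2, 1))$rho, -1)
  # agreement with cor.test's exact AS89 distribution at small n
  set.seed(4)
  for (i in 1:5) {
    x <- rnorm(7); y <- rnorm(7)
    mine <- spearmanRho(x, y)
    ref <- cor.test(x, y, method = "spearman", exact = TRUE)
    expect_equal(mine$rho, unname(ref$estimate))
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  }
  # invariance under strictly monotone transforms
  x <- c(0.3, 2, 5, 1, 9, 4, 7, 6, 8, 2.5, 0.1)
  y <- c(5, 1, 4, 2, 10, 3, 8, 7, 9, 6, 0.5)
  expect_equal(spearmanRho(exp(x), y)$rho, spearmanRho(x, y)$rho)
  expect_error(spearmanRho(x, rep(2, 11)), "rank variance")
})

test_that("class-level richness correlations handle ties", {
  cl <- regionalClasses()
  sp <- spearmanRho(cl$live_s, cl$dead_s)
  expect_equal(sp$rho, 0.79, tolerance = 0.005)
  pe <- pearsonR(cl$live_s, cl$dead_s)
  expect_equal(pe$r, 0.79, tolerance = 0.005)
  expect_equal(pe$p, 0.004, tolerance = 0.2)
})

test_that("bray-curtis matches hand computations and its bounds", {
  expect_equal(brayCurtis(c(0.5, 0.5, 0), c(0, 0.5, 0.5),
                          "dissimilarity"), 0.5)
  v <- c(3, 9, 1)
  expect_equal(brayCurtis(v, 5 * v), 1)  # proportional: identical
  expect_equal(brayCurtis(c(1, 0), c(0, 2)), 0)  # disjoint supports
  expect_error(brayCurtis(c(0, 0), c(1, 2)), "zero-total")
  set.seed(7)
  for (i in 1:10) {
    a <- rpois(6, 4); b <- rpois(6, 4)
    if (sum(a) == 0 || sum(b) == 0) next
    d <- brayCurtis(a, b, "dissimilarity")
    expect_gte(d, 0); expect_lte(d, 1)
    expect_equal(d, brayCurtis(b, a, "dissimilarity"))  # symmetric
  }
})

test_that("livedead fidelity is exact on degenerate pairs", {
  # dead an exact copy of live: all statistics perfect
  pair <- new("LiveDeadPair", scope = "site", siteId = "S1",
              taxa = letters[1:5], live = c(10, 5, 3, 2, 1),
              dead = c(10, 5, 3, 2, 1))
  fr <- livedeadFidelity(pair, standardizationPlan(reps = 2, seed = 1))
  expect_equal(fr@rho, 1)
  expect_equal(fr@brayCurtis, 1)
  # disjoint species lists: similarity 0, rho <= 0
  dis <- new("LiveDeadPair", scope = "site", siteId = "S1",
             taxa = letters[1:6], live = c(5, 3, 2, 0, 0, 0),
             dead = c(0, 0, 0, 5, 3, 2))
  fd <- livedeadFidelity(dis, plan = NULL)
  expect_equal(fd@brayCurtis, 0)
  expect_lte(fd@rho, 0)
  tiny <- new("LiveDeadPair", scope = "site", siteId = "S1",
              taxa = c("a", "b"), live = c(3, 1), dead = c(2, 2))
  expect_error(livedeadFidelity(tiny, plan = NULL), "3 union taxa")
})

test_that("standardized fidelity of exchangeable samples sits in the null", {
  # live and dead drawn independently from one multinomial: observed rho
  # should fall in the central mass of the perfect-fidelity null
  set.seed(21)
  probs <- as.numeric(rlnorm(20, 0, 1)); probs <- probs / sum(probs)
  live <- as.numeric(rmultinom(1, 500, probs))
  dead <- as.numeric(rmultinom(1, 500, probs))
  pair <- new("LiveDeadPair", scope = "region", siteId = NA_character_,
              taxa = sprintf("t%02d", 1:20), live = live, dead = dead)
  fr <- livedeadFidelity(pair, standardizationPlan(reps = 50, seed = 3))
  null <- perfectFidelityNull(pair, "rho", B = 400, seed = 4)
  expect_gte(fr@rho, unname(null@quantiles["2.5%"]) - 0.05)
  expect_lte(fr@rho, 1)
})

test_that("within-taxon summary mirrors regional table conventions", {
  sites <- paste0("S", 1:4)
  taxa <- c("biv1", "biv2", "gas1", "crab1", "rare1")
  tax_phy <- c("Mollusca", "Mollusca", "Mollusca", "Arthropoda",
               "Brachiopoda")
  tax_cls <- c("Bivalvia", "Bivalvia", "Gastropoda", "Malacostraca",
               "Lingulida")
  # mollusc richness varies across sites (2, 2, 3, 3)
  lv_ab <- cbind(biv1 = c(1, 2, 3, 4), biv2 = c(0, 1, 1, 2),
                 gas1 = c(1, 0, 2, 2), crab1 = c(1, 1, 1, 1),
                 rare1 = c(1, 0, 0, 0))
  rownames(lv_ab) <- sites
  # dead proportional to live for molluscs; brachiopod absent from dead
  dv_ab <- lv_ab * 2
  dv_ab[, "rare1"] <- 0
  lv <- toyMatrix(lv_ab, "live", phylum = tax_phy, class = tax_cls)
  dv <- toyMatrix(dv_ab, "dead", phylum = tax_phy, class = tax_cls)
  summ <- taxonFidelitySummary(lv, dv, "phylum")
  tab <- summ$correlations
  # dead = 2 x live: all within-taxon correlations are 1 where defined
  mol <- tab[tab$group == "Mollusca", ]
  expect_equal(mol$abundance_r, 1)
  expect_equal(mol$richness_rho, 1)
  expect_equal(mol$richness_r, 1)
  # higher taxon absent from dead -> missing entry, not an error
  bra <- tab[tab$group == "Brachiopoda", ]
  expect_true(is.na(bra$abundance_rho))
  expect_equal(bra$dead_s, 0)
  # arthropods have a single species -> missing too
  expect_true(is.na(tab[tab$group == "Arthropoda", "richness_r"]))
  # regional table conserves totals
  expect_equal(sum(summ$regional$live_n), sum(lv_ab))
})

test_that("two-site proportional abundance gives r = 1 within a taxon", {
  sites <- c("S1", "S2")
  lv <- toyMatrix(matrix(c(4, 1, 2, 3), 2, 2,
                         dimnames = list(sites, c("a", "b"))),
                  "live")
  dv <- toyMatrix(matrix(c(8, 2, 4, 6), 2, 2,
                         dimnames = list(sites, c("a", "b"))),
                  "dead")
  summ <- taxonFidelitySummary(lv, dv, "phylum")
  # only 2 sites: spearman/pearson need >= 3, so correlations are NA,
  # but the regional accounting is exact
  expect_equal(summ$regional$live_n, 10)
  expect_equal(summ$regional$dead_n, 20)
})

test_that("cross-taxon correlations reproduce the fixture table values", {
  ct <- crossTaxonCorrelations(regionalPhyla())
  rl <- ct[ct$comparison == "richness_live_dead", ]
  expect_equal(rl$rho, 1)
  expect_equal(rl$r, 0.91, tolerance = 0.005)
  ad <- ct[ct$comparison == "abundance_richness_dead", ]
  expect_equal(ad$r, 0.99, tolerance = 0.005)
  expect_error(crossTaxonCorrelations(data.frame(live_n = 1)),
               "needs columns")
})
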