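test_that("dissimilarity matrices match hand values and axioms", {
  ab <- matrix(c(1, 0, 1,   1, 1, 0,   1, 1, 0,   0, 1, 1), 3, 4,
               dimnames = list(c("S1", "S2", "S3"),
                               c("a", "b", "c", "d")))
  # S1 = {a,b,c}, S2 = {b,c,d} share 2 of 4: Jaccard 0.5
  dj <- dissimilarityMatrix(toyMatrix(ab), "jaccard")
  expect_equal(dj["S1", "S2"], 0.5)
  expect_equal(diag(dj), c(S1 = 0, S2 = 0, S3 = 0))
  # identical rows -> 0; disjoint presence -> 1
  ab2 <- rbind(S1 = c(2, 3, 0, 0), S2 = c(4, 6, 0, 0),
               S3 = c(0, 0, 1, 5))
  colnames(ab2) <- c("a", "b", "c", "d")
  db <- dissimilarityMatrix(toyMatrix(ab2), "bray_curtis")
  expect_equal(db["S1", "S2"], 0)  # proportional rows identical
  expect_equal(dissimilarityMatrix(toyMatrix(ab2), "jaccard")["S1",
                                                              "S3"], 1)
  empty <- rbind(S1 = c(1, 0), S2 = c(0, 0))
  colnames(empty) <- c("a", "b")
  expect_error(dissimilarityMatrix(toyMatrix(empty)), "S2")
  # symmetry and identity of indiscernibles on random inputs
  set.seed(16)
  r <- matrix(rpois(30, 3) + 1, 5, 6,
              dimnames = list(paste0("S", 1:5), paste0("t", 1:6)))
  for (metric in c("jaccard", "bray_curtis")) {
    d <- dissimilarityMatrix(toyMatrix(r), metric)
    expect_equal(d, t(d))
    expect_equal(unname(diag(d)), rep(0, 5))
  }
})

test_that("pcoa embedding is exact for metric inputs", {
  # equilateral: three points with all pairwise distances 1
  d3 <- matrix(1, 3, 3) - diag(3)
  dimnames(d3) <- list(paste0("P", 1:3), paste0("P", 1:3))
  emb <- pcoaEmbed(d3)
  expect_equal(ncol(emb$imaginary), 0)
  dd <- as.matrix(dist(emb$points))
  expect_equal(unname(dd), unname(d3), tolerance = 1e-9)
  # Euclidean input distances reproduced exactly
  set.seed(17)
  pts <- matrix(rnorm(12), 4, 3)
  de <- as.matrix(dist(pts))
  emb2 <- pcoaEmbed(de)
  expect_equal(unname(as.matrix(dist(emb2$points))), unname(de),
               tolerance = 1e-9)
  # agreement with cmdscale eigenvalues
  ref <- cmdscale(de, k = 2, eig = TRUE)
  expect_equal(sort(emb2$eigenvalues, decreasing = TRUE)[1:2],
               ref$eig[1:2], tolerance = 1e-8)
  asym <- d3; asym[1, 2] <- 0.5
  expect_error(pcoaEmbed(asym), "symmetric")
})

test_that("semi-metric jaccard inputs yield negative eigenvalues", {
  # four-point configuration violating the Euclidean embedding condition
  ab <- rbind(S1 = c(1, 1, 0, 0, 1, 1),
              S2 = c(0, 0, 1, 1, 1, 1),
              S3 = c(1, 0, 1, 0, 1, 0),
              S4 = c(0, 1, 0, 1, 0, 1))
  colnames(ab) <- paste0("t", 1:6)
  d <- dissimilarityMatrix(toyMatrix(ab), "jaccard")
  emb <- pcoaEmbed(d)
  expect_gt(sum(emb$eigenvalues < -1e-9), 0)
  expect_gt(ncol(emb$imaginary), 0)
})

test_that("identical live and dead matrices give zero overdispersion", {
  set.seed(18)
  ab <- matrix(rpois(40, 6) + 1, 5, 8,
               dimnames = list(paste0("S", 1:5), paste0("t", 1:8)))
  lv <- toyMatrix(ab, "live"); dv <- toyMatrix(ab, "dead")
  res <- livedeadDispersion(lv, dv, "bray_curtis", permutations = 99,
                            seed = 19)
  expect_equal(res@perSite$d_total, res@perSite$d_premortem,
               tolerance = 1e-8)
  expect_equal(res@overdispersion, 0, tolerance = 1e-8)
  expect_gt(res@pValue, 0.5)
  expect_error(livedeadDispersion(toyMatrix(ab[1:2, ], "live"),
                                  toyMatrix(ab[1:2, ], "dead"),
                                  "jaccard"),
               "3 paired")
})

test_that("strong differential preservation is detected as overdispersion", {
  detected <- 0L
  n_sim <- 20L
  for (i in seq_len(n_sim)) {
    g <- defaultGroupSpec()
    g$preservation <- 1
    g$preservation[g$group == "malacostracans"] <- 0.05
    cfg <- taphonomicConfig(nSpecies = 60, groups = g, nSites = 15,
                            liveNPerSite = 120, deadNMultiplier = 4,
                            tSteps = 5, seed = 300 + i)
    mats <- suppressWarnings(simulateMatrices(cfg))
    res <- livedeadDispersion(mats$live, mats$dead, "bray_curtis",
                              permutations = 99, seed = i)
    if (res@overdispersion > 0 && res@pValue < 0.05)
      detected <- detected + 1L
  }
  expect_gte(detected / n_sim, 0.9)
})

test_that("premortem proportion falls as postmortem bias grows", {
  props <- vapply(c(0, 0.3, 0.6, 0.9), function(b) {
    g <- defaultGroupSpec()
    g$preservation <- 1
    g$preservation[g$phylum != "Mollusca"] <- 1 - b
    cfg <- taphonomicConfig(nSpecies = 60, groups = g, nSites = 15,
                            liveNPerSite = 150, deadNMultiplier = 4,
                            tSteps = 5, seed = 77)
    mats <- suppressWarnings(simulateMatrices(cfg))
    livedeadDispersion(mats$live, mats$dead, "bray_curtis",
                       permutations = 49,
                       seed = 78)@proportionPremortem
  }, numeric(1))
  expect_true(all(diff(props) < 0))
})

test_that("site classification respects the agreement band", {
  ps <- data.frame(site = c("A", "B", "C"),
                   d_premortem = c(0.2, 0.2, 0.5),
                   d_total = c(0.2, 0.5, 0.3))
  res <- new("DispersionResult", metric = "jaccard", perSite = ps,
             meanPremortem = 0.3, meanTotal = 0.33,
             overdispersion = 0.03, proportionPremortem = 0.9,
             pValue = 0.2, nSites = 3, permutations = 99)
  lab <- classifySites(res, band = 0.1)
  expect_equal(lab$label, c("within_agreement", "overdispersed",
                            "underdispersed"))
  expect_equal(classifySites(res, band = 0)$label[1],
               "within_agreement")
  expect_true(all(classifySites(res, band = 10)$label ==
                    "within_agreement"))
  expect_error(classifySites(res, band = -1), ">= 0")
})
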