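## all permutations of 1..n as an (n!) x n matrix (used for exact
## Spearman p at small n)
allPermutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- allPermutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (k in seq_len(n)) {
    rows <- (k - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- k
    shifted <- sub
    shifted[sub >= k] <- shifted[sub >= k] + 1L
    out[rows, -1L] <- shifted
  }
  out
}

#' Pearson product-moment correlation with two-sided p
#'
#' Standard Pearson correlation with the two-sided p-value from the
#' t-transform.  Zero variance in either argument is an error, not a
#' silent zero.
#'
#' @param x,y equal-length numeric vectors (length >= 3).
#' @return list with elements `r` and `p`.
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (length(x) < 3) stopf("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("undefined statistic: zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Spearman rank correlation with exact small-sample p
#'
#' Spearman's rho as the Pearson correlation of average ranks (ties get
#' mean ranks).  The two-sided p-value is exact by full permutation
#' enumeration for n <= 9 (counting permutations with |rho| at least the
#' observed |rho|) and uses the t-approximation otherwise.
#'
#' @param x,y equal-length numeric vectors (length >= 3).
#' @return list with elements `rho` and `p`.
#' @examples
#' # six points in perfect rank agreement: rho = 1, exact p = 2/720
#' spearmanRho(1:6, c(2, 4, 8, 16, 32, 64))
#' @export
spearmanRho <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  n <- length(x)
  if (n < 3) stopf("need at least 3 observations")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stopf("undefined statistic: zero rank variance")
  rho <- stats::cor(rx, ry)
  if (n <= 9) {
    perms <- allPermutations(n)
    rxp <- matrix(rx[perms], nrow = nrow(perms))
    s <- as.numeric(rxp %*% ry)
    rho_perm <- (s - n * mean(rx) * mean(ry)) /
      ((n - 1) * stats::sd(rx) * stats::sd(ry))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  } else {
    tt <- rho * sqrt((n - 2) / max(1e-300, 1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = p)
}

#' Bray-Curtis similarity / dissimilarity of two vectors
#'
#' Computed on proportional abundances by default (each vector divided
#' by its total), as
#' \deqn{d = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)}
#' with similarity `1 - d`.
#'
#' @param x,y non-negative vectors of equal length, each with a positive
#'   total.
#' @param type `"similarity"` or `"dissimilarity"`.
#' @param proportional divide each vector by its total first?
#' @return a value in `[0, 1]`.
#' @export
brayCurtis <- function(x, y, type = c("similarity", "dissimilarity"),
                       proportional = TRUE) {
  type <- match.arg(type)
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (any(x < 0) || any(y < 0)) stopf("abundances must be non-negative")
  if (sum(x) <= 0 || sum(y) <= 0) stopf("zero-total vector")
  if (proportional) { x <- x / sum(x); y <- y / sum(y) }
  d <- sum(abs(x - y)) / sum(x + y)
  if (type == "similarity") 1 - d else d
}

## the three statistics on one (already standardized) pair; NA when a
## statistic is undefined on a degenerate replicate
fidelityStats <- function(live, dead) {
  p <- live / sum(live); q <- dead / sum(dead)
  rho <- if (stats::sd(rank(p)) > 0 && stats::sd(rank(q)) > 0)
    stats::cor(rank(p), rank(q)) else NA_real_
  r <- if (stats::sd(p) > 0 && stats::sd(q) > 0) stats::cor(p, q)
       else NA_real_
  bc <- 1 - sum(abs(p - q)) / sum(p + q)
  c(rho = rho, r = r, bc = bc)
}

#' Live-dead fidelity of one pair
#'
#' Standardizes the pair by rarefaction, then computes the three
#' fidelity statistics on proportional abundances over the union taxon
#' list: Spearman's rho of proportional rank abundance (absent taxa
#' share the minimum average rank), Pearson's r on the same proportion
#' vectors, and Bray-Curtis similarity.  Statistics are averaged across
#' the plan's Monte-Carlo replicates.
#'
#' @param pair a [LiveDeadPair-class] with integer counts.
#' @param plan a [StandardizationPlan-class]; `NULL` skips
#'   standardization (statistics on the raw pair).
#' @param group,scope labels stored on the result.
#' @return a [FidelityResult-class].
#' @export
livedeadFidelity <- function(pair, plan = standardizationPlan(),
                             group = "all", scope = pair@scope) {
  if (sum(pair@live > 0 | pair@dead > 0) < 3)
    stopf("undefined statistic: fewer than 3 union taxa")
  reps <- if (is.null(plan)) list(pair) else standardizePair(pair, plan)
  stats_mat <- vapply(reps, function(p) fidelityStats(p@live, p@dead),
                      numeric(3))
  n_taxa <- mean(vapply(reps, function(p)
    sum(p@live > 0 | p@dead > 0), numeric(1)))
  avg <- rowMeans(stats_mat, na.rm = TRUE)
  new("FidelityResult", scope = scope, group = group,
      rho = unname(avg["rho"]), r = unname(avg["r"]),
      brayCurtis = unname(avg["bc"]),
      nLive = sum(reps[[1]]@live), nDead = sum(reps[[1]]@dead),
      nTaxa = n_taxa,
      ciRho = c(NA_real_, NA_real_), ciR = c(NA_real_, NA_real_),
      ciBC = c(NA_real_, NA_real_), pRho = NA_real_, pR = NA_real_)
}

## correlation pair (rho + r with p-values) or NAs when undefined
corPairSafe <- function(x, y) {
  out <- c(rho = NA_real_, p_rho = NA_real_, r = NA_real_,
           p_r = NA_real_)
  sp <- tryCatch(spearmanRho(x, y), error = function(e) NULL)
  if (!is.null(sp)) { out["rho"] <- sp$rho; out["p_rho"] <- sp$p }
  pe <- tryCatch(pearsonR(x, y), error = function(e) NULL)
  if (!is.null(pe)) { out["r"] <- pe$r; out["p_r"] <- pe$p }
  out
}

#' Within-higher-taxon fidelity summary
#'
#' For each class or phylum, computes the locality-focused live-dead
#' correlations of (a) per-site abundance totals and (b) per-site
#' species richness within that higher taxon, across sites.  Higher taxa
#' with fewer than two species in either assemblage are reported as
#' missing (`NA`), mirroring the dashes of regional summary tables.
#' Also emits the regional abundance/richness vectors per higher taxon
#' for cross-taxon correlations.
#'
#' @param live,dead [CommunityMatrix-class] objects sharing sites (after
#'   filtering).
#' @param rank `"phylum"` or `"class"`.
#' @return list with `correlations` (one row per higher taxon:
#'   abundance and richness rho/r with p-values) and `regional`
#'   (`group, live_n, dead_n, live_s, dead_s`).
#' @export
taxonFidelitySummary <- function(live, dead, rank = c("phylum",
                                                      "class")) {
  rank <- match.arg(rank)
  sites <- intersect(siteNames(live), siteNames(dead))
  if (!length(sites)) stopf("no shared sites")
  al <- aggregateRank(live, rank); ad <- aggregateRank(dead, rank)
  groups <- union(colnames(al$abundance), colnames(ad$abundance))
  get <- function(agg, comp, g)
    if (g %in% colnames(agg[[comp]]))
      agg[[comp]][sites, g] else rep(0, length(sites))
  ## regional species richness within a group = species with nonzero
  ## pooled count
  poolS <- function(m, g) {
    tax <- taxonomyMap(m)
    cols <- tax$taxon[tax[[rank]] == g]
    cols <- intersect(cols, taxonNames(m))
    if (!length(cols)) return(0L)
    sum(colSums(abundances(m)[sites, cols, drop = FALSE]) > 0)
  }
  rows <- lapply(groups, function(g) {
    ls <- poolS(live, g); ds <- poolS(dead, g)
    regional <- data.frame(group = g,
                           live_n = sum(get(al, "abundance", g)),
                           dead_n = sum(get(ad, "abundance", g)),
                           live_s = ls, dead_s = ds)
    if (ls < 2 || ds < 2) {
      corr <- rep(NA_real_, 8)
    } else {
      corr <- c(corPairSafe(get(al, "abundance", g),
                            get(ad, "abundance", g)),
                corPairSafe(get(al, "richness", g),
                            get(ad, "richness", g)))
    }
    names(corr) <- c("abundance_rho", "abundance_p_rho", "abundance_r",
                     "abundance_p_r", "richness_rho", "richness_p_rho",
                     "richness_r", "richness_p_r")
    cbind(regional, as.data.frame(as.list(corr)))
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(correlations = tab[, c("group", "live_n", "dead_n",
                              "abundance_rho", "abundance_p_rho",
                              "abundance_r", "abundance_p_r", "live_s",
                              "dead_s", "richness_rho", "richness_p_rho",
                              "richness_r", "richness_p_r")],
       regional = tab[, c("group", "live_n", "dead_n", "live_s",
                          "dead_s")])
}

#' Cross-taxon correlations of a regional summary table
#'
#' Given regional abundance and richness per higher taxon for both
#' assemblages (columns `live_n, dead_n, live_s, dead_s`), computes the
#' live-dead richness correlation, the live-dead abundance correlation,
#' and the within-assemblage abundance-vs-richness correlations, each as
#' Spearman rho and Pearson r with two-sided p-values.
#'
#' @param regional data.frame with columns `live_n`, `dead_n`, `live_s`,
#'   `dead_s` (one row per higher taxon).
#' @return data.frame with one row per comparison.
#' @export
crossTaxonCorrelations <- function(regional) {
  need <- c("live_n", "dead_n", "live_s", "dead_s")
  if (!all(need %in% names(regional)))
    stopf("regional table needs columns %s", paste(need, collapse = ", "))
  comparisons <- list(
    richness_live_dead = c("live_s", "dead_s"),
    abundance_live_dead = c("live_n", "dead_n"),
    abundance_richness_live = c("live_n", "live_s"),
    abundance_richness_dead = c("dead_n", "dead_s"))
  rows <- lapply(names(comparisons), function(nm) {
    v <- comparisons[[nm]]
    cp <- corPairSafe(regional[[v[1]]], regional[[v[2]]])
    data.frame(comparison = nm, rho = cp["rho"], p_rho = cp["p_rho"],
               r = cp["r"], p_r = cp["p_r"], row.names = NULL)
  })
  do.call(rbind, rows)
}
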