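#' Pairwise dissimilarity matrix of sites
#'
#' Jaccard dissimilarity (`1 - |A intersect B| / |A union B|` on
#' presence sets) or Bray-Curtis dissimilarity on row-proportional
#' abundances (each site divided by its total), both via
#' [vegan::vegdist()].  Rows with a zero total are an error naming the
#' site.
#'
#' @param matrix a [CommunityMatrix-class] or plain site x taxon matrix
#'   (>= 2 sites).
#' @param metric `"jaccard"` or `"bray_curtis"`.
#' @return a full symmetric dissimilarity matrix with zero diagonal.
#' @export
dissimilarityMatrix <- function(matrix, metric = c("jaccard",
                                                   "bray_curtis")) {
  metric <- match.arg(metric)
  ab <- if (is(matrix, "CommunityMatrix")) abundances(matrix) else matrix
  if (nrow(ab) < 2) stopf("need at least 2 sites")
  empty <- rownames(ab)[rowSums(ab) <= 0]
  if (length(empty))
    stopf("empty site row(s): %s", paste(empty, collapse = ", "))
  d <- if (metric == "jaccard") {
    vegan::vegdist((ab > 0) * 1, method = "jaccard", binary = TRUE)
  } else {
    vegan::vegdist(ab / rowSums(ab), method = "bray")
  }
  as.matrix(d)
}

#' Principal coordinates embedding retaining imaginary axes
#'
#' Gower double-centering of `-d^2 / 2` followed by eigendecomposition.
#' Unlike [stats::cmdscale()], axes with negative eigenvalues (which
#' arise for semi-metric dissimilarities such as Jaccard or Bray-Curtis)
#' are retained as "imaginary" coordinates scaled by `sqrt(-lambda)`, so
#' distances can later be corrected rather than distorted by truncation.
#'
#' @param dissimilarity symmetric matrix with zero diagonal (asymmetry
#'   beyond 1e-10 is an error).
#' @return list with `points` (real axes), `imaginary` (imaginary axes,
#'   zero-column when the input is Euclidean-embeddable), and
#'   `eigenvalues`.
#' @export
pcoaEmbed <- function(dissimilarity) {
  d <- as.matrix(dissimilarity)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-10)
    stopf("dissimilarity matrix must be symmetric (tolerance 1e-10)")
  n <- nrow(d)
  A <- -0.5 * d^2
  G <- t(t(A - rowMeans(A)) - colMeans(A)) + mean(A)
  eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
  tol <- max(abs(eg$values)) * 1e-9
  pos <- which(eg$values > tol)
  neg <- which(eg$values < -tol)
  pts <- if (length(pos))
    eg$vectors[, pos, drop = FALSE] %*%
      diag(sqrt(eg$values[pos]), length(pos))
  else matrix(0, n, 0)
  imag <- if (length(neg))
    eg$vectors[, neg, drop = FALSE] %*%
      diag(sqrt(-eg$values[neg]), length(neg))
  else matrix(0, n, 0)
  rownames(pts) <- rownames(imag) <- rownames(d)
  list(points = pts, imaginary = imag, eigenvalues = eg$values)
}

## distance of each row of (pts, imag) to a centroid, combining real and
## imaginary parts as sqrt(max(0, d_real^2 - d_imag^2)) -- the standard
## correction for semi-metric PCoA
centroidDistances <- function(pts, imag, c_real, c_imag,
                              squared = FALSE) {
  d2r <- rowSums(sweep(pts, 2, c_real)^2)
  d2i <- if (ncol(imag)) rowSums(sweep(imag, 2, c_imag)^2) else 0
  d2 <- pmax(0, d2r - d2i)
  if (squared) d2 else sqrt(d2)
}

## overdispersion statistic for a given live/dead role assignment
## (live_rows index the pseudo-live points in the joint embedding)
dispersionStat <- function(emb, live_rows, dead_rows,
                           centroid = "live", squared = FALSE) {
  c_real <- colMeans(emb$points[live_rows, , drop = FALSE])
  c_imag <- if (ncol(emb$imaginary))
    colMeans(emb$imaginary[live_rows, , drop = FALSE]) else numeric(0)
  d_pre <- centroidDistances(emb$points[live_rows, , drop = FALSE],
                             emb$imaginary[live_rows, , drop = FALSE],
                             c_real, c_imag, squared)
  if (centroid == "classical") {
    c_real <- colMeans(emb$points[dead_rows, , drop = FALSE])
    c_imag <- if (ncol(emb$imaginary))
      colMeans(emb$imaginary[dead_rows, , drop = FALSE]) else numeric(0)
  }
  d_tot <- centroidDistances(emb$points[dead_rows, , drop = FALSE],
                             emb$imaginary[dead_rows, , drop = FALSE],
                             c_real, c_imag, squared)
  list(d_pre = d_pre, d_tot = d_tot,
       stat = mean(d_tot) - mean(d_pre))
}

#' Premortem / postmortem decomposition of multivariate dispersion
#'
#' Modified homogeneity-of-multivariate-dispersions (HMD) analysis.
#' Live and dead site points are embedded jointly by PCoA of the chosen
#' dissimilarity; premortem variation is each live assemblage's distance
#' to the live centroid, and total live-dead variation is each death
#' assemblage's distance to the *same* live centroid (the classical
#' two-centroid variant is available via `centroid = "classical"`).
#' Overdispersion is `mean(d_total) - mean(d_premortem)`; its one-sided
#' p-value comes from permuting live/dead roles within site pairs.
#' Distances combine real and imaginary PCoA axes as
#' `sqrt(max(0, d_real^2 - d_imag^2))`.
#'
#' @param live,dead [CommunityMatrix-class] objects with paired sites
#'   (>= 3 shared sites).
#' @param metric `"jaccard"` or `"bray_curtis"`.
#' @param permutations number of within-site label permutations.
#' @param seed optional seed.
#' @param centroid `"live"` (modified HMD) or `"classical"`.
#' @param squared use mean squared distances instead of mean distances.
#' @return a [DispersionResult-class].
#' @export
livedeadDispersion <- function(live, dead,
                               metric = c("jaccard", "bray_curtis"),
                               permutations = 999, seed = NULL,
                               centroid = c("live", "classical"),
                               squared = FALSE) {
  metric <- match.arg(metric)
  centroid <- match.arg(centroid)
  sites <- intersect(siteNames(live), siteNames(dead))
  ## drop sites empty in either assemblage: a distance needs a nonempty row
  ln <- rowSums(abundances(live))[sites]
  dn <- rowSums(abundances(dead))[sites]
  sites <- sites[ln > 0 & dn > 0]
  if (length(sites) < 3) stopf("need at least 3 paired non-empty sites")
  taxa <- union(taxonNames(live), taxonNames(dead))
  expand <- function(m, tag) {
    out <- matrix(0, nrow = length(sites), ncol = length(taxa),
                  dimnames = list(paste0(tag, ":", sites), taxa))
    out[, taxonNames(m)] <- abundances(m)[sites, , drop = FALSE]
    out
  }
  comb <- rbind(expand(live, "L"), expand(dead, "D"))
  emb <- pcoaEmbed(dissimilarityMatrix(comb, metric))
  ns <- length(sites)
  live_rows <- seq_len(ns); dead_rows <- ns + seq_len(ns)
  obs <- dispersionStat(emb, live_rows, dead_rows, centroid, squared)
  perm_stats <- withSeed(seed, vapply(seq_len(permutations),
    function(b) {
      swap <- stats::runif(ns) < 0.5
      pl <- ifelse(swap, dead_rows, live_rows)
      pd <- ifelse(swap, live_rows, dead_rows)
      dispersionStat(emb, pl, pd, centroid, squared)$stat
    }, numeric(1)))
  p <- (1 + sum(perm_stats >= obs$stat - 1e-12)) / (permutations + 1)
  per_site <- data.frame(site = sites, d_premortem = unname(obs$d_pre),
                         d_total = unname(obs$d_tot))
  mp <- mean(obs$d_pre); mt <- mean(obs$d_tot)
  new("DispersionResult", metric = metric, perSite = per_site,
      meanPremortem = mp, meanTotal = mt, overdispersion = mt - mp,
      proportionPremortem = if (mt > 0) mp / mt else NA_real_,
      pValue = p, nSites = ns, permutations = permutations)
}

#' Classify sites against the line of good agreement
#'
#' Labels each site by where it falls relative to the 1:1 line of the
#' premortem-vs-total dispersion plot: `within_agreement` when
#' `|d_total - d_premortem| <= band`, `overdispersed` when the excess is
#' above the band (death assemblage altered by postmortem processes),
#' `underdispersed` below.
#'
#' @param result a [DispersionResult-class].
#' @param band half-width of the good-agreement region (>= 0); the
#'   magnitude of compositional change expected from within-habitat
#'   time-averaging alone is a reasonable choice.
#' @return data.frame `site, d_premortem, d_total, label`.
#' @export
classifySites <- function(result, band = 0) {
  if (band < 0) stopf("band must be >= 0")
  ps <- result@perSite
  delta <- ps$d_total - ps$d_premortem
  ps$label <- ifelse(abs(delta) <= band, "within_agreement",
                     ifelse(delta > band, "overdispersed",
                            "underdispersed"))
  ps
}
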