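#' Convert element counts to estimated individuals
#'
#' Many benthic invertebrates leave multiple skeletal elements per
#' individual (two valves, dozens of echinoid plates and spines), so raw
#' death-assemblage counts of elements inflate abundance.  Every cell is
#' divided by the catalog value for its taxon (resolution order
#' taxon > class > phylum > 1); zero stays zero and results may be
#' fractional.  Live counts are individuals already, so correcting a
#' live matrix requires `force = TRUE`.  Correcting twice is refused.
#'
#' @param matrix a raw [CommunityMatrix-class].
#' @param catalog an [ElementCatalog-class].
#' @param force allow correction of a live matrix.
#' @return the corrected matrix, `stage = "element_corrected"`.
#' @examples
#' # 10 valves of a 2-valved bivalve -> 5 individuals
#' @export
elementCorrect <- function(matrix, catalog, force = FALSE) {
  if (analysisStage(matrix) == "element_corrected")
    stopf("matrix is already element-corrected; refusing to correct twice")
  if (assemblageType(matrix) == "live" && !force)
    stopf("live counts are individuals; use force = TRUE to correct anyway")
  tax <- taxonomyMap(matrix)
  div <- vapply(seq_len(nrow(tax)), function(i)
    elementsPerIndividual(catalog, tax$taxon[i], tax$class[i],
                          tax$phylum[i]), numeric(1))
  ab <- sweep(abundances(matrix), 2, div, "/")
  newCommunityMatrix(ab, tax, assemblageType(matrix),
                     stage = "element_corrected",
                     flaggedSites = matrix@flaggedSites)
}

#' Convert fractional corrected counts to integers
#'
#' Individual-level resampling (rarefaction, the randomization null)
#' needs integer counts.  `ceil_presence` (the default) maps any value in
#' (0, 1) to 1 and otherwise rounds half-up, so a taxon observed in the
#' field is never erased; `round` rounds half-up everywhere; `floor`
#' truncates (dropped taxa are reported in a message).
#'
#' @param matrix an element-corrected [CommunityMatrix-class].
#' @param mode `"ceil_presence"`, `"round"` or `"floor"`.
#' @return the integerized matrix (stage unchanged).
#' @export
integerize <- function(matrix, mode = c("ceil_presence", "round",
                                        "floor")) {
  mode <- match.arg(mode)
  if (analysisStage(matrix) != "element_corrected")
    stopf("integerize expects an element-corrected matrix")
  ab <- abundances(matrix)
  out <- switch(mode,
    ceil_presence = ifelse(ab > 0 & ab < 1, 1, floor(ab + 0.5)),
    round = floor(ab + 0.5),
    floor = floor(ab))
  if (mode == "floor") {
    dropped <- colnames(ab)[colSums(ab > 0) > 0 & colSums(out > 0) == 0]
    if (length(dropped))
      message("integerize(floor) dropped taxa: ",
              paste(dropped, collapse = ", "))
  }
  newCommunityMatrix(out, taxonomyMap(matrix), assemblageType(matrix),
                     stage = analysisStage(matrix),
                     flaggedSites = matrix@flaggedSites)
}

#' Exclude small samples from a live-dead site set
#'
#' Removes localities whose sample size falls below `minN`, the standard
#' guard against unstable fidelity estimates from tiny samples.  Under
#' rule `"either"` (default) a site is removed when either assemblage is
#' below the threshold; `"both"` removes only when both are; `"combined"`
#' thresholds the summed total.
#'
#' @param live,dead [CommunityMatrix-class] objects sharing a site
#'   universe.
#' @param minN minimum number of individuals.
#' @param rule `"either"`, `"both"` or `"combined"`.
#' @return a list with elements `live`, `dead` (filtered matrices) and
#'   `report` (data.frame `site, live_n, dead_n, removed, reason`).
#' @export
filterSites <- function(live, dead, minN = 50,
                        rule = c("either", "both", "combined")) {
  rule <- match.arg(rule)
  if (!setequal(siteNames(live), siteNames(dead)))
    stopf("live and dead matrices must share a site universe")
  sites <- siteNames(live)
  ln <- rowSums(abundances(live))[sites]
  dn <- rowSums(abundances(dead))[sites]
  removed <- switch(rule,
    either = ln < minN | dn < minN,
    both = ln < minN & dn < minN,
    combined = (ln + dn) < minN)
  reason <- ifelse(!removed, "",
                   sprintf("n below %d under rule '%s'", minN, rule))
  report <- data.frame(site = sites, live_n = unname(ln),
                       dead_n = unname(dn), removed = unname(removed),
                       reason = reason, row.names = NULL)
  keep <- sites[!removed]
  if (!length(keep))
    stopf("all sites removed at minN = %d (rule '%s')", minN, rule)
  subrows <- function(m)
    newCommunityMatrix(abundances(m)[keep, , drop = FALSE],
                       taxonomyMap(m), assemblageType(m),
                       stage = analysisStage(m),
                       flaggedSites = m@flaggedSites)
  list(live = subrows(live), dead = subrows(dead), report = report)
}

#' Restrict a community matrix to a taxon group
#'
#' Splits the fauna into molluscs (durable, heavily biomineralized
#' skeletons; `phylum == "Mollusca"`) and non-molluscs, or applies an
#' arbitrary predicate on the taxonomy table.  Sites whose row total
#' drops to zero are flagged in the result (and reported by
#' `object@flaggedSites`), not silently dropped.
#'
#' @param matrix a [CommunityMatrix-class].
#' @param group `"all"`, `"molluscs"`, `"non_molluscs"`, or a function
#'   taking the taxonomy data.frame and returning a logical column mask.
#' @return the restricted [CommunityMatrix-class].
#' @export
subsetTaxa <- function(matrix, group = "all") {
  tax <- taxonomyMap(matrix)
  keep <- if (is.function(group)) {
    group(tax)
  } else if (identical(group, "all")) {
    rep(TRUE, nrow(tax))
  } else if (identical(group, "molluscs")) {
    tax$phylum == "Mollusca"
  } else if (identical(group, "non_molluscs")) {
    tax$phylum != "Mollusca"
  } else {
    stopf("unknown taxon group '%s'", as.character(group)[1])
  }
  ab <- abundances(matrix)[, keep, drop = FALSE]
  flagged <- rownames(ab)[rowSums(ab) == 0]
  newCommunityMatrix(ab, tax[keep, , drop = FALSE],
                     assemblageType(matrix),
                     stage = analysisStage(matrix), flaggedSites = flagged)
}

#' Aggregate a species matrix to a higher taxonomic rank
#'
#' Returns per-site abundance (summed counts) and richness (number of
#' species with a positive count) within each class or phylum.
#'
#' @param matrix a [CommunityMatrix-class].
#' @param rank `"species"`, `"class"` or `"phylum"`.
#' @return list with `abundance` and `richness` matrices (sites x
#'   higher taxa).
#' @export
aggregateRank <- function(matrix, rank = c("species", "class",
                                           "phylum")) {
  rank <- match.arg(rank)
  ab <- abundances(matrix)
  if (rank == "species")
    return(list(abundance = ab, richness = (ab > 0) * 1))
  tax <- taxonomyMap(matrix)
  grp <- tax[[rank]]
  if (any(is.na(grp) | grp == ""))
    stopf("rank '%s' unresolved for taxon '%s'", rank,
          tax$taxon[which(is.na(grp) | grp == "")[1]])
  groups <- unique(grp)
  agg <- function(x) {
    out <- vapply(groups, function(g)
      rowSums(x[, grp == g, drop = FALSE]), numeric(nrow(x)))
    if (nrow(x) == 1L) out <- matrix(out, nrow = 1,
                                     dimnames = list(rownames(x), groups))
    out
  }
  list(abundance = agg(ab), richness = agg((ab > 0) * 1))
}

#' Pool a community matrix across localities
#'
#' Column sums over sites: the regional abundance vector over taxa,
#' order preserved.
#'
#' @param matrix a [CommunityMatrix-class].
#' @return named numeric vector over taxa.
#' @export
poolRegional <- function(matrix) colSums(abundances(matrix))
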