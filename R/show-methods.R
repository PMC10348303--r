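#' @describeIn OccurrenceTable-class compact summary
#' @param object the object to display.
#' @export
setMethod("show", "OccurrenceTable", function(object) {
  rec <- object@records
  cat(sprintf(
    "OccurrenceTable: %d records, %d sites, %d taxa (%d live / %d dead specimens)\n",
    nrow(rec), length(unique(rec$site)), length(unique(rec$taxon)),
    round(sum(rec$count[rec$assemblage == "live"])),
    round(sum(rec$count[rec$assemblage == "dead"]))))
})

#' @describeIn CommunityMatrix-class compact summary
#' @export
setMethod("show", "CommunityMatrix", function(object) {
  ab <- object@abundance
  cat(sprintf(
    "CommunityMatrix [%s, %s]: %d sites x %d taxa, total %.1f\n",
    object@assemblage, object@stage, nrow(ab), ncol(ab), sum(ab)))
  if (length(object@flaggedSites))
    cat("  flagged empty sites:",
        paste(object@flaggedSites, collapse = ", "), "\n")
})

#' @describeIn LiveDeadPair-class compact summary
#' @export
setMethod("show", "LiveDeadPair", function(object) {
  cat(sprintf(
    "LiveDeadPair [%s%s]: %d taxa, n_live = %.0f, n_dead = %.0f\n",
    object@scope,
    if (is.na(object@siteId)) "" else paste0(" ", object@siteId),
    length(object@taxa), sum(object@live), sum(object@dead)))
})

#' @describeIn FidelityResult-class compact summary
#' @export
setMethod("show", "FidelityResult", function(object) {
  cat(sprintf(
    "FidelityResult [%s, %s]: rho = %.3f, r = %.3f, Bray-Curtis = %.3f\n",
    object@scope, object@group, object@rho, object@r,
    object@brayCurtis))
  cat(sprintf("  n_live = %.0f, n_dead = %.0f, taxa = %.1f\n",
              object@nLive, object@nDead, object@nTaxa))
})

#' @describeIn NullDistribution-class compact summary
#' @export
setMethod("show", "NullDistribution", function(object) {
  cat(sprintf(
    "Perfect-fidelity null [%s]: observed = %.3f, null mean = %.3f (95%%: %.3f-%.3f, B = %d)\n",
    object@statistic, object@observed, object@expectedMean,
    object@quantiles["2.5%"], object@quantiles["97.5%"],
    length(object@replicates)))
})

#' @describeIn DispersionResult-class compact summary
#' @export
setMethod("show", "DispersionResult", function(object) {
  cat(sprintf(
    "DispersionResult [%s]: %d sites, premortem = %.3f, total = %.3f\n",
    object@metric, object@nSites, object@meanPremortem,
    object@meanTotal))
  cat(sprintf(
    "  overdispersion = %.3f (p = %.4g), premortem proportion = %.2f\n",
    object@overdispersion, object@pValue, object@proportionPremortem))
})

#' @describeIn TaphonomicConfig-class compact summary
#' @export
setMethod("show", "TaphonomicConfig", function(object) {
  cat(sprintf(
    "TaphonomicConfig: %d species in %d groups, %d sites, live n = %d/site, dead multiplier = %.1f\n",
    object@nSpecies, nrow(object@groups), object@nSites,
    object@liveNPerSite, object@deadNMultiplier))
})
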