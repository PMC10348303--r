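#' Accessors for the core classes
#'
#' Small accessor generics so that slot layout stays an implementation
#' detail: `abundances()` returns the site x taxon grid, `siteNames()` and
#' `taxonNames()` its dimnames, `taxonomyMap()` the taxon -> (class,
#' phylum) table, `assemblageType()` and `analysisStage()` the provenance
#' flags, `liveCounts()`/`deadCounts()` the two vectors of a pair and
#' `pairTaxa()` its union taxon list.
#'
#' @param object a [CommunityMatrix-class], [LiveDeadPair-class] or
#'   [OccurrenceTable-class].
#' @return the corresponding component.
#' @name accessors
#' @aliases abundances siteNames taxonNames taxonomyMap assemblageType
#'   analysisStage liveCounts deadCounts pairTaxa occurrenceRecords
NULL

#' @rdname accessors
#' @export
setGeneric("abundances", function(object) standardGeneric("abundances"))

#' @rdname accessors
#' @export
setGeneric("siteNames", function(object) standardGeneric("siteNames"))

#' @rdname accessors
#' @export
setGeneric("taxonNames", function(object) standardGeneric("taxonNames"))

#' @rdname accessors
#' @export
setGeneric("taxonomyMap", function(object) standardGeneric("taxonomyMap"))

#' @rdname accessors
#' @export
setGeneric("assemblageType",
           function(object) standardGeneric("assemblageType"))

#' @rdname accessors
#' @export
setGeneric("analysisStage",
           function(object) standardGeneric("analysisStage"))

#' @rdname accessors
#' @export
setGeneric("liveCounts", function(object) standardGeneric("liveCounts"))

#' @rdname accessors
#' @export
setGeneric("deadCounts", function(object) standardGeneric("deadCounts"))

#' @rdname accessors
#' @export
setGeneric("pairTaxa", function(object) standardGeneric("pairTaxa"))

#' @rdname accessors
#' @export
setGeneric("occurrenceRecords",
           function(object) standardGeneric("occurrenceRecords"))

#' @rdname accessors
#' @export
setMethod("abundances", "CommunityMatrix", function(object) object@abundance)

#' @rdname accessors
#' @export
setMethod("siteNames", "CommunityMatrix",
          function(object) rownames(object@abundance))

#' @rdname accessors
#' @export
setMethod("taxonNames", "CommunityMatrix",
          function(object) colnames(object@abundance))

#' @rdname accessors
#' @export
setMethod("taxonomyMap", "CommunityMatrix", function(object) object@taxonomy)

#' @rdname accessors
#' @export
setMethod("assemblageType", "CommunityMatrix",
          function(object) object@assemblage)

#' @rdname accessors
#' @export
setMethod("analysisStage", "CommunityMatrix", function(object) object@stage)

#' @rdname accessors
#' @export
setMethod("liveCounts", "LiveDeadPair",
          function(object) setNames(object@live, object@taxa))

#' @rdname accessors
#' @export
setMethod("deadCounts", "LiveDeadPair",
          function(object) setNames(object@dead, object@taxa))

#' @rdname accessors
#' @export
setMethod("pairTaxa", "LiveDeadPair", function(object) object@taxa)

#' @rdname accessors
#' @export
setMethod("occurrenceRecords", "OccurrenceTable",
          function(object) object@records)
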