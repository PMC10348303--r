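#' @importFrom utils read.csv write.csv
NULL

#' Construct an occurrence table from a data frame
#'
#' Normalizes column order, collapses duplicated
#' (site, taxon, assemblage, season) keys by summing their counts (with a
#' warning) and validates the result.
#'
#' @param records data.frame with columns `site`, `taxon`, `class`,
#'   `phylum`, `assemblage`, `count` and optionally `season`.
#' @return an [OccurrenceTable-class].
#' @export
occurrenceTable <- function(records) {
  if (!"season" %in% names(records)) records$season <- NA_character_
  records <- records[, OCC_COLUMNS]
  for (col in setdiff(OCC_COLUMNS, "count"))
    records[[col]] <- as.character(records[[col]])
  records$count <- as.numeric(records$count)
  bad <- which(!is.finite(records$count) | records$count < 0)
  if (length(bad))
    stopf("negative or non-numeric count in row(s) %s",
          paste(utils::head(bad, 5), collapse = ", "))
  key <- paste(records$site, records$taxon, records$assemblage,
               records$season, sep = "\r")
  if (anyDuplicated(key)) {
    ndup <- sum(duplicated(key))
    warnf("%d duplicated occurrence key(s) collapsed by summation", ndup)
    agg <- stats::aggregate(count ~ site + taxon + class + phylum +
                              assemblage + season,
                            data = transform(records,
                                             season = ifelse(is.na(season),
                                                             "\r<none>",
                                                             season)),
                            FUN = sum)
    agg$season[agg$season == "\r<none>"] <- NA_character_
    records <- agg[, OCC_COLUMNS]
  }
  rownames(records) <- NULL
  new("OccurrenceTable", records = records)
}

#' Read a long-format occurrence table
#'
#' Reads a comma-delimited file (UTF-8, "." decimal) with columns
#' `site,taxon,class,phylum,assemblage,count[,season]`; column names can
#' be remapped through `schema`.  Duplicate keys are collapsed by
#' summation with a warning; taxonomy consistency (one (class, phylum)
#' per taxon) is enforced.
#'
#' @param file path or connection.
#' @param schema named character vector mapping canonical column names
#'   (`site`, `taxon`, ...) to the names used in the file.
#' @return an [OccurrenceTable-class].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("site,taxon,class,phylum,assemblage,count",
#'              "S1,Abra alba,Bivalvia,Mollusca,live,5",
#'              "S1,Abra alba,Bivalvia,Mollusca,dead,12"), f)
#' occ <- readOccurrences(f)
#' @export
readOccurrences <- function(file, schema = NULL) {
  raw <- read.csv(file, stringsAsFactors = FALSE, check.names = FALSE)
  mapping <- c(site = "site", taxon = "taxon", class = "class",
               phylum = "phylum", assemblage = "assemblage",
               count = "count", season = "season")
  if (!is.null(schema)) mapping[names(schema)] <- schema
  required <- setdiff(OCC_COLUMNS, "season")
  missing_cols <- required[!mapping[required] %in% names(raw)]
  if (length(missing_cols))
    stopf("schema error: missing column(s) %s",
          paste(mapping[missing_cols], collapse = ", "))
  out <- data.frame(site = raw[[mapping["site"]]],
                    taxon = raw[[mapping["taxon"]]],
                    class = raw[[mapping["class"]]],
                    phylum = raw[[mapping["phylum"]]],
                    assemblage = raw[[mapping["assemblage"]]],
                    count = raw[[mapping["count"]]],
                    stringsAsFactors = FALSE)
  out$season <- if (mapping["season"] %in% names(raw))
    as.character(raw[[mapping["season"]]]) else NA_character_
  occurrenceTable(out)
}

#' Write an occurrence table
#'
#' Emits the canonical dialect: comma-delimited, stable column order
#' `site,taxon,class,phylum,assemblage,count[,season]`, no row names.
#' The `season` column is dropped when entirely missing.  Writing then
#' reading reproduces identical records.
#'
#' @param table an [OccurrenceTable-class].
#' @param file output path.
#' @export
writeOccurrences <- function(table, file) {
  rec <- table@records
  if (all(is.na(rec$season))) rec$season <- NULL
  write.csv(rec, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Construct an element catalog
#'
#' @param taxon,class,phylum named numeric vectors of elements-per-
#'   individual values (all >= 1) at each taxonomic level.
#' @param default global fallback (1: counts treated as individuals).
#' @return an [ElementCatalog-class].
#' @export
elementCatalog <- function(taxon = numeric(), class = numeric(),
                           phylum = numeric(), default = 1) {
  new("ElementCatalog", byTaxon = taxon, byClass = class,
      byPhylum = phylum, default = default)
}

#' Read a skeletal-element catalog
#'
#' Reads a comma-delimited file with columns `key,level,elements`, where
#' `level` is one of `taxon`, `class` or `phylum`.  An empty file yields
#' a defaults-only catalog (with a warning); values below 1 are an error.
#'
#' @param file path or connection.
#' @return an [ElementCatalog-class].
#' @export
readElementCatalog <- function(file) {
  raw <- tryCatch(read.csv(file, stringsAsFactors = FALSE),
                  error = function(e) NULL)
  if (is.null(raw) || nrow(raw) == 0L) {
    warnf("empty element catalog: all lookups fall back to 1")
    return(elementCatalog())
  }
  need <- c("key", "level", "elements")
  if (!all(need %in% names(raw)))
    stopf("element catalog needs columns %s", paste(need, collapse = ", "))
  if (!all(raw$level %in% c("taxon", "class", "phylum")))
    stopf("element catalog level must be taxon, class or phylum")
  vals <- as.numeric(raw$elements)
  if (any(!is.finite(vals) | vals < 1))
    stopf("elements-per-individual values must be >= 1")
  pick <- function(lv) setNames(vals[raw$level == lv],
                                raw$key[raw$level == lv])
  elementCatalog(taxon = pick("taxon"), class = pick("class"),
                 phylum = pick("phylum"))
}

#' Write a skeletal-element catalog
#'
#' @param catalog an [ElementCatalog-class].
#' @param file output path.
#' @export
writeElementCatalog <- function(catalog, file) {
  one <- function(v, lv)
    data.frame(key = names(v), level = rep(lv, length(v)),
               elements = unname(v))
  df <- rbind(one(catalog@byTaxon, "taxon"),
              one(catalog@byClass, "class"),
              one(catalog@byPhylum, "phylum"))
  write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Elements-per-individual lookup
#'
#' Resolves the number of skeletal elements per live individual for a
#' taxon, with resolution order taxon > class > phylum > global default.
#'
#' @param catalog an [ElementCatalog-class].
#' @param taxon taxon name.
#' @param class,phylum higher-rank names used for fallback lookup.
#' @return a numeric value >= 1.
#' @examples
#' cat <- elementCatalog(class = c(Bivalvia = 2))
#' elementsPerIndividual(cat, "Abra alba", class = "Bivalvia")  # 2
#' elementsPerIndividual(cat, "Unknown sp.")                    # 1
#' @export
elementsPerIndividual <- function(catalog, taxon, class = NA,
                                  phylum = NA) {
  if (!is.na(taxon) && taxon %in% names(catalog@byTaxon))
    return(unname(catalog@byTaxon[[taxon]]))
  if (!is.na(class) && class %in% names(catalog@byClass))
    return(unname(catalog@byClass[[class]]))
  if (!is.na(phylum) && phylum %in% names(catalog@byPhylum))
    return(unname(catalog@byPhylum[[phylum]]))
  catalog@default
}

## internal constructor keeping taxonomy aligned with columns
newCommunityMatrix <- function(abundance, taxonomy, assemblage,
                               stage = "raw", flaggedSites = character()) {
  taxonomy <- taxonomy[match(colnames(abundance), taxonomy$taxon), ,
                       drop = FALSE]
  rownames(taxonomy) <- NULL
  new("CommunityMatrix", abundance = abundance, taxonomy = taxonomy,
      assemblage = assemblage, stage = stage, flaggedSites = flaggedSites)
}

#' Cross-tabulate an occurrence table into a community matrix
#'
#' Builds the site x taxon abundance grid for one assemblage.  By
#' default repeated seasonal visits to a site are pooled (summed) into a
#' single locality row; with `poolSeasons = FALSE` each visit becomes its
#' own row labelled `site@season`.
#'
#' @param table an [OccurrenceTable-class].
#' @param assemblage `"live"` or `"dead"`.
#' @param poolSeasons pool repeat visits into one locality row?
#' @return a [CommunityMatrix-class] with `stage = "raw"`.
#' @examples
#' rec <- data.frame(site = c("S1","S1","S2"),
#'                   taxon = c("a","b","b"),
#'                   class = "Bivalvia", phylum = "Mollusca",
#'                   assemblage = "live", count = c(3, 1, 4))
#' m <- toMatrix(occurrenceTable(rec), "live")
#' abundances(m)
#' @export
toMatrix <- function(table, assemblage = c("live", "dead"),
                     poolSeasons = TRUE) {
  assemblage <- match.arg(assemblage)
  rec <- table@records[table@records$assemblage == assemblage, ,
                       drop = FALSE]
  if (nrow(rec) == 0L)
    stopf("assemblage '%s' absent from the occurrence table", assemblage)
  site_key <- if (poolSeasons || all(is.na(rec$season))) rec$site
  else ifelse(is.na(rec$season), rec$site,
              paste0(rec$site, "@", rec$season))
  sites <- unique(site_key)
  taxa <- unique(rec$taxon)
  ab <- matrix(0, nrow = length(sites), ncol = length(taxa),
               dimnames = list(sites, taxa))
  idx <- cbind(match(site_key, sites), match(rec$taxon, taxa))
  for (i in seq_len(nrow(rec)))
    ab[idx[i, 1], idx[i, 2]] <- ab[idx[i, 1], idx[i, 2]] + rec$count[i]
  taxonomy <- unique(rec[, c("taxon", "class", "phylum")])
  newCommunityMatrix(ab, taxonomy, assemblage, stage = "raw")
}

#' Build aligned live-dead pairs from two community matrices
#'
#' Aligns a live and a dead matrix on their union taxon list and returns
#' one [LiveDeadPair-class] per shared site (`scope = "site"`), or a
#' single regional pair of pooled column sums (`scope = "region"`).
#' Sites with a zero total in either assemblage are skipped with a
#' warning (a pair needs positive totals on both sides).
#'
#' @param live,dead [CommunityMatrix-class] objects of the two
#'   assemblages.
#' @param scope `"site"` or `"region"`.
#' @return a list of [LiveDeadPair-class] (site scope) or a single pair
#'   (region scope).
#' @export
makePairs <- function(live, dead, scope = c("site", "region")) {
  scope <- match.arg(scope)
  taxa <- union(taxonNames(live), taxonNames(dead))
  expand <- function(m) {
    out <- matrix(0, nrow = nrow(abundances(m)), ncol = length(taxa),
                  dimnames = list(siteNames(m), taxa))
    out[, taxonNames(m)] <- abundances(m)
    out
  }
  lv <- expand(live); dv <- expand(dead)
  if (scope == "region") {
    return(new("LiveDeadPair", scope = "region", siteId = NA_character_,
               taxa = taxa, live = colSums(lv), dead = colSums(dv)))
  }
  shared <- intersect(rownames(lv), rownames(dv))
  if (!length(shared)) stopf("no shared sites between assemblages")
  pairs <- list()
  for (s in shared) {
    if (sum(lv[s, ]) <= 0 || sum(dv[s, ]) <= 0) {
      warnf("site '%s' skipped: zero total in one assemblage", s)
      next
    }
    pairs[[s]] <- new("LiveDeadPair", scope = "site", siteId = s,
                      taxa = taxa, live = lv[s, ], dead = dv[s, ])
  }
  pairs
}
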