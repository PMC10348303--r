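#' Default study configuration
#'
#' Analysis-local sample-size thresholds (50 individuals for the
#' fidelity/correlation tables, 20 for diversity and the
#' mollusc/non-mollusc splits, 30 for the dispersion analysis), the
#' resampling sizes, and the master seed.
#'
#' @param ... overrides of the default keys.
#' @return named list of configuration values.
#' @export
studyConfig <- function(...) {
  cfg <- list(min_n_fidelity = 50, min_n_diversity = 20, min_n_hmd = 30,
              filter_rule = "either", reps = 250, diversity_reps = 50,
              B = 1000, null_B_site = 250, permutations = 999, seed = 1,
              pool_seasons = TRUE)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Read a flat key=value study configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments are
#' ignored; numeric values are coerced.
#'
#' @param path file path.
#' @return named list merged over [studyConfig()] defaults.
#' @export
readStudyConfig <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- lapply(kv, function(x) {
    v <- trimws(x[2])
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num
    else if (v %in% c("TRUE", "FALSE")) as.logical(v)
    else v
  })
  names(vals) <- vapply(kv, function(x) trimws(x[1]), character(1))
  do.call(studyConfig, vals)
}

#' Locality-focused standardized richness fidelity per higher taxon
#'
#' For each class or phylum: per site, the live and dead counts within
#' the group are rarefied to the smaller of the pair's totals using the
#' analytic (Hurlbert) expected richness; the live-dead Spearman
#' correlation of those rarefied richnesses across sites is reported
#' with a BCa bootstrap confidence interval obtained by resampling
#' sites (live-dead pairs jointly).
#'
#' @param live,dead [CommunityMatrix-class] objects sharing sites.
#' @param rank `"phylum"` or `"class"`.
#' @param minN per-group site inclusion threshold (both assemblage
#'   totals within the group must reach it).
#' @param B bootstrap replicates for the BCa interval.
#' @param seed seed for the bootstrap.
#' @return data.frame `group, n_sites, rho, p, ci_lo, ci_hi`.
#' @export
localityRichnessFidelity <- function(live, dead,
                                     rank = c("phylum", "class"),
                                     minN = 20, B = 1000, seed = 1) {
  rank <- match.arg(rank)
  sites <- intersect(siteNames(live), siteNames(dead))
  tax_l <- taxonomyMap(live); tax_d <- taxonomyMap(dead)
  groups <- union(tax_l[[rank]], tax_d[[rank]])
  rows <- list()
  for (g in groups) {
    cols_l <- tax_l$taxon[tax_l[[rank]] == g]
    cols_d <- tax_d$taxon[tax_d[[rank]] == g]
    sl <- abundances(live)[sites, intersect(cols_l, taxonNames(live)),
                           drop = FALSE]
    sd_ <- abundances(dead)[sites, intersect(cols_d, taxonNames(dead)),
                            drop = FALSE]
    pairs <- lapply(sites, function(s) {
      lv <- round(sl[s, ]); dv <- round(sd_[s, ])
      nl <- sum(lv); nd <- sum(dv)
      if (nl < minN || nd < minN) return(NULL)
      m <- min(nl, nd)
      c(live = expectedRichness(lv, m), dead = expectedRichness(dv, m))
    })
    pairs <- do.call(rbind, Filter(Negate(is.null), pairs))
    if (is.null(pairs) || nrow(pairs) < 5) {
      rows[[g]] <- data.frame(group = g,
                              n_sites = if (is.null(pairs)) 0
                                        else nrow(pairs),
                              rho = NA_real_, p = NA_real_,
                              ci_lo = NA_real_, ci_hi = NA_real_)
      next
    }
    sp <- tryCatch(spearmanRho(pairs[, "live"], pairs[, "dead"]),
                   error = function(e) list(rho = NA_real_,
                                            p = NA_real_))
    ci <- if (is.finite(sp$rho)) {
      tryCatch(suppressWarnings(bcaInterval(
        pairs,
        function(d) {
          if (stats::sd(rank(d[, 1])) == 0 ||
              stats::sd(rank(d[, 2])) == 0) return(NA_real_)
          stats::cor(rank(d[, 1]), rank(d[, 2]))
        },
        B = B, seed = deriveSeed(seed, g))),
        error = function(e) c(NA_real_, NA_real_))
    } else c(NA_real_, NA_real_)
    rows[[g]] <- data.frame(group = g, n_sites = nrow(pairs),
                            rho = sp$rho, p = sp$p,
                            ci_lo = unname(ci[1]), ci_hi = unname(ci[2]))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## rarefied per-site diversity averaged over subsampling replicates
rarefiedDiversity <- function(counts, target, reps, seed) {
  vals <- vapply(seq_len(reps), function(b) {
    sub <- subsampleCounts(counts, target, seed = seed + b)
    di <- diversityIndices(sub)
    c(S = di$S, H = di$H, D = di$D,
      J = if (is.na(di$J)) NA_real_ else di$J)
  }, numeric(4))
  rowMeans(vals, na.rm = TRUE)
}

#' Run the full live-dead fidelity study
#'
#' Executes the complete analysis sequence on an occurrence table and an
#' element catalog: ingestion and validation, element correction of the
#' death assemblage, pooling of repeat visits, per-analysis site
#' filtering, then (a) regional abundance/richness summaries per phylum
#' and class with within-taxon and cross-taxon correlations, (b)
#' locality-focused standardized richness fidelity per higher taxon with
#' BCa confidence intervals, (c) regional and locality compositional
#' fidelity for the multi-taxic, mollusc and non-mollusc subsets with
#' perfect-fidelity randomization nulls, (d) sample-standardized site
#' diversity and Kruskal-Wallis group comparisons with Bonferroni
#' correction, and (e) the modified HMD dispersion decomposition for the
#' three subsets under both Jaccard and Bray-Curtis dissimilarity.
#' All tables are written as CSV together with a JSON run manifest
#' (thresholds, seeds, resampling sizes, retained-site counts); reruns
#' with the same manifest are bit-identical.
#'
#' @param occurrences path to an occurrence CSV or an
#'   [OccurrenceTable-class].
#' @param elementCatalog path to an element-catalog CSV or an
#'   [ElementCatalog-class] (`NULL` for a defaults-only catalog).
#' @param outDir output directory for the report bundle.
#' @param config a [studyConfig()] list.
#' @return invisibly, a named list of the result tables.
#' @export
runStudy <- function(occurrences, elementCatalog = NULL, outDir,
                     config = studyConfig()) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  stage <- "ingest"
  res <- list()
  tryCatch({
    occ <- if (is(occurrences, "OccurrenceTable")) occurrences
           else readOccurrences(occurrences)
    cat_ <- if (is.null(elementCatalog)) elementCatalog()
            else if (is(elementCatalog, "ElementCatalog")) elementCatalog
            else readElementCatalog(elementCatalog)
    live <- toMatrix(occ, "live", poolSeasons = config$pool_seasons)
    dead_raw <- toMatrix(occ, "dead", poolSeasons = config$pool_seasons)
    ## align site universes: a site sampled in only one assemblage gets
    ## a zero row in the other
    all_sites <- union(siteNames(live), siteNames(dead_raw))
    pad <- function(m) {
      ab <- matrix(0, length(all_sites), ncol(abundances(m)),
                   dimnames = list(all_sites, taxonNames(m)))
      ab[siteNames(m), ] <- abundances(m)
      newCommunityMatrix(ab, taxonomyMap(m), assemblageType(m),
                         analysisStage(m))
    }
    live <- pad(live); dead_raw <- pad(dead_raw)
    dead_corr <- elementCorrect(dead_raw, cat_)
    dead_int <- integerize(dead_corr)

    stage <- "taxon_summaries"
    f50 <- filterSites(live, dead_int, config$min_n_fidelity,
                       config$filter_rule)
    write.csv(f50$report, file.path(outDir, "filter_fidelity.csv"),
              row.names = FALSE)
    for (rk in c("phylum", "class")) {
      summ <- taxonFidelitySummary(f50$live, f50$dead, rk)
      res[[paste0("summary_", rk)]] <- summ
      write.csv(summ$correlations,
                file.path(outDir, sprintf("fidelity_%s.csv", rk)),
                row.names = FALSE)
      write.csv(summ$regional,
                file.path(outDir, sprintf("regional_%s.csv", rk)),
                row.names = FALSE)
      ct <- crossTaxonCorrelations(summ$regional)
      ct$rank <- rk
      res[[paste0("cross_", rk)]] <- ct
    }
    write.csv(rbind(res$cross_phylum, res$cross_class),
              file.path(outDir, "cross_taxon_correlations.csv"),
              row.names = FALSE)

    stage <- "locality_richness"
    f20 <- filterSites(live, dead_int, config$min_n_diversity,
                       config$filter_rule)
    for (rk in c("phylum", "class")) {
      lr <- localityRichnessFidelity(f20$live, f20$dead, rk,
                                     minN = config$min_n_diversity,
                                     B = config$B, seed = config$seed)
      res[[paste0("locality_richness_", rk)]] <- lr
      write.csv(lr,
                file.path(outDir,
                          sprintf("locality_richness_%s.csv", rk)),
                row.names = FALSE)
    }

    stage <- "compositional_fidelity"
    comp_rows <- list()
    for (grp in c("all", "molluscs", "non_molluscs")) {
      lg <- subsetTaxa(f20$live, grp)
      dg <- subsetTaxa(f20$dead, grp)
      keep <- rowSums(abundances(lg)) >= config$min_n_diversity &
        rowSums(abundances(dg)) >= config$min_n_diversity
      if (sum(keep) < 3) next
      sub <- function(m) newCommunityMatrix(
        abundances(m)[keep, , drop = FALSE], taxonomyMap(m),
        assemblageType(m), analysisStage(m))
      lg <- sub(lg); dg <- sub(dg)
      plan <- standardizationPlan(reps = config$reps,
                                  seed = config$seed)
      ## regional
      rp <- makePairs(lg, dg, "region")
      fr <- livedeadFidelity(rp, plan, group = grp, scope = "region")
      nullr <- perfectFidelityNull(rp, "rho", B = config$B,
                                   seed = deriveSeed(config$seed, grp))
      comp_rows[[paste0(grp, "_region")]] <- data.frame(
        scope = "region", group = grp, n_sites = sum(keep),
        rho = fr@rho, r = fr@r, bray_curtis = fr@brayCurtis,
        null_mean_rho = nullr@expectedMean,
        null_q025 = unname(nullr@quantiles["2.5%"]),
        null_q975 = unname(nullr@quantiles["97.5%"]),
        explained_by_sampling = fr@rho >=
          unname(nullr@quantiles["2.5%"]))
      ## locality: mean observed and mean null expectation over sites
      sps <- makePairs(lg, dg, "site")
      site_obs <- c(); site_null <- c()
      for (p in sps) {
        fo <- tryCatch(livedeadFidelity(p, plan, group = grp),
                       error = function(e) NULL)
        if (is.null(fo)) next
        nn <- perfectFidelityNull(p, "rho", B = config$null_B_site,
                                  seed = deriveSeed(config$seed,
                                                    p@siteId))
        site_obs <- c(site_obs, fo@rho)
        site_null <- c(site_null, nn@expectedMean)
      }
      comp_rows[[paste0(grp, "_locality")]] <- data.frame(
        scope = "locality", group = grp, n_sites = length(site_obs),
        rho = mean(site_obs), r = NA_real_, bray_curtis = NA_real_,
        null_mean_rho = mean(site_null), null_q025 = NA_real_,
        null_q975 = NA_real_, explained_by_sampling = NA)
    }
    res$compositional <- do.call(rbind, comp_rows)
    rownames(res$compositional) <- NULL
    write.csv(res$compositional,
              file.path(outDir, "compositional_fidelity.csv"),
              row.names = FALSE)

    stage <- "diversity"
    groups <- list(multitaxic_LA = f20$live,
                   mollusc_DA = subsetTaxa(f20$dead, "molluscs"),
                   nonmollusc_DA = subsetTaxa(f20$dead, "non_molluscs"))
    totals <- vapply(groups, function(m) rowSums(abundances(m)),
                     numeric(length(siteNames(f20$live))))
    ok_sites <- siteNames(f20$live)[apply(
      totals >= config$min_n_diversity, 1, all)]
    div_rows <- list()
    for (s in ok_sites) {
      target <- floor(min(totals[match(s, siteNames(f20$live)), ]))
      for (g in names(groups)) {
        counts <- round(abundances(groups[[g]])[s, ])
        dv <- rarefiedDiversity(counts, min(target, sum(counts)),
                                config$diversity_reps,
                                deriveSeed(config$seed, paste(s, g)))
        div_rows[[paste(s, g)]] <- data.frame(
          site = s, group = g, index = names(dv), value = unname(dv))
      }
    }
    empty_div <- data.frame(site = character(), group = character(),
                            index = character(), value = numeric())
    res$diversity_site <- if (length(div_rows))
      do.call(rbind, div_rows) else empty_div
    rownames(res$diversity_site) <- NULL
    write.csv(res$diversity_site,
              file.path(outDir, "diversity_site.csv"),
              row.names = FALSE)
    pairs <- list(c("multitaxic_LA", "mollusc_DA"),
                  c("multitaxic_LA", "nonmollusc_DA"),
                  c("mollusc_DA", "nonmollusc_DA"))
    res$diversity_tests <- if (length(ok_sites) >= 3) {
      compareAssemblageGroups(res$diversity_site, pairs)
    } else {
      message("diversity comparisons skipped: fewer than 3 sites meet ",
              "the threshold in every assemblage group")
      data.frame(index = character(), comparison = character(),
                 n1 = numeric(), n2 = numeric(), H = numeric(),
                 p = numeric(), p_adjusted = numeric())
    }
    write.csv(res$diversity_tests,
              file.path(outDir, "diversity_tests.csv"),
              row.names = FALSE)

    stage <- "hmd"
    f30 <- filterSites(live, dead_int, config$min_n_hmd,
                       config$filter_rule)
    hmd_rows <- list()
    for (grp in c("all", "molluscs", "non_molluscs")) {
      lg <- subsetTaxa(f30$live, grp); dg <- subsetTaxa(f30$dead, grp)
      for (metric in c("jaccard", "bray_curtis")) {
        dr <- tryCatch(
          livedeadDispersion(lg, dg, metric,
                             permutations = config$permutations,
                             seed = deriveSeed(config$seed,
                                               paste(grp, metric))),
          error = function(e) NULL)
        if (is.null(dr)) next
        hmd_rows[[paste(grp, metric)]] <- data.frame(
          group = grp, metric = metric, n_sites = dr@nSites,
          mean_premortem = dr@meanPremortem,
          mean_total = dr@meanTotal,
          overdispersion = dr@overdispersion,
          proportion_premortem = dr@proportionPremortem,
          p = dr@pValue)
        write.csv(classifySites(dr),
                  file.path(outDir,
                            sprintf("hmd_sites_%s_%s.csv", grp,
                                    metric)),
                  row.names = FALSE)
      }
    }
    res$hmd <- do.call(rbind, hmd_rows)
    rownames(res$hmd) <- NULL
    write.csv(res$hmd, file.path(outDir, "hmd_summary.csv"),
              row.names = FALSE)

    stage <- "manifest"
    manifest <- c(config,
                  list(package_version =
                         as.character(utils::packageVersion(
                           "taphofidelity")),
                       sites_total = length(all_sites),
                       sites_fidelity = sum(!f50$report$removed),
                       sites_diversity = sum(!f20$report$removed),
                       sites_hmd = sum(!f30$report$removed)))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    res$manifest <- manifest
  }, error = function(e) {
    stopf("study failed at stage '%s': %s", stage, conditionMessage(e))
  })
  invisible(res)
}
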