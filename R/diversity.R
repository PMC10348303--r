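#' Diversity indices of one abundance vector
#'
#' Richness `S` (count of positive entries), Shannon's
#' `H = -sum(p_i log p_i)` (natural log), Simpson's `D` and Pielou's
#' evenness `J = H / log(S)` (`NA` when `S = 1`).  `D` defaults to the
#' Gini-Simpson form `1 - sum(p_i^2)` so that, like `H` and `J`, larger
#' means more diverse; the probability-of-identity (`"complement"`,
#' `sum p_i^2`) and inverse (`1 / sum p_i^2`) forms are available by
#' flag.  Shannon and Simpson are delegated to [vegan::diversity()].
#'
#' @param abundances non-negative vector with a positive total.
#' @param simpson `"gini_simpson"`, `"complement"` or `"inverse"`.
#' @return named list with elements `S`, `H`, `D`, `J`.
#' @examples
#' diversityIndices(rep(5, 4))  # S=4, H=log(4), D=0.75, J=1
#' @export
diversityIndices <- function(abundances,
                             simpson = c("gini_simpson", "complement",
                                         "inverse")) {
  simpson <- match.arg(simpson)
  if (any(abundances < 0)) stopf("abundances must be non-negative")
  if (sum(abundances) <= 0) stopf("zero-total vector")
  x <- abundances[abundances > 0]
  S <- length(x)
  H <- unname(vegan::diversity(x, index = "shannon"))
  gini <- unname(vegan::diversity(x, index = "simpson"))
  D <- switch(simpson, gini_simpson = gini, complement = 1 - gini,
              inverse = 1 / (1 - gini))
  J <- if (S > 1) H / log(S) else NA_real_
  list(S = S, H = H, D = D, J = J)
}

#' Per-site diversity table for assemblage groups
#'
#' Convenience wrapper computing the four indices per site for a named
#' list of community matrices (e.g. the multi-taxic live assemblage, the
#' mollusc death assemblage and the non-mollusc death assemblage).
#' Sites with a zero row total are skipped.
#'
#' @param matrices named list of [CommunityMatrix-class] objects.
#' @param simpson passed to [diversityIndices()].
#' @return long data.frame `site, group, index, value`.
#' @export
siteDiversityTable <- function(matrices, simpson = "gini_simpson") {
  rows <- list()
  for (g in names(matrices)) {
    ab <- abundances(matrices[[g]])
    for (s in rownames(ab)) {
      if (sum(ab[s, ]) <= 0) next
      di <- diversityIndices(ab[s, ], simpson = simpson)
      rows[[length(rows) + 1L]] <-
        data.frame(site = s, group = g,
                   index = c("S", "H", "D", "J"),
                   value = c(di$S, di$H, di$D, di$J))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## kruskal.test with the all-tied degenerate case mapped to H = 0, p = 1
## (the tie correction otherwise divides by zero)
safeKruskal <- function(value, group) {
  if (length(unique(value)) == 1L) return(list(H = 0, p = 1))
  kw <- stats::kruskal.test(value ~ factor(group))
  list(H = unname(kw$statistic), p = kw$p.value)
}

#' Pairwise Kruskal-Wallis comparisons of assemblage-group diversity
#'
#' For each diversity index, compares site-level values between the
#' requested group pairs with a tie-corrected Kruskal-Wallis test
#' (chi-square p) and applies a Bonferroni correction across the pairs
#' (`p_adjusted = min(1, m * p)`).  A global test across all groups is
#' appended.  A pair in which one group has zero variance across sites
#' triggers a warning but is still tested.
#'
#' @param diversities data.frame with columns `site`, `group`, `value`
#'   and optionally `index` (tests are run per index level).
#' @param pairs list of length-2 character vectors of group names;
#'   `NULL` tests all pairwise combinations of the groups present.
#' @return data.frame `index, comparison, n1, n2, H, p, p_adjusted`.
#' @export
compareAssemblageGroups <- function(diversities, pairs = NULL) {
  if (!all(c("site", "group", "value") %in% names(diversities)))
    stopf("diversities needs columns site, group, value")
  if (!"index" %in% names(diversities)) diversities$index <- "value"
  groups <- unique(diversities$group)
  if (length(groups) < 2) stopf("need at least 2 groups")
  if (is.null(pairs))
    pairs <- utils::combn(groups, 2, simplify = FALSE)
  out <- list()
  for (ix in unique(diversities$index)) {
    di <- diversities[diversities$index == ix &
                        is.finite(diversities$value), ]
    m <- length(pairs)
    for (pr in pairs) {
      sub <- di[di$group %in% pr, ]
      counts <- table(factor(sub$group, levels = pr))
      if (any(counts < 3))
        stopf("group '%s' has fewer than 3 sites for index %s",
              pr[which.min(counts)], ix)
      for (g in pr) {
        if (stats::sd(sub$value[sub$group == g]) == 0)
          warnf("group '%s' has zero variance for index %s; test still run",
                g, ix)
      }
      kw <- safeKruskal(sub$value, sub$group)
      out[[length(out) + 1L]] <- data.frame(
        index = ix, comparison = paste(pr, collapse = " vs "),
        n1 = unname(counts[1]), n2 = unname(counts[2]),
        H = kw$H, p = kw$p, p_adjusted = min(1, m * kw$p))
    }
    kw_all <- safeKruskal(di$value, di$group)
    out[[length(out) + 1L]] <- data.frame(
      index = ix, comparison = "global",
      n1 = nrow(di), n2 = NA_real_,
      H = kw_all$H, p = kw_all$p, p_adjusted = kw_all$p)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
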