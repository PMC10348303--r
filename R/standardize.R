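#' Create a rarefaction standardization plan
#'
#' @param targetN target sample size; `NA` (default) uses the smaller of
#'   each pair's totals.
#' @param reps Monte-Carlo replicates (default 1000, matching the other
#'   resampling procedures).
#' @param seed integer master seed.
#' @param mode `"monte_carlo"` or `"analytic_richness"`.
#' @return a [StandardizationPlan-class].
#' @export
standardizationPlan <- function(targetN = NA, reps = 1000, seed = 1,
                                mode = c("monte_carlo",
                                         "analytic_richness")) {
  new("StandardizationPlan", targetN = as.numeric(targetN),
      reps = as.numeric(reps), seed = as.numeric(seed),
      mode = match.arg(mode))
}

#' Expected species richness under rarefaction
#'
#' The analytic (Hurlbert) expectation of the number of species in a
#' random subsample of `m` individuals drawn without replacement:
#' \deqn{E[S_m] = \sum_i \left[1 - \binom{N - N_i}{m} / \binom{N}{m}\right]}
#' computed with log-combinatorial arithmetic so large totals do not
#' overflow.
#'
#' @param abundances non-negative integer vector of species counts.
#' @param m subsample size, `1 <= m <= sum(abundances)`.
#' @return expected richness (real).
#' @examples
#' expectedRichness(c(5, 3, 2), 2)   # 76/45
#' expectedRichness(c(5, 3, 2), 10)  # 3, the observed richness
#' @export
expectedRichness <- function(abundances, m) {
  if (!length(abundances) || all(abundances == 0))
    stopf("empty abundance vector")
  if (any(abundances < 0)) stopf("abundances must be non-negative")
  N <- sum(abundances)
  if (m < 1 || m > N) stopf("m must lie in [1, N = %d]", N)
  x <- abundances[abundances > 0]
  ## lchoose(N - x, m) is -Inf when N - x < m, giving the exact term 1
  sum(1 - exp(lchoose(N - x, m) - lchoose(N, m)))
}

#' Subsample individuals without replacement
#'
#' Draws `m` individuals from a species-abundance vector without
#' replacement (a multivariate hypergeometric draw), via a sequential
#' hypergeometric scheme that is O(number of species) per draw.
#'
#' @param abundances non-negative integer vector.
#' @param m subsample size.
#' @param seed optional seed for a reproducible draw; `NULL` uses the
#'   current RNG stream.
#' @return integer vector of the same length summing to `m`.
#' @export
subsampleCounts <- function(abundances, m, seed = NULL) {
  if (any(abundances < 0)) stopf("abundances must be non-negative")
  if (any(abs(abundances - round(abundances)) > 1e-8))
    stopf("subsampling needs integer counts (apply integerize first)")
  abundances <- round(abundances)
  N <- sum(abundances)
  if (m < 0 || m > N) stopf("m must lie in [0, N = %d]", N)
  withSeed(seed, {
    out <- integer(length(abundances))
    remaining <- N
    left <- m
    for (i in seq_along(abundances)) {
      if (left == 0L) break
      xi <- abundances[i]
      if (xi == 0L) next
      k <- stats::rhyper(1, xi, remaining - xi, left)
      out[i] <- k
      left <- left - k
      remaining <- remaining - xi
    }
    names(out) <- names(abundances)
    out
  })
}

#' Standardize a live-dead pair by rarefaction
#'
#' Rarefies the pair to the smaller of its two totals: only the larger
#' assemblage is subsampled, the one already at the target passes
#' through unchanged.  Returns `plan@reps` replicate pairs; downstream
#' statistics average over replicates.  Per-replicate seeds are derived
#' from the plan's master seed and the pair's site id, so site order
#' never changes results.
#'
#' @param pair a [LiveDeadPair-class] with integer counts.
#' @param plan a [StandardizationPlan-class].
#' @return list of standardized [LiveDeadPair-class] replicates.
#' @export
standardizePair <- function(pair, plan = standardizationPlan()) {
  nl <- sum(pair@live); nd <- sum(pair@dead)
  if (nl <= 0 || nd <= 0) stopf("degenerate pair: zero total")
  target <- if (is.na(plan@targetN)) min(nl, nd) else plan@targetN
  if (target > min(nl, nd))
    stopf("targetN = %d exceeds the smaller total %d", target, min(nl, nd))
  key <- if (is.na(pair@siteId)) "region" else pair@siteId
  lapply(seq_len(plan@reps), function(rep) {
    sd <- deriveSeed(plan@seed, key, rep)
    lv <- if (nl > target) subsampleCounts(pair@live, target, seed = sd)
          else pair@live
    dv <- if (nd > target)
      subsampleCounts(pair@dead, target, seed = sd + 1L)
    else pair@dead
    new("LiveDeadPair", scope = pair@scope, siteId = pair@siteId,
        taxa = pair@taxa, live = as.numeric(lv), dead = as.numeric(dv))
  })
}
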