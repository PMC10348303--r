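## index-based unit extraction: vectors by element, matrices/data.frames
## by row
takeUnits <- function(sample, idx) {
  if (is.matrix(sample) || is.data.frame(sample))
    sample[idx, , drop = FALSE]
  else sample[idx]
}

nUnits <- function(sample) {
  if (is.matrix(sample) || is.data.frame(sample)) nrow(sample)
  else length(sample)
}

#' BCa bootstrap confidence interval
#'
#' Accelerated bias-corrected (BCa) percentile interval: units are
#' resampled with replacement `B` times, the bias term is
#' `z0 = qnorm(fraction of replicates below the observed value)`, and
#' the acceleration `a` comes from the jackknife third-moment formula
#' \deqn{a = \sum (\bar\theta - \theta_{(i)})^3 /
#'   \{6 [\sum (\bar\theta - \theta_{(i)})^2]^{3/2}\}.}
#' The adjusted percentile endpoints are returned.  When a replicate
#' leaves the statistic undefined (`NA`), it is redrawn (bounded
#' retries).  When all replicates are identical the interval degenerates
#' to a point with a warning.
#'
#' @param sample the data collection: a vector (units = elements) or a
#'   matrix / data.frame (units = rows, preserving within-unit pairing).
#' @param statistic function of such a collection returning one number.
#' @param B bootstrap replicates (>= 100).
#' @param alpha two-sided miss probability (0.05 for a 95% interval).
#' @param seed optional seed.
#' @return numeric `c(lo, hi)`.
#' @examples
#' bcaInterval(rnorm(30), mean, B = 500, seed = 1)
#' @export
bcaInterval <- function(sample, statistic, B = 1000, alpha = 0.05,
                        seed = NULL) {
  n <- nUnits(sample)
  if (n < 3) stopf("need at least 3 units")
  if (B < 100) stopf("B must be >= 100")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must lie in (0, 1)")
  obs <- statistic(sample)
  if (!is.finite(obs)) stopf("statistic undefined on the full sample")
  withSeed(seed, {
    reps <- numeric(B)
    retries <- 0L
    for (b in seq_len(B)) {
      val <- NA_real_
      while (!is.finite(val)) {
        val <- tryCatch(
          statistic(takeUnits(sample, sample.int(n, n, replace = TRUE))),
          error = function(e) NA_real_)
        if (!is.finite(val)) {
          retries <- retries + 1L
          if (retries > 10L * B)
            stopf("statistic undefined on too many bootstrap replicates")
        }
      }
      reps[b] <- val
    }
    if (stats::sd(reps) == 0) {
      warnf("degenerate bootstrap distribution: interval collapsed")
      return(c(lo = reps[1], hi = reps[1]))
    }
    z0 <- stats::qnorm((sum(reps < obs) + 0.5 * sum(reps == obs)) / B)
    jack <- vapply(seq_len(n), function(i)
      statistic(takeUnits(sample, setdiff(seq_len(n), i))), numeric(1))
    jm <- mean(jack)
    denom <- sum((jm - jack)^2)^1.5
    a <- if (denom > 0) sum((jm - jack)^3) / (6 * denom) else 0
    zlo <- stats::qnorm(alpha / 2); zhi <- stats::qnorm(1 - alpha / 2)
    adj <- function(z) stats::pnorm(z0 + (z0 + z) / (1 - a * (z0 + z)))
    q <- stats::quantile(reps, probs = c(adj(zlo), adj(zhi)),
                         names = FALSE, type = 6)
    c(lo = q[1], hi = q[2])
  })
}

#' Perfect-fidelity randomization null
#'
#' Estimates the distribution of a fidelity statistic when fidelity is
#' perfect and departures reflect sampling alone: live and dead counts
#' are pooled into one species-abundance distribution, and in each of
#' `B` replicates the pooled specimens are partitioned at random without
#' replacement into a pseudo-live sample of the original live size and a
#' pseudo-dead sample of the original dead size; the statistic is then
#' recomputed on the pseudo-pair.
#'
#' @param pair a [LiveDeadPair-class] with integer counts (apply
#'   [integerize()] upstream for element-corrected data).
#' @param statistic `"rho"`, `"r"` or `"bray_curtis"`.
#' @param B replicates (>= 100).
#' @param seed optional seed.
#' @return a [NullDistribution-class].
#' @export
perfectFidelityNull <- function(pair, statistic = c("rho", "r",
                                                    "bray_curtis"),
                                B = 1000, seed = NULL) {
  statistic <- match.arg(statistic)
  if (B < 100) stopf("B must be >= 100")
  if (any(abs(c(pair@live, pair@dead) -
              round(c(pair@live, pair@dead))) > 1e-8))
    stopf("null model needs integer counts (apply integerize upstream)")
  live <- round(pair@live); dead <- round(pair@dead)
  nl <- sum(live); nd <- sum(dead)
  if (nl < 1 || nd < 1) stopf("both sample sizes must be >= 1")
  pooled <- live + dead
  stat_fun <- switch(statistic,
    rho = function(l, d) {
      p <- l / sum(l); q <- d / sum(d)
      if (stats::sd(rank(p)) == 0 || stats::sd(rank(q)) == 0)
        return(NA_real_)
      stats::cor(rank(p), rank(q))
    },
    r = function(l, d) {
      p <- l / sum(l); q <- d / sum(d)
      if (stats::sd(p) == 0 || stats::sd(q) == 0) return(NA_real_)
      stats::cor(p, q)
    },
    bray_curtis = function(l, d) {
      p <- l / sum(l); q <- d / sum(d)
      1 - sum(abs(p - q)) / sum(p + q)
    })
  observed <- stat_fun(live, dead)
  reps <- withSeed(seed, vapply(seq_len(B), function(b) {
    pl <- subsampleCounts(pooled, nl)
    stat_fun(pl, pooled - pl)
  }, numeric(1)))
  bad <- sum(!is.finite(reps))
  if (bad > 0.1 * B)
    stopf("statistic undefined on %d of %d replicates (degenerate pool)",
          bad, B)
  reps <- reps[is.finite(reps)]
  q <- stats::quantile(reps, c(0.025, 0.5, 0.975))
  new("NullDistribution", statistic = statistic, replicates = reps,
      observed = observed, quantiles = q, expectedMean = mean(reps))
}

#' Compare an observed fidelity statistic with its sampling null
#'
#' Reports the observed value next to the null mean and central 95%
#' interval, with the verdict `"explained by sampling"` iff the observed
#' value is at or above the null 2.5% quantile (boundary inclusive).
#'
#' @param observed a [FidelityResult-class] or a single numeric value.
#' @param null a [NullDistribution-class] for the same statistic.
#' @return data.frame with columns `statistic`, `observed`, `null_mean`,
#'   `q025`, `q975`, `explained_by_sampling`.
#' @export
samplingEffectReport <- function(observed, null) {
  obs <- if (is(observed, "FidelityResult")) {
    switch(null@statistic, rho = observed@rho, r = observed@r,
           bray_curtis = observed@brayCurtis)
  } else as.numeric(observed)
  q025 <- unname(null@quantiles["2.5%"])
  data.frame(statistic = null@statistic, observed = obs,
             null_mean = null@expectedMean, q025 = q025,
             q975 = unname(null@quantiles["97.5%"]),
             explained_by_sampling = obs >= q025)
}
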