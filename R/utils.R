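#' @importFrom stats setNames
NULL

#' Derive a reproducible sub-seed from a master seed and a key
#'
#' One master seed drives every stochastic step; per-site (and
#' per-replicate) streams are derived by hashing the key so that results
#' are independent of site ordering.  The derived seed always stays below
#' 2^31.
#'
#' @param seed integer master seed.
#' @param key a character key (e.g. a site id).
#' @param rep an integer replicate index.
#' @return an integer seed.
#' @export
deriveSeed <- function(seed, key = "", rep = 0L) {
  h <- 0
  for (cc in utf8ToInt(as.character(key)))
    h <- (h * 131 + cc) %% 1046527
  as.integer((abs(seed) + 1000003 * h + 7919 * rep) %% 2147483629)
}

## run expr under a temporary RNG state when seed is given
withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) expr
  else withr::with_seed(as.integer(seed), expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
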