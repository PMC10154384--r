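#' @importFrom stats aov coef lm lm.fit mad median oneway.test p.adjust pnorm
#'   rbeta rgamma rlnorm rnorm rpois sd shapiro.test TukeyHSD var
#'   wilcox.test kruskal.test t.test optimize
#' @importFrom utils head tail read.csv write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Lognormal parameters matching a target mean and standard deviation
#'
#' Converts a (mean, sd) pair on the natural scale to the (meanlog, sdlog)
#' parameters of a lognormal distribution with those first two moments.
#' Used throughout the cohort generator so that per-cell truths are positive
#' while the cohort mean converges to the published summary value.
#'
#' @param mean target arithmetic mean (> 0).
#' @param sd target standard deviation (>= 0).
#' @return list with `meanlog` and `sdlog`.
#' @export
lognormal_params <- function(mean, sd) {
  stopifnot(is.finite(mean), mean > 0, is.finite(sd), sd >= 0)
  sdlog2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Draw positive per-cell truths with a given cohort mean and SD
#'
#' @param n number of draws.
#' @param mean,sd cohort mean and standard deviation on the natural scale.
#' @return numeric vector of length `n` (all positive). `sd = 0` returns
#'   `rep(mean, n)` (degenerate cohort).
#' @export
rlnorm_matched <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  p <- lognormal_params(mean, sd)
  rlnorm(n, meanlog = p$meanlog, sdlog = p$sdlog)
}

#' Draw bounded fractions with a given mean and SD (moment-matched beta)
#'
#' @param n number of draws.
#' @param mean target mean in (0, 1).
#' @param sd target standard deviation; must satisfy sd^2 < mean (1 - mean).
#' @return numeric vector in (0, 1); `sd = 0` returns `rep(mean, n)`.
#' @export
rbeta_matched <- function(n, mean, sd) {
  stopifnot(mean > 0, mean < 1)
  if (sd == 0) return(rep(mean, n))
  v <- sd^2
  stopifnot(v < mean * (1 - mean))
  k <- mean * (1 - mean) / v - 1
  rbeta(n, shape1 = mean * k, shape2 = (1 - mean) * k)
}

# Derive independent per-cell sub-seeds from one master seed (kept < 2^31).
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
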