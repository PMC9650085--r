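## Between-generation heteroplasmy transition kernels.
##
## A daughter's mutant fraction is the mother's transformed by two normal
## perturbation kernels applied in a fixed order: mutation first, then
## segregation, each clamped to [0, 1]. These coarse-grained kernels stand
## in for the discrete molecular processes (copying errors, subsampling,
## turnover, cell divisions) whose net between-generation effect they
## moment-match.

## Draw N(mean, sd) element-wise, but only where sd > 0; where sd == 0 the
## result is the mean exactly and no randomness is consumed. Skipping
## zero-scale draws (rather than drawing with sd = 0) is what makes reduced
## models consume identical RNG streams; see package-level notes.
.draw_normal <- function(mean, sd) {
  k <- max(length(mean), length(sd))
  mean <- rep_len(mean, k)
  sd <- rep_len(sd, k)
  out <- mean
  idx <- which(sd > 0)
  if (length(idx)) out[idx] <- rnorm(length(idx), mean[idx], sd[idx])
  out
}

.mut_sd <- function(mu, n, form) {
  if (form == "sqrt") sqrt(mu / n) else mu / n
}

#' Clamp a value to the unit interval
#'
#' Mutant fractions are proportions; every kernel output is constrained to
#' lie between 0 and 1 by clamping. Values clamped to exactly 0 or 1 are
#' treated as exact homoplasmy downstream (no tolerance band).
#'
#' @param x Numeric vector.
#' @return `pmin(1, pmax(0, x))`.
#' @examples
#' clamp01(c(-0.2, 0.5, 1.3))
#' @export
clamp01 <- function(x) pmin(1, pmax(0, x))

#' Mutation kernel
#'
#' One generation of organelle mutation changes a cell's mutant fraction
#' `h` by a normal kernel with mean `h + mu * (1 - 2 * h)` (per-molecule
#' switching at rate `mu` in both directions drifts `h` towards 1/2) and
#' standard deviation `sqrt(mu / n)` by default (the binomial copy-number
#' spread for `n` molecules; see [kernel_params()] for the alternative
#' literal `mu / n` form). The result is clamped to [0, 1]. With `mu = 0`
#' the kernel is the exact identity and consumes no randomness.
#'
#' @param h Mutant fraction(s) in [0, 1].
#' @param params A [kernel_params()] object (only `mu`, `n`, `mut_sd` are
#'   used). Alternatively `mu` may be a vector of per-cell rates of the same
#'   length as `h` via the `mu` override.
#' @param mu Optional per-cell mutation-rate vector overriding
#'   `params$mu` (used by the evolvable layer).
#' @param clamp Clamp the result to [0, 1]? Default `TRUE`. `clamp = FALSE`
#'   exposes the raw kernel variate for moment diagnostics.
#' @return Numeric vector of daughter mutant fractions, one draw per entry.
#' @examples
#' set.seed(1)
#' mutate_h(0.3, kernel_params(mu = 0))      # identity
#' mutate_h(rep(0.5, 5), kernel_params(mu = 0.01))
#' @export
mutate_h <- function(h, params, mu = NULL, clamp = TRUE) {
  if (is.null(mu)) mu <- params$mu
  m <- h + mu * (1 - 2 * h)
  x <- .draw_normal(m, .mut_sd(mu, params$n, params$mut_sd))
  if (clamp) clamp01(x) else x
}

#' Segregation (bottleneck) kernel
#'
#' One generation of segregation perturbs the mutant fraction by a normal
#' kernel with mean `h` and variance `sigma * h * (1 - h)` — the classical
#' drift-variance form, so that `sigma` plays the role of the normalised
#' heteroplasmy variance V'(h) (the inverse of an effective bottleneck
#' size). The result is clamped to [0, 1]. Homoplasmic cells (`h` exactly 0
#' or 1) and `sigma = 0` are fixed points and consume no randomness:
#' segregation redistributes existing variation but never creates new
#' alleles.
#'
#' @param h Mutant fraction(s) in [0, 1].
#' @param sigma Segregation strength (scalar or per-cell vector, >= 0).
#' @param clamp Clamp the result to [0, 1]? Default `TRUE`.
#' @return Numeric vector of post-segregation mutant fractions.
#' @examples
#' set.seed(1)
#' segregate_h(0, 0.5)                  # homoplasmy is absorbing
#' segregate_h(rep(0.5, 5), 0.02)
#' @export
segregate_h <- function(h, sigma, clamp = TRUE) {
  x <- .draw_normal(h, sqrt(sigma * h * (1 - h)))
  if (clamp) clamp01(x) else x
}

#' Mother-to-daughter transmission
#'
#' Composes the two kernels in the model's fixed order — mutation, then
#' segregation — with one independent draw per daughter per operator, and
#' clamping after each operator.
#'
#' @inheritParams mutate_h
#' @param sigma Optional per-cell segregation-strength vector overriding
#'   `params$sigma`.
#' @return Numeric vector of daughter mutant fractions.
#' @examples
#' set.seed(1)
#' transmit_h(rep(0.5, 3), kernel_params(mu = 0.01, sigma = 0.02))
#' transmit_h(0, kernel_params(mu = 0, sigma = 0.3))  # exact 0
#' @export
transmit_h <- function(h, params, mu = NULL, sigma = NULL) {
  if (is.null(sigma)) sigma <- params$sigma
  segregate_h(mutate_h(h, params, mu = mu), sigma)
}

#' Normalised heteroplasmy variance V'(h)
#'
#' The sample variance of a set of mutant fractions divided by
#' `h0 * (1 - h0)`, where `h0` is the founding mutant fraction. For
#' near-normal heteroplasmy distributions this diagnostic recovers the
#' segregation strength `sigma` of the kernel that generated the samples.
#'
#' @param samples Numeric vector of mutant fractions (length >= 2).
#' @param h0 Founding mutant fraction, strictly inside (0, 1).
#' @return `var(samples) / (h0 * (1 - h0))` (sample variance, n - 1
#'   denominator).
#' @examples
#' normalised_variance(c(0, 1, 0, 1), 0.5)  # 4/3
#' @export
normalised_variance <- function(samples, h0) {
  stopifnot(length(samples) >= 2)
  if (!is.numeric(h0) || length(h0) != 1 || h0 <= 0 || h0 >= 1)
    stop("normalised variance is undefined at homoplasmic h0 (0 or 1)",
         call. = FALSE)
  var(samples) / (h0 * (1 - h0))
}
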