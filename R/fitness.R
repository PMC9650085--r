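## Environment-dependent cell fitness. Two environments, A and B: the oDNA
## wildtype performs better in A, the mutant in B. Heteroplasmic cells pay
## an admixture penalty, creating a fitness valley between the two
## homoplasmic optima. All parts are combined through a sigmoid so fitness
## is strictly between 0 and 1 and roulette selection is always defined.

#' Environmental performance part of fitness
#'
#' `-h` in environment A (wildtype favoured), `+h` in environment B (mutant
#' favoured).
#'
#' @param h Mutant fraction(s) in [0, 1].
#' @param env `"A"` or `"B"` (scalar).
#' @return Numeric vector.
#' @examples
#' performance(c(0, 0.3, 1), "A")
#' @export
performance <- function(h, env) {
  stopifnot(length(env) == 1, env %in% c("A", "B"))
  if (env == "A") -h else h
}

#' Admixture (heteroplasmy) penalty part of fitness
#'
#' The penalty a cell pays for carrying a mixed oDNA population, in one of
#' the three shapes described in [fitness_spec()]. Homoplasmy is decided by
#' exact comparison with 0 and 1 (kernel outputs are clamped, so clamped
#' values count as exactly homoplasmic).
#'
#' @param h Mutant fraction(s) in [0, 1].
#' @param spec A [fitness_spec()] object.
#' @return Numeric vector of penalties (<= 0).
#' @examples
#' admixture_penalty(c(0, 0.5, 1), fitness_spec(epsilon = 0.5))
#' admixture_penalty(0.5, fitness_spec(epsilon = 0.5, variant = "smooth"))
#' @export
admixture_penalty <- function(h, spec) {
  eps <- spec$epsilon
  switch(spec$variant,
    step = ifelse(h == 0 | h == 1, 0, -eps),
    smooth = 4 * eps * (h - 0.5)^2 - eps,
    threshold = {
      exempt <- h <= spec$threshold_h |
        (spec$exempt_mutant_homoplasmy & h == 1)
      ifelse(exempt, 0, -eps)
    }
  )
}

#' Cell fitness
#'
#' Sigmoidal fitness `1 / (1 + exp(-2 * (f_E(h) + f_eps(h))))`, strictly
#' inside (0, 1), combining environmental performance and the admixture
#' penalty.
#'
#' @inheritParams admixture_penalty
#' @param env `"A"` or `"B"`.
#' @return Numeric vector of fitness values in (0, 1).
#' @examples
#' cell_fitness(0, "A", fitness_spec(epsilon = 0.5))   # 0.5
#' cell_fitness(1, "B", fitness_spec(epsilon = 0.5))   # 1 / (1 + exp(-2))
#' @export
cell_fitness <- function(h, env, spec) {
  1 / (1 + exp(-2 * (performance(h, env) + admixture_penalty(h, spec))))
}

#' Cell fitness with a dysfunctional-oDNA load
#'
#' In the three-type extension the performance part is reduced by the
#' dysfunctional proportion, `f_E(h) - h_D`, so dysfunctional load is purely
#' detrimental; the admixture penalty still acts on the functional mutant
#' fraction `h`. At `hD = 0` this reduces exactly to [cell_fitness()], and
#' for fixed `h` it is strictly decreasing in `hD`.
#'
#' @inheritParams cell_fitness
#' @param hD Dysfunctional proportion(s) in [0, 1].
#' @return Numeric vector of fitness values in (0, 1).
#' @examples
#' cell_fitness_dys(0, 0, "A", fitness_spec())    # 0.5
#' cell_fitness_dys(0, 1, "A", fitness_spec())    # 1 / (1 + exp(2))
#' @export
cell_fitness_dys <- function(h, hD, env, spec) {
  1 / (1 + exp(-2 * (performance(h, env) - hD + admixture_penalty(h, spec))))
}
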