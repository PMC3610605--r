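# Branch-choice probability functions of the discrete network model.
#
# At a symmetrical bifurcation the probability of taking a branch follows the
# classical nonlinear pheromone-choice function of trail-laying ants:
#   P1 = (k + C1)^n / ((k + C1)^n + (k + C2)^n)
# with k the intrinsic attractivity (in pheromone units) and n the degree of
# nonlinearity; defaults are the values fitted against the four-condition
# foraging-efficiency ratios. At an asymmetrical bifurcation the branch deviating less from
# the incoming direction gets an extra geometry bias that is maximal when the
# two branches carry equal pheromone (P_sym = 1/2) and vanishes as the
# pheromone choice saturates (P_sym -> 0 or 1):
#   P_direct = P_sym + 4 * alpha * P_sym * (1 - P_sym)
# With the default alpha = 1/6 an unmarked asymmetrical bifurcation is taken
# on the direct side with probability 2/3.

#' Choice-function parameters
#'
#' @param k intrinsic attractivity, in pheromone units (> 0).
#' @param n nonlinearity exponent (>= 1).
#' @param alpha geometry-bias amplitude in `[0, 0.5]`; `alpha = 1/6` makes the
#'   unmarked direct-branch probability 2/3.
#' @return a list of class `choice_params`.
#' @export
choice_params <- function(k = 9, n = 2.5, alpha = 1 / 6) {
  stopifnot(k > 0, n >= 1, alpha >= 0, alpha <= 0.5)
  structure(list(k = k, n = n, alpha = alpha), class = "choice_params")
}

#' Branch probability at a symmetrical bifurcation
#'
#' @param C1,C2 pheromone quantities on the two branches (>= 0, recycled).
#' @param params a [choice_params()].
#' @return probability of choosing branch 1.
#' @export
choice_symmetric <- function(C1, C2, params = choice_params()) {
  if (any(C1 < 0) || any(C2 < 0)) stop("pheromone quantities must be non-negative")
  a <- (params$k + C1)^params$n
  b <- (params$k + C2)^params$n
  a / (a + b)
}

#' Branch probability at an asymmetrical bifurcation
#'
#' Returns the probability of choosing the branch that deviates *less* from
#' the incoming direction, given the pheromone on the direct (`C_direct`) and
#' wide-angle (`C_wide`) branches.
#'
#' @param C_direct,C_wide pheromone quantities (>= 0, recycled).
#' @param params a [choice_params()].
#' @return probability of choosing the direct branch, clamped to `[0, 1]`.
#' @export
choice_asymmetric <- function(C_direct, C_wide, params = choice_params()) {
  p <- choice_symmetric(C_direct, C_wide, params)
  pmin(pmax(p + 4 * params$alpha * p * (1 - p), 0), 1)
}
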