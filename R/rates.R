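#' Instantaneous rate of change of energy
#'
#' Energy is gained as a saturating (Michaelis-Menten) function of current
#' knowledge, `f_max * L / (L + k_L)`, and lost to the fixed maintenance
#' cost `m` and to the learning investment `u` (which enters the energy
#' balance one-for-one, since `u` is itself an energy expenditure rate):
#'
#' \deqn{dE/dt = f_{max} \frac{L}{L + k_L} - m - u}
#'
#' @param E Current energy (unused by the rate law itself, accepted for a
#'   uniform signature; the energy balance does not depend on `E`).
#' @param L Current knowledge (non-negative; vectorized).
#' @param u Learning investment rate (non-negative; vectorized).
#' @param params A [model_params()] object.
#' @return The energy rate of change, in energy per time.
#' @export
#' @examples
#' p <- model_params()
#' energy_rate(5.5, L = 1, u = 0, p)   # 1 * 1/(1+1) - 0.02 = 0.48
energy_rate <- function(E, L, u, params) {
  if (any(L < 0)) stop("knowledge L must be non-negative")
  if (any(u < 0)) stop("learning investment u must be non-negative")
  params$f_max * L / (L + params$k_L) - params$m - u
}

#' Instantaneous rate of change of knowledge
#'
#' Knowledge grows in proportion to the learning investment, with
#' efficiency `alpha`, and decays in proportion to its current amount at
#' rate `m_L` (forgetting / environmental turnover):
#'
#' \deqn{dL/dt = \alpha u - m_L L}
#'
#' For a constant investment `u`, the unique fixed point is
#' `L* = alpha * u / m_L`.
#'
#' @inheritParams energy_rate
#' @return The knowledge rate of change, in knowledge per time.
#' @export
#' @examples
#' p <- model_params()
#' knowledge_rate(L = 0, u = 1, p)        # alpha * 1 = 1
#' knowledge_rate(L = 1 / 0.08, u = 1, p) # fixed point: 0
knowledge_rate <- function(L, u, params) {
  if (any(L < 0)) stop("knowledge L must be non-negative")
  if (any(u < 0)) stop("learning investment u must be non-negative")
  params$alpha * u - params$m_L * L
}

# Derivative of the intake term with respect to L:
# d/dL [f_max L/(L+k_L)] = f_max k_L / (L+k_L)^2. Used by the collocation
# gradient and the adjoint equations.
intake_slope <- function(L, params) {
  params$f_max * params$k_L / (L + params$k_L)^2
}
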