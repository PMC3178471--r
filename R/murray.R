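#' Poiseuille pumping power
#'
#' Power dissipated by steady laminar (Poiseuille) flow in a rigid
#' cylindrical tube: \eqn{8 \mu l Q^2 / (\pi r^4)}. The steep
#' \eqn{r^{-4}} dependence is why small calibre changes dominate the
#' frictional cost of a vascular segment.
#'
#' @param Q volumetric flow, m^3/s.
#' @param r tube radius, m.
#' @param l tube length, m.
#' @param mu dynamic viscosity, Pa s (blood ~ 3.5e-3).
#' @return power in W.
#' @examples
#' poiseuille_power(1e-6, 2e-3, 0.1, 3.5e-3)
#' @export
poiseuille_power <- function(Q, r, l, mu) {
  if (any(c(Q, r, l, mu) <= 0)) stopf("all arguments must be > 0")
  8 * mu * l * Q^2 / (pi * r^4)
}

#' Frictional saving from scaling the radius
#'
#' Percent reduction in Poiseuille pumping power when the radius is
#' multiplied by `scale` at fixed flow, length and viscosity:
#' `100 * (1 - scale^-4)`. Doubling the radius saves 93.75% ("almost
#' 94%") of the frictional losses.
#'
#' @param scale radius multiplier (> 0).
#' @return percent saving (negative for `scale < 1`).
#' @examples
#' friction_saving_on_scaling(2)  # 93.75
#' @export
friction_saving_on_scaling <- function(scale) {
  if (any(scale <= 0)) stopf("scale must be > 0")
  100 * (1 - scale^-4)
}

#' Total segment cost in Murray's model
#'
#' Sum of the Poiseuille pumping power and a metabolic cost proportional
#' to blood volume: \eqn{E(r) = 8 \mu l Q^2/(\pi r^4) + b \pi r^2 l}.
#' Strictly convex in r for positive parameters, with a unique minimum
#' at [murray_optimal_radius()].
#'
#' @inheritParams poiseuille_power
#' @param b metabolic cost per unit blood volume, W/m^3.
#' @return cost in W.
#' @export
murray_energy <- function(r, Q, l, mu, b) {
  if (any(c(r, Q, l, mu, b) <= 0)) stopf("all arguments must be > 0")
  poiseuille_power(Q, r, l, mu) + b * pi * r^2 * l
}

#' Cost-minimizing vessel radius
#'
#' Radius minimizing [murray_energy()]; the length cancels, giving the
#' closed form \eqn{r^* = (16 \mu Q^2 / (\pi^2 b))^{1/6}}, so
#' \eqn{Q \propto r^{*3}} -- the origin of the cube law. The
#' `"numeric"` method minimizes the cost by 1-D search on the log-radius
#' scale without using the closed form, as an internal consistency
#' route.
#'
#' @inheritParams murray_energy
#' @param method `"closed-form"` or `"numeric"`.
#' @return optimal radius in m.
#' @examples
#' murray_optimal_radius(1e-6, 3.5e-3, 1000)
#' @export
murray_optimal_radius <- function(Q, mu, b,
                                  method = c("closed-form", "numeric")) {
  method <- match.arg(method)
  if (any(c(Q, mu, b) <= 0)) stopf("all arguments must be > 0")
  if (method == "closed-form")
    return((16 * mu * Q^2 / (pi^2 * b))^(1 / 6))
  # bracket by orders of magnitude (costs balance between capillary and
  # aortic scales for any physiological parameter set), then polish the
  # stationarity condition dE/dr = 0 with Newton steps: Brent alone
  # stalls near sqrt(machine eps) relative precision
  obj <- function(logr) murray_energy(exp(logr), Q, l = 1, mu = mu, b = b)
  r <- exp(optimize(obj, interval = log(c(1e-8, 1)), tol = 1e-10)$minimum)
  dE <- function(r) -32 * mu * Q^2 / (pi * r^5) + 2 * b * pi * r
  d2E <- function(r) 160 * mu * Q^2 / (pi * r^6) + 2 * b * pi
  for (i in 1:8) {
    step <- dE(r) / d2E(r)
    r <- r - step
    if (abs(step) < 1e-15 * r) break
  }
  r
}

#' Energy-optimal bifurcation and its power-law exponent
#'
#' Builds the bifurcation Murray's model predicts: given daughter flows,
#' flow conservation fixes the parent flow, each branch radius is set to
#' its cost-minimizing value (by numeric 1-D minimization of the
#' pumping-plus-metabolic cost), and the bifurcation power-law exponent
#' is recovered from the optimal radius triple with [solve_exponent()].
#' Because \eqn{Q \propto r^3} at the optimum and flows are conserved,
#' the exponent is 3 regardless of the flows or parameters.
#'
#' @param Q_ica,Q_eca daughter volumetric flows, m^3/s (> 0).
#' @param mu viscosity, Pa s.
#' @param b metabolic coefficient, W/m^3.
#' @param method radius optimization route, see
#'   [murray_optimal_radius()].
#' @return list with `triple` (a [radius_triple()], radii in mm) and
#'   `n` (the solved exponent).
#' @examples
#' murray_bifurcation(4e-6, 2e-6)$n  # 3
#' @export
murray_bifurcation <- function(Q_ica, Q_eca, mu = 3.5e-3, b = 1000,
                               method = "numeric") {
  if (any(c(Q_ica, Q_eca) <= 0)) stopf("flows must be > 0")
  Q_cca <- Q_ica + Q_eca
  r <- vapply(c(Q_cca, Q_ica, Q_eca), murray_optimal_radius,
              numeric(1), mu = mu, b = b, method = method)
  triple <- radius_triple(r[1] * 1e3, r[2] * 1e3, r[3] * 1e3,
                          method = "theory")
  sol <- solve_exponent(triple)
  list(triple = triple, n = sol$n, status = sol$status)
}
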