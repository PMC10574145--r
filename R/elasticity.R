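# Elasticity model layer: FJC and two-state (TSQM-)FJC force-extension
# relations.  Units: force pN, length nm, energy k_BT unless stated.

# Langevin function coth(x) - 1/x, series-expanded near 0 to avoid
# cancellation (x < 1e-3 keeps the relative error below 1e-13).
langevin <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-3
  xs <- x[small]
  out[small] <- xs / 3 - xs^3 / 45
  xl <- x[!small]
  out[!small] <- 1 / tanh(xl) - 1 / xl
  out
}

backbone_factor <- function(force, params) {
  if (is.null(params$backbone_modulus)) 1 else 1 + force / params$backbone_modulus
}

#' Freely-jointed-chain fractional extension
#'
#' Entropic FJC extension \eqn{z = [L(F)/L_0]\,[\coth(F l_k/k_BT) - k_BT/(F l_k)]}
#' at stretching force F.  With the default inextensible backbone
#' (`backbone_modulus = NULL`) the enthalpic factor L(F)/L0 is 1 and z
#' saturates below 1; with a linear modulus it is 1 + F/K_seg.
#'
#' @param force Stretching force(s), pN; must be > 0 except for the exact
#'   zero-force limit, which returns 0.
#' @param params A [two_state_parameters()] object.
#' @return Fractional extension(s), dimensionless.
#' @examples
#' p <- two_state_parameters()
#' fjc_extension(300, p)
#' @export
fjc_extension <- function(force, params) {
  if (any(force < 0)) stop("force must be non-negative")
  kbt <- thermal_energy(params$const, params$temperature)
  x <- force * params$kuhn_length / kbt
  backbone_factor(force, params) * langevin(x)
}

#' Force-dependent effective saccharide unit length
#'
#' Two-state Boltzmann average of the unit length: a short (water-bridged,
#' l_u) and a long (stretched, l_f) state separated by free energy delta_g
#' (k_BT) and tilted by force through delta_l = l_f - l_u.  The long state is
#' favored at high force; the population crossover occurs at
#' F = delta_g k_BT / delta_l (see [transition_force()]).
#'
#' @param force Force(s), pN; must be >= 0.
#' @param params A [two_state_parameters()] object.
#' @return Effective unit length(s) in nm, strictly within (l_u, l_f).
#' @examples
#' p <- two_state_parameters(delta_g = 0)
#' effective_unit_length(0, p)  # (l_u + l_f) / 2
#' @export
effective_unit_length <- function(force, params) {
  if (any(force < 0)) stop("force must be non-negative")
  kbt <- thermal_energy(params$const, params$temperature)
  # a = (F * delta_l - delta_g * kbt) / kbt, in thermal units
  a <- force * delta_l(params) / kbt - params$delta_g
  params$unit_length_free * stats::plogis(-a) +
    params$unit_length_forced * stats::plogis(a)
}

#' Two-state FJC (TSQM-FJC) fractional extension
#'
#' Extension of the two-state chain relative to the free-state contour length
#' L0 = N l_u: the FJC extension rescaled by the force-dependent effective
#' unit length, \eqn{z_{TS}(F) = [l_{eff}(F)/l_u]\, z_{FJC}(F)}.  Exceeds the
#' plain FJC extension at every force and, for an inextensible backbone,
#' approaches l_f/l_u at high force.
#'
#' @inheritParams effective_unit_length
#' @return Fractional extension(s) relative to N l_u, dimensionless.
#' @examples
#' p <- two_state_parameters(delta_g = 5.53)
#' tsqm_fjc_extension(c(100, 500, 1500), p)
#' @export
tsqm_fjc_extension <- function(force, params) {
  effective_unit_length(force, params) / params$unit_length_free *
    fjc_extension(force, params)
}

#' Two-state transition (plateau) force
#'
#' Force at which the short and long unit states are equally populated,
#' F = delta_g k_BT / delta_l.  This is the midpoint of the shoulder-like
#' force plateau seen in polysaccharide force-extension curves.
#'
#' @param params A [two_state_parameters()] object; requires delta_l > 0.
#' @return Force in pN.
#' @examples
#' transition_force(two_state_parameters(delta_g = 5.53))  # ~253 pN
#' @export
transition_force <- function(params) {
  dl <- delta_l(params)
  if (!(dl > 0)) stop("delta_l must be positive")
  params$delta_g * thermal_energy(params$const, params$temperature) / dl
}

# Supremum of tsqm_fjc_extension over force (inextensible backbone only).
tsqm_supremum <- function(params) {
  if (!is.null(params$backbone_modulus)) return(Inf)
  params$unit_length_forced / params$unit_length_free
}

#' Invert the TSQM-FJC model: extension to force
#'
#' Bracketed root finding of [tsqm_fjc_extension()].  Vectorized over `z`.
#'
#' @param z Target fractional extension(s), >= 0 and below the model
#'   supremum (l_f/l_u for an inextensible backbone).
#' @param params A [two_state_parameters()] object.
#' @param tolerance Residual tolerance on extension.
#' @param upper Upper force bracket, pN; grown automatically if needed.
#' @return Force(s) in pN with |tsqm_fjc_extension(F) - z| <= tolerance.
#' @export
invert_extension_to_force <- function(z, params, tolerance = 1e-9,
                                      upper = 1e5) {
  if (any(z < 0)) stop("extension must be non-negative")
  sup <- tsqm_supremum(params)
  if (any(z >= sup)) {
    stop(sprintf(
      "unreachable extension: z >= model supremum (%.6g); chain cannot stretch that far",
      sup))
  }
  out <- numeric(length(z))
  pos <- z > 0
  if (!any(pos)) return(out)
  zp <- z[pos]
  hi0 <- upper
  while (tsqm_fjc_extension(hi0, params) < max(zp)) {
    hi0 <- hi0 * 10
    if (hi0 > 1e12) stop("failed to bracket the target extension")
  }
  # simultaneous bisection: the model is monotone, so one vectorized
  # evaluation per iteration refines every bracket at once
  lo <- numeric(length(zp))
  hi <- rep(hi0, length(zp))
  mid <- (lo + hi) / 2
  for (iter in 1:200) {
    zm <- tsqm_fjc_extension(mid, params)
    if (max(abs(zm - zp)) <= tolerance) break
    below <- zm < zp
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
    mid <- (lo + hi) / 2
  }
  out[pos] <- mid
  out
}
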