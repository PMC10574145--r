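# Conformational metrics over molecular frames: radius of gyration,
# end-to-end distance, characteristic viscosity.

#' Mass-weighted radius of gyration
#'
#' \eqn{R_g = \sqrt{\sum_i m_i |r_i - r_{com}|^2 / \sum_i m_i}} over the
#' selected atoms, where r_com is their center of mass.
#'
#' @param frame A [molecular_frame()].
#' @param selection A role (`"solute"`, `"solvent"`, `"ion"`) or one or more
#'   molecule ids.
#' @return R_g in Angstrom.
#' @examples
#' # symmetric dimer of unit masses 2 A apart has R_g = 1 A
#' @export
radius_of_gyration <- function(frame, selection = "solute") {
  idx <- select_atoms(frame, selection)
  m <- frame$atoms$mass[idx]
  r <- coords_matrix(frame, idx)
  com <- colSums(r * m) / sum(m)
  d2 <- rowSums(sweep(r, 2, com)^2)
  sqrt(sum(m * d2) / sum(m))
}

#' Radius of gyration over a frame series
#'
#' @param frames List of [molecular_frame()] objects.
#' @param selection Passed to [radius_of_gyration()].
#' @return A list with per-frame `rg` (Angstrom), `mean` and standard error
#'   `se` (0 for a single frame).
#' @export
rg_series <- function(frames, selection = "solute") {
  if (inherits(frames, "molecular_frame")) frames <- list(frames)
  if (length(frames) < 1) stop("need at least one frame")
  rg <- vapply(frames, radius_of_gyration, numeric(1), selection = selection)
  se <- if (length(rg) > 1) stats::sd(rg) / sqrt(length(rg)) else 0
  list(rg = rg, mean = mean(rg), se = se, n = length(rg))
}

#' End-to-end distance of a chain molecule
#'
#' Euclidean distance between the first and last heavy (non-hydrogen) atoms
#' of the molecule in file order, the conventional backbone endpoints when no
#' explicit atom rule is available.
#'
#' @param frame A [molecular_frame()].
#' @param molecule_id Molecule to measure; defaults to the first solute
#'   molecule.
#' @return Distance in Angstrom.
#' @export
end_to_end_distance <- function(frame, molecule_id = NULL) {
  a <- frame$atoms
  if (is.null(molecule_id)) {
    sol <- a$molecule_id[a$role == "solute"]
    if (length(sol) == 0) stop("frame has no solute molecule")
    molecule_id <- sol[1]
  }
  idx <- which(a$molecule_id == molecule_id & toupper(a$element) != "H")
  if (length(idx) < 2) stop("molecule needs at least 2 heavy atoms")
  p1 <- as.numeric(a[idx[1], c("x", "y", "z")])
  p2 <- as.numeric(a[idx[length(idx)], c("x", "y", "z")])
  vec_norm(p2 - p1)
}

#' Viscosity input bundle
#'
#' @param rg Radius of gyration, Angstrom.
#' @param density Cell density rho, kg/L (numerically equal to g/cm^3).
#' @param molar_mass Chain molar mass M, g/mol.
#' @return A list of class `viscosity_input`.
#' @export
viscosity_input <- function(rg, density, molar_mass) {
  stopifnot(rg > 0, density > 0, molar_mass > 0)
  structure(list(rg = rg, density = density, molar_mass = molar_mass),
            class = "viscosity_input")
}

#' Characteristic viscosity of a dilute chain solution
#'
#' Flory-type scaling \eqn{\eta = (10\pi N_A/3)\, R_g^3\, \rho / M} with R_g
#' converted to cm and rho in g/cm^3.  The absolute value carries the units
#' implied by this convention (cm^3 scale per gram); only ratios between
#' conditions are interpreted, which is why [normalized_viscosity()] is the
#' reported quantity.
#'
#' @param input A [viscosity_input()].
#' @param const A [physical_constants()] object (for Avogadro's number).
#' @return Characteristic viscosity (model units).
#' @export
characteristic_viscosity <- function(input, const = physical_constants()) {
  stopifnot(inherits(input, "viscosity_input"))
  rg_cm <- input$rg * 1e-8
  (10 * pi * const$avogadro / 3) * rg_cm^3 * input$density / input$molar_mass
}

#' Normalized characteristic viscosity across conditions
#'
#' Divides each condition's characteristic viscosity by the reference
#' condition's (conventionally pure water, normalized to 1).
#'
#' @param inputs Named list of [viscosity_input()] objects.
#' @param reference Name of the reference condition.
#' @param const A [physical_constants()] object.
#' @return Named numeric vector of ratios; the reference maps to exactly 1.
#' @examples
#' normalized_viscosity(
#'   list(water = viscosity_input(9.48, 0.991, 1015),
#'        pH3   = viscosity_input(12.27, 0.983, 1015)),
#'   reference = "water")
#' @export
normalized_viscosity <- function(inputs, reference,
                                 const = physical_constants()) {
  if (!reference %in% names(inputs)) {
    stop(sprintf("reference condition '%s' missing from inputs", reference))
  }
  eta <- vapply(inputs, characteristic_viscosity, numeric(1), const = const)
  out <- eta / eta[[reference]]
  out[[reference]] <- 1
  out
}
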