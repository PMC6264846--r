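#' Cell physiology parameters
#'
#' Geometry, permeability and composition of the spherical model cell.
#' Exchange with the medium is purely diffusive; the dimensionless
#' coefficient `eps_m` scales the bulk-water diffusivity of every
#' substrate identically, representing the resistance of the cell
#' membrane layers.  Its default is calibrated to the carbon-to-nitrogen
#' threshold for the onset of nitrogen fixation at 1 percent O2
#' saturation, the regime where energetically balanced respiration just
#' depletes the diffusive oxygen influx; the thresholds at higher oxygen
#' are then out-of-sample predictions (see [calibrate_physiology()] and
#' the package vignette).  All other defaults are literature-scale
#' values for an *Azotobacter vinelandii*-like cell at 30 degrees C.
#'
#' @param radius Cell radius (m).
#' @param eps_m Dimensionless membrane-layer diffusivity coefficient in
#'   `(0, 1]`.  Default 0.0076 (calibrated).
#' @param diffusivity_o2,diffusivity_sucrose,diffusivity_nh4,diffusivity_n2
#'   Aqueous diffusion coefficients at 30 degrees C (m^2 h^-1).
#' @param carbon_per_cell Mol biomass carbon per cell.
#' @param protein_mass_fraction Gram protein per gram dry biomass.
#' @param biomass_formula Biomass [elemental_formula()].
#' @param energy An [energy_parameters()] object.
#' @return An object of class `cell_physiology`.
#' @export
cell_physiology <- function(radius = 1e-6,
                            eps_m = 0.0076,
                            diffusivity_o2 = 8.64e-6,
                            diffusivity_sucrose = 1.9e-6,
                            diffusivity_nh4 = 7.2e-6,
                            diffusivity_n2 = 7.6e-6,
                            carbon_per_cell = 4e-14,
                            protein_mass_fraction = 0.55,
                            biomass_formula = biomass_formula_default(),
                            energy = energy_parameters()) {
  if (!(radius > 0)) stop("radius must be > 0", call. = FALSE)
  if (!(eps_m > 0 && eps_m <= 1)) stop("eps_m must be in (0, 1]", call. = FALSE)
  d <- c(diffusivity_o2, diffusivity_sucrose, diffusivity_nh4, diffusivity_n2)
  if (any(!is.finite(d)) || any(d <= 0)) {
    stop("diffusivities must be positive and finite", call. = FALSE)
  }
  if (!(carbon_per_cell > 0)) stop("carbon_per_cell must be > 0", call. = FALSE)
  if (!(protein_mass_fraction > 0 && protein_mass_fraction < 1)) {
    stop("protein_mass_fraction must be in (0, 1)", call. = FALSE)
  }
  stopifnot(inherits(biomass_formula, "elemental_formula"),
            inherits(energy, "energy_parameters"))
  if (biomass_formula$n < 1) {
    stop("biomass formula must contain nitrogen", call. = FALSE)
  }
  structure(list(radius = radius, eps_m = eps_m,
                 diffusivity_o2 = diffusivity_o2,
                 diffusivity_sucrose = diffusivity_sucrose,
                 diffusivity_nh4 = diffusivity_nh4,
                 diffusivity_n2 = diffusivity_n2,
                 carbon_per_cell = carbon_per_cell,
                 protein_mass_fraction = protein_mass_fraction,
                 biomass_formula = biomass_formula,
                 energy = energy),
            class = "cell_physiology")
}

#' Ambient dissolved-gas environment
#'
#' Oxygen is specified as a fraction of saturation; 100 percent
#' saturation corresponds to 225 uM (0.225 mol m^-3) at 30 degrees C
#' under normal air composition.  Dinitrogen is held at its
#' air-equilibrium concentration.
#'
#' @param o2_fraction Ambient O2 as a fraction of saturation (>= 0;
#'   values above 1 describe hyperoxic media).
#' @param o2_saturation Saturation concentration (mol m^-3, default 0.225).
#' @param n2_concentration Dissolved N2 (mol m^-3, default 0.4,
#'   air equilibrium at 30 degrees C).
#' @return An object of class `ambient_environment`.
#' @export
ambient_environment <- function(o2_fraction,
                                o2_saturation = 0.225,
                                n2_concentration = 0.4) {
  if (!is.finite(o2_fraction) || o2_fraction < 0) {
    stop("o2_fraction must be >= 0", call. = FALSE)
  }
  if (!(o2_saturation > 0)) stop("o2_saturation must be > 0", call. = FALSE)
  if (n2_concentration < 0) stop("n2_concentration must be >= 0", call. = FALSE)
  structure(list(o2_fraction = o2_fraction, o2_saturation = o2_saturation,
                 n2_concentration = n2_concentration, temperature_c = 30),
            class = "ambient_environment")
}

#' Diffusive flux into a spherical cell
#'
#' Steady diffusion to a sphere: `4 * pi * radius * diffusivity * eps_m *
#' (c_ambient - c_internal)`.  Positive values are influx; a negative
#' result simply means efflux.
#'
#' @param phys A [cell_physiology()] object.
#' @param diffusivity Aqueous diffusivity of the species (m^2 h^-1).
#' @param c_ambient,c_internal Concentrations (mol m^-3).
#' @return Per-cell flux (mol cell^-1 h^-1).
#' @export
diffusive_flux <- function(phys, diffusivity, c_ambient, c_internal = 0) {
  stopifnot(inherits(phys, "cell_physiology"))
  if (c_ambient < 0 || c_internal < 0) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  4 * pi * phys$radius * diffusivity * phys$eps_m * (c_ambient - c_internal)
}

#' Oxygen-scavenging respiration demand
#'
#' The sucrose oxidation rate whose O2 consumption exactly balances the
#' diffusive O2 influx when the cytosol is held anoxic (internal O2 = 0),
#' i.e. the respiratory-protection requirement for nitrogenase.  Complete
#' oxidation of sucrose consumes 12 O2 per mol, so the demand is the O2
#' influx divided by 12.  Linear in the ambient oxygen fraction.
#'
#' @param phys A [cell_physiology()] object.
#' @param env An [ambient_environment()] object.
#' @return Per-cell sucrose respiration rate (mol sucrose cell^-1 h^-1).
#' @export
o2_scavenging_demand <- function(phys, env) {
  stopifnot(inherits(env, "ambient_environment"))
  o2_per_sucrose <- electron_equivalents(sucrose_formula()) / 4
  diffusive_flux(phys, phys$diffusivity_o2,
                 env$o2_fraction * env$o2_saturation, 0) / o2_per_sucrose
}

#' Maximum diffusive uptake of a substrate
#'
#' The diffusive flux at zero internal concentration: the ceiling on
#' per-cell uptake at a given ambient concentration.  The chemostat
#' solver assumes complete drawdown of the limiting substrates; this
#' ceiling (evaluated at the inflow concentration) verifies that the
#' required fluxes are attainable with residual concentrations far below
#' the inflow.
#'
#' @param phys A [cell_physiology()] object.
#' @param env An [ambient_environment()] object (supplies the ambient
#'   concentration for `"o2"` and `"n2"`).
#' @param substrate One of `"sucrose"`, `"nh4"`, `"n2"`, `"o2"`.
#' @param c_ambient Ambient concentration (mol m^-3); required for
#'   `"sucrose"` and `"nh4"`, optional override for the gases.
#' @return Per-cell maximum uptake (mol cell^-1 h^-1).
#' @export
uptake_ceiling <- function(phys, env, substrate = c("sucrose", "nh4", "n2", "o2"),
                           c_ambient = NULL) {
  stopifnot(inherits(env, "ambient_environment"))
  substrate <- match.arg(substrate)
  diffusivity <- switch(substrate,
                        sucrose = phys$diffusivity_sucrose,
                        nh4 = phys$diffusivity_nh4,
                        n2 = phys$diffusivity_n2,
                        o2 = phys$diffusivity_o2)
  if (is.null(c_ambient)) {
    c_ambient <- switch(substrate,
                        n2 = env$n2_concentration,
                        o2 = env$o2_fraction * env$o2_saturation,
                        stop("c_ambient is required for ", substrate,
                             call. = FALSE))
  }
  diffusive_flux(phys, diffusivity, c_ambient, 0)
}
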