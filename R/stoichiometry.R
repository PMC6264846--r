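#' Empirical elemental formula
#'
#' Builds the empirical formula `C_c H_h O_o N_n` of a compound used in the
#' half-reaction bookkeeping: the carbon substrate (sucrose, `C12H22O11`),
#' the biomass macromolecule pool (default `C5H7O2N`), or a carbon-free
#' electron acceptor such as `O2`.
#'
#' @param c,h,o,n Non-negative integer subscripts.  `n` defaults to 0.
#' @return An object of class `elemental_formula`.
#' @examples
#' sucrose_formula()                 # C12H22O11
#' elemental_formula(5, 7, 2, 1)     # the standard cell formula
#' @export
elemental_formula <- function(c, h, o, n = 0) {
  v <- c(c = c, h = h, o = o, n = n)
  if (length(v) != 4L || !all(is.finite(v))) {
    stop("formula subscripts must be four finite numbers", call. = FALSE)
  }
  if (any(v < 0)) stop("formula subscripts must be non-negative", call. = FALSE)
  if (sum(v) == 0) stop("empty formula", call. = FALSE)
  structure(as.list(v), class = "elemental_formula")
}

#' @export
print.elemental_formula <- function(x, ...) {
  sub <- function(s, k) if (k == 0) "" else if (k == 1) s else paste0(s, k)
  cat("<elemental_formula> ", sub("C", x$c), sub("H", x$h), sub("O", x$o),
      sub("N", x$n), "\n", sep = "")
  invisible(x)
}

#' Sucrose and default biomass formulas
#'
#' `sucrose_formula()` is the carbon substrate of the simulated medium.
#' `biomass_formula_default()` is `C5H7O2N`, the standard empirical cell
#' formula of the half-reaction framework (N:C = 1:5); the physiology
#' accepts any other nitrogen-containing formula.
#'
#' @return An `elemental_formula`.
#' @export
sucrose_formula <- function() elemental_formula(12, 22, 11, 0)

#' @rdname sucrose_formula
#' @export
biomass_formula_default <- function() elemental_formula(5, 7, 2, 1)

#' Electron equivalents of a compound
#'
#' Degree-of-reduction bookkeeping: the number of electron equivalents
#' transferred per mole when the compound is fully oxidized to CO2 and
#' H2O, with nitrogen entering or leaving in a stated reference form.
#'
#' The value is `4c + h - 2o - k n`.  With the ammonium reference
#' (`NH3`/`NH4+`, nitrogen at oxidation state -III) each nitrogen carries
#' its three reducing equivalents in and out unchanged, so `k = 3`.  With
#' the dinitrogen reference (`N2`, oxidation state 0) those three
#' equivalents per nitrogen count as part of the compound's reducing
#' power, so `k = 0`.  Hence biomass `C5H7O2N` holds 20 electron
#' equivalents against ammonium but 23 against `N2`; the extra 3 per
#' nitrogen are exactly what nitrogenase must supply (plus the equivalents
#' it loses to obligatory H2 evolution, accounted separately in
#' [fixation_overhead()]).
#'
#' @param formula An [elemental_formula()].
#' @param n_reference `"ammonium"` (`k = 3`) or `"n2"` (`k = 0`).
#' @param role `"donor"` (default) counts equivalents released on
#'   oxidation; `"acceptor"` counts equivalents consumed on reduction
#'   (e.g. `O2 + 4H+ + 4e- -> 2H2O` gives 4 per mol O2).
#' @return Electron equivalents per mole (non-negative scalar).
#' @examples
#' electron_equivalents(sucrose_formula())                   # 48
#' electron_equivalents(elemental_formula(0, 0, 2), role = "acceptor")  # 4
#' electron_equivalents(biomass_formula_default())           # 20
#' @export
electron_equivalents <- function(formula,
                                 n_reference = c("ammonium", "n2"),
                                 role = c("donor", "acceptor")) {
  stopifnot(inherits(formula, "elemental_formula"))
  n_reference <- match.arg(n_reference)
  role <- match.arg(role)
  k <- if (n_reference == "ammonium") 3 else 0
  ee <- 4 * formula$c + formula$h - 2 * formula$o - k * formula$n
  if (role == "acceptor") ee <- -ee
  if (ee < 0) {
    stop("negative electron equivalents: formula is not a valid ", role,
         " under the ", n_reference, " reference", call. = FALSE)
  }
  ee
}

#' Energy and nitrogenase cost parameters
#'
#' Collects the energetic constants of the stoichiometric network.  The
#' energy currency is ATP equivalents; respiration yields
#' `atp_per_electron_pair_to_o2` ATP per pair of electron equivalents
#' delivered to oxygen, of which only a fraction (the transfer efficiency
#' `eps_nh4` or `eps_n2`, depending on the nitrogen source the energy is
#' spent on) is usable for biosynthesis.  Note that the product
#' `eps * atp_per_electron_pair_to_o2` together with the synthesis demand
#' `atp_per_biomass_c` is what actually fixes the growth yield, so the
#' individual constants are partially degenerate; see the package
#' vignette.
#'
#' @param eps_nh4 Energy transfer efficiency for ammonium-based growth
#'   (dimensionless, default 0.54).
#' @param eps_n2 Efficiency for fixation-based growth (default 0.45,
#'   at most `eps_nh4`).
#' @param atp_per_electron_pair_to_o2 ATP equivalents generated per 2
#'   electron equivalents respired (default 3, classical P/O bookkeeping).
#' @param atp_per_n2_fixed ATP demand of nitrogenase per mol N2 (default
#'   16, from `N2 + 8e- + 16ATP -> 2NH3 + H2`).
#' @param electrons_per_n2_fixed Electron equivalents consumed by
#'   nitrogenase per mol N2 (default 8; the 2 equivalents evolved as H2
#'   are counted as lost).
#' @param atp_per_biomass_c ATP demand of macromolecular synthesis per mol
#'   biomass carbon (default 0.8).
#' @param atp_per_n_assimilated ATP demand of ammonium assimilation
#'   (glutamine synthetase step) per mol N incorporated, paid for both
#'   nitrogen sources (default 1).
#' @return An object of class `energy_parameters`.
#' @export
energy_parameters <- function(eps_nh4 = 0.54,
                              eps_n2 = 0.45,
                              atp_per_electron_pair_to_o2 = 3,
                              atp_per_n2_fixed = 16,
                              electrons_per_n2_fixed = 8,
                              atp_per_biomass_c = 0.8,
                              atp_per_n_assimilated = 1) {
  if (!(eps_nh4 > 0 && eps_nh4 <= 1)) stop("eps_nh4 must be in (0, 1]", call. = FALSE)
  if (!(eps_n2 > 0 && eps_n2 <= 1)) stop("eps_n2 must be in (0, 1]", call. = FALSE)
  if (atp_per_electron_pair_to_o2 <= 0) stop("atp_per_electron_pair_to_o2 must be > 0", call. = FALSE)
  if (atp_per_n2_fixed < 0 || electrons_per_n2_fixed < 0) {
    stop("nitrogenase costs must be non-negative", call. = FALSE)
  }
  if (atp_per_biomass_c < 0 || atp_per_n_assimilated < 0) {
    stop("synthesis costs must be non-negative", call. = FALSE)
  }
  structure(list(eps_nh4 = eps_nh4, eps_n2 = eps_n2,
                 atp_per_electron_pair_to_o2 = atp_per_electron_pair_to_o2,
                 atp_per_n2_fixed = atp_per_n2_fixed,
                 electrons_per_n2_fixed = electrons_per_n2_fixed,
                 atp_per_biomass_c = atp_per_biomass_c,
                 atp_per_n_assimilated = atp_per_n_assimilated),
            class = "energy_parameters")
}

# sucrose cost of biomass production, mol sucrose per mol biomass N,
# for a pure nitrogen source; the energy balance is closed exactly:
# ATP from respired electrons (efficiency-scaled) equals ATP demand.
.sucrose_per_n <- function(params, n_source, biomass) {
  if (biomass$n < 1) stop("biomass formula must contain nitrogen", call. = FALSE)
  e_don <- electron_equivalents(sucrose_formula())
  gamma <- electron_equivalents(biomass) / biomass$n    # e-eq per biomass N
  beta <- biomass$c / biomass$n                         # C per biomass N
  atp_per_e <- params$atp_per_electron_pair_to_o2 / 2
  if (n_source == "ammonium") {
    eps <- params$eps_nh4
    e_direct <- 0
    atp <- params$atp_per_biomass_c * beta + params$atp_per_n_assimilated
  } else {
    eps <- params$eps_n2
    e_direct <- params$electrons_per_n2_fixed / 2
    atp <- params$atp_per_biomass_c * beta + params$atp_per_n_assimilated +
      params$atp_per_n2_fixed / 2
  }
  s <- (gamma + e_direct + atp / (eps * atp_per_e)) / e_don
  if (!is.finite(s) || s <= 0) {
    stop("infeasible energy balance for ", n_source, "-based growth", call. = FALSE)
  }
  s
}

#' Biomass yield on sucrose for a pure nitrogen source
#'
#' Splits the electron equivalents of the sucrose consumed for growth
#' between biomass synthesis and respiration such that the ATP generated
#' (efficiency-scaled electrons to O2 times the P/O constant) exactly
#' covers the ATP demand of synthesis, ammonium assimilation and, for
#' `n_source = "n2"`, nitrogenase.  Ammonium-based growth always yields
#' more biomass carbon per sucrose than fixation-based growth because
#' fixation adds electron and ATP costs.
#'
#' @inheritParams fixation_overhead
#' @param n_source `"ammonium"` or `"n2"`.
#' @param biomass Biomass [elemental_formula()]; must contain nitrogen.
#' @return Mol biomass carbon produced per mol sucrose consumed
#'   (consumption includes the respired share that pays for growth energy).
#' @export
synthesis_yield <- function(params, n_source = c("ammonium", "n2"),
                            biomass = biomass_formula_default()) {
  stopifnot(inherits(params, "energy_parameters"),
            inherits(biomass, "elemental_formula"))
  n_source <- match.arg(n_source)
  beta <- biomass$c / biomass$n
  y <- beta / .sucrose_per_n(params, n_source, biomass)
  if (y > sucrose_formula()$c) {
    stop("infeasible energy balance: implied yield exceeds the carbon content ",
         "of the substrate", call. = FALSE)
  }
  y
}

#' Carbon overhead of nitrogen fixation
#'
#' The sucrose that must be additionally oxidized per mol nitrogen
#' incorporated through nitrogenase rather than by ammonium uptake:
#' the direct electron demand of the enzyme plus the electrons respired
#' to generate its ATP demand at the efficiency-scaled ATP yield.
#'
#' @param params An [energy_parameters()] object.
#' @return Mol sucrose per mol N fixed (strictly positive for any
#'   non-zero nitrogenase cost).
#' @export
fixation_overhead <- function(params) {
  stopifnot(inherits(params, "energy_parameters"))
  e_don <- electron_equivalents(sucrose_formula())
  e_fix <- params$electrons_per_n2_fixed / 2
  atp_fix <- params$atp_per_n2_fixed / 2
  atp_per_e <- params$atp_per_electron_pair_to_o2 / 2
  (e_fix + atp_fix / (params$eps_n2 * atp_per_e)) / e_don
}

#' Stoichiometric mode for a mixed nitrogen source
#'
#' The organism may take any fraction `f_n2` of its nitrogen from
#' fixation and the rest from ammonium.  The mixed mode is the linear
#' blend of the two pure modes on a per-nitrogen basis: the sucrose cost
#' per mol biomass N is `(1 - f_n2) * s_A + f_n2 * s_B`, where `s_A` and
#' `s_B` are the energy-closed costs of pure ammonium- and pure
#' fixation-based growth.  The itemized electron ledger (per mol sucrose
#' consumed for growth) closes exactly on the donor's electron content.
#'
#' @param f_n2 Fraction of assimilated nitrogen from fixation, in
#'   `[0, 1]`.
#' @inheritParams synthesis_yield
#' @return An object of class `stoichiometric_mode` with fields `f_n2`,
#'   `yield_biomass_c_per_sucrose`, `sucrose_per_n_fixed`,
#'   `o2_per_sucrose_respired` and `ledger` (electron equivalents per mol
#'   sucrose: `to_biomass`, `to_o2`, `to_n2`).
#' @export
mode_for <- function(f_n2, params, biomass = biomass_formula_default()) {
  stopifnot(inherits(params, "energy_parameters"))
  if (!is.finite(f_n2) || f_n2 < 0 || f_n2 > 1) {
    stop("f_n2 must lie in [0, 1]", call. = FALSE)
  }
  e_don <- electron_equivalents(sucrose_formula())
  gamma <- electron_equivalents(biomass) / biomass$n
  beta <- biomass$c / biomass$n
  s_a <- .sucrose_per_n(params, "ammonium", biomass)
  s_b <- .sucrose_per_n(params, "n2", biomass)
  s <- (1 - f_n2) * s_a + f_n2 * s_b
  e_fix <- params$electrons_per_n2_fixed / 2
  to_biomass <- gamma / s
  to_n2 <- f_n2 * e_fix / s
  structure(list(
    f_n2 = f_n2,
    yield_biomass_c_per_sucrose = beta / s,
    sucrose_per_n_fixed = fixation_overhead(params),
    o2_per_sucrose_respired = e_don / 4,
    ledger = c(to_biomass = to_biomass,
               to_o2 = e_don - to_biomass - to_n2,
               to_n2 = to_n2)
  ), class = "stoichiometric_mode")
}

#' @export
print.stoichiometric_mode <- function(x, ...) {
  cat(sprintf("<stoichiometric_mode> f_N2 = %.3f\n", x$f_n2))
  cat(sprintf("  yield: %.4f mol biomass C / mol sucrose\n",
              x$yield_biomass_c_per_sucrose))
  cat(sprintf("  fixation overhead: %.4f mol sucrose / mol N fixed\n",
              x$sucrose_per_n_fixed))
  cat("  electron ledger (per mol sucrose):\n")
  print(round(x$ledger, 6))
  invisible(x)
}
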