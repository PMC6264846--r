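#' Chemostat forcing
#'
#' Inflow composition and dilution rate of the continuous culture.  The
#' supply ratio `c_over_n = sucrose_in / ammonium_in` (mol sucrose per
#' mol N) and its elemental form `c_to_n = 12 * c_over_n` (mol C per mol
#' N; sucrose carries 12 carbons) are derived fields.
#'
#' @param sucrose_in Inflow sucrose (mol m^-3; 1 mM = 1 mol m^-3).
#' @param ammonium_in Inflow ammonium (mol m^-3, default 2.5).
#' @param dilution_rate Dilution rate D (h^-1, default 0.15); at steady
#'   state the specific growth rate equals D.
#' @param env An [ambient_environment()] object.
#' @return An object of class `culture_conditions`.
#' @export
culture_conditions <- function(sucrose_in,
                               ammonium_in = 2.5,
                               dilution_rate = 0.15,
                               env = ambient_environment(0.05)) {
  if (!(dilution_rate > 0)) stop("dilution_rate must be > 0", call. = FALSE)
  if (sucrose_in < 0 || ammonium_in < 0) {
    stop("inflow concentrations must be >= 0", call. = FALSE)
  }
  stopifnot(inherits(env, "ambient_environment"))
  c_over_n <- if (ammonium_in > 0) sucrose_in / ammonium_in else Inf
  structure(list(sucrose_in = sucrose_in, ammonium_in = ammonium_in,
                 dilution_rate = dilution_rate, env = env,
                 c_over_n = c_over_n,
                 c_to_n = sucrose_formula()$c * c_over_n),
            class = "culture_conditions")
}

#' Respiration policy
#'
#' Under `"sim1"`, carbohydrate in excess of the energetic demand of
#' growth is respired in all regimes, including nitrogen-limited growth
#' on ammonium.  Under `"sim2"` such excess respiration occurs only while
#' the cells are fixing nitrogen; otherwise the excess washes out as
#' unconsumed residual sucrose.  The two policies yield identical
#' biomass, protein and fixation; only respiration differs, and only in
#' the ammonium-limited regime.
#'
#' @param mode `"sim1"` or `"sim2"`.
#' @return An object of class `respiration_policy`.
#' @export
respiration_policy <- function(mode = c("sim1", "sim2")) {
  mode <- match.arg(mode)
  structure(list(mode = mode), class = "respiration_policy")
}

# Reduced coefficients of the steady-state model.  All per-biomass-carbon
# rates are in h^-1 equivalents; sucrose costs s_* are mol sucrose per mol
# biomass N.
.coefs <- function(cond, phys) {
  en <- phys$energy
  bm <- phys$biomass_formula
  D <- cond$dilution_rate
  e_don <- electron_equivalents(sucrose_formula())
  gamma <- electron_equivalents(bm) / bm$n
  beta <- bm$c / bm$n
  e_fix <- en$electrons_per_n2_fixed / 2
  s_a <- .sucrose_per_n(en, "ammonium", bm)
  s_b <- .sucrose_per_n(en, "n2", bm)
  # per-biomass-C O2 influx ceiling at zero internal O2 (mol O2 per mol C h^-1)
  phi <- diffusive_flux(phys, phys$diffusivity_o2,
                        cond$env$o2_fraction * cond$env$o2_saturation, 0) /
    phys$carbon_per_cell
  # energy-balanced growth respiration, mol O2 per mol biomass C h^-1, at f
  demand <- function(f) {
    s <- (1 - f) * s_a + f * s_b
    (D / beta) * (e_don * s - gamma - f * e_fix) / 4
  }
  # sucrose cost per biomass C in the anoxic (fixing) state, where total
  # O2 consumption is pinned at the influx ceiling: c(f) = c0 + c1 * f
  c0 <- (D * gamma / beta + 4 * phi) / e_don
  c1 <- D * e_fix / (e_don * beta)
  # largest f whose growth respiration still fits under the O2 ceiling
  f_anox <- (4 * beta * phi / D - (e_don * s_a - gamma)) /
    (e_don * (s_b - s_a) - e_fix)
  list(D = D, e_don = e_don, gamma = gamma, beta = beta, e_fix = e_fix,
       s_a = s_a, s_b = s_b, phi = phi, demand = demand,
       c0 = c0, c1 = c1, f_anox = f_anox)
}

# assemble a flux_solution from the primitive state
.build_solution <- function(cond, phys, policy, B, f, res_suc, res_nh4,
                            excess, fixing) {
  k <- .coefs(cond, phys)
  en <- phys$energy
  D <- k$D
  nb <- D * B / k$beta                       # N into biomass, mol N m^-3 h^-1
  n_fixed <- f * nb
  nh4_consumed <- (1 - f) * nb
  sucrose_consumed <- D * (cond$sucrose_in - res_suc)
  # electron closure -> volumetric O2 respiration
  e_to_o2 <- k$e_don * sucrose_consumed - electron_equivalents(phys$biomass_formula) /
    phys$biomass_formula$n * nb - k$e_fix * n_fixed
  o2_respired <- e_to_o2 / 4
  # carbon allocation, itemized as sucrose fluxes (mol sucrose m^-3 h^-1)
  atp_per_e <- en$atp_per_electron_pair_to_o2 / 2
  blend_eps <- (1 - f) / en$eps_nh4 + f / en$eps_n2
  synth_e <- blend_eps * en$atp_per_biomass_c * k$beta / atp_per_e +
    (k$gamma - 4 * k$beta)
  nh4_e <- (1 - f) * en$atp_per_n_assimilated / (en$eps_nh4 * atp_per_e)
  fix_e <- f * (k$e_fix + (en$atp_per_n2_fixed / 2 + en$atp_per_n_assimilated) /
                  (en$eps_n2 * atp_per_e))
  s_f <- (1 - f) * k$s_a + f * k$s_b
  growth_sucrose <- nb * s_f
  protection <- if (fixing) max(sucrose_consumed - growth_sucrose - excess, 0) else 0
  alloc <- c(
    biomass_c = nb * k$beta / sucrose_formula()$c,
    synthesis_energy = nb * synth_e / k$e_don,
    nh4_assimilation_energy = nb * nh4_e / k$e_don,
    fixation_energy = nb * fix_e / k$e_don,
    respiratory_protection = protection,
    excess_respiration = excess
  )
  gdw_per_c <- .dry_mass_per_c(phys$biomass_formula)
  protein <- phys$protein_mass_fraction * gdw_per_c * B
  sol <- structure(list(
    biomass = B,
    biomass_gdw = gdw_per_c * B,
    protein = protein,
    f_n2 = f,
    regime = NA_character_,
    sucrose_consumed = sucrose_consumed,
    nh4_consumed = nh4_consumed,
    n_fixed = n_fixed,
    o2_respired = o2_respired,
    residual_nh4 = res_nh4,
    residual_sucrose = res_suc,
    n_fixation_per_protein = if (protein > 0) n_fixed / protein else NA_real_,
    respiration_per_protein = if (protein > 0) o2_respired / protein else NA_real_,
    carbon_allocation = alloc,
    conditions = cond,
    policy = policy$mode
  ), class = "flux_solution")
  sol$regime <- classify_regime(sol, cond)
  sol
}

# g dry biomass per mol biomass C, from the empirical formula
.dry_mass_per_c <- function(bm) {
  (12.011 * bm$c + 1.008 * bm$h + 15.999 * bm$o + 14.007 * bm$n) / bm$c
}

#' Solve the chemostat steady state
#'
#' Finds the steady state of the continuous culture at the given dilution
#' rate that maximizes the standing stock of biomass over all feasible
#' fractions `f_n2` of nitrogen acquired by fixation.  The balances are:
#' supply flux `D * inflow` for each substrate, with the limiting
#' substrates drawn down to (effectively) zero residual; electron, carbon
#' and nitrogen conservation through the stoichiometric network; and the
#' respiratory-protection constraint that nitrogen fixation is possible
#' only when total respiration consumes the entire diffusive O2 influx at
#' zero internal O2.  Because the per-cell O2 influx and the per-cell
#' respiration both scale with biomass, the optimal `f_n2` reduces to a
#' piecewise-linear problem solved analytically (see the vignette); a
#' brute-force grid over `f_n2` gives identical answers and is kept as a
#' test oracle.
#'
#' If the energy-balanced respiration of ammonium-based growth already
#' exceeds the maximal O2 influx, the imposed growth rate is not
#' attainable (oxygen-limited) and the culture washes out: the solution
#' has zero biomass and the inflows as residuals.
#'
#' @param cond A [culture_conditions()] object.
#' @param phys A [cell_physiology()] object.
#' @param policy A [respiration_policy()] object.
#' @return An object of class `flux_solution`: volumetric pools
#'   (`biomass` in mol C m^-3, `biomass_gdw` and `protein` in g m^-3),
#'   `f_n2`, `regime`, volumetric rates (`sucrose_consumed`,
#'   `nh4_consumed`, `n_fixed`, `o2_respired`, mol m^-3 h^-1), residual
#'   concentrations, protein-specific rates (mol (g protein)^-1 h^-1) and
#'   the itemized `carbon_allocation` (mol sucrose m^-3 h^-1, summing to
#'   `sucrose_consumed`).
#' @examples
#' cond <- culture_conditions(20, 2.5, env = ambient_environment(0.05))
#' sol <- solve_steady_state(cond)
#' sol$f_n2
#' @export
solve_steady_state <- function(cond, phys = cell_physiology(),
                               policy = respiration_policy("sim1")) {
  stopifnot(inherits(cond, "culture_conditions"),
            inherits(phys, "cell_physiology"),
            inherits(policy, "respiration_policy"))
  k <- .coefs(cond, phys)
  D <- k$D
  S <- cond$sucrose_in
  A <- cond$ammonium_in
  # no carbon, or growth at D infeasible under the O2 ceiling: washout
  if (S <= 0 || k$demand(0) > k$phi * (1 + 1e-12)) {
    return(.build_solution(cond, phys, policy, B = 0, f = 0,
                           res_suc = S, res_nh4 = A, excess = 0,
                           fixing = FALSE))
  }
  f_anox <- min(max(k$f_anox, 0), 1)
  growth_cost0 <- D * k$s_a / k$beta      # sucrose per biomass C, f = 0
  bc0 <- D * S / growth_cost0             # carbon-limited biomass at f = 0
  if (A <= 0) {
    f <- min(1, f_anox)
    cf <- k$c0 + k$c1 * f
    B <- D * S / cf
    return(.build_solution(cond, phys, policy, B = B, f = f,
                           res_suc = 0, res_nh4 = 0, excess = 0,
                           fixing = TRUE))
  }
  bn0 <- k$beta * A
  # onset test: biomass attainable at f -> 0+ in the anoxic state
  if (D * S / k$c0 <= bn0 * (1 + 1e-12)) {
    # no fixation: regime A (carbon-limited) or B (ammonium-limited)
    B <- min(bc0, bn0)
    res_nh4 <- max(A - B / k$beta, 0)
    excess_supply <- max(D * S - B * growth_cost0, 0)
    if (excess_supply > 0 && policy$mode == "sim1") {
      # excess respiration is itself capped by the per-cell O2 ceiling
      cap <- B * max(k$phi - k$demand(0), 0) *
        4 / k$e_don  # O2 headroom -> sucrose
      excess <- min(excess_supply, cap)
    } else {
      excess <- 0
    }
    res_suc <- (excess_supply - excess) / D
    return(.build_solution(cond, phys, policy, B = B, f = 0,
                           res_suc = res_suc, res_nh4 = res_nh4,
                           excess = excess, fixing = FALSE))
  }
  # regime C: fixation carries flux.  Crossing of the nitrogen-capped
  # biomass beta*A/(1-f) with the carbon-capped biomass D*S/c(f).
  f_star <- (D * S - bn0 * k$c0) / (D * S + bn0 * k$c1)
  if (f_star <= f_anox) {
    f <- f_star
    B <- bn0 / (1 - f)
    res_suc <- 0
  } else {
    f <- f_anox
    B <- bn0 / (1 - f)
    res_suc <- max(S - B * (k$c0 + k$c1 * f) / D, 0)
  }
  .build_solution(cond, phys, policy, B = B, f = f,
                  res_suc = res_suc, res_nh4 = 0, excess = 0, fixing = TRUE)
}

#' Classify a steady state into the three metabolic regimes
#'
#' Regime `A` (carbon-limited growth on ammonium): no fixation and
#' residual ammonium above tolerance.  Regime `B` (ammonium-limited
#' growth): no fixation and ammonium drawn down.  Regime `C` (mixed
#' assimilation and fixation): `f_n2 > 0`.  A state with residual
#' ammonium and active fixation violates the model's optimality
#' invariant (ammonium is always the cheaper nitrogen source) and raises
#' an error.
#'
#' @param sol A [solve_steady_state()] solution.
#' @param cond The [culture_conditions()] (unused beyond validation;
#'   the solution carries its own residuals).
#' @param tolerance Residual-concentration tolerance (mol m^-3).
#' @return One of `"A"`, `"B"`, `"C"`.
#' @export
classify_regime <- function(sol, cond = NULL, tolerance = .TOL_RESIDUAL) {
  f <- sol$f_n2
  res <- sol$residual_nh4
  if (f > .TOL_FN2) {
    if (res > tolerance) {
      stop("inconsistent steady state: residual ammonium ", format(res),
           " mol m^-3 with f_n2 = ", format(f), call. = FALSE)
    }
    return("C")
  }
  if (res > tolerance) "A" else "B"
}

#' Protein-specific rates
#'
#' Divides the volumetric nitrogen-fixation and respiration rates by the
#' protein concentration (`protein_mass_fraction` times dry biomass).  A
#' zero-biomass solution has no defined per-protein rates; this is
#' signalled explicitly through `defined = FALSE` rather than by
#' propagating NaN.
#'
#' @param sol A [solve_steady_state()] solution.
#' @param phys The [cell_physiology()] used to produce it.
#' @return A list with `defined`, `n_fixation_per_protein` and
#'   `respiration_per_protein` (mol (g protein)^-1 h^-1).
#' @export
protein_specific <- function(sol, phys = cell_physiology()) {
  stopifnot(inherits(sol, "flux_solution"))
  if (!(sol$biomass > 0)) {
    return(list(defined = FALSE,
                n_fixation_per_protein = NA_real_,
                respiration_per_protein = NA_real_))
  }
  protein <- phys$protein_mass_fraction *
    .dry_mass_per_c(phys$biomass_formula) * sol$biomass
  list(defined = TRUE,
       n_fixation_per_protein = sol$n_fixed / protein,
       respiration_per_protein = sol$o2_respired / protein)
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("<flux_solution> regime %s, f_N2 = %.4f\n", x$regime, x$f_n2))
  cat(sprintf("  biomass %.4g mol C m^-3 (%.4g g dw m^-3, %.4g g protein m^-3)\n",
              x$biomass, x$biomass_gdw, x$protein))
  cat(sprintf("  rates (mol m^-3 h^-1): sucrose %.4g, NH4+ %.4g, N fixed %.4g, O2 %.4g\n",
              x$sucrose_consumed, x$nh4_consumed, x$n_fixed, x$o2_respired))
  cat(sprintf("  residuals (mol m^-3): NH4+ %.3g, sucrose %.3g\n",
              x$residual_nh4, x$residual_sucrose))
  invisible(x)
}
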