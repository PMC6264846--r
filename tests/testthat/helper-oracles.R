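# Independent oracles used by the unit and acceptance tests.  They share
# only the primitive parameter definitions with the package; every
# derived quantity is re-assembled here from first principles.

# Electron-split grid search for the growth yield: scan the biomass
# carbon produced per mol sucrose and find where the ATP generated by
# respiring the remaining electrons exactly covers the ATP demand.
oracle_yield <- function(params, n_source, biomass = biomass_formula_default(),
                         step = 1e-6) {
  e_don <- 4 * 12 + 22 - 2 * 11                      # sucrose C12H22O11
  gamma_mol <- 4 * biomass$c + biomass$h - 2 * biomass$o - 3 * biomass$n
  beta <- biomass$c / biomass$n
  atp_per_pair <- params$atp_per_electron_pair_to_o2
  x <- seq(step, 12 - step, by = step)               # mol biomass C per sucrose
  e_bio <- (gamma_mol / biomass$c) * x               # electrons into biomass
  if (n_source == "ammonium") {
    eps <- params$eps_nh4
    e_direct <- 0
    atp_demand <- (params$atp_per_biomass_c +
                     params$atp_per_n_assimilated / beta) * x
  } else {
    eps <- params$eps_n2
    e_direct <- (params$electrons_per_n2_fixed / 2) * x / beta
    atp_demand <- (params$atp_per_biomass_c +
                     (params$atp_per_n_assimilated +
                        params$atp_per_n2_fixed / 2) / beta) * x
  }
  e_resp <- e_don - e_bio - e_direct
  atp_gen <- eps * atp_per_pair * e_resp / 2
  gap <- atp_gen - atp_demand
  ok <- e_resp >= 0
  if (!any(ok)) stop("oracle: no feasible electron split")
  i <- which.min(abs(gap[ok]))
  x[ok][i]
}

# Brute-force optimizer over a 2001-point f_N2 grid with per-value
# budget closure, used to check the analytic steady-state solver.
oracle_solve <- function(sucrose_in, ammonium_in, o2_fraction,
                         dilution_rate = 0.15, phys = cell_physiology(),
                         n_grid = 2001) {
  en <- phys$energy
  bm <- phys$biomass_formula
  D <- dilution_rate
  e_don <- 48
  gamma <- (4 * bm$c + bm$h - 2 * bm$o - 3 * bm$n) / bm$n
  beta <- bm$c / bm$n
  e_fix <- en$electrons_per_n2_fixed / 2
  atp_e <- en$atp_per_electron_pair_to_o2 / 2
  s_a <- (gamma + (en$atp_per_biomass_c * beta + en$atp_per_n_assimilated) /
            (en$eps_nh4 * atp_e)) / e_don
  s_b <- (gamma + e_fix +
            (en$atp_per_biomass_c * beta + en$atp_per_n_assimilated +
               en$atp_per_n2_fixed / 2) / (en$eps_n2 * atp_e)) / e_don
  phi <- 4 * pi * phys$radius * phys$diffusivity_o2 * phys$eps_m *
    o2_fraction * 0.225 / phys$carbon_per_cell
  S <- sucrose_in
  A <- ammonium_in
  f <- seq(0, 1, length.out = n_grid)
  s_f <- (1 - f) * s_a + f * s_b
  # energy-balanced growth respiration per biomass C at each f
  demand <- (D / beta) * (e_don * s_f - gamma - f * e_fix) / 4
  # sucrose cost per biomass C: free-running at f = 0, O2-pinned at f > 0
  cost <- D / 12 + D * (gamma - 4 * beta) / (e_don * beta) +
    f * D * e_fix / (e_don * beta) + phi / 12
  cost[1] <- D * s_a / beta
  b_carbon <- D * S / cost
  b_nitrogen <- ifelse(f < 1, beta * A / (1 - f), Inf)
  B <- pmin(b_carbon, b_nitrogen)
  B[demand > phi * (1 + 1e-12)] <- -Inf               # O2-infeasible growth
  if (S <= 0) B[] <- 0
  i <- which(B >= max(B) * (1 - 1e-12))[1]            # tie -> lowest f
  list(f_n2 = if (B[i] > 0) f[i] else 0, biomass = max(B[i], 0))
}

# random culture conditions under a fixed seed, reused by property tests
draw_conditions <- function(n, seed = 42) {
  set.seed(seed)
  data.frame(
    sucrose_in = runif(n, 0.05, 40),
    ammonium_in = runif(n, 0.2, 6),
    o2_fraction = runif(n, 0.02, 0.8),
    dilution_rate = runif(n, 0.05, 0.30)
  )
}

# closure checks shared between the unit and acceptance suites; returns
# the worst relative violation over carbon, nitrogen and electron
# balances plus the allocation sum
balance_violation <- function(sol, phys = cell_physiology()) {
  bm <- phys$biomass_formula
  gamma <- (4 * bm$c + bm$h - 2 * bm$o - 3 * bm$n) / bm$n
  beta <- bm$c / bm$n
  e_fix <- phys$energy$electrons_per_n2_fixed / 2
  n_bio <- sol$nh4_consumed + sol$n_fixed
  scale_e <- max(48 * sol$sucrose_consumed, 1e-30)
  electron <- abs(48 * sol$sucrose_consumed -
                    (gamma * n_bio + 4 * sol$o2_respired + e_fix * sol$n_fixed)) /
    scale_e
  nitrogen <- abs(sol$conditions$dilution_rate * sol$biomass / beta - n_bio) /
    max(n_bio, 1e-30)
  carbon_alloc <- abs(sum(sol$carbon_allocation) - sol$sucrose_consumed) /
    max(sol$sucrose_consumed, 1e-30)
  biomass_item <- abs(12 * sol$carbon_allocation[["biomass_c"]] -
                        sol$conditions$dilution_rate * sol$biomass) /
    max(sol$conditions$dilution_rate * sol$biomass, 1e-30)
  max(electron, nitrogen, carbon_alloc, biomass_item)
}
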