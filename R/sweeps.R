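# Bisection on a monotone TRUE/FALSE indicator over sucrose inflow.
# Returns the smallest x with indicator TRUE, to relative precision
# rel_tol, expanding the upper bracket if needed.
.bisect_indicator <- function(indicator, lo, hi, rel_tol = .TOL_BISECT_REL,
                              hi_max = NULL, what = "boundary") {
  n_eval <- 0L
  probe <- function(x) {
    n_eval <<- n_eval + 1L
    isTRUE(indicator(x))
  }
  if (probe(lo)) {
    stop("bracket failure searching for ", what,
         ": condition already holds at the lower bracket ", format(lo),
         call. = FALSE)
  }
  while (!probe(hi)) {
    if (is.null(hi_max) || hi * 5 > hi_max) {
      stop("bracket failure searching for ", what,
           ": condition does not hold up to ", format(hi),
           call. = FALSE)
    }
    lo <- hi
    hi <- hi * 5
  }
  while ((hi - lo) > rel_tol * hi) {
    mid <- 0.5 * (lo + hi)
    if (probe(mid)) hi <- mid else lo <- mid
  }
  list(value = hi, lower = lo, n_eval = n_eval)
}

#' Oxygen-dependent C/N threshold for the onset of nitrogen fixation
#'
#' Bisects on the inflow sucrose concentration for the smallest supply
#' ratio at which the optimal steady state carries nitrogen-fixation
#' flux (the boundary between the ammonium-limited regime B and the
#' mixed regime C).  Returns the threshold both as `rc_over_n_f`
#' (mol sucrose per mol N) and in elemental form `rc_to_n_f = 12 *
#' rc_over_n_f` (mol C per mol N).  The threshold is non-decreasing in
#' the ambient oxygen fraction: more oxygen demands more respiratory
#' protection before fixation becomes worthwhile.
#'
#' @param o2_fraction Ambient O2 as a fraction of saturation.
#' @param phys A [cell_physiology()] object.
#' @param cond_template A [culture_conditions()] fixing `ammonium_in`,
#'   `dilution_rate` and the non-oxygen environment fields; its
#'   `sucrose_in` and `o2_fraction` are ignored.
#' @param policy A [respiration_policy()] (the threshold is
#'   policy-independent; accepted for interface symmetry).
#' @param bracket Search bracket on the supply ratio `c_over_n`.
#' @return An object of class `threshold_result` with fields
#'   `o2_fraction`, `rc_over_n_f`, `rc_to_n_f`, `n_evaluations`.
#' @examples
#' find_threshold_cn(0.05, cell_physiology(),
#'                   culture_conditions(0, 2.5))$rc_to_n_f
#' @export
find_threshold_cn <- function(o2_fraction, phys = cell_physiology(),
                              cond_template = culture_conditions(0, 2.5),
                              policy = respiration_policy("sim1"),
                              bracket = .BRACKET_C_OVER_N) {
  stopifnot(inherits(cond_template, "culture_conditions"))
  A <- cond_template$ammonium_in
  if (!(A > 0)) stop("cond_template must fix a positive ammonium_in", call. = FALSE)
  env <- ambient_environment(o2_fraction,
                             cond_template$env$o2_saturation,
                             cond_template$env$n2_concentration)
  fixes <- function(s_in) {
    cond <- culture_conditions(s_in, A, cond_template$dilution_rate, env)
    solve_steady_state(cond, phys, policy)$f_n2 > .TOL_FN2
  }
  res <- .bisect_indicator(fixes, bracket[1] * A, bracket[2] * A,
                           hi_max = .BRACKET_C_OVER_N_MAX * A,
                           what = "fixation-onset threshold")
  rc <- res$value / A
  structure(list(o2_fraction = o2_fraction,
                 rc_over_n_f = rc,
                 rc_to_n_f = sucrose_formula()$c * rc,
                 n_evaluations = res$n_eval),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result> O2 %.3g%%: RC/Nf = %.4f mol sucrose / mol N (RC:Nf = %.3f)\n",
              100 * x$o2_fraction, x$rc_over_n_f, x$rc_to_n_f))
  invisible(x)
}

#' Supply ratio at which f_N2 crosses a given level
#'
#' Uses the monotone increase of `f_n2` with the supply ratio at fixed
#' ammonium inflow and oxygen: bisects on inflow sucrose for the
#' smallest `c_over_n` with `f_n2 >= level`.  At low oxygen the
#' attainable `f_n2` saturates below 1 (the diffusive O2 influx cannot
#' support the respiration of fully fixation-based growth at the imposed
#' dilution rate); an unattainable level yields an explicit no-crossing
#' result rather than an error.  `level = 0` reduces to the
#' fixation-onset threshold.
#'
#' @inheritParams find_threshold_cn
#' @param level Target fixation fraction in `[0, 1)`.
#' @return An object of class `fn2_crossing`: `o2_fraction`, `level`,
#'   `attained`, `c_over_n` (NA when not attained), `c_to_n`,
#'   `n_evaluations`.
#' @export
find_fn2_crossing <- function(o2_fraction, level, phys = cell_physiology(),
                              cond_template = culture_conditions(0, 2.5),
                              policy = respiration_policy("sim1"),
                              bracket = .BRACKET_C_OVER_N) {
  if (!is.finite(level) || level < 0 || level >= 1) {
    stop("level must lie in [0, 1)", call. = FALSE)
  }
  if (level == 0) {
    thr <- find_threshold_cn(o2_fraction, phys, cond_template, policy, bracket)
    return(structure(list(o2_fraction = o2_fraction, level = 0,
                          attained = TRUE, c_over_n = thr$rc_over_n_f,
                          c_to_n = thr$rc_to_n_f,
                          n_evaluations = thr$n_evaluations),
                     class = "fn2_crossing"))
  }
  A <- cond_template$ammonium_in
  if (!(A > 0)) stop("cond_template must fix a positive ammonium_in", call. = FALSE)
  env <- ambient_environment(o2_fraction,
                             cond_template$env$o2_saturation,
                             cond_template$env$n2_concentration)
  f_at <- function(s_in) {
    cond <- culture_conditions(s_in, A, cond_template$dilution_rate, env)
    solve_steady_state(cond, phys, policy)$f_n2
  }
  hi <- .BRACKET_C_OVER_N_MAX * A
  if (f_at(hi) < level) {
    return(structure(list(o2_fraction = o2_fraction, level = level,
                          attained = FALSE, c_over_n = NA_real_,
                          c_to_n = NA_real_, n_evaluations = 1L),
                     class = "fn2_crossing"))
  }
  res <- .bisect_indicator(function(s) f_at(s) >= level,
                           bracket[1] * A, bracket[2] * A,
                           hi_max = .BRACKET_C_OVER_N_MAX * A,
                           what = sprintf("f_N2 = %g crossing", level))
  rc <- res$value / A
  structure(list(o2_fraction = o2_fraction, level = level, attained = TRUE,
                 c_over_n = rc, c_to_n = sucrose_formula()$c * rc,
                 n_evaluations = res$n_eval + 1L),
            class = "fn2_crossing")
}

#' @export
print.fn2_crossing <- function(x, ...) {
  if (x$attained) {
    cat(sprintf("<fn2_crossing> O2 %.3g%%: f_N2 = %g at C/N = %.4f (C:N = %.3f)\n",
                100 * x$o2_fraction, x$level, x$c_over_n, x$c_to_n))
  } else {
    cat(sprintf("<fn2_crossing> O2 %.3g%%: f_N2 = %g is not attained at this oxygen level\n",
                100 * x$o2_fraction, x$level))
  }
  invisible(x)
}

#' Ammonium supply rate of the chemostat
#'
#' @param cond A [culture_conditions()] object.
#' @return `dilution_rate * ammonium_in` (mol m^-3 h^-1); 0.375 for the
#'   reference conditions D = 0.15 h^-1, 2.5 mol m^-3 inflow.
#' @export
ammonium_supply_rate <- function(cond) {
  stopifnot(inherits(cond, "culture_conditions"))
  cond$dilution_rate * cond$ammonium_in
}

#' Sweep steady states over a condition grid
#'
#' Solves one steady state per point of the grid
#' `sucrose_in x ammonium_in x o2_fraction` and returns a long-format
#' table (class `sweep_table`, a `data.frame`) with one row per grid
#' point: the conditions, the biomass/protein pools, `f_n2`, the regime
#' label, volumetric and protein-specific rates, residuals and the
#' itemized carbon allocation (columns prefixed `alloc_`).  Failures at
#' individual grid points are caught, reported as warnings and marked by
#' an `error` column; they never abort the sweep.
#'
#' The attribute `"boundaries"` holds, per (ammonium, oxygen) slice, the
#' two regime boundaries found by root-finding on inflow sucrose: the
#' carbon-to-ammonium-limitation transition (A/B) and the fixation onset
#' (B/C).
#'
#' @param sucrose_in,ammonium_in,o2_fraction Numeric grid axes
#'   (mol m^-3, mol m^-3, fraction of saturation).
#' @param dilution_rate Dilution rate (h^-1).
#' @param phys A [cell_physiology()] object.
#' @param policy A [respiration_policy()] object.
#' @param boundaries Compute the regime-boundary curves (default TRUE).
#' @return A `sweep_table`.
#' @export
sweep_conditions <- function(sucrose_in, ammonium_in = 2.5, o2_fraction,
                             dilution_rate = 0.15,
                             phys = cell_physiology(),
                             policy = respiration_policy("sim1"),
                             boundaries = TRUE) {
  grid <- expand.grid(sucrose_in = sucrose_in, ammonium_in = ammonium_in,
                      o2_fraction = o2_fraction, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    out <- tryCatch({
      cond <- culture_conditions(g$sucrose_in, g$ammonium_in, dilution_rate,
                                 ambient_environment(g$o2_fraction))
      sol <- solve_steady_state(cond, phys, policy)
      data.frame(
        sucrose_in = g$sucrose_in, ammonium_in = g$ammonium_in,
        o2_fraction = g$o2_fraction, dilution_rate = dilution_rate,
        policy = policy$mode, c_over_n = cond$c_over_n,
        biomass = sol$biomass, biomass_gdw = sol$biomass_gdw,
        protein = sol$protein, f_n2 = sol$f_n2, regime = sol$regime,
        sucrose_consumed = sol$sucrose_consumed,
        nh4_consumed = sol$nh4_consumed, n_fixed = sol$n_fixed,
        o2_respired = sol$o2_respired,
        n_fixation_per_protein = sol$n_fixation_per_protein,
        respiration_per_protein = sol$respiration_per_protein,
        residual_nh4 = sol$residual_nh4,
        residual_sucrose = sol$residual_sucrose,
        alloc_biomass_c = sol$carbon_allocation[["biomass_c"]],
        alloc_synthesis_energy = sol$carbon_allocation[["synthesis_energy"]],
        alloc_nh4_assimilation_energy =
          sol$carbon_allocation[["nh4_assimilation_energy"]],
        alloc_fixation_energy = sol$carbon_allocation[["fixation_energy"]],
        alloc_respiratory_protection =
          sol$carbon_allocation[["respiratory_protection"]],
        alloc_excess_respiration =
          sol$carbon_allocation[["excess_respiration"]],
        error = NA_character_,
        stringsAsFactors = FALSE)
    }, error = function(e) {
      warning("grid point ", i, " failed: ", conditionMessage(e),
              call. = FALSE)
      data.frame(sucrose_in = g$sucrose_in, ammonium_in = g$ammonium_in,
                 o2_fraction = g$o2_fraction, dilution_rate = dilution_rate,
                 policy = policy$mode, c_over_n = NA_real_,
                 biomass = NA_real_, biomass_gdw = NA_real_,
                 protein = NA_real_, f_n2 = NA_real_, regime = NA_character_,
                 sucrose_consumed = NA_real_, nh4_consumed = NA_real_,
                 n_fixed = NA_real_, o2_respired = NA_real_,
                 n_fixation_per_protein = NA_real_,
                 respiration_per_protein = NA_real_,
                 residual_nh4 = NA_real_, residual_sucrose = NA_real_,
                 alloc_biomass_c = NA_real_, alloc_synthesis_energy = NA_real_,
                 alloc_nh4_assimilation_energy = NA_real_,
                 alloc_fixation_energy = NA_real_,
                 alloc_respiratory_protection = NA_real_,
                 alloc_excess_respiration = NA_real_,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
    out
  })
  tab <- do.call(rbind, rows)
  class(tab) <- c("sweep_table", "data.frame")
  if (boundaries) {
    slices <- expand.grid(ammonium_in = unique(ammonium_in),
                          o2_fraction = unique(o2_fraction),
                          KEEP.OUT.ATTRS = FALSE)
    bnd <- lapply(seq_len(nrow(slices)), function(i) {
      A <- slices$ammonium_in[i]
      frac <- slices$o2_fraction[i]
      tmpl <- culture_conditions(0, A, dilution_rate,
                                 ambient_environment(frac))
      ab <- tryCatch({
        lim <- function(s_in) {
          cond <- culture_conditions(s_in, A, dilution_rate,
                                     ambient_environment(frac))
          sol <- solve_steady_state(cond, phys, policy)
          sol$residual_nh4 <= .TOL_RESIDUAL
        }
        .bisect_indicator(lim, .BRACKET_C_OVER_N[1] * A,
                          .BRACKET_C_OVER_N[2] * A,
                          hi_max = .BRACKET_C_OVER_N_MAX * A,
                          what = "A/B boundary")$value / A
      }, error = function(e) NA_real_)
      bc <- tryCatch(find_threshold_cn(frac, phys, tmpl, policy)$rc_over_n_f,
                     error = function(e) NA_real_)
      data.frame(ammonium_in = A, o2_fraction = frac,
                 c_over_n_ab = ab, c_over_n_bc = bc)
    })
    attr(tab, "boundaries") <- do.call(rbind, bnd)
  }
  tab
}

#' Calibrate the free physiological parameters
#'
#' The model has two free parameters: the membrane-layer diffusivity
#' coefficient `eps_m` and the energy transfer efficiency of
#' fixation-based growth `eps_n2` (the ammonium-growth efficiency is
#' pinned at 0.54).  They are fitted by least squares on the logarithm of
#' the oxygen-dependent elemental C:N thresholds for the onset of
#' nitrogen fixation, against the target thresholds supplied (default:
#' 6.5 at 1 percent, 15 at 5 percent and 100 at 60 percent of O2
#' saturation).  The thresholds constrain `eps_m` strongly but carry
#' essentially no information on `eps_n2` (fixation onset is governed by
#' the oxygen-scavenging budget, not by the fixation-growth energetics);
#' a flat objective direction is detected and reported as a warning.
#'
#' @param phys Starting [cell_physiology()]; fitted parameters replace
#'   the corresponding fields.
#' @param targets Data frame with columns `o2_fraction` and `rc_to_n_f`.
#' @param free Character vector of parameters to fit, a subset of
#'   `c("eps_m", "eps_n2")`.
#' @param cond_template A [culture_conditions()] fixing `ammonium_in`
#'   and `dilution_rate` for the threshold searches.
#' @return The fitted `cell_physiology`, with attribute `"calibration"`
#'   (targets, fitted values, achieved thresholds, relative residuals,
#'   objective).
#' @export
calibrate_physiology <- function(phys = cell_physiology(),
                                 targets = data.frame(
                                   o2_fraction = c(0.01, 0.05, 0.60),
                                   rc_to_n_f = c(6.5, 15, 100)),
                                 free = "eps_m",
                                 cond_template = culture_conditions(0, 2.5)) {
  stopifnot(all(free %in% c("eps_m", "eps_n2")),
            all(c("o2_fraction", "rc_to_n_f") %in% names(targets)),
            nrow(targets) >= 1)
  with_params <- function(theta) {
    p <- phys
    for (j in seq_along(free)) {
      if (free[j] == "eps_m") p$eps_m <- theta[j]
      else p$energy$eps_n2 <- theta[j]
    }
    p
  }
  objective <- function(log_theta) {
    p <- tryCatch(with_params(exp(log_theta)), error = function(e) NULL)
    if (is.null(p)) return(1e6)
    sum(vapply(seq_len(nrow(targets)), function(i) {
      t <- tryCatch(
        find_threshold_cn(targets$o2_fraction[i], p, cond_template)$rc_to_n_f,
        error = function(e) NA_real_)
      if (is.na(t)) 100 else log(t / targets$rc_to_n_f[i])^2
    }, numeric(1)))
  }
  start <- log(vapply(free, function(nm) {
    if (nm == "eps_m") phys$eps_m else phys$energy$eps_n2
  }, numeric(1)))
  if (length(free) == 1L) {
    opt <- stats::optimize(objective, interval = log(c(1e-5, 1)), tol = 1e-10)
    theta <- exp(opt$minimum)
    value <- opt$objective
  } else {
    opt <- stats::optim(start, objective, method = "Nelder-Mead",
                        control = list(reltol = 1e-12, maxit = 500))
    theta <- exp(opt$par)
    value <- opt$value
  }
  # identifiability: a +/-10 percent perturbation that leaves the
  # objective essentially unchanged marks a flat direction
  base_log <- log(theta)
  flat <- vapply(seq_along(free), function(j) {
    up <- base_log; up[j] <- up[j] + log(1.1)
    dn <- base_log; dn[j] <- dn[j] - log(1.1)
    max(abs(objective(up) - value), abs(objective(dn) - value)) < 1e-6
  }, logical(1))
  if (any(flat)) {
    warning("calibration objective is flat in: ",
            paste(free[flat], collapse = ", "),
            " (parameter not identified by the threshold targets)",
            call. = FALSE)
  }
  fitted_phys <- with_params(theta)
  achieved <- vapply(targets$o2_fraction, function(fr) {
    tryCatch(find_threshold_cn(fr, fitted_phys, cond_template)$rc_to_n_f,
             error = function(e) NA_real_)
  }, numeric(1))
  attr(fitted_phys, "calibration") <- list(
    targets = targets,
    fitted = stats::setNames(theta, free),
    achieved = achieved,
    relative_residuals = achieved / targets$rc_to_n_f - 1,
    objective = value)
  fitted_phys
}
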