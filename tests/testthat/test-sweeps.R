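test_that("threshold results carry both ratio conventions", {
  tmpl <- culture_conditions(0, 2.5)
  thr <- find_threshold_cn(0.05, cond_template = tmpl)
  expect_s3_class(thr, "threshold_result")
  expect_equal(thr$rc_to_n_f, 12 * thr$rc_over_n_f)
  expect_gt(thr$n_evaluations, 0)
  # just below the threshold: no fixation; just above: fixation
  below <- solve_steady_state(
    culture_conditions(0.999 * thr$rc_over_n_f * 2.5, 2.5,
                       env = ambient_environment(0.05)))
  above <- solve_steady_state(
    culture_conditions(1.001 * thr$rc_over_n_f * 2.5, 2.5,
                       env = ambient_environment(0.05)))
  expect_equal(below$f_n2, 0)
  expect_gt(above$f_n2, 0)
})

test_that("f_N2 crossings reduce to the threshold at level zero and order in O2", {
  tmpl <- culture_conditions(0, 2.5)
  thr <- find_threshold_cn(0.30, cond_template = tmpl)
  zero <- find_fn2_crossing(0.30, 0, cond_template = tmpl)
  expect_true(zero$attained)
  expect_equal(zero$c_over_n, thr$rc_over_n_f)
  crossings <- vapply(c(0.05, 0.30, 0.60), function(fr) {
    find_fn2_crossing(fr, 0.5, cond_template = tmpl)$c_over_n
  }, numeric(1))
  expect_true(all(diff(crossings) > 0))
  # at very low oxygen the attainable f_N2 saturates below high levels
  low <- find_fn2_crossing(0.01, 0.9, cond_template = tmpl)
  expect_false(low$attained)
  expect_true(is.na(low$c_over_n))
  expect_error(find_fn2_crossing(0.30, 1.0, cond_template = tmpl), "level")
})

test_that("sweeps keep the schema, mark failures, and emit boundary curves", {
  tab <- sweep_conditions(c(0, 5, 20), c(1, 2.5), c(0.05, 0.30))
  expect_s3_class(tab, "sweep_table")
  expect_equal(nrow(tab), 12)
  expect_true(all(tab$biomass[tab$sucrose_in == 0] == 0))
  expect_true(all(is.na(tab$error)))
  bnd <- attr(tab, "boundaries")
  expect_equal(nrow(bnd), 4)
  # fixation onset sits at or beyond the ammonium-limitation boundary
  expect_true(all(bnd$c_over_n_bc >= bnd$c_over_n_ab))
  # boundaries depend on oxygen only through the B/C edge
  ab <- tapply(bnd$c_over_n_ab, bnd$ammonium_in, function(x) diff(range(x)))
  expect_true(all(ab < 1e-3))
})

test_that("ammonium supply rate is dilution times inflow", {
  expect_equal(ammonium_supply_rate(culture_conditions(0, 2.5, 0.15)), 0.375)
  expect_equal(ammonium_supply_rate(culture_conditions(0, 5, 0.3)), 1.5)
})

test_that("sweep tables round-trip through CSV and JSON", {
  tab <- sweep_conditions(c(5, 20), 2.5, 0.05, boundaries = FALSE)
  csv <- tempfile(fileext = ".csv")
  write_sweep_csv(tab, csv)
  back <- read_sweep_csv(csv)
  expect_equal(names(back), names(tab))
  for (nm in names(tab)) {
    if (is.numeric(tab[[nm]])) {
      expect_equal(back[[nm]], tab[[nm]], tolerance = 1e-12)
    } else {
      expect_equal(back[[nm]], tab[[nm]])
    }
  }
  # JSON path: write -> read -> write is byte-identical
  j1 <- tempfile(fileext = ".json")
  j2 <- tempfile(fileext = ".json")
  write_sweep_json(tab, j1, parameters = list(eps_m = 0.0076,
                                              source = "calibrated"))
  back_j <- read_sweep_json(j1)
  write_sweep_json(back_j, j2, parameters = attr(back_j, "parameters"))
  expect_identical(readLines(j1), readLines(j2))
  # malformed header is a schema error
  bad <- tempfile(fileext = ".csv")
  lines <- readLines(csv)
  writeLines(c(sub("sucrose_in", "sugar", lines[1]), lines[-1]), bad)
  expect_error(read_sweep_csv(bad), "malformed")
})

test_that("config files apply and log defaults, and reject unknown keys", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c(
    "conditions:",
    "  sucrose_in: 20",
    "environment:",
    "  o2_fraction: 0.05",
    "policy:",
    "  mode: sim2"
  ), cfg)
  expect_message(out <- read_config(cfg), "dilution_rate not given")
  expect_equal(out$conditions$dilution_rate, 0.15)
  expect_equal(out$conditions$sucrose_in, 20)
  expect_equal(out$policy$mode, "sim2")
  prov <- out$provenance
  expect_equal(prov$source[prov$key == "sucrose_in" &
                             prov$section == "conditions"], "user")
  expect_equal(prov$source[prov$key == "dilution_rate"], "default")
  bad <- tempfile(fileext = ".yaml")
  writeLines(c("conditions:", "  dilution: 0.2"), bad)
  expect_error(read_config(bad, quiet = TRUE), "unknown key")
  bad2 <- tempfile(fileext = ".yaml")
  writeLines(c("physiology:", "  eps_m: 1.7"), bad2)
  expect_error(read_config(bad2, quiet = TRUE), "eps_m")
})

test_that("calibration recovers eps_m and flags the flat eps_n2 direction", {
  phys <- cell_physiology()
  tmpl <- culture_conditions(0, 2.5)
  # self-consistency: fitting to this model's own thresholds returns eps_m
  own <- data.frame(
    o2_fraction = c(0.05, 0.60),
    rc_to_n_f = vapply(c(0.05, 0.60), function(fr) {
      find_threshold_cn(fr, phys, tmpl)$rc_to_n_f
    }, numeric(1)))
  refit <- calibrate_physiology(phys, own, free = "eps_m", cond_template = tmpl)
  expect_equal(refit$eps_m, phys$eps_m, tolerance = 1e-3)
  cal <- attr(refit, "calibration")
  expect_lt(max(abs(cal$relative_residuals)), 1e-3)
  # raising eps_m raises every threshold (more oxygen to scavenge)
  up <- cell_physiology(eps_m = phys$eps_m * 1.1)
  for (fr in c(0.05, 0.60)) {
    expect_gt(find_threshold_cn(fr, up, tmpl)$rc_to_n_f,
              find_threshold_cn(fr, phys, tmpl)$rc_to_n_f)
  }
  # the threshold targets carry no information on eps_n2
  expect_warning(
    calibrate_physiology(phys, own[1, , drop = FALSE], free = "eps_n2",
                         cond_template = tmpl),
    "flat")
})
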