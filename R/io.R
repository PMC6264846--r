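# column -> unit map for sweep tables; also defines the CSV schema order
.SWEEP_UNITS <- c(
  sucrose_in = "mol m^-3", ammonium_in = "mol m^-3",
  o2_fraction = "fraction of saturation", dilution_rate = "h^-1",
  policy = "sim1|sim2", c_over_n = "mol sucrose mol N^-1",
  biomass = "mol C m^-3", biomass_gdw = "g m^-3", protein = "g m^-3",
  f_n2 = "dimensionless", regime = "A|B|C",
  sucrose_consumed = "mol m^-3 h^-1", nh4_consumed = "mol m^-3 h^-1",
  n_fixed = "mol m^-3 h^-1", o2_respired = "mol m^-3 h^-1",
  n_fixation_per_protein = "mol (g protein)^-1 h^-1",
  respiration_per_protein = "mol (g protein)^-1 h^-1",
  residual_nh4 = "mol m^-3", residual_sucrose = "mol m^-3",
  alloc_biomass_c = "mol sucrose m^-3 h^-1",
  alloc_synthesis_energy = "mol sucrose m^-3 h^-1",
  alloc_nh4_assimilation_energy = "mol sucrose m^-3 h^-1",
  alloc_fixation_energy = "mol sucrose m^-3 h^-1",
  alloc_respiratory_protection = "mol sucrose m^-3 h^-1",
  alloc_excess_respiration = "mol sucrose m^-3 h^-1",
  error = "message")

#' Write and read sweep tables
#'
#' The CSV layout is: a header row with the documented column names, a
#' units row (every cell the unit string of its column), then the data
#' rows.  UTF-8, `.` decimal separator.  `read_sweep_csv()` validates the
#' header against the schema and strips the units row; any mismatch is a
#' schema error.  The JSON writer emits the full table together with the
#' column units and an optional parameter-provenance block; writing,
#' re-reading and writing again is byte-identical.
#'
#' @param table A `sweep_table` from [sweep_conditions()].
#' @param path Output file path.
#' @return `write_*` return `path` invisibly; `read_sweep_csv()` returns
#'   a `sweep_table`.
#' @export
write_sweep_csv <- function(table, path) {
  stopifnot(is.data.frame(table))
  cols <- names(.SWEEP_UNITS)
  if (!identical(names(table), cols)) {
    stop("table does not follow the sweep schema; expected columns: ",
         paste(cols, collapse = ", "), call. = FALSE)
  }
  units_row <- as.data.frame(as.list(.SWEEP_UNITS), stringsAsFactors = FALSE)
  body <- as.data.frame(lapply(table, as.character), stringsAsFactors = FALSE)
  utils::write.table(rbind(units_row, body), path, sep = ",", row.names = FALSE,
                     col.names = TRUE, qmethod = "double", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_sweep_csv
#' @export
read_sweep_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                         fileEncoding = "UTF-8", check.names = FALSE)
  cols <- names(.SWEEP_UNITS)
  if (!identical(names(raw), cols)) {
    stop("malformed sweep CSV header in ", path, "; expected columns: ",
         paste(cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) < 1 || !identical(unname(unlist(raw[1, ])),
                                  unname(.SWEEP_UNITS))) {
    stop("malformed sweep CSV: missing or altered units row in ", path,
         call. = FALSE)
  }
  body <- raw[-1, , drop = FALSE]
  character_cols <- c("policy", "regime", "error")
  for (nm in cols) {
    if (!nm %in% character_cols) body[[nm]] <- as.numeric(body[[nm]])
    else body[[nm]][body[[nm]] == "NA"] <- NA_character_
  }
  rownames(body) <- NULL
  class(body) <- c("sweep_table", "data.frame")
  body
}

#' @rdname write_sweep_csv
#' @param parameters Optional named list recording the parameter values
#'   and their provenance (defaults vs calibrated vs user-set), stored
#'   verbatim in the JSON output.
#' @export
write_sweep_json <- function(table, path, parameters = NULL) {
  stopifnot(is.data.frame(table))
  payload <- list(
    schema = list(columns = names(.SWEEP_UNITS),
                  units = as.list(.SWEEP_UNITS)),
    parameters = parameters,
    rows = as.data.frame(table))
  json <- jsonlite::toJSON(payload, dataframe = "rows", auto_unbox = TRUE,
                           digits = NA, na = "null", pretty = TRUE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_sweep_csv
#' @export
read_sweep_json <- function(path) {
  payload <- jsonlite::fromJSON(path)
  tab <- payload$rows
  class(tab) <- c("sweep_table", "data.frame")
  attr(tab, "parameters") <- payload$parameters
  tab
}

# allowed configuration keys per section
.CONFIG_SCHEMA <- list(
  physiology = c("radius", "eps_m", "diffusivity_o2", "diffusivity_sucrose",
                 "diffusivity_nh4", "diffusivity_n2", "carbon_per_cell",
                 "protein_mass_fraction", "biomass_formula"),
  energy = c("eps_nh4", "eps_n2", "atp_per_electron_pair_to_o2",
             "atp_per_n2_fixed", "electrons_per_n2_fixed",
             "atp_per_biomass_c", "atp_per_n_assimilated"),
  environment = c("o2_fraction", "o2_saturation", "n2_concentration"),
  conditions = c("dilution_rate", "sucrose_in", "ammonium_in"),
  policy = c("mode"),
  sweep = c("sucrose_in", "ammonium_in", "o2_fraction"))

#' Read a scenario configuration file
#'
#' Parses a YAML configuration with sections `physiology`, `energy`,
#' `environment`, `conditions`, `policy` and `sweep` (all optional; any
#' key left out takes the package default and the substitution is
#' logged to stderr).  Unknown sections or keys, and values outside
#' their physical ranges, are rejected with messages naming the
#' offending key.  Units follow the function documentation of
#' [cell_physiology()], [energy_parameters()], [ambient_environment()]
#' and [culture_conditions()]; concentrations are mol m^-3 (equivalently
#' mM).
#'
#' @param path Path to a YAML file.
#' @param quiet Suppress default-substitution messages.
#' @return A list with elements `physiology` ([cell_physiology()]),
#'   `environment`, `conditions` (NULL unless `sucrose_in` given),
#'   `policy`, `sweep` (NULL or list of grid axes) and `provenance`
#'   (data frame: section, key, source = `"user"` or `"default"`).
#' @export
read_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg)) stop("config must be a YAML mapping", call. = FALSE)
  unknown_sections <- setdiff(names(cfg), names(.CONFIG_SCHEMA))
  if (length(unknown_sections)) {
    stop("unknown config section(s): ", paste(unknown_sections, collapse = ", "),
         call. = FALSE)
  }
  prov <- list()
  note <- function(section, key, source) {
    prov[[length(prov) + 1L]] <<- data.frame(section = section, key = key,
                                             source = source,
                                             stringsAsFactors = FALSE)
    if (source == "default" && !quiet) {
      message("config: ", section, ".", key, " not given; using default")
    }
  }
  take <- function(section, defaults) {
    given <- cfg[[section]]
    if (is.null(given)) given <- list()
    unknown <- setdiff(names(given), .CONFIG_SCHEMA[[section]])
    if (length(unknown)) {
      stop("unknown key(s) in section '", section, "': ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    out <- defaults
    for (key in names(defaults)) {
      if (key %in% names(given)) {
        out[[key]] <- given[[key]]
        note(section, key, "user")
      } else {
        note(section, key, "default")
      }
    }
    out
  }
  en_def <- energy_parameters()
  en_args <- take("energy", unclass(en_def))
  energy <- do.call(energy_parameters, en_args)
  ph_def <- cell_physiology()
  ph_args <- take("physiology", list(
    radius = ph_def$radius, eps_m = ph_def$eps_m,
    diffusivity_o2 = ph_def$diffusivity_o2,
    diffusivity_sucrose = ph_def$diffusivity_sucrose,
    diffusivity_nh4 = ph_def$diffusivity_nh4,
    diffusivity_n2 = ph_def$diffusivity_n2,
    carbon_per_cell = ph_def$carbon_per_cell,
    protein_mass_fraction = ph_def$protein_mass_fraction,
    biomass_formula = unclass(ph_def$biomass_formula)))
  bf <- ph_args$biomass_formula
  if (!all(c("c", "h", "o", "n") %in% names(bf))) {
    stop("physiology.biomass_formula must give subscripts c, h, o, n",
         call. = FALSE)
  }
  ph_args$biomass_formula <- elemental_formula(bf$c, bf$h, bf$o, bf$n)
  ph_args$energy <- energy
  phys <- do.call(cell_physiology, ph_args)
  env_args <- take("environment", list(o2_fraction = 0.05,
                                       o2_saturation = 0.225,
                                       n2_concentration = 0.4))
  env <- do.call(ambient_environment, env_args)
  cn_args <- take("conditions", list(dilution_rate = 0.15,
                                     sucrose_in = NULL, ammonium_in = 2.5))
  conditions <- NULL
  if (!is.null(cn_args$sucrose_in)) {
    conditions <- culture_conditions(cn_args$sucrose_in, cn_args$ammonium_in,
                                     cn_args$dilution_rate, env)
  }
  pol_args <- take("policy", list(mode = "sim1"))
  policy <- respiration_policy(pol_args$mode)
  sweep <- NULL
  if (!is.null(cfg$sweep)) {
    sw <- take("sweep", list(sucrose_in = NULL, ammonium_in = 2.5,
                             o2_fraction = env$o2_fraction))
    if (is.null(sw$sucrose_in)) {
      stop("sweep section requires sucrose_in", call. = FALSE)
    }
    sweep <- list(sucrose_in = as.numeric(sw$sucrose_in),
                  ammonium_in = as.numeric(sw$ammonium_in),
                  o2_fraction = as.numeric(sw$o2_fraction),
                  dilution_rate = cn_args$dilution_rate)
  }
  list(physiology = phys, environment = env, conditions = conditions,
       policy = policy, sweep = sweep,
       provenance = do.call(rbind, prov))
}
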