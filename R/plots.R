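# Plotting is a convenience layer over sweep tables; nothing downstream
# depends on rendered figures.

.need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
}

#' Plot protein-specific rates against the supply ratio
#'
#' Draws the protein-specific nitrogen-fixation rate (or respiration
#' rate) as a function of the sucrose-to-ammonium supply ratio, one
#' curve per ambient oxygen level: the classic three-phase response
#' (zero below the oxygen-dependent threshold, then rising and
#' saturating).
#'
#' @param table A `sweep_table` from [sweep_conditions()].
#' @param rate `"n_fixation_per_protein"` or `"respiration_per_protein"`.
#' @return A ggplot object.
#' @export
plot_rate_curves <- function(table, rate = c("n_fixation_per_protein",
                                             "respiration_per_protein")) {
  .need_ggplot()
  rate <- match.arg(rate)
  df <- as.data.frame(table)
  df$o2 <- factor(sprintf("%g%% O2", 100 * df$o2_fraction))
  ggplot2::ggplot(df, ggplot2::aes(x = .data[["c_over_n"]],
                                   y = .data[[rate]],
                                   colour = .data[["o2"]])) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "C/N supply ratio (mol sucrose / mol N)",
                  y = paste(rate, "(mol (g protein)^-1 h^-1)"),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the itemized carbon allocation
#'
#' Stacked-area view of where the consumed sucrose goes (biomass carbon,
#' synthesis energy, ammonium assimilation, fixation, respiratory
#' protection, excess respiration) along the supply-ratio axis of a
#' single-oxygen sweep.
#'
#' @param table A `sweep_table` restricted to one oxygen level.
#' @return A ggplot object.
#' @export
plot_carbon_allocation <- function(table) {
  .need_ggplot()
  df <- as.data.frame(table)
  if (length(unique(df$o2_fraction)) != 1L) {
    stop("restrict the table to a single o2_fraction before plotting allocation",
         call. = FALSE)
  }
  items <- grep("^alloc_", names(df), value = TRUE)
  long <- do.call(rbind, lapply(items, function(it) {
    data.frame(c_over_n = df$c_over_n, flux = df[[it]],
               item = sub("^alloc_", "", it), stringsAsFactors = FALSE)
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = .data[["c_over_n"]],
                                     y = .data[["flux"]],
                                     fill = .data[["item"]])) +
    ggplot2::geom_area(position = "stack") +
    ggplot2::labs(x = "C/N supply ratio (mol sucrose / mol N)",
                  y = "sucrose flux (mol m^-3 h^-1)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the oxygen dependence of the fixation-onset threshold
#'
#' @param thresholds A list of [find_threshold_cn()] results, or a data
#'   frame with columns `o2_fraction` and `rc_to_n_f`.
#' @return A ggplot object.
#' @export
plot_threshold_curve <- function(thresholds) {
  .need_ggplot()
  if (!is.data.frame(thresholds)) {
    thresholds <- do.call(rbind, lapply(thresholds, function(t) {
      data.frame(o2_fraction = t$o2_fraction, rc_to_n_f = t$rc_to_n_f)
    }))
  }
  ggplot2::ggplot(thresholds, ggplot2::aes(x = 100 * .data[["o2_fraction"]],
                                           y = .data[["rc_to_n_f"]])) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "ambient O2 (% of saturation)",
                  y = "RC:Nf (mol C / mol N)") +
    ggplot2::theme_minimal()
}
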