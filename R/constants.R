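# Numerical tolerances and search settings, collected in one place.

# residual concentrations below this (mol m^-3) are treated as complete
# drawdown when classifying regimes
.TOL_RESIDUAL <- 1e-9

# f_N2 below this is treated as "not fixing"
.TOL_FN2 <- 1e-12

# relative precision of bisection searches on the inflow sucrose axis
.TOL_BISECT_REL <- 1e-4

# default search bracket for threshold / crossing searches,
# in mol sucrose per mol N of the supply ratio
.BRACKET_C_OVER_N <- c(0.01, 200)

# hard cap when expanding a failed bracket
.BRACKET_C_OVER_N_MAX <- 1e4
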