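# diazosim

A coarse-grained flux-balance simulator of a heterotrophic
nitrogen-fixing bacterium (an *Azotobacter vinelandii*-like cell)
growing in continuous culture on sucrose plus ammonium.  It is written
for microbial ecologists and biogeochemical modelers who need a
quantitative, mechanistic answer to the question: *under which
combinations of organic-carbon supply, fixed-nitrogen supply and
ambient oxygen does a diazotroph assimilate ammonium, fix N2, or do
both — and at what rate?*

## The model in brief

Metabolism is a balanced ledger of carbon, electron equivalents
(degree of reduction, `e = 4c + h − 2o − 3n` against the NH4+
reference) and ATP equivalents.  Sucrose (48 e-eq) fuels synthesis of
biomass (default C5H7O2N, β = 5 C per N, γ = 20 e-eq per N) and
respiration (ε-scaled ATP yield per electron pair); nitrogenase
follows `N2 + 8e− + 16ATP → 2NH3 + H2`.  Substrates enter a spherical
cell by diffusion, `4π r D εm (c∞ − c_in)`, and fixation requires an
anoxic cytosol: total respiration must consume the whole O2 influx at
zero internal O2 (respiratory protection).  In a chemostat at dilution
rate D, the fraction of nitrogen from fixation, `f_N2`, is chosen to
maximize the standing biomass.  Along the supply ratio
C/N = sucrose/ammonium this yields three regimes — carbon-limited
growth on ammonium (A), ammonium-limited growth with excess
respiration (B) and mixed assimilation plus fixation (C) — separated
by an oxygen-dependent C/N threshold `RC:Nf` for the onset of
fixation.

The two free parameters (membrane permeability `eps_m`, fixation-growth
efficiency `eps_n2`) and the calibration protocol are documented in the
vignette, `vignettes/diazotroph-chemostat.Rmd`.

## Worked example

Steady state at C/N = 8 (sucrose 20 mol m^-3, ammonium 2.5 mol m^-3),
5 % O2 saturation, D = 0.15 h^-1:

```r
library(diazosim)
cond <- culture_conditions(sucrose_in = 20, ammonium_in = 2.5,
                           env = ambient_environment(0.05))
sol <- solve_steady_state(cond)
sol
#> <flux_solution> regime C, f_N2 = 0.8584
#>   biomass 88.27 mol C m^-3 (1997 g dw m^-3, 1098 g protein m^-3)
#>   rates (mol m^-3 h^-1): sucrose 3, NH4+ 0.375, N fixed 2.273, O2 20.49
#>   residuals (mol m^-3): NH4+ 0, sucrose 0
```

The culture is in the mixed regime C: ammonium is drawn down to zero
yet supplies only 14 % of the biomass nitrogen — the remaining 86 %
(`f_N2 = 0.86`) comes from fixation, because the abundant carbohydrate
can pay both the direct nitrogenase costs and the oxygen-scavenging
respiration.  The itemized fate of the consumed sucrose
(mol sucrose m^-3 h^-1, summing to the 3.0 consumed):

```r
round(sol$carbon_allocation, 4)
#>               biomass_c        synthesis_energy nh4_assimilation_energy
#>                  1.1034                  0.3192                  0.0096
#>         fixation_energy  respiratory_protection      excess_respiration
#>                  0.8209                  0.7469                  0.0000
```

Oxygen-dependent threshold for the onset of fixation, at 30 %
saturation:

```r
find_threshold_cn(0.30, cond_template = culture_conditions(0, 2.5))
#> <threshold_result> O2 30%: RC/Nf = 4.2849 mol sucrose / mol N (RC:Nf = 51.419)
```

i.e. below a supply ratio of ~4.3 mol sucrose per mol N (elemental
C:N ≈ 51) the optimal cell does not fix nitrogen at 30 % O2.

A command line interface wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "diazosim.R", package = "diazosim"))')" \
  threshold --o2 0.05,0.30,0.60
```

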