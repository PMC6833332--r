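# senodyn

Dynamical modelling of a cell culture's transition to replicative
senescence.

Continuously passaged primary cells (the motivating system is human dermal
fibroblasts) drift from exponential growth into a mixture of proliferative,
growth-arrested, apoptotic and senescent cells. No single assay isolates
the senescent fraction: SA-β-Gal, Ki-67, γH2AX and TUNEL each stain
overlapping subsets of these states. `senodyn` is for experimentalists and
modellers who want to turn such joint marker time-courses into a full
description of the underlying population — and to plan how few measurements
a senescence time-course actually needs.

## The model

Live cells occupy compartments `P_0 … P_{N-1}` (proliferative, indexed by
*doubling age* — the number of divisions completed, up to a Hayflick-like
limit `N` = 50), `G` (growth-arrested), `A` (apoptotic) and `S` (senescent,
absorbing); apoptotic cells drain into a detached dead pool `D`. With
`exit_i = div_i + sen_i + arr_i + apo_i`,

    dP_0/dt = −exit_0 · P_0
    dP_i/dt = 2·div_{i−1}·P_{i−1} − exit_i · P_i
    dG/dt   = Σ_i arr_i·P_i − m_GS·G
    dA/dt   = Σ_i apo_i·P_i − m_AD·A
    dS/dt   = 2·div_{N−1}·P_{N−1} + Σ_i sen_i·P_i + m_GS·G
    dD/dt   = m_AD·A

Mitosis doubles: cells leave `P_i` at rate `div_i` and arrive in `P_{i+1}`
at twice that flux. Each age-dependent rate is a linear *ladder* in
doubling age, fitted through its two endpoints, giving 13 tunable
parameters in all (8 endpoints, `m_GS`, `m_AD`, and 3 marker-contribution
fractions). Readouts are percentages of the live total
`TP = ΣP + G + A + S`, with `PD(t) = log2 TP(t)/TP(0)`:

    SA-β-Gal = 100·S/TP                TUNEL = 100·A/TP
    Ki-67    = 100·(ΣP + f_GK·G)/TP    γH2AX = 100·(S + A + f_P·ΣP + f_GH·G)/TP

Fitting minimizes a range-normalized mean squared error over all records
with a genetic algorithm refined by box-constrained quasi-Newton descent.
A synthetic-data module reproduces the canonical design — 16 passages at
160 h spacing, five markers, triplicates, Gaussian assay noise — so the
whole pipeline is testable without any external data.

## Worked example

```r
library(senodyn)
ref <- reference_parameters()          # packaged optimized parameter set
traj <- simulate_population(ref$params, t_end = 5000,
                            output_times = seq(0, 5000, by = 1))
traj
#> Senescence trajectory: 5001 output times over [ 0 , 5000 ] h, N = 50
#>   final composition (of TP): P 1.29e-11%, G 3.81%, A 0.692%, S 95.5%
```

By 5000 h proliferation has ceased and essentially all live cells are
senescent or growth-arrested. The growth-arrested fraction peaks on the
way there, and the culture crosses 85% senescent a while later:

```r
peak_growth_arrest_time(traj)                        # 1835.884 h
time_to_senescence_fraction(ref$params, 0.85)        # 3374.221 h
```

Marker readouts along the trajectory (stains in % of live cells, PD in
doublings):

```r
marker_readouts(traj, ref$mparams)[c(1, 1201, 2401), ]
#>  time_h    pd sa_b_gal   ki67 gH2AX tunel
#>       0  0.00     0.00 100.00 23.85  0.00
#>    1200 18.11    35.84  53.33 71.41 10.79
#>    2400 20.34    69.23  22.46 95.20  8.27
```

At the seed state every cell is young and proliferative, so Ki-67 is 100%
and γH2AX equals the fitted proliferative fraction (23.85%). Generate a
noisy triplicate dataset and refit it:

```r
ds  <- generate_dataset(ref$params, ref$mparams, seed = 1)   # 240 records
fit <- fit_model(ds, ga = ga_config(pop_size = 80, generations = 60), seed = 2)
fit
#> Senescence model fit: cost 0.0397972 (gradient-refined)
#>   seed 2 | generations 60 | N 50
#>   gradient norm at termination: 0.0008252678
```

The cost (~0.04) is the noise floor of the synthetic assay noise; the small
terminal gradient norm is the local-minimum check. Sparse-design planning:

```r
sk <- apply_strategy(ds, design_strategy("skip", 2))
nrow(unique(sk[, c("passage", "marker")]))   # 30 of 80 measurements retained
design_strategy_error(ds, design_strategy("skip", 2), seed = 2)
```

`design_strategy_error()` refits on the reduced design and scores on the
full data: the percent increase over the full-data fit measures the
information the skipped measurements carried. `sensitivity_grid()`,
`sensitivity_scan()` and `holdout_analysis()` probe the fitted optimum the
same way.

A command-line surface over the same functions ships in
`inst/cli/senodyn.R` (subcommands `simulate`, `fit`, `generate`, `design`,
`sensitivity`, `peak`, `t2sen`).

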