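# oefsim

Tools for studying how the strength of organism–environment feedback (OEF)
shapes ecosystem responses to gradual environmental change — for theoretical
and microbial-community ecologists who want to quantify nonlinearity,
hysteresis and alternative dynamic regimes in ramped-driver experiments and
models.

In aquatic systems, organism respiration draws down dissolved oxygen while
oxygen feeds back on vital rates. `oefsim` packages the three pieces needed
to reason about such loops quantitatively:

1. **A minimal ecosystem model.** The scalar system

   dY/dt = a − bY + r·f(Y),  f(Y) = Yᵖ / (Yᵖ + hᵖ),

   where *Y* is an ecosystem property, *a* an environmental driver, *b* the
   decay rate, *r* the self-replacement rate, *h* a threshold, and the
   exponent *p* the feedback strength. The package simulates the model under
   triangular driver ramps (fast or slow), finds equilibria and fold
   bifurcations, and locates the critical exponent at which alternative
   stable states appear (`critical_p()` ≈ 3.717 for b = r = h = 1; on an
   integer grid, bistability first appears at p = 4).

2. **Two response statistics.** *Absolute nonlinearity* — the RMS difference
   between a penalized-spline fit (`mgcv`, GCV smoothness) and a straight
   line of state against driver — and *hysteresis* — the mean absolute
   difference between ascending- and descending-phase states paired at
   equal driver levels. `run_sweep()` maps both over feedback strength ×
   ramp rate × direction.

3. **A synthetic microcosm experiment and regime detection.**
   `generate_experiment()` emulates a temperature-ramped (15→25→15 °C)
   predator–prey–bacteria community in jars whose oxygen exchange with the
   atmosphere is manipulated in five treatments (open, +200/+100/+50 ml air
   every 2 days, closed), with replicate-level divergence into persistence
   (low-oxygen) versus functional-extinction regimes recorded as hidden
   ground truth. `cluster_regimes()` detects regimes from the time series by
   dynamic-time-warping distances + Ward clustering; `association_lrt()`
   tests the cluster–treatment association by a likelihood-ratio test; and
   `metric_anova()` compares the response metrics across treatments
   (ANOVA/ANCOVA).

See the methods vignette (`vignettes/feedback-hysteresis-methods.Rmd`) for
the model assumptions, numerical choices and generator design.

## Worked example

```r
library(oefsim)

## Theory: feedback strength controls bistability and hysteresis
critical_p()
#> [1] 3.717431
bistable_interval(minimal_model_params(p = 8))
#> [1] 0.388644 0.660038

sw <- run_sweep(p_grid = c(0, 2, 4, 6, 8), step_grid = c(200, 2000))
sw[, c("p", "total_steps", "nonlinearity_up", "hysteresis", "max_stable_states")]
#>    p total_steps nonlinearity_up hysteresis max_stable_states
#> 1  0         200        7.09e-04    0.01973                 1
#> 2  2         200        5.61e-02    0.06627                 1
#> 3  4         200        1.65e-01    0.14016                 1
#> 4  6         200        2.22e-01    0.28190                 2
#> 5  8         200        2.52e-01    0.40493                 2
#> 6  0        2000        8.35e-06    0.00200                 1
#> 7  2        2000        5.87e-02    0.00669                 1
#> 8  4        2000        1.63e-01    0.02794                 1
#> 9  6        2000        2.23e-01    0.15554                 2
#> 10 8        2000        2.40e-01    0.28282                 2
```

Nonlinearity rises with feedback strength at both rates; hysteresis under
the fast ramp (200 steps) is partly *apparent* — transient lag, present even
where only one stable state exists (p ≤ 3) — while under the slower ramp it
collapses unless genuine alternative stable states exist (p ≥ 4, where
`max_stable_states` reaches 2).

```r
## Synthetic experiment: regimes, their detection, and treatment effects
ex <- generate_experiment(seed = 1)
ex
#> Synthetic microcosm experiment: 30 microcosms (5 treatments x 6 replicates), 34 sampling days, seed 1
#>          extinction persistence
#>   add100          6           0
#>   add200          6           0
#>   add50           3           3
#>   closed          1           5
#>   open            6           0

cl <- cluster_regimes(ex, "O_liq")   # DTW + Ward on the oxygen series
cl
#> Regime clustering of O_liq: 30 series, 2 clusters (sizes: 22, 8)

association_lrt(cl$labels == 2, ex$microcosms$treatment)
#> Likelihood-ratio test: deviance = 21.07, df = 4, p = 0.0003067

met <- experiment_metrics(ex, "total_biomass")
metric_anova(met$hysteresis, met$treatment)
#>        term df    sum_sq     F  p_value
#> 1 treatment  4 4.346e+15 15.59  1.6e-06
#> 2 Residuals 25 1.742e+15    NA       NA
```

The clustering recovers the planted low-oxygen regime (8 of the 9 planted
persistent replicates form the low-oxygen cluster here, all in the weaker
exchange treatments), membership is strongly associated with the
gas-exchange treatment, and biomass hysteresis differs across treatments
(F₄,₂₅ = 15.59) — larger where exchange is weaker and feedback stronger.

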