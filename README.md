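# thermetab

Thermal metabolic phenotyping of small fish, from raw respirometry oxygen
traces to population-level inference.

Ectotherm populations that have spent many generations in warmed habitats
(for example geothermally heated streams) may express a changed temperature
sensitivity of metabolism and correlated shifts in behaviour. Testing that
requires a chain of quite different computations: turning intermittent-flow
respirometry traces into standard, routine and maximum metabolic rates
(SMR, RMR, MMR); estimating allometric scaling exponents and Arrhenius
activation energies; and fitting mixed, censored and overdispersed-count
models of traits against thermal history and acclimation temperature.
`thermetab` implements that whole chain for a two-temperature
(20 / 30 °C), two-history (warm- / ambient-source) laboratory design, plus
a synthetic-data generator with exact ground truth so every stage is
verifiable without access to archived field data.

The core quantities:

- **MO₂** = (V_r − V_f) × ΔC_wO₂/Δt, in µg O₂ min⁻¹ (volumes ml,
  concentration mg L⁻¹); blank-corrected by linear interpolation between
  pre- and post-trial microbial controls.
- **SMR** = mean of the lowest 10 % of overnight cycle rates after a
  ±2 SD outlier screen; **AS** = MMR − SMR; **FAS** = MMR / SMR.
- **b** = slope of log₁₀ MO₂ on log₁₀ mass (mg), per history × temperature
  group; **E_a** = [ln R₂ − ln R₁] / (1/kT₂ − 1/kT₁) on mass-normalized
  rates MO₂·M⁻ᵇ, k = 8.62×10⁻⁵ eV K⁻¹ (negative when rates rise with
  temperature).
- Inference: seven candidate linear mixed models (random intercepts for
  population and tank) ranked by AICc and model-averaged over ΔAICc < 4;
  binomial mixed model for refuge emergence; Poisson-lognormal mixed model
  (observation-level random effect) for activity; right-censored Tobit
  regression of emergence latency (limit 600 s) on mass and metabolic rate.

See the vignette (`vignettes/thermal-metabolic-phenotyping.Rmd`) for the
models, parameter defaults and design choices in detail.

## Worked example

Simulate the default cohort (8 populations, 198 fish), compute per-group
allometry and per-history activation energies of SMR:

```r
library(thermetab)

co  <- generate_cohort(cohort_config(seed = 42))
est <- dplyr::bind_rows(lapply(seq_len(nrow(co)), function(i)
  summarize_metabolism(co$fish_id[i], co$true_smr[i],
                       co$true_rmr[i], co$true_mmr[i])))

group_scaling(est, co, traits = "smr")
#>   trait history accl_temp_C intercept_log10_a exponent_b   se_b r_squared  n
#> 1   smr ambient          20            -1.084      0.470 0.0342     0.794 51
#> 2   smr ambient          30            -0.383      0.350 0.0348     0.674 51
#> 3   smr    warm          20            -1.084      0.517 0.0412     0.774 48
#> 4   smr    warm          30            -0.632      0.418 0.0497     0.606 48

activation_energy_table(est, co, traits = "smr", by = "history")
#>   trait history   Ea_eV rate_20C rate_30C
#> 1   smr ambient -1.2414  0.08459   0.4276
#> 2   smr    warm -0.8064  0.08531   0.2444
```

Exponents sit in the 0.35–0.52 band with log-log r² of 0.6–0.8, and the
warm-source fish show the flatter (less negative) activation energy — the
reduced temperature sensitivity the design probes. Model selection on the
same cohort picks the structure that generated it (main effects plus
history × temperature and mass × temperature interactions):

```r
sel <- select_metabolic_models(
  dplyr::rename(co, smr = true_smr, rmr = true_rmr, mmr = true_mmr), "smr")
sel$table[order(sel$table$delta), ][1:3, ]
#>   model  k loglik    AICc   delta  weight retained
#> 1    m5  9 175.69 -332.42  0.0000 0.81533     TRUE
#> 2    m2 11 176.44 -329.45  2.9701 0.18467     TRUE
#> 3    m4  8 167.88 -318.99 13.4290 0.00000    FALSE
```

Raw-trace processing works the same way from simulated (or real)
long-format oxygen logs:

```r
tr  <- generate_trial_traces(co[1, ], trace_config(), seed = 7)
extract_metabolism(tr, co)
#>   fish_id   smr   rmr   mmr aerobic_scope factorial_scope n_cycles_used ...
#> 1    F001 2.407 3.561 4.519         2.113           1.878             5
```

against a true SMR of 2.421 µg O₂ min⁻¹ for that fish — the lowest-decile
rule sheds the activity bursts, sensor noise and drifting blank the
simulator injected.

A thin command-line wrapper over the same functions lives at
`inst/cli/respiro.R` (`simulate`, `extract`, `scale`, `infer`, `behavior`,
`run-all`), and `run_pipeline()` orchestrates all stages with a JSON
manifest and per-stage logging.

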