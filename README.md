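# fwnndmp

Modelling the biodegradation of dimethyl phthalate (DMP) — a plasticizer
and priority pollutant — in an anaerobic/anoxic/oxic (A/A/O)
activated-sludge wastewater train. The package is aimed at environmental
process engineers and modellers who want to predict effluent DMP from
routine operating measurements (pH, influent DMP, dissolved oxygen, ORP,
MLSS) and to compare a mechanistic description against data-driven
soft sensors.

Two modelling routes are implemented side by side:

**Mechanistic — ASM2-style hydrolysis kinetics.** Per redox zone, DMP is
removed at the Monod-type biomass-specific rate

    r = η · K · u / (Ks + u) · X_H,   u = S / X_H,

optionally multiplied by oxygen/nitrate switching functions
(S_O2/(K_O2+S_O2) aerobic, and the corresponding inhibition forms for the
anoxic and anaerobic zones). Constants are estimated by the
double-reciprocal (Lineweaver–Burk) linearization — with x = 1/u, y = 1/v
Monod data fall on y = (Ks/K)·x + 1/K, so an OLS line gives
K = 1/intercept, Ks = slope/intercept, and the zone reduction factor
η = K_zone/K_aerobic. Effluent is predicted by chaining three steady-state
completely mixed zones (anaerobic → anoxic → aerobic).

**Data-driven — fuzzy wavelet neural network (FWNN).** A five-layer
Takagi–Sugeno-style network: Gaussian fuzzification per rule and input,
product AND to per-rule firing strengths μ_j, wavelet-neuron consequents
ψ̂_j = w_j · Π_i ψ((x_i − b_ji)/a_ji) with the Mexican hat
ψ(z) = (1 − z²)·exp(−z²/2), and the normalized output
ŷ = Σ μ_j ψ̂_j / Σ μ_j. All parameters are trained by a hybrid scheme:
a real-coded genetic algorithm for global search (tournament selection,
blend crossover, Gaussian mutation, elitism) followed by full-batch
gradient descent with analytic gradients. A GA-trained perceptron baseline
and an evaluation harness (R², MAPE, RMSE, MSE) complete the three-model
comparison workflow.

Because the original 50-sample plant campaign is unpublished, a synthetic
generator reproduces the reactor's operating envelope (influent DMP at
feed levels 30–80 µg L⁻¹, aerobic DO 2.54–5.72 mg L⁻¹, MLSS ≈ 3000
mg L⁻¹) so the whole pipeline runs end to end. See the methods vignette
(`vignettes/fwnn-aao-modelling.Rmd`) for the model details and design
choices.

## Worked example

```r
library(fwnndmp)

# a 50-sample synthetic A/A/O campaign
ds <- generate_dataset(generator_config(n_samples = 50, seed = 7))
head(as.data.frame(ds), 3)
#>         pH   DMP_in       DO        ORP     MLSS   DMP_eff
#> 1 7.433259 40.16015 3.153944 -210.78236 2934.281  8.744779
#> 2 6.849270 49.41979 5.479273  -92.26072 2977.399 11.226159
#> 3 6.936119 61.29637 2.700758   42.39114 3077.859 15.315453

# split 35/15, scale on the training split, train the FWNN and the GA-NN
# baseline, evaluate all three models on the identical held-out rows
res <- run_comparison(ds, n_rules = 8,
  ga = ga_config(population_size = 40, max_generations = 60),
  gd = gd_config(learning_rate = 0.5, max_epochs = 300, target_error = 1e-6),
  seed = 7)
res$table
#>  metric   FWNN  GA_NN Kinetic
#>      R2 0.9668 0.9568 -0.7911
#>    MAPE 4.5033 5.0921 35.3230
#>    RMSE 0.5555 0.6337  4.0802
#>     MSE 0.3086 0.4016 16.6480
```

The table is the metric-by-model comparison on the 15 held-out samples, in
concentration units (µg L⁻¹): both learned models track the effluent to
within ~0.6 µg L⁻¹ RMSE, while the simplified pure-Monod kinetic chain —
blind to the dissolved-oxygen modulation present in the data — carries a
systematic bias roughly seven times larger.

Kinetic constants are recovered from rate observations by the linearized
fit:

```r
u <- seq(20, 600, length.out = 15)            # substrate-to-biomass ratios
v <- 9.68 * u / (148.31 + u)                  # specific removal rates
fit <- fit_linear(linearize_rates(u, v))
coefficients_to_params(fit, zone = "anaerobic", K_aerobic = 14.27)
#> Kinetic parameters (anaerobic): K = 9.68, Ks = 148.31, eta = 0.68
```

A command-line interface wraps the same workflow
(`inst/scripts/fwnndmp`): subcommands `simulate`, `train`, `predict`,
`evaluate`, `kinetics-fit` and `compare`, all seeded and writing CSV/JSON
artifacts.

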