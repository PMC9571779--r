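# mixqsar

QSAR modelling of the aquatic toxicity of **binary chemical mixtures** from
*hypothetical mixture descriptors*.

Chemicals rarely pollute water alone.  Risk assessment nevertheless tends to
rely on single-compound toxicity, although mixture toxicity can deviate
strongly from it.  A practical alternative to testing every mixture is a
quantitative structure–activity relationship (QSAR): a mixture does not have
molecular descriptors of its own, so a *hypothetical* mixture descriptor is
built from the components' descriptors `D1`, `D2` and their composition
fractions `X1`, `X2` (`X1 + X2 = 1`), and a regression model maps those
descriptors to the mixture toxicity `pEC50mix = -log10 EC50 (mol/L)`.

`mixqsar` provides, for 35 individual aquatic toxicants (aldehydes, cyanides,
sulfonamides, trimethoprim) and 79 of their binary mixtures:

* **Eleven mixing rules** turning `(D1, D2, X1, X2)` into one mixture
  descriptor `DMIX`, from the concentration-addition-like linear weighting
  (rule 4, `DMIX = X1·D1 + X2·D2`) to the default cubic rule 9,
  `DMIX = X1·D1³ + X2·D2³`, which lets the component with the larger
  descriptor dominate; plus `compare_rules()`, a preliminary-modelling screen
  over all eleven.
* **Descriptor screening and forward stepwise MLR** (`screen_descriptors()`,
  `forward_stepwise_mlr()`, `fit_ols()`), with the two published
  five-descriptor linear models available as fixed objects.
* An **RBF neural network** regressor (`train_rbfnn()`): Gaussian hidden
  units `h_j(x) = exp(-||x - c_j||² / r²)` centred on training samples chosen
  by forward subset selection, a single shared width `r` scanned over
  0.1–4.0, and a least-squares linear output layer.
* A **validation suite**: R² (squared Pearson correlation of observed vs
  predicted), RMS, the correlation-form `F = R²(n-2)/(1-R²)`, MAE,
  leave-one-out `Q²`, external `q²_ext`, through-origin slope `k`,
  Y-randomization and blocked five-fold cross-validation.
* A **Williams-plot applicability domain** (`leverages()`,
  `williams_report()`): leverage threshold `h* = 3m/n` and ±3σ standardized
  cross-validated residuals.
* The **packaged toxicity tables** (`load_compound_table()`,
  `load_mixture_table()`) with experimental values, both models' predictions,
  residuals, train/test splits and five-fold blocks — plus a **synthetic
  study generator** (`sim_config()`, `simulate_study()`) emulating the
  five-descriptor correlation structure, since the quantum-chemical
  descriptor values of the 35 compounds are not public.

## Worked example

Recompute the headline statistics of the packaged linear mixture model from
the stored experimental and predicted columns:

```r
library(mixqsar)
mix <- load_mixture_table()
tr  <- mix$split == "train"
sprintf("MLR train: R2 = %.3f, RMS = %.3f, F = %.3f",
        r_squared(mix$pEC50mix_exp[tr], mix$pEC50mix_pred_mlr[tr]),
        rms_error(mix$pEC50mix_exp[tr], mix$pEC50mix_pred_mlr[tr]),
        f_statistic(mix$pEC50mix_exp[tr], mix$pEC50mix_pred_mlr[tr]))
#> "MLR train: R2 = 0.727, RMS = 0.494, F = 159.537"
```

over the 62 training mixtures: 72.7% of the variance in mixture toxicity is
explained, with a 0.494 log-unit error.  A mixture descriptor under the
default cubic rule:

```r
apply_rule(9, d1 = 2, d2 = 1, x1 = 0.75, x2 = 0.25)
#> [1] 6.25            # 0.75 * 2^3 + 0.25 * 1^3
```

Model a synthetic study end to end:

```r
st <- simulate_study(sim_config(seed = 1))
trm <- st$mixtures$split == "train"
m <- fit_ols(st$mixture_descriptors[trm, ], st$y_mixtures[trm])
m
#> Linear QSAR model (fitted)
#>   intercept: 3.547475
#>   DRn-N        0.2776103
#>   DHOMO        0.1046951
#>   DTot-pc      -0.2396539
#>   DMin-C       -0.3166179
#>   DMax-C-H     -0.1419247
#>   training R2: 0.7702 n = 62
validation_report(st$y_mixtures[!trm],
                  predict(m, st$mixture_descriptors[!trm, ]),
                  train_mean = mean(st$y_mixtures[trm]))[c("r2", "rms", "q2_ext")]
#> $r2 [1] 0.777   $rms [1] 0.494   $q2_ext [1] 0.742
```

The external statistics (R² 0.78, q²_ext 0.74 over 17 test mixtures) sit in
the same regime as the packaged study.  `run_pipeline()` chains screening,
stepwise selection, both models, validation and the applicability-domain
report in one call; `verify_packaged_tables()` recomputes all 32 published
summary checks from the packaged tables (all pass).

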