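# longprs

Polygenic risk scores (PGRS) for **longitudinal alcohol consumption**,
built for the setting where a curated candidate panel of SNPs (the
default is an 89-marker panel, part genotyped, part imputed) is tested
against repeated self-reports of weekly alcohol units in a mother /
offspring cohort, and the resulting score is assessed as a potential
instrument for Mendelian randomisation (MR).

The package covers the whole workflow:

* **Synthetic cohorts** (`snp_panel()`, `simulate_genotypes()`,
  `simulate_effects()`, `simulate_phenotypes()`,
  `simulate_covariates()`): zero-inflated log-normal weekly units with a
  person random intercept, 10 maternal or 5 adolescent measurement
  occasions, sparse marker effects, PC-like covariates and a null
  confounder panel. Individual-level cohorts of this kind are
  access-controlled, so all development and testing runs on this
  generator.
* **Association** (`apply_filters()`, `fit_repeated()`,
  `fit_cross_sectional()`, `assoc_scan()`, `bonferroni_threshold()`,
  `pleiotropy_screen()`, `percent_change()`): linear mixed model
  `log_units ~ dosage + age + PCs + (1 | person)` among ever-drinkers,
  per-occasion OLS, candidate-panel Bonferroni control, instrument
  pleiotropy screening.
* **Score selection** (`build_score()`, `evaluate_score()`,
  `cross_validate()`): weighted scores
  `S_i = Σ_{j: p_j ≤ p_T} β̂_j g_ij` over the threshold grid
  {0.01, 0.05, 0.1, 0.2, 0.4, 0.5}, chosen by repeated 80/20
  person-level cross-validation on test-set R².
* **Variance explained** (`expected_r2()`, `estimate_vg()`,
  `simulate_prs_experiment()`): truncated-normal forward model for the
  expected score-trait R² —
  `ρ² = Cov²/Var_S` with
  `Cov = m(1−π₀)·σγ²/(σγ²+s²)·E[X²1(|X|>c)]`, `s² = 1/n₁` — which
  reduces to the Daetwyler closed form `vg²/(vg + m/n₁)` without
  selection, plus maximum-likelihood inversion with profile-likelihood
  intervals and a brute-force simulation validator.
* **MR design** (`power_query()`, `required_n_binary()`,
  `power_binary()`, `required_n_continuous()`):
  `n = (z_{1−α/2}+z_{pow})² / (R²·ln(OR)²·φ(1−φ))`, reported to the
  next multiple of 100.
* **Pipeline and I/O** (`run_pipeline()`, VCF/TSV/CSV/JSON readers and
  writers, a thin CLI at `inst/cli/longprs.R`).

## Worked example

```r
library(longprs)

panel <- snp_panel(m = 89, seed = 1)
geno  <- simulate_genotypes(panel, n = 800, seed = 2)
eff   <- simulate_effects(genetic_architecture(89, vg = 0.2, pi0 = 0.5,
                                               seed = 3), panel)
pheno <- simulate_phenotypes(geno, eff, cohort_design("mother", 800),
                             variance_components(), seed = 4)
covars <- simulate_covariates(800, seed = 5, geno = geno)

analysis <- apply_filters(pheno, filter_spec())
attr(analysis, "audit")
#> never_drinker_persons  zero_unit_records  excluded_occasion_records  flagged_records
#>                    89                862                          0                0
```

89 of 800 simulated mothers never drank and are removed person-wise;
862 zero-unit occasions are dropped record-wise (log 0 is undefined).
A mixed-model scan of the first ten markers ranks them by p-value:

```r
top <- assoc_scan(analysis, geno[, 1:10], covars)
head(top[, c("rank", "target_id", "beta", "se", "p")], 3)
#>   rank target_id       beta         se           p
#> 1    1   snp_002 -0.1649705 0.05271941 0.001752728
#> 2    2   snp_001 -0.1492504 0.05547195 0.007133293
#> 3    3   snp_010 -0.1234436 0.05437287 0.023188429
format_p(bonferroni_threshold(0.05, 89))   # panel-wide threshold
#> "0.00056"
format_percent_change(-0.177)              # log-scale effect as % units
#> "16.2% fewer"
```

The top effect, −0.165 log units per minor allele (p = 0.0018), does not
pass the panel-wide Bonferroni threshold of 0.00056. Cross-validation
then picks the score threshold:

```r
cv <- cross_validate(analysis, geno[, 1:10], covars, repeats = 3, seed = 6)
cv
#> Cross-validated polygenic score selection
#>   3 repeats, 80%/20% person-level split (seed 6)
#>   mean test R-squared by threshold:
#>     p <= 0.01   0.0059
#>     ...
#>     p <= 0.5    0.0127
#>   best threshold: 0.5 (7 SNPs in final score)
```

and the forward model converts the held-out R² into an estimate of the
trait variance the panel explains:

```r
best <- cv$best_threshold
obs <- data.frame(p_threshold = best,
                  r2 = unname(cv$mean_r2[as.character(best)]),
                  n1 = cv$n_train_persons, n2 = cv$n_test_persons, m = 10)
estimate_vg(obs, pi0 = 0.5)
#> Variance explained: 2.261% (95% CI 0.000% to 8.608%), pi0 fixed = 0.50
```

Finally, the MR design module sizes a study that would use such a score
as an instrument — e.g. alcohol on coronary heart disease (OR 0.71)
with a score explaining 0.3% of exposure variance:

```r
required_n_binary(power_query(odds_ratio = 0.71, r2 = 0.003))
#> $n_raw      89217.46
#> $n_reported 89300
```

`run_pipeline(default_run_config(), "out/")` chains all stages and
writes the ranked association TSV, cross-validation JSON, score
definition (PLINK `--score` layout), variance-explained estimate and MR
design table, stamped with the seed and a config hash.

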