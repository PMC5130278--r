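---
title: "Methods: polygenic scores for longitudinal alcohol consumption"
author: "longprs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polygenic scores for longitudinal alcohol consumption}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longprs)
```

## The problem

Weekly alcohol consumption is a noisy, zero-inflated, self-reported
phenotype, and no single common variant except *ADH1B* (rs1229984) is
robustly associated with it in European-ancestry samples. A weighted
polygenic risk score (PGRS) over a curated candidate panel can explain
more exposure variance than a single variant and thereby serve as an
instrument in Mendelian randomisation (MR). `longprs` implements that
workflow end to end for repeated-measures data: per-SNP association under
a linear mixed model, p-value-threshold score construction selected by
cross-validation, model-based estimation of the variance the score
explains, pleiotropy screening, and MR design calculations. Because
individual-level cohort data of this kind are access-controlled, the
package ships a synthetic cohort generator with the same statistical
structure, so every stage is testable and reproducible without any data
download.

## Phenotype model and the analysis sample

All modelling is on **natural-log** weekly units. The internal
consistency check is the standard epidemiological conversion: a
coefficient of $-0.177$ log units per allele corresponds to
$100\,(1 - e^{-0.177}) = 16.2\%$ fewer units per week, which only works
out on the natural scale.

The generator draws, for person $i$ at occasion $t$,

$$\log u_{it} = \beta_0 + \beta_{\text{age}}\,\mathrm{age}_{it} + G_i
  + u_i + e_{it}, \qquad u_i \sim N(0, \tau^2),\;
  e_{it} \sim N(0, \sigma^2),$$

with $G_i = \sum_j \beta_j g^{(s)}_{ij}$ the aggregate genetic value on
the standardized-genotype scale. Zeros arise at two levels, emulating the
observed "zeros (%)" pattern in longitudinal consumption tables: a
fraction of persons never drink (default 0.10) and any remaining occasion
is zero with probability 0.15 (no drinking in the reference week). Both
defaults are fixed study conditions of the generator, not tuning knobs.
Dropout is monotone with a 5% per-occasion hazard. Occasion schedules
default to 10 maternal questionnaires (mean ages 28–48) or 5 adolescent
ones (ages 15–21).

The analysis sample drops never-drinkers person-wise (the ever-drinker
restriction) and zero-unit occasions record-wise, because $\log 0$ is
undefined; `apply_filters()` returns audit counts so both removals are
transparent. Sensitivity filters exclude listed occasions or flagged
(e.g. pregnancy) records.

Default variance components are $\tau^2 = 0.5$, $\sigma^2 = 1.0$,
$\beta_{\text{age}} = 0.02$/yr, $\beta_0 = 0.5$: these put the marginal
standard deviation of log units near 1.2 and the intra-class correlation
near 1/3, which is the order observed for repeated self-reported
consumption. The generator deliberately omits linkage disequilibrium
(the panel is a curated candidate set and the accuracy model assumes
independent markers), random age slopes (only a random intercept is
simulated, since richer covariance is not identified by the data
structure being emulated), real population structure (PCs are plain
standard normals, with genotype-independent confounders so the
pleiotropy screen is null by construction), and reporting biases of
self-report. Passing tests therefore demonstrate correctness of the
estimators under the stated model, not robustness to those real-data
features.

Imputed markers are simulated as scaled-Beta dosages on $[0,2]$ with the
exact Hardy–Weinberg mean $2\,\mathrm{maf}$ and about 90% of the binomial
variance, mimicking imputation uncertainty without modelling haplotypes;
hard calls are $\mathrm{Binomial}(2, \mathrm{maf})$.

## Association

`fit_repeated()` fits
`log_units ~ dosage + age + PC1..PC10 + (1 | person)` by REML (lme4) and
reports the Wald test of the dosage term, i.e. log units per copy of the
minor allele. Non-convergence triggers one ML refit and is otherwise
flagged, never returned as silent `NaN`; monomorphic markers raise an
explicit error. Cross-sectional analysis is OLS at one occasion.
Wald p-values use the normal approximation, appropriate at the sample
sizes involved. The scan default disables lme4's finite-difference
derivative check (`calc.derivs = FALSE`), which roughly halves the cost
of a panel scan without changing the estimates.

Multiplicity follows the Bonferroni convention for a candidate panel:
$0.05/89 = 0.00056$ for repeated measures and
$0.05/(89 \times 15) = 0.000037$ across the 15 cross-sectional occasions
(10 maternal + 5 offspring). Reports round thresholds and p-values to
two significant figures; machine outputs keep full precision. The
pleiotropy screen regresses each confounder on each instrument (linear
for continuous, logistic for binary) and judges pairs against
$\alpha$ divided by the number of tests; with 89 instruments and 5
covariate families that threshold prints as 0.00011.

## Score construction and cross-validation

At threshold $p_T$, the score is
$S_i = \sum_{j:\, p_j \le p_T} \hat\beta_j g_{ij}$ with training-sample
mixed-model weights. Thresholds $\{0.01, 0.05, 0.1, 0.2, 0.4, 0.5\}$ are
compared by repeated (5×) 80/20 cross-validation. Splits are at person
level — all of a person's occasions travel together, since
record-level splits would leak the person random intercept across the
partition — and are stratified by cohort if several are present.

The data structure leaves "R-squared for predicting repeated measures"
underdetermined, so the package defines it as the squared Pearson
correlation between the score and **person-mean log units**, both
residualized on person-mean age and the PCs. This is model-free, targets
the between-person variance a genetic instrument can actually explain,
and is invariant to affine rescaling of the score. Ties in mean
R-squared resolve to the smaller threshold (the more parsimonious
score). Final weights are refit on all persons at the selected
threshold. The grid is configurable and admits 1.0 (an all-SNP score).

## Expected score accuracy and variance explained

The forward model works on standardized genotypes with a unit-variance
trait. Training effect estimates have sampling variance $s^2 = 1/n_1$;
non-null effects (a $1-\pi_0$ fraction of $m$ markers) have variance
$\sigma_\gamma^2 = v_g/(m(1-\pi_0))$. Selection keeps estimates beyond
$c = z_{1-p_T/2}\, s$. With
$E_2(v, c) = E[X^2 \mathbf{1}(|X|>c)] = 2v\{\Phi(-a) + a\phi(a)\}$,
$a = c/\sqrt v$:

$$\mathrm{Cov} = m(1-\pi_0)\frac{\sigma_\gamma^2}{\sigma_\gamma^2+s^2}
  E_2(\sigma_\gamma^2+s^2,\, c), \quad
  \mathrm{Var}_S = m(1-\pi_0)E_2(\sigma_\gamma^2+s^2, c)
  + m\pi_0 E_2(s^2, c),$$

$$\rho^2 = \mathrm{Cov}^2/\mathrm{Var}_S .$$

At $p_T = 1$ this collapses exactly to the no-selection closed form
$v_g^2/(v_g + m/n_1)$, which the tests verify to $10^{-10}$ across a
parameter grid. Note that $\rho^2$ is a **ratio of expectations**; the
mean of per-replicate squared correlations in a finite-$m$ experiment
sits a few percent above it (mean-of-ratio versus ratio-of-means), which
is why the brute-force validator `simulate_prs_experiment()` reports
both the per-replicate mean and the pooled moment-ratio estimator — the
latter is the forward model's exact empirical counterpart, with a
block-resampled Monte-Carlo standard error. The validator also assigns
null status i.i.d. with probability $\pi_0$, matching the mixture
assumption of the model it checks.

Inversion (`estimate_vg()`) treats each observed threshold result as a
Wald statistic $z \sim N(\sqrt{\lambda}, 1)$ with
$\lambda = n_2 \rho^2/(1-\rho^2)$, maximizes the likelihood over
$v_g \in [0, 1)$, and reports a 95% profile-likelihood interval
($\chi^2_1$ cut-off 3.841; one-sided profile at the $v_g = 0$ boundary,
where the interval's lower end is pinned to 0). $\pi_0$ is fixed by
default; joint estimation over at least two thresholds is available but
nested thresholds are correlated, so multi-threshold likelihoods are an
approximation and the default workflow supplies the single selected
threshold. Observed $\hat R^2$ values convert via
$z = \sqrt{n_2 \hat R^2/(1-\hat R^2)}$. Only the continuous-trait model
is implemented; liability-scale extensions for binary outcomes are out
of scope.

## MR design calculations

For a binary outcome, detecting a causal log odds ratio through an
instrument explaining $R^2$ of the exposure in a case-control sample
with case fraction $\phi$ requires

$$n = \frac{(z_{1-\alpha/2} + z_{\text{power}})^2}
  {R^2 (\ln \mathrm{OR})^2\, \phi(1-\phi)} .$$

Reported figures round *up* to the next multiple of 100 — the
conservative convention for design numbers, and the one under which the
four standard alcohol–cardiovascular design points (OR 0.75/0.71 by
$R^2$ 0.3%/0.7%, 80% power, $\alpha = 0.05$, 1:1) come out at 126,500,
54,200, 89,300 and 38,300 exactly. `power_binary()` is the exact inverse;
`required_n_continuous()` covers continuous outcomes via
$n = (z_{1-\alpha/2}+z_{\text{power}})^2/(R^2\beta^2)$.

## Numerical choices and problem sizes

* Dosage variance below $10^{-12}$ is treated as monomorphic;
  zero-variance scores evaluate to $R^2 = 0$ with a degeneracy flag.
* `optimize()` cannot return the boundary, so the likelihood at
  $v_g = 0$ is checked explicitly; profile-interval roots are bracketed
  by `uniroot()` at tolerance $10^{-8}$.
* The test suite validates the forward model against 500-replicate
  two-stage simulations at $m = 89$, $n_1 = 4000$,
  $v_g \in \{0.05, 0.20\}$, $p_T \in \{0.05, 0.5\}$; estimator coverage
  over 200 replicates at $n_1 = n_2 = 20{,}000$; association type-I
  error over a 500-marker null panel in a 300-person cohort; and the
  full cross-validation loop on a 4,000-person cohort with
  $v_g = 0.20$, $\pi_0 = 0.5$, compared against the forward-model
  prediction computed with the *realized* marker variance
  ($\sum_j \beta_j^2$ from the drawn effects) rescaled by the variance of
  residualized person-mean log units — the realized value is used
  because a single draw of 45 non-null effects has a relative SD of
  about 20% around its target. These sizes were chosen as the smallest
  at which the Monte-Carlo error bands are meaningfully tight.
* For that calibration check the variance components are
  $\tau^2 = 0.5$, $\sigma^2 = 1.5$ with 5 occasions, so person-mean log
  units have total variance near 1 and the generator's $v_g$ is directly
  the variance *fraction* the forward model expects.

## Known limitations

The score R-squared definition is one of several defensible choices; a
likelihood-based marginal R-squared would weight persons by occasion
count instead. Selection of the best threshold by maximum mean
R-squared carries a small winner's-curse optimism with only five
repeats. The forward model ignores estimation error correlation across
nested thresholds, LD, and case-control ascertainment. The generator's
imputed-dosage distribution is a convenience (correct first two moments,
not a haplotype model), and its confounders are genotype-independent
except by explicit injection.
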