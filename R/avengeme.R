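#' Probability a marker estimate passes an absolute cut-off
#'
#' For an estimator `X ~ N(0, v)` and absolute cut-off `c`,
#' `P(|X| > c) = 2 * pnorm(-c / sqrt(v))`. The cut-off corresponding to a
#' two-sided training p-value threshold `p` at per-marker sampling
#' variance `1/n1` is `qnorm(1 - p/2) / sqrt(n1)`.
#'
#' @param v Variance of the estimator (> 0).
#' @param c Absolute selection cut-off (>= 0).
#' @return Probability in `[0, 1]`.
#' @export
selection_probability <- function(v, c) {
  assert_scalar_number(v, "v", 0, open_lower = TRUE)
  assert_scalar_number(c, "c", 0)
  2 * stats::pnorm(-c / sqrt(v))
}

#' Truncated second moment of a centred normal
#'
#' `E[X^2 * 1(|X| > c)]` for `X ~ N(0, v)`:
#' `v * 2 * (pnorm(-a) + a * dnorm(a))` with `a = c / sqrt(v)`.
#' This is the workhorse of the selection model: the variance contributed
#' by effect estimates retained by a p-value threshold.
#'
#' @inheritParams selection_probability
#' @return Non-negative expectation; equals `v` at `c = 0`.
#' @export
truncated_second_moment <- function(v, c) {
  assert_scalar_number(v, "v", 0, open_lower = TRUE)
  assert_scalar_number(c, "c", 0)
  a <- c / sqrt(v)
  v * 2 * (stats::pnorm(-a) + a * stats::dnorm(a))
}

#' Specify the polygenic-accuracy forward model
#'
#' Continuous unit-variance trait, `m` independent standardized markers of
#' which a fraction `pi0` are null; non-null effects are
#' `N(0, vg / (m (1 - pi0)))` so the panel jointly explains `vg` of the
#' trait variance. Training effect estimates from `n1` individuals carry
#' sampling variance `1/n1`; markers with two-sided training p-value below
#' `p_threshold` enter the score, evaluated in `n2` test individuals.
#'
#' @param n1 Training sample size.
#' @param n2 Test sample size.
#' @param m Number of independent markers.
#' @param vg Marker-explained variance fraction, `0 <= vg < 1`.
#' @param pi0 Fraction of null markers.
#' @param p_threshold Selection p-value in (0, 1].
#' @return List of class `avengeme_model`.
#' @export
avengeme_model <- function(n1, n2 = n1, m = 89, vg = 0.05, pi0 = 0,
                           p_threshold = 1) {
  assert_count(n1, "n1"); assert_count(n2, "n2"); assert_count(m, "m")
  assert_scalar_number(vg, "vg", 0, 1, open_upper = TRUE)
  assert_scalar_number(pi0, "pi0", 0, 1)
  assert_scalar_number(p_threshold, "p_threshold", 0, 1, open_lower = TRUE)
  if (pi0 == 1 && vg > 0)
    stop("pi0 = 1 is incompatible with vg > 0", call. = FALSE)
  structure(list(n1 = n1, n2 = n2, m = m, vg = vg, pi0 = pi0,
                 p_threshold = p_threshold),
            class = "avengeme_model")
}

#' Expected squared correlation between score and trait
#'
#' Forward model for the accuracy of a p-value-thresholded polygenic
#' score. With `s2 = 1/n1`, per-marker effect variance
#' `sg2 = vg / (m (1 - pi0))` and cut-off
#' `c = qnorm(1 - p_threshold/2) * sqrt(s2)`:
#' the score-trait covariance is
#' `m (1 - pi0) * sg2 / (sg2 + s2) * E[X^2 1(|X|>c)]` for
#' `X ~ N(0, sg2 + s2)`, the score variance adds the analogous null-marker
#' term with `X ~ N(0, s2)`, and the expected squared correlation is
#' `Cov^2 / VarS` (trait variance 1). At `p_threshold = 1` this reduces
#' exactly to the no-selection closed form `vg^2 / (vg + m / n1)`.
#'
#' @param model An [avengeme_model()].
#' @return Expected squared correlation in `[0, 1]`; 0 when no marker can
#'   be selected.
#' @export
#' @examples
#' expected_r2(avengeme_model(n1 = 5000, m = 89, vg = 0.05, p_threshold = 1))
expected_r2 <- function(model) {
  stopifnot(inherits(model, "avengeme_model"))
  s2 <- 1 / model$n1
  c <- stats::qnorm(1 - model$p_threshold / 2) * sqrt(s2)
  pi0 <- model$pi0
  m <- model$m
  if (model$vg == 0 && pi0 < 1) sg2 <- 0
  else if (pi0 < 1) sg2 <- model$vg / (m * (1 - pi0))
  else sg2 <- 0
  e2_alt <- if (pi0 < 1) truncated_second_moment(sg2 + s2, c) else 0
  e2_null <- truncated_second_moment(s2, c)
  cov <- if (pi0 < 1) m * (1 - pi0) * (sg2 / (sg2 + s2)) * e2_alt else 0
  var_s <- m * (1 - pi0) * e2_alt + m * pi0 * e2_null
  if (var_s <= 0) return(0)
  cov^2 / var_s
}

#' Non-centrality of the test-sample score-trait association
#'
#' `lambda = n2 * rho2 / (1 - rho2)` where `rho2` is the forward-model
#' expected squared correlation; the test-sample Wald statistic is
#' approximately `N(sqrt(lambda), 1)`.
#'
#' @param model An [avengeme_model()].
#' @param n2 Test sample size (default from the model).
#' @return Non-centrality parameter `lambda >= 0`.
#' @export
expected_ncp <- function(model, n2 = model$n2) {
  rho2 <- expected_r2(model)
  n2 * rho2 / (1 - rho2)
}

#' Estimate variance explained from observed score-trait results
#'
#' Maximum-likelihood inversion of the forward model. Each observed
#' threshold result contributes a Wald statistic
#' `z ~ N(sqrt(lambda(vg, pi0)), 1)`; observed R-squared values are
#' converted via `z = sqrt(n2 * r2 / (1 - r2))`. `vg` is profiled over
#' `[0, 1)` and the 95% confidence interval is the profile-likelihood set
#' `{vg : 2 * (loglik_max - loglik(vg)) <= 3.841}` (one-sided at the
#' `vg = 0` boundary). Multiple thresholds are treated as independent
#' observations, an approximation since nested thresholds share markers;
#' the default workflow supplies the single selected threshold.
#'
#' @param observed `data.frame` with columns `p_threshold`, `n1`, `n2`,
#'   `m` and either `z` or `r2`.
#' @param pi0 Fixed null fraction (default), or `"estimate"` to profile it
#'   jointly (requires at least 2 thresholds).
#' @return List of class `avengeme_estimate`: `vg_hat`, `ci_low`,
#'   `ci_high`, `pi0_mode`, `pi0_hat`, `loglik`, `converged`,
#'   `n_thresholds`.
#' @export
estimate_vg <- function(observed, pi0 = 0) {
  stopifnot(is.data.frame(observed), nrow(observed) >= 1,
            all(c("p_threshold", "n1", "n2", "m") %in% names(observed)))
  if (!"z" %in% names(observed)) {
    if (!"r2" %in% names(observed))
      stop("observed needs a `z` or `r2` column", call. = FALSE)
    observed$z <- sqrt(observed$n2 * observed$r2 / (1 - observed$r2))
  }
  estimate_pi0 <- identical(pi0, "estimate")
  if (estimate_pi0 && nrow(observed) < 2)
    stop("pi0 estimation requires results at >= 2 thresholds", call. = FALSE)

  loglik <- function(vg, p0) {
    ll <- 0
    for (i in seq_len(nrow(observed))) {
      mod <- avengeme_model(observed$n1[i], observed$n2[i], observed$m[i],
                            vg = vg, pi0 = p0,
                            p_threshold = observed$p_threshold[i])
      ll <- ll + stats::dnorm(observed$z[i], sqrt(expected_ncp(mod)), 1,
                              log = TRUE)
    }
    ll
  }
  vg_hi <- 0.999
  if (estimate_pi0) {
    obj <- function(par) -loglik(par[1], par[2])
    opt <- stats::optim(c(0.05, 0.5), obj, method = "L-BFGS-B",
                        lower = c(0, 0), upper = c(vg_hi, 0.999))
    vg_hat <- opt$par[1]; pi0_hat <- opt$par[2]
    ll_max <- -opt$value
    converged <- opt$convergence == 0
    prof <- function(vg) {
      o <- stats::optimize(function(p0) -loglik(vg, p0), c(0, 0.999))
      -o$objective
    }
  } else {
    assert_scalar_number(pi0, "pi0", 0, 1)
    opt <- stats::optimize(function(v) -loglik(v, pi0), c(0, vg_hi))
    vg_hat <- opt$minimum
    ll_max <- -opt$objective
    # optimize never returns an interior boundary point: check vg = 0
    if (loglik(0, pi0) >= ll_max) {
      vg_hat <- 0
      ll_max <- loglik(0, pi0)
    }
    pi0_hat <- pi0
    converged <- TRUE
    prof <- function(vg) loglik(vg, pi0)
  }
  cut <- ll_max - stats::qchisq(0.95, 1) / 2
  drop_fun <- function(vg) prof(vg) - cut
  ci_low <- if (vg_hat <= 1e-8 || drop_fun(0) >= 0) 0 else
    stats::uniroot(drop_fun, c(0, vg_hat), tol = 1e-8)$root
  ci_high <- if (drop_fun(vg_hi) >= 0) vg_hi else
    stats::uniroot(drop_fun, c(max(vg_hat, 1e-8), vg_hi), tol = 1e-8)$root
  structure(list(vg_hat = vg_hat, ci_low = ci_low, ci_high = ci_high,
                 pi0_mode = if (estimate_pi0) "estimated" else "fixed",
                 pi0_hat = pi0_hat, loglik = ll_max, converged = converged,
                 n_thresholds = nrow(observed)),
            class = "avengeme_estimate")
}

#' @export
print.avengeme_estimate <- function(x, ...) {
  cat(sprintf(
    "Variance explained: %.3f%% (95%% CI %.3f%% to %.3f%%), pi0 %s = %.2f\n",
    100 * x$vg_hat, 100 * x$ci_low, 100 * x$ci_high, x$pi0_mode, x$pi0_hat))
  invisible(x)
}

#' Brute-force two-stage polygenic-score experiment
#'
#' Monte-Carlo check of the forward model that shares none of its
#' truncated-normal algebra. Per replicate: assign each marker null status
#' independently with probability `pi0`; draw true standardized effects of
#' the non-null markers; draw training estimates
#' `beta_hat_j ~ N(beta_j, 1/n1)` (the exact sampling distribution for a
#' standardized marker and unit-variance trait); select markers whose
#' two-sided training p passes the threshold; then simulate an actual test
#' cohort of `n2_sim` individuals with standardized genotypes and trait
#' `y = sum(beta_j g_j) + e`, and record the score-trait moments.
#'
#' Two summaries are returned. `pooled_r2` is the moment-ratio estimator
#' `mean(cov)^2 / (mean(var_score) * mean(var_y))`, the empirical
#' counterpart of the forward model's ratio-of-expectations; its
#' Monte-Carlo standard error comes from block resampling. `mean_r2`
#' averages the per-replicate squared sample correlations; it estimates
#' `E[r^2]`, which sits slightly above the forward value at small `m`
#' (mean of a ratio versus ratio of means) and carries the usual upward
#' finite-`n2` bias of a squared correlation.
#'
#' @param model An [avengeme_model()].
#' @param n_reps Number of replicates.
#' @param n2_sim Test-cohort size actually simulated per replicate.
#' @param seed Integer seed.
#' @param n_blocks Number of blocks for the pooled-estimator standard
#'   error.
#' @return List: `pooled_r2`, `pooled_se`, `mean_r2`, `mc_se`, `r2`
#'   (per-replicate squared correlations).
#' @export
simulate_prs_experiment <- function(model, n_reps = 500, n2_sim = 1000,
                                    seed = 1L, n_blocks = 10) {
  stopifnot(inherits(model, "avengeme_model"))
  set.seed(seed)
  m <- model$m
  s <- sqrt(1 / model$n1)
  zcut <- stats::qnorm(1 - model$p_threshold / 2)
  sg <- if (model$pi0 < 1) sqrt(model$vg / (m * (1 - model$pi0))) else 0
  r2 <- cov_sy <- var_s <- var_y <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    nulls <- stats::runif(m) < model$pi0
    beta <- numeric(m)
    beta[!nulls] <- stats::rnorm(sum(!nulls), 0, sg)
    beta_hat <- beta + stats::rnorm(m, 0, s)
    sel <- abs(beta_hat) / s > zcut
    g <- matrix(stats::rnorm(n2_sim * m), n2_sim, m)
    y <- drop(g %*% beta) +
      stats::rnorm(n2_sim, 0, sqrt(max(1 - sum(beta^2), 1e-12)))
    var_y[r] <- stats::var(y)
    if (!any(sel)) next
    score <- drop(g[, sel, drop = FALSE] %*% beta_hat[sel])
    cov_sy[r] <- stats::cov(score, y)
    var_s[r] <- stats::var(score)
    r2[r] <- if (var_s[r] > 0) stats::cor(score, y)^2 else 0
  }
  block <- rep(seq_len(n_blocks), length.out = n_reps)
  pooled <- function(idx)
    mean(cov_sy[idx])^2 / (mean(var_s[idx]) * mean(var_y[idx]))
  block_vals <- vapply(split(seq_len(n_reps), block), pooled, numeric(1))
  list(pooled_r2 = pooled(seq_len(n_reps)),
       pooled_se = stats::sd(block_vals) / sqrt(n_blocks),
       mean_r2 = mean(r2), mc_se = stats::sd(r2) / sqrt(n_reps),
       r2 = r2)
}
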