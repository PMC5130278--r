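test_that("genotype matrix honours panel dimensions, range and HWE", {
  panel <- snp_panel(m = 89, seed = 3)
  g <- simulate_genotypes(panel, n = 100, seed = 4)
  expect_identical(dim(g), c(100L, 89L))
  expect_true(all(g >= 0 & g <= 2))
  hard <- panel$snp_id[!panel$imputed]
  expect_true(all(g[, hard] %in% 0:2))

  # hard-called genotype counts follow p^2, 2pq, q^2 at n = 5000
  # (chi-square goodness of fit, df = 2)
  g5 <- simulate_genotypes(panel, n = 5000, seed = 5)
  for (s in hard[1:10]) {
    q <- panel$maf[panel$snp_id == s]
    exp_n <- 5000 * c((1 - q)^2, 2 * q * (1 - q), q^2)
    obs <- tabulate(g5[, s] + 1, 3)
    stat <- sum((obs - exp_n)^2 / exp_n)
    expect_lt(stat, qchisq(0.9999, df = 2), label = s)
  }
})

test_that("degenerate and large-sample allele frequencies behave", {
  panel <- data.frame(snp_id = c("z", "h"), effect_allele = "A",
                      other_allele = "G", maf = c(0, 0.5),
                      imputed = FALSE, stringsAsFactors = FALSE)
  g <- simulate_genotypes(panel, n = 10000, seed = 6)
  expect_true(all(g[, "z"] == 0))
  # mean dosage at maf 0.5 within 3 * sqrt(0.5/n) of 1
  expect_lt(abs(mean(g[, "h"]) - 1), 3 * sqrt(0.5 / 10000))
  expect_error(simulate_genotypes(panel, n = 0), "n")
})

test_that("imputed dosages are continuous with the HWE mean", {
  panel <- snp_panel(m = 40, seed = 7)
  g <- simulate_genotypes(panel, n = 20000, seed = 8)
  imp <- panel$snp_id[panel$imputed]
  expect_true(any(g[, imp[1]] != round(g[, imp[1]])))
  for (s in imp[1:5]) {
    maf <- panel$maf[panel$snp_id == s]
    se <- sqrt(2 * maf * (1 - maf) / 20000)
    expect_lt(abs(mean(g[, s]) - 2 * maf), 4 * se)
  }
})

test_that("effect draws respect sparsity and total variance", {
  panel <- snp_panel(m = 89, seed = 9)
  # fully null architecture
  eff0 <- simulate_effects(genetic_architecture(89, 0, 1, seed = 1), panel)
  expect_true(all(eff0$beta_std == 0))
  expect_error(genetic_architecture(89, 0.1, 1), "pi0")

  # exact null count and dosage-scale conversion
  eff <- simulate_effects(genetic_architecture(89, 0.05, 0.5, seed = 2),
                          panel)
  expect_identical(nrow(eff), 89L)
  expect_identical(sum(eff$beta_std == 0), as.integer(round(89 * 0.5)))
  j <- which(!eff$is_null)[1]
  expect_equal(eff$beta_dosage[j],
               eff$beta_std[j] / sqrt(2 * panel$maf[j] * (1 - panel$maf[j])))

  # law of large numbers: mean total variance over 1000 draws ~ vg
  tot <- vapply(seq_len(1000), function(k)
    sum(simulate_effects(genetic_architecture(89, 0.05, 0.5, seed = k),
                         panel)$beta_std^2), numeric(1))
  expect_lt(abs(mean(tot) - 0.05), 3 * sd(tot) / sqrt(1000))
})

test_that("phenotype model reduces to its deterministic core without noise", {
  panel <- snp_panel(m = 4, seed = 10)
  g <- simulate_genotypes(panel, 50, seed = 11)
  eff <- simulate_effects(genetic_architecture(4, 0, 1, seed = 1), panel)
  design <- cohort_design("offspring", 50, p_never_drinker = 0,
                          p_zero_occasion = 0, dropout_per_occasion = 0)
  vc <- variance_components(tau2 = 0, sigma2 = 1e-12, beta_age = 0.03,
                            intercept = 0.4)
  ph <- simulate_phenotypes(g, eff, design, vc, seed = 12, p_flag = 0)
  expect_identical(nrow(ph), 250L)  # 50 persons x 5 occasions
  expect_equal(ph$log_units, 0.4 + 0.03 * ph$age, tolerance = 1e-4)
})

test_that("phenotype generator recovers the genetic signal it planted", {
  s <- tiny_sim(n = 3000, m = 89, vg = 0.20, pi0 = 0.5, seed = 21,
                p_never = 0, p_zero = 0, dropout = 0)
  gv <- attr(s$pheno, "genetic_value")
  ybar <- tapply(s$pheno$log_units, s$pheno$person_id, mean)
  fit <- summary(lm(as.numeric(ybar) ~ gv[names(ybar)]))$coefficients
  expect_lt(abs(fit[2, 1] - 1), 3 * fit[2, 2])
})

test_that("variance decomposition of simulated log units is honest", {
  s <- tiny_sim(n = 10000, m = 89, vg = 0.2, pi0 = 0.5, seed = 31,
                tau2 = 0.5, sigma2 = 1.0, beta_age = 0,
                p_never = 0, p_zero = 0, dropout = 0)
  vg_real <- sum(s$effects$beta_std^2)
  v_obs <- var(s$pheno$log_units)
  v_exp <- vg_real + 0.5 + 1.0
  expect_lt(abs(v_obs - v_exp) / v_exp, 0.05)
})

test_that("seeded generation is byte-identical and zero-inflation is consistent", {
  a <- tiny_sim(seed = 41)
  b <- tiny_sim(seed = 41)
  expect_identical(a$geno, b$geno)
  expect_identical(a$pheno, b$pheno)
  expect_identical(a$covars, b$covars)

  never <- attr(a$pheno, "never_drinker")
  for (p in names(never)[never]) {
    rows <- a$pheno$units[a$pheno$person_id == p]
    expect_true(all(rows == 0))
  }
})

test_that("covariate table has PCs plus confounders and supports injection", {
  cv <- simulate_covariates(150, seed = 51)
  expect_identical(dim(cv), c(150L, 59L))  # id + 10 PCs + 48 confounders
  expect_true(all(paste0("PC", 1:10) %in% names(cv)))

  panel <- snp_panel(m = 5, seed = 52)
  g <- simulate_genotypes(panel, 2000, seed = 53)
  cvi <- simulate_covariates(2000, seed = 54, geno = g,
                             inject = list(snp = "snp_002", rho = 0.3))
  inj <- attr(cvi, "injected")
  expect_identical(inj$snp, "snp_002")
  expect_lt(abs(cor(cvi[[inj$confounder]], g[, "snp_002"]) - 0.3), 0.07)
})
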