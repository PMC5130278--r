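test_that("filters drop never-drinkers person-wise and zero occasions record-wise", {
  ph <- toy_pheno()
  out <- apply_filters(ph, filter_spec())
  expect_false("A" %in% out$person_id)        # all-zero person removed
  expect_identical(nrow(out), 2L)             # B keeps the 2 non-zero records
  audit <- attr(out, "audit")
  expect_identical(unname(audit["never_drinker_persons"]), 1L)
  expect_identical(unname(audit["zero_unit_records"]), 1L)
})

test_that("occasion exclusion removes exactly the listed labels", {
  s <- tiny_sim(n = 80, m = 4, cohort = "mother", seed = 61, dropout = 0)
  expect_identical(length(unique(s$pheno$occasion)), 10L)
  out <- apply_filters(s$pheno, filter_spec(
    drop_never_drinkers = FALSE, drop_zero_occasions = FALSE,
    exclude_occasions = c("4y", "7y", "8y", "12y")))
  expect_identical(sort(unique(out$occasion)),
                   sort(c("0y", "1y", "2y", "3y", "6y", "18y")))
  expect_error(apply_filters(s$pheno,
                             filter_spec(exclude_occasions = "99y")),
               "unknown occasion")
})

test_that("an empty filter spec is the identity with a zero audit", {
  ph <- toy_pheno()
  out <- apply_filters(ph, filter_spec(drop_never_drinkers = FALSE,
                                       drop_zero_occasions = FALSE))
  expect_equal(as.data.frame(out), ph, ignore_attr = TRUE)
  expect_true(all(attr(out, "audit") == 0L))
})

test_that("flagged records are excluded and audited", {
  ph <- toy_pheno()
  ph$pregnant <- c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE)
  out <- apply_filters(ph, filter_spec(drop_never_drinkers = FALSE,
                                       drop_zero_occasions = FALSE,
                                       exclude_flagged = "pregnant"))
  expect_identical(nrow(out), 5L)
  expect_identical(unname(attr(out, "audit")["flagged_records"]), 1L)
})

test_that("cross-sectional fit is exact on a hand-built toy", {
  ph <- data.frame(person_id = paste0("P", 1:4), cohort = "mother",
                   occasion = "0y", age = 30,
                   units = exp(c(0, 0.1, 0.2, 0.1)),
                   stringsAsFactors = FALSE)
  ph$log_units <- log(ph$units)
  dos <- stats::setNames(c(0, 1, 2, 1), ph$person_id)
  res <- suppressWarnings(  # lm warns on an exactly perfect fit
    fit_cross_sectional(ph, "0y", dos, adjust_age = FALSE))
  expect_equal(res$beta, 0.1, tolerance = 1e-10)
  expect_identical(res$kind, "cross_sectional")
  expect_error(fit_cross_sectional(ph, "9y", dos), "occasion")
})

test_that("rank-deficient and monomorphic inputs raise explicit errors", {
  s <- tiny_sim(n = 30, m = 3, seed = 71)
  f <- s$filtered
  occ <- f$occasion[1]
  small <- f[f$person_id %in% unique(f$person_id)[1:3], ]
  expect_error(
    fit_cross_sectional(small, occ, person_dosage(s$geno, "snp_001"),
                        s$covars),
    "under-determined")
  flat <- stats::setNames(rep(2, nrow(s$geno)), rownames(s$geno))
  expect_error(fit_repeated(f, flat), "monomorphic")
})

test_that("mixed-model estimate recovers a planted dosage effect", {
  s <- tiny_sim(n = 500, m = 4, vg = 0, pi0 = 1, seed = 81,
                p_never = 0, p_zero = 0, dropout = 0)
  ph <- s$pheno
  beta_true <- 0.10
  dos <- s$geno[, "snp_002"]
  ph$log_units <- ph$log_units + beta_true * dos[ph$person_id]
  ph$units <- exp(ph$log_units)
  res <- fit_repeated(apply_filters(ph, filter_spec()),
                      person_dosage(s$geno, "snp_002"), s$covars)
  expect_lt(abs(res$beta - beta_true), 3 * res$se)
  expect_true(res$converged)
  expect_gt(res$n, res$n_persons)
})

test_that("repeated and pooled cross-sectional estimators agree on exchangeable data", {
  s <- tiny_sim(n = 800, m = 4, vg = 0.3, pi0 = 0, seed = 91,
                p_never = 0, p_zero = 0, dropout = 0)
  f <- s$filtered
  dos <- person_dosage(s$geno, "snp_001")
  rep_fit <- fit_repeated(f, dos, s$covars)
  occ <- unique(f$occasion)
  cs <- lapply(occ, function(o) fit_cross_sectional(f, o, dos, s$covars))
  w <- vapply(cs, function(x) 1 / x$se^2, numeric(1))
  b <- vapply(cs, function(x) x$beta, numeric(1))
  pooled <- sum(w * b) / sum(w)
  expect_lt(abs(pooled - rep_fit$beta), 3 * rep_fit$se)
})

test_that("association results ignore row order of the input table", {
  s <- tiny_sim(n = 150, m = 3, seed = 101)
  f <- s$filtered
  dos <- person_dosage(s$geno, "snp_003")
  r1 <- fit_repeated(f, dos, s$covars)
  set.seed(1)
  shuffled <- f[sample(nrow(f)), ]
  r2 <- fit_repeated(shuffled, dos, s$covars)
  expect_equal(r1$beta, r2$beta, tolerance = 1e-8)
  expect_equal(r1$se, r2$se, tolerance = 1e-8)
})

test_that("Bonferroni thresholds match the panel conventions", {
  expect_identical(format_p(bonferroni_threshold(0.05, 89)), "0.00056")
  expect_identical(format_p(bonferroni_threshold(0.05, 89, 15)), "0.000037")
  expect_identical(format_p(bonferroni_threshold(0.05, 89, 5)), "0.00011")
  expect_equal(bonferroni_threshold(0.05, 1, 1), 0.05)
  expect_error(bonferroni_threshold(0.05, 0), "n_snps")
  # doubling alpha doubles every threshold
  for (k in c(1L, 7L, 89L))
    expect_equal(bonferroni_threshold(0.10, k, 3L),
                 2 * bonferroni_threshold(0.05, k, 3L))
})

test_that("percent-change conversion and its inverse are exact", {
  expect_equal(round(percent_change(-0.177)$percent, 1), 16.2)
  expect_identical(percent_change(-0.177)$direction, "fewer")
  expect_identical(format_percent_change(-0.177), "16.2% fewer")
  expect_equal(percent_change(0)$percent, 0)
  expect_equal(percent_change(log(0.5))$percent, 50)
  for (x in c(1, 5, 16.2, 50, 99))
    expect_equal(percent_change(log(1 - x / 100))$percent, x)
  expect_equal(percent_change(0.25)$direction, "more")
})

test_that("pleiotropy screen flags an injected confounder and only that", {
  panel <- snp_panel(m = 6, seed = 111)
  g <- simulate_genotypes(panel, 2000, seed = 112)
  cv <- simulate_covariates(2000, n_confounders = 10, seed = 113, geno = g,
                            inject = list(snp = "snp_003", rho = 0.3))
  res <- pleiotropy_screen(g, cv)
  inj <- attr(cv, "injected")
  hit <- res[res$pass_bonferroni, ]
  expect_true(any(hit$target_id == inj$snp & hit$variable == inj$confounder))
  expect_error(
    pleiotropy_screen(g, transform(cv, conf_02 = 1), vars = "conf_02"),
    "constant")
})

test_that("null confounder panels rarely produce family-wise flags", {
  flags <- vapply(1:10, function(k) {
    panel <- snp_panel(m = 10, seed = 120 + k)
    g <- simulate_genotypes(panel, 400, seed = 220 + k)
    cv <- simulate_covariates(400, n_confounders = 12, seed = 320 + k,
                              geno = g)
    sum(pleiotropy_screen(g, cv)$pass_bonferroni)
  }, numeric(1))
  expect_lte(sum(flags > 0), 2)  # FWER 0.05 per seed
})

test_that("screen reports the corrected threshold it applied", {
  panel <- snp_panel(m = 3, seed = 131)
  g <- simulate_genotypes(panel, 100, seed = 132)
  cv <- simulate_covariates(100, n_confounders = 4, seed = 133, geno = g)
  res <- pleiotropy_screen(g, cv, n_tests = 89 * 5)
  expect_identical(attr(res, "threshold_reported"), "0.00011")
})
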