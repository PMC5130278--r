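test_that("selection probability matches the normal tail", {
  expect_equal(selection_probability(1, 0), 1)
  expect_equal(selection_probability(1, qnorm(0.975)), 0.05,
               tolerance = 1e-6)
  expect_lte(selection_probability(1, 10), 1.6e-23)
  expect_equal(selection_probability(4, 2 * 1.5),
               selection_probability(1, 1.5))
  expect_error(selection_probability(0, 1), "v")
  expect_error(selection_probability(1, -1), "c")
})

test_that("truncated second moment agrees with numerical quadrature", {
  expect_equal(truncated_second_moment(2.5, 0), 2.5)
  quad <- function(v, c)
    2 * integrate(function(x) x^2 * dnorm(x, 0, sqrt(v)), c, Inf,
                  rel.tol = 1e-12)$value
  for (v in c(0.5, 1, 3)) for (c in c(0.1, 0.7, 2)) {
    expect_equal(truncated_second_moment(v, c), quad(v, c),
                 tolerance = 1e-9)
  }
  expect_equal(truncated_second_moment(1, qnorm(0.975)), 0.2791,
               tolerance = 1e-3)
  # variance scaling: value(4v, 2c) = 4 value(v, c)
  expect_equal(truncated_second_moment(4 * 1.3, 2 * 0.8),
               4 * truncated_second_moment(1.3, 0.8), tolerance = 1e-12)
})

test_that("forward model hits the no-selection closed form and null limits", {
  # Daetwyler closed form vg^2/(vg + m/n1) exactly at p_threshold = 1
  for (vg in c(0.01, 0.05, 0.2, 0.5))
    for (m in c(10L, 89L, 500L))
      for (n1 in c(500L, 5000L, 50000L)) {
        mod <- avengeme_model(n1, m = m, vg = vg, pi0 = 0, p_threshold = 1)
        expect_equal(expected_r2(mod), vg^2 / (vg + m / n1),
                     tolerance = 1e-12)
      }
  # null architecture gives zero at every threshold
  for (pt in c(0.001, 0.05, 0.5, 1))
    expect_equal(expected_r2(avengeme_model(1000, m = 89, vg = 0,
                                            pi0 = 0.5, p_threshold = pt)),
                 0)
  expect_equal(expected_r2(avengeme_model(1000, m = 89, vg = 0, pi0 = 1,
                                          p_threshold = 0.5)), 0)
})

test_that("expected accuracy is monotone in signal and training size, and bounded", {
  vgs <- c(0.01, 0.05, 0.1, 0.2, 0.4)
  n1s <- c(200L, 1000L, 5000L, 20000L)
  for (pt in c(0.05, 0.5, 1)) {
    r_vg <- vapply(vgs, function(v)
      expected_r2(avengeme_model(2000, m = 89, vg = v, pi0 = 0.5,
                                 p_threshold = pt)), numeric(1))
    expect_true(all(diff(r_vg) > 0))
    r_n1 <- vapply(n1s, function(n)
      expected_r2(avengeme_model(n, m = 89, vg = 0.1, pi0 = 0.5,
                                 p_threshold = pt)), numeric(1))
    expect_true(all(diff(r_n1) > 0))
    expect_true(all(r_vg >= 0 & r_vg <= vgs + 1e-12))
  }
})

test_that("non-centrality follows n2 * rho2 / (1 - rho2)", {
  mod <- avengeme_model(5000, m = 89, vg = 0.05, pi0 = 0, p_threshold = 1)
  rho2 <- expected_r2(mod)          # Daetwyler limit ~ 0.0369
  expect_equal(expected_ncp(mod, 1000), 1000 * rho2 / (1 - rho2))
  expect_equal(expected_ncp(mod, 1000), 38.3, tolerance = 0.1)
  lam <- vapply(c(100, 1000, 10000), function(n2) expected_ncp(mod, n2),
                numeric(1))
  expect_true(all(diff(lam) > 0))
  expect_equal(expected_ncp(avengeme_model(1000, m = 10, vg = 0, pi0 = 0,
                                           p_threshold = 1)), 0)
})

test_that("maximum-likelihood inversion handles null data and boundaries", {
  obs0 <- data.frame(p_threshold = 0.5, z = 0, n1 = 5000, n2 = 5000,
                     m = 89)
  est <- estimate_vg(obs0, pi0 = 0.5)
  expect_equal(est$vg_hat, 0, tolerance = 1e-6)
  expect_equal(est$ci_low, 0)
  expect_gt(est$ci_high, 0)
  expect_identical(est$pi0_mode, "fixed")
  expect_error(estimate_vg(obs0, pi0 = "estimate"), ">= 2 thresholds")
  expect_error(estimate_vg(data.frame(p_threshold = 0.5, n1 = 1, n2 = 1,
                                      m = 1)), "z")
})

test_that("inversion recovers the generating signal from forward-model data", {
  truth <- avengeme_model(20000, 20000, 89, vg = 0.05, pi0 = 0.5,
                          p_threshold = 0.5)
  lam <- expected_ncp(truth)
  set.seed(13)
  z <- rnorm(1, sqrt(lam), 1)
  est <- estimate_vg(data.frame(p_threshold = 0.5, z = z, n1 = 20000,
                                n2 = 20000, m = 89), pi0 = 0.5)
  half <- (est$ci_high - est$ci_low) / 2
  expect_lt(abs(est$vg_hat - 0.05), 3 * half)
  expect_true(est$ci_low <= est$vg_hat && est$vg_hat <= est$ci_high)
  # r2-form input reproduces the z-form fit
  r2 <- z^2 / (20000 + z^2)
  est2 <- estimate_vg(data.frame(p_threshold = 0.5, r2 = r2, n1 = 20000,
                                 n2 = 20000, m = 89), pi0 = 0.5)
  expect_equal(est2$vg_hat, est$vg_hat, tolerance = 1e-5)
})

test_that("joint pi0 estimation works with multi-threshold data", {
  truth <- avengeme_model(50000, 50000, 89, vg = 0.1, pi0 = 0.5,
                          p_threshold = 1)
  set.seed(17)
  grid <- c(0.01, 0.1, 0.5, 1)
  obs <- data.frame(p_threshold = grid, n1 = 50000, n2 = 50000, m = 89)
  obs$z <- vapply(grid, function(pt)
    rnorm(1, sqrt(expected_ncp(avengeme_model(50000, 50000, 89, 0.1, 0.5,
                                              pt))), 1), numeric(1))
  est <- estimate_vg(obs, pi0 = "estimate")
  expect_identical(est$pi0_mode, "estimated")
  expect_lt(abs(est$vg_hat - 0.1), 0.05)
})
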