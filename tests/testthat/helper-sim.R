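# shared small-cohort fixture builders (all generated in code)

tiny_sim <- function(n = 200, m = 8, vg = 0.2, pi0 = 0.5,
                     cohort = "offspring", seed = 11L,
                     tau2 = 0.5, sigma2 = 1.0, beta_age = 0.02,
                     p_never = 0.1, p_zero = 0.15, dropout = 0.05,
                     n_pcs = 10, n_confounders = 12) {
  panel <- snp_panel(m = m, seed = seed)
  geno <- simulate_genotypes(panel, n, seed = seed + 1L)
  arch <- genetic_architecture(m, vg, pi0, seed = seed + 2L)
  eff <- simulate_effects(arch, panel)
  design <- cohort_design(cohort, n, p_never_drinker = p_never,
                          p_zero_occasion = p_zero,
                          dropout_per_occasion = dropout)
  vc <- variance_components(tau2 = tau2, sigma2 = sigma2,
                            beta_age = beta_age)
  pheno <- simulate_phenotypes(geno, eff, design, vc, seed = seed + 3L)
  covars <- simulate_covariates(n, n_pcs = n_pcs,
                                n_confounders = n_confounders,
                                seed = seed + 4L, geno = geno)
  list(panel = panel, geno = geno, effects = eff, design = design,
       vc = vc, pheno = pheno, covars = covars,
       filtered = apply_filters(pheno, filter_spec()))
}

person_dosage <- function(geno, snp) {
  stats::setNames(geno[, snp], rownames(geno))
}

# hand-built long table for filter tests
toy_pheno <- function() {
  ph <- data.frame(
    person_id = c("A", "A", "A", "B", "B", "B"),
    cohort = "mother",
    occasion = rep(c("1y", "2y", "3y"), 2),
    age = rep(c(30, 31, 32), 2),
    units = c(0, 0, 0, 0, 2, 4),
    stringsAsFactors = FALSE)
  ph$log_units <- ifelse(ph$units > 0, log(ph$units), NA_real_)
  ph
}
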