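#' Default run configuration for the end-to-end pipeline
#'
#' A compact, fully specified configuration for a single simulated cohort:
#' every stochastic stage derives from `seed`.
#'
#' @param seed Integer master seed.
#' @param cohort `"mother"` or `"offspring"`.
#' @param n_individuals Cohort size.
#' @param m Panel size.
#' @param vg Marker-explained variance fraction.
#' @param pi0 Null-marker fraction.
#' @return Nested named list understood by [run_pipeline()].
#' @export
default_run_config <- function(seed = 1L, cohort = "mother",
                               n_individuals = 600, m = 89,
                               vg = 0.10, pi0 = 0.5) {
  list(
    seed = as.integer(seed),
    cohort = list(name = cohort, n_individuals = n_individuals,
                  p_never_drinker = 0.10, p_zero_occasion = 0.15,
                  dropout_per_occasion = 0.05),
    architecture = list(m = m, vg = vg, pi0 = pi0),
    variance = list(tau2 = 0.5, sigma2 = 1.0, beta_age = 0.02,
                    intercept = 0.5),
    filters = list(exclude_occasions = NULL, exclude_flagged = NULL),
    cv = list(thresholds = c(0.01, 0.05, 0.1, 0.2, 0.4, 0.5),
              train_fraction = 0.8, repeats = 5),
    avengeme = list(pi0 = pi0),
    mrpower = list(
      list(label = "cvd_mother", odds_ratio = 0.75, r2 = 0.003),
      list(label = "cvd_offspring", odds_ratio = 0.75, r2 = 0.007),
      list(label = "chd_mother", odds_ratio = 0.71, r2 = 0.003),
      list(label = "chd_offspring", odds_ratio = 0.71, r2 = 0.007))
  )
}

validate_run_config <- function(config) {
  for (nm in c("seed", "cohort", "architecture", "variance", "cv"))
    if (is.null(config[[nm]]))
      stop("config is missing `", nm, "`", call. = FALSE)
  assert_count(config$cv$repeats, "cv$repeats")
  assert_count(config$cohort$n_individuals, "cohort$n_individuals")
  assert_scalar_number(config$cv$train_fraction, "cv$train_fraction", 0, 1,
                       open_lower = TRUE, open_upper = TRUE)
  invisible(config)
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage `%s` failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full simulate-filter-associate-score-estimate pipeline
#'
#' Executes every stage in order for one simulated cohort and writes the
#' run artifacts to `out_dir`: ranked association table (`assoc.tsv`,
#' Table-2-style columns), filter audit (`audit.json`), cross-validation
#' result (`cv.json`), final score definition (`score.tsv`, PLINK
#' `--score` layout), variance-explained estimate (`avengeme.json`),
#' MR design table (`mrpower.tsv`), the simulated panel and inputs, and a
#' `report.json` stamped with the seed and a config hash. A
#' `schemas.json` sidecar declares every table's columns. No timestamps
#' are written, so identical config + seed reproduces the directory
#' byte-for-byte.
#'
#' @param config Nested list (see [default_run_config()]) or a path to a
#'   JSON/YAML file.
#' @param out_dir Output directory (created if needed).
#' @param write_vcf Also write genotypes as VCF v4.2 (default FALSE; the
#'   wide TSV is always written).
#' @return The run report (named list), invisibly.
#' @export
run_pipeline <- function(config, out_dir, write_vcf = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  validate_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  arch_cfg <- config$architecture

  sim <- pipeline_stage("simulate", {
    panel <- snp_panel(m = arch_cfg$m, seed = seed)
    geno <- simulate_genotypes(panel, config$cohort$n_individuals,
                               seed = seed + 1L)
    arch <- genetic_architecture(arch_cfg$m, arch_cfg$vg, arch_cfg$pi0,
                                 seed = seed + 2L)
    eff <- simulate_effects(arch, panel)
    design <- cohort_design(config$cohort$name,
                            config$cohort$n_individuals,
                            p_never_drinker = config$cohort$p_never_drinker,
                            p_zero_occasion = config$cohort$p_zero_occasion,
                            dropout_per_occasion =
                              config$cohort$dropout_per_occasion)
    vc <- do.call(variance_components, config$variance)
    pheno <- simulate_phenotypes(geno, eff, design, vc, seed = seed + 3L)
    covars <- simulate_covariates(config$cohort$n_individuals,
                                  seed = seed + 4L, geno = geno)
    utils::write.table(panel, file.path(out_dir, "panel.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_genotypes_tsv(geno, file.path(out_dir, "genotypes.tsv"))
    if (write_vcf)
      write_genotypes_vcf(geno, file.path(out_dir, "genotypes.vcf"))
    write_phenotypes_csv(pheno, file.path(out_dir, "phenotypes.csv"))
    list(panel = panel, geno = geno, pheno = pheno, covars = covars)
  })

  filtered <- pipeline_stage("filter", {
    spec <- filter_spec(
      exclude_occasions = config$filters$exclude_occasions,
      exclude_flagged = config$filters$exclude_flagged)
    ph <- apply_filters(sim$pheno, spec)
    jsonlite::write_json(as.list(attr(ph, "audit")),
                         file.path(out_dir, "audit.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    ph
  })

  assoc <- pipeline_stage("assoc", {
    scan <- assoc_scan(filtered, sim$geno, sim$covars)
    tab <- data.frame(rank = scan$rank, snp = scan$target_id, n = scan$n,
                      effect_size = scan$beta, se = scan$se, t = scan$stat,
                      p_value = scan$p)
    utils::write.table(tab, file.path(out_dir, "assoc.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    scan
  })

  cv <- pipeline_stage("prs", {
    cv <- cross_validate(filtered, sim$geno, sim$covars,
                         thresholds = unlist(config$cv$thresholds),
                         train_fraction = config$cv$train_fraction,
                         repeats = config$cv$repeats, seed = seed + 5L)
    write_cv_json(cv, file.path(out_dir, "cv.json"))
    write_score_tsv(cv$final_score, file.path(out_dir, "score.tsv"))
    cv
  })

  avg <- pipeline_stage("avengeme", {
    best <- cv$best_threshold
    obs <- data.frame(p_threshold = best,
                      r2 = max(cv$mean_r2[as.character(best)], 1e-8),
                      n1 = cv$n_train_persons, n2 = cv$n_test_persons,
                      m = arch_cfg$m)
    est <- estimate_vg(obs, pi0 = config$avengeme$pi0)
    jsonlite::write_json(unclass(est), file.path(out_dir, "avengeme.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    est
  })

  mrp <- pipeline_stage("mrpower", {
    rows <- lapply(config$mrpower, function(q) {
      req <- required_n_binary(power_query(q$odds_ratio, q$r2))
      data.frame(label = q$label, odds_ratio = q$odds_ratio, r2 = q$r2,
                 n_raw = req$n_raw, n_reported = req$n_reported)
    })
    tab <- do.call(rbind, rows)
    utils::write.table(tab, file.path(out_dir, "mrpower.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    tab
  })

  schemas <- list(
    panel.tsv = names(sim$panel),
    genotypes.tsv = c("person_id", colnames(sim$geno)),
    phenotypes.csv = c("person_id", "cohort", "occasion", "age", "units",
                       "pregnant"),
    assoc.tsv = c("rank", "snp", "n", "effect_size", "se", "t", "p_value"),
    score.tsv = names(cv$final_score$entries),
    mrpower.tsv = names(mrp))
  jsonlite::write_json(schemas, file.path(out_dir, "schemas.json"),
                       auto_unbox = FALSE, pretty = TRUE)

  report <- list(
    seed = seed,
    config_hash = config_hash(config),
    cohort = config$cohort$name,
    n_individuals = config$cohort$n_individuals,
    records_analysed = nrow(filtered),
    audit = as.list(attr(filtered, "audit")),
    bonferroni_repeated = bonferroni_threshold(0.05, arch_cfg$m),
    top_snp = assoc$target_id[1],
    top_beta = assoc$beta[1],
    top_p = assoc$p[1],
    best_threshold = cv$best_threshold,
    n_snps_in_score = nrow(cv$final_score$entries),
    mean_r2_best = unname(cv$mean_r2[as.character(cv$best_threshold)]),
    vg_hat = avg$vg_hat, vg_ci = c(avg$ci_low, avg$ci_high))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
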