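#' Construct a candidate SNP panel
#'
#' Builds the metadata table for a curated candidate panel of independent
#' markers, the kind assembled from published GWAS hits and functional
#' literature on alcohol metabolism. The default panel size is 89 with 58
#' imputed markers (dosages in `[0, 2]`) and 31 directly genotyped ones,
#' mirroring the composition of the panel the package emulates.
#'
#' @param m Number of markers (default 89).
#' @param maf_range Range from which minor allele frequencies are drawn
#'   uniformly; must lie within (0, 0.5].
#' @param prop_imputed Fraction of markers flagged imputed (default 58/89).
#' @param prop_gwas Fraction of markers sourced from GWAS catalogue hits
#'   rather than functional studies.
#' @param seed Integer seed.
#' @return A `data.frame` with columns `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `maf`, `imputed`, `source`.
#' @export
#' @examples
#' panel <- snp_panel(m = 10, seed = 1)
snp_panel <- function(m = 89, maf_range = c(0.05, 0.5),
                      prop_imputed = 58 / 89, prop_gwas = 66 / 89,
                      seed = 1L) {
  assert_count(m, "m")
  assert_scalar_number(maf_range[1], "maf_range[1]", 0, 0.5, open_lower = TRUE)
  assert_scalar_number(maf_range[2], "maf_range[2]", maf_range[1], 0.5)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ea <- sample(bases, m, replace = TRUE)
  oa <- vapply(ea, function(b) sample(setdiff(bases, b), 1L), character(1))
  n_imp <- round(m * prop_imputed)
  imputed <- rep(FALSE, m)
  imputed[sample.int(m, n_imp)] <- TRUE
  src <- rep("functional", m)
  src[sample.int(m, round(m * prop_gwas))] <- "gwas"
  panel <- data.frame(
    snp_id = sprintf("snp_%03d", seq_len(m)),
    chrom = as.character(sample(1:22, m, replace = TRUE)),
    pos = sort(sample.int(2.5e8, m)),
    effect_allele = ea,
    other_allele = unname(oa),
    maf = stats::runif(m, maf_range[1], maf_range[2]),
    imputed = imputed,
    source = src,
    stringsAsFactors = FALSE
  )
  validate_snp_panel(panel)
  panel
}

validate_snp_panel <- function(panel) {
  stopifnot(is.data.frame(panel), nrow(panel) >= 1)
  req <- c("snp_id", "effect_allele", "other_allele", "maf", "imputed")
  miss <- setdiff(req, names(panel))
  if (length(miss))
    stop("panel is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(panel$snp_id))
    stop("panel snp_ids must be unique", call. = FALSE)
  if (any(panel$maf <= 0 | panel$maf > 0.5))
    stop("panel maf must lie in (0, 0.5]", call. = FALSE)
  invisible(panel)
}

#' Describe a sparse genetic architecture
#'
#' @param m Number of markers.
#' @param vg Total fraction of (unit-variance) trait variance jointly
#'   explained by the markers; `0 <= vg < 1`.
#' @param pi0 Fraction of truly null markers; `pi0 = 1` forces `vg = 0`.
#' @param seed Integer seed used when effects are drawn.
#' @return A list of class `genetic_architecture`.
#' @export
genetic_architecture <- function(m = 89, vg = 0.05, pi0 = 0.5, seed = 1L) {
  assert_count(m, "m")
  assert_scalar_number(vg, "vg", 0, 1, open_upper = TRUE)
  assert_scalar_number(pi0, "pi0", 0, 1)
  if (pi0 == 1 && vg > 0)
    stop("pi0 = 1 (all markers null) is incompatible with vg > 0",
         call. = FALSE)
  structure(list(m = as.integer(m), vg = vg, pi0 = pi0,
                 seed = as.integer(seed)),
            class = "genetic_architecture")
}

#' Cohort measurement design
#'
#' Occasion schedules default to the emulated study: mothers answer 10
#' questionnaires from mean age 28 to 48; offspring report at 5 occasions
#' from age 15 to 21. Weekly units are zero-inflated at two levels: a
#' fraction of persons never drink, and any remaining occasion can record
#' zero units (no drinking that week).
#'
#' @param cohort `"mother"` or `"offspring"`.
#' @param n_individuals Cohort size.
#' @param occasions `data.frame` with columns `label`, `mean_age`, `sd_age`;
#'   `NULL` selects the cohort default schedule.
#' @param p_never_drinker Fraction of persons who never report drinking.
#' @param p_zero_occasion Probability an ever-drinker's occasion records 0
#'   units.
#' @param dropout_per_occasion Per-occasion monotone dropout hazard.
#' @return A list of class `cohort_design`.
#' @export
cohort_design <- function(cohort = c("mother", "offspring"),
                          n_individuals = 1000,
                          occasions = NULL,
                          p_never_drinker = 0.10,
                          p_zero_occasion = 0.15,
                          dropout_per_occasion = 0.05) {
  cohort <- match.arg(cohort)
  assert_count(n_individuals, "n_individuals")
  for (nm in c("p_never_drinker", "p_zero_occasion", "dropout_per_occasion"))
    assert_scalar_number(get(nm), nm, 0, 1)
  if (is.null(occasions)) {
    occasions <- if (cohort == "mother") {
      data.frame(
        label = c("0y", "1y", "2y", "3y", "4y", "6y", "7y", "8y",
                  "12y", "18y"),
        mean_age = c(28.2, 29.5, 30.7, 32.9, 34.0, 34.2, 36.3, 37.5,
                     41.5, 48.3),
        sd_age = c(4.8, 4.7, 4.6, 4.5, 4.5, 4.5, 4.5, 4.4, 4.4, 4.3),
        stringsAsFactors = FALSE
      )
    } else {
      data.frame(
        label = c("15y", "16y", "17y", "18y", "21y"),
        mean_age = c(15.1, 16.2, 17.2, 18.2, 20.5),
        sd_age = c(0.3, 0.4, 0.4, 0.6, 0.5),
        stringsAsFactors = FALSE
      )
    }
  }
  stopifnot(is.data.frame(occasions),
            all(c("label", "mean_age", "sd_age") %in% names(occasions)))
  if (anyDuplicated(occasions$label))
    stop("occasion labels must be unique", call. = FALSE)
  if (any(occasions$mean_age <= 0)) stop("ages must be positive", call. = FALSE)
  structure(list(cohort = cohort,
                 n_individuals = as.integer(n_individuals),
                 occasions = occasions,
                 p_never_drinker = p_never_drinker,
                 p_zero_occasion = p_zero_occasion,
                 dropout_per_occasion = dropout_per_occasion),
            class = "cohort_design")
}

#' Variance components of the longitudinal log-units model
#'
#' Natural-log scale throughout: the phenotype model is
#' `log(units)_it = intercept + beta_age * age_it + G_i + u_i + e_it`
#' with person random intercept `u_i ~ N(0, tau2)` and occasion residual
#' `e_it ~ N(0, sigma2)`.
#'
#' @param tau2 Person random-intercept variance (log-units squared).
#' @param sigma2 Occasion residual variance (log-units squared); must be
#'   positive.
#' @param beta_age Fixed age effect, log-units per year.
#' @param intercept Fixed intercept, log-units.
#' @return A list of class `variance_components`.
#' @export
variance_components <- function(tau2 = 0.5, sigma2 = 1.0,
                                beta_age = 0.02, intercept = 0.5) {
  assert_scalar_number(tau2, "tau2", 0)
  assert_scalar_number(sigma2, "sigma2", 0, open_lower = TRUE)
  structure(list(tau2 = tau2, sigma2 = sigma2, beta_age = beta_age,
                 intercept = intercept),
            class = "variance_components")
}

#' Simulate a genotype dosage matrix
#'
#' Directly genotyped markers are hard calls in `{0, 1, 2}` drawn
#' `Binomial(2, maf)` (Hardy-Weinberg equilibrium); imputed markers carry
#' continuous dosages in `[0, 2]` with the same mean `2 * maf` (a scaled
#' Beta draw whose spread emulates imputation uncertainty). Markers are
#' mutually independent (no linkage disequilibrium), appropriate for a
#' curated candidate panel.
#'
#' @param panel SNP panel `data.frame` (see [snp_panel()]).
#' @param n Number of individuals.
#' @param seed Integer seed.
#' @return An `n x m` numeric matrix, rows named `P000001...`, columns by
#'   `snp_id`, with the panel attached as attribute `"panel"`.
#' @export
#' @examples
#' g <- simulate_genotypes(snp_panel(m = 5, seed = 1), n = 20, seed = 2)
simulate_genotypes <- function(panel, n, seed = 1L) {
  assert_count(n, "n")
  if (!is.data.frame(panel) || nrow(panel) < 1)
    stop("panel must be a non-empty data.frame", call. = FALSE)
  if (any(panel$maf < 0 | panel$maf > 0.5))
    stop("maf must lie in [0, 0.5]", call. = FALSE)
  set.seed(seed)
  m <- nrow(panel)
  geno <- matrix(0, n, m, dimnames = list(sprintf("P%06d", seq_len(n)),
                                          panel$snp_id))
  for (j in seq_len(m)) {
    maf <- panel$maf[j]
    if (isTRUE(panel$imputed[j]) && maf > 0) {
      # concentration chosen so Var(d) ~ 0.9 * 2 maf (1-maf), i.e. r2 ~ 0.9
      kappa <- 2 / 0.9 - 1
      geno[, j] <- 2 * stats::rbeta(n, maf * kappa, (1 - maf) * kappa)
    } else {
      geno[, j] <- stats::rbinom(n, 2L, maf)
    }
  }
  attr(geno, "panel") <- panel
  geno
}

#' Draw sparse per-SNP effects
#'
#' Exactly `round(m * pi0)` markers (chosen uniformly at random) are null.
#' Non-null effects are drawn `N(0, vg / (m * (1 - pi0)))` on the
#' standardized-genotype scale, so the drawn effects jointly explain `vg`
#' of a unit-variance trait in expectation. Dosage-scale effects
#' (per copy of the effect allele) are
#' `beta_std / sqrt(2 * maf * (1 - maf))`.
#'
#' @param arch A [genetic_architecture()].
#' @param panel The SNP panel (supplies `m` consistency check and MAFs).
#' @return `data.frame` with `snp_id`, `beta_std`, `beta_dosage`, `is_null`.
#' @export
simulate_effects <- function(arch, panel) {
  stopifnot(inherits(arch, "genetic_architecture"))
  validate_snp_panel(panel)
  m <- nrow(panel)
  if (m != arch$m)
    stop("panel size and architecture m disagree", call. = FALSE)
  set.seed(arch$seed)
  n_null <- round(m * arch$pi0)
  beta_std <- numeric(m)
  if (n_null < m) {
    idx_null <- sample.int(m, n_null)
    nonnull <- setdiff(seq_len(m), idx_null)
    beta_std[nonnull] <- stats::rnorm(length(nonnull), 0,
                                      sqrt(arch$vg / (m * (1 - arch$pi0))))
  }
  data.frame(
    snp_id = panel$snp_id,
    beta_std = beta_std,
    beta_dosage = beta_std / sqrt(2 * panel$maf * (1 - panel$maf)),
    is_null = beta_std == 0,
    stringsAsFactors = FALSE
  )
}

#' Simulate longitudinal zero-inflated weekly alcohol units
#'
#' Generates the long-format repeated-measures table the association stage
#' consumes. On the natural-log scale each retained occasion follows the
#' linear mixed model described in [variance_components()], with the
#' aggregate genetic value computed from standardized genotypes and
#' standardized-scale effects. Zero inflation: never-drinkers have all
#' occasions zeroed; each remaining occasion is independently zeroed with
#' probability `p_zero_occasion`. Dropout is monotone with per-occasion
#' hazard `dropout_per_occasion`. Mothers additionally carry a `pregnant`
#' occasion flag (rate `p_flag`) used by sensitivity filters.
#'
#' @param geno Genotype matrix from [simulate_genotypes()]; rows must match
#'   `design$n_individuals`.
#' @param effects Effect table from [simulate_effects()].
#' @param design A [cohort_design()].
#' @param vc A [variance_components()].
#' @param seed Integer seed.
#' @param p_flag Occasion-level rate of the `pregnant` flag (mothers only).
#' @return Long `data.frame`: `person_id`, `cohort`, `occasion`, `age`,
#'   `units`, `log_units` (`NA` where `units == 0`), `pregnant`. Attributes
#'   `genetic_value` (named per-person vector) and `never_drinker` carry
#'   the simulation truth for validation.
#' @export
simulate_phenotypes <- function(geno, effects, design, vc, seed = 1L,
                                p_flag = if (design$cohort == "mother") 0.03 else 0) {
  stopifnot(inherits(design, "cohort_design"),
            inherits(vc, "variance_components"))
  n <- design$n_individuals
  if (nrow(geno) != n)
    stop("geno has ", nrow(geno), " rows but design expects ", n,
         call. = FALSE)
  panel <- attr(geno, "panel")
  if (is.null(panel)) stop("geno lacks a panel attribute", call. = FALSE)
  if (!identical(colnames(geno), effects$snp_id))
    stop("effects and genotype columns disagree", call. = FALSE)
  set.seed(seed)

  # aggregate genetic value on standardized-genotype scale
  sdg <- sqrt(2 * panel$maf * (1 - panel$maf))
  sdg[sdg == 0] <- 1
  gs <- sweep(sweep(geno, 2, 2 * panel$maf), 2, sdg, "/")
  gval <- drop(gs %*% effects$beta_std)
  names(gval) <- rownames(geno)

  occ <- design$occasions
  n_occ <- nrow(occ)
  u <- stats::rnorm(n, 0, sqrt(vc$tau2))
  age_offset <- stats::rnorm(n, 0, 1)  # person-level age deviation, scaled below
  never <- stats::runif(n) < design$p_never_drinker

  # monotone dropout: person observed through occasion K_i
  keep_through <- rep(n_occ, n)
  if (design$dropout_per_occasion > 0 && n_occ > 1) {
    for (i in seq_len(n)) {
      drops <- stats::runif(n_occ - 1) < design$dropout_per_occasion
      keep_through[i] <- if (any(drops)) which(drops)[1] else n_occ
    }
  }

  rows <- vector("list", n_occ)
  for (t in seq_len(n_occ)) {
    present <- which(keep_through >= t)
    age <- occ$mean_age[t] + occ$sd_age[t] * age_offset[present]
    e <- stats::rnorm(length(present), 0, sqrt(vc$sigma2))
    logu <- vc$intercept + vc$beta_age * age + gval[present] +
      u[present] + e
    units <- exp(logu)
    zero <- never[present] |
      (stats::runif(length(present)) < design$p_zero_occasion)
    units[zero] <- 0
    rows[[t]] <- data.frame(
      person_id = rownames(geno)[present],
      cohort = design$cohort,
      occasion = occ$label[t],
      age = age,
      units = units,
      pregnant = if (p_flag > 0)
        stats::runif(length(present)) < p_flag else FALSE,
      stringsAsFactors = FALSE
    )
  }
  pheno <- do.call(rbind, rows)
  pheno <- pheno[order(match(pheno$person_id, rownames(geno)),
                       match(pheno$occasion, occ$label)), ]
  rownames(pheno) <- NULL
  pheno$log_units <- ifelse(pheno$units > 0, log(pheno$units), NA_real_)
  attr(pheno, "genetic_value") <- gval
  attr(pheno, "never_drinker") <- stats::setNames(never, rownames(geno))
  attr(pheno, "occasions") <- occ$label
  pheno
}

#' Simulate principal-component and confounder covariates
#'
#' PCs are independent standard normals (orthogonal in expectation),
#' emulating ancestry principal components in a homogeneous sample. The
#' confounder panel mixes continuous and binary variables generated
#' independently of genotype, so the pleiotropy screen is null by
#' construction. A single confounder can be injected with a given
#' correlation to a named SNP as a positive control.
#'
#' @param n Number of individuals.
#' @param n_pcs Number of PC columns (default 10).
#' @param n_confounders Number of confounder columns (default 48).
#' @param seed Integer seed.
#' @param geno Optional genotype matrix, required for `inject`.
#' @param inject Optional `list(snp = <snp_id>, rho = <correlation>,
#'   confounder = <index>)` making one continuous confounder correlated
#'   with a SNP.
#' @return `data.frame` with `person_id`, `PC1..`, `conf_01..`; binary
#'   confounders are 0/1 integers.
#' @export
simulate_covariates <- function(n, n_pcs = 10, n_confounders = 48,
                                seed = 1L, geno = NULL, inject = NULL) {
  assert_count(n, "n")
  assert_count(n_pcs, "n_pcs", min = 0L)
  assert_count(n_confounders, "n_confounders", min = 0L)
  set.seed(seed)
  ids <- if (!is.null(geno)) rownames(geno) else sprintf("P%06d", seq_len(n))
  out <- data.frame(person_id = ids, stringsAsFactors = FALSE)
  for (k in seq_len(n_pcs)) out[[paste0("PC", k)]] <- stats::rnorm(n)
  is_binary <- rep(c(FALSE, TRUE), length.out = n_confounders)
  for (k in seq_len(n_confounders)) {
    nm <- sprintf("conf_%02d", k)
    out[[nm]] <- if (is_binary[k])
      stats::rbinom(n, 1L, stats::runif(1, 0.1, 0.5)) else stats::rnorm(n)
  }
  if (!is.null(inject)) {
    if (is.null(geno)) stop("inject requires geno", call. = FALSE)
    stopifnot(inject$snp %in% colnames(geno))
    rho <- inject$rho
    assert_scalar_number(rho, "inject$rho", -1, 1)
    idx <- if (!is.null(inject$confounder)) inject$confounder else
      which(!is_binary)[1]
    g <- geno[, inject$snp]
    gz <- (g - mean(g)) / stats::sd(g)
    out[[sprintf("conf_%02d", idx)]] <-
      rho * gz + sqrt(1 - rho^2) * stats::rnorm(n)
    attr(out, "injected") <- list(snp = inject$snp,
                                  confounder = sprintf("conf_%02d", idx),
                                  rho = rho)
  }
  attr(out, "pc_cols") <- paste0("PC", seq_len(n_pcs))
  attr(out, "confounder_cols") <- sprintf("conf_%02d", seq_len(n_confounders))
  out
}
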