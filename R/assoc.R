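#' Specify record filters for the analysis sample
#'
#' @param drop_never_drinkers Remove persons whose units are zero at every
#'   observed occasion.
#' @param drop_zero_occasions Remove occasion records with zero units
#'   (log undefined).
#' @param exclude_occasions Character vector of occasion labels to drop
#'   (sensitivity analyses).
#' @param exclude_flagged Name of a logical record column (e.g.
#'   `"pregnant"`); flagged records are dropped.
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(drop_never_drinkers = TRUE,
                        drop_zero_occasions = TRUE,
                        exclude_occasions = NULL,
                        exclude_flagged = NULL) {
  structure(list(drop_never_drinkers = isTRUE(drop_never_drinkers),
                 drop_zero_occasions = isTRUE(drop_zero_occasions),
                 exclude_occasions = exclude_occasions,
                 exclude_flagged = exclude_flagged),
            class = "filter_spec")
}

#' Filter a longitudinal phenotype table to the analysis sample
#'
#' Log-linear analyses of weekly units are restricted to ever-drinkers,
#' and occasions reporting zero units are dropped record-wise because
#' `log(0)` is undefined. Sensitivity analyses can additionally exclude
#' whole occasions or flagged records. An audit of removed persons/records
#' is attached so the filtering is fully reconstructible.
#'
#' @param pheno Long phenotype table (see [simulate_phenotypes()]).
#' @param spec A [filter_spec()].
#' @return The filtered table, with attribute `"audit"` (named counts).
#' @export
#' @examples
#' ph <- data.frame(person_id = c("A","A","B","B","B"),
#'                  occasion = c("1y","2y","1y","2y","3y"),
#'                  units = c(0, 0, 0, 2, 4))
#' ph$log_units <- ifelse(ph$units > 0, log(ph$units), NA)
#' apply_filters(ph, filter_spec())
apply_filters <- function(pheno, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"), is.data.frame(pheno))
  audit <- c(never_drinker_persons = 0L, zero_unit_records = 0L,
             excluded_occasion_records = 0L, flagged_records = 0L)
  out <- pheno
  if (!is.null(spec$exclude_occasions)) {
    unknown <- setdiff(spec$exclude_occasions, unique(pheno$occasion))
    if (length(unknown))
      stop("unknown occasion label(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    drop <- out$occasion %in% spec$exclude_occasions
    audit["excluded_occasion_records"] <- sum(drop)
    out <- out[!drop, ]
  }
  if (!is.null(spec$exclude_flagged)) {
    if (!spec$exclude_flagged %in% names(out))
      stop("no such flag column: ", spec$exclude_flagged, call. = FALSE)
    drop <- isTRUE_vec(out[[spec$exclude_flagged]])
    audit["flagged_records"] <- sum(drop)
    out <- out[!drop, ]
  }
  if (spec$drop_never_drinkers) {
    tot <- tapply(out$units, out$person_id, function(u) sum(u > 0))
    never <- names(tot)[tot == 0]
    audit["never_drinker_persons"] <- length(never)
    out <- out[!out$person_id %in% never, ]
  }
  if (spec$drop_zero_occasions) {
    drop <- out$units == 0
    audit["zero_unit_records"] <- sum(drop)
    out <- out[!drop, ]
  }
  rownames(out) <- NULL
  attr(out, "audit") <- audit
  attr(out, "genetic_value") <- attr(pheno, "genetic_value")
  attr(out, "occasions") <- attr(pheno, "occasions")
  out
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

assoc_row <- function(target_id, fit_coef, n, n_persons, kind,
                      occasion = NA_character_, converged = TRUE) {
  beta <- fit_coef[1]; se <- fit_coef[2]
  stat <- beta / se
  data.frame(target_id = target_id, beta = unname(beta), se = unname(se),
             stat = unname(stat), p = 2 * stats::pnorm(-abs(unname(stat))),
             n = n, n_persons = n_persons, kind = kind, occasion = occasion,
             converged = converged, stringsAsFactors = FALSE)
}

build_assoc_data <- function(pheno, dosage, covars, adjust_age) {
  d <- pheno[is.finite(pheno$log_units), , drop = FALSE]
  if (is.null(names(dosage)))
    stop("dosage must be a named per-person vector", call. = FALSE)
  d$dosage <- dosage[d$person_id]
  if (anyNA(d$dosage)) d <- d[!is.na(d$dosage), , drop = FALSE]
  pc_cols <- character(0)
  if (!is.null(covars)) {
    pc_cols <- grep("^PC[0-9]+$", names(covars), value = TRUE)
    if (length(pc_cols)) {
      idx <- match(d$person_id, covars$person_id)
      for (pc in pc_cols) d[[pc]] <- covars[[pc]][idx]
    }
  }
  list(data = d, pc_cols = pc_cols,
       rhs = paste(c("dosage", if (adjust_age) "age", pc_cols),
                   collapse = " + "))
}

#' Repeated-measures SNP association via a linear mixed model
#'
#' Fits `log_units ~ dosage + age + PC1..PCk + (1 | person_id)` by REML
#' (lme4) on the filtered analysis sample and returns the Wald test of the
#' dosage term: the effect is log units of alcohol per copy of the effect
#' (minor) allele. Non-convergence triggers one maximum-likelihood refit;
#' a still-unconverged fit is returned flagged rather than as silent NaN.
#'
#' @param pheno Filtered long phenotype table.
#' @param dosage Named per-person dosage vector (names = person ids).
#' @param covars Optional covariate table with `person_id` and `PC*`
#'   columns.
#' @param target_id Label for the result row.
#' @param adjust_age Include age as a fixed effect (default TRUE).
#' @param control `lme4::lmerControl()`; the default skips the costly
#'   finite-difference derivative check, which matters when scanning a
#'   whole panel.
#' @return One-row `data.frame` (beta, se, stat, p, n, n_persons, kind,
#'   occasion, converged).
#' @export
fit_repeated <- function(pheno, dosage, covars = NULL,
                         target_id = "snp", adjust_age = TRUE,
                         control = lme4::lmerControl(calc.derivs = FALSE)) {
  prep <- build_assoc_data(pheno, dosage, covars, adjust_age)
  d <- prep$data
  if (stats::var(d$dosage) < 1e-12)
    stop("monomorphic target: dosage has zero variance in the analysis sample",
         call. = FALSE)
  form <- stats::as.formula(paste("log_units ~", prep$rhs, "+ (1 | person_id)"))
  converged <- TRUE
  fit <- withCallingHandlers(
    tryCatch(lme4::lmer(form, data = d, REML = TRUE, control = control),
             error = function(e) e),
    warning = function(w) {
      converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  if (inherits(fit, "error") || !converged) {
    converged <- TRUE
    fit2 <- withCallingHandlers(
      tryCatch(lme4::lmer(form, data = d, REML = FALSE, control = control),
               error = function(e) e),
      warning = function(w) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      })
    if (!inherits(fit2, "error")) fit <- fit2
  }
  if (inherits(fit, "error"))
    return(assoc_row(target_id, c(NA_real_, NA_real_), nrow(d),
                     length(unique(d$person_id)), "repeated",
                     converged = FALSE))
  co <- summary(fit)$coefficients["dosage", c("Estimate", "Std. Error")]
  assoc_row(target_id, co, nrow(d), length(unique(d$person_id)),
            "repeated", converged = converged)
}

#' Cross-sectional SNP association at one occasion
#'
#' Ordinary least squares of log units on dosage (+ age + PCs) among
#' drinkers at a single occasion.
#'
#' @inheritParams fit_repeated
#' @param occasion Occasion label to analyse.
#' @return One-row `data.frame` as in [fit_repeated()] with
#'   `kind = "cross_sectional"`.
#' @export
fit_cross_sectional <- function(pheno, occasion, dosage, covars = NULL,
                                target_id = "snp", adjust_age = TRUE) {
  if (!occasion %in% unique(pheno$occasion))
    stop("occasion not present: ", occasion, call. = FALSE)
  prep <- build_assoc_data(pheno[pheno$occasion == occasion, , drop = FALSE],
                           dosage, covars, adjust_age)
  d <- prep$data
  n_par <- 2L + as.integer(adjust_age) + length(prep$pc_cols)
  if (nrow(d) <= n_par)
    stop("under-determined: ", nrow(d), " records for ", n_par,
         " parameters at occasion ", occasion, call. = FALSE)
  if (stats::var(d$dosage) < 1e-12)
    stop("monomorphic target: dosage has zero variance in the analysis sample",
         call. = FALSE)
  fit <- stats::lm(stats::as.formula(paste("log_units ~", prep$rhs)), data = d)
  co <- summary(fit)$coefficients["dosage", c("Estimate", "Std. Error")]
  assoc_row(target_id, co, nrow(d), length(unique(d$person_id)),
            "cross_sectional", occasion = occasion)
}

#' Scan every SNP in a genotype matrix
#'
#' Applies [fit_repeated()] (or [fit_cross_sectional()] per occasion) to
#' each marker and returns the stacked association table, ranked by
#' p-value.
#'
#' @param pheno Filtered long phenotype table.
#' @param geno Genotype dosage matrix.
#' @param covars Optional covariate table.
#' @param kind `"repeated"` or `"cross_sectional"`.
#' @param occasions Occasion labels for cross-sectional scans (default:
#'   all in `pheno`).
#' @param ... Passed to the per-SNP fitter.
#' @return `data.frame` of association rows plus a `rank` column.
#' @export
assoc_scan <- function(pheno, geno, covars = NULL,
                       kind = c("repeated", "cross_sectional"),
                       occasions = NULL, ...) {
  kind <- match.arg(kind)
  snps <- colnames(geno)
  res <- list()
  for (s in snps) {
    dos <- stats::setNames(geno[, s], rownames(geno))
    if (kind == "repeated") {
      res[[length(res) + 1L]] <-
        fit_repeated(pheno, dos, covars, target_id = s, ...)
    } else {
      occs <- if (is.null(occasions)) unique(pheno$occasion) else occasions
      for (o in occs)
        res[[length(res) + 1L]] <-
          fit_cross_sectional(pheno, o, dos, covars, target_id = s, ...)
    }
  }
  out <- do.call(rbind, res)
  out <- out[order(out$p), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Bonferroni-corrected significance threshold
#'
#' For a candidate panel of `n_snps` markers tested at `n_occasions` time
#' points the family-wise threshold is `alpha / (n_snps * n_occasions)`.
#' With `alpha = 0.05` and 89 markers this is 0.00056 (repeated measures);
#' across 15 time points it is 0.000037. Use [format_p()] for the
#' two-significant-figure report form.
#'
#' @param alpha Family-wise error rate.
#' @param n_snps Number of markers tested.
#' @param n_occasions Number of time points (1 for repeated-measures).
#' @return The corrected threshold (full precision).
#' @export
#' @examples
#' format_p(bonferroni_threshold(0.05, 89))
#' format_p(bonferroni_threshold(0.05, 89, 15))
bonferroni_threshold <- function(alpha, n_snps, n_occasions = 1) {
  assert_scalar_number(alpha, "alpha", 0, 1, open_lower = TRUE)
  assert_count(n_snps, "n_snps")
  assert_count(n_occasions, "n_occasions")
  alpha / (n_snps * n_occasions)
}

#' Screen instruments against candidate confounders or outcomes
#'
#' For each instrument (SNP dosage or polygenic score) and each screen
#' variable, fits a linear model (continuous variable) or logistic
#' regression (binary variable) of the variable on the instrument,
#' optionally adjusting for age. Pairs are judged against a Bonferroni
#' threshold over all instrument-by-variable tests (configurable via
#' `n_tests`). Evidence of association between an instrument and a
#' pre-exposure confounder signals pleiotropy, which would invalidate the
#' instrument for Mendelian randomisation; the same operation with
#' `kind = "outcome"` serves score-on-risk-factor regressions.
#'
#' @param instruments Named list or n-by-k matrix/data.frame of per-person
#'   instrument values (rownames = person ids), or a single named vector.
#' @param screen_vars `data.frame` with `person_id` and the variables to
#'   screen.
#' @param vars Columns of `screen_vars` to use (default: its
#'   `confounder_cols` attribute, else every non-id, non-PC column).
#' @param age Optional named per-person age vector to adjust for.
#' @param alpha Family-wise error rate for the verdict (default 0.05).
#' @param n_tests Number of tests for the Bonferroni verdict; default the
#'   number of instrument-variable pairs.
#' @param kind Result label, `"covariate_screen"` or `"outcome"`.
#' @return `data.frame` with one row per pair: `target_id`, `variable`,
#'   `model`, `beta`, `se`, `stat`, `p`, `pass_bonferroni`; the corrected
#'   threshold is attached as attribute `"threshold"`.
#' @export
pleiotropy_screen <- function(instruments, screen_vars, vars = NULL,
                              age = NULL, alpha = 0.05, n_tests = NULL,
                              kind = c("covariate_screen", "outcome")) {
  kind <- match.arg(kind)
  if (is.numeric(instruments) && is.null(dim(instruments)))
    instruments <- matrix(instruments, ncol = 1,
                          dimnames = list(names(instruments), "score"))
  inst <- as.matrix(instruments)
  if (is.null(vars)) {
    vars <- attr(screen_vars, "confounder_cols")
    if (is.null(vars))
      vars <- setdiff(names(screen_vars),
                      c("person_id", grep("^PC[0-9]+$", names(screen_vars),
                                          value = TRUE)))
  }
  idx <- match(rownames(inst), screen_vars$person_id)
  if (anyNA(idx)) stop("instrument persons missing from screen_vars",
                       call. = FALSE)
  if (is.null(n_tests)) n_tests <- ncol(inst) * length(vars)
  thr <- alpha / n_tests
  out <- vector("list", ncol(inst) * length(vars))
  k <- 0L
  for (j in seq_len(ncol(inst))) {
    x <- inst[, j]
    for (v in vars) {
      y <- screen_vars[[v]][idx]
      uy <- unique(y[!is.na(y)])
      if (length(uy) < 2)
        stop("constant screen variable: ", v, call. = FALSE)
      binary <- length(uy) == 2
      df <- data.frame(y = y, x = x)
      if (!is.null(age)) df$age <- age[rownames(inst)]
      form <- if (is.null(age)) y ~ x else y ~ x + age
      fit <- if (binary)
        stats::glm(form, data = df, family = stats::binomial())
      else stats::lm(form, data = df)
      co <- summary(fit)$coefficients["x", 1:2]
      k <- k + 1L
      out[[k]] <- data.frame(
        target_id = colnames(inst)[j], variable = v,
        model = if (binary) "logistic" else "linear",
        beta = unname(co[1]), se = unname(co[2]),
        stat = unname(co[1] / co[2]),
        p = 2 * stats::pnorm(-abs(unname(co[1] / co[2]))),
        kind = kind, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res$pass_bonferroni <- res$p < thr
  attr(res, "threshold") <- thr
  attr(res, "threshold_reported") <- format_p(thr)
  res
}

#' Convert a log-scale effect to a percent change in units
#'
#' A coefficient `beta` on natural-log units corresponds to a
#' multiplicative change `exp(beta)` in weekly units per allele:
#' `beta = -0.177` is 16.2% fewer units per week.
#'
#' @param beta Numeric vector of log-units effects.
#' @return `data.frame` with `beta`, `percent` (non-negative magnitude,
#'   `100 * (1 - exp(beta))` for negative effects, `100 * (exp(beta) - 1)`
#'   for positive) and `direction` (`"fewer"`/`"more"`).
#' @export
#' @examples
#' percent_change(-0.177)
percent_change <- function(beta) {
  stopifnot(is.numeric(beta))
  data.frame(
    beta = beta,
    percent = ifelse(beta <= 0, 100 * (1 - exp(beta)), 100 * (exp(beta) - 1)),
    direction = ifelse(beta <= 0, "fewer", "more"),
    stringsAsFactors = FALSE
  )
}

#' @rdname percent_change
#' @param digits Decimal places in the formatted report.
#' @return `format_percent_change`: character, e.g. `"16.2% fewer"`.
#' @export
format_percent_change <- function(beta, digits = 1) {
  pc <- percent_change(beta)
  sprintf("%.*f%% %s", digits, pc$percent, pc$direction)
}
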