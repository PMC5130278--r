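#' Build a weighted polygenic risk score at a p-value threshold
#'
#' `score_i = sum over {j : p_j <= threshold} of beta_j * g_ij`, with
#' weights taken from the training-sample association table. An empty
#' selection yields all-zero scores with attribute `"empty" = TRUE`.
#'
#' @param geno Genotype dosage matrix (persons to score).
#' @param training_results Association table with `target_id`, `beta`,
#'   `p` covering the panel.
#' @param threshold Inclusion p-value cut-off in (0, 1].
#' @return Named numeric vector of per-person scores; attribute
#'   `"definition"` carries the [score definition][cross_validate]
#'   (`threshold`, `entries`, `training_meta`).
#' @export
#' @examples
#' g <- matrix(c(2, 1, 0), 1, dimnames = list("P1", c("a", "b", "c")))
#' tr <- data.frame(target_id = c("a", "b", "c"),
#'                  beta = c(0.2, -0.1, 0.05), p = c(0.001, 0.03, 0.2))
#' build_score(g, tr, 0.05)  # 2*0.2 + 1*(-0.1) = 0.30
build_score <- function(geno, training_results, threshold) {
  assert_scalar_number(threshold, "threshold", 0, 1, open_lower = TRUE)
  tr <- training_results[training_results$target_id %in% colnames(geno), ,
                         drop = FALSE]
  sel <- tr[!is.na(tr$p) & tr$p <= threshold & is.finite(tr$beta), ,
            drop = FALSE]
  panel <- attr(geno, "panel")
  entries <- data.frame(
    snp_id = sel$target_id,
    effect_allele = if (!is.null(panel))
      panel$effect_allele[match(sel$target_id, panel$snp_id)]
    else rep(NA_character_, nrow(sel)),
    weight = sel$beta,
    p_train = sel$p,
    stringsAsFactors = FALSE
  )
  if (nrow(sel) == 0) {
    score <- stats::setNames(rep(0, nrow(geno)), rownames(geno))
    attr(score, "empty") <- TRUE
    warning("no SNP passes threshold ", threshold,
            "; returning all-zero scores", call. = FALSE)
  } else {
    score <- drop(geno[, sel$target_id, drop = FALSE] %*% sel$beta)
    names(score) <- rownames(geno)
    attr(score, "empty") <- FALSE
  }
  attr(score, "definition") <- list(
    threshold = threshold, entries = entries,
    training_meta = list(
      n_train_persons = if (!is.null(training_results$n_persons))
        max(training_results$n_persons) else NA_integer_,
      model = if (!is.null(training_results$kind))
        training_results$kind[1] else NA_character_))
  score
}

#' Predictive accuracy of a score for repeated measures
#'
#' R-squared is defined as the squared Pearson correlation between the
#' score and person-mean log units, both residualized on mean age and
#' ancestry PCs. This model-free definition targets between-person
#' prediction, which is what a polygenic instrument captures (a score is
#' constant within person). A zero-variance score returns 0 with attribute
#' `"degenerate" = TRUE`.
#'
#' @param test_pheno Filtered long phenotype table for the test persons.
#' @param scores Named per-person score vector.
#' @param covars Optional covariate table with `person_id` and `PC*`.
#' @param adjust_age Residualize on person-mean age (default TRUE).
#' @return Scalar R-squared in `[0, 1]`.
#' @export
evaluate_score <- function(test_pheno, scores, covars = NULL,
                           adjust_age = TRUE) {
  d <- test_pheno[is.finite(test_pheno$log_units), , drop = FALSE]
  ybar <- tapply(d$log_units, d$person_id, mean)
  agebar <- tapply(d$age, d$person_id, mean)
  ids <- intersect(names(ybar), names(scores))
  if (length(ids) < 3) stop("fewer than 3 test persons", call. = FALSE)
  s <- scores[ids]
  if (stats::var(s) < 1e-14) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  df <- data.frame(y = as.numeric(ybar[ids]), s = as.numeric(s))
  rhs <- character(0)
  if (adjust_age) {
    df$age <- as.numeric(agebar[ids])
    rhs <- "age"
  }
  if (!is.null(covars)) {
    pc_cols <- grep("^PC[0-9]+$", names(covars), value = TRUE)
    idx <- match(ids, covars$person_id)
    for (pc in pc_cols) df[[pc]] <- covars[[pc]][idx]
    rhs <- c(rhs, pc_cols)
  }
  if (length(rhs)) {
    fy <- stats::lm(stats::reformulate(rhs, "y"), data = df)
    fs <- stats::lm(stats::reformulate(rhs, "s"), data = df)
    r2 <- stats::cor(stats::resid(fy), stats::resid(fs))^2
  } else {
    r2 <- stats::cor(df$y, df$s)^2
  }
  unname(r2)
}

#' Select the score threshold by repeated cross-validation
#'
#' Persons are split 80/20 into training and discovery sets (at person
#' level -- all of a person's occasions stay together; stratified by
#' cohort when several are present). Per repeat, every SNP is refit by the
#' repeated-measures mixed model on the training persons; a weighted score
#' is built at each threshold and its test-set R-squared recorded. The
#' threshold with the highest mean R-squared over repeats wins (ties go to
#' the smaller threshold); final weights are refit on all persons at the
#' winning threshold.
#'
#' @param pheno Filtered long phenotype table.
#' @param geno Genotype matrix (all persons).
#' @param covars Optional covariate table.
#' @param thresholds Inclusion p-value grid (default
#'   `c(0.01, 0.05, 0.1, 0.2, 0.4, 0.5)`).
#' @param train_fraction Training fraction (default 0.8).
#' @param repeats Number of random splits (default 5).
#' @param seed Integer seed governing the splits.
#' @param ... Passed to [fit_repeated()] via [assoc_scan()].
#' @return Object of class `cv_result`: `grid` (threshold-by-repeat
#'   R-squared matrix), `mean_r2`, `best_threshold`, `repeats`,
#'   `train_fraction`, `seed`, `final_score` (threshold, entries,
#'   training_meta), and `final_assoc` (full-sample association table).
#' @export
cross_validate <- function(pheno, geno, covars = NULL,
                           thresholds = c(0.01, 0.05, 0.1, 0.2, 0.4, 0.5),
                           train_fraction = 0.8, repeats = 5, seed = 1L,
                           ...) {
  assert_scalar_number(train_fraction, "train_fraction", 0, 1,
                       open_lower = TRUE, open_upper = TRUE)
  assert_count(repeats, "repeats")
  stopifnot(all(thresholds > 0 & thresholds <= 1))
  thresholds <- sort(unique(thresholds))
  persons <- rownames(geno)
  persons <- persons[persons %in% unique(pheno$person_id)]
  if (length(persons) < 10)
    stop("too few persons for an 80/20 split", call. = FALSE)
  strata <- tapply(pheno$cohort, pheno$person_id, function(x) x[1])[persons]
  set.seed(seed)
  grid <- matrix(NA_real_, length(thresholds), repeats,
                 dimnames = list(as.character(thresholds),
                                 paste0("rep", seq_len(repeats))))
  splits <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    train <- unlist(lapply(split(persons, strata), function(p)
      sample(p, round(train_fraction * length(p)))), use.names = FALSE)
    test <- setdiff(persons, train)
    splits[[r]] <- list(train = train, test = test)
    tr_pheno <- pheno[pheno$person_id %in% train, , drop = FALSE]
    te_pheno <- pheno[pheno$person_id %in% test, , drop = FALSE]
    scan <- assoc_scan(tr_pheno, geno[train, , drop = FALSE], covars, ...)
    for (ti in seq_along(thresholds)) {
      sc <- suppressWarnings(
        build_score(geno[test, , drop = FALSE], scan, thresholds[ti]))
      grid[ti, r] <- evaluate_score(te_pheno, sc, covars)
    }
  }
  mean_r2 <- rowMeans(grid)
  best <- thresholds[which.max(mean_r2)]  # ascending order: ties -> smallest
  final_scan <- assoc_scan(pheno, geno[persons, , drop = FALSE], covars, ...)
  final_sc <- suppressWarnings(
    build_score(geno[persons, , drop = FALSE], final_scan, best))
  structure(list(grid = grid, mean_r2 = stats::setNames(mean_r2,
                                                        rownames(grid)),
                 best_threshold = best, thresholds = thresholds,
                 repeats = repeats, train_fraction = train_fraction,
                 seed = as.integer(seed),
                 n_train_persons = round(train_fraction * length(persons)),
                 n_test_persons = length(persons) -
                   round(train_fraction * length(persons)),
                 final_score = attr(final_sc, "definition"),
                 final_assoc = final_scan, splits = splits),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Cross-validated polygenic score selection\n")
  cat(sprintf("  %d repeats, %.0f%%/%.0f%% person-level split (seed %d)\n",
              x$repeats, 100 * x$train_fraction, 100 * (1 - x$train_fraction),
              x$seed))
  cat("  mean test R-squared by threshold:\n")
  for (i in seq_along(x$mean_r2))
    cat(sprintf("    p <= %-5s  %.4f\n", names(x$mean_r2)[i], x$mean_r2[i]))
  cat(sprintf("  best threshold: %s (%d SNPs in final score)\n",
              format(x$best_threshold), nrow(x$final_score$entries)))
  invisible(x)
}
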