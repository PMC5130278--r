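#' Write a genotype matrix as VCF v4.2
#'
#' Hard-called markers are written as GT plus DS; fractional dosages get
#' `GT = ./.` plus DS. One sample column per person, REF = other allele,
#' ALT = effect allele, so DS counts the effect allele.
#'
#' @param geno Genotype matrix with a `panel` attribute (or pass `panel`).
#' @param path Output path.
#' @param panel SNP panel; default from `attr(geno, "panel")`.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(geno, path, panel = attr(geno, "panel")) {
  if (is.null(panel)) stop("a SNP panel is required", call. = FALSE)
  ids <- rownames(geno)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=longprs",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage of ALT allele\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t"))
  body <- vapply(seq_len(nrow(panel)), function(j) {
    d <- geno[, panel$snp_id[j]]
    hard <- all(d %in% 0:2)
    gt <- if (hard) c("0/0", "0/1", "1/1")[d + 1] else rep("./.", length(d))
    paste(c(panel$chrom[j], panel$pos[j], panel$snp_id[j],
            panel$other_allele[j], panel$effect_allele[j], ".", "PASS", ".",
            "GT:DS", paste0(gt, ":", formatC(d, format = "f", digits = 6))),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a genotype dosage matrix
#'
#' VCF v4.2 (via vcfR) with DS preferred over GT, or a wide TSV
#' (first column person id, one column per SNP). Multi-allelic VCF
#' records are rejected by name; sample order is preserved.
#'
#' @param path Input file.
#' @param format `"vcf"` or `"tsv"`.
#' @return Person-by-SNP dosage matrix; for VCF input a reconstructed
#'   panel (id, chrom, pos, alleles, sample MAF, imputed flag) is attached
#'   as attribute `"panel"`.
#' @export
read_genotypes <- function(path, format = c("vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- utils::read.delim(path, check.names = FALSE)
    g <- as.matrix(tab[, -1, drop = FALSE])
    rownames(g) <- tab[[1]]
    if (anyDuplicated(rownames(g)))
      stop("duplicate sample ids", call. = FALSE)
    return(g)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))  # single-record files drop to a vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi))
    stop("multi-allelic record(s) not supported: ",
         paste(fix[multi, "ID"], collapse = ", "), call. = FALSE)
  fmt_keys <- unique(unlist(strsplit(v@gt[, "FORMAT"], ":", fixed = TRUE)))
  if (!any(c("DS", "GT") %in% fmt_keys))
    stop("VCF has neither DS nor GT in FORMAT", call. = FALSE)
  if ("DS" %in% fmt_keys) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    if (is.null(dim(gt)))
      gt <- matrix(gt, nrow = nrow(fix), dimnames = list(NULL, names(gt)))
    counts <- vapply(strsplit(as.vector(gt), "[/|]"), function(a)
      sum(suppressWarnings(as.numeric(a))), numeric(1))
    ds <- matrix(counts, nrow = nrow(gt), dimnames = dimnames(gt))
  }
  g <- t(ds)
  colnames(g) <- fix[, "ID"]
  if (anyDuplicated(rownames(g))) stop("duplicate sample ids", call. = FALSE)
  maf <- colMeans(g) / 2
  attr(g, "panel") <- data.frame(
    snp_id = fix[, "ID"], chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    effect_allele = fix[, "ALT"], other_allele = fix[, "REF"],
    maf = pmin(pmax(maf, 1e-6), 0.5),
    imputed = apply(g, 2, function(d) any(d != round(d))),
    stringsAsFactors = FALSE)
  g
}

#' Write a genotype matrix as a wide TSV
#'
#' @param geno Genotype matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(geno, path) {
  tab <- data.frame(person_id = rownames(geno), geno, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write/read the long phenotype table as CSV
#'
#' Columns `person_id, cohort, occasion, age, units` (plus any flags);
#' `log_units` is recomputed on read.
#'
#' @param pheno Long phenotype table.
#' @param path File path.
#' @return `path` / the table.
#' @export
write_phenotypes_csv <- function(pheno, path) {
  keep <- intersect(c("person_id", "cohort", "occasion", "age", "units",
                      "pregnant"), names(pheno))
  utils::write.csv(pheno[, keep], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes_csv
#' @export
read_phenotypes_csv <- function(path) {
  ph <- utils::read.csv(path, stringsAsFactors = FALSE)
  ph$occasion <- as.character(ph$occasion)
  ph$log_units <- ifelse(ph$units > 0, log(ph$units), NA_real_)
  ph
}

#' Write a score definition in PLINK --score layout
#'
#' Three leading columns `snp_id`, `effect_allele`, `weight` (plus the
#' training p-value), tab-separated.
#'
#' @param definition A score definition (from [build_score()] or
#'   `cv_result$final_score`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_tsv <- function(definition, path) {
  utils::write.table(definition$entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Serialize a cross-validation result as JSON
#'
#' @param cv A `cv_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cv_json <- function(cv, path) {
  obj <- list(
    grid = apply(cv$grid, 1, as.numeric, simplify = FALSE),
    mean_r2 = as.list(cv$mean_r2),
    best_threshold = cv$best_threshold,
    thresholds = cv$thresholds, repeats = cv$repeats,
    train_fraction = cv$train_fraction, seed = cv$seed,
    n_train_persons = cv$n_train_persons,
    n_test_persons = cv$n_test_persons,
    final_score = list(threshold = cv$final_score$threshold,
                       n_snps = nrow(cv$final_score$entries),
                       entries = cv$final_score$entries))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a run configuration (JSON or YAML)
#'
#' @param path Config file; `.json` or `.yaml`/`.yml`.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}
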