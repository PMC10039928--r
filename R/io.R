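#' Write / read a cohort as plain-text files
#'
#' The genotype matrix is stored as a TSV dosage matrix (variants in
#' columns, preceded by an `IID` column), variant metadata as a TSV, the
#' exposure/phenotype/covariates as a TSV with header `IID <name>...`,
#' and the truth record as JSON.  All files round-trip losslessly.
#'
#' @param cohort a `gxe_cohort`.
#' @param prefix output path prefix; files `<prefix>.dosage.tsv`,
#'   `<prefix>.variants.tsv`, `<prefix>.pheno.tsv`, `<prefix>.truth.json`
#'   are written.
#' @return invisibly, the vector of file paths.
#' @export
write_cohort <- function(cohort, prefix) {
  paths <- c(dosage = paste0(prefix, ".dosage.tsv"),
             variants = paste0(prefix, ".variants.tsv"),
             pheno = paste0(prefix, ".pheno.tsv"),
             truth = paste0(prefix, ".truth.json"))
  write_dosage(cohort$genotypes, paths["dosage"], paths["variants"])
  n <- length(cohort$phenotype)
  ph <- data.table::data.table(IID = sprintf("id%06d", seq_len(n)),
                               phenotype = cohort$phenotype,
                               exposure = cohort$exposure$transformed)
  if (!is.null(cohort$covariates))
    ph <- cbind(ph, data.table::as.data.table(cohort$covariates))
  data.table::fwrite(ph, paths["pheno"], sep = "\t", na = "NA",
                     quote = FALSE)
  truth <- cohort$truth
  truth$realized <- as.list(truth$realized)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Write a variant QC report as TSV
#'
#' One row of counts plus, optionally, the retained variant ids in a
#' second file `<path>.ids`.
#'
#' @param report a `variant_qc_report` from [variant_qc()].
#' @param path output TSV path.
#' @param ids also write retained ids, one per line.
#' @return invisibly, `path`.
#' @export
write_qc_report <- function(report, path, ids = FALSE) {
  dt <- data.table::data.table(
    N_INPUT = report$n_input,
    N_REMOVED_MISSINGNESS = report$n_removed_missingness,
    N_REMOVED_MAF = report$n_removed_maf,
    N_REMOVED_HWE = report$n_removed_hwe,
    N_RETAINED = report$n_retained)
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  if (ids)
    writeLines(report$retained_ids, paste0(path, ".ids"))
  invisible(path)
}

#' Write an inflation report as TSV
#'
#' @param report an `inflation_report`.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_inflation_report <- function(report, path) {
  dt <- data.table::data.table(
    LAMBDA_GC = report$lambda_gc,
    MEDIAN_CHI2 = report$median_chi2,
    LDSC_INTERCEPT = report$ldsc_intercept,
    GC_APPLIED = report$gc_applied)
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Write / read a TSV dosage matrix with variant metadata
#'
#' @param genotypes a `genotype_matrix`.
#' @param path dosage TSV path (first column `IID`, then one column per
#'   variant).
#' @param variants_path variant metadata TSV path.
#' @return `write_dosage` invisibly returns `path`; `read_dosage` returns
#'   a `genotype_matrix`.
#' @export
write_dosage <- function(genotypes, path, variants_path) {
  n <- nrow(genotypes$dosage)
  dt <- data.table::as.data.table(genotypes$dosage)
  dt <- cbind(data.table::data.table(IID = sprintf("id%06d", seq_len(n))),
              dt)
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  data.table::fwrite(data.table::as.data.table(genotypes$variants),
                     variants_path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_dosage
#' @export
read_dosage <- function(path, variants_path) {
  dt <- data.table::fread(path, sep = "\t", na.strings = "NA")
  if (names(dt)[1] != "IID")
    stop("dosage file must start with an IID column", call. = FALSE)
  v <- as.data.frame(data.table::fread(variants_path, sep = "\t",
                                       na.strings = "NA"))
  G <- as.matrix(dt[, -1L, with = FALSE])
  storage.mode(G) <- "integer"
  new_genotype_matrix(G, v)
}
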