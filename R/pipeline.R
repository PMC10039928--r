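#' Greedy LD clumping of an interaction scan
#'
#' PLINK-style clumping: variants are sorted by p-value; the most
#' significant unassigned variant with `p <= p1` becomes an index SNP, and
#' every unassigned variant with `p <= p2`, within `+/- kb`, and squared
#' dosage correlation `r2 >= r2_threshold` to the index joins its clump;
#' repeat until no candidate index remains.  Ties in p are broken by
#' (chrom, bp) ascending.  Defaults mirror the common
#' `--clump-p1 5e-6 --clump-p2 5e-6 --clump-r2 0.01 --clump-kb 1000`
#' invocation.
#'
#' @param results a `gwis_result` table.
#' @param panel a `genotype_matrix` sharing variant ids with `results`
#'   (used for r2).
#' @param p1 index-SNP p-value ceiling.
#' @param p2 member p-value ceiling.
#' @param r2 squared-correlation threshold for clump membership.
#' @param kb half-window in kilobases.
#' @return object of class `clump_result`: list of clumps, each with
#'   `index_snp`, `index_p`, `chrom`, `bp_span`, and `members`
#'   (data.frame `snp_id`, `r2`).  Zero clumps when nothing passes `p1`.
#' @export
ld_clump <- function(results, panel, p1 = 5e-6, p2 = 5e-6, r2 = 0.01,
                     kb = 1000) {
  ok <- results$status == "ok" & !is.na(results$p_value)
  res <- results[ok, , drop = FALSE]
  col <- match(res$snp_id, panel$variants$snp_id)
  if (anyNA(col))
    stop("ld_clump: sumstats contain variants absent from the panel",
         call. = FALSE)
  ord <- order(res$p_value, res$chrom, res$bp)
  res <- res[ord, , drop = FALSE]
  col <- col[ord]

  assigned <- rep(FALSE, nrow(res))
  clumps <- list()
  window_bp <- kb * 1000
  G <- panel$dosage
  for (i in seq_len(nrow(res))) {
    if (assigned[i] || res$p_value[i] > p1) next
    assigned[i] <- TRUE
    cand <- which(!assigned &
                  res$p_value <= p2 &
                  res$chrom == res$chrom[i] &
                  abs(res$bp - res$bp[i]) <= window_bp)
    members <- data.frame(snp_id = character(0), r2 = numeric(0))
    if (length(cand)) {
      gi <- as.numeric(G[, col[i]])
      r2v <- vapply(cand, function(k) {
        gk <- as.numeric(G[, col[k]])
        cc <- !is.na(gi) & !is.na(gk)
        if (stats::sd(gi[cc]) == 0 || stats::sd(gk[cc]) == 0) return(0)
        stats::cor(gi[cc], gk[cc])^2
      }, numeric(1))
      inr <- r2v >= r2
      assigned[cand[inr]] <- TRUE
      members <- data.frame(snp_id = res$snp_id[cand[inr]],
                            r2 = r2v[inr], stringsAsFactors = FALSE)
    }
    span <- range(c(res$bp[i], res$bp[match(members$snp_id, res$snp_id)]))
    clumps[[length(clumps) + 1L]] <- list(
      index_snp = res$snp_id[i], index_p = res$p_value[i],
      chrom = res$chrom[i], bp_span = span, members = members)
  }
  structure(list(clumps = clumps,
                 params = list(p1 = p1, p2 = p2, r2 = r2, kb = kb)),
            class = "clump_result")
}

#' @export
print.clump_result <- function(x, ...) {
  cat(sprintf("clump_result: %d clump(s) (p1=%g, p2=%g, r2=%g, kb=%g)\n",
              length(x$clumps), x$params$p1, x$params$p2, x$params$r2,
              x$params$kb))
  for (cl in x$clumps)
    cat(sprintf("  %s (p=%.3g, chr%s) + %d member(s)\n", cl$index_snp,
                cl$index_p, cl$chrom, nrow(cl$members)))
  invisible(x)
}

#' Run the full GxE heritability pipeline on simulated cohorts
#'
#' For each exposure: simulate a cohort, run variant QC and the
#' interaction scan, fit a preliminary LD-score regression, decide on
#' genomic control from its intercept (> 1.1), optionally divide the
#' chi-squares by lambda and refit, run the likelihood tagging estimator
#' on the same (possibly corrected) statistics, compute Bonferroni
#' thresholds (genome-wide `5e-8 / k` and nominal `0.05 / k` for k
#' exposures), and clump at the suggestive threshold.  All randomness
#' derives from the master seed; identical configurations give identical
#' reports.
#'
#' @param config list with elements `n_samples`, `n_variants`, and
#'   `exposures` (a named list; each element is a list of [sim_config()]
#'   overrides such as `h2_gxe`, `exposure_kind`, `confound_inflation`),
#'   plus optional shared overrides (`block_size`, `within_block_rho`,
#'   `h2_additive`, `var_exposure_main`, `n_covariates`, ...),
#'   `window_kb`, `n_blocks`, `panel_n` (reference-panel size, default
#'   1000), and `seed`.  `confound_inflation` (> 1) multiplies the scan
#'   chi-squares to emulate uniform confounding.
#' @return object of class `pipeline_report`: per-exposure list with
#'   `inflation` (an `inflation_report`), `ldsc`, `sumher`
#'   (`h2_estimate`s), `clumps`, `sumstats`; plus `thresholds`, `totals`
#'   (summed heritabilities per method) and `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$exposures),
            length(config$exposures) >= 1L)
  seed <- as.integer(config$seed %||% 1L)
  k <- length(config$exposures)
  window_kb <- config$window_kb %||% 1000
  n_blocks <- config$n_blocks %||% 200L

  shared <- config[intersect(names(config),
    c("n_samples", "n_variants", "block_size", "within_block_rho",
      "maf_range", "h2_additive", "var_exposure_main", "n_covariates"))]

  # one shared reference panel for LD scores and clumping r2
  panel_cfg <- do.call(sim_config, c(shared[setdiff(names(shared),
                                                    "n_samples")],
    list(n_samples = config$panel_n %||% 1000L, seed = seed + 9000L)))
  panel <- simulate_genotypes(panel_cfg)
  scores <- ld_score(panel, window_kb = window_kb)
  tagging <- gcta_tagging(scores)

  thr_gw <- bonferroni_threshold(5e-8, k)
  thr_nom <- bonferroni_threshold(0.05, k)
  thr_suggestive <- 5e-6

  per_exposure <- vector("list", k)
  names(per_exposure) <- names(config$exposures)
  for (i in seq_len(k)) {
    ov <- config$exposures[[i]]
    inflate <- ov$confound_inflation %||% 1
    ov <- ov[setdiff(names(ov), "confound_inflation")]
    cfg <- do.call(sim_config,
                   c(shared, ov, list(seed = seed + 100L * i)))
    cohort <- simulate_cohort(cfg)
    qc <- variant_qc(cohort$genotypes)
    scan <- gwis_scan(qc$genotypes, cohort$exposure, cohort$phenotype,
                      cohort$covariates)
    scan$chi2 <- scan$chi2 * inflate
    scan$p_value <- ifelse(is.na(scan$chi2), NA_real_,
                           stats::pchisq(scan$chi2, 1, lower.tail = FALSE))

    prelim <- ldsc_h2(scan, scores, n_blocks = n_blocks)
    gc_on <- gc_decision(prelim$intercept)
    lambda <- gc_lambda(scan$chi2[scan$status == "ok"])
    final_scan <- scan
    if (gc_on) {
      final_scan$chi2 <- apply_gc(scan$chi2, lambda)
      final_scan$p_value <- ifelse(is.na(final_scan$chi2), NA_real_,
        stats::pchisq(final_scan$chi2, 1, lower.tail = FALSE))
    }
    ldsc <- ldsc_h2(final_scan, scores, n_blocks = n_blocks,
                    gc_applied = gc_on)
    sumher <- sumher_h2(final_scan, tagging, n_blocks = n_blocks,
                        gc_applied = gc_on)
    infl <- inflation_report(scan$chi2[scan$status == "ok"],
                             ldsc_intercept = prelim$intercept,
                             gc_applied = gc_on)
    clumps <- ld_clump(final_scan, cohort$genotypes,
                       p1 = thr_suggestive, p2 = thr_suggestive)
    per_exposure[[i]] <- list(
      qc_report = qc$report, inflation = infl, ldsc = ldsc,
      sumher = sumher, clumps = clumps, sumstats = final_scan)
  }

  totals <- list(
    ldsc = sum_heritabilities(lapply(per_exposure, `[[`, "ldsc")),
    sumher_gcta = sum_heritabilities(lapply(per_exposure, `[[`, "sumher")))

  structure(list(
    exposures = per_exposure,
    thresholds = list(genome_wide = as.numeric(thr_gw),
                      nominal = as.numeric(thr_nom),
                      suggestive = thr_suggestive,
                      k_exposures = k),
    totals = totals,
    provenance = list(seed = seed,
                      package_version = as.character(
                        utils::packageVersion("gxeherit")),
                      config_hash = config_hash(config))
  ), class = "pipeline_report")
}

config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                        force = TRUE)
  # small stable checksum; avoids an external digest dependency
  sum(utf8ToInt(as.character(s)) *
        (seq_along(utf8ToInt(as.character(s))) %% 97 + 1)) %% 1e9
}

#' @export
print.pipeline_report <- function(x, ...) {
  k <- x$thresholds$k_exposures
  cat(sprintf("pipeline_report: %d exposure(s); thresholds gw=%.3g, nominal=%.3g, suggestive=%.3g\n",
              k, x$thresholds$genome_wide, x$thresholds$nominal,
              x$thresholds$suggestive))
  for (nm in names(x$exposures)) {
    ex <- x$exposures[[nm]]
    cat(sprintf("- %s: lambda=%.3f gc=%s | ldsc h2=%.4f (SE %.4f) | sumher h2=%.4f (SE %.4f) | %d clump(s)\n",
                nm, ex$inflation$lambda_gc,
                ifelse(ex$inflation$gc_applied, "yes", "no"),
                ex$ldsc$h2_gxe, ex$ldsc$se, ex$sumher$h2_gxe,
                ex$sumher$se, length(ex$clumps$clumps)))
  }
  cat(sprintf("totals: ldsc %.4f (SE %.4f); sumher %.4f (SE %.4f)\n",
              x$totals$ldsc$total_h2, x$totals$ldsc$total_se,
              x$totals$sumher_gcta$total_h2, x$totals$sumher_gcta$total_se))
  invisible(x)
}

#' Export plot-ready tables from a pipeline report
#'
#' Writes, per exposure, a Manhattan table (`CHR BP P`), a QQ table
#' (`EXPECTED OBSERVED`, -log10 scale), and one combined heritability
#' bar-plot table (`EXPOSURE METHOD H2 SE NEGLOG10P`).  Also writes the
#' estimate report TSV
#' (`EXPOSURE N H2_PCT SE_PCT P INTERCEPT METHOD GC_APPLIED`).
#'
#' @param report a `pipeline_report`.
#' @param prefix output path prefix.
#' @return invisibly, character vector of written paths.
#' @export
export_plot_data <- function(report, prefix) {
  paths <- character(0)
  bar <- list(); est <- list()
  for (nm in names(report$exposures)) {
    ex <- report$exposures[[nm]]
    ss <- ex$sumstats
    man <- data.table::data.table(CHR = ss$chrom, BP = ss$bp,
                                  P = ss$p_value)
    p_man <- paste0(prefix, ".", nm, ".manhattan.tsv")
    data.table::fwrite(man, p_man, sep = "\t", na = "NA", quote = FALSE)
    qq <- qq_points(ss$p_value[ss$status == "ok" & !is.na(ss$p_value)])
    p_qq <- paste0(prefix, ".", nm, ".qq.tsv")
    data.table::fwrite(data.table::data.table(EXPECTED = qq$expected,
                                              OBSERVED = qq$observed),
                       p_qq, sep = "\t", quote = FALSE)
    paths <- c(paths, p_man, p_qq)
    for (est_obj in list(ex$ldsc, ex$sumher)) {
      bar[[length(bar) + 1L]] <- data.table::data.table(
        EXPOSURE = nm, METHOD = est_obj$method, H2 = est_obj$h2_gxe,
        SE = est_obj$se, NEGLOG10P = -log10(est_obj$p_value))
      est[[length(est) + 1L]] <- data.table::data.table(
        EXPOSURE = nm, N = est_obj$n_samples,
        H2_PCT = 100 * est_obj$h2_gxe, SE_PCT = 100 * est_obj$se,
        P = est_obj$p_value, INTERCEPT = est_obj$intercept,
        METHOD = est_obj$method, GC_APPLIED = est_obj$gc_applied)
    }
  }
  p_bar <- paste0(prefix, ".h2_barplot.tsv")
  data.table::fwrite(data.table::rbindlist(bar), p_bar, sep = "\t",
                     quote = FALSE)
  p_est <- paste0(prefix, ".h2_report.tsv")
  data.table::fwrite(data.table::rbindlist(est), p_est, sep = "\t",
                     quote = FALSE)
  invisible(c(paths, p_bar, p_est))
}
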