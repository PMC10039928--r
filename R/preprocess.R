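#' Construct a lifestyle (exposure) variable
#'
#' Container for one exposure vector with its kind and transform
#' provenance.  `transformed` defaults to `raw` with tag `"none"`.
#'
#' @param name variable name.
#' @param kind one of `"continuous"`, `"ordinal"`, `"binary"`.
#' @param raw numeric vector, `NA` allowed.
#' @param transformed numeric vector aligned with `raw`; defaults to `raw`.
#' @param transform_tag one of `"none"`, `"rank_int"`, `"group_recode"`,
#'   `"log"`.
#' @return object of class `lifestyle_variable`.
#' @export
lifestyle_variable <- function(name, kind, raw, transformed = raw,
                               transform_tag = "none") {
  kind <- match.arg(kind, c("continuous", "ordinal", "binary"))
  transform_tag <- match.arg(transform_tag,
                             c("none", "rank_int", "group_recode", "log"))
  stopifnot(is.numeric(raw), length(transformed) == length(raw))
  if (any(is.na(transformed) & !is.na(raw)))
    stop("transformed must be defined wherever raw is non-missing",
         call. = FALSE)
  structure(list(name = name, kind = kind, raw = as.numeric(raw),
                 transformed = as.numeric(transformed),
                 transform_tag = transform_tag),
            class = "lifestyle_variable")
}

#' @export
print.lifestyle_variable <- function(x, ...) {
  cat(sprintf("lifestyle_variable '%s' (%s, transform=%s): n=%d, missing=%d\n",
              x$name, x$kind, x$transform_tag, length(x$raw),
              sum(is.na(x$raw))))
  invisible(x)
}

# current analysis values of an exposure
exposure_values <- function(x) {
  if (inherits(x, "lifestyle_variable")) x$transformed else as.numeric(x)
}

#' Apply a transform to a lifestyle variable
#'
#' @param x a `lifestyle_variable`.
#' @param method `"rank_int"` (rank-based inverse normal) or `"log"`.
#' @return the variable with `transformed` and `transform_tag` updated.
#' @export
transform_exposure <- function(x, method = c("rank_int", "log")) {
  method <- match.arg(method)
  x$transformed <- switch(method,
                          rank_int = rank_int(x$raw),
                          log = log_transform(x$raw))
  x$transform_tag <- if (method == "log") "log" else "rank_int"
  x
}

#' Variant quality control
#'
#' Removes variants failing any of three criteria, applied in the fixed
#' order missingness -> MAF -> HWE so that report counts are deterministic;
#' each variant is counted under the first filter it fails.  MAF is computed
#' on non-missing calls.  Defaults mirror common GWAS practice: call-rate
#' missingness > 0.05, MAF < 0.05 (strictly below excluded), and
#' Hardy-Weinberg exact-test p < 1e-6.
#'
#' @param genotypes a `genotype_matrix`.
#' @param miss_max maximum tolerated per-variant missing-call fraction.
#' @param maf_min minimum minor allele frequency (variants with MAF strictly
#'   below are removed).
#' @param hwe_p_min minimum HWE test p-value.
#' @param hwe_method `"exact"` (mid-p off) or `"chisq"` (1-df, faster).
#' @return list with `genotypes` (filtered `genotype_matrix`; zero columns
#'   if nothing survives) and `report` (class `variant_qc_report`).
#' @export
variant_qc <- function(genotypes, miss_max = 0.05, maf_min = 0.05,
                       hwe_p_min = 1e-6, hwe_method = c("exact", "chisq")) {
  hwe_method <- match.arg(hwe_method)
  stopifnot(miss_max > 0, miss_max < 1, maf_min > 0, maf_min < 1,
            hwe_p_min > 0, hwe_p_min < 1)
  G <- genotypes$dosage
  m <- ncol(G)
  n <- nrow(G)

  n_miss <- colSums(is.na(G))
  fail_miss <- n_miss / n > miss_max

  af <- colMeans(G, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  fail_maf <- !fail_miss & maf < maf_min

  hwe_p <- vapply(seq_len(m), function(j) {
    g <- G[, j]
    g <- g[!is.na(g)]
    n_aa <- sum(g == 2L); n_ab <- sum(g == 1L); n_bb <- sum(g == 0L)
    if (hwe_method == "exact") hwe_exact_p(n_ab, n_aa, n_bb)
    else hwe_chisq_p(n_ab, n_aa, n_bb)
  }, numeric(1))
  fail_hwe <- !fail_miss & !fail_maf & hwe_p < hwe_p_min

  keep <- !(fail_miss | fail_maf | fail_hwe)
  report <- structure(list(
    n_input = m,
    n_removed_missingness = sum(fail_miss),
    n_removed_maf = sum(fail_maf),
    n_removed_hwe = sum(fail_hwe),
    n_retained = sum(keep),
    retained_ids = genotypes$variants$snp_id[keep]
  ), class = "variant_qc_report")

  filtered <- new_genotype_matrix(G[, keep, drop = FALSE],
                                  genotypes$variants[keep, , drop = FALSE])
  list(genotypes = filtered, report = report)
}

#' @export
print.variant_qc_report <- function(x, ...) {
  cat(sprintf(paste0("variant QC: %d in, %d removed (missingness %d, ",
                     "MAF %d, HWE %d), %d retained\n"),
              x$n_input,
              x$n_removed_missingness + x$n_removed_maf + x$n_removed_hwe,
              x$n_removed_missingness, x$n_removed_maf, x$n_removed_hwe,
              x$n_retained))
  invisible(x)
}

#' Hardy-Weinberg exact test p-value
#'
#' Exact (conditional on allele counts) test of Hardy-Weinberg equilibrium:
#' the p-value sums the probabilities of all heterozygote counts with
#' probability no larger than the observed one, under the null distribution
#' of heterozygote counts given the minor-allele count.  No mid-p
#' adjustment.
#'
#' @param n_het count of heterozygotes.
#' @param n_hom1,n_hom2 counts of the two homozygote classes.
#' @return two-sided exact p-value in (0, 1].
#' @export
hwe_exact_p <- function(n_het, n_hom1, n_hom2) {
  stopifnot(n_het >= 0, n_hom1 >= 0, n_hom2 >= 0)
  n <- n_het + n_hom1 + n_hom2
  if (n == 0L) return(1)
  n_rare <- 2L * min(n_hom1, n_hom2) + n_het
  # heterozygote count shares the parity of the rare-allele count
  hets <- seq.int(n_rare %% 2L, n_rare, by = 2L)
  logp <- vapply(hets, function(h) {
    hom_r <- (n_rare - h) %/% 2L
    hom_c <- n - h - hom_r
    # log P(het = h | allele counts): multinomial over genotype configs
    h * log(2) + lgamma(n + 1) -
      (lgamma(hom_r + 1) + lgamma(h + 1) + lgamma(hom_c + 1)) +
      lgamma(n_rare + 1) + lgamma(2L * n - n_rare + 1) - lgamma(2L * n + 1)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  p_obs <- p[match(n_het, hets)]
  min(1, sum(p[p <= p_obs * (1 + 1e-10)]))
}

hwe_chisq_p <- function(n_het, n_hom1, n_hom2) {
  n <- n_het + n_hom1 + n_hom2
  if (n == 0L) return(1)
  p <- (2 * n_hom1 + n_het) / (2 * n)
  q <- 1 - p
  if (p == 0 || q == 0) return(1)
  exp_counts <- n * c(p^2, 2 * p * q, q^2)
  obs <- c(n_hom1, n_het, n_hom2)
  stats::pchisq(sum((obs - exp_counts)^2 / exp_counts), df = 1,
                lower.tail = FALSE)
}

#' Natural-log transform
#'
#' @param x numeric vector, all non-missing values strictly positive
#'   (`NA` passes through).
#' @return `log(x)` elementwise.
#' @export
log_transform <- function(x) {
  bad <- which(!is.na(x) & x <= 0)
  if (length(bad))
    stop("log_transform: non-positive value at index ", bad[1], call. = FALSE)
  log(x)
}

#' Rank-based inverse normal transform
#'
#' Gaussianization of a quantitative variable: non-missing values are
#' ranked (average ranks for ties), mapped to probability points
#' `(rank - 0.5) / n` and through the standard normal quantile function.
#' Missing values stay missing.
#'
#' @param x numeric vector; needs >= 2 distinct non-missing values.
#' @return numeric vector of the same length.
#' @export
rank_int <- function(x) {
  obs <- !is.na(x)
  v <- x[obs]
  if (length(unique(v)) < 2L)
    stop("rank_int: fewer than 2 distinct non-missing values", call. = FALSE)
  n <- length(v)
  out <- x
  out[obs] <- stats::qnorm((rank(v, ties.method = "average") - 0.5) / n)
  out
}

#' Sex-stratified quartile groups
#'
#' Cuts a phenotype into quartiles separately within each sex (type-7
#' quantiles at 0.25/0.5/0.75) and combines same-quartile groups across
#' sexes.  A value equal to a cut point goes to the lower group
#' ("value <= threshold" convention).
#'
#' @param phenotype numeric vector.
#' @param sex binary vector (two distinct codes, e.g. 0/1).
#' @return factor with levels `Q1`-`Q4`.
#' @export
quartile_by_sex <- function(phenotype, sex) {
  stopifnot(length(phenotype) == length(sex))
  codes <- sort(unique(sex[!is.na(sex)]))
  if (length(codes) != 2L)
    stop("quartile_by_sex: both sexes must be present", call. = FALSE)
  out <- factor(rep(NA_character_, length(phenotype)),
                levels = paste0("Q", 1:4))
  for (s in codes) {
    idx <- which(sex == s & !is.na(phenotype))
    if (length(idx) < 4L)
      stop("quartile_by_sex: a sex stratum has fewer than 4 observations",
           call. = FALSE)
    cuts <- stats::quantile(phenotype[idx], c(0.25, 0.5, 0.75), type = 7)
    grp <- 1L + (phenotype[idx] > cuts[1]) + (phenotype[idx] > cuts[2]) +
      (phenotype[idx] > cuts[3])
    out[idx] <- paste0("Q", grp)
  }
  out
}

#' Exposure-outcome association adjusted for age and sex
#'
#' OLS of the phenotype on `[1, exposure, age, sex]` with a two-sided t
#' test on the exposure coefficient; the standard screen run before an
#' interaction scan.
#'
#' @param phenotype,exposure,age,sex numeric vectors of equal length.
#' @return list with `beta`, `se`, `p` for the exposure term.
#' @export
exposure_outcome_assoc <- function(phenotype, exposure, age, sex) {
  n <- length(phenotype)
  stopifnot(n > 4, length(exposure) == n, length(age) == n, length(sex) == n)
  X <- cbind(`(Intercept)` = 1, exposure = as.numeric(exposure),
             age = as.numeric(age), sex = as.numeric(sex))
  cc <- stats::complete.cases(X, phenotype)
  X <- X[cc, , drop = FALSE]
  y <- phenotype[cc]
  fit <- stats::lm.fit(X, y)
  if (fit$rank < ncol(X))
    stop("exposure_outcome_assoc: rank-deficient design (collinear columns)",
         call. = FALSE)
  rss <- sum(fit$residuals^2)
  df <- length(y) - ncol(X)
  XtX_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(rss / df * XtX_inv[2, 2])
  beta <- unname(fit$coefficients["exposure"])
  t <- beta / se
  list(beta = beta, se = se,
       p = 2 * stats::pt(-abs(t), df = df))
}
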