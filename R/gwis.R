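#' Genome-wide interaction scan
#'
#' Fits, for every variant j, the fixed-effect linear model
#' \deqn{y = \beta_0 + \beta_1 G_j + \beta_2 (G_j \times E) + \beta_3 E
#'       + \mathbf{\beta}_c^\top \mathrm{covariates} + \epsilon}
#' and reports the interaction coefficient \eqn{\beta_2}, its standard
#' error, t statistic with `df = n_used - p_full`, two-sided p-value from
#' the t distribution, and \eqn{\chi^2 = t^2}.
#'
#' Internally the shared columns `[1, E, covariates]` are projected out
#' once (Frisch-Waugh-Lovell), and the per-variant fit reduces to a
#' two-column regression of the residualized phenotype on the residualized
#' `G_j` and `G_j x E`; the reported `(beta, SE, p)` equal the full-design
#' OLS with the stated degrees of freedom.  Rows with missing phenotype,
#' exposure or covariates are dropped globally before the scan; per-variant
#' genotype missingness is handled complete-case for that variant (such
#' variants fall back to an explicit small fit).
#'
#' Monomorphic variants and variants whose interaction column has no
#' residual variance get `status = "degenerate"` with missing statistics;
#' the scan continues.  Globally collinear covariates are a hard error.
#'
#' @param genotypes a `genotype_matrix`.
#' @param exposure a `lifestyle_variable` or numeric vector; enters the
#'   model exactly as transformed upstream (not re-standardized here).
#' @param phenotype numeric vector.
#' @param covariates optional numeric matrix (n x k), e.g. age, sex, array,
#'   principal components.
#' @return a `data.frame` of class `gwis_result` with columns
#'   `snp_id, chrom, bp, a1, a2, n_used, beta_gxe, se, t_stat, p_value,
#'   chi2, status`.
#' @export
gwis_scan <- function(genotypes, exposure, phenotype, covariates = NULL) {
  G <- genotypes$dosage
  e <- exposure_values(exposure)
  y <- as.numeric(phenotype)
  n <- nrow(G)
  stopifnot(length(e) == n, length(y) == n)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == n)
  }

  keep <- !is.na(e) & !is.na(y)
  if (!is.null(covariates)) keep <- keep & stats::complete.cases(covariates)
  if (sum(keep) < 5L) stop("too few complete rows for the scan", call. = FALSE)
  G <- G[keep, , drop = FALSE]
  e <- e[keep]; y <- y[keep]
  if (!is.null(covariates)) covariates <- covariates[keep, , drop = FALSE]

  W <- cbind(intercept = 1, E = e, covariates)
  qrW <- qr(W)
  if (qrW$rank < ncol(W))
    stop("collinear covariate design (rank ", qrW$rank, " < ", ncol(W), ")",
         call. = FALSE)
  p_full <- ncol(W) + 2L
  y_res <- qr.resid(qrW, y)

  m <- ncol(G)
  out <- data.frame(
    snp_id = genotypes$variants$snp_id,
    chrom = genotypes$variants$chrom,
    bp = genotypes$variants$bp,
    a1 = genotypes$variants$a1,
    a2 = genotypes$variants$a2,
    n_used = NA_integer_, beta_gxe = NA_real_, se = NA_real_,
    t_stat = NA_real_, p_value = NA_real_, chi2 = NA_real_,
    status = "ok", stringsAsFactors = FALSE
  )

  has_na <- colSums(is.na(G)) > 0L
  # fast path: variants with complete genotype calls, processed in chunks
  full_idx <- which(!has_na)
  nobs <- length(y)
  yty <- sum(y_res^2)
  chunk <- 500L
  for (start in seq(1L, length(full_idx), by = chunk)) {
    jj <- full_idx[start:min(start + chunk - 1L, length(full_idx))]
    Gc <- G[, jj, drop = FALSE]
    storage.mode(Gc) <- "double"
    GE <- Gc * e
    X1 <- Gc - qr.fitted(qrW, Gc)
    X2 <- GE - qr.fitted(qrW, GE)
    a <- colSums(X1^2)
    b <- colSums(X1 * X2)
    cc <- colSums(X2^2)
    d1 <- colSums(X1 * y_res)
    d2 <- colSums(X2 * y_res)
    det <- a * cc - b^2
    # degenerate when the residualized G or GxE column has (numerically)
    # no variance left, or the two are collinear
    ok <- a > 1e-9 * pmax(colSums(Gc^2), 1) &
      cc > 1e-9 * pmax(colSums(GE^2), 1) &
      det > 1e-12 * a * cc
    b2 <- (a * d2 - b * d1) / det
    b1 <- (cc * d1 - b * d2) / det
    rss <- yty - (b1 * d1 + b2 * d2)
    df <- nobs - p_full
    sigma2 <- pmax(rss, 0) / df
    se <- sqrt(sigma2 * a / det)
    tstat <- b2 / se
    pval <- 2 * stats::pt(-abs(tstat), df = df)
    rows <- jj
    out$n_used[rows] <- nobs
    out$beta_gxe[rows] <- ifelse(ok, b2, NA_real_)
    out$se[rows] <- ifelse(ok, se, NA_real_)
    out$t_stat[rows] <- ifelse(ok, tstat, NA_real_)
    out$p_value[rows] <- ifelse(ok, pval, NA_real_)
    out$chi2[rows] <- ifelse(ok, tstat^2, NA_real_)
    out$status[rows] <- ifelse(ok, "ok", "degenerate")
    out$n_used[rows[!ok]] <- NA_integer_
  }
  # slow path: per-variant complete-case full OLS
  for (j in which(has_na)) {
    g <- as.numeric(G[, j])
    ccj <- !is.na(g)
    fit <- tryCatch(
      full_interaction_ols(y[ccj], g[ccj], e[ccj],
                           W[ccj, -1L, drop = FALSE]),
      error = function(err) NULL)
    if (is.null(fit)) {
      out$status[j] <- "degenerate"
    } else {
      out$n_used[j] <- sum(ccj)
      out$beta_gxe[j] <- fit$beta; out$se[j] <- fit$se
      out$t_stat[j] <- fit$t; out$p_value[j] <- fit$p
      out$chi2[j] <- fit$t^2
    }
  }
  class(out) <- c("gwis_result", "data.frame")
  out
}

# reference full-design OLS for one variant; W_extra excludes the intercept
full_interaction_ols <- function(y, g, e, W_extra) {
  X <- cbind(1, g, g * e, W_extra)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("degenerate design", call. = FALSE)
  cf <- qr.coef(qrX, y)
  res <- qr.resid(qrX, y)
  df <- length(y) - ncol(X)
  if (df <= 0) stop("no residual degrees of freedom", call. = FALSE)
  sigma2 <- sum(res^2) / df
  Rinv <- backsolve(qr.R(qrX), diag(ncol(X)))
  vc <- sigma2 * tcrossprod(Rinv)
  # column 3 of X is the interaction term; qr may permute, use pivot
  pos <- match(3L, qrX$pivot)
  beta <- cf[3L]
  se <- sqrt(vc[pos, pos])
  t <- beta / se
  list(beta = unname(beta), se = se, t = unname(t),
       p = 2 * stats::pt(-abs(t), df = df))
}

#' Write / read interaction summary statistics
#'
#' Tab-separated exchange format with columns
#' `SNP CHR BP A1 A2 N BETA_GXE SE T P CHI2 STATUS`; missing statistics are
#' encoded as `NA`.  The round trip is lossless.
#'
#' @param results a `gwis_result` table (non-empty).
#' @param path output file path.
#' @return `write_sumstats` invisibly returns `path`; `read_sumstats`
#'   returns a `gwis_result` data.frame.
#' @export
write_sumstats <- function(results, path) {
  if (nrow(results) == 0L) stop("refusing to write an empty sumstats table",
                                call. = FALSE)
  dt <- data.table::data.table(
    SNP = results$snp_id, CHR = results$chrom, BP = results$bp,
    A1 = results$a1, A2 = results$a2, N = results$n_used,
    BETA_GXE = results$beta_gxe, SE = results$se, T = results$t_stat,
    P = results$p_value, CHI2 = results$chi2, STATUS = results$status)
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  dt <- data.table::fread(path, sep = "\t", na.strings = "NA",
                          colClasses = list(character = c("SNP", "A1", "A2")))
  need <- c("SNP", "CHR", "BP", "A1", "A2", "N", "BETA_GXE", "SE", "T",
            "P", "CHI2", "STATUS")
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols))
    stop("sumstats file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(dt) == 0L)
    stop("sumstats file has no rows (empty input)", call. = FALSE)
  out <- data.frame(
    snp_id = dt$SNP, chrom = dt$CHR, bp = dt$BP, a1 = dt$A1, a2 = dt$A2,
    n_used = as.integer(dt$N), beta_gxe = as.numeric(dt$BETA_GXE),
    se = as.numeric(dt$SE), t_stat = as.numeric(dt$T),
    p_value = as.numeric(dt$P), chi2 = as.numeric(dt$CHI2),
    status = as.character(dt$STATUS), stringsAsFactors = FALSE)
  class(out) <- c("gwis_result", "data.frame")
  out
}

#' Export LDSC-style Z sumstats
#'
#' Writes the `SNP A1 A2 N Z` layout consumed by LD-score regression
#' tooling, with `Z = sign(beta_gxe) * sqrt(chi2)`.
#'
#' @param results a `gwis_result` table.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_ldsc_sumstats <- function(results, path) {
  ok <- results$status == "ok"
  dt <- data.table::data.table(
    SNP = results$snp_id[ok], A1 = results$a1[ok], A2 = results$a2[ok],
    N = results$n_used[ok],
    Z = sign(results$beta_gxe[ok]) * sqrt(results$chi2[ok]))
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}
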