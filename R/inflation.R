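#' Genomic-control inflation factor
#'
#' \eqn{\lambda_{GC}} is the sample median of the association \eqn{\chi^2}
#' statistics divided by the constant 0.45656 (the null median used by the
#' originating procedure; it differs in the fifth decimal from the exact
#' 1-df chi-square median 0.4549364).  For an even-length vector the median
#' is the mean of the two middle order statistics.
#'
#' @param chi2 non-empty numeric vector of non-negative statistics.
#' @return scalar lambda.
#' @export
gc_lambda <- function(chi2) {
  chi2 <- chi2[!is.na(chi2)]
  if (!length(chi2)) stop("gc_lambda: empty chi-square vector", call. = FALSE)
  if (any(chi2 < 0)) stop("gc_lambda: negative chi-square value",
                          call. = FALSE)
  stats::median(chi2) / gc_null_median
}

# null median divisor, taken verbatim from the genomic-control recipe
gc_null_median <- 0.45656

#' Apply genomic control
#'
#' Divides every chi-square statistic by a previously computed lambda.
#' When lambda was computed from the same vector, the corrected median is
#' exactly 0.45656.
#'
#' @param chi2 numeric vector.
#' @param lambda_gc positive scalar from [gc_lambda()].
#' @return corrected vector.
#' @export
apply_gc <- function(chi2, lambda_gc) {
  if (!is.finite(lambda_gc) || lambda_gc <= 0)
    stop("apply_gc: lambda must be positive and finite", call. = FALSE)
  chi2 / lambda_gc
}

#' Genomic-control decision rule
#'
#' Genomic control is applied only to scans whose LD-score-regression
#' intercept exceeds 1.1 (strictly).
#'
#' @param ldsc_intercept finite scalar intercept.
#' @return `TRUE` iff intercept > 1.1.
#' @export
gc_decision <- function(ldsc_intercept) {
  stopifnot(is.finite(ldsc_intercept))
  ldsc_intercept > 1.1
}

#' Quantile-quantile plot coordinates
#'
#' Sorted observed p-values against uniform expected points
#' `(i - 0.5) / m`, both on the -log10 scale.
#'
#' @param p_values numeric vector with values in (0, 1].
#' @return data.frame with columns `expected`, `observed` (-log10 scale),
#'   ordered from least to most significant.
#' @export
qq_points <- function(p_values) {
  p <- p_values[!is.na(p_values)]
  if (any(p <= 0 | p > 1))
    stop("qq_points: p-values must lie in (0, 1]", call. = FALSE)
  m <- length(p)
  data.frame(expected = -log10((seq_len(m) - 0.5) / m),
             observed = -log10(sort(p)))
}

#' Inflation report for one scan
#'
#' @param chi2 chi-square vector of a scan.
#' @param ldsc_intercept optional LDSC intercept (may be `NA` before the
#'   preliminary fit).
#' @param gc_applied logical.
#' @return list of class `inflation_report` with `lambda_gc`,
#'   `median_chi2`, `ldsc_intercept`, `gc_applied`.
#' @export
inflation_report <- function(chi2, ldsc_intercept = NA_real_,
                             gc_applied = FALSE) {
  med <- stats::median(chi2, na.rm = TRUE)
  structure(list(lambda_gc = med / gc_null_median, median_chi2 = med,
                 ldsc_intercept = ldsc_intercept,
                 gc_applied = isTRUE(gc_applied)),
            class = "inflation_report")
}

#' @export
print.inflation_report <- function(x, ...) {
  cat(sprintf("inflation: lambda_GC=%.4f (median chi2=%.4f), intercept=%s, GC %s\n",
              x$lambda_gc, x$median_chi2,
              ifelse(is.na(x$ldsc_intercept), "NA",
                     sprintf("%.3f", x$ldsc_intercept)),
              ifelse(x$gc_applied, "applied", "not applied")))
  invisible(x)
}
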