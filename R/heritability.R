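#' LD-score regression estimate of GxE interaction heritability
#'
#' Regresses per-variant interaction \eqn{\chi^2} statistics on LD scores,
#' \deqn{E[\chi^2_j] = a + \frac{N h^2}{M} \ell_j,}
#' by iteratively weighted least squares: weights are initialized as
#' `1 / max(l2, 1)`, then updated to
#' `1 / (max(l2, 1) * 2 * fitted^2)` and the model is refit once (two
#' iterations total; fitted values are floored at 0.01 before squaring so a
#' stray non-positive fit cannot produce an infinite weight).  The slope is
#' converted to heritability as `h2 = slope * M / N`.  Standard errors of
#' both the heritability and the intercept come from a delete-one-block
#' jackknife over `n_blocks` contiguous, position-ordered blocks, with the
#' final weights held fixed.  The p-value is one-sided normal against
#' `h2 > 0`.
#'
#' This is a single-step fit with a free intercept: no chi-square
#' truncation and no two-step intercept constraint, appropriate at
#' simulation scale where statistics are small.
#'
#' @param sumstats a `gwis_result` table (or data.frame with `snp_id`,
#'   `chrom`, `bp`, `chi2`, `status`).
#' @param ldscores an `ldscore_table`.
#' @param n_samples scan sample size N; defaults to the median `n_used`.
#' @param n_blocks jackknife block count (default 200; reduced to
#'   `floor(M/2)` with a warning when M is small).
#' @param gc_applied bookkeeping flag recorded in the estimate.
#' @param min_snps minimum number of joined variants (default 50; lower it
#'   only for didactic examples).
#' @param jackknife set `FALSE` to skip jackknife SEs (then `se` and
#'   `p_value` are `NA`; useful on noiseless toy inputs).
#' @return object of class `h2_estimate` with fields `method`, `h2_gxe`,
#'   `se`, `p_value`, `intercept`, `intercept_se`, `n_samples`, `n_snps`,
#'   `n_blocks`, `gc_applied`, `negative_flag`.
#' @export
ldsc_h2 <- function(sumstats, ldscores, n_samples = NULL, n_blocks = 200L,
                    gc_applied = FALSE, min_snps = 50L, jackknife = TRUE) {
  d <- join_scores(sumstats, ldscores$snp_id, ldscores$l2, min_snps)
  M <- nrow(d)
  N <- n_samples %||% stats::median(sumstats$n_used, na.rm = TRUE)
  if (stats::var(d$x) == 0)
    stop("ldsc_h2: zero variance in LD scores, model unidentifiable",
         call. = FALSE)

  w <- 1 / pmax(d$x, 1)
  fit <- wls_line(d$x, d$y, w)
  fitted <- pmax(fit$a + fit$b * d$x, 0.01)
  w <- 1 / (pmax(d$x, 1) * 2 * fitted^2)
  fit <- wls_line(d$x, d$y, w)

  h2 <- fit$b * M / N
  if (jackknife) {
    n_blocks <- check_blocks(M, n_blocks)
    blocks <- jk_blocks(M, n_blocks)
    jk <- jackknife_wls(d$x, d$y, w, blocks)
    se <- jk$se_b * M / N
    se_a <- jk$se_a
  } else {
    n_blocks <- 0L
    se <- NA_real_
    se_a <- NA_real_
  }
  new_h2_estimate(method = "ldsc", h2 = h2, se = se,
                  intercept = fit$a, intercept_se = se_a,
                  n_samples = N, n_snps = M, n_blocks = n_blocks,
                  gc_applied = gc_applied)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

join_scores <- function(sumstats, ids, values, min_snps = 50L) {
  ok <- sumstats$status == "ok" & is.finite(sumstats$chi2)
  i <- match(sumstats$snp_id, ids)
  keep <- ok & !is.na(i) & is.finite(values[i])
  d <- data.frame(snp_id = sumstats$snp_id[keep],
                  chrom = sumstats$chrom[keep], bp = sumstats$bp[keep],
                  y = sumstats$chi2[keep], x = values[i][keep])
  d <- d[order(d$chrom, d$bp), , drop = FALSE]
  if (nrow(d) < min_snps)
    stop("need at least ", min_snps,
         " variants after joining sumstats with scores", call. = FALSE)
  d
}

check_blocks <- function(M, n_blocks) {
  n_blocks <- as.integer(n_blocks)
  if (M < n_blocks * 2L) {
    n_blocks <- max(2L, M %/% 2L)
    warning("fewer variants than requested jackknife blocks; using ",
            n_blocks, " blocks", call. = FALSE)
  }
  n_blocks
}

# exactly n_blocks contiguous, nearly equal-sized blocks over M items
jk_blocks <- function(M, n_blocks) {
  pmin(n_blocks, 1L + floor((seq_len(M) - 1L) * n_blocks / M))
}

# weighted least squares of y on [1, x]
wls_line <- function(x, y, w) {
  sw <- sum(w); sx <- sum(w * x); sxx <- sum(w * x^2)
  sy <- sum(w * y); sxy <- sum(w * x * y)
  det <- sw * sxx - sx^2
  b <- (sw * sxy - sx * sy) / det
  a <- (sy - b * sx) / sw
  list(a = a, b = b)
}

# delete-one-block jackknife of the weighted line fit (fixed weights)
jackknife_wls <- function(x, y, w, blocks) {
  tab <- function(v) vapply(split(v, blocks), sum, numeric(1))
  SW <- tab(w); SX <- tab(w * x); SXX <- tab(w * x^2)
  SY <- tab(w * y); SXY <- tab(w * x * y)
  tw <- sum(SW); tx <- sum(SX); txx <- sum(SXX); ty <- sum(SY); txy <- sum(SXY)
  B <- length(SW)
  ajk <- bjk <- numeric(B)
  for (k in seq_len(B)) {
    sw <- tw - SW[k]; sx <- tx - SX[k]; sxx <- txx - SXX[k]
    sy <- ty - SY[k]; sxy <- txy - SXY[k]
    det <- sw * sxx - sx^2
    bjk[k] <- (sw * sxy - sx * sy) / det
    ajk[k] <- (sy - bjk[k] * sx) / sw
  }
  list(se_a = sqrt((B - 1) / B * sum((ajk - mean(ajk))^2)),
       se_b = sqrt((B - 1) / B * sum((bjk - mean(bjk))^2)),
       a_reps = ajk, b_reps = bjk)
}

new_h2_estimate <- function(method, h2, se, intercept, intercept_se,
                            n_samples, n_snps, n_blocks, gc_applied,
                            boundary = FALSE) {
  if (!is.na(se) && (!is.finite(se) || se < 0))
    stop("heritability SE is not finite and non-negative; fit failed",
         call. = FALSE)
  p <- if (is.na(se)) NA_real_
       else max(stats::pnorm(h2 / se, lower.tail = FALSE), 1e-300)
  structure(list(
    method = method,
    h2_gxe = h2,
    se = se,
    p_value = p,
    intercept = intercept,
    intercept_se = intercept_se,
    n_samples = n_samples,
    n_snps = n_snps,
    n_blocks = n_blocks,
    gc_applied = isTRUE(gc_applied),
    negative_flag = h2 < 0,
    boundary_flag = isTRUE(boundary)
  ), class = "h2_estimate")
}

#' @export
print.h2_estimate <- function(x, ...) {
  cat(sprintf(
    "h2_GxE [%s]: %.4f%% (SE %.4f%%), one-sided p = %.3g, intercept = %.3f\n",
    x$method, 100 * x$h2_gxe, 100 * x$se, x$p_value, x$intercept))
  cat(sprintf("  N = %d, M = %d, %d jackknife blocks%s%s\n",
              as.integer(x$n_samples), x$n_snps, x$n_blocks,
              if (x$gc_applied) ", GC applied" else "",
              if (x$negative_flag) ", NEGATIVE estimate" else ""))
  invisible(x)
}

#' Likelihood-based tagging estimate of GxE interaction heritability
#'
#' Models each interaction statistic as a scaled 1-df chi-square,
#' \eqn{\chi^2_j \sim e_j \chi^2_1} with
#' \eqn{e_j = a + \frac{N h^2}{M} \tau_j} under the GCTA (equal expected
#' contribution) tagging model, and maximizes the log-likelihood
#' \deqn{\sum_j \left[-\tfrac12 \ln e_j - \frac{\chi^2_j}{2 e_j}\right]}
#' over `(h2, a)` subject to `a > 0` and all `e_j > 0`, by Nelder-Mead
#' from `(0, 1)` with an infeasibility penalty.  With `intercept =
#' "fixed"` the multiplier is pinned (default 1) and only `h2` is
#' profiled.  Standard errors come from the same delete-one-block
#' jackknife as [ldsc_h2()], warm-started at the full-data optimum; the
#' p-value is one-sided normal.
#'
#' Note the free intercept is chosen for comparability with LDSC; external
#' SumHer defaults differ.
#'
#' @param sumstats a `gwis_result` table.
#' @param tagging a `tagging_table` from [gcta_tagging()].
#' @param n_samples scan sample size N; defaults to median `n_used`.
#' @param n_blocks jackknife block count.
#' @param intercept `"free"` or `"fixed"`.
#' @param intercept_value value of `a` when fixed.
#' @param gc_applied bookkeeping flag.
#' @param min_snps minimum number of joined variants.
#' @param jackknife set `FALSE` to skip jackknife SEs.
#' @return an `h2_estimate` with `method = "sumher_gcta"`.
#' @export
sumher_h2 <- function(sumstats, tagging, n_samples = NULL, n_blocks = 200L,
                      intercept = c("free", "fixed"), intercept_value = 1,
                      gc_applied = FALSE, min_snps = 50L, jackknife = TRUE) {
  intercept <- match.arg(intercept)
  d <- join_scores(sumstats, tagging$snp_id, tagging$tau, min_snps)
  M <- nrow(d)
  N <- n_samples %||% stats::median(sumstats$n_used, na.rm = TRUE)
  scale_tau <- N / M

  opt <- sumher_mle(d$y, d$x, scale_tau, intercept, intercept_value)
  if (!opt$converged)
    stop("sumher_h2: likelihood maximization did not converge; ",
         "last iterate h2 = ", signif(opt$h2, 6), ", a = ",
         signif(opt$a, 6), call. = FALSE)

  if (jackknife) {
    n_blocks <- check_blocks(M, n_blocks)
    blocks <- jk_blocks(M, n_blocks)
    h2jk <- numeric(n_blocks)
    for (k in seq_len(n_blocks)) {
      keep <- blocks != k
      o <- sumher_mle(d$y[keep], d$x[keep], scale_tau, intercept,
                      intercept_value, start = c(opt$h2, opt$a))
      h2jk[k] <- o$h2
    }
    B <- n_blocks
    se <- sqrt((B - 1) / B * sum((h2jk - mean(h2jk))^2))
  } else {
    n_blocks <- 0L
    se <- NA_real_
  }
  new_h2_estimate(method = "sumher_gcta", h2 = opt$h2, se = se,
                  intercept = opt$a, intercept_se = NA_real_,
                  n_samples = N, n_snps = M, n_blocks = n_blocks,
                  gc_applied = gc_applied, boundary = opt$boundary)
}

# negative log-likelihood of scaled chi-square model; Inf-penalty outside
# the feasible region keeps Nelder-Mead inside e_j > 0, a > 0
sumher_nll <- function(par, chi2, tau, scale_tau, a_fixed = NULL) {
  h2 <- par[1]
  a <- if (is.null(a_fixed)) par[2] else a_fixed
  e <- a + scale_tau * h2 * tau
  if (a <= 0 || any(e <= 0)) return(1e12 + sum(pmax(-e, 0)) + max(-a, 0))
  sum(0.5 * log(e) + chi2 / (2 * e))
}

sumher_mle <- function(chi2, tau, scale_tau, intercept, intercept_value,
                       start = NULL) {
  if (intercept == "fixed") {
    start_h2 <- if (is.null(start)) 0 else start[1]
    f <- function(h2) sumher_nll(h2, chi2, tau, scale_tau,
                                 a_fixed = intercept_value)
    o <- stats::optim(start_h2, f, method = "Brent",
                      lower = -intercept_value / (scale_tau * max(tau)) + 1e-9,
                      upper = 5)
    nll0 <- f(0)
    if (o$value > nll0) o <- list(par = 0, value = nll0, convergence = 0L)
    return(list(h2 = o$par[1], a = intercept_value, nll = o$value,
                converged = TRUE, boundary = FALSE))
  }
  st <- if (is.null(start)) c(0, 1) else start
  f <- function(p) sumher_nll(p, chi2, tau, scale_tau)
  o <- stats::optim(st, f, method = "Nelder-Mead",
                    control = list(maxit = 2000, reltol = 1e-12))
  nll0 <- f(c(0, 1))
  if (o$value > nll0) {
    o$par <- c(0, 1); o$value <- nll0; o$convergence <- 0L
  }
  list(h2 = o$par[1], a = o$par[2], nll = o$value,
       converged = o$convergence == 0L,
       boundary = o$par[2] < 1e-6)
}

#' Sum heritabilities across exposures
#'
#' Total GxE heritability as the plain sum of per-exposure estimates, with
#' the standard error combined as the root sum of squares.  Both rest on
#' an independence assumption across exposures: if the exposures overlap,
#' the true total is smaller than the sum.
#'
#' @param estimates list of `h2_estimate` objects (>= 1).
#' @return list with `total_h2`, `total_se`, `n_terms`, `methods`.
#' @export
sum_heritabilities <- function(estimates) {
  if (!length(estimates)) stop("no estimates to sum", call. = FALSE)
  if (inherits(estimates, "h2_estimate")) estimates <- list(estimates)
  methods <- vapply(estimates, function(x) x$method, character(1))
  if (length(unique(methods)) > 1L)
    warning("summing heritabilities across different estimation methods",
            call. = FALSE)
  h2 <- vapply(estimates, function(x) x$h2_gxe, numeric(1))
  se <- vapply(estimates, function(x) x$se, numeric(1))
  list(total_h2 = sum(h2), total_se = sqrt(sum(se^2)),
       n_terms = length(h2), methods = unique(methods))
}

#' Bonferroni-corrected significance threshold
#'
#' @param base_alpha base significance level (e.g. 5e-8 genome-wide,
#'   0.05 nominal).
#' @param k_tests number of tests (>= 1).
#' @return the unrounded threshold `base_alpha / k_tests`, with a
#'   `"display"` attribute rounded to 3 significant figures; comparisons
#'   should use the unrounded value.
#' @export
bonferroni_threshold <- function(base_alpha, k_tests) {
  stopifnot(base_alpha > 0, base_alpha < 1)
  if (k_tests < 1) stop("k_tests must be >= 1", call. = FALSE)
  thr <- base_alpha / k_tests
  attr(thr, "display") <- signif(thr, 3)
  thr
}
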