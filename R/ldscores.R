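#' LD scores from a genotype reference panel
#'
#' For each variant j the LD score is the sum, over all variants k within
#' a physical window of `window_kb` around j (including j itself), of the
#' bias-adjusted squared dosage correlation
#' \deqn{r^2_{adj} = r^2 - \frac{1 - r^2}{n_{panel} - 2},}
#' where r is the sample correlation of dosages in the panel.  The self
#' term contributes exactly 1.  Pairs involving a monomorphic variant
#' contribute 0; fully monomorphic variants get a missing LD score and are
#' excluded from downstream regression.
#'
#' The window is physical distance (the synthetic map has a uniform 1 kb
#' spacing, so kb windows and cM windows coincide up to a constant).
#'
#' @param panel a `genotype_matrix` with at least 3 samples and positions
#'   sorted within chromosome.
#' @param window_kb half-window in kilobases (default 1000, i.e. +/- 1 Mb).
#' @param adjust apply the finite-sample adjustment (default `TRUE`); with
#'   `FALSE` the plain r-squared sum is returned, which is exactly
#'   monotone in the window size.
#' @return data.frame of class `ldscore_table` with columns
#'   `snp_id, chrom, bp, l2, n_panel, window_kb`.
#' @export
ld_score <- function(panel, window_kb = 1000, adjust = TRUE) {
  G <- panel$dosage
  v <- panel$variants
  n <- nrow(G)
  if (n < 3L)
    stop("ld_score: panel needs >= 3 samples for the r2 adjustment",
         call. = FALSE)
  m <- ncol(G)
  window_bp <- window_kb * 1000

  # standardize columns; flag monomorphic
  mu <- colMeans(G)
  sdv <- sqrt(colMeans(G^2) - mu^2) * sqrt(n / (n - 1))
  mono <- sdv == 0 | is.na(sdv)
  Gs <- matrix(0, n, m)
  ok <- which(!mono)
  if (length(ok))
    Gs[, ok] <- sweep(sweep(G[, ok, drop = FALSE], 2L, mu[ok], "-"),
                      2L, sdv[ok], "/")

  l2 <- rep(NA_real_, m)
  ord <- order(v$chrom, v$bp)
  if (any(ord != seq_len(m)))
    stop("ld_score: variants must be sorted by (chrom, bp)", call. = FALSE)

  adj <- if (adjust) function(r2) r2 - (1 - r2) / (n - 2) else identity
  for (chr in unique(v$chrom)) {
    cidx <- which(v$chrom == chr)
    bp <- v$bp[cidx]
    # process in tiles; correlations via crossprod of standardized columns
    tile <- 512L
    for (start in seq(1L, length(cidx), by = tile)) {
      jj <- start:min(start + tile - 1L, length(cidx))
      lo <- findInterval(bp[jj[1]] - window_bp - 1L, bp) + 1L
      hi <- findInterval(bp[jj[length(jj)]] + window_bp, bp)
      kk <- lo:hi
      R <- crossprod(Gs[, cidx[jj], drop = FALSE],
                     Gs[, cidx[kk], drop = FALSE]) / (n - 1)
      r2 <- R^2
      # window mask per row
      for (a in seq_along(jj)) {
        j <- jj[a]
        inw <- abs(bp[kk] - bp[j]) <= window_bp
        if (mono[cidx[j]]) next
        contrib <- adj(r2[a, inw])
        # zero-out pairs with monomorphic partners, fix the self term to 1
        contrib[mono[cidx[kk[inw]]]] <- 0
        contrib[kk[inw] == j] <- 1
        l2[cidx[j]] <- sum(contrib)
      }
    }
  }
  out <- data.frame(snp_id = v$snp_id, chrom = v$chrom, bp = v$bp, l2 = l2,
                    n_panel = n, window_kb = window_kb,
                    stringsAsFactors = FALSE)
  class(out) <- c("ldscore_table", "data.frame")
  out
}

#' Tagging values under the GCTA model
#'
#' Under the GCTA heritability model every SNP contributes equally in
#' expectation, so the tagging value of variant j equals its LD score on
#' the well-imputed panel: `tau_j = l2_j`.
#'
#' @param ldscores an `ldscore_table` (non-empty).
#' @return data.frame of class `tagging_table` with `snp_id`, `tau`.
#' @export
gcta_tagging <- function(ldscores) {
  if (nrow(ldscores) == 0L)
    stop("gcta_tagging: empty LD-score table", call. = FALSE)
  out <- data.frame(snp_id = ldscores$snp_id, tau = ldscores$l2,
                    stringsAsFactors = FALSE)
  class(out) <- c("tagging_table", "data.frame")
  out
}

#' Write / read an LD-score table
#'
#' Tab-separated `CHR SNP BP L2` layout, readable in place of downloaded
#' `.l2.ldscore` files.
#'
#' @param ldscores an `ldscore_table`.
#' @param path file path.
#' @return `write_ldscores` invisibly returns `path`.
#' @export
write_ldscores <- function(ldscores, path) {
  dt <- data.table::data.table(CHR = ldscores$chrom, SNP = ldscores$snp_id,
                               BP = ldscores$bp, L2 = ldscores$l2)
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_ldscores
#' @export
read_ldscores <- function(path) {
  dt <- data.table::fread(path, sep = "\t", na.strings = "NA")
  need <- c("CHR", "SNP", "BP", "L2")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("LD-score file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- data.frame(snp_id = as.character(dt$SNP), chrom = dt$CHR,
                    bp = dt$BP, l2 = as.numeric(dt$L2),
                    n_panel = NA_integer_, window_kb = NA_real_,
                    stringsAsFactors = FALSE)
  class(out) <- c("ldscore_table", "data.frame")
  out
}
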