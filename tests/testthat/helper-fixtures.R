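# shared fixture builders (everything generated in code, no stored data)

# genotype_matrix from a bare dosage matrix, variants at 1 kb spacing
toy_genotypes <- function(dosage, chrom = 1L, bp = NULL) {
  m <- ncol(dosage)
  variants <- data.frame(
    snp_id = sprintf("snp%06d", seq_len(m)),
    chrom = chrom,
    bp = if (is.null(bp)) 1L + (seq_len(m) - 1L) * 1000L else bp,
    a1 = "A", a2 = "G", stringsAsFactors = FALSE)
  new_genotype_matrix(as.matrix(dosage), variants)
}

# HWE-consistent dosage column with given allele frequency (deterministic
# counts, shuffled order under the caller's RNG state)
hwe_column <- function(n, af) {
  n_aa <- round(n * af^2)
  n_ab <- round(n * 2 * af * (1 - af))
  g <- c(rep(2L, n_aa), rep(1L, n_ab), rep(0L, n - n_aa - n_ab))
  sample(g)
}

# quick small cohort for scan-level tests
small_cohort <- function(n = 400, m = 80, h2_gxe = 0.1, h2_additive = 0.2,
                         rho = 0.3, seed = 42, ...) {
  cfg <- sim_config(n_samples = n, n_variants = m, within_block_rho = rho,
                    h2_gxe = h2_gxe, h2_additive = h2_additive,
                    seed = seed, ...)
  simulate_cohort(cfg)
}

# gwis_result-shaped table built directly from chi2 values
chi2_table <- function(chi2, n = 1000L, bp = NULL) {
  m <- length(chi2)
  structure(data.frame(
    snp_id = sprintf("snp%06d", seq_len(m)), chrom = 1L,
    bp = if (is.null(bp)) 1L + (seq_len(m) - 1L) * 1000L else bp,
    a1 = "A", a2 = "G", n_used = as.integer(n), beta_gxe = sqrt(chi2),
    se = 1, t_stat = sqrt(chi2),
    p_value = stats::pchisq(chi2, 1, lower.tail = FALSE),
    chi2 = chi2, status = "ok", stringsAsFactors = FALSE),
    class = c("gwis_result", "data.frame"))
}

ld_table <- function(l2) {
  m <- length(l2)
  structure(data.frame(snp_id = sprintf("snp%06d", seq_len(m)), chrom = 1L,
                       bp = 1L + (seq_len(m) - 1L) * 1000L, l2 = l2,
                       n_panel = 1000L, window_kb = 1000,
                       stringsAsFactors = FALSE),
            class = c("ldscore_table", "data.frame"))
}

# independent greedy clumping oracle (set-based, no shared code with
# ld_clump's vectorized implementation)
brute_force_clump <- function(res, panel, p1, p2, r2, kb) {
  ok <- res[res$status == "ok" & !is.na(res$p_value), ]
  ok <- ok[order(ok$p_value, ok$chrom, ok$bp), ]
  taken <- character(0)
  clumps <- list()
  repeat {
    cand <- ok[!(ok$snp_id %in% taken) & ok$p_value <= p1, ]
    if (nrow(cand) == 0) break
    idx <- cand[1, ]
    taken <- c(taken, idx$snp_id)
    members <- character(0)
    pool <- ok[!(ok$snp_id %in% taken) & ok$p_value <= p2 &
               ok$chrom == idx$chrom & abs(ok$bp - idx$bp) <= kb * 1000, ]
    gi <- panel$dosage[, match(idx$snp_id, panel$variants$snp_id)]
    for (s in pool$snp_id) {
      gk <- panel$dosage[, match(s, panel$variants$snp_id)]
      if (stats::sd(gi) > 0 && stats::sd(gk) > 0 &&
          stats::cor(gi, gk)^2 >= r2)
        members <- c(members, s)
    }
    taken <- c(taken, members)
    clumps[[length(clumps) + 1L]] <- list(index = idx$snp_id,
                                          members = sort(members))
  }
  clumps
}

# minimal h2_estimate stand-in for arithmetic on published-style values
fake_estimate <- function(h2, se, method = "ldsc") {
  structure(list(method = method, h2_gxe = h2, se = se,
                 p_value = stats::pnorm(h2 / se, lower.tail = FALSE),
                 intercept = 1, intercept_se = NA_real_,
                 n_samples = 1000, n_snps = 1000, n_blocks = 0L,
                 gc_applied = FALSE, negative_flag = h2 < 0,
                 boundary_flag = FALSE),
            class = "h2_estimate")
}
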