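# cohort generator: determinism, allele frequencies, LD, exact variance
# components

test_that("identical seeds give bit-identical cohorts", {
  cfg <- sim_config(n_samples = 300, n_variants = 120, seed = 11,
                    n_covariates = 2L)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$genotypes$dosage, c2$genotypes$dosage)
  expect_identical(c1$exposure$raw, c2$exposure$raw)
  expect_identical(c1$phenotype, c2$phenotype)
  expect_identical(c1$covariates, c2$covariates)
  expect_identical(c1$truth, c2$truth)
})

test_that("realized allele frequency tracks the target MAF", {
  # binomial oracle: realized AF over 2n draws has SD sqrt(p(1-p)/(2n))
  n <- 20000
  cfg <- sim_config(n_samples = n, n_variants = 10,
                    maf_range = c(0.3, 0.3), within_block_rho = 0,
                    seed = 5)
  g <- simulate_genotypes(cfg)
  af <- colMeans(g$dosage) / 2
  sd_binom <- sqrt(0.3 * 0.7 / (2 * n))
  expect_true(all(abs(af - 0.3) < 3 * sd_binom))
})

test_that("rho = 0 gives independent variants; rho > 0 gives decaying LD", {
  n <- 5000
  g0 <- simulate_genotypes(sim_config(n_samples = n, n_variants = 40,
                                      within_block_rho = 0, seed = 2))
  C0 <- cor(g0$dosage)
  off0 <- abs(C0[upper.tri(C0)])
  # mean |r| for independent pairs is ~ sqrt(2/(pi*n)) ~ 0.011
  expect_lt(mean(off0), 0.02)

  g5 <- simulate_genotypes(sim_config(n_samples = n, n_variants = 40,
                                      block_size = 40,
                                      within_block_rho = 0.7, seed = 2))
  C5 <- cor(g5$dosage)
  adj <- mean(abs(C5[cbind(1:39, 2:40)]))
  far <- mean(abs(C5[cbind(1:20, 21:40)]))
  expect_gt(adj, 0.3)
  expect_gt(adj, far + 0.2)
})

test_that("genotypes respect Hardy-Weinberg at the nominal test level", {
  g <- simulate_genotypes(sim_config(n_samples = 800, n_variants = 400,
                                     within_block_rho = 0, seed = 9))
  p <- apply(g$dosage, 2, function(col) {
    hwe_exact_p(sum(col == 1L), sum(col == 2L), sum(col == 0L))
  })
  rate <- mean(p < 0.05)
  # exact test is discrete, hence conservative: at most ~nominal
  expect_lt(rate, 0.08)
})

test_that("exposure kinds follow their stated distributions", {
  n <- 10000
  e_cont <- simulate_exposure(sim_config(n, 10, seed = 3))
  expect_lt(abs(mean(e_cont$raw)), 0.04)
  expect_lt(abs(var(e_cont$raw) - 1), 0.06)

  e_bin <- simulate_exposure(sim_config(n, 10, exposure_kind = "binary:0.5",
                                        seed = 3))
  se <- sqrt(0.25 / n)
  expect_lt(abs(mean(e_bin$raw) - 0.5), 3 * se)

  e_ord <- simulate_exposure(sim_config(n, 10, exposure_kind = "ordinal:4",
                                        seed = 3))
  expect_identical(sort(unique(e_ord$raw)), as.numeric(1:4))

  mask <- rep(c(TRUE, FALSE), length.out = n)
  e_na <- simulate_exposure(sim_config(n, 10, seed = 3),
                            missing_mask = mask)
  expect_identical(is.na(e_na$raw), mask)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(100, 10, maf_range = c(0.05, 0.6)), "maf_range")
  expect_error(sim_config(100, 10, h2_additive = 0.6, h2_gxe = 0.3,
                          var_exposure_main = 0.2), "< 1")
  expect_error(sim_config(100, 10, h2_gxe = -0.1), ">= 0")
  expect_error(sim_config(100, 10, n_causal_gxe = 11), "causal")
  expect_error(sim_config(100, 10, exposure_kind = "ordinal:1"), "k >= 2")
  expect_error(sim_config(100, 10, exposure_kind = "binary:1.5"),
               "prevalence")
  expect_error(sim_config(100, 10, exposure_kind = "weird"), "unknown")
})

test_that("realized variance components equal the configured fractions exactly", {
  cfg <- sim_config(n_samples = 500, n_variants = 100, h2_additive = 0.3,
                    h2_gxe = 0.05, var_exposure_main = 0.1, seed = 21)
  co <- simulate_cohort(cfg)
  expect_equal(unname(co$truth$realized["h2_additive"]), 0.3,
               tolerance = 1e-12)
  expect_equal(unname(co$truth$realized["h2_gxe"]), 0.05, tolerance = 1e-12)
  expect_equal(unname(co$truth$realized["var_exposure_main"]), 0.1,
               tolerance = 1e-12)
  expect_equal(unname(co$truth$realized["var_noise"]), 0.55,
               tolerance = 1e-12)
  expect_lte(sum(co$truth$realized[1:3]), 1)
})

test_that("regressing the phenotype on true components recovers total R2", {
  # direct OLS oracle for the generating model
  cfg <- sim_config(n_samples = 3000, n_variants = 200, h2_additive = 0.25,
                    h2_gxe = 0.1, var_exposure_main = 0.05, seed = 31)
  co <- simulate_cohort(cfg)
  G <- co$genotypes$dosage
  et <- scale(co$exposure$transformed)[, 1]
  Gs_a <- scale(G[, co$truth$idx_additive])
  Gs_g <- scale(G[, co$truth$idx_gxe])
  u_add <- drop(Gs_a %*% co$truth$beta_additive)
  u_gxe <- drop((Gs_g * et) %*% co$truth$beta_gxe)
  fit <- lm(co$phenotype ~ u_add + u_gxe + et)
  expect_equal(summary(fit)$r.squared, 0.4, tolerance = 0.03)
})

test_that("h2_gxe = 0 leaves no interaction signal", {
  cfg <- sim_config(n_samples = 1500, n_variants = 40, h2_gxe = 0,
                    h2_additive = 0.3, seed = 13)
  co <- simulate_cohort(cfg)
  expect_identical(co$truth$beta_gxe,
                   rep(0, length(co$truth$idx_gxe)))
  # partial correlation of y with g*e given g and e is null-distributed
  et <- scale(co$exposure$transformed)[, 1]
  pcors <- vapply(seq_len(40), function(j) {
    g <- scale(co$genotypes$dosage[, j])[, 1]
    W <- cbind(1, g, et)
    ry <- lm.fit(W, co$phenotype)$residuals
    rx <- lm.fit(W, g * et)$residuals
    cor(ry, rx)
  }, numeric(1))
  expect_lt(max(abs(pcors)), 4 / sqrt(1500))
})

test_that("overlap_causal draws interaction causals from the additive set", {
  cfg <- sim_config(n_samples = 200, n_variants = 100,
                    n_causal_additive = 20, n_causal_gxe = 10,
                    overlap_causal = TRUE, seed = 8)
  co <- simulate_cohort(cfg)
  expect_true(all(co$truth$idx_gxe %in% co$truth$idx_additive))
})

test_that("cohorts round-trip through plain-text files", {
  cfg <- sim_config(n_samples = 50, n_variants = 20, seed = 77,
                    n_covariates = 1L)
  co <- simulate_cohort(cfg)
  prefix <- file.path(withr::local_tempdir(), "coh")
  paths <- write_cohort(co, prefix)
  expect_true(all(file.exists(paths)))
  g2 <- read_dosage(paths["dosage"], paths["variants"])
  expect_identical(unname(g2$dosage), unname(co$genotypes$dosage))
  expect_identical(g2$variants$snp_id, co$genotypes$variants$snp_id)
  truth <- jsonlite::read_json(paths["truth"], simplifyVector = TRUE)
  expect_equal(unlist(truth$realized), co$truth$realized,
               tolerance = 1e-12)
})
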