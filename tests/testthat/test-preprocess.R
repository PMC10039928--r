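# variant QC and phenotype/exposure transforms

test_that("variant_qc applies missingness -> MAF -> HWE in order", {
  set.seed(1)
  n <- 100
  g_ok <- hwe_column(n, 0.30)
  g_maf_low <- hwe_column(n, 0.04)       # MAF 0.04 -> removed (strictly < 0.05)
  g_maf_edge <- hwe_column(n, 0.05)      # MAF 0.05 -> retained
  g_missing <- hwe_column(n, 0.30)
  g_missing[1:6] <- NA                   # 6% missing -> removed first
  g_hwe_bad <- sample(c(rep(2L, 10), rep(1L, 80), rep(0L, 10)))  # het excess

  gm <- toy_genotypes(cbind(g_ok, g_maf_low, g_maf_edge, g_missing,
                            g_hwe_bad))
  res <- variant_qc(gm, miss_max = 0.05, maf_min = 0.05, hwe_p_min = 1e-6)
  r <- res$report
  expect_equal(r$n_input, 5L)
  expect_equal(r$n_removed_missingness, 1L)
  expect_equal(r$n_removed_maf, 1L)
  expect_equal(r$n_removed_hwe, 1L)
  expect_equal(r$n_retained, 2L)
  expect_identical(r$retained_ids, c("snp000001", "snp000003"))
  expect_equal(r$n_input - (r$n_removed_missingness + r$n_removed_maf +
                            r$n_removed_hwe), r$n_retained)

  # idempotence: re-running on the retained set changes nothing
  res2 <- variant_qc(res$genotypes)
  expect_identical(res2$report$retained_ids, r$retained_ids)
  expect_equal(res2$report$n_retained, r$n_retained)

  # empty retained set is a status, not a crash
  all_bad <- variant_qc(toy_genotypes(cbind(hwe_column(n, 0.02))))
  expect_equal(all_bad$report$n_retained, 0L)
  expect_equal(ncol(all_bad$genotypes$dosage), 0L)
})

test_that("HWE exact p-values match a direct enumeration oracle", {
  # oracle: normalized probabilities of every heterozygote count consistent
  # with the rare-allele total, summed over outcomes as improbable as the
  # observation
  oracle <- function(n_het, n_hom_rare, n_hom_com) {
    n <- n_het + n_hom_rare + n_hom_com
    nr <- 2 * n_hom_rare + n_het
    hets <- seq(nr %% 2, nr, by = 2)
    pr <- vapply(hets, function(h) {
      hr <- (nr - h) / 2
      hc <- n - h - hr
      exp(sum(log(2) * h) + lfactorial(n) - lfactorial(hr) -
            lfactorial(h) - lfactorial(hc) + lfactorial(nr) +
            lfactorial(2 * n - nr) - lfactorial(2 * n))
    }, numeric(1))
    pr <- pr / sum(pr)
    sum(pr[pr <= pr[match(n_het, hets)] * (1 + 1e-10)])
  }
  cases <- list(c(5, 2, 13), c(80, 10, 10), c(21, 1, 49), c(0, 5, 10),
                c(10, 0, 30))
  for (cs in cases) {
    expect_equal(hwe_exact_p(cs[1], cs[2], cs[3]),
                 oracle(cs[1], cs[2], cs[3]), tolerance = 1e-12)
  }
  # (AA, Aa, aa) = (10, 80, 10): gross heterozygote excess fails QC
  expect_lt(hwe_exact_p(80, 10, 10), 1e-6)
  # Monte-Carlo cross-check on a mid-range case: pair shuffled alleles
  set.seed(4)
  n <- 20; n_het_obs <- 10; n_rare <- 2 * 5 + 10
  draws <- replicate(20000, {
    alleles <- sample(c(rep(1L, n_rare), rep(0L, 2 * n - n_rare)))
    sum(alleles[seq(1, 2 * n, 2)] != alleles[seq(2, 2 * n, 2)])
  })
  tab <- table(draws) / length(draws)
  p_mc <- sum(tab[tab <= tab[as.character(n_het_obs)] * (1 + 1e-10)])
  expect_equal(hwe_exact_p(10, 5, 5), unname(p_mc), tolerance = 0.02)
})

test_that("the chi-square HWE option agrees with the exact test at scale", {
  set.seed(2)
  n <- 4000
  col_bad <- sample(c(rep(2L, 150), rep(1L, 2400), rep(0L, n - 2550)))
  gm <- toy_genotypes(cbind(hwe_column(n, 0.3), col_bad))
  exact <- variant_qc(gm, hwe_method = "exact")
  chisq <- variant_qc(gm, hwe_method = "chisq")
  expect_identical(exact$report$retained_ids, chisq$report$retained_ids)
  expect_equal(exact$report$n_removed_hwe, 1L)
})

test_that("log transform is the natural log with domain checking", {
  expect_equal(log_transform(c(1.0)), 0.0)
  expect_equal(log_transform(c(exp(1))), 1.0)
  expect_equal(diff(log_transform(c(2, 4))), log(2))
  expect_error(log_transform(c(1, -2, 3)), "index 2")
  expect_equal(log_transform(c(1, NA)), c(0, NA))
})

test_that("rank-based inverse normal transform matches the quantile oracle", {
  expect_equal(rank_int(c(10, 20, 30)),
               qnorm(c(1, 3, 5) / 6), tolerance = 1e-12)
  expect_equal(rank_int(c(10, 20, 30))[2], 0)
  # average-rank ties: duplicated values share the mapped quantile
  out <- rank_int(c(1, 5, 5, 9))
  expect_equal(out[2], out[3])
  expect_equal(out[2], qnorm((2.5 - 0.5) / 4))
  # middle element of an odd-length tie-free vector maps exactly to 0
  expect_equal(rank_int(c(3, 100, -4, 7, 2))[1], 0)
  # missing stays missing, others unaffected by it
  expect_equal(rank_int(c(10, NA, 20, 30))[c(1, 3, 4)],
               qnorm(c(1, 3, 5) / 6))
  expect_true(is.na(rank_int(c(10, NA, 20, 30))[2]))
  expect_error(rank_int(c(5, 5)), "distinct")
})

test_that("rank_int is mean-zero and rank-monotone", {
  set.seed(6)
  for (rep in 1:5) {
    x <- rnorm(101)
    y <- rank_int(x)
    expect_lt(abs(mean(y)), 1e-12)
    expect_identical(order(x), order(y))
  }
})

test_that("sex-stratified quartiles follow the <= threshold convention", {
  ph <- c(1:8, 101:108)
  sex <- rep(c(0, 1), each = 8)
  q <- quartile_by_sex(ph, sex)
  expect_equal(as.integer(table(q)), rep(4L, 4))
  expect_equal(as.character(q[1:8]),
               rep(paste0("Q", 1:4), each = 2))
  # type-7 quartiles of 1..8 are (2.75, 4.5, 6.25): value 2 <= 2.75 -> Q1
  expect_equal(as.character(q[2]), "Q1")
  expect_error(quartile_by_sex(1:8, rep(0, 8)), "both sexes")
  expect_error(quartile_by_sex(c(1:6, 1:3), c(rep(0, 6), rep(1, 3))),
               "fewer than 4")
})

test_that("exposure-outcome association recovers a constructed effect", {
  set.seed(7)
  n <- 500
  expo <- rnorm(n); age <- rnorm(n); sex <- rbinom(n, 1, 0.5)
  y <- 2 * expo + 1e-8 * rnorm(n)
  a <- exposure_outcome_assoc(y, expo, age, sex)
  expect_equal(a$beta, 2, tolerance = 1e-6)
  expect_lt(a$p, 1e-100)
  expect_error(exposure_outcome_assoc(y, expo, expo, sex), "rank-deficient")
})

test_that("association p-values are uniform under the null", {
  set.seed(8)
  p <- replicate(300, {
    n <- 150
    exposure_outcome_assoc(rnorm(n), rnorm(n), rnorm(n),
                           rbinom(n, 1, 0.5))$p
  })
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})

test_that("lifestyle_variable container validates and transforms", {
  lv <- lifestyle_variable("bmi", "continuous", c(20, 25, NA, 30))
  expect_identical(lv$transform_tag, "none")
  lt <- transform_exposure(lv, "log")
  expect_equal(lt$transformed[1], log(20))
  expect_identical(lt$transform_tag, "log")
  ri <- transform_exposure(lv, "rank_int")
  expect_identical(ri$transform_tag, "rank_int")
  expect_true(is.na(ri$transformed[3]))
  expect_error(lifestyle_variable("x", "continuous", c(1, 2),
                                  transformed = c(NA, 2)),
               "wherever raw")
})
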