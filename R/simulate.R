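#' Simulation configuration for synthetic GxE cohorts
#'
#' Builds and validates the configuration object consumed by
#' [simulate_genotypes()], [simulate_exposure()] and [simulate_phenotype()].
#' The generating model for the phenotype is
#' \deqn{y = \sum_j \tilde g_j b_j + \sum_j (\tilde g_j \circ \tilde e) c_j
#'       + \gamma \tilde e + \epsilon,}
#' with each component rescaled so that its realized sample variance equals
#' the requested fraction exactly (see [simulate_phenotype()]).
#'
#' @param n_samples number of individuals.
#' @param n_variants number of biallelic variants.
#' @param block_size variants per LD block; the last block may be short.
#' @param within_block_rho AR(1) correlation of the latent haplotype process
#'   within a block, in `[0, 1)`.  `0` gives independent variants.
#' @param maf_range length-2 numeric, allele-frequency bounds in `(0, 0.5]`;
#'   per-variant MAFs are drawn uniformly in this range.
#' @param h2_additive fraction of phenotypic variance from additive SNP
#'   effects.
#' @param h2_gxe fraction of phenotypic variance from SNP-by-exposure
#'   interaction effects.
#' @param var_exposure_main fraction of phenotypic variance from the
#'   exposure main effect.
#' @param n_causal_additive,n_causal_gxe numbers of causal variants for the
#'   additive and interaction components.
#' @param exposure_kind one of `"continuous"`, `"ordinal:k"` (k equiprobable
#'   integer levels, k >= 2) or `"binary:p"` (Bernoulli with prevalence p).
#' @param n_covariates number of nuisance covariates (independent standard
#'   normals with zero true effect); they exercise covariate adjustment only.
#' @param overlap_causal if `TRUE`, interaction-causal variants are drawn
#'   from the additive-causal set (when that set is large enough); the
#'   default is independent draws.
#' @param seed integer seed; identical seeds give bit-identical cohorts.
#' @return a validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_samples = 200, n_variants = 100, seed = 7)
#' cohort <- simulate_cohort(cfg)
#' cohort$truth$realized
#' @export
sim_config <- function(n_samples, n_variants,
                       block_size = 50L,
                       within_block_rho = 0.5,
                       maf_range = c(0.05, 0.5),
                       h2_additive = 0.2,
                       h2_gxe = 0.05,
                       var_exposure_main = 0.05,
                       n_causal_additive = max(1L, n_variants %/% 10L),
                       n_causal_gxe = max(1L, n_variants %/% 10L),
                       exposure_kind = "continuous",
                       n_covariates = 0L,
                       overlap_causal = FALSE,
                       seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples),
    n_variants = as.integer(n_variants),
    block_size = as.integer(block_size),
    within_block_rho = as.numeric(within_block_rho),
    maf_range = as.numeric(maf_range),
    h2_additive = as.numeric(h2_additive),
    h2_gxe = as.numeric(h2_gxe),
    var_exposure_main = as.numeric(var_exposure_main),
    n_causal_additive = as.integer(n_causal_additive),
    n_causal_gxe = as.integer(n_causal_gxe),
    exposure_kind = as.character(exposure_kind),
    n_covariates = as.integer(n_covariates),
    overlap_causal = isTRUE(overlap_causal),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_samples >= 2L, cfg$n_variants >= 1L, cfg$block_size >= 1L)
  if (cfg$within_block_rho < 0 || cfg$within_block_rho >= 1)
    stop("within_block_rho must be in [0, 1)", call. = FALSE)
  if (length(cfg$maf_range) != 2L ||
      any(cfg$maf_range <= 0) || any(cfg$maf_range > 0.5) ||
      cfg$maf_range[1] > cfg$maf_range[2])
    stop("maf_range must be an increasing pair in (0, 0.5]", call. = FALSE)
  fr <- c(cfg$h2_additive, cfg$h2_gxe, cfg$var_exposure_main)
  if (any(fr < 0))
    stop("variance fractions must be >= 0", call. = FALSE)
  if (sum(fr) >= 1)
    stop("h2_additive + h2_gxe + var_exposure_main must be < 1", call. = FALSE)
  if (cfg$n_causal_additive > cfg$n_variants ||
      cfg$n_causal_gxe > cfg$n_variants)
    stop("causal counts cannot exceed n_variants", call. = FALSE)
  parse_exposure_kind(cfg$exposure_kind)
  invisible(cfg)
}

parse_exposure_kind <- function(kind) {
  if (kind == "continuous") return(list(kind = "continuous"))
  if (grepl("^ordinal:[0-9]+$", kind)) {
    k <- as.integer(sub("^ordinal:", "", kind))
    if (k < 2L) stop("ordinal exposure needs k >= 2 levels", call. = FALSE)
    return(list(kind = "ordinal", k = k))
  }
  if (grepl("^binary:", kind)) {
    p <- suppressWarnings(as.numeric(sub("^binary:", "", kind)))
    if (!is.finite(p) || p <= 0 || p >= 1)
      stop("binary exposure prevalence must be in (0, 1)", call. = FALSE)
    return(list(kind = "binary", prevalence = p))
  }
  stop("unknown exposure_kind: ", kind, call. = FALSE)
}

#' Simulate LD-structured genotype dosages
#'
#' Genotypes are built from two independent latent haplotypes per sample.
#' Within each block the latent Gaussian process is AR(1) with coefficient
#' `within_block_rho` across adjacent variants; an allele is present on a
#' haplotype when its latent value falls below the normal quantile of the
#' variant's allele frequency, and the dosage is the sum over the two
#' haplotypes.  Hardy-Weinberg equilibrium holds by construction and LD
#' between variants at latent distance d decays with rho^d.  Variants are
#' placed on one synthetic chromosome at a fixed 1 kb spacing (1-based),
#' which makes window and clump semantics deterministic.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `genotype_matrix`: a list with `dosage`
#'   (n_samples x n_variants integer matrix in 0/1/2) and `variants`
#'   (data.frame with `snp_id`, `chrom`, `bp`, `a1`, `a2`, `maf_target`).
#'   A1 is the counted (effect) allele.
#' @export
simulate_genotypes <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_samples
  m <- config$n_variants
  rho <- config$within_block_rho
  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  thr <- stats::qnorm(maf)

  blocks <- block_index(m, config$block_size)
  dosage <- matrix(0L, n, m)
  for (b in unique(blocks)) {
    idx <- which(blocks == b)
    lat1 <- ar1_latent(n, length(idx), rho)
    lat2 <- ar1_latent(n, length(idx), rho)
    th <- matrix(thr[idx], n, length(idx), byrow = TRUE)
    dosage[, idx] <- (lat1 < th) + (lat2 < th)
  }
  storage.mode(dosage) <- "integer"
  variants <- data.frame(
    snp_id = sprintf("snp%06d", seq_len(m)),
    chrom = 1L,
    bp = 1L + (seq_len(m) - 1L) * 1000L,
    a1 = "A",
    a2 = "G",
    maf_target = maf,
    stringsAsFactors = FALSE
  )
  new_genotype_matrix(dosage, variants)
}

# latent AR(1) Gaussian process across m variants for n samples
ar1_latent <- function(n, m, rho) {
  z <- matrix(stats::rnorm(n * m), n, m)
  if (rho > 0 && m > 1L) {
    s <- sqrt(1 - rho^2)
    for (j in 2:m) z[, j] <- rho * z[, j - 1L] + s * z[, j]
  }
  z
}

block_index <- function(m, block_size) {
  rep(seq_len(ceiling(m / block_size)), each = block_size)[seq_len(m)]
}

#' Construct a genotype_matrix container
#'
#' @param dosage samples x variants matrix with entries in 0/1/2 or `NA`.
#' @param variants data.frame with at least `snp_id`, `chrom`, `bp`,
#'   `a1`, `a2`; one row per column of `dosage`.
#' @return an object of class `genotype_matrix`.
#' @export
new_genotype_matrix <- function(dosage, variants) {
  stopifnot(is.matrix(dosage), ncol(dosage) == nrow(variants),
            all(c("snp_id", "chrom", "bp", "a1", "a2") %in% names(variants)))
  colnames(dosage) <- variants$snp_id
  structure(list(dosage = dosage, variants = variants),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants (chrom %s, bp %d-%d)\n",
              nrow(x$dosage), ncol(x$dosage),
              paste(unique(x$variants$chrom), collapse = ","),
              min(x$variants$bp), max(x$variants$bp)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Simulate a lifestyle exposure
#'
#' Continuous exposures are standard normal; `ordinal:k` draws k equiprobable
#' integer levels `1..k`; `binary:p` draws Bernoulli(p).  The exposure is
#' independent of genotypes.  Missingness can be injected with a logical
#' mask.
#'
#' @param config a [sim_config()] object.
#' @param missing_mask optional logical vector (length n_samples); `TRUE`
#'   entries are set to `NA`.
#' @return a `lifestyle_variable` (see [lifestyle_variable()]), untransformed.
#' @export
simulate_exposure <- function(config, missing_mask = NULL) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  kd <- parse_exposure_kind(config$exposure_kind)
  n <- config$n_samples
  e <- switch(kd$kind,
    continuous = stats::rnorm(n),
    ordinal = as.numeric(sample.int(kd$k, n, replace = TRUE)),
    binary = as.numeric(stats::rbinom(n, 1L, kd$prevalence))
  )
  if (!is.null(missing_mask)) {
    stopifnot(is.logical(missing_mask), length(missing_mask) == n)
    e[missing_mask] <- NA_real_
  }
  lifestyle_variable(name = "exposure", kind = kd$kind, raw = e)
}

#' Simulate a phenotype with exactly controlled variance components
#'
#' Causal genotype columns and the exposure are standardized; raw effect
#' sizes are i.i.d. normal; the additive, interaction and exposure-main
#' component vectors are each rescaled so their realized sample variance
#' equals `h2_additive`, `h2_gxe` and `var_exposure_main` exactly, and the
#' Gaussian noise is rescaled to the remaining fraction, so the phenotype
#' has unit sample variance up to component cross-covariances.  Exact
#' rescaling removes one layer of Monte-Carlo noise from parameter-recovery
#' experiments.
#'
#' Covariates, when requested, are independent standard normals with zero
#' true effect: they exercise the downstream adjustment code, not the
#' signal.
#'
#' @param genotypes a `genotype_matrix`.
#' @param exposure a `lifestyle_variable` (no missing values).
#' @param config the [sim_config()] that generated both.
#' @return an object of class `gxe_cohort`: list with `genotypes`,
#'   `exposure`, `covariates` (n x k matrix or NULL), `phenotype`, and
#'   `truth` (causal indices, effects on the standardized scale, realized
#'   variance fractions).
#' @export
simulate_phenotype <- function(genotypes, exposure, config) {
  validate_sim_config(config)
  G <- genotypes$dosage
  e <- exposure_values(exposure)
  n <- nrow(G)
  stopifnot(n == config$n_samples, length(e) == n)
  if (anyNA(e)) stop("exposure has missing values; mask rows upstream",
                     call. = FALSE)
  set.seed(config$seed + 2L)

  idx_add <- sort(sample.int(ncol(G), config$n_causal_additive))
  idx_gxe <- if (config$overlap_causal &&
                 config$n_causal_gxe <= config$n_causal_additive) {
    sort(sample(idx_add, config$n_causal_gxe))
  } else {
    sort(sample.int(ncol(G), config$n_causal_gxe))
  }
  b_raw <- stats::rnorm(length(idx_add))
  c_raw <- stats::rnorm(length(idx_gxe))
  eps <- stats::rnorm(n)
  covariates <- if (config$n_covariates > 0L) {
    matrix(stats::rnorm(n * config$n_covariates), n, config$n_covariates,
           dimnames = list(NULL, paste0("COV", seq_len(config$n_covariates))))
  } else NULL

  et <- standardize(e)
  u_add <- drop(standardize_columns(G[, idx_add, drop = FALSE]) %*% b_raw)
  u_gxe <- drop((standardize_columns(G[, idx_gxe, drop = FALSE]) * et) %*% c_raw)

  r_add <- rescale_to(u_add, config$h2_additive)
  r_gxe <- rescale_to(u_gxe, config$h2_gxe)
  r_env <- rescale_to(et, config$var_exposure_main)
  h2_noise <- 1 - config$h2_additive - config$h2_gxe - config$var_exposure_main
  r_eps <- rescale_to(eps, h2_noise)

  y <- r_add$u + r_gxe$u + r_env$u + r_eps$u

  truth <- list(
    idx_additive = idx_add,
    idx_gxe = idx_gxe,
    beta_additive = b_raw * r_add$scale,
    beta_gxe = c_raw * r_gxe$scale,
    gamma_exposure = r_env$scale,
    realized = c(h2_additive = stats::var(r_add$u),
                 h2_gxe = stats::var(r_gxe$u),
                 var_exposure_main = stats::var(r_env$u),
                 var_noise = stats::var(r_eps$u))
  )
  structure(list(genotypes = genotypes, exposure = exposure,
                 covariates = covariates, phenotype = y, truth = truth,
                 config = config),
            class = "gxe_cohort")
}

# rescale a vector so its sample variance is exactly v (zero vector if v == 0)
rescale_to <- function(u, v) {
  if (v == 0) return(list(u = u * 0, scale = 0))
  s <- stats::var(u)
  if (s <= 0) stop("cannot rescale a constant component vector", call. = FALSE)
  sc <- sqrt(v / s)
  list(u = u * sc, scale = sc)
}

standardize <- function(x) {
  s <- stats::sd(x)
  if (s == 0) stop("constant vector cannot be standardized", call. = FALSE)
  (x - mean(x)) / s
}

standardize_columns <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd)
  if (any(sd == 0))
    stop("monomorphic causal variant cannot be standardized", call. = FALSE)
  sweep(sweep(X, 2L, mu, "-"), 2L, sd, "/")
}

#' @export
print.gxe_cohort <- function(x, ...) {
  cat(sprintf("gxe_cohort: n=%d, M=%d, exposure kind=%s\n",
              length(x$phenotype), ncol(x$genotypes$dosage),
              x$exposure$kind))
  cat("realized variance fractions:\n")
  print(round(x$truth$realized, 6))
  invisible(x)
}

#' Simulate a complete cohort in one call
#'
#' Convenience wrapper chaining [simulate_genotypes()],
#' [simulate_exposure()] and [simulate_phenotype()].
#'
#' @param config a [sim_config()] object.
#' @return a `gxe_cohort`.
#' @export
simulate_cohort <- function(config) {
  g <- simulate_genotypes(config)
  e <- simulate_exposure(config)
  simulate_phenotype(g, e, config)
}
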