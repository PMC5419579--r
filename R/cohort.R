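#' Draw a diploid cohort with imputation-like dosage noise
#'
#' Pairs haplotypes sampled with replacement from a reference panel into
#' diploid genotypes, then emulates genotype imputation by degrading the
#' hard genotypes to dosages whose empirical info score — the ratio of
#' dosage variance to the binomial variance 2f(1-f) — approaches
#' `info_target`. The dosage is the posterior mean of the genotype given a
#' Gaussian-corrupted signal, `d = E[g | g + eta]` under the
#' `Binomial(2, f)` population prior, with the noise SD solved per variant
#' so the expected variance ratio equals the target. Posterior-mean dosages
#' lie in (0, 2), satisfy `cov(d, g) = Var(d)` — so the per-variant
#' regression slope stays unbiased while its sampling variance inflates by
#' 1/info, the way dosages from an imputation engine behave. Hard genotypes
#' are masked at `missing_rate` to drive the call-rate filter.
#'
#' @param panel a `HaplotypePanel`.
#' @param n_ind number of individuals; haplotypes are sampled with
#'   replacement so `n_ind` may exceed half the panel size.
#' @param info_target per-variant imputation quality in `(0, 1]`; scalar or
#'   length-M vector. 1 means dosages equal hard genotypes exactly.
#' @param missing_rate fraction of hard-genotype entries masked (dosages are
#'   never missing, as with imputed data).
#' @param seed integer seed.
#'
#' @return a `CohortGenotypes` list: `dosages` (N x M, in \[0,2\]),
#'   `hard_genotypes` (N x M integer, NA where masked), `info`, `eaf`,
#'   `call_rate` per variant, plus the source panel's `variant_ids`,
#'   `positions_bp`, `alleles`, `cM` and `chromosome`.
#' @export
draw_cohort <- function(panel, n_ind, info_target = 1, missing_rate = 0,
                        seed = 1L) {
  stopifnot(inherits(panel, "HaplotypePanel"))
  if (any(info_target <= 0) || any(info_target > 1))
    stop("info_target must be in (0, 1]")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  H <- panel$haplotypes
  m <- ncol(H)
  info_target <- rep_len(info_target, m)
  i1 <- sample.int(nrow(H), n_ind, replace = TRUE)
  i2 <- sample.int(nrow(H), n_ind, replace = TRUE)
  G <- H[i1, , drop = FALSE] + H[i2, , drop = FALSE]
  storage.mode(G) <- "integer"
  f <- colMeans(G) / 2
  v <- 2 * f * (1 - f)
  t_ <- info_target
  if (all(t_ == 1)) {
    D <- G + 0
  } else {
    D <- G + 0
    noise <- matrix(stats::rnorm(n_ind * m), n_ind, m)
    for (j in seq_len(m)) {
      if (t_[j] == 1 || v[j] == 0) next
      tau <- .info_noise_sd(f[j], t_[j])
      s <- G[, j] + tau * noise[, j]
      D[, j] <- .dosage_posterior_mean(s, f[j], tau)
    }
  }
  hard <- G
  if (missing_rate > 0) {
    mask <- matrix(stats::runif(n_ind * m) < missing_rate, n_ind, m)
    hard[mask] <- NA_integer_
  }
  info_emp <- apply(D, 2, stats::var) / ifelse(v > 0, v, NA_real_)
  info_emp[!is.finite(info_emp)] <- 0
  info_emp <- pmin(info_emp, 1)
  structure(
    list(dosages = D,
         hard_genotypes = hard,
         info = info_emp,
         eaf = colMeans(D) / 2,
         call_rate = colMeans(!is.na(hard)),
         variant_ids = panel$variant_ids,
         positions_bp = panel$positions_bp,
         alleles = panel$alleles,
         cM = panel$cM,
         chromosome = panel$chromosome),
    class = "CohortGenotypes")
}

#' @export
print.CohortGenotypes <- function(x, ...) {
  cat(sprintf("CohortGenotypes: %d individuals x %d variants, mean info %.3f\n",
              nrow(x$dosages), ncol(x$dosages), mean(x$info)))
  invisible(x)
}

# posterior mean E[g | s] with g ~ Binomial(2, f) and s | g ~ N(g, tau^2)
.dosage_posterior_mean <- function(s, f, tau) {
  pg <- stats::dbinom(0:2, 2, f)
  w0 <- pg[1] * stats::dnorm(s, 0, tau)
  w1 <- pg[2] * stats::dnorm(s, 1, tau)
  w2 <- pg[3] * stats::dnorm(s, 2, tau)
  (w1 + 2 * w2) / (w0 + w1 + w2)
}

# expected info ratio Var(d)/(2f(1-f)) for a given noise SD, by quadrature
.info_expected <- function(f, tau, nodes = 25L) {
  gh_x <- seq(-4, 4, length.out = nodes)
  gh_w <- stats::dnorm(gh_x); gh_w <- gh_w / sum(gh_w)
  pg <- stats::dbinom(0:2, 2, f)
  ed2 <- 0
  for (g in 0:2) {
    d <- .dosage_posterior_mean(g + tau * gh_x, f, tau)
    ed2 <- ed2 + pg[g + 1] * sum(gh_w * d^2)
  }
  v <- 2 * f * (1 - f)
  (ed2 - (2 * f)^2) / v
}

# solve the noise SD giving the requested expected info ratio
.info_noise_sd <- function(f, target) {
  stats::uniroot(function(lt) .info_expected(f, exp(lt)) - target,
                 lower = -7, upper = 4, tol = 1e-4)$root |> exp()
}

#' Simulate a standard-normal phenotype with controlled variance explained
#'
#' Builds `y = sum_c sqrt(q_c) * x_c_std + C gamma + e`, where `x_c_std` is
#' the standardized dosage of causal variant c, so each causal explains its
#' specified fraction `q_c` of trait variance. On the allele-dosage scale
#' this corresponds to the effect size `beta = sqrt(q / (2 f (1-f)))` SD
#' units. Residual variance is set to `1 - sum(q) - var(C gamma)` so the
#' phenotype has unit variance in expectation.
#'
#' @param cohort a `CohortGenotypes`.
#' @param causal_indices variant column indices of the causal variants
#'   (may be empty).
#' @param variance_explained vector `q` of per-causal trait-variance
#'   fractions; recycled against `causal_indices`. `sum(q) < 1` required.
#' @param covariates optional numeric matrix (N x K) of covariates.
#' @param covariate_effects length-K linear effects for `covariates`.
#' @param seed integer seed.
#'
#' @return numeric phenotype vector of length N with attribute
#'   `"beta_sd"` carrying the causal effects in SD units per copy.
#' @export
simulate_phenotype <- function(cohort, causal_indices = integer(0),
                               variance_explained = numeric(0),
                               covariates = NULL, covariate_effects = NULL,
                               seed = 1L) {
  stopifnot(inherits(cohort, "CohortGenotypes"))
  n <- nrow(cohort$dosages)
  causal_indices <- as.integer(causal_indices)
  if (length(causal_indices) > 0) {
    if (any(causal_indices < 1 | causal_indices > ncol(cohort$dosages)))
      stop("causal index out of range")
    q <- rep_len(variance_explained, length(causal_indices))
    if (sum(q) >= 1) stop("total variance explained must be < 1")
  } else q <- numeric(0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  g_part <- numeric(n)
  beta_sd <- numeric(length(causal_indices))
  for (k in seq_along(causal_indices)) {
    x <- cohort$dosages[, causal_indices[k]]
    sdx <- stats::sd(x)
    if (sdx == 0) stop("causal variant is monomorphic in the cohort")
    g_part <- g_part + sqrt(q[k]) * (x - mean(x)) / sdx
    beta_sd[k] <- sqrt(q[k]) / sdx
  }
  c_part <- numeric(n)
  cov_var <- 0
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (is.null(covariate_effects) ||
        length(covariate_effects) != ncol(covariates))
      stop("covariate_effects must match ncol(covariates)")
    c_part <- drop(covariates %*% covariate_effects)
    cov_var <- stats::var(c_part)
  }
  resid_var <- 1 - sum(q) - cov_var
  if (resid_var <= 0)
    stop("genetic + covariate variance exceeds 1; shrink q or effects")
  y <- g_part + c_part + stats::rnorm(n, 0, sqrt(resid_var))
  attr(y, "beta_sd") <- beta_sd
  y
}

#' Per-variant association scan
#'
#' Regresses a (residualized, inverse-normal transformed) phenotype on the
#' allele dosage of each variant, one variant at a time under an additive
#' model, optionally within strata (e.g. sex). When raw covariates are
#' supplied the phenotype is residualized on them and inverse-normal
#' transformed within each stratum first. Computation is the closed-form
#' simple-regression solution, vectorized across variants.
#'
#' @param cohort a `CohortGenotypes`.
#' @param phenotype numeric vector, length N.
#' @param covariates optional covariate matrix to residualize on (adds an
#'   intercept); `NULL` means the phenotype is used as given.
#' @param strata optional factor/vector of stratum labels; strata with
#'   fewer than 10 individuals are skipped with a warning.
#' @param transform apply the rank-based inverse-normal transform after
#'   residualization (default `TRUE` when `covariates` supplied).
#' @param min_stratum_n smallest analyzable stratum (default 10).
#'
#' @return a `SumStatsTable` (data.table) with one row per variant per
#'   stratum: `variant_id, chr, pos, effect_allele, other_allele, eaf, beta,
#'   se, p, n, info, stratum`. The effect allele is the panel alt allele.
#' @export
gwas_scan <- function(cohort, phenotype, covariates = NULL, strata = NULL,
                      transform = !is.null(covariates),
                      min_stratum_n = 10L) {
  stopifnot(inherits(cohort, "CohortGenotypes"))
  n <- nrow(cohort$dosages)
  if (length(phenotype) != n) stop("phenotype length must equal cohort size")
  if (is.null(strata)) strata <- rep("all", n)
  strata <- as.character(strata)
  out <- list()
  for (s in unique(strata)) {
    idx <- which(strata == s)
    if (length(idx) < min_stratum_n) {
      warning(sprintf("stratum '%s' has %d < %d individuals; skipped",
                      s, length(idx), min_stratum_n))
      next
    }
    y <- phenotype[idx]
    if (!is.null(covariates))
      y <- residualize(y, as.matrix(covariates)[idx, , drop = FALSE])
    if (transform) y <- inverse_normal_transform(y)
    X <- cohort$dosages[idx, , drop = FALSE]
    res <- .fast_simple_regression(X, y)
    out[[s]] <- data.table::data.table(
      variant_id = cohort$variant_ids,
      chr = cohort$chromosome,
      pos = cohort$positions_bp,
      effect_allele = cohort$alleles$alt,
      other_allele = cohort$alleles$ref,
      eaf = colMeans(X) / 2,
      beta = res$beta, se = res$se, p = res$p,
      n = length(idx),
      info = cohort$info,
      stratum = s)
  }
  if (length(out) == 0) stop("no stratum large enough to analyze")
  data.table::rbindlist(out)
}

# closed-form y ~ x per column of X; two-sided p from t with n-2 df
.fast_simple_regression <- function(X, y) {
  n <- length(y)
  yc <- y - mean(y)
  xm <- colMeans(X)
  Sxx <- colSums(X^2) - n * xm^2
  Sxy <- drop(crossprod(X, yc))
  Syy <- sum(yc^2)
  beta <- ifelse(Sxx > 0, Sxy / Sxx, NA_real_)
  rss <- pmax(Syy - beta * Sxy, 0)
  se <- ifelse(Sxx > 0, sqrt(rss / ((n - 2) * Sxx)), NA_real_)
  tstat <- beta / se
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  # a monomorphic or exact-fit variant yields p = NA; keep as NA
  list(beta = beta, se = se, p = p)
}
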