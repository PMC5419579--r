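#' Residualize a trait on covariates
#'
#' Ordinary least squares of the trait on the covariates plus an intercept;
#' returns the residuals. This is the first step of the standard quantitative
#' trait preparation (e.g. BMI regressed on age, age squared, principal
#' components and study site), performed separately by stratum upstream.
#'
#' @param y numeric trait vector.
#' @param covariates numeric matrix (N x K), or `NULL` for intercept only.
#' @return residual vector orthogonal to the intercept and every covariate.
#' @export
residualize <- function(y, covariates = NULL) {
  n <- length(y)
  X <- cbind(intercept = rep(1, n))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) stop("covariate rows must match length(y)")
    X <- cbind(X, covariates)
  }
  qr_X <- qr(X)
  if (qr_X$rank < ncol(X)) {
    dropped <- colnames(X)[qr_X$pivot[(qr_X$rank + 1):ncol(X)]]
    if (is.null(dropped)) dropped <- as.character(qr_X$pivot[(qr_X$rank + 1):ncol(X)])
    stop("rank-deficient covariate design; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  qr.resid(qr_X, y)
}

#' Rank-based inverse-normal transform
#'
#' Maps values to standard-normal quantiles of their Blom-offset ranks,
#' `qnorm((rank - 3/8) / (n + 1/4))`, with average ranks for ties. The
#' result has mean ~0 and SD ~1, is rank-preserving, and is invariant to
#' any strictly monotone transform of the input.
#'
#' @param values numeric vector with at least 2 distinct values.
#' @return transformed vector on the standard-normal scale.
#' @export
inverse_normal_transform <- function(values) {
  if (length(unique(values[!is.na(values)])) < 2)
    stop("inverse-normal transform needs >= 2 distinct values")
  n <- sum(!is.na(values))
  r <- rank(values, na.last = "keep", ties.method = "average")
  stats::qnorm((r - 3 / 8) / (n + 1 / 4))
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Conditional on the observed allele counts, enumerates every possible
#' heterozygote count, computes its probability under Hardy-Weinberg
#' proportions, and sums the probabilities of all tables as or less likely
#' than the observed one (two-sided exact test).
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts (non-negative, total
#'   >= 1).
#' @return exact p-value in `(0, 1]`.
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(counts < 0)) stop("genotype counts must be non-negative")
  n <- sum(counts)
  if (n < 1) stop("total genotype count must be >= 1")
  n_a <- 2 * n_hom_alt + n_het    # minor-side allele count, symmetric anyway
  n_b <- 2 * n_hom_ref + n_het
  rare <- min(n_a, n_b)
  # possible heterozygote counts share the parity of the rare allele count
  hets <- seq(rare %% 2, rare, by = 2)
  # Levene/Haldane probability of each het count given the allele counts:
  # P(h) = n! 2^h / (h! ((rare-h)/2)! ((2n-rare-h)/2)!) * rare!(2n-rare)!/(2n)!
  logp <- vapply(hets, function(h) {
    ra <- (rare - h) / 2
    cb <- (2 * n - rare - h) / 2
    lgamma(n + 1) - lgamma(h + 1) - lgamma(ra + 1) - lgamma(cb + 1) +
      h * log(2) + lgamma(rare + 1) + lgamma(2 * n - rare + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- which(hets == n_het)
  if (length(obs) != 1) stop("observed het count inconsistent with allele counts")
  min(1, sum(p[p <= p[obs] * (1 + 1e-12)]))
}

#' QC thresholds
#'
#' The per-variant filter set used before meta-analysis: call rate >= 0.95,
#' minor allele count > 6 (MAC <= 6 excluded), Hardy-Weinberg exact
#' p >= 1e-4, imputation info >= 0.3 (minimac dialect) or >= 0.4 (IMPUTE
#' dialect), and absolute difference <= 0.3 between the observed effect-
#' allele frequency and the admixture-expected frequency
#' `w_afr * f_AFR + w_eur * f_EUR` (defaults 0.8/0.2 for African-American
#' cohorts).
#'
#' @param min_call_rate minimum call rate (default 0.95).
#' @param max_mac_excluded largest excluded minor-allele count (default 6).
#' @param hwe_p_min smallest acceptable HWE p (default 1e-4).
#' @param info_min minimum info score, minimac dialect (default 0.3).
#' @param info_min_impute minimum info score, IMPUTE dialect (default 0.4).
#' @param max_freq_diff largest tolerated |EAF - expected| (default 0.3).
#' @param admixture_weights named vector `c(afr=, eur=)` summing to 1.
#' @return a `QCThresholds` list.
#' @export
qc_thresholds <- function(min_call_rate = 0.95, max_mac_excluded = 6L,
                          hwe_p_min = 1e-4, info_min = 0.3,
                          info_min_impute = 0.4, max_freq_diff = 0.3,
                          admixture_weights = c(afr = 0.8, eur = 0.2)) {
  stopifnot(min_call_rate >= 0, min_call_rate <= 1,
            max_mac_excluded >= 0, hwe_p_min > 0, hwe_p_min < 1,
            info_min >= 0, info_min <= 1,
            info_min_impute >= 0, info_min_impute <= 1,
            max_freq_diff >= 0, max_freq_diff <= 1,
            abs(sum(admixture_weights) - 1) < 1e-8)
  structure(list(min_call_rate = min_call_rate,
                 max_mac_excluded = as.integer(max_mac_excluded),
                 hwe_p_min = hwe_p_min, info_min = info_min,
                 info_min_impute = info_min_impute,
                 max_freq_diff = max_freq_diff,
                 admixture_weights = admixture_weights),
            class = "QCThresholds")
}

#' Per-variant QC verdict
#'
#' Evaluates every filter and returns all violated ones, not just the first.
#' The expected-frequency filter compares the observed effect-allele
#' frequency against the admixture-weighted reference frequency; if either
#' reference frequency is missing that filter is skipped with a warning.
#'
#' @param call_rate,mac,hwe_p,info,eaf the variant's per-cohort statistics.
#' @param dialect `"minimac"` (info cutoff 0.3) or `"impute"` (0.4).
#' @param ref_afr_freq,ref_eur_freq reference-panel effect-allele
#'   frequencies, or `NA` to skip the frequency filter.
#' @param thresholds a `QCThresholds` object.
#' @return a `QCVerdict` list with `passed` (logical) and `reasons`
#'   (character vector of failed-filter tags, empty iff passed).
#' @export
variant_qc <- function(call_rate, mac, hwe_p, info, eaf,
                       dialect = c("minimac", "impute"),
                       ref_afr_freq = NA, ref_eur_freq = NA,
                       thresholds = qc_thresholds()) {
  dialect <- match.arg(dialect)
  th <- thresholds
  reasons <- character(0)
  if (call_rate < th$min_call_rate) reasons <- c(reasons, "call_rate")
  if (mac <= th$max_mac_excluded) reasons <- c(reasons, "mac")
  if (hwe_p < th$hwe_p_min) reasons <- c(reasons, "hwe")
  info_cut <- if (dialect == "impute") th$info_min_impute else th$info_min
  if (info < info_cut) reasons <- c(reasons, "info")
  if (is.na(ref_afr_freq) || is.na(ref_eur_freq)) {
    warning("reference frequency missing; expected-frequency filter skipped")
  } else {
    expected <- th$admixture_weights[["afr"]] * ref_afr_freq +
      th$admixture_weights[["eur"]] * ref_eur_freq
    if (abs(eaf - expected) > th$max_freq_diff)
      reasons <- c(reasons, "freq_diff")
  }
  structure(list(passed = length(reasons) == 0, reasons = reasons),
            class = "QCVerdict")
}

#' Genomic-control lambda and correction
#'
#' `lambda = median(chi2) / qchisq(0.5, 1)` (the 1-df chi-square median,
#' 0.4549). Correction divides every statistic by `max(lambda, 1)`: inflated
#' scans are deflated to a median at the null expectation, but a lambda
#' below 1 is reported as-is and never used to inflate the statistics.
#'
#' @param chi2_stats non-negative association chi-square statistics.
#' @return list with `lambda` (uncapped) and `corrected` (vector).
#' @export
genomic_control <- function(chi2_stats) {
  if (length(chi2_stats) == 0) stop("empty statistic vector")
  if (any(chi2_stats < 0, na.rm = TRUE)) stop("chi-square statistics must be >= 0")
  lambda <- stats::median(chi2_stats, na.rm = TRUE) / stats::qchisq(0.5, df = 1)
  list(lambda = lambda, corrected = chi2_stats / max(lambda, 1))
}

#' Apply genomic control to a summary-statistics table
#'
#' Converts p-values to 1-df chi-squares, computes lambda, and when lambda
#' exceeds 1 inflates every standard error by `sqrt(lambda)` (equivalently
#' divides chi-square by lambda), recomputing p-values.
#'
#' @param sumstats a `SumStatsTable` with `beta`, `se`, `p` columns.
#' @return the table with corrected `se`/`p` and attribute `"lambda"`.
#' @export
gc_correct_sumstats <- function(sumstats) {
  ss <- data.table::as.data.table(sumstats)
  chi2 <- stats::qchisq(ss$p, df = 1, lower.tail = FALSE)
  gc <- genomic_control(chi2[is.finite(chi2)])
  if (gc$lambda > 1) {
    ss[, se := se * sqrt(gc$lambda)]
    ss[, p := 2 * stats::pnorm(abs(beta / se), lower.tail = FALSE)]
  }
  data.table::setattr(ss, "lambda", gc$lambda)
  ss
}
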