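#' Inverse-variance weighted fixed-effect meta-analysis
#'
#' Combines per-study effect estimates with weights `w = 1/se^2`:
#' `beta_hat = sum(w * beta) / sum(w)`, `SE = 1/sqrt(sum(w))`, two-sided p
#' from the normal (the METAL convention). Heterogeneity is summarized by
#' Cochran's Q, its p-value, and `I^2 = max(0, (Q - df)/Q) * 100`.
#'
#' @param beta per-study effects (SD units per effect-allele copy).
#' @param se per-study standard errors (> 0).
#' @param n optional per-study sample sizes (summed into `n_total`).
#' @return a `MetaResult` list: `beta`, `se`, `z`, `p`, `q_stat`, `df`,
#'   `i2` (0-100), `p_het`, `n_total`, `n_studies`.
#' @export
ivw_meta <- function(beta, se, n = NULL) {
  keep <- is.finite(beta) & is.finite(se) & se > 0
  beta <- beta[keep]; se <- se[keep]
  if (!is.null(n)) n <- n[keep]
  if (length(beta) == 0) stop("no studies with finite beta and se")
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  s <- 1 / sqrt(sum(w))
  z <- b / s
  k <- length(beta)
  if (k >= 2) {
    q <- sum(w * (beta - b)^2)
    df <- k - 1
    i2 <- max(0, (q - df) / q) * 100
    p_het <- stats::pchisq(q, df, lower.tail = FALSE)
  } else {
    q <- 0; df <- 0; i2 <- 0; p_het <- NA_real_
  }
  structure(list(beta = b, se = s, z = z,
                 p = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
                 q_stat = q, df = df, i2 = i2, p_het = p_het,
                 n_total = if (is.null(n)) NA_real_ else sum(n),
                 n_studies = k),
            class = "MetaResult")
}

#' @export
print.MetaResult <- function(x, ...) {
  cat(sprintf("MetaResult: beta %.4g (SE %.4g), z %.3f, p %.3g, k=%d, I2=%.1f\n",
              x$beta, x$se, x$z, x$p, x$n_studies, x$i2))
  invisible(x)
}

#' Sample-size weighted fixed-effect z-score meta-analysis
#'
#' Combines signed z-scores with weights `w_i = sqrt(N_i)`:
#' `z = sum(w_i z_i) / sqrt(sum(w_i^2))`. Used when per-study betas and SEs
#' are unavailable (e.g. one input stream carries only LD-imputed z-scores).
#'
#' @param z per-study signed z-scores.
#' @param n per-study sample sizes (> 0).
#' @return list with `z`, `p` (two-sided normal), `n_total`.
#' @export
samplesize_meta <- function(z, n) {
  keep <- is.finite(z) & is.finite(n)
  z <- z[keep]; n <- n[keep]
  if (length(z) == 0) stop("no studies with finite z and n")
  if (any(n <= 0)) stop("sample sizes must be positive")
  w <- sqrt(n)
  zc <- sum(w * z) / sqrt(sum(w^2))
  list(z = zc, p = 2 * stats::pnorm(abs(zc), lower.tail = FALSE),
       n_total = sum(n))
}

#' Between-study heterogeneity statistics
#'
#' Cochran's Q with inverse-variance weights, its degrees of freedom and
#' p-value, and the `I^2` statistic on the 0-100 scale. Also the test used
#' for male-female effect differences at nominal `p_het < 0.05`.
#'
#' @param beta,se per-study effects and standard errors (>= 2 studies).
#' @return list with `q_stat`, `df`, `i2`, `p_het`.
#' @export
heterogeneity <- function(beta, se) {
  keep <- is.finite(beta) & is.finite(se) & se > 0
  beta <- beta[keep]; se <- se[keep]
  if (length(beta) < 2) stop("heterogeneity needs >= 2 studies")
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  q <- sum(w * (beta - b)^2)
  df <- length(beta) - 1
  list(q_stat = q, df = df,
       i2 = if (q > 0) max(0, (q - df) / q) * 100 else 0,
       p_het = stats::pchisq(q, df, lower.tail = FALSE))
}

#' Sex-difference test for a variant
#'
#' Cochran's Q between the male and female stratum effects; a difference is
#' declared at nominal `p_het < 0.05`.
#'
#' @param beta_m,se_m male-stratum effect and SE.
#' @param beta_f,se_f female-stratum effect and SE.
#' @param alpha nominal level (default 0.05).
#' @return list with the heterogeneity statistics plus `different` (logical).
#' @export
sex_difference_test <- function(beta_m, se_m, beta_f, se_f, alpha = 0.05) {
  h <- heterogeneity(c(beta_m, beta_f), c(se_m, se_f))
  h$different <- is.finite(h$p_het) && h$p_het < alpha
  h
}

#' Record-level exclusions before and after combination
#'
#' Drops study inputs with `|beta| >= 10` or `se >= 10` (artifacts of tiny
#' strata or minor-allele counts) before combining, and drops combined
#' records whose total sample size is below 50% of the trait's full sample.
#'
#' @param records data.table with at least `beta`, `se`, `n` columns.
#' @param trait_total_n total sample size for the trait; `NULL` skips the
#'   50%-of-N rule.
#' @return list with `kept` and `removed` (with `reason` column:
#'   `"extreme_beta"`, `"extreme_se"`, `"low_n"`).
#' @export
meta_filters <- function(records, trait_total_n = NULL) {
  rec <- data.table::as.data.table(records)
  reason <- rep(NA_character_, nrow(rec))
  if ("beta" %in% names(rec))
    reason[is.na(reason) & is.finite(rec$beta) & abs(rec$beta) >= 10] <- "extreme_beta"
  if ("se" %in% names(rec))
    reason[is.na(reason) & is.finite(rec$se) & rec$se >= 10] <- "extreme_se"
  if (!is.null(trait_total_n) && "n" %in% names(rec))
    reason[is.na(reason) & rec$n < 0.5 * trait_total_n] <- "low_n"
  keep <- is.na(reason)
  removed <- rec[!keep]
  if (nrow(removed)) removed[, reason := reason[!keep]] else removed[, reason := character(0)]
  list(kept = rec[keep], removed = removed)
}

#' Meta-analyze per-study summary-statistics tables
#'
#' Inverse-variance combination of several aligned `SumStatsTable`s, one row
#' per variant key, applying the extreme-value exclusions first and the
#' 50%-of-N rule after combination. Genomic control can be applied to each
#' study before and to the result after (double GC).
#'
#' @param studies list of `SumStatsTable`s with shared variant keys.
#' @param trait_total_n total trait sample size for the 50% rule (default:
#'   sum of per-study maxima).
#' @param gc_pre,gc_post apply genomic control per study / to the result.
#' @return data.table keyed by variant with combined `beta`, `se`, `z`, `p`,
#'   `n`, heterogeneity columns and `n_studies`; attributes `lambda_pre`
#'   (per-study vector) and `lambda_post`.
#' @export
meta_analyze_studies <- function(studies, trait_total_n = NULL,
                                 gc_pre = TRUE, gc_post = TRUE) {
  stopifnot(length(studies) >= 1)
  lambda_pre <- numeric(length(studies))
  prepped <- vector("list", length(studies))
  for (i in seq_along(studies)) {
    ss <- data.table::as.data.table(studies[[i]])
    if (gc_pre) {
      ss <- gc_correct_sumstats(ss)
      lambda_pre[i] <- attr(ss, "lambda")
    } else lambda_pre[i] <- NA_real_
    ss <- meta_filters(ss)$kept
    ss[, study := i]
    prepped[[i]] <- ss
  }
  all_ss <- data.table::rbindlist(prepped, fill = TRUE)
  key_cols <- c("variant_id", "chr", "pos", "effect_allele", "other_allele")
  key_cols <- intersect(key_cols, names(all_ss))
  combined <- all_ss[, {
    m <- ivw_meta(beta, se, n)
    list(eaf = if ("eaf" %in% names(.SD)) sum(eaf * n) / sum(n) else NA_real_,
         beta = m$beta, se = m$se, z = m$z, p = m$p,
         q_stat = m$q_stat, df = m$df, i2 = m$i2, p_het = m$p_het,
         n = m$n_total, n_studies = m$n_studies)
  }, by = key_cols]
  if (is.null(trait_total_n))
    trait_total_n <- sum(vapply(prepped, function(s) max(s$n), numeric(1)))
  combined <- meta_filters(combined, trait_total_n = trait_total_n)$kept
  lambda_post <- NA_real_
  if (gc_post && nrow(combined)) {
    combined <- gc_correct_sumstats(combined)
    combined[, z := beta / se]
    lambda_post <- attr(combined, "lambda")
  }
  data.table::setattr(combined, "lambda_pre", lambda_pre)
  data.table::setattr(combined, "lambda_post", lambda_post)
  combined[]
}

#' Parse and check METAL-style direction strings
#'
#' Direction strings like `"++-?"` give per-study effect signs. Each
#' non-missing character must agree with the sign of the corresponding
#' study z-score; disagreement is an error, not a silent fix.
#'
#' @param direction character vector of strings over `+`, `-`, `?`.
#' @param z_list list of per-study signed z-scores (one vector per record),
#'   or a matrix with one column per study.
#' @return invisible `TRUE` if all consistent; otherwise an error naming
#'   the first offending record.
#' @export
check_directions <- function(direction, z_list) {
  if (is.matrix(z_list)) z_list <- asplit(z_list, 1)
  stopifnot(length(direction) == length(z_list))
  for (i in seq_along(direction)) {
    ch <- strsplit(direction[i], "")[[1]]
    z <- z_list[[i]]
    if (length(ch) != length(z))
      stop(sprintf("record %d: direction string length %d != %d studies",
                   i, length(ch), length(z)))
    for (j in seq_along(ch)) {
      if (ch[j] == "?") { if (is.finite(z[j])) stop(sprintf(
        "record %d study %d: direction '?' but z present", i, j)); next }
      if (!is.finite(z[j]))
        stop(sprintf("record %d study %d: direction '%s' but z missing",
                     i, j, ch[j]))
      if ((ch[j] == "+") != (z[j] >= 0))
        stop(sprintf("record %d study %d: direction '%s' disagrees with z=%.3g",
                     i, j, ch[j], z[j]))
    }
  }
  invisible(TRUE)
}
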