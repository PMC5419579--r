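#' Harmonize summary statistics against a reference panel
#'
#' Aligns each record's effect/other alleles to the panel's ref/alt pair.
#' Palindromic variants (A/T or C/G) are removed outright — their strand
#' cannot be resolved from alleles alone — as are records whose allele pair
#' does not match the panel at that position. Records whose effect allele is
#' the panel ref (rather than alt) are flipped: alleles swapped, and the
#' signs of `beta` and/or `z` negated, with `eaf` complemented.
#'
#' @param sumstats a `SumStatsTable` (needs `chr`, `pos`, `effect_allele`,
#'   `other_allele`; `beta`/`z`/`eaf` adjusted when present).
#' @param panel a `HaplotypePanel`.
#' @return list with `aligned` (surviving records, effect allele = panel
#'   alt) and `removed` (records plus a `reason` column:
#'   `"palindromic"`, `"not_in_panel"`, or `"allele_mismatch"`).
#' @export
harmonize_alleles <- function(sumstats, panel) {
  ss <- data.table::as.data.table(sumstats)
  stopifnot(all(c("chr", "pos", "effect_allele", "other_allele") %in% names(ss)))
  ss[, effect_allele := toupper(effect_allele)]
  ss[, other_allele := toupper(other_allele)]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  pal <- ss$effect_allele == comp[ss$other_allele]
  key <- paste(ss$chr, ss$pos)
  pkey <- paste(panel$chromosome, panel$positions_bp)
  pidx <- match(key, pkey)
  in_panel <- !is.na(pidx)
  pref <- rep(NA_character_, nrow(ss)); palt <- pref
  pref[in_panel] <- panel$alleles$ref[pidx[in_panel]]
  palt[in_panel] <- panel$alleles$alt[pidx[in_panel]]
  straight <- in_panel & ss$effect_allele == palt & ss$other_allele == pref
  flipped  <- in_panel & ss$effect_allele == pref & ss$other_allele == palt
  reason <- rep(NA_character_, nrow(ss))
  reason[pal] <- "palindromic"
  reason[!pal & !in_panel] <- "not_in_panel"
  reason[!pal & in_panel & !straight & !flipped] <- "allele_mismatch"
  keep <- is.na(reason)
  aligned <- ss[keep]
  flip <- flipped[keep]
  if (any(flip)) {
    swap <- aligned$effect_allele[flip]
    aligned[flip, effect_allele := other_allele]
    aligned[which(flip), other_allele := swap]
    for (col in intersect(c("beta", "z"), names(aligned)))
      aligned[flip, (col) := -get(col)]
    if ("eaf" %in% names(aligned)) aligned[flip, eaf := 1 - eaf]
    if ("direction" %in% names(aligned))
      aligned[flip, direction := chartr("+-", "-+", direction)]
  }
  removed <- ss[!keep]
  removed[, reason := reason[!keep]]
  list(aligned = aligned, removed = removed)
}

#' Z-score panel for one imputation window
#'
#' Bundles the LD correlation matrix over a window's variants with the
#' observed z-scores and sample sizes, partitioned into observed and
#' unobserved variants.
#'
#' @param panel a `HaplotypePanel` restricted to the window.
#' @param observed_mask logical per variant: `TRUE` where a z-score was
#'   observed.
#' @param z z-scores for the observed variants (length `sum(observed_mask)`),
#'   aligned to the panel alt allele.
#' @param n sample sizes for the observed variants (same length as `z`).
#' @param window_bounds optional bp interval of the window core.
#' @return a `ZScorePanel` list with `sigma` computed as the haplotype
#'   correlation matrix (unit diagonal, so predicted accuracy lands in
#'   `[0, 1]`).
#' @export
zscore_panel <- function(panel, observed_mask, z, n,
                         window_bounds = range(panel$positions_bp)) {
  stopifnot(inherits(panel, "HaplotypePanel"),
            length(observed_mask) == ncol(panel$haplotypes),
            length(z) == sum(observed_mask),
            length(n) == sum(observed_mask))
  if (any(!is.finite(z))) stop("observed z-scores must be finite")
  structure(list(sigma = panel_ld(panel),
                 observed_mask = as.logical(observed_mask),
                 z = as.numeric(z), n = as.numeric(n),
                 variant_ids = panel$variant_ids,
                 positions_bp = panel$positions_bp,
                 window_bounds = window_bounds),
            class = "ZScorePanel")
}

#' Impute z-scores of unobserved variants from LD
#'
#' For each unobserved variant i, the imputed z-score is the best linear
#' predictor from the observed z-scores under the LD-induced covariance:
#' `z_hat_i = Sigma_{i,obs} (Sigma_{obs,obs} + ridge*I)^{-1} z_obs`, with
#' predicted accuracy
#' `r2pred_i = Sigma_{i,obs} (Sigma_{obs,obs} + ridge*I)^{-1} Sigma_{obs,i}`.
#' The sample size is interpolated with the LD weights:
#' `N_i = sum_t |w_{i,t}| N_t / sum_t |w_{i,t}|` where `w_{i,t}` is the LD
#' covariance between unobserved variant i and observed variant t.
#'
#' @param zpanel a `ZScorePanel`.
#' @param ridge diagonal regularization added to the observed-observed
#'   block (default 0.1, which also bounds imputed z-scores).
#' @return data.table with one row per unobserved variant: `variant_id`,
#'   `pos`, `z_hat`, `r2pred`, `n_interp`, `weights_row_sum`.
#' @export
impute_zscores <- function(zpanel, ridge = 0.1) {
  stopifnot(inherits(zpanel, "ZScorePanel"))
  obs <- zpanel$observed_mask
  if (!any(obs)) stop("no observed variants in window")
  if (all(obs)) {
    return(data.table::data.table(variant_id = character(0), pos = integer(0),
                                  z_hat = numeric(0), r2pred = numeric(0),
                                  n_interp = numeric(0),
                                  weights_row_sum = numeric(0)))
  }
  S <- zpanel$sigma
  Soo <- S[obs, obs, drop = FALSE]
  Suo <- S[!obs, obs, drop = FALSE]     # unobserved x observed
  A <- Soo + diag(ridge, nrow(Soo))
  ch <- tryCatch(chol(A), error = function(e)
    stop("observed LD block singular even after ridge"))
  # W: observed x unobserved solve, so z_hat = W' z and r2pred = colSums(Suo' * W)
  W <- backsolve(ch, forwardsolve(t(ch), t(Suo)))
  z_hat <- drop(crossprod(W, zpanel$z))
  r2pred <- colSums(t(Suo) * W)
  r2pred <- pmin(pmax(r2pred, 0), 1)
  absw <- abs(Suo)
  wsum <- rowSums(absw)
  n_interp <- ifelse(wsum > 0, drop(absw %*% zpanel$n) / wsum, NA_real_)
  data.table::data.table(variant_id = zpanel$variant_ids[!obs],
                         pos = zpanel$positions_bp[!obs],
                         z_hat = ifelse(wsum > 0, z_hat, 0),
                         r2pred = ifelse(wsum > 0, r2pred, 0),
                         n_interp = n_interp,
                         weights_row_sum = rowSums(abs(t(W))))
}

#' Filter imputed z-scores by predicted accuracy
#'
#' Keeps results whose `r2pred` meets the threshold (inclusive). The
#' conventional cutoff is 0.6.
#'
#' @param results data.table from [impute_zscores()].
#' @param r2pred_min minimum predicted accuracy (default 0.6).
#' @return the kept subset.
#' @export
filter_imputed <- function(results, r2pred_min = 0.6) {
  res <- data.table::as.data.table(results)
  res[r2pred >= r2pred_min]
}

#' Impute z-scores genome-wide in tiled windows
#'
#' Splits the panel into non-overlapping core windows (default 1 Mb) with
#' flanking buffers (default 250 kb) on each side; each unobserved variant
#' is imputed in the window whose core contains it, using all observed
#' variants within core + buffer.
#'
#' @param panel a `HaplotypePanel`.
#' @param observed data.table with `pos`, `z`, `n` for observed variants
#'   (aligned to the panel alt allele).
#' @param window_bp core window size (default 1e6).
#' @param buffer_bp flank added on each side for LD context (default 2.5e5).
#' @param ridge ridge passed to [impute_zscores()].
#' @return data.table of imputed results across all windows.
#' @export
impute_zscores_tiled <- function(panel, observed, window_bp = 1e6,
                                 buffer_bp = 2.5e5, ridge = 0.1) {
  obs_dt <- data.table::as.data.table(observed)
  stopifnot(all(c("pos", "z", "n") %in% names(obs_dt)))
  pos <- panel$positions_bp
  obs_mask_all <- pos %in% obs_dt$pos
  starts <- seq(min(pos), max(pos), by = window_bp)
  out <- list()
  for (s in starts) {
    core <- pos >= s & pos < s + window_bp
    win <- pos >= s - buffer_bp & pos < s + window_bp + buffer_bp
    if (!any(core & !obs_mask_all)) next
    idx <- which(win)
    sub <- panel_subset(panel, idx)
    om <- obs_mask_all[idx]
    if (!any(om)) next
    mo <- match(sub$positions_bp[om], obs_dt$pos)
    zp <- zscore_panel(sub, om, obs_dt$z[mo], obs_dt$n[mo],
                       window_bounds = c(s, s + window_bp - 1))
    res <- impute_zscores(zp, ridge = ridge)
    # report only unobserved variants inside the core
    core_pos <- pos[core & !obs_mask_all]
    out[[length(out) + 1]] <- res[pos %in% core_pos]
  }
  if (length(out) == 0)
    return(data.table::data.table(variant_id = character(0), pos = integer(0),
                                  z_hat = numeric(0), r2pred = numeric(0),
                                  n_interp = numeric(0),
                                  weights_row_sum = numeric(0)))
  data.table::rbindlist(out)
}
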