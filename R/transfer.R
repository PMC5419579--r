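#' Greedy locus assembly from significant variants
#'
#' Repeatedly takes the most significant unassigned variant below `sig_p`
#' as a lead and masks all variants within half the lead window on each
#' side, so each lead is the most significant variant within a 1 Mb region.
#' A locus is novel when its lead lies more than `novel_distance_bp` from
#' every established lead.
#'
#' @param genome_stats data.table with `variant_id`, `chr`, `pos`, `p`.
#' @param sig_p genome-wide significance threshold (default 5e-8).
#' @param lead_window_bp window defining one locus (default 1e6; masking
#'   extends `lead_window_bp / 2` each side).
#' @param novel_distance_bp novelty distance (default 5e5).
#' @param established data.table with `chr`, `pos` of established leads
#'   (may be empty).
#' @return data.table of loci: `variant_id`, `chr`, `pos`, `p`,
#'   `region_start`, `region_end`, `novel`, `n_masked`.
#' @export
define_loci <- function(genome_stats, sig_p = 5e-8, lead_window_bp = 1e6,
                        novel_distance_bp = 5e5,
                        established = NULL) {
  gs <- data.table::as.data.table(genome_stats)
  stopifnot(all(c("variant_id", "chr", "pos", "p") %in% names(gs)))
  sig <- gs[is.finite(p) & p < sig_p][order(p)]
  half <- lead_window_bp / 2
  loci <- list()
  while (nrow(sig) > 0) {
    lead <- sig[1]
    in_win <- sig$chr == lead$chr & abs(sig$pos - lead$pos) <= half
    novel <- TRUE
    if (!is.null(established) && nrow(established) > 0) {
      est <- data.table::as.data.table(established)
      same <- est[chr == lead$chr]
      if (nrow(same) > 0)
        novel <- min(abs(same$pos - lead$pos)) > novel_distance_bp
    }
    loci[[length(loci) + 1]] <- data.table::data.table(
      variant_id = lead$variant_id, chr = lead$chr, pos = lead$pos,
      p = lead$p,
      region_start = lead$pos - half, region_end = lead$pos + half,
      novel = novel, n_masked = sum(in_win) - 1L)
    sig <- sig[!in_win]
  }
  if (length(loci) == 0)
    return(data.table::data.table(variant_id = character(0), chr = character(0),
                                  pos = integer(0), p = numeric(0),
                                  region_start = numeric(0),
                                  region_end = numeric(0), novel = logical(0),
                                  n_masked = integer(0)))
  data.table::rbindlist(loci)
}

#' SNP-level transferability between ancestries
#'
#' Aligns the target record's effect allele to the source's (flipping the
#' effect sign when the alleles are swapped), then asks whether the same
#' allele raises the trait in both ancestries and whether the target
#' association is nominally significant.
#'
#' @param source_beta,source_ea,source_oa source-ancestry effect and
#'   effect/other alleles.
#' @param target_beta,target_p,target_ea,target_oa target-ancestry effect,
#'   p-value and alleles.
#' @param alpha nominal significance level (default 0.05).
#' @return list: `testable`, `directionally_consistent`, `transferable`
#'   (consistent AND target p < alpha), `aligned_target_beta`.
#' @export
snp_transferability <- function(source_beta, source_ea, source_oa,
                                target_beta, target_p, target_ea, target_oa,
                                alpha = 0.05) {
  source_ea <- toupper(source_ea); source_oa <- toupper(source_oa)
  target_ea <- toupper(target_ea); target_oa <- toupper(target_oa)
  if (target_ea == source_ea && target_oa == source_oa) {
    b <- target_beta
  } else if (target_ea == source_oa && target_oa == source_ea) {
    b <- -target_beta
  } else {
    return(list(testable = FALSE, directionally_consistent = NA,
                transferable = NA, aligned_target_beta = NA_real_))
  }
  consistent <- sign(b) == sign(source_beta) && sign(b) != 0
  list(testable = TRUE, directionally_consistent = consistent,
       transferable = consistent && is.finite(target_p) && target_p < alpha,
       aligned_target_beta = b)
}

#' Exact one-sided binomial sign test
#'
#' Upper-tail probability `P(X >= k)` for `X ~ Binomial(n, p0)`. Used to
#' ask whether the number of directionally consistent (p0 = 0.5) or
#' nominally significant (p0 = alpha) variants exceeds chance.
#'
#' @param k observed successes (0 <= k <= n).
#' @param n trials.
#' @param p0 null success probability in (0, 1).
#' @return exact one-sided p-value.
#' @export
binomial_sign_test <- function(k, n, p0) {
  if (k < 0 || k > n || n < 1) stop("need 0 <= k <= n, n >= 1")
  if (p0 <= 0 || p0 >= 1) stop("p0 must be in (0, 1)")
  if (k == 0) return(1)
  stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
}

#' Li-Ji effective number of independent tests
#'
#' From the eigenvalues of the variant correlation matrix:
#' `Meff = sum_i [ I(|lambda_i| >= 1) + (|lambda_i| - floor(|lambda_i|)) ]`.
#' Equals M for independent variants and collapses toward 1 as correlations
#' approach 1.
#'
#' @param R symmetric correlation matrix with unit diagonal.
#' @return the effective number of tests (1 <= Meff <= M).
#' @export
li_ji_meff <- function(R) {
  R <- as.matrix(R)
  if (nrow(R) != ncol(R)) stop("R must be square")
  if (max(abs(diag(R) - 1)) > 1e-8) stop("R must have unit diagonal")
  lam <- abs(eigen((R + t(R)) / 2, symmetric = TRUE, only.values = TRUE)$values)
  sum(ifelse(lam >= 1, 1, 0) + (lam - floor(lam)))
}

#' Locus-level transferability test
#'
#' Searches the candidate region (the flanking 0.1 cM of the source-ancestry
#' lead) for the most significant target-ancestry variant, and declares
#' locus-wide significance when that best p-value beats the Bonferroni
#' threshold `0.05 / Meff`, with Meff the Li-Ji effective number of tests
#' from the region's LD matrix.
#'
#' @param region_p target-ancestry p-values for the region variants.
#' @param R LD correlation matrix over the same variants.
#' @param variant_ids optional identifiers.
#' @param alpha locus-wide level before correction (default 0.05).
#' @return list: `best_variant`, `min_p`, `meff`, `threshold`,
#'   `significant`.
#' @export
locus_transferability <- function(region_p, R,
                                  variant_ids = as.character(seq_along(region_p)),
                                  alpha = 0.05) {
  if (length(region_p) == 0) stop("empty region")
  stopifnot(length(region_p) == nrow(as.matrix(R)))
  meff <- li_ji_meff(R)
  thr <- alpha / meff
  best <- which.min(region_p)
  list(best_variant = variant_ids[best], min_p = region_p[best],
       meff = meff, threshold = thr,
       significant = is.finite(region_p[best]) && region_p[best] < thr)
}

#' Effect size in SD units from variance explained
#'
#' For a variant with minor-allele frequency `maf` explaining fraction `q`
#' of the variance of a standardized trait, the additive per-allele effect
#' is `beta = sqrt(q / (2 maf (1 - maf)))` SD units; [varexp_from_effect()]
#' is the exact inverse.
#'
#' @param q variance-explained fraction in (0, 1).
#' @param maf minor-allele frequency in (0, 0.5].
#' @return effect size in SD units per allele copy.
#' @export
effect_from_varexp <- function(q, maf) {
  if (any(q <= 0) || any(q >= 1)) stop("q must be in (0, 1)")
  if (any(maf <= 0) || any(maf > 0.5)) stop("maf must be in (0, 0.5]")
  sqrt(q / (2 * maf * (1 - maf)))
}

#' @rdname effect_from_varexp
#' @param beta_sd effect size in SD units.
#' @export
varexp_from_effect <- function(beta_sd, maf) {
  if (any(maf <= 0) || any(maf > 0.5)) stop("maf must be in (0, 0.5]")
  2 * maf * (1 - maf) * beta_sd^2
}

#' Analytic power of a single-variant association test
#'
#' The association chi-square of a variant explaining fraction `q` of a
#' standardized trait's variance in `n` individuals is noncentral
#' chi-square with 1 df and noncentrality `n * q`; power at level `alpha`
#' is the probability of exceeding the central critical value.
#'
#' @param n sample size (>= 1).
#' @param q variance-explained fraction in (0, 1).
#' @param alpha significance level (default 5e-8, genome-wide).
#' @return power in (0, 1).
#' @export
gwas_power <- function(n, q, alpha = 5e-8) {
  if (any(alpha <= 0) || any(alpha >= 1)) stop("alpha must be in (0, 1)")
  if (any(n < 1)) stop("n must be >= 1")
  if (any(q <= 0) || any(q >= 1)) stop("q must be in (0, 1)")
  crit <- stats::qchisq(1 - alpha, df = 1)
  stats::pchisq(crit, df = 1, ncp = n * q, lower.tail = FALSE)
}
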