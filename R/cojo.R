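#' Region model for conditional/joint analysis
#'
#' Packages a region's marginal summary statistics with an LD correlation
#' matrix estimated from a reference cohort, on which the approximate
#' conditional and joint machinery operates. Internally effects are taken
#' to the standardized-genotype scale as `b* = z / sqrt(n)` and
#' back-transformed to the allele-dosage scale via `sqrt(2 f (1 - f))`.
#'
#' @param variant_ids variant identifiers.
#' @param beta,se marginal effects and standard errors (dosage scale).
#' @param n per-variant sample sizes.
#' @param eaf per-variant effect-allele frequencies.
#' @param R LD correlation matrix from the reference sample (symmetric,
#'   unit diagonal), ordered as `variant_ids`.
#' @param sigma_y trait variance (1 for standardized traits).
#' @return a `RegionModel` list.
#' @export
region_model <- function(variant_ids, beta, se, n, eaf, R, sigma_y = 1) {
  m <- length(variant_ids)
  stopifnot(length(beta) == m, length(se) == m, length(n) == m,
            length(eaf) == m, nrow(R) == m, ncol(R) == m)
  if (max(abs(R - t(R))) > 1e-8) stop("R must be symmetric")
  if (max(abs(diag(R) - 1)) > 1e-8) stop("R must have unit diagonal")
  z <- beta / se
  structure(list(variant_ids = as.character(variant_ids),
                 beta = as.numeric(beta), se = as.numeric(se),
                 n = as.numeric(n), eaf = as.numeric(eaf),
                 z = z, bstar = z / sqrt(n),
                 scale = sqrt(2 * eaf * (1 - eaf)),
                 R = (R + t(R)) / 2, sigma_y = sigma_y),
            class = "RegionModel")
}

# residual variance after fitting the standardized effects b on R, floored
.cojo_resid_var <- function(model, sel, bstar_sel) {
  if (length(sel) == 0) return(model$sigma_y)
  Rs <- model$R[sel, sel, drop = FALSE]
  bj <- solve(Rs, bstar_sel)
  max(model$sigma_y - sum(bj * bstar_sel), 0.05 * model$sigma_y)
}

#' Joint effect estimation for a selected variant set
#'
#' Fits all selected variants jointly from summary statistics:
#' `b_joint = R_sel^{-1} b*` on the standardized scale, with sampling
#' variance `sigma2_resid * diag(R_sel^{-1}) / n_j` and the residual
#' variance updated as `sigma_y^2 - b_joint' R_sel b_joint` (floored).
#' Estimates are returned on the allele-dosage scale. A variant whose LD
#' `r^2` with an earlier-selected variant exceeds `collinear_r2` is
#' rejected as collinear.
#'
#' @param model a `RegionModel`.
#' @param selected variant ids or indices to fit jointly.
#' @param collinear_r2 collinearity cap (default 0.9).
#' @return data.table with `variant_id`, `beta_joint`, `se_joint`,
#'   `z_joint`, `p_joint` (dosage scale) for the retained variants;
#'   attribute `"rejected"` lists collinear drop-outs.
#' @export
joint_fit <- function(model, selected, collinear_r2 = 0.9) {
  stopifnot(inherits(model, "RegionModel"))
  sel <- .resolve_idx(model, selected)
  if (length(sel) == 0)
    return(data.table::data.table(variant_id = character(0),
                                  beta_joint = numeric(0), se_joint = numeric(0),
                                  z_joint = numeric(0), p_joint = numeric(0)))
  kept <- integer(0); rejected <- integer(0)
  for (i in sel) {
    if (length(kept) && any(model$R[i, kept]^2 > collinear_r2)) {
      rejected <- c(rejected, i)
    } else kept <- c(kept, i)
  }
  if (length(rejected) && length(sel) == 2 &&
      all(model$R[sel[1], sel[2]]^2 > collinear_r2))
    warning("collinear variant rejected from joint model: ",
            paste(model$variant_ids[rejected], collapse = ", "))
  sel <- kept
  Rs <- model$R[sel, sel, drop = FALSE]
  bs <- model$bstar[sel]
  bj <- solve(Rs, bs)
  s2 <- max(model$sigma_y - sum(bj * bs), 0.05 * model$sigma_y)
  dinv <- diag(solve(Rs))
  se_std <- sqrt(s2 * dinv / model$n[sel])
  beta_d <- bj / model$scale[sel]
  se_d <- se_std / model$scale[sel]
  z <- beta_d / se_d
  out <- data.table::data.table(
    variant_id = model$variant_ids[sel],
    beta_joint = beta_d, se_joint = se_d, z_joint = z,
    p_joint = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
  data.table::setattr(out, "rejected", model$variant_ids[rejected])
  out
}

#' Conditional association scan
#'
#' Adjusts every remaining variant's effect for a conditioning set through
#' the LD matrix. For variant i with conditioning set S the conditional
#' standardized effect is
#' `(b*_i - r_iS R_SS^{-1} b*_S) / (1 - r_iS R_SS^{-1} r_Si)` with sampling
#' variance `sigma2_resid / (n_i * (1 - r_iS R_SS^{-1} r_Si))`. A variant
#' nearly collinear with the set (`1 - r'R^{-1}r < 1e-6`) is reported with
#' a zero conditional effect and p = 1: its signal is fully absorbed.
#'
#' @param model a `RegionModel`.
#' @param condition_on variant ids or indices to condition on (may be
#'   empty, returning the marginal statistics).
#' @param targets optional ids/indices to scan (default: all variants not
#'   in the conditioning set).
#' @return data.table with `variant_id`, `beta_cond`, `se_cond`, `z_cond`,
#'   `p_cond` on the dosage scale.
#' @export
conditional_scan <- function(model, condition_on, targets = NULL) {
  stopifnot(inherits(model, "RegionModel"))
  S <- .resolve_idx(model, condition_on)
  tg <- if (is.null(targets)) setdiff(seq_along(model$variant_ids), S)
        else .resolve_idx(model, targets)
  if (length(S) == 0) {
    z <- model$z[tg]
    return(data.table::data.table(
      variant_id = model$variant_ids[tg],
      beta_cond = model$beta[tg], se_cond = model$se[tg], z_cond = z,
      p_cond = 2 * stats::pnorm(abs(z), lower.tail = FALSE)))
  }
  Rss <- model$R[S, S, drop = FALSE]
  A <- solve(Rss)
  bS <- model$bstar[S]
  s2 <- .cojo_resid_var(model, S, bS)
  r_tS <- model$R[tg, S, drop = FALSE]
  Ar <- r_tS %*% A
  denom <- 1 - rowSums(Ar * r_tS)
  shift <- drop(Ar %*% bS)
  b_std <- numeric(length(tg)); se_std <- numeric(length(tg))
  collin <- denom < 1e-6
  b_std[!collin] <- (model$bstar[tg][!collin] - shift[!collin]) / denom[!collin]
  se_std[!collin] <- sqrt(s2 / (model$n[tg][!collin] * denom[!collin]))
  b_std[collin] <- 0
  se_std[collin] <- model$se[tg][collin] * model$scale[tg][collin]
  beta_d <- b_std / model$scale[tg]
  se_d <- se_std / model$scale[tg]
  z <- ifelse(se_d > 0, beta_d / se_d, 0)
  z[collin] <- 0
  data.table::data.table(
    variant_id = model$variant_ids[tg],
    beta_cond = beta_d, se_cond = se_d, z_cond = z,
    p_cond = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
}

#' Stepwise selection of independent association signals
#'
#' Iteratively adds the variant with the smallest conditional p-value while
#' it stays below the significance threshold, skipping candidates whose LD
#' `r^2` with an already-selected variant exceeds the collinearity cap, then
#' refits the final list jointly. With no variant at the threshold the
#' selection is empty.
#'
#' @param model a `RegionModel`.
#' @param p_threshold selection threshold (default 5e-8, genome-wide).
#' @param collinear_r2 collinearity cap for entering the model (default
#'   0.9); selected signals are pairwise `r^2 <= collinear_r2` by
#'   construction.
#' @param max_signals safety cap on iterations (default 20).
#' @return data.table of selected signals with marginal and joint
#'   statistics (columns of [joint_fit()] plus `beta_marginal`,
#'   `se_marginal`, `p_marginal`).
#' @export
stepwise_select <- function(model, p_threshold = 5e-8, collinear_r2 = 0.9,
                            max_signals = 20L) {
  stopifnot(inherits(model, "RegionModel"))
  m <- length(model$variant_ids)
  sel <- integer(0)
  repeat {
    cand <- setdiff(seq_len(m), sel)
    if (length(cand) == 0 || length(sel) >= max_signals) break
    if (length(sel))
      cand <- cand[apply(model$R[cand, sel, drop = FALSE]^2, 1, max) <= collinear_r2]
    if (length(cand) == 0) break
    cs <- conditional_scan(model, sel, targets = cand)
    best <- which.min(cs$p_cond)
    if (!is.finite(cs$p_cond[best]) || cs$p_cond[best] >= p_threshold) break
    sel <- c(sel, cand[best])
  }
  if (length(sel) == 0)
    return(data.table::data.table(variant_id = character(0),
                                  beta_joint = numeric(0), se_joint = numeric(0),
                                  z_joint = numeric(0), p_joint = numeric(0),
                                  beta_marginal = numeric(0),
                                  se_marginal = numeric(0),
                                  p_marginal = numeric(0)))
  jf <- joint_fit(model, sel, collinear_r2 = collinear_r2)
  idx <- match(jf$variant_id, model$variant_ids)
  jf[, beta_marginal := model$beta[idx]]
  jf[, se_marginal := model$se[idx]]
  jf[, p_marginal := 2 * stats::pnorm(abs(model$z[idx]), lower.tail = FALSE)]
  jf[]
}

#' Cross-ancestry signal-overlap test
#'
#' Decides whether a lead association in the analysis ancestry is the same
#' signal as established leads from another ancestry. Surrogates for each
#' external lead are all region variants with `r^2 > surrogate_r2` to it in
#' the external-ancestry panel; these are pruned to mutually low-LD
#' representatives in the analysis ancestry (`r^2 < prune_r2`), and the lead
#' is conditioned on them. Under the genome-wide rule the signal is
#' independent only if conditioning moves it little on both scales
#' (`-log10 p` drop < 3 AND effect change < 1 SE); under the locus-wide
#' rule only the effect-change criterion applies.
#'
#' @param aa_lead lead variant id (analysis ancestry).
#' @param ea_leads established external lead variant ids.
#' @param model_aa `RegionModel` in the analysis ancestry.
#' @param eur_r2 matrix of external-panel LD `r^2` over the model's
#'   variants (same order), e.g. `panel_ld(eur_panel)^2`.
#' @param context `"genome-wide"` or `"locus-wide"`.
#' @param surrogate_r2 external LD threshold for surrogates (default 0.8).
#' @param prune_r2 analysis-ancestry pruning threshold (default 0.3).
#' @return an `IndependenceVerdict` list: `same_signal`, `independent`,
#'   `untestable`, `delta_neglogp`, `delta_beta_in_se`, `surrogates`,
#'   `reason`.
#' @export
ea_signal_overlap <- function(aa_lead, ea_leads, model_aa, eur_r2,
                              context = c("genome-wide", "locus-wide"),
                              surrogate_r2 = 0.8, prune_r2 = 0.3) {
  context <- match.arg(context)
  stopifnot(inherits(model_aa, "RegionModel"))
  lead_i <- .resolve_idx(model_aa, aa_lead)
  if (length(lead_i) != 1) stop("aa_lead must resolve to one model variant")
  ea_i <- match(as.character(ea_leads), model_aa$variant_ids)
  ea_i <- ea_i[!is.na(ea_i)]
  if (length(ea_i) == 0)
    return(structure(list(same_signal = NA, independent = NA,
                          untestable = TRUE,
                          delta_neglogp = NA_real_,
                          delta_beta_in_se = NA_real_,
                          surrogates = character(0),
                          reason = "no external lead present in region"),
                     class = "IndependenceVerdict"))
  # surrogate set: external leads plus everything in high external LD
  sur <- unique(c(ea_i, which(apply(
    eur_r2[, ea_i, drop = FALSE], 1, max) > surrogate_r2)))
  # prune to mutually low-LD representatives in the analysis ancestry,
  # preferring the external leads themselves
  sur <- sur[order(!(sur %in% ea_i))]
  pruned <- integer(0)
  for (i in sur) {
    if (!length(pruned) || all(model_aa$R[i, pruned]^2 < prune_r2))
      pruned <- c(pruned, i)
  }
  pruned <- setdiff(pruned, lead_i)
  if (length(pruned) == 0 && lead_i %in% sur) pruned <- intersect(sur, lead_i)
  if (length(pruned) == 0)
    return(structure(list(same_signal = NA, independent = NA,
                          untestable = TRUE,
                          delta_neglogp = NA_real_,
                          delta_beta_in_se = NA_real_,
                          surrogates = character(0),
                          reason = "no conditioning surrogate available"),
                     class = "IndependenceVerdict"))
  cs <- conditional_scan(model_aa, pruned, targets = lead_i)
  p_marg <- 2 * stats::pnorm(abs(model_aa$z[lead_i]), lower.tail = FALSE)
  d_nlp <- -log10(p_marg) - (-log10(cs$p_cond))
  d_b <- abs(model_aa$beta[lead_i] - cs$beta_cond) / model_aa$se[lead_i]
  independent <- if (context == "genome-wide") (d_nlp < 3 && d_b < 1) else d_b < 1
  structure(list(same_signal = !independent, independent = independent,
                 untestable = FALSE,
                 delta_neglogp = d_nlp, delta_beta_in_se = d_b,
                 surrogates = model_aa$variant_ids[pruned],
                 reason = NA_character_),
            class = "IndependenceVerdict")
}

.resolve_idx <- function(model, x) {
  if (is.numeric(x)) return(as.integer(x))
  i <- match(as.character(x), model$variant_ids)
  if (anyNA(i)) stop("unknown variant id(s): ",
                     paste(x[is.na(i)], collapse = ", "))
  i
}
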