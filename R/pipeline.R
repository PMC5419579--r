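#' Pipeline configuration
#'
#' Builds the configuration for [run_pipeline()] from defaults, a YAML file
#' and/or overrides. Every analysis threshold defaults to the convention
#' used throughout the package (QC filter set, ridge 0.1, r2pred 0.6,
#' 5e-8 significance, 1 Mb lead windows, 500 kb novelty, 0.1 cM flanks).
#' Unknown keys are a startup error, not silently ignored.
#'
#' @param path optional YAML file of overrides.
#' @param ... named overrides applied after the file.
#' @return a validated `PipelineConfig` list.
#' @export
pipeline_config <- function(path = NULL, ...) {
  defaults <- list(
    seed = 1L,
    # synthetic study conditions
    n_var = 600L, region_bp = 3e6L, n_hap = 1000L, rho = 0.9,
    maf_low = 0.05, maf_high = 0.5, fst = 0.15,
    n_aa_cohorts = 2L, n_aa = 1500L, n_ea = 4000L, n_ld_ref = 2000L,
    info_target = 0.95, missing_rate = 0.02,
    n_causal = 3L, variance_explained = 0.004,
    ea_observed_fraction = 0.7,
    # analysis thresholds
    min_call_rate = 0.95, max_mac_excluded = 6L, hwe_p_min = 1e-4,
    info_min = 0.3, max_freq_diff = 0.3,
    ridge = 0.1, r2pred_min = 0.6, impute_window_bp = 1e6,
    impute_buffer_bp = 2.5e5,
    sig_p = 5e-8, lead_window_bp = 1e6, novel_distance_bp = 5e5,
    flank_cm = 0.1, credible_level = 0.99, tractable_max = 20L,
    collinear_r2 = 0.9,
    output_dir = "transgwas_output")
  cfg <- defaults
  if (!is.null(path)) {
    file_cfg <- yaml::read_yaml(path)
    unknown <- setdiff(names(file_cfg), names(defaults))
    if (length(unknown))
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    cfg[names(file_cfg)] <- file_cfg
  }
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(defaults))
    if (length(unknown))
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  stopifnot(cfg$n_causal * cfg$variance_explained < 1,
            cfg$r2pred_min >= 0, cfg$r2pred_min <= 1,
            cfg$sig_p > 0, cfg$sig_p < 1)
  structure(cfg, class = "PipelineConfig")
}

#' Serialize / restore a pipeline configuration
#'
#' @param config a `PipelineConfig`.
#' @param path YAML file path.
#' @return `write_pipeline_config` the path invisibly;
#'   `pipeline_config(path)` restores it losslessly.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "PipelineConfig"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the summary-statistics pipeline end-to-end on synthetic data
#'
#' Chains every stage on a generated two-ancestry study: haplotype panels
#' (analysis ancestry plus a drifted external ancestry), cohorts with
#' imputation noise, phenotypes with shared causal variants, per-study
#' association scans, variant QC, per-study genomic control,
#' inverse-variance meta-analysis with post-meta genomic control, LD-based
#' z-score imputation of the external study's masked variants, sample-size
#' weighted cross-ancestry combination, locus definition, stepwise
#' conditional/joint selection, 99% credible sets per analysis, and SNP and
#' locus transferability. Every stage writes a tab-separated artifact plus
#' an exclusion log into `config$output_dir`; the run is deterministic
#' given `config$seed`.
#'
#' @param config a `PipelineConfig` from [pipeline_config()].
#' @return (invisibly) a list of the in-memory stage results:
#'   `panels`, `meta_aa`, `combined`, `loci`, `signals`, `credible_sets`,
#'   `transferability`, `exclusions`, `lambda`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "PipelineConfig"))
  cfg <- config
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$output_dir, "exclusions.tsv")
  exclusions <- list()
  note <- function(stage, dt) {
    if (nrow(dt) > 0) {
      dt <- data.table::copy(dt)[, stage := stage]
      exclusions[[length(exclusions) + 1]] <<- dt
    }
  }

  ## 1. panels -------------------------------------------------------------
  aa_panel <- simulate_haplotypes(cfg$n_hap, cfg$n_var, cfg$region_bp,
                                  rho = cfg$rho, maf_low = cfg$maf_low,
                                  maf_high = cfg$maf_high, seed = cfg$seed,
                                  ancestry_label = "AFR_SYNTH")
  ea_panel <- drift_population(aa_panel, fst = cfg$fst, seed = cfg$seed + 1L,
                               rho = cfg$rho, ancestry_label = "EUR_SYNTH")
  gmap <- panel_genetic_map(aa_panel)
  write_genetic_map(gmap, file.path(cfg$output_dir, "genetic_map.tsv"))

  ## 2. cohorts and phenotypes --------------------------------------------
  causal <- unique(round(seq(1, cfg$n_var,
                             length.out = cfg$n_causal + 2)))[2:(cfg$n_causal + 1)]
  q <- rep(cfg$variance_explained, length(causal))
  aa_scans <- vector("list", cfg$n_aa_cohorts)
  for (i in seq_len(cfg$n_aa_cohorts)) {
    coh <- draw_cohort(aa_panel, cfg$n_aa, info_target = cfg$info_target,
                       missing_rate = cfg$missing_rate,
                       seed = cfg$seed + 10L + i)
    sex <- rep_len(c(0, 1), cfg$n_aa)
    y <- simulate_phenotype(coh, causal, q, covariates = cbind(sex = sex),
                            covariate_effects = 0.1,
                            seed = cfg$seed + 20L + i)
    scan <- gwas_scan(coh, y, covariates = cbind(sex = sex))
    ## per-variant QC on the cohort's own hard calls
    qc_keep <- logical(nrow(scan))
    qc_reason <- character(nrow(scan))
    afr_f <- panel_freq(aa_panel); eur_f <- panel_freq(ea_panel)
    hard <- coh$hard_genotypes
    for (v in seq_len(ncol(hard))) {
      g <- hard[, v][!is.na(hard[, v])]
      cnt <- tabulate(g + 1L, 3L)
      mac <- min(2 * length(g) - sum(g), sum(g))
      hwe_p <- if (length(g) > 0) hwe_exact_test(cnt[1], cnt[2], cnt[3]) else 1
      verdict <- variant_qc(coh$call_rate[v], mac, hwe_p, coh$info[v],
                            coh$eaf[v], dialect = "minimac",
                            ref_afr_freq = afr_f[v], ref_eur_freq = eur_f[v],
                            thresholds = qc_thresholds(
                              min_call_rate = cfg$min_call_rate,
                              max_mac_excluded = cfg$max_mac_excluded,
                              hwe_p_min = cfg$hwe_p_min,
                              info_min = cfg$info_min,
                              max_freq_diff = cfg$max_freq_diff))
      qc_keep[v] <- verdict$passed
      qc_reason[v] <- paste(verdict$reasons, collapse = ";")
    }
    note(sprintf("qc_study%d", i),
         scan[!qc_keep, .(variant_id, reason = qc_reason[!qc_keep])])
    aa_scans[[i]] <- scan[qc_keep]
    write_sumstats(aa_scans[[i]],
                   file.path(cfg$output_dir, sprintf("study%d_sumstats.tsv", i)))
  }

  ## 3. AA meta-analysis with double genomic control -----------------------
  meta_aa <- meta_analyze_studies(aa_scans, gc_pre = TRUE, gc_post = TRUE)
  write_sumstats(meta_aa, file.path(cfg$output_dir, "meta_aa.tsv"))

  ## 4. external-ancestry scan, masking + z-score imputation --------------
  ea_coh <- draw_cohort(ea_panel, cfg$n_ea, info_target = 1,
                        seed = cfg$seed + 40L)
  y_ea <- simulate_phenotype(ea_coh, causal, q, seed = cfg$seed + 41L)
  ea_scan <- gwas_scan(ea_coh, y_ea, transform = TRUE)
  old <- .Random.seed_save(); set.seed(cfg$seed + 42L)
  obs_mask <- stats::runif(nrow(ea_scan)) < cfg$ea_observed_fraction
  .Random.seed_restore(old)
  observed <- ea_scan[obs_mask, .(pos, z = beta / se, n)]
  imputed <- impute_zscores_tiled(ea_panel, observed,
                                  window_bp = cfg$impute_window_bp,
                                  buffer_bp = cfg$impute_buffer_bp,
                                  ridge = cfg$ridge)
  kept_imp <- filter_imputed(imputed, cfg$r2pred_min)
  note("impute_r2pred",
       imputed[r2pred < cfg$r2pred_min,
               .(variant_id, reason = "r2pred_below_threshold")])
  ea_z <- rbind(
    ea_scan[obs_mask, .(variant_id, pos, z = beta / se, n, source = "observed")],
    kept_imp[, .(variant_id, pos, z = z_hat, n = n_interp, source = "imputed")])
  write_sumstats(ea_z, file.path(cfg$output_dir, "ea_zscores.tsv"))

  ## 5. cross-ancestry sample-size-weighted combination --------------------
  comb <- merge(meta_aa[, .(variant_id, chr, pos, z_aa = z, n_aa = n, p_aa = p,
                            beta, se)],
                ea_z[, .(variant_id, z_ea = z, n_ea = n)],
                by = "variant_id", all.x = TRUE)
  comb[, z_comb := ifelse(is.na(z_ea), z_aa,
                          combine_z(z_aa, z_ea, n_aa, n_ea))]
  comb[, n_comb := ifelse(is.na(z_ea), n_aa, n_aa + n_ea)]
  comb[, p_comb := 2 * stats::pnorm(abs(z_comb), lower.tail = FALSE)]
  data.table::setorder(comb, pos)
  write_sumstats(comb, file.path(cfg$output_dir, "meta_combined.tsv"))

  ## 6. loci ---------------------------------------------------------------
  loci <- define_loci(comb[, .(variant_id, chr, pos, p = p_comb)],
                      sig_p = cfg$sig_p, lead_window_bp = cfg$lead_window_bp,
                      novel_distance_bp = cfg$novel_distance_bp)
  data.table::fwrite(loci, file.path(cfg$output_dir, "loci.tsv"), sep = "\t")

  ## 7. per-locus conditional/joint selection, credible sets, transfer -----
  ld_ref <- draw_cohort(aa_panel, cfg$n_ld_ref, info_target = 1,
                        seed = cfg$seed + 50L)
  signals <- list(); cs_rows <- list(); trans_rows <- list()
  for (k in seq_len(nrow(loci))) {
    region <- define_region(loci$pos[k], gmap, flank_cm = cfg$flank_cm)
    in_reg <- comb$pos >= region$bp_bounds[1] & comb$pos <= region$bp_bounds[2]
    reg <- comb[in_reg & !is.na(beta)]
    vidx <- match(reg$variant_id, aa_panel$variant_ids)
    R <- suppressWarnings(stats::cor(ld_ref$dosages[, vidx, drop = FALSE]))
    R[!is.finite(R)] <- 0; diag(R) <- 1
    model <- region_model(reg$variant_id, reg$beta, reg$se, reg$n_aa,
                          meta_aa$eaf[match(reg$variant_id, meta_aa$variant_id)],
                          R)
    sel <- stepwise_select(model, p_threshold = cfg$sig_p,
                           collinear_r2 = cfg$collinear_r2)
    if (nrow(sel)) signals[[length(signals) + 1]] <-
      data.table::copy(sel)[, locus := loci$variant_id[k]]
    z_ea_reg <- ea_z$z[match(reg$variant_id, ea_z$variant_id)]
    zl <- list(aa = reg$z_aa,
               ea = if (all(is.na(z_ea_reg))) NULL else
                 ifelse(is.na(z_ea_reg), 0, z_ea_reg),
               combined = reg$z_comb)
    cmp <- compare_ancestry_sets(zl, reg$pos, reg$variant_id,
                                 level = cfg$credible_level,
                                 tractable_max = cfg$tractable_max)
    cs_rows[[length(cs_rows) + 1]] <-
      data.table::copy(cmp$summary)[, locus := loci$variant_id[k]]
    lt <- locus_transferability(reg$p_aa, R, reg$variant_id)
    trans_rows[[length(trans_rows) + 1]] <- data.table::data.table(
      locus = loci$variant_id[k], best_variant = lt$best_variant,
      min_p = lt$min_p, meff = lt$meff, threshold = lt$threshold,
      locus_transferable = lt$significant)
  }
  signals <- if (length(signals)) data.table::rbindlist(signals) else
    data.table::data.table(variant_id = character(0), beta_joint = numeric(0),
                           se_joint = numeric(0), z_joint = numeric(0),
                           p_joint = numeric(0), beta_marginal = numeric(0),
                           se_marginal = numeric(0), p_marginal = numeric(0),
                           locus = character(0))
  cs_tab <- if (length(cs_rows)) data.table::rbindlist(cs_rows) else
    data.table::data.table(analysis = character(0), size = integer(0),
                           span_bp = numeric(0), lead_pp = numeric(0),
                           tractable = logical(0), missing = logical(0),
                           locus = character(0))
  trans_tab <- if (length(trans_rows)) data.table::rbindlist(trans_rows) else
    data.table::data.table(locus = character(0), best_variant = character(0),
                           min_p = numeric(0), meff = numeric(0),
                           threshold = numeric(0),
                           locus_transferable = logical(0))
  data.table::fwrite(signals, file.path(cfg$output_dir, "signals.tsv"), sep = "\t")
  data.table::fwrite(cs_tab, file.path(cfg$output_dir, "credible_sets.tsv"), sep = "\t")
  data.table::fwrite(trans_tab, file.path(cfg$output_dir, "transferability.tsv"),
                     sep = "\t")
  excl <- if (length(exclusions)) data.table::rbindlist(exclusions, fill = TRUE)
          else data.table::data.table(variant_id = character(0),
                                      reason = character(0),
                                      stage = character(0))
  data.table::fwrite(excl, log_path, sep = "\t")
  invisible(list(panels = list(aa = aa_panel, ea = ea_panel),
                 meta_aa = meta_aa, combined = comb, loci = loci,
                 signals = signals, credible_sets = cs_tab,
                 transferability = trans_tab, exclusions = excl,
                 lambda = list(pre = attr(meta_aa, "lambda_pre"),
                               post = attr(meta_aa, "lambda_post"))))
}
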