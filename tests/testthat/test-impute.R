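test_that("allele harmonization removes palindromes and flips swaps", {
  panel <- haplotype_panel(
    matrix(c(0L, 1L, 0L, 1L, 1L, 0L, 0L, 1L), 2, 4),
    positions_bp = c(100, 200, 300, 400),
    alleles = data.frame(ref = c("A", "A", "G", "C"),
                         alt = c("G", "C", "C", "T")),
    chromosome = "1")
  ss <- data.table::data.table(
    chr = "1", pos = c(100, 200, 300, 400, 500),
    effect_allele = c("G", "A", "A", "T", "A"),
    other_allele  = c("A", "T", "G", "C", "G"),
    beta = c(0.1, 0.2, 0.3, 0.4, 0.5), z = c(1, 2, 3, 4, 5),
    eaf = c(0.3, 0.3, 0.3, 0.3, 0.3))
  out <- harmonize_alleles(ss, panel)
  # pos 100: effect allele is panel alt -> kept as-is
  r100 <- out$aligned[pos == 100]
  expect_equal(r100$beta, 0.1); expect_equal(r100$effect_allele, "G")
  # pos 200: A/T palindromic -> removed
  expect_identical(out$removed[pos == 200]$reason, "palindromic")
  # pos 300: record A/G vs panel G/C -> mismatch
  expect_identical(out$removed[pos == 300]$reason, "allele_mismatch")
  # pos 400: effect allele is panel alt (T), other is ref (C) -> kept
  expect_equal(out$aligned[pos == 400]$beta, 0.4)
  # pos 500: not in panel
  expect_identical(out$removed[pos == 500]$reason, "not_in_panel")
  # swapped orientation: effect allele = panel ref -> sign flip
  ss_fl <- data.table::data.table(chr = "1", pos = 100,
                                  effect_allele = "A", other_allele = "G",
                                  beta = 0.1, z = 1.5, eaf = 0.3)
  fl <- harmonize_alleles(ss_fl, panel)$aligned
  expect_equal(fl$beta, -0.1); expect_equal(fl$z, -1.5)
  expect_equal(fl$eaf, 0.7)
  expect_equal(fl$effect_allele, "G")
})

test_that("z-score imputation reproduces the closed-form small cases", {
  # perfect proxy: 2 variants in complete LD, one observed with z = 4
  H <- cbind(rep(c(0L, 1L), each = 20), rep(c(0L, 1L), each = 20))
  panel <- haplotype_panel(H, c(100, 200),
                           data.frame(ref = c("A", "A"), alt = c("G", "G")))
  zp <- zscore_panel(panel, c(TRUE, FALSE), z = 4, n = 1000)
  out <- impute_zscores(zp, ridge = 0.01)
  expect_equal(out$z_hat, 4 / 1.01, tolerance = 1e-10)
  expect_equal(out$r2pred, 1 / 1.01, tolerance = 1e-10)
  expect_equal(out$n_interp, 1000)

  # uncorrelated target: z_hat = 0, r2pred = 0
  set.seed(4)
  H2 <- cbind(rep(c(0L, 1L), each = 30), sample(rep(c(0L, 1L), 30)))
  while (abs(cor(H2[, 1], H2[, 2])) > 1e-9)
    H2[, 2] <- sample(H2[, 2])
  panel2 <- haplotype_panel(H2, c(100, 200),
                            data.frame(ref = c("A", "A"), alt = c("G", "G")))
  out2 <- impute_zscores(zscore_panel(panel2, c(TRUE, FALSE), 3, 500), 0.1)
  expect_equal(out2$z_hat, 0, tolerance = 1e-9)
  expect_equal(out2$r2pred, 0, tolerance = 1e-9)

  # sample-size interpolation with equal |weights|: N = (1000 + 2000)/2
  set.seed(5)
  h <- rep(c(0L, 1L), each = 30)
  panel3 <- haplotype_panel(cbind(h, h, h), c(100, 200, 300),
                            data.frame(ref = rep("A", 3), alt = rep("G", 3)))
  out3 <- impute_zscores(zscore_panel(panel3, c(TRUE, TRUE, FALSE),
                                      z = c(2, 2), n = c(1000, 2000)), 0.1)
  expect_equal(out3$n_interp, 1500)
  expect_error(impute_zscores(zscore_panel(panel3, c(FALSE, FALSE, FALSE),
                                           numeric(0), numeric(0))))
})

test_that("the r2pred filter is inclusive at the threshold", {
  res <- data.table::data.table(variant_id = c("a", "b", "c"),
                                r2pred = c(0.59, 0.60, 0.95))
  kept <- filter_imputed(res)
  expect_identical(kept$variant_id, c("b", "c"))
  expect_identical(nrow(filter_imputed(res[0])), 0L)
  expect_identical(filter_imputed(res, 0)$variant_id, res$variant_id)
})

test_that("imputed z-scores are shrunk, never amplified beyond LD bounds", {
  for (s in 1:20) {
    panel <- simulate_haplotypes(400, 30, 2e5, rho = 0.9, seed = 900 + s)
    set.seed(s)
    obs <- runif(30) < 0.6
    if (!any(obs) || all(obs)) next
    z_obs <- rnorm(sum(obs), 0, 2)
    out <- impute_zscores(zscore_panel(panel, obs, z_obs, rep(1000, sum(obs))),
                          ridge = 0.1)
    expect_true(all(abs(out$z_hat) <= 1.5 * max(abs(z_obs)) + 1e-9))
    expect_true(all(out$r2pred >= 0 & out$r2pred <= 1 + 1e-9))
    expect_true(all(out$n_interp >= 1000 - 1e-9 & out$n_interp <= 1000 + 1e-9))
  }
})

test_that("masking an observed variant reproduces its z through its proxies", {
  panel <- simulate_haplotypes(1000, 40, 2e5, rho = 0.95, seed = 77)
  coh <- draw_cohort(panel, 4000, seed = 78)
  y <- simulate_phenotype(coh, 20, 0.01, seed = 79)
  sc <- gwas_scan(coh, y)
  z_all <- sc$beta / sc$se
  mask <- rep(TRUE, 40); mask[20] <- FALSE
  out <- impute_zscores(zscore_panel(panel, mask, z_all[mask], sc$n[mask]),
                        ridge = 0.1)
  # best-proxy accuracy bounds the reproduction error
  R <- panel_ld(panel)
  best_r2 <- max(R[20, -20]^2)
  expect_gt(best_r2, 0.8)
  expect_lt(abs(out$z_hat - z_all[20]), 3 * sqrt(1 - best_r2) * abs(z_all[20]) + 2)
  expect_gt(out$r2pred, 0.8)
})
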