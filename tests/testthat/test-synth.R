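test_that("haplotype simulation honors its invariants and determinism", {
  p1 <- simulate_haplotypes(200, 50, 5e5, rho = 0.7, seed = 11)
  p2 <- simulate_haplotypes(200, 50, 5e5, rho = 0.7, seed = 11)
  expect_identical(p1$haplotypes, p2$haplotypes)
  expect_identical(p1$positions_bp, p2$positions_bp)
  expect_true(all(p1$haplotypes %in% c(0L, 1L)))
  expect_true(all(diff(p1$positions_bp) > 0))
  expect_true(all(diff(p1$cM) >= 0))
  p3 <- simulate_haplotypes(200, 50, 5e5, rho = 0.7, seed = 12)
  expect_false(identical(p1$haplotypes, p3$haplotypes))
  expect_error(simulate_haplotypes(200, 50, maf_low = 0.2, maf_high = 0.6))
  expect_error(simulate_haplotypes(0, 50))
})

test_that("copy probability controls LD from independence to identity", {
  p0 <- simulate_haplotypes(1000, 60, 1e6, rho = 0, seed = 21)
  r2 <- sapply(seq_len(59), function(j)
    suppressWarnings(cor(p0$haplotypes[, j], p0$haplotypes[, j + 1]))^2)
  expect_lt(mean(r2, na.rm = TRUE), 0.02)
  p1 <- simulate_haplotypes(400, 30, 1e6, rho = 1, seed = 22)
  expect_true(all(p1$haplotypes == p1$haplotypes[, 1]))
})

test_that("LD decays with inter-variant distance under partial copying", {
  p <- simulate_haplotypes(1000, 120, 1e6, rho = 0.8, seed = 31)
  H <- p$haplotypes
  lags <- c(1, 3, 6, 12, 24)
  mean_r2 <- sapply(lags, function(L) {
    idx <- seq_len(120 - L)
    mean(sapply(idx, function(j)
      suppressWarnings(cor(H[, j], H[, j + L]))^2), na.rm = TRUE)
  })
  expect_true(all(diff(mean_r2) <= 0.02))   # non-increasing up to noise
  expect_gt(mean_r2[1], mean_r2[5])
})

test_that("Balding-Nichols drift has the closed-form frequency variance", {
  src <- simulate_haplotypes(400, 6000, 2e7, rho = 0, seed = 41)
  # F -> 0: the Beta degenerates and derived frequencies equal the source's
  expect_identical(drift_population(src, 0, seed = 1)$target_freq,
                   src$target_freq)
  drifted <- drift_population(src, 0.2, seed = 42, rho = 0)
  p <- src$target_freq; p2 <- drifted$target_freq
  expect_true(all(p2 >= 0 & p2 <= 1))
  expect_true(all(panel_freq(drifted) >= 0 & panel_freq(drifted) <= 1))
  # Var(p' - p) = F p (1 - p) across >= 5000 variants
  ratio <- mean((p2 - p)^2) / mean(0.2 * p * (1 - p))
  expect_gt(ratio, 0.85)
  expect_lt(ratio, 1.15)
  # drifted panel's realized frequencies track the drawn targets
  expect_gt(cor(panel_freq(drifted), p2), 0.6)
  expect_error(drift_population(src, 1.0))
})

test_that("cohort dosages hit their info target and call rate", {
  panel <- small_panel()
  exact <- draw_cohort(panel, 500, info_target = 1, missing_rate = 0, seed = 5)
  expect_identical(unname(exact$dosages), unname(exact$hard_genotypes + 0))
  expect_true(all(exact$call_rate == 1))
  expect_true(all(abs(exact$eaf - colMeans(exact$dosages) / 2) < 1e-12))

  noisy <- draw_cohort(panel, 5000, info_target = 0.5, seed = 6)
  common <- noisy$eaf > 0.2 & noisy$eaf < 0.8
  expect_true(all(noisy$info[common] > 0.45 & noisy$info[common] < 0.55))
  expect_true(all(noisy$dosages >= 0 & noisy$dosages <= 2))

  miss <- draw_cohort(panel, 2000, missing_rate = 0.1, seed = 7)
  expect_true(all(abs(miss$call_rate - 0.9) < 0.04))
  expect_error(draw_cohort(panel, 100, info_target = 0))
  expect_error(draw_cohort(panel, 100, info_target = 1.2))
})

test_that("phenotypes carry the requested variance explained", {
  panel <- small_panel()
  coh <- draw_cohort(panel, 20000, seed = 8)
  y0 <- simulate_phenotype(coh, seed = 9)
  expect_lt(abs(mean(y0)), 3 / sqrt(20000))
  expect_lt(abs(sd(y0) - 1), 0.05)

  y1 <- simulate_phenotype(coh, 10, 0.01, seed = 10)
  r2 <- summary(lm(y1 ~ coh$dosages[, 10]))$r.squared
  expect_gt(r2, 0.005); expect_lt(r2, 0.015)

  sex <- rep_len(c(0, 1), 20000)
  y2 <- simulate_phenotype(coh, covariates = cbind(sex), covariate_effects = 0.5,
                           seed = 11)
  # corr(y, sex) = c * sd(sex) when Var(y) = 1
  expect_lt(abs(cor(y2, sex) - 0.5 * sd(sex)), 0.03)
  expect_error(simulate_phenotype(coh, c(1, 2), c(0.6, 0.5)))
  expect_error(simulate_phenotype(coh, ncol(coh$dosages) + 1L, 0.01))
})

test_that("the association scan recovers effects and passes through EAF", {
  panel <- small_panel()
  coh <- draw_cohort(panel, 10000, seed = 12)
  y <- simulate_phenotype(coh, 20, 0.01, seed = 13)
  sc <- gwas_scan(coh, y)
  true_beta <- attr(y, "beta_sd")
  expect_lt(abs(sc$beta[20] - true_beta), 3 * sc$se[20])
  expect_identical(sc$eaf, unname(coh$eaf))
  expect_identical(sc$effect_allele, panel$alleles$alt)
  expect_warning(
    gwas_scan(coh, y, strata = c(rep("big", 9995), rep("tiny", 5))),
    "tiny")
})

test_that("repeated cohorts give an unbiased effect estimate", {
  panel <- simulate_haplotypes(400, 1, 1000, rho = 0, maf_low = 0.3,
                               maf_high = 0.3, seed = 14)
  R <- 200
  est <- numeric(R); truth <- numeric(R)
  for (r in seq_len(R)) {
    coh <- draw_cohort(panel, 400, seed = 7000 + r)
    y <- simulate_phenotype(coh, 1, 0.02, seed = 8000 + r)
    sc <- gwas_scan(coh, y)
    est[r] <- sc$beta; truth[r] <- attr(y, "beta_sd")
  }
  mc_se <- sd(est - truth) / sqrt(R)
  expect_lt(abs(mean(est - truth)), 2 * mc_se + 1e-12)
})
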