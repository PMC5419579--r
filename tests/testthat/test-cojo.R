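# helper: region model from a cohort scan using the cohort's own LD
scan_model <- function(coh, sc) {
  R <- suppressWarnings(cor(coh$dosages))
  R[!is.finite(R)] <- 0; diag(R) <- 1
  region_model(sc$variant_id, sc$beta, sc$se, sc$n, sc$eaf, (R + t(R)) / 2)
}

test_that("joint estimates collapse to marginals when LD is absent", {
  set.seed(8)
  m <- 5
  n <- rep(5000, m); eaf <- rep(0.3, m)
  bet <- rnorm(m, 0, 0.03)
  # standard errors consistent with a unit-variance trait and dosage scale
  se <- 1 / (sqrt(n) * sqrt(2 * eaf * (1 - eaf)))
  model <- region_model(letters[1:m], bet, se, n, eaf, diag(m))
  jf <- joint_fit(model, letters[1:m])
  expect_equal(jf$beta_joint, bet, tolerance = 1e-10)
  # standardized joint effects equal the standardized marginals exactly
  expect_equal(jf$beta_joint * model$scale, model$bstar, tolerance = 1e-12)
})

test_that("perfectly collinear pairs are rejected from the joint model", {
  R <- matrix(c(1, 1, 1, 1), 2)
  model <- region_model(c("a", "b"), c(0.1, 0.1), c(0.01, 0.01),
                        c(5000, 5000), c(0.3, 0.3), R)
  expect_warning(jf <- joint_fit(model, c("a", "b")), "collinear")
  expect_identical(jf$variant_id, "a")
  expect_identical(attr(jf, "rejected"), "b")
})

test_that("conditioning on a perfect proxy removes the signal entirely", {
  h <- rep(c(0L, 1L), each = 100)
  set.seed(9)
  g <- rbinom(200, 1, 0.4)
  panel <- haplotype_panel(cbind(h, h, g), c(100, 200, 300),
                           data.frame(ref = rep("A", 3), alt = rep("G", 3)))
  R <- panel_ld(panel)
  model <- region_model(c("v1", "v2", "v3"), c(0.1, 0.1, 0.001),
                        c(0.01, 0.01, 0.01), rep(8000, 3), rep(0.4, 3), R)
  cs <- conditional_scan(model, "v1", targets = c("v2", "v3"))
  expect_equal(cs[variant_id == "v2"]$beta_cond, 0)
  expect_equal(cs[variant_id == "v2"]$p_cond, 1)
  # near-independent variant keeps its marginal effect
  r13 <- R[1, 3]
  expect_lt(abs(r13), 0.2)
  expect_lt(abs(cs[variant_id == "v3"]$beta_cond - 0.001), 0.05)
  # empty conditioning set returns marginals
  cs0 <- conditional_scan(model, integer(0))
  expect_equal(cs0$beta_cond, model$beta)
})

test_that("summary-level conditional/joint estimates match individual-level OLS", {
  ok_joint <- 0; ok_cond <- 0; tot <- 0
  for (r in 1:10) {
    panel <- simulate_haplotypes(800, 30, 2e5, rho = 0.85, seed = 1100 + r)
    coh <- draw_cohort(panel, 2000, seed = 1200 + r)
    cidx <- order(-pmin(coh$eaf, 1 - coh$eaf))[c(1, 15)]
    y <- simulate_phenotype(coh, cidx, c(0.01, 0.008), seed = 1300 + r)
    sc <- gwas_scan(coh, y)
    model <- scan_model(coh, sc)
    jf <- joint_fit(model, cidx)
    ref <- coef(summary(lm(y ~ coh$dosages[, cidx])))[-1, , drop = FALSE]
    for (i in seq_len(nrow(ref))) {
      tot <- tot + 1
      ok_joint <- ok_joint + (abs(jf$beta_joint[i] - ref[i, 1]) < 2 * ref[i, 2])
    }
    cnd <- conditional_scan(model, cidx[1], targets = cidx[2])
    ref2 <- coef(summary(lm(y ~ coh$dosages[, cidx[2]] + coh$dosages[, cidx[1]])))[2, ]
    ok_cond <- ok_cond + (abs(cnd$beta_cond - ref2[1]) < 2 * ref2[2])
  }
  expect_gte(ok_joint, 0.9 * tot)
  expect_gte(ok_cond, 9)
})

test_that("conditioning on the causal variant flattens the region", {
  z2 <- c(); zmax <- 0
  for (r in 1:15) {
    panel <- simulate_haplotypes(2000, 30, 2e5, rho = 0.85, seed = 1400 + r)
    coh <- draw_cohort(panel, 1000, seed = 1500 + r)
    cidx <- which.max(pmin(coh$eaf, 1 - coh$eaf))
    y <- simulate_phenotype(coh, cidx, 0.05, seed = 1600 + r)
    sc <- gwas_scan(coh, y)
    cs <- conditional_scan(scan_model(coh, sc), cidx)
    keep <- cs$se_cond > 0 & abs(cs$z_cond) > 0
    z2 <- c(z2, cs$z_cond[keep]^2)
    zmax <- max(zmax, abs(cs$z_cond[keep]))
  }
  # pooled residual statistics look null: mean chi-square near 1 and no
  # genome-wide signal left anywhere
  expect_lt(abs(mean(z2) - 1), 0.35)
  expect_lt(zmax, 5.5)
})

test_that("stepwise selection finds the right number of signals", {
  # no significant variant -> empty selection
  set.seed(10)
  m <- 20
  model0 <- region_model(paste0("v", 1:m), rnorm(m, 0, 0.01),
                         rep(0.01, m), rep(5000, m), rep(0.3, m), diag(m))
  expect_identical(nrow(stepwise_select(model0)), 0L)

  one_hits <- 0; two_hits <- 0
  for (r in 1:15) {
    panel <- simulate_haplotypes(4000, 40, 3e5, rho = 0.85, seed = 1700 + r)
    coh <- draw_cohort(panel, 4000, seed = 1800 + r)
    maf <- pmin(coh$eaf, 1 - coh$eaf)
    cidx <- which.max(maf)
    y <- simulate_phenotype(coh, cidx, 0.012, seed = 1900 + r)
    sel <- stepwise_select(scan_model(coh, gwas_scan(coh, y)))
    one_hits <- one_hits + (nrow(sel) == 1)

    # two causals in low mutual LD
    R <- panel_ld(panel)
    cand <- which(maf > 0.2)
    pair <- NULL
    for (i in cand) for (j in cand)
      if (j > i && R[i, j]^2 < 0.05) { pair <- c(i, j); break }
    if (is.null(pair)) next
    y2 <- simulate_phenotype(coh, pair, c(0.012, 0.012), seed = 2000 + r)
    sel2 <- stepwise_select(scan_model(coh, gwas_scan(coh, y2)))
    two_hits <- two_hits + (nrow(sel2) == 2)
    # selected signals are pairwise r2 <= 0.9 by construction
    if (nrow(sel2) >= 2) {
      ii <- match(sel2$variant_id, paste0(panel$variant_ids))
      expect_lte(max(R[ii, ii]^2 - diag(length(ii))), 0.9)
    }
  }
  expect_gte(one_hits, 13)
  expect_gte(two_hits, 10)
})

test_that("variant order never changes joint estimates", {
  panel <- simulate_haplotypes(800, 25, 2e5, rho = 0.8, seed = 2100)
  coh <- draw_cohort(panel, 3000, seed = 2101)
  cidx <- order(-pmin(coh$eaf, 1 - coh$eaf))[c(1, 10)]
  y <- simulate_phenotype(coh, cidx, c(0.01, 0.01), seed = 2102)
  sc <- gwas_scan(coh, y)
  model <- scan_model(coh, sc)
  set.seed(11)
  perm <- sample(25)
  R <- suppressWarnings(cor(coh$dosages))[perm, perm]
  R[!is.finite(R)] <- 0; diag(R) <- 1
  model_p <- region_model(sc$variant_id[perm], sc$beta[perm], sc$se[perm],
                          sc$n[perm], sc$eaf[perm], (R + t(R)) / 2)
  a <- joint_fit(model, cidx)
  b <- joint_fit(model_p, model$variant_ids[cidx])
  b <- b[match(a$variant_id, b$variant_id)]
  expect_equal(a$beta_joint, b$beta_joint, tolerance = 1e-9)
  expect_equal(a$se_joint, b$se_joint, tolerance = 1e-9)
})

test_that("cross-ancestry overlap verdicts follow the two-delta rules", {
  panel <- simulate_haplotypes(3000, 60, 5e5, rho = 0.8, seed = 2200)
  coh <- draw_cohort(panel, 3000, seed = 2201)
  cidx <- which.max(pmin(coh$eaf, 1 - coh$eaf))
  y <- simulate_phenotype(coh, cidx, 0.01, seed = 2202)
  sc <- gwas_scan(coh, y)
  R <- suppressWarnings(cor(coh$dosages)); R[!is.finite(R)] <- 0; diag(R) <- 1
  model <- region_model(sc$variant_id, sc$beta, sc$se, sc$n, sc$eaf,
                        (R + t(R)) / 2)
  eur_r2 <- panel_ld(panel)^2
  lead_id <- model$variant_ids[cidx]

  # external lead identical to the analysis lead -> same signal
  v1 <- ea_signal_overlap(lead_id, lead_id, model, eur_r2, "genome-wide")
  expect_false(v1$untestable)
  expect_true(v1$same_signal)

  # external lead uncorrelated with the analysis lead -> independent
  far <- setdiff(order(pmax(R[cidx, ]^2, eur_r2[cidx, ])), cidx)[1]
  expect_lt(max(R[cidx, far]^2, eur_r2[cidx, far]), 0.05)
  v2 <- ea_signal_overlap(lead_id, model$variant_ids[far], model, eur_r2,
                          "genome-wide")
  expect_false(v2$untestable)
  expect_true(v2$independent)
  expect_lt(v2$delta_beta_in_se, 1)

  # external lead absent from the region -> untestable
  v3 <- ea_signal_overlap(lead_id, "rs_not_here", model, eur_r2, "genome-wide")
  expect_true(v3$untestable)
})

test_that("a shared causal tagged by different leads is called the same signal", {
  same <- 0
  for (r in 1:10) {
    panel <- simulate_haplotypes(3000, 30, 2e5, rho = 0.92, seed = 2300 + r)
    coh <- draw_cohort(panel, 3000, seed = 2400 + r)
    cidx <- which.max(pmin(coh$eaf, 1 - coh$eaf))
    y <- simulate_phenotype(coh, cidx, 0.012, seed = 2500 + r)
    sc <- gwas_scan(coh, y)
    R <- suppressWarnings(cor(coh$dosages)); R[!is.finite(R)] <- 0; diag(R) <- 1
    model <- region_model(sc$variant_id, sc$beta, sc$se, sc$n, sc$eaf,
                          (R + t(R)) / 2)
    eur_r2 <- panel_ld(panel)^2
    # analysis-ancestry lead: most significant variant
    aa_lead <- model$variant_ids[which.max(abs(model$z))]
    # external lead: the best tag of the causal that is not the AA lead
    tags <- order(-eur_r2[cidx, ])
    ea_lead <- model$variant_ids[setdiff(tags, match(aa_lead, model$variant_ids))[1]]
    v <- ea_signal_overlap(aa_lead, ea_lead, model, eur_r2, "genome-wide")
    if (!v$untestable && isTRUE(v$same_signal)) same <- same + 1
  }
  expect_gte(same, 9)
})
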