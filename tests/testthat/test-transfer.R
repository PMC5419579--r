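test_that("locus assembly is greedy by significance with distance masking", {
  gs <- data.table::data.table(
    variant_id = c("a", "b", "c", "d"),
    chr = "1",
    pos = c(1e6, 1.4e6, 3e6, 9e6),
    p = c(1e-10, 1e-9, 1e-12, 1e-3))
  loci <- define_loci(gs)
  # c is most significant; a absorbs b (400 kb apart); d not significant
  expect_identical(loci$variant_id, c("c", "a"))
  expect_equal(loci[variant_id == "a"]$n_masked, 1L)
  # two significant variants 1.2 Mb apart form two loci
  gs2 <- data.table::data.table(variant_id = c("x", "y"), chr = "1",
                                pos = c(1e6, 2.2e6), p = c(1e-9, 1e-10))
  expect_equal(nrow(define_loci(gs2)), 2L)
  # novelty: > 500 kb from every established lead
  est <- data.table::data.table(chr = "1", pos = 2.4e6)
  loci3 <- define_loci(gs2, established = est)
  expect_true(loci3[variant_id == "x"]$novel)    # 1.4 Mb away
  expect_false(loci3[variant_id == "y"]$novel)   # 200 kb away
  # exactly 500 kb is not novel (strict >)
  est2 <- data.table::data.table(chr = "1", pos = 1e6 + 5e5)
  expect_false(define_loci(gs2, established = est2)[variant_id == "x"]$novel)
})

test_that("SNP transferability aligns alleles before judging direction", {
  v1 <- snp_transferability(0.08, "A", "G", 0.05, 0.03, "A", "G")
  expect_true(v1$transferable)
  v2 <- snp_transferability(0.08, "A", "G", -0.05, 0.001, "A", "G")
  expect_false(v2$transferable)
  expect_false(v2$directionally_consistent)
  # swapped alleles with negated effect: flip restores consistency
  v3 <- snp_transferability(0.08, "A", "G", -0.05, 0.03, "G", "A")
  expect_true(v3$directionally_consistent)
  expect_equal(v3$aligned_target_beta, 0.05)
  # direction right but not nominally significant
  v4 <- snp_transferability(0.08, "A", "G", 0.05, 0.4, "A", "G")
  expect_true(v4$directionally_consistent)
  expect_false(v4$transferable)
  # unalignable alleles
  v5 <- snp_transferability(0.08, "A", "G", 0.05, 0.03, "A", "C")
  expect_false(v5$testable)
})

test_that("strand-consistent relabeling never changes the verdict", {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  base <- snp_transferability(0.08, "A", "G", 0.05, 0.03, "A", "G")
  flipped_strand <- snp_transferability(0.08, comp[["A"]], comp[["G"]],
                                        0.05, 0.03, comp[["A"]], comp[["G"]])
  expect_identical(base$transferable, flipped_strand$transferable)
  swapped <- snp_transferability(0.08, "A", "G", -0.05, 0.03, "G", "A")
  expect_identical(base$transferable, swapped$transferable)
})

test_that("the exact binomial tail matches closed forms", {
  expect_equal(binomial_sign_test(10, 10, 0.5), 0.5^10)
  expect_equal(binomial_sign_test(0, 10, 0.5), 1)
  expect_equal(binomial_sign_test(5, 10, 0.05),
               sum(dbinom(5:10, 10, 0.05)), tolerance = 1e-12)
  expect_equal(binomial_sign_test(5, 10, 0.05), 6.369e-5, tolerance = 1e-3)
  expect_error(binomial_sign_test(11, 10, 0.5))
  expect_error(binomial_sign_test(5, 10, 0))
})

test_that("Li-Ji effective tests follow the eigenvalue rule", {
  expect_equal(li_ji_meff(diag(5)), 5)
  expect_equal(li_ji_meff(matrix(c(1, 1, 1, 1), 2)), 1)
  expect_equal(li_ji_meff(matrix(c(1, 0.5, 0.5, 1), 2)), 2)
  expect_lt(li_ji_meff(matrix(c(1, 1, 1, 1), 2)),
            li_ji_meff(matrix(c(1, 0.5, 0.5, 1), 2)))
  # 1 <= Meff <= M over random LD matrices
  for (s in 1:10) {
    panel <- simulate_haplotypes(300, 15, 1e5, rho = runif(1, 0.3, 0.95),
                                 seed = 3000 + s)
    meff <- li_ji_meff(panel_ld(panel))
    expect_gte(meff, 1)
    expect_lte(meff, 15 + 1e-9)
  }
  expect_error(li_ji_meff(matrix(1, 2, 3)))
})

test_that("locus transferability applies the Meff-Bonferroni threshold", {
  R10 <- diag(10)
  lt1 <- locus_transferability(c(0.01, rep(0.5, 9)), R10)
  expect_equal(lt1$threshold, 0.005)
  expect_false(lt1$significant)
  lt2 <- locus_transferability(c(1e-4, rep(0.5, 9)), R10)
  expect_true(lt2$significant)
  lt3 <- locus_transferability(0.03, matrix(1, 1, 1))
  expect_equal(lt3$meff, 1)
  expect_equal(lt3$threshold, 0.05)
  expect_true(lt3$significant)
  expect_error(locus_transferability(numeric(0), diag(0)))
})

test_that("variance-explained and SD-unit effects interconvert exactly", {
  expect_equal(round(effect_from_varexp(0.0008, 0.05), 4), 0.0918)
  expect_equal(round(effect_from_varexp(0.0008, 0.01), 3), 0.201)
  expect_equal(round(effect_from_varexp(0.0018, 0.05), 4), 0.1376)
  expect_equal(round(effect_from_varexp(0.0018, 0.01), 4), 0.3015)
  for (q in c(1e-4, 0.0008, 0.01)) for (f in c(0.01, 0.05, 0.4))
    expect_equal(varexp_from_effect(effect_from_varexp(q, f), f), q)
  expect_error(effect_from_varexp(0, 0.1))
  expect_error(effect_from_varexp(0.01, 0.6))
})

test_that("analytic power behaves like the noncentral chi-square tail", {
  expect_gt(gwas_power(52895, 0.0008), 0.8)
  expect_gt(gwas_power(23095, 0.0018), 0.8)
  # q -> 0 recovers the significance level
  expect_equal(gwas_power(1000, 1e-12), 5e-8, tolerance = 1e-6)
  # monotone in n and q
  expect_true(all(diff(gwas_power(c(1e4, 3e4, 1e5), 0.0008)) > 0))
  expect_true(all(diff(gwas_power(3e4, c(5e-4, 1e-3, 2e-3))) > 0))
  expect_error(gwas_power(1000, 0.5, alpha = 0))
})
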