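test_that("genotype counts round-trip through individual expansion", {
  fx <- table1_fixture()
  mk <- study_markers()
  ds <- counts_to_dataset(mk$TaqIB, fx$TaqIB$control, fx$TaqIB$case)
  cc <- genotype_counts(ds, "TaqIB", "controls")
  expect_equal(unname(cc$counts), c(12L, 123L, 388L))
  expect_equal(cc$N, 523L)
  # invariance to subject order
  perm <- sample(length(ds$subjects))
  ds_p <- genotype_dataset(ds$subjects[perm], ds$phenotype[perm],
                           ds$genotypes[perm, , drop = FALSE], ds$markers)
  expect_equal(genotype_counts(ds_p, "TaqIB", "controls")$counts, cc$counts)
})

test_that("all-missing strata are rejected", {
  mk <- list(A = marker_definition("A", "G", "SNP", c("C", "T"), "T"))
  geno <- matrix(c("C/T", NA), 2, 1, dimnames = list(NULL, "A"))
  ds <- genotype_dataset(c("s1", "s2"), c(1L, 0L), geno, mk)
  expect_error(genotype_counts(ds, "A", "controls"), "missing")
  expect_error(genotype_counts(ds, "nope", "cases"), "unknown marker")
})

test_that("Hardy-Weinberg goodness-of-fit reproduces hand-verified statistics", {
  hw <- hwe_test(genotype_counts_table("TaqIA", "controls",
                                       c(TT = 17, CT = 148, CC = 366)), df = 2)
  expect_equal(hw$chi2, -2 * log(0.912), tolerance = 1e-3)
  expect_equal(hw$p, 0.912, tolerance = 5e-4)
  hw_b <- hwe_test(genotype_counts_table("TaqIB", "controls",
                                         c(AA = 12, AG = 123, GG = 388)), df = 2)
  expect_equal(hw_b$p, 0.833, tolerance = 5e-4)
  # perfect HWE counts give chi2 = 0, p = 1 at either df
  perfect <- genotype_counts_table("X", "all", c(25, 50, 25))
  expect_equal(hwe_test(perfect, df = 1)$chi2, 0, tolerance = 1e-12)
  expect_equal(hwe_test(perfect, df = 1)$p, 1)
  expect_equal(hwe_test(perfect, df = 2)$p, 1)
})

test_that("the df = 1 p-value never exceeds the df = 2 p-value", {
  set.seed(3)
  for (i in 1:20) {
    cnt <- genotype_counts_table("X", "all",
                                 c(rpois(1, 20) + 1, rpois(1, 80) + 1,
                                   rpois(1, 200) + 1))
    h1 <- hwe_test(cnt, df = 1)
    h2 <- hwe_test(cnt, df = 2)
    expect_equal(h1$chi2, h2$chi2)
    if (h1$chi2 > 0) expect_lte(h1$p, h2$p)
  }
})

test_that("monomorphic counts return p = 1 with a flag", {
  mono <- genotype_counts_table("X", "all", c(0, 0, 100))
  h <- hwe_test(mono)
  expect_true(h$monomorphic)
  expect_equal(h$p, 1)
  expect_error(hwe_test(genotype_counts_table("X", "all", c(0, 0, 0))),
               "empty")
})

test_that("dominant association reproduces the reference single-marker results", {
  fx <- table1_fixture()
  taqib <- dominant_association(fx$TaqIB$case, fx$TaqIB$control)
  expect_equal(taqib$odds_ratio, 1.6127, tolerance = 1e-4)
  expect_equal(taqib$p, 0.00263, tolerance = 1e-2)
  expect_equal(taqib$chi2, 9.046, tolerance = 1e-3)
  m521 <- dominant_association(fx$DRD4_521$case, fx$DRD4_521$control)
  expect_equal(m521$odds_ratio, 0.6559, tolerance = 1e-4)
  expect_equal(m521$ci_low, 0.4836, tolerance = 1e-3)
  expect_equal(m521$ci_high, 0.8896, tolerance = 1e-3)
})

test_that("identical case/control distributions give the null result", {
  eq <- genotype_counts_table("X", "cases", c(present = 50, absent = 50),
                              type = "dominant")
  eq2 <- genotype_counts_table("X", "controls", c(present = 50, absent = 50),
                               type = "dominant")
  res <- dominant_association(eq, eq2)
  expect_equal(res$odds_ratio, 1)
  expect_equal(res$chi2, 0, tolerance = 1e-12)
  expect_equal(res$p, 1)
})

test_that("transposing the exposure reciprocates the odds ratio", {
  a <- genotype_counts_table("X", "cases", c(present = 30, absent = 70),
                             type = "dominant")
  b <- genotype_counts_table("X", "controls", c(present = 45, absent = 55),
                             type = "dominant")
  a_t <- genotype_counts_table("X", "cases", c(present = 70, absent = 30),
                               type = "dominant")
  b_t <- genotype_counts_table("X", "controls", c(present = 55, absent = 45),
                               type = "dominant")
  r1 <- dominant_association(a, b)
  r2 <- dominant_association(a_t, b_t)
  expect_equal(r1$odds_ratio, 1 / r2$odds_ratio, tolerance = 1e-12)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
})

test_that("zero cells are flagged instead of corrected", {
  a <- genotype_counts_table("X", "cases", c(present = 0, absent = 100),
                             type = "dominant")
  b <- genotype_counts_table("X", "controls", c(present = 10, absent = 90),
                             type = "dominant")
  res <- dominant_association(a, b)
  expect_true(res$zero_cell)
  expect_equal(res$odds_ratio, 0)
  expect_true(is.na(res$ci_low))
})

test_that("exact 2x2 p-values match brute-force enumeration", {
  tab <- matrix(c(1, 11, 9, 3), 2, 2)
  # oracle: full hypergeometric enumeration with Fisher's probability rule
  enum_fisher <- function(t) {
    r1 <- sum(t[1, ]); r2 <- sum(t[2, ]); c1 <- sum(t[, 1])
    ks <- max(0, c1 - r2):min(c1, r1)
    pr <- dhyper(ks, r1, r2, c1)
    sum(pr[pr <= dhyper(t[1, 1], r1, r2, c1) * (1 + 1e-7)])
  }
  expect_equal(fisher_exact_2x2(tab), enum_fisher(tab), tolerance = 1e-9)
  expect_equal(fisher_exact_2x2(tab), 0.0027595, tolerance = 1e-4)
  expect_equal(exact_pearson_2x2(tab), 0.0027595, tolerance = 1e-4)
  # degenerate margins
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 5, 7), 2, 2)), 1)
  expect_equal(exact_pearson_2x2(matrix(c(3, 4, 0, 0), 2, 2)), 1)
})

test_that("exact and asymptotic Pearson p-values agree on large balanced tables", {
  set.seed(8)
  for (i in 1:5) {
    tab <- matrix(rpois(4, 150) + 50, 2, 2)
    exact <- exact_pearson_2x2(tab)
    asym <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))$p.value
    expect_equal(exact, asym, tolerance = 0.1)
  }
})

test_that("stratified analysis is null when the stratifier is independent", {
  mk <- list(E = marker_definition("E", "G1", "SNP", c("e", "x"), "e"),
             S = marker_definition("S", "G2", "SNP", c("s", "x"), "s"))
  cfg <- simulation_config(mk, n_cases = 800, n_controls = 800,
                           freqs = list(E = c(e = 0.3, x = 0.7),
                                        S = c(s = 0.4, x = 0.6)),
                           disease_model = list(baseline = -0.5,
                                                beta = c(E = log(1.6))))
  ds <- simulate_dataset(cfg, seed = 21)
  marginal <- dominant_association(genotype_counts(ds, "E", "cases"),
                                   genotype_counts(ds, "E", "controls"))
  strat <- stratified_association(ds, "E", "S")
  for (s in strat) {
    expect_gt(s$odds_ratio, marginal$ci_low * 0.8)
    expect_lt(s$odds_ratio, marginal$ci_high * 1.2)
  }
})

test_that("Bonferroni flags follow the family-wise threshold", {
  bf <- bonferroni_adjust(rep(0.01, 11))
  expect_equal(bf$threshold, 0.05 / 11, tolerance = 1e-12)
  expect_false(any(bf$flags))
  expect_equal(bonferroni_adjust(0.04)$threshold, 0.05)
  expect_true(bonferroni_adjust(0.04)$flags)
  expect_true(bonferroni_adjust(c(0.004, 0.02, rep(0.5, 9)))$flags[1L])
})
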