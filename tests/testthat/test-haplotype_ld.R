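test_that("phase-known data reduces EM to direct counting", {
  # homozygotes only: every haplotype is read off directly
  ds <- toy_dataset(
    list(M1 = c("A/A", "A/A", "a/a", "a/a", "a/a"),
         M2 = c("B/B", "b/b", "B/B", "b/b", "b/b")),
    phenotype = rep(0L, 5),
    markers = list(
      M1 = marker_definition("M1", "G1", "SNP", c("a", "A"), "A"),
      M2 = marker_definition("M2", "G2", "SNP", c("b", "B"), "B")))
  em <- em_haplotype_frequencies(ds, c("M1", "M2"))
  expect_equal(unname(em$freqs[c("A~B", "A~b", "a~B", "a~b")]),
               c(0.2, 0.2, 0.2, 0.4), tolerance = 1e-12)
})

test_that("a lone double heterozygote stays at the symmetric fixed point", {
  ds <- toy_dataset(
    list(M1 = "A/a", M2 = "B/b"), phenotype = 0L,
    markers = list(
      M1 = marker_definition("M1", "G1", "SNP", c("a", "A"), "A"),
      M2 = marker_definition("M2", "G2", "SNP", c("b", "B"), "B")))
  em <- em_haplotype_frequencies(ds, c("M1", "M2"))
  expect_equal(unname(em$freqs), rep(0.25, 4), tolerance = 1e-9)
})

test_that("EM recovers the generating haplotype pool at n = 2000", {
  truth <- c("A~B" = 0.14, "A~b" = 0.03, "a~B" = 0.03, "a~b" = 0.80)
  ds <- pool_dataset(2000, truth, seed = 31)
  em <- em_haplotype_frequencies(ds, c("M1", "M2"))
  expect_lt(max(abs(em$freqs[names(truth)] - truth)), 0.02)
})

test_that("EM matches an independent likelihood maximization on a toy instance", {
  truth <- c("A~B" = 0.35, "A~b" = 0.15, "a~B" = 0.2, "a~b" = 0.3)
  ds <- pool_dataset(40, truth, seed = 13)
  em <- em_haplotype_frequencies(ds, c("M1", "M2"))
  # independent oracle: brute-force genotype likelihood over all ordered
  # haplotype pairs, maximized with Nelder-Mead on softmax coordinates
  haps <- expand.grid(a1 = c("A", "a"), a2 = c("B", "b"),
                      stringsAsFactors = FALSE)
  geno <- ds$genotypes
  loglik <- function(f) {
    ll <- 0
    for (i in seq_len(nrow(geno))) {
      pair <- strsplit(geno[i, ], "/", fixed = TRUE)
      pg <- 0
      for (h1 in seq_len(4)) for (h2 in seq_len(4)) {
        ok1 <- all(sort(c(haps$a1[h1], haps$a1[h2])) == sort(pair[[1]]))
        ok2 <- all(sort(c(haps$a2[h1], haps$a2[h2])) == sort(pair[[2]]))
        if (ok1 && ok2) pg <- pg + f[h1] * f[h2]
      }
      ll <- ll + log(pg)
    }
    ll
  }
  best_val <- -Inf
  best_f <- NULL
  for (start in 1:3) {
    set.seed(start)
    opt <- optim(rnorm(4),
                 function(th) -loglik(exp(th) / sum(exp(th))),
                 method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-12))
    f <- exp(opt$par) / sum(exp(opt$par))
    if (loglik(f) > best_val) {
      best_val <- loglik(f)
      best_f <- f
    }
  }
  key <- paste(haps$a1, haps$a2, sep = "~")
  expect_equal(em$loglik, best_val, tolerance = 1e-3)
  expect_lt(max(abs(em$freqs[key] - best_f)), 1e-3)
})

test_that("LD statistics follow their closed forms", {
  indep <- c("A~B" = 0.09, "A~b" = 0.21, "a~B" = 0.21, "a~b" = 0.49)
  ld0 <- ld_stats(indep, "A", "B")
  expect_equal(ld0$D, 0, tolerance = 1e-12)
  expect_equal(ld0$d_prime, 0, tolerance = 1e-12)
  expect_equal(ld0$r2, 0, tolerance = 1e-12)
  perfect <- c("A~B" = 0.3, "A~b" = 0, "a~B" = 0, "a~b" = 0.7)
  ld1 <- ld_stats(perfect, "A", "B")
  expect_equal(ld1$D, 0.21, tolerance = 1e-12)
  expect_equal(ld1$d_prime, 1, tolerance = 1e-12)
  expect_equal(ld1$r2, 1, tolerance = 1e-12)
  mono <- c("A~B" = 0.6, "A~b" = 0.4, "a~B" = 0, "a~b" = 0)
  expect_true(ld_stats(mono, "A", "B")$monomorphic)
})

test_that("complementary allele relabeling permutes haplotype frequencies", {
  truth <- c("A~B" = 0.25, "A~b" = 0.25, "a~B" = 0.1, "a~b" = 0.4)
  ds <- pool_dataset(300, truth, seed = 7)
  em <- em_haplotype_frequencies(ds, c("M1", "M2"))
  swapped <- chartr("Aa", "aA", ds$genotypes[, "M1"])
  geno2 <- cbind(M1 = swapped, M2 = ds$genotypes[, "M2"])
  ds2 <- genotype_dataset(ds$subjects, ds$phenotype, geno2, ds$markers)
  em2 <- em_haplotype_frequencies(ds2, c("M1", "M2"))
  relabeled <- em$freqs
  names(relabeled) <- chartr("Aa", "aA", names(relabeled))
  expect_equal(em2$freqs[sort(names(em2$freqs))],
               relabeled[sort(names(relabeled))], tolerance = 1e-9)
})

test_that("identical case and control samples give a null haplotype LRT", {
  truth <- c("A~B" = 0.2, "A~b" = 0.2, "a~B" = 0.2, "a~b" = 0.4)
  half <- pool_dataset(120, truth, seed = 2)
  geno <- rbind(half$genotypes, half$genotypes)
  ds <- genotype_dataset(sprintf("S%04d", 1:240),
                         rep(c(1L, 0L), each = 120), geno, half$markers)
  lrt <- haplotype_association_lrt(ds, c("M1", "M2"))
  expect_equal(lrt$chi2, 0, tolerance = 1e-6)
  expect_equal(lrt$p, 1, tolerance = 1e-6)
})

test_that("phase-known LRT equals the direct multinomial G-test", {
  # homozygote-only subjects: haplotype counts are observable
  make_homo <- function(n_ab, n_aB, n_Ab, n_AB, phen) {
    toks1 <- c(rep("a/a", n_ab + n_aB), rep("A/A", n_Ab + n_AB))
    toks2 <- c(rep("b/b", n_ab), rep("B/B", n_aB), rep("b/b", n_Ab),
               rep("B/B", n_AB))
    list(M1 = toks1, M2 = toks2,
         phen = rep(phen, n_ab + n_aB + n_Ab + n_AB))
  }
  ca <- make_homo(20, 14, 8, 18, 1L)
  co <- make_homo(30, 10, 12, 8, 0L)
  mk <- list(M1 = marker_definition("M1", "G1", "SNP", c("a", "A"), "A"),
             M2 = marker_definition("M2", "G2", "SNP", c("b", "B"), "B"))
  ds <- toy_dataset(list(M1 = c(ca$M1, co$M1), M2 = c(ca$M2, co$M2)),
                    c(ca$phen, co$phen), markers = mk)
  lrt <- haplotype_association_lrt(ds, c("M1", "M2"))
  # oracle: G-statistic on the 2x4 haplotype count table (2 per homozygote)
  case_counts <- 2 * c(20, 14, 8, 18)
  ctrl_counts <- 2 * c(30, 10, 12, 8)
  g <- 0
  for (k in 1:4) {
    pooled <- case_counts[k] + ctrl_counts[k]
    exp_case <- pooled * sum(case_counts) / (sum(case_counts) + sum(ctrl_counts))
    exp_ctrl <- pooled - exp_case
    g <- g + 2 * (case_counts[k] * log(case_counts[k] / exp_case) +
                    ctrl_counts[k] * log(ctrl_counts[k] / exp_ctrl))
  }
  expect_equal(lrt$chi2, g, tolerance = 1e-6)
  expect_equal(lrt$df, 3L)
})

test_that("study-scale haplotype frequency contrast is usually detected", {
  # pools mimicking the linked-minor-allele contrast: case focal haplotype
  # 0.199 vs control 0.138
  case_pool <- c("T~A" = 0.199, "T~G" = 0.031, "C~A" = 0.001, "C~G" = 0.769)
  ctrl_pool <- c("T~A" = 0.138, "T~G" = 0.032, "C~A" = 0.001, "C~G" = 0.829)
  mk <- list(M1 = marker_definition("M1", "ANKK1", "SNP", c("C", "T"), "T"),
             M2 = marker_definition("M2", "DRD2", "SNP", c("A", "G"), "A"))
  hits <- 0
  for (s in 1:10) {
    ca <- pool_dataset(303, case_pool, seed = 1000 + s, markers = mk)
    co <- pool_dataset(555, ctrl_pool, seed = 2000 + s, markers = mk)
    ds <- genotype_dataset(sprintf("S%04d", 1:858),
                           rep(c(1L, 0L), c(303, 555)),
                           rbind(ca$genotypes, co$genotypes), mk)
    lrt <- haplotype_association_lrt(ds, c("M1", "M2"))
    if (lrt$p < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 6)
})
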