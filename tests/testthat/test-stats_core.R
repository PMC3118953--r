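test_that("G2 is zero on an exactly independent table and matches brute force", {
  tab <- matrix(c(10, 10, 10, 10), 2)
  obs <- table_to_obs(tab)
  t0 <- g2_test(obs$y, obs$x)
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)
  expect_true(t0$independent)

  tab <- matrix(c(30, 10, 10, 30), 2, byrow = TRUE)
  obs <- table_to_obs(tab)
  t1 <- g2_test(obs$y, obs$x)
  expect_equal(t1$statistic, brute_g2_2d(tab), tolerance = 1e-12)
  expect_equal(t1$p_value,
               pchisq(brute_g2_2d(tab), df = 1, lower.tail = FALSE))
  expect_equal(t1$df, 1L)
})

test_that("G2 on random tables agrees with the brute-force likelihood ratio", {
  set.seed(101)
  for (r in 1:100) {
    nr <- sample(2:3, 1); nc <- sample(2:3, 1)
    tab <- matrix(rpois(nr * nc, lambda = 8) + 1L, nr, nc)
    obs <- table_to_obs(tab)
    expect_equal(g2_test(obs$y, obs$x)$statistic, brute_g2_2d(tab),
                 tolerance = 1e-9)
  }
})

test_that("conditional G2 sums per-stratum statistics and df over non-empty margins", {
  set.seed(102)
  n <- 400
  z <- sample(0:2, n, TRUE)
  y <- rbinom(n, 1, 0.5)
  x <- sample(0:2, n, TRUE, prob = c(.5, .3, .2))
  t <- g2_test(y, x, cond = z)
  # oracle: brute-force per stratum
  stat <- 0; df <- 0
  for (s in 0:2) {
    tab <- table(y[z == s], x[z == s])
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    stat <- stat + brute_g2_2d(tab)
    df <- df + (nrow(tab) - 1) * (ncol(tab) - 1)
  }
  expect_equal(t$statistic, stat, tolerance = 1e-9)
  expect_equal(t$df, df)
  expect_equal(t$p_value, pchisq(stat, df, lower.tail = FALSE))
})

test_that("reliability heuristic uses the average-cell-count rule", {
  set.seed(103)
  n <- 100
  y <- rep(0:1, 50)
  x <- sample(0:2, n, TRUE)
  z1 <- sample(0:2, n, TRUE); z2 <- sample(0:2, n, TRUE)
  # 100 < 5 * 2 * 3 * 9 = 270 -> unreliable, no decision
  t <- g2_test(y, x, cond = cbind(z1, z2))
  expect_false(t$reliable)
  expect_true(is.na(t$independent))
  # marginal: 100 >= 5 * 2 * 3 = 30 -> reliable
  expect_true(g2_test(y, x)$reliable)
})

test_that("marginal G2 is invariant to permuting subjects and rejects a constant target", {
  set.seed(104)
  y <- rbinom(200, 1, 0.4); x <- sample(0:2, 200, TRUE)
  perm <- sample(200)
  expect_equal(g2_test(y, x)$statistic, g2_test(y[perm], x[perm])$statistic)
  expect_error(g2_test(rep(1L, 50), sample(0:2, 50, TRUE)),
               "degenerate target")
})

test_that("rows with missing values are dropped pairwise per test", {
  y <- c(0, 0, 1, 1, 0, 1)
  x <- c(0, 1, NA, 2, 1, 0)
  t <- g2_test(y, x)
  expect_equal(t$n_used, 5L)
})

test_that("max conditioning size follows the floor-log derivation", {
  expect_equal(max_conditioning_size(1366, 5, 2, 3, 3), 3L)
  expect_equal(max_conditioning_size(90, 5, 2, 3, 3), 1L)
  expect_equal(max_conditioning_size(29, 5, 2, 3, 3), 0L)
  # exact powers must not fall to the lower integer through floating point
  expect_equal(max_conditioning_size(5 * 2 * 3 * 27, 5, 2, 3, 3), 3L)
})

test_that("HWE test matches hand-computed chi-squared values", {
  t0 <- hwe_test(25, 50, 25)
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)

  t1 <- hwe_test(50, 0, 50)  # no heterozygotes at p = q = 0.5
  expect_equal(t1$statistic, 100, tolerance = 1e-12)
  expect_lt(t1$p_value, 1e-5)

  # statistic is proportional to n at fixed genotype proportions
  a <- hwe_test(30, 40, 30)
  b <- hwe_test(300, 400, 300)
  expect_equal(b$statistic, 10 * a$statistic, tolerance = 1e-9)
})

test_that("MAF counts alleles over non-missing calls", {
  expect_equal(maf(rep(0L, 20)), 0)
  expect_equal(maf(rep(1L, 10)), 0.5)
  # minor-homozygote 182, het 468, major-homozygote 213 -> 832/1726
  g <- counts_to_dosage(182, 468, 213)
  expect_equal(maf(g), (2 * 182 + 468) / (2 * 863), tolerance = 1e-12)
  expect_equal(round(100 * maf(g)), 48)
  expect_error(maf(c(NA_integer_, NA_integer_)), "missing")
})

test_that("LD r2 is 1 for exact copies, near 0 for independent SNPs", {
  set.seed(105)
  a <- sample(0:2, 200, TRUE)
  expect_equal(ld_r2(a, a), 1)
  b <- sample(0:2, 10000, TRUE)
  a2 <- sample(0:2, 10000, TRUE)
  expect_lt(ld_r2(a2, b), 0.01)
  expect_error(ld_r2(rep(1L, 10), sample(0:2, 10, TRUE)), "monomorphic")
})

test_that("complete-LD anti-diagonal contingency pattern gives r2 = 1", {
  cnt <- dup_pair_counts()
  pooled <- cnt$cases + cnt$controls  # (2,0): 248, (1,1): 921, (0,2): 875
  a <- c(rep(2L, pooled[["aa_bb"]]), rep(1L, pooled[["het_het"]]),
         rep(0L, pooled[["AA_BB"]]))
  b <- c(rep(0L, pooled[["aa_bb"]]), rep(1L, pooled[["het_het"]]),
         rep(2L, pooled[["AA_BB"]]))
  expect_equal(ld_r2(a, b), 1, tolerance = 1e-12)
})

test_that("hypergeometric upper tail matches exhaustive enumeration", {
  # literal enumeration of all C(10, 4) draws from a 5-marked population
  pop <- c(rep(1, 5), rep(0, 5))
  draws <- combn(10, 4)
  k_obs <- colSums(matrix(pop[draws], nrow = 4))
  expect_equal(hypergeom_enrichment(10, 5, 4, 4), mean(k_obs >= 4),
               tolerance = 1e-12)
  expect_equal(hypergeom_enrichment(10, 5, 4, 4), 5 / 210, tolerance = 1e-12)
  expect_equal(hypergeom_enrichment(12, 7, 5, 0), 1)
  expect_error(hypergeom_enrichment(10, 5, 4, 6), "invalid")
})

test_that("BH-FDR step-up rejects the hand-computed set", {
  expect_equal(bh_fdr(rep(1, 5)), rep(FALSE, 5))
  expect_equal(bh_fdr(0.04, q = 0.05), TRUE)
  # step-up: p(3)=0.04 > 3/4*0.05; p(2)=0.012 <= 2/4*0.05 -> reject ranks 1-2
  expect_equal(bh_fdr(c(0.001, 0.012, 0.04, 0.9), q = 0.05),
               c(TRUE, TRUE, FALSE, FALSE))
})

test_that("BH never rejects hypotheses whose p-value exceeds q", {
  set.seed(106)
  for (r in 1:50) {
    p <- runif(40)^sample(1:3, 1)
    expect_true(all(p[bh_fdr(p, 0.05)] <= 0.05))
  }
})
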