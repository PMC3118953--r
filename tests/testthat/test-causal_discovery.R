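# Shared planted-truth dataset: 5 causal SNPs among 200, moderate LD.
planted_ds <- local({
  spec <- simulation_spec(n_cases = 1000, n_controls = 1000, n_snps = 200,
                          maf_range = c(0.2, 0.4),
                          ld_block_size = 10, ld_rho = 0.5,
                          causal_snps = list(indices = c(15, 55, 95, 135, 175),
                                             betas = c(0.8, 1.0, 0.7, 1.2, 0.9)),
                          beta0 = -1, seed = 42)
  generate_dataset(spec)
})

test_that("marginal ranking has calibrated type-I error on null SNPs", {
  set.seed(201)
  fracs <- vapply(1:10, function(r) {
    spec <- simulation_spec(n_cases = 400, n_controls = 400, n_snps = 300,
                            ld_block_size = 1, seed = 300 + r)
    g <- generate_dataset(spec)
    length(rank_candidates(g$dataset)) / 300
  }, numeric(1))
  expect_gt(mean(fracs), 0.02)
  expect_lt(mean(fracs), 0.08)
})

test_that("the strongest causal SNP ranks first and empty input ranks empty", {
  spec <- simulation_spec(n_cases = 500, n_controls = 500, n_snps = 50,
                          causal_snps = list(indices = 25L, betas = 2),
                          beta0 = -1, seed = 11)
  g <- generate_dataset(spec)
  expect_equal(rank_candidates(g$dataset)[1], "snp0025")

  empty <- subset_dataset(g$dataset, snps = integer(0))
  expect_equal(rank_candidates(empty), character(0))
})

test_that("GLL returns an empty boundary when the phenotype is independent of all SNPs", {
  spec <- simulation_spec(n_cases = 300, n_controls = 300, n_snps = 30,
                          ld_block_size = 1, seed = 12)
  g <- generate_dataset(spec)
  mb <- gll_mb(g$dataset)
  expect_equal(mb$snp_ids, character(0))
})

test_that("GLL recovers a planted 5-SNP Markov boundary", {
  mb <- gll_mb(planted_ds$dataset)
  expect_setequal(mb$snp_ids, names(planted_ds$truth$causal_effects))
})

test_that("exactly one of a perfect-LD pair survives elimination", {
  spec <- simulation_spec(n_cases = 800, n_controls = 800, n_snps = 40,
                          causal_snps = list(indices = 10L, betas = 1.2),
                          beta0 = -1, duplicate_pairs = list(c(10L, 30L)),
                          seed = 13)
  g <- generate_dataset(spec)
  mb <- gll_mb(g$dataset)
  expect_equal(length(intersect(mb$snp_ids, c("snp0010", "snp0030"))), 1L)
})

test_that("GLL matches the d-separation boundary on a tiny known network", {
  # y has parents x1, x2 and child x3; x4, x5 are disconnected noise.
  # Markov boundary of y (no spouses) = {x1, x2, x3}.
  set.seed(202)
  n <- 50000
  x1 <- sample(0:2, n, TRUE, prob = c(.45, .4, .15))
  x2 <- sample(0:2, n, TRUE, prob = c(.3, .5, .2))
  y <- rbinom(n, 1, plogis(-1 + 0.9 * x1 + 0.8 * x2))
  x3 <- rbinom(n, 1, plogis(-0.8 + 1.2 * y))
  x4 <- sample(0:2, n, TRUE)
  x5 <- sample(0:1, n, TRUE)
  ds <- make_dataset(list(x1 = x1, x2 = x2, x3 = x3, x4 = x4, x5 = x5), y)
  mb <- gll_mb(ds)
  expect_setequal(mb$snp_ids, c("x1", "x2", "x3"))
})

test_that("verify_equivalence accepts identity and duplicates, rejects omissions", {
  spec <- simulation_spec(n_cases = 800, n_controls = 800, n_snps = 60,
                          causal_snps = list(indices = c(10L, 30L, 50L),
                                             betas = c(1.0, 1.1, 0.9)),
                          beta0 = -1, duplicate_pairs = list(c(30L, 40L)),
                          seed = 14)
  g <- generate_dataset(spec)
  ds <- g$dataset
  mb <- c("snp0010", "snp0030", "snp0050")
  expect_true(verify_equivalence(mb, mb, ds))
  # duplicate substitution carries the same information
  expect_true(verify_equivalence(mb, c("snp0010", "snp0040", "snp0050"), ds))
  # dropping a strong causal SNP with no equivalent loses information
  expect_false(verify_equivalence(mb, c("snp0010", "snp0030"), ds))
})

test_that("TIE* returns a single boundary when no equivalences exist", {
  tie <- tie_star(planted_ds$dataset)
  expect_equal(length(tie$boundaries), 1L)
  expect_setequal(tie$boundaries[[1]]$snp_ids,
                  names(planted_ds$truth$causal_effects))
})

test_that("TIE* enumerates substitution products of duplicated boundary members", {
  # one duplicated member of a 5-SNP boundary: exactly 2 boundaries, 4 shared
  spec <- simulation_spec(n_cases = 800, n_controls = 800, n_snps = 100,
                          maf_range = c(0.2, 0.4), ld_block_size = 10,
                          ld_rho = 0.3,
                          causal_snps = list(indices = c(15, 35, 55, 75, 95),
                                             betas = c(0.9, 1.0, 0.8, 1.1, 0.9)),
                          beta0 = -1, duplicate_pairs = list(c(55L, 60L)),
                          seed = 7)
  g <- generate_dataset(spec)
  tie <- tie_star(g$dataset)
  expect_equal(length(tie$boundaries), 2L)
  expect_equal(length(tie$shared_core), 4L)
  expect_setequal(lapply(tie$boundaries, `[[`, "snp_ids"),
                  truth_boundaries(g$truth))

  # two disjoint duplicate pairs inside a 4-SNP boundary: 4 boundaries
  spec2 <- simulation_spec(n_cases = 800, n_controls = 800, n_snps = 60,
                           maf_range = c(0.2, 0.4), ld_block_size = 10,
                           ld_rho = 0,
                           causal_snps = list(indices = c(5, 15, 25, 35),
                                              betas = c(1.0, 1.1, 0.9, 1.2)),
                           beta0 = -1,
                           duplicate_pairs = list(c(5L, 50L), c(25L, 55L)),
                           seed = 8)
  g2 <- generate_dataset(spec2)
  tie2 <- tie_star(g2$dataset)
  expect_equal(length(tie2$boundaries), 4L)
  expect_setequal(lapply(tie2$boundaries, `[[`, "snp_ids"),
                  truth_boundaries(g2$truth))
})

test_that("every TIE* boundary passes verification and output is deterministic", {
  spec <- simulation_spec(n_cases = 600, n_controls = 600, n_snps = 50,
                          causal_snps = list(indices = c(10L, 30L),
                                             betas = c(1.0, 1.1)),
                          beta0 = -1, duplicate_pairs = list(c(10L, 45L)),
                          seed = 15)
  g <- generate_dataset(spec)
  tie_a <- tie_star(g$dataset)
  tie_b <- tie_star(g$dataset)
  expect_identical(lapply(tie_a$boundaries, `[[`, "snp_ids"),
                   lapply(tie_b$boundaries, `[[`, "snp_ids"))
  for (b in tie_a$boundaries)
    expect_true(verify_equivalence(tie_a$reference, b, g$dataset))
})
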