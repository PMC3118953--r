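test_that("stratified split keeps per-stratum proportions with round-half-up", {
  spec <- simulation_spec(n_cases = 9, n_controls = 9, n_snps = 4, seed = 1)
  ds <- generate_dataset(spec)$dataset
  sp <- stratified_split(ds, 2 / 3, seed = 2)
  expect_equal(sum(sp$train$phenotype == 1L), 6L)
  expect_equal(sum(sp$train$phenotype == 0L), 6L)
  expect_equal(sum(sp$test$phenotype == 1L), 3L)
  expect_equal(sum(sp$test$phenotype == 0L), 3L)
  expect_equal(length(intersect(sp$train$subject_ids, sp$test$subject_ids)), 0L)
  expect_setequal(c(sp$train$subject_ids, sp$test$subject_ids),
                  ds$subject_ids)
})

test_that("splits are deterministic per seed and vary across seeds", {
  spec <- simulation_spec(n_cases = 100, n_controls = 100, n_snps = 4,
                          seed = 3)
  ds <- generate_dataset(spec)$dataset
  a <- stratified_split(ds, seed = 7)
  b <- stratified_split(ds, seed = 7)
  c_ <- stratified_split(ds, seed = 8)
  expect_identical(a$train$subject_ids, b$train$subject_ids)
  expect_false(identical(a$train$subject_ids, c_$train$subject_ids))
})

test_that("train case:control ratio stays within one subject of the full data", {
  spec <- simulation_spec(n_cases = 427, n_controls = 573, n_snps = 3,
                          seed = 4)
  ds <- generate_dataset(spec)$dataset
  sp <- stratified_split(ds, 2 / 3, seed = 5)
  n_tr_case <- sum(sp$train$phenotype == 1L)
  n_tr_ctrl <- sum(sp$train$phenotype == 0L)
  expect_lte(abs(n_tr_case - 2 / 3 * 427), 0.5 + 1e-9)
  expect_lte(abs(n_tr_ctrl - 2 / 3 * 573), 0.5 + 1e-9)
})

test_that("AUC equals exhaustive pair counting with half-credit ties", {
  expect_equal(auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auc(rep(0.3, 6), rep(c(0, 1), 3)), 0.5)
  # 4 case-control pairs: 0.35>0.1, 0.35<0.4, 0.8>0.1, 0.8>0.4 -> 3/4
  expect_equal(auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)

  set.seed(401)
  for (r in 1:20) {
    s <- round(runif(30), 2)  # rounding provokes ties
    y <- rbinom(30, 1, 0.5)
    if (length(unique(y)) < 2) next
    pairs <- outer(s[y == 1], s[y == 0],
                   function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(auc(s, y), mean(pairs), tolerance = 1e-12)
  }
  expect_error(auc(1:4, rep(1, 4)), "both classes")
})

test_that("AUC of negated tie-free scores is the complement", {
  set.seed(402)
  s <- rnorm(40)
  y <- rbinom(40, 1, 0.5)
  expect_equal(auc(s, y) + auc(-s, y), 1, tolerance = 1e-12)
})

test_that("ROC curve is monotone from (0,0) to (1,1)", {
  set.seed(403)
  s <- rnorm(50); y <- rbinom(50, 1, 0.4)
  rc <- roc_curve(s, y)
  expect_equal(unlist(rc[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(rc[nrow(rc), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(rc$fpr) >= 0))
  expect_true(all(diff(rc$tpr) >= 0))
})

test_that("DeLong interval is symmetric about AUC and collapses when degenerate", {
  set.seed(404)
  s <- c(rnorm(50, 0), rnorm(50, 1))
  y <- rep(c(0, 1), each = 50)
  ci <- delong_ci(s, y)
  expect_equal(ci$auc - ci$ci_low, ci$ci_high - ci$auc, tolerance = 1e-12)
  expect_true(ci$ci_low <= ci$auc && ci$auc <= ci$ci_high)

  # perfect separation: zero variance, interval collapses at 1
  perf <- delong_ci(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(perf$auc, 1)
  expect_equal(perf$ci_low, 1)
  expect_equal(perf$ci_high, 1)
})

test_that("DeLong interval width shrinks with sample size", {
  width_at <- function(n, seed) {
    set.seed(seed)
    s <- c(rnorm(n, 0), rnorm(n, 0.8))
    y <- rep(c(0, 1), each = n)
    ci <- delong_ci(s, y)
    ci$ci_high - ci$ci_low
  }
  expect_lt(width_at(1000, 405), width_at(100, 405))
})

test_that("DeLong AUC and interval agree with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(406)
  s <- rnorm(120)
  y <- rbinom(120, 1, 0.5)
  ours <- delong_ci(s, y)
  ref <- pROC::ci.auc(pROC::roc(y, s, quiet = TRUE, direction = "<"),
                      method = "delong")
  expect_equal(ours$auc, as.numeric(ref[2]), tolerance = 1e-10)
  expect_equal(ours$ci_low, as.numeric(ref[1]), tolerance = 1e-10)
  expect_equal(ours$ci_high, as.numeric(ref[3]), tolerance = 1e-10)
})

test_that("a one-split robustness run reduces to the hold-out protocol", {
  spec <- simulation_spec(n_cases = 250, n_controls = 250, n_snps = 20,
                          maf_range = c(0.2, 0.4),
                          causal_snps = list(indices = c(5L, 15L),
                                             betas = c(1.2, 1.4)),
                          beta0 = -1, seed = 6)
  ds <- generate_dataset(spec)$dataset
  rob <- robustness(ds, n_splits = 1L, folds = 3L,
                    gamma_grid = 0.25, seed = 20)
  expect_equal(length(rob$failures), 0L)
  expect_equal(sum(!is.na(rob$auc)), 1L)
  expect_true(rob$auc_mean > 0.5)
  expect_true(all(rob$selection_freq %in% c(0, 1)))
})

test_that("duplicated causal SNPs both accumulate selection frequency", {
  spec <- simulation_spec(n_cases = 300, n_controls = 300, n_snps = 20,
                          maf_range = c(0.2, 0.4),
                          causal_snps = list(indices = c(5L, 15L),
                                             betas = c(1.3, 1.3)),
                          beta0 = -1, duplicate_pairs = list(c(5L, 10L)),
                          seed = 7)
  ds <- generate_dataset(spec)$dataset
  rob <- robustness(ds, n_splits = 12L, folds = 3L, gamma_grid = 0.25,
                    seed = 30)
  expect_equal(length(rob$failures), 0L)
  f <- rob$selection_freq
  # TIE* reports both members of the duplicated pair (multiplicity), so
  # their frequencies jointly dominate what either would carry alone
  expect_gte(f[["snp0005"]] + f[["snp0010"]], max(f[["snp0005"]], f[["snp0010"]]))
  expect_gt(f[["snp0005"]], 0)
  expect_gt(f[["snp0010"]], 0)
  expect_gte(f[["snp0015"]], 0.5)
  # bit-reproducible under an identical seed
  rob2 <- robustness(ds, n_splits = 12L, folds = 3L, gamma_grid = 0.25,
                     seed = 30)
  expect_identical(rob$auc, rob2$auc)
  expect_identical(rob$selection_freq, rob2$selection_freq)
})
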