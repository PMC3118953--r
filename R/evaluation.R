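#' Stratified train/test split
#'
#' Samples, within each phenotype stratum and without replacement,
#' `round(train_fraction * stratum size)` subjects (round half up) into the
#' training set; the remainder form the test set. The split therefore retains
#' the case/control proportion to within one subject per stratum and is
#' deterministic for a fixed seed.
#'
#' @param ds A [genotype_dataset()] with phenotype.
#' @param train_fraction Fraction of each stratum assigned to training
#'   (default 2/3).
#' @param seed Integer seed.
#' @return List with `train` and `test` datasets.
#' @export
stratified_split <- function(ds, train_fraction = 2 / 3, seed = 1L) {
  if (is.null(ds$phenotype)) stop("stratified split requires a phenotype")
  stopifnot(train_fraction > 0, train_fraction < 1)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  train_rows <- integer(0)
  for (cls in c(1L, 0L)) {
    rows <- which(ds$phenotype == cls)
    if (length(rows) == 0L) stop("empty phenotype stratum: ", cls)
    n_tr <- as.integer(floor(train_fraction * length(rows) + 0.5))
    n_tr <- max(1L, min(n_tr, length(rows) - 1L))
    train_rows <- c(train_rows, sample(rows, n_tr))
  }
  train_rows <- sort(train_rows)
  test_rows <- setdiff(seq_len(nrow(ds$calls)), train_rows)
  list(train = subset_dataset(ds, subjects = train_rows),
       test = subset_dataset(ds, subjects = test_rows))
}

#' Area under the ROC curve
#'
#' Mann-Whitney form: the probability that a random case scores above a
#' random control, ties counted one half.
#'
#' @param scores Numeric scores (higher = more case-like).
#' @param labels Binary 0/1 labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("AUC needs both classes present")
  m <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  r <- rank(scores)
  (sum(r[labels == 1L]) - m * (m + 1) / 2) / (m * n0)
}

#' ROC curve points
#'
#' Threshold sweep over the unique scores; the curve starts at (0, 0), ends at
#' (1, 1) and is monotone non-decreasing.
#'
#' @inheritParams auc
#' @return Data frame with `fpr` and `tpr`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  s <- scores[ord]
  keep <- c(diff(s) != 0, TRUE)  # one point per distinct threshold
  tpr <- cumsum(y == 1L) / sum(y == 1L)
  fpr <- cumsum(y == 0L) / sum(y == 0L)
  data.frame(fpr = c(0, fpr[keep]), tpr = c(0, tpr[keep]))
}

#' DeLong confidence interval for the AUC
#'
#' Nonparametric interval `AUC +/- z * sqrt(S10/m + S01/n)` where `S10` and
#' `S01` are the variances of the case and control placement values; the
#' interval is symmetric about the AUC before truncation to `[0, 1]`.
#' Degenerate variance (e.g. perfect separation) collapses the interval onto
#' the AUC.
#'
#' @inheritParams auc
#' @param level Confidence level (default 0.95).
#' @return List with `auc`, `ci_low`, `ci_high`, `se`.
#' @export
delong_ci <- function(scores, labels, level = 0.95) {
  labels <- as.integer(labels)
  s1 <- scores[labels == 1L]
  s0 <- scores[labels == 0L]
  if (length(s1) < 2L || length(s0) < 2L)
    stop("DeLong interval needs at least two subjects per class")
  psi <- outer(s1, s0, function(a, b) (a > b) + 0.5 * (a == b))
  v10 <- rowMeans(psi)   # case placement values
  v01 <- colMeans(psi)   # control placement values
  a <- mean(psi)
  se <- sqrt(stats::var(v10) / length(s1) + stats::var(v01) / length(s0))
  z <- stats::qnorm((1 + level) / 2)
  list(auc = a,
       ci_low = max(0, a - z * se),
       ci_high = min(1, a + z * se),
       se = se)
}

#' Full ROC report for a score vector
#'
#' @inheritParams delong_ci
#' @return A `roc_report`: `auc`, `ci_low`, `ci_high`, `curve`, `n_cases`,
#'   `n_controls`.
#' @export
roc_report <- function(scores, labels, level = 0.95) {
  ci <- delong_ci(scores, labels, level)
  structure(list(auc = ci$auc, ci_low = ci$ci_low, ci_high = ci$ci_high,
                 curve = roc_curve(scores, labels),
                 n_cases = sum(labels == 1L),
                 n_controls = sum(labels == 0L)),
            class = "roc_report")
}

#' @export
print.roc_report <- function(x, ...) {
  cat(sprintf("AUC = %.3f (%.0f%% CI [%.3f; %.3f]), %d cases / %d controls\n",
              x$auc, 95, x$ci_low, x$ci_high, x$n_cases, x$n_controls))
  invisible(x)
}

#' Resampling robustness protocol
#'
#' For each of `n_splits` random stratified splits: discover all
#' information-equivalent Markov boundaries on the training part with
#' [tie_star()], tune and fit a kernel ridge regression signature per
#' boundary, and score the held-out part. Aggregates the per-split AUC (mean
#' over that split's boundaries) and, per SNP, the fraction of splits in
#' which it was selected (membership in at least one boundary). A failing
#' split is recorded with its index, never silently dropped.
#'
#' @param ds A QC'd [genotype_dataset()] with phenotype.
#' @param n_splits Number of random splits (default 1000).
#' @param cfg A [discovery_config()].
#' @param train_fraction Training fraction per stratum (default 2/3).
#' @param lambda_grid,gamma_grid Hyperparameter grids for [tune_krr()];
#'   `NULL` gamma grid defaults per boundary size.
#' @param folds Cross-validation folds inside each training set.
#' @param seed Base seed; split `i` uses `seed + i`.
#' @return A `robustness_report`: `auc` (per split), `auc_mean`, `auc_sd`,
#'   `selection_freq` (named per snp_id), `boundary_counts`, `failures`.
#' @export
robustness <- function(ds, n_splits = 1000L, cfg = discovery_config(),
                       train_fraction = 2 / 3,
                       lambda_grid = default_lambda_grid(),
                       gamma_grid = NULL, folds = 10L, seed = 1L) {
  all_ids <- ds$snps$snp_id
  sel_count <- stats::setNames(numeric(length(all_ids)), all_ids)
  aucs <- rep(NA_real_, n_splits)
  n_bound <- rep(NA_integer_, n_splits)
  failures <- list()
  for (i in seq_len(n_splits)) {
    res <- tryCatch({
      sp <- stratified_split(ds, train_fraction, seed = seed + i)
      tie <- tie_star(sp$train, cfg)
      split_aucs <- vapply(tie$boundaries, function(b) {
        if (length(b$snp_ids) == 0L) return(0.5)  # empty signature: random
        enc <- encode(sp$train, b$snp_ids)
        gg <- if (is.null(gamma_grid)) default_gamma_grid(length(b$snp_ids))
              else gamma_grid
        tuned <- tune_krr(enc$X, sp$train$phenotype, lambda_grid, gg,
                          folds = folds, seed = seed + i)
        fit <- krr_fit(enc$X, sp$train$phenotype, tuned$lambda, tuned$gamma,
                       snp_ids = b$snp_ids, encode_params = enc$params)
        auc(predict(fit, sp$test), sp$test$phenotype)
      }, numeric(1))
      selected <- unique(unlist(lapply(tie$boundaries, `[[`, "snp_ids")))
      list(auc = mean(split_aucs), selected = selected,
           n_boundaries = length(tie$boundaries))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <- list(split = i,
                                                message = conditionMessage(res))
    } else {
      aucs[i] <- res$auc
      n_bound[i] <- res$n_boundaries
      sel_count[res$selected] <- sel_count[res$selected] + 1
    }
  }
  ok <- sum(!is.na(aucs))
  structure(list(auc = aucs,
                 auc_mean = mean(aucs, na.rm = TRUE),
                 auc_sd = stats::sd(aucs, na.rm = TRUE),
                 selection_freq = sel_count / max(ok, 1L),
                 boundary_counts = n_bound,
                 failures = failures,
                 n_splits = n_splits),
            class = "robustness_report")
}

#' @export
print.robustness_report <- function(x, ...) {
  cat(sprintf("robustness: %d splits, AUC %.3f +/- %.3f; %d failures\n",
              x$n_splits, x$auc_mean, x$auc_sd, length(x$failures)))
  top <- sort(x$selection_freq[x$selection_freq > 0], decreasing = TRUE)
  top <- utils::head(top, 10L)
  if (length(top) > 0) {
    cat("  top selection frequencies:\n")
    for (nm in names(top)) cat(sprintf("    %s: %.2f\n", nm, top[[nm]]))
  }
  invisible(x)
}
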