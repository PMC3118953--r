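#' SNP call-rate filter
#'
#' Retains SNPs whose call must be present in strictly more than `min_rate` of
#' subjects (non-missing fraction > `min_rate`).
#'
#' @param ds A [genotype_dataset()].
#' @param min_rate Minimum call-rate fraction (default 0.95).
#' @return List with `dataset` (the filtered dataset) and `removed`
#'   (character vector of removed snp_ids).
#' @export
call_rate_filter <- function(ds, min_rate = 0.95) {
  stopifnot(min_rate > 0, min_rate <= 1)
  rate <- 1 - colMeans(is.na(ds$calls))
  keep <- rate > min_rate
  list(dataset = subset_dataset(ds, snps = which(keep)),
       removed = ds$snps$snp_id[!keep])
}

#' Minor-allele-frequency filter
#'
#' Retains SNPs whose pooled minor-allele frequency, computed on non-missing
#' calls, is strictly above `min_maf`. A SNP with no non-missing calls is
#' removed with reason `"no data"`.
#'
#' @param ds A [genotype_dataset()].
#' @param min_maf MAF threshold (default 0.01).
#' @return List with `dataset`, `removed` and `reasons` (named by snp_id).
#' @export
maf_filter <- function(ds, min_maf = 0.01) {
  stopifnot(min_maf >= 0, min_maf < 0.5)
  n_obs <- colSums(!is.na(ds$calls))
  freq <- ifelse(n_obs > 0, colSums(ds$calls, na.rm = TRUE) / (2 * n_obs), NA)
  freq <- pmin(freq, 1 - freq)  # minor frequency even if orientation drifted
  keep <- !is.na(freq) & freq > min_maf
  reasons <- ifelse(n_obs == 0, "no data", "maf")
  removed <- ds$snps$snp_id[!keep]
  list(dataset = subset_dataset(ds, snps = which(keep)),
       removed = removed,
       reasons = stats::setNames(reasons[!keep], removed))
}

#' Hardy-Weinberg equilibrium filter
#'
#' Retains SNPs whose HWE goodness-of-fit p-value ([hwe_test()]) is at least
#' `alpha` in the chosen cohort. Following common GWAS practice the test runs
#' on controls by default; set `cohort = "all"` to pool everyone.
#'
#' @param ds A [genotype_dataset()] (phenotype required when
#'   `cohort = "controls"`).
#' @param alpha Significance threshold (default 1e-5).
#' @param cohort `"controls"` or `"all"`.
#' @return List with `dataset` and `removed`.
#' @export
hwe_filter <- function(ds, alpha = 1e-5, cohort = c("controls", "all")) {
  cohort <- match.arg(cohort)
  if (cohort == "controls") {
    if (is.null(ds$phenotype)) stop("cohort = 'controls' requires a phenotype")
    rows <- ds$phenotype == 0L
  } else {
    rows <- rep(TRUE, nrow(ds$calls))
  }
  g <- ds$calls[rows, , drop = FALSE]
  pvals <- vapply(seq_len(ncol(g)), function(j) {
    col <- g[, j]
    col <- col[!is.na(col)]
    if (length(col) == 0L) return(1)  # no data in cohort: cannot reject HWE
    hwe_test(sum(col == 2L), sum(col == 1L), sum(col == 0L))$p_value
  }, numeric(1))
  keep <- pvals >= alpha
  list(dataset = subset_dataset(ds, snps = which(keep)),
       removed = ds$snps$snp_id[!keep])
}

#' QC report bookkeeping
#'
#' Builds the per-step removal report for the sequential filter chain
#' (call rate, then MAF, then HWE). `n_output` is always
#' `n_input - (removed_call_rate + removed_maf + removed_hwe)`.
#'
#' @param n_input SNPs entering QC.
#' @param removed_call_rate,removed_maf,removed_hwe Per-step removal counts,
#'   each counted on the survivors of the previous step.
#' @param reasons Optional named character vector mapping snp_id to the first
#'   failing rule.
#' @return A `qc_report` list.
#' @export
qc_report <- function(n_input, removed_call_rate, removed_maf, removed_hwe,
                      reasons = character(0)) {
  structure(list(
    n_input = as.integer(n_input),
    removed_call_rate = as.integer(removed_call_rate),
    removed_maf = as.integer(removed_maf),
    removed_hwe = as.integer(removed_hwe),
    n_output = as.integer(n_input - removed_call_rate - removed_maf -
                            removed_hwe),
    reasons = reasons), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC:", x$n_input, "SNPs in;",
      x$removed_call_rate, "failed call rate,",
      x$removed_maf, "failed MAF,",
      x$removed_hwe, "failed HWE;",
      x$n_output, "SNPs out\n")
  invisible(x)
}

#' Apply the full SNP QC chain
#'
#' Runs the three filters sequentially in the fixed order call rate, MAF, HWE;
#' each step's removals are counted among the survivors of the previous step,
#' so the removal sets are disjoint and sum to `n_input - n_output`.
#'
#' @param ds A [genotype_dataset()].
#' @param min_call_rate Call-rate threshold (default 0.95, strict).
#' @param min_maf MAF threshold (default 0.01, strict).
#' @param hwe_alpha HWE significance threshold (default 1e-5).
#' @param hwe_cohort `"controls"` (default) or `"all"`.
#' @return List with `dataset` and `report` (a [qc_report()]).
#' @export
apply_qc <- function(ds, min_call_rate = 0.95, min_maf = 0.01,
                     hwe_alpha = 1e-5, hwe_cohort = "controls") {
  n_input <- ncol(ds$calls)
  s1 <- call_rate_filter(ds, min_call_rate)
  s2 <- maf_filter(s1$dataset, min_maf)
  s3 <- hwe_filter(s2$dataset, hwe_alpha, hwe_cohort)
  reasons <- c(stats::setNames(rep("call_rate", length(s1$removed)), s1$removed),
               s2$reasons,
               stats::setNames(rep("hwe", length(s3$removed)), s3$removed))
  list(dataset = s3$dataset,
       report = qc_report(n_input, length(s1$removed), length(s2$removed),
                          length(s3$removed), reasons))
}
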