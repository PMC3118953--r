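#' Binarize missing genotype calls
#'
#' Returns a matrix of the same shape as the call matrix with 1 wherever a
#' call is missing and 0 elsewhere — the representation used to ask whether
#' the missingness pattern itself predicts the phenotype.
#'
#' @param ds A [genotype_dataset()].
#' @return Integer matrix (subjects x SNPs) with snp_id column names.
#' @export
binarize_missing <- function(ds) {
  M <- is.na(ds$calls) * 1L
  colnames(M) <- ds$snps$snp_id
  rownames(M) <- ds$subject_ids
  M
}

#' Enrichment bookkeeping for significant-missingness counts
#'
#' Given the four counts of the locus-enrichment contrast — `N` SNPs with
#' missing values genome-wide, `K` of them significantly associated with the
#' phenotype, `n` SNPs with missing values inside the locus and `k`
#' significant among those — returns the two significant fractions (as
#' percentages) and the hypergeometric upper-tail enrichment p-value.
#'
#' @param N,K,n,k Counts as above.
#' @return List with `pct_genomewide` (`100 * K / N`), `pct_locus`
#'   (`100 * k / n`) and `enrichment_p`.
#' @export
enrichment_summary <- function(N, K, n, k) {
  list(pct_genomewide = 100 * K / N,
       pct_locus = 100 * k / n,
       enrichment_p = hypergeom_enrichment(N, K, n, k))
}

#' Missingness-pattern analysis
#'
#' Restricts to SNPs with at least one missing call, tests each SNP's
#' missingness indicator against the phenotype with the marginal G2 test,
#' applies Benjamini-Hochberg FDR at `fdr_q`, and evaluates hypergeometric
#' enrichment of significant-missingness SNPs inside a coordinate locus
#' window. Additionally fits a kernel ridge regression classifier on the
#' binarized missingness matrix over a stratified split and reports its
#' held-out ROC: under purely random (MCAR) missingness this classifier is
#' uninformative, while phenotype-dependent (NMAR) missingness makes it
#' predictive.
#'
#' @param ds A [genotype_dataset()] with phenotype.
#' @param locus Length-3 vector/list `(chromosome, start, end)` defining the
#'   locus window (1-based, inclusive), or `NULL` to skip enrichment.
#' @param fdr_q FDR level for the per-SNP missingness association
#'   (default 0.05).
#' @param seed Seed for the classifier's stratified split and tuning folds.
#' @param train_fraction Training fraction of the classifier split.
#' @param lambda_grid,gamma_grid,folds Tuning controls for the classifier;
#'   `NULL` gamma grid defaults to [default_gamma_grid()] of the feature
#'   count.
#' @return A `missingness_report`: per-SNP table, counts, `enrichment_p`
#'   (NA with an explanatory `note` when the locus holds no missing-value
#'   SNPs) and the classifier `roc_report`.
#' @export
missingness_analysis <- function(ds, locus = NULL, fdr_q = 0.05, seed = 1L,
                                 train_fraction = 2 / 3,
                                 lambda_grid = default_lambda_grid(),
                                 gamma_grid = NULL, folds = 5L) {
  if (is.null(ds$phenotype)) stop("missingness analysis requires a phenotype")
  M <- binarize_missing(ds)
  has_missing <- colSums(M) > 0L
  ids <- ds$snps$snp_id[has_missing]
  Mm <- M[, has_missing, drop = FALSE]

  pvals <- vapply(seq_len(ncol(Mm)), function(j)
    g2_test(ds$phenotype, Mm[, j])$p_value, numeric(1))
  sig <- bh_fdr(pvals, fdr_q)
  per_snp <- data.frame(snp_id = ids, p_value = pvals, significant = sig,
                        stringsAsFactors = FALSE)

  enrichment_p <- NA_real_
  n_locus_missing <- NA_integer_
  n_locus_significant <- NA_integer_
  note <- NULL
  if (!is.null(locus)) {
    in_locus <- ds$snps$chromosome == as.character(locus[[1]]) &
      ds$snps$position >= as.numeric(locus[[2]]) &
      ds$snps$position <= as.numeric(locus[[3]])
    locus_ids <- ds$snps$snp_id[in_locus & has_missing]
    n_locus_missing <- length(locus_ids)
    n_locus_significant <- sum(sig[ids %in% locus_ids])
    if (n_locus_missing == 0L) {
      note <- "locus window contains no SNPs with missing calls; enrichment undefined"
    } else {
      enrichment_p <- hypergeom_enrichment(length(ids), sum(sig),
                                           n_locus_missing,
                                           n_locus_significant)
    }
  }

  classifier <- NULL
  if (ncol(Mm) > 0L) {
    sp <- stratified_split(ds, train_fraction, seed = seed)
    Xtr <- M[match(sp$train$subject_ids, ds$subject_ids), has_missing,
             drop = FALSE]
    Xte <- M[match(sp$test$subject_ids, ds$subject_ids), has_missing,
             drop = FALSE]
    storage.mode(Xtr) <- "double"; storage.mode(Xte) <- "double"
    gg <- if (is.null(gamma_grid)) default_gamma_grid(ncol(Xtr)) else gamma_grid
    tuned <- tune_krr(Xtr, sp$train$phenotype, lambda_grid, gg,
                      folds = folds, seed = seed)
    fit <- krr_fit(Xtr, sp$train$phenotype, tuned$lambda, tuned$gamma)
    classifier <- roc_report(predict(fit, Xte), sp$test$phenotype)
  }

  structure(list(n_snps_with_missing = length(ids),
                 n_significant = sum(sig),
                 locus = locus,
                 n_locus_missing = n_locus_missing,
                 n_locus_significant = n_locus_significant,
                 enrichment_p = enrichment_p,
                 note = note,
                 per_snp = per_snp,
                 classifier = classifier),
            class = "missingness_report")
}

#' @export
print.missingness_report <- function(x, ...) {
  cat("missingness:", x$n_snps_with_missing, "SNPs with missing calls;",
      x$n_significant, "significantly associated with the phenotype\n")
  if (!is.na(x$enrichment_p))
    cat(sprintf("  locus: %d missing-value SNPs, %d significant, enrichment p = %.3g\n",
                x$n_locus_missing, x$n_locus_significant, x$enrichment_p))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  if (!is.null(x$classifier))
    cat(sprintf("  missingness classifier AUC = %.3f [%.3f; %.3f]\n",
                x$classifier$auc, x$classifier$ci_low, x$classifier$ci_high))
  invisible(x)
}

#' Conditional-independence audit of externally reported SNPs
#'
#' For each known marker SNP: test its marginal G2 association with the
#' phenotype, then search the subsets of a discovered Markov boundary (in
#' increasing size up to `max_subset`, lexicographic within a size) for the
#' first subset whose reliable test renders the SNP conditionally independent
#' of the phenotype. A known SNP that is itself a boundary member is flagged
#' and excluded from the search; a known SNP absent from the dataset is
#' reported, not errored.
#'
#' @param ds A [genotype_dataset()] with phenotype.
#' @param known_snps Character vector of snp_ids to audit.
#' @param boundary A `markov_boundary` or character vector of boundary
#'   snp_ids.
#' @param alpha Significance level of the G2 tests.
#' @param max_subset Largest conditioning subset searched (default 4).
#' @param min_avg_cell Reliability requirement of the G2 test.
#' @return Data frame with one row per known SNP: `snp_id`, `in_dataset`,
#'   `in_boundary`, `marginally_associated`, `minimal_set_size` (0 when not
#'   marginally associated, NA when no separating subset was found) and
#'   `minimal_conditioning_set` (comma-joined ids, `""`, or `"none found"`).
#' @export
ci_audit <- function(ds, known_snps, boundary, alpha = 0.05, max_subset = 4L,
                     min_avg_cell = 5L) {
  b_ids <- if (inherits(boundary, "markov_boundary")) boundary$snp_ids
           else boundary
  b_idx <- match(b_ids, ds$snps$snp_id)
  if (anyNA(b_idx)) stop("boundary SNP not in dataset")
  cfg <- discovery_config(alpha = alpha,
                          max_k = max(max_subset, 1L),
                          min_avg_cell = min_avg_cell)
  cache <- new.env(parent = emptyenv())

  rows <- lapply(known_snps, function(id) {
    row <- data.frame(snp_id = id, in_dataset = TRUE, in_boundary = FALSE,
                      marginally_associated = NA,
                      minimal_set_size = NA_integer_,
                      minimal_conditioning_set = NA_character_,
                      stringsAsFactors = FALSE)
    xi <- match(id, ds$snps$snp_id)
    if (is.na(xi)) {
      row$in_dataset <- FALSE
      return(row)
    }
    if (id %in% b_ids) {
      row$in_boundary <- TRUE
      return(row)
    }
    marg <- g2_test(ds$phenotype, ds$calls[, xi], alpha = alpha,
                    min_avg_cell = min_avg_cell)
    assoc <- marg$reliable && !isTRUE(marg$independent)
    row$marginally_associated <- assoc
    if (!assoc) {
      row$minimal_set_size <- 0L
      row$minimal_conditioning_set <- ""
      return(row)
    }
    for (S in subsets_up_to(b_idx, max_subset, include_empty = FALSE)) {
      t <- g2_cached(ds$calls, ds$phenotype, xi, S, cfg, cache)
      if (t$reliable && isTRUE(t$independent)) {
        row$minimal_set_size <- length(S)
        row$minimal_conditioning_set <-
          paste(ds$snps$snp_id[S], collapse = ",")
        return(row)
      }
    }
    row$minimal_conditioning_set <- "none found"
    row
  })
  do.call(rbind, rows)
}
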