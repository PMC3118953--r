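#' Genotype dataset container
#'
#' A `genotype_dataset` bundles a subjects-by-SNPs matrix of minor-allele
#' dosage calls (0, 1, 2 or `NA` for a missing call) with SNP metadata, subject
#' identifiers, an optional binary phenotype (1 = case, 0 = control) and
#' optional per-subject covariates.
#'
#' @param calls Integer matrix, subjects in rows, SNPs in columns. Non-missing
#'   entries must be 0, 1 or 2; missing calls are `NA`.
#' @param snps A data frame of SNP metadata with columns `snp_id`,
#'   `chromosome`, `position` (1-based base-pair coordinate), `allele_minor`,
#'   `allele_major` and optionally `gene`. One row per column of `calls`;
#'   `snp_id` must be unique.
#' @param subject_ids Character vector of subject identifiers, one per row of
#'   `calls`.
#' @param phenotype Optional integer vector of 0/1 labels (1 = case). When
#'   supplied it must contain at least one case and one control.
#' @param covariates Optional data frame of extra per-subject columns (for
#'   example a 0/1 shared-epitope status).
#'
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(calls, snps, subject_ids, phenotype = NULL,
                             covariates = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  if (is.null(snps$gene)) snps$gene <- rep(NA_character_, nrow(snps))
  ds <- structure(
    list(calls = calls, snps = snps,
         subject_ids = as.character(subject_ids),
         phenotype = if (is.null(phenotype)) NULL else as.integer(phenotype),
         covariates = covariates),
    class = "genotype_dataset")
  validate_genotype_dataset(ds)
  ds
}

#' Validate a genotype dataset
#'
#' Checks the structural invariants: dimensions match the identifier lists,
#' `snp_id` values are unique, positions are 1-based, every non-missing call is
#' in \{0, 1, 2\} and, when a phenotype is present, both classes occur.
#'
#' @param ds A `genotype_dataset`.
#' @return `ds`, invisibly, or an error describing the violated invariant.
#' @export
validate_genotype_dataset <- function(ds) {
  stopifnot(inherits(ds, "genotype_dataset"))
  needed <- c("snp_id", "chromosome", "position", "allele_minor", "allele_major")
  missing_cols <- setdiff(needed, names(ds$snps))
  if (length(missing_cols) > 0L)
    stop("snps metadata lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(ds$snps) != ncol(ds$calls))
    stop("snps metadata rows (", nrow(ds$snps), ") != call matrix columns (",
         ncol(ds$calls), ")")
  if (length(ds$subject_ids) != nrow(ds$calls))
    stop("subject_ids length (", length(ds$subject_ids),
         ") != call matrix rows (", nrow(ds$calls), ")")
  if (anyDuplicated(ds$snps$snp_id))
    stop("duplicate snp_id: ",
         ds$snps$snp_id[anyDuplicated(ds$snps$snp_id)][1L])
  if (any(ds$snps$position < 1L, na.rm = TRUE))
    stop("SNP positions must be >= 1 (1-based coordinates)")
  vals <- ds$calls[!is.na(ds$calls)]
  if (length(vals) > 0L && !all(vals %in% 0:2))
    stop("non-missing calls must be 0, 1 or 2 (minor-allele dosage)")
  if (!is.null(ds$phenotype)) {
    if (length(ds$phenotype) != nrow(ds$calls))
      stop("phenotype length != number of subjects")
    ph <- ds$phenotype[!is.na(ds$phenotype)]
    if (!all(ph %in% 0:1)) stop("phenotype must be 0/1")
    if (length(unique(ph)) < 2L)
      stop("phenotype must contain at least one case and one control")
  }
  invisible(ds)
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", nrow(x$calls), "subjects x", ncol(x$calls), "SNPs\n")
  if (!is.null(x$phenotype))
    cat("  phenotype:", sum(x$phenotype == 1L), "cases /",
        sum(x$phenotype == 0L), "controls\n")
  nmiss <- sum(is.na(x$calls))
  cat("  missing calls:", nmiss,
      sprintf("(%.2f%%)\n", 100 * nmiss / length(x$calls)))
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$calls)

#' Subset a genotype dataset
#'
#' @param ds A `genotype_dataset`.
#' @param subjects Subject index (integer/logical) or subject-id character
#'   vector; `NULL` keeps all.
#' @param snps SNP index or snp-id character vector; `NULL` keeps all.
#' @return The subsetted `genotype_dataset`. Phenotype and covariates follow
#'   the subject subset; subsetting never revalidates the two-class phenotype
#'   requirement so single-class intermediates (e.g. a control-only view) are
#'   representable.
#' @export
subset_dataset <- function(ds, subjects = NULL, snps = NULL) {
  stopifnot(inherits(ds, "genotype_dataset"))
  si <- if (is.null(subjects)) seq_len(nrow(ds$calls))
        else if (is.character(subjects)) match(subjects, ds$subject_ids)
        else subjects
  vi <- if (is.null(snps)) seq_len(ncol(ds$calls))
        else if (is.character(snps)) match(snps, ds$snps$snp_id)
        else snps
  if (anyNA(si)) stop("unknown subject id(s)")
  if (anyNA(vi)) stop("unknown snp id(s)")
  out <- ds
  out$calls <- ds$calls[si, vi, drop = FALSE]
  out$snps <- ds$snps[vi, , drop = FALSE]
  rownames(out$snps) <- NULL
  out$subject_ids <- ds$subject_ids[si]
  out$phenotype <- if (is.null(ds$phenotype)) NULL else ds$phenotype[si]
  out$covariates <- if (is.null(ds$covariates)) NULL
                    else ds$covariates[si, , drop = FALSE]
  out
}

#' SNP identifiers of a dataset
#' @param ds A `genotype_dataset`.
#' @return Character vector of `snp_id`s in column order.
#' @export
snp_ids <- function(ds) ds$snps$snp_id
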