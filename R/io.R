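#' Read a genotype dataset from disk
#'
#' Two plain-text dialects are supported:
#' \describe{
#'   \item{`ped-map`}{Whitespace-delimited PLINK-style `.ped` (six leading
#'     columns: family id, subject id, paternal id, maternal id, sex,
#'     phenotype; then two allele tokens per SNP) plus `.map` (chromosome,
#'     snp id, genetic distance, 1-based position). `path` is the file prefix
#'     without extension. Phenotype 2 = case, 1 = control, 0 or -9 = missing;
#'     a dataset whose phenotype column is entirely missing is returned with
#'     `phenotype = NULL`. The genotype pair `0 0` denotes a missing call.}
#'   \item{`dosage-table`}{A TSV with header `subject_id`, `phenotype`, then
#'     one column per SNP holding minor-allele dosages 0/1/2; `NA` or `.`
#'     denote a missing call.}
#' }
#'
#' Calls are recoded to minor-allele dosage with the minor allele determined
#' from the pooled data (cases and controls together); an allele-count tie is
#' broken by taking the lexicographically smaller allele as minor. A SNP whose
#' observed alleles exceed two raises an error naming the SNP.
#'
#' @param path File prefix (`ped-map`) or file path (`dosage-table`).
#' @param format `"ped-map"` or `"dosage-table"`.
#' @return A [genotype_dataset()].
#' @export
read_dataset <- function(path, format = c("ped-map", "dosage-table")) {
  format <- match.arg(format)
  if (format == "ped-map") read_ped_map(path) else read_dosage_table(path)
}

read_ped_map <- function(prefix) {
  ped_file <- paste0(prefix, ".ped")
  map_file <- paste0(prefix, ".map")
  for (f in c(ped_file, map_file))
    if (!file.exists(f)) stop("file not found: ", f)

  map_lines <- readLines(map_file)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  map_tok <- strsplit(trimws(map_lines), "[ \t]+")
  bad <- which(vapply(map_tok, length, 1L) < 4L)
  if (length(bad) > 0L)
    stop("malformed .map line ", bad[1L], ": expected 4 fields")
  snps <- data.frame(
    snp_id = vapply(map_tok, `[[`, "", 2L),
    chromosome = vapply(map_tok, `[[`, "", 1L),
    position = as.integer(vapply(map_tok, `[[`, "", 4L)),
    stringsAsFactors = FALSE)
  p <- nrow(snps)

  ped_lines <- readLines(ped_file)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  ped_tok <- strsplit(trimws(ped_lines), "[ \t]+")
  n <- length(ped_tok)
  expected <- 6L + 2L * p
  for (i in seq_len(n))
    if (length(ped_tok[[i]]) != expected)
      stop("malformed .ped line ", i, ": expected ", expected, " fields, got ",
           length(ped_tok[[i]]))

  subject_ids <- vapply(ped_tok, `[[`, "", 2L)
  pheno_raw <- vapply(ped_tok, `[[`, "", 6L)
  # allele tokens as an n x 2p matrix
  al <- matrix("0", nrow = n, ncol = 2L * p)
  for (i in seq_len(n)) al[i, ] <- ped_tok[[i]][-(1:6)]

  calls <- matrix(NA_integer_, nrow = n, ncol = p)
  allele_minor <- character(p)
  allele_major <- character(p)
  for (j in seq_len(p)) {
    a1 <- al[, 2L * j - 1L]
    a2 <- al[, 2L * j]
    miss <- a1 == "0" | a2 == "0"
    obs <- c(a1[!miss], a2[!miss])
    tab <- sort(table(obs))
    if (length(tab) > 2L)
      stop("SNP ", snps$snp_id[j], ": more than two alleles observed (",
           paste(names(tab), collapse = ", "), ")")
    if (length(tab) == 0L) {
      allele_minor[j] <- NA_character_
      allele_major[j] <- NA_character_
      next
    }
    alleles <- names(tab)
    if (length(tab) == 1L) {
      # monomorphic: observed allele is major, minor unknown
      minor <- NA_character_; major <- alleles[1L]
    } else if (tab[[1L]] == tab[[2L]]) {
      minor <- min(alleles); major <- max(alleles)
    } else {
      minor <- alleles[1L]; major <- alleles[2L]
    }
    allele_minor[j] <- minor
    allele_major[j] <- major
    d <- rep(0L, n)
    if (!is.na(minor)) d <- (a1 == minor) + (a2 == minor)
    d[miss] <- NA_integer_
    calls[, j] <- d
  }
  snps$allele_minor <- allele_minor
  snps$allele_major <- allele_major

  phenotype <- suppressWarnings(as.numeric(pheno_raw))
  phenotype <- ifelse(is.na(phenotype) | phenotype %in% c(0, -9), NA,
                      ifelse(phenotype == 2, 1L, 0L))
  if (all(is.na(phenotype))) phenotype <- NULL

  genotype_dataset(calls, snps, subject_ids, phenotype)
}

read_dosage_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", "."))
  if (!all(c("subject_id", "phenotype") %in% names(df)))
    stop("dosage table must have 'subject_id' and 'phenotype' columns")
  snp_cols <- setdiff(names(df), c("subject_id", "phenotype"))
  calls <- as.matrix(df[, snp_cols, drop = FALSE])
  storage.mode(calls) <- "integer"
  bad <- which(!is.na(calls) & !(calls %in% 0:2), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("SNP ", snp_cols[bad[1L, 2L]], ": dosage outside {0,1,2} at row ",
         bad[1L, 1L])
  phenotype <- df$phenotype
  if (all(is.na(phenotype))) phenotype <- NULL
  p <- length(snp_cols)
  snps <- data.frame(snp_id = snp_cols,
                     chromosome = rep(NA_character_, p),
                     position = rep(NA_integer_, p),
                     allele_minor = rep(NA_character_, p),
                     allele_major = rep(NA_character_, p),
                     stringsAsFactors = FALSE)
  genotype_dataset(calls, snps, df$subject_id, phenotype)
}

#' Write a genotype dataset to disk
#'
#' Inverse of [read_dataset()]. Output is deterministic for a fixed dataset
#' (column order follows the `snps` metadata order). In the `ped-map` dialect
#' missing calls are written as `0 0` and the phenotype column uses 2 = case,
#' 1 = control, 0 = missing; a monomorphic SNP (no stored minor allele) is
#' written as homozygous major throughout. The `dosage-table` dialect keeps
#' calls, identifiers and phenotype but not SNP metadata.
#'
#' @param ds A [genotype_dataset()].
#' @param path File prefix (`ped-map`: writes `path.ped` and `path.map`) or
#'   file path (`dosage-table`).
#' @param format `"ped-map"` or `"dosage-table"`.
#' @return The written file path(s), invisibly.
#' @export
write_dataset <- function(ds, path, format = c("ped-map", "dosage-table")) {
  format <- match.arg(format)
  validate_genotype_dataset(ds)
  if (format == "ped-map") write_ped_map(ds, path) else write_dosage_table(ds, path)
}

write_ped_map <- function(ds, prefix) {
  ped_file <- paste0(prefix, ".ped")
  map_file <- paste0(prefix, ".map")
  p <- ncol(ds$calls)
  n <- nrow(ds$calls)
  map <- paste(ds$snps$chromosome, ds$snps$snp_id, 0L, ds$snps$position,
               sep = "\t")
  writeLines(map, map_file)

  pheno <- if (is.null(ds$phenotype)) rep(0L, n) else ds$phenotype + 1L
  geno_tok <- matrix("0 0", nrow = n, ncol = p)
  for (j in seq_len(p)) {
    mi <- ds$snps$allele_minor[j]
    ma <- ds$snps$allele_major[j]
    if (is.na(ma)) ma <- "A"
    if (is.na(mi)) mi <- ma
    d <- ds$calls[, j]
    tok <- c(paste(ma, ma), paste(mi, ma), paste(mi, mi))[d + 1L]
    tok[is.na(d)] <- "0 0"
    geno_tok[, j] <- tok
  }
  lead <- paste(ds$subject_ids, ds$subject_ids, 0L, 0L, 0L, pheno)
  body <- apply(geno_tok, 1L, paste, collapse = " ")
  writeLines(if (p > 0L) paste(lead, body) else lead, ped_file)
  invisible(c(ped_file, map_file))
}

write_dosage_table <- function(ds, path) {
  df <- as.data.frame(ds$calls)
  names(df) <- ds$snps$snp_id
  out <- cbind(data.frame(subject_id = ds$subject_ids,
                          phenotype = if (is.null(ds$phenotype)) NA_integer_
                                      else ds$phenotype,
                          stringsAsFactors = FALSE),
               df)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
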