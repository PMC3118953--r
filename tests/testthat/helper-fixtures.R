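# Shared fixtures, built in code.

# Small hand-specified dataset: n subjects, dosage columns given as a list.
make_dataset <- function(cols, phenotype = NULL, chromosome = NULL,
                         position = NULL) {
  calls <- do.call(cbind, cols)
  p <- ncol(calls)
  ids <- if (is.null(names(cols)) || any(names(cols) == ""))
    sprintf("rs%03d", seq_len(p)) else names(cols)
  snps <- data.frame(
    snp_id = ids,
    chromosome = if (is.null(chromosome)) rep("1", p) else chromosome,
    position = if (is.null(position)) seq_len(p) * 100L else position,
    allele_minor = "A", allele_major = "G",
    stringsAsFactors = FALSE)
  genotype_dataset(calls, snps, sprintf("s%03d", seq_len(nrow(calls))),
                   phenotype)
}

# Expand genotype-class counts into a dosage vector (2 = minor homozygote).
counts_to_dosage <- function(n_hom_minor, n_het, n_hom_major) {
  c(rep(2L, n_hom_minor), rep(1L, n_het), rep(0L, n_hom_major))
}

# Contingency counts of the exact-duplicate SNP pair fixture
# (complete LD: only the anti-diagonal cells are populated).
dup_pair_counts <- function() {
  list(cases = c(aa_bb = 182L, het_het = 468L, AA_BB = 213L),
       controls = c(aa_bb = 66L, het_het = 453L, AA_BB = 662L))
}

# Independent brute-force G2 on a 2-d table (no strata): direct evaluation
# of 2 * sum O * log(O / E), looping over cells.
brute_g2_2d <- function(tab) {
  n <- sum(tab)
  stat <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    O <- tab[i, j]
    if (O > 0) {
      E <- sum(tab[i, ]) * sum(tab[, j]) / n
      stat <- stat + 2 * O * log(O / E)
    }
  }
  stat
}

# Expand a 2-way table of counts into paired observation vectors.
table_to_obs <- function(tab) {
  y <- integer(0); x <- integer(0)
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    k <- tab[i, j]
    y <- c(y, rep.int(i, k)); x <- c(x, rep.int(j, k))
  }
  list(y = y, x = x)
}
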