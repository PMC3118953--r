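#' G-squared (conditional) independence test for discrete variables
#'
#' Likelihood-ratio test of independence between a discrete target and a
#' discrete variable `x`, optionally within the strata defined by a set of
#' discrete conditioning variables. The statistic is
#' \deqn{G^2 = 2 \sum_s \sum_{t,x} O \log(O/E)}
#' with `E` the product-margin expectation inside each conditioning stratum
#' `s`; observed zero cells contribute nothing. Degrees of freedom sum, over
#' non-empty strata, `(r_s - 1)(c_s - 1)` where `r_s` and `c_s` count only the
#' target/`x` levels with non-zero marginal in that stratum. The p-value is
#' the upper tail of the chi-squared distribution.
#'
#' A test is flagged *reliable* when the retained sample satisfies the
#' average-cell-count heuristic
#' `n >= min_avg_cell * L(target) * L(x) * prod(L(cond))`, with level counts
#' taken as the distinct values observed among the tested rows. When a test is
#' unreliable, no independence decision is made (`independent` is `NA`): the
#' caller must not conclude independence from an underpowered table.
#'
#' Rows with a missing value in any of the tested variables are dropped
#' pairwise for this test only.
#'
#' @param target Discrete vector (the phenotype in the GWAS use).
#' @param x Discrete vector of equal length.
#' @param cond Optional conditioning set: a vector, matrix or list of vectors.
#' @param alpha Significance level for the independence decision.
#' @param min_avg_cell Required average sample count per contingency cell for
#'   the reliability heuristic (default 5).
#' @return A `ci_test` list: `statistic`, `df`, `p_value`, `reliable`,
#'   `independent` (`TRUE`/`FALSE` when reliable, `NA` otherwise), `n_used`,
#'   `alpha`.
#' @export
g2_test <- function(target, x, cond = NULL, alpha = 0.05, min_avg_cell = 5) {
  if (is.null(cond)) {
    cond_list <- list()
  } else if (is.list(cond) && !is.data.frame(cond)) {
    cond_list <- cond
  } else if (is.matrix(cond) || is.data.frame(cond)) {
    cond_list <- lapply(seq_len(ncol(cond)), function(j) cond[, j])
  } else {
    cond_list <- list(cond)
  }
  keep <- !is.na(target) & !is.na(x)
  for (z in cond_list) keep <- keep & !is.na(z)
  y <- target[keep]
  xv <- x[keep]
  n <- length(y)
  if (length(unique(y)) < 2L) stop("degenerate target: fewer than two levels")

  yl <- as.integer(factor(y))
  xl <- as.integer(factor(xv))
  Ly <- max(yl); Lx <- max(xl)
  Lz <- 1L
  if (length(cond_list) > 0L) {
    sl <- rep(1L, n)
    for (z in cond_list) {
      zi <- as.integer(factor(z[keep]))
      Lz <- Lz * max(zi)
      sl <- (sl - 1L) * max(zi) + zi
    }
    sl <- as.integer(factor(sl))  # compact to observed strata
  } else {
    sl <- rep(1L, n)
  }
  S <- max(sl)

  # counts as an S x Ly x Lx array via linear indexing
  idx <- (sl - 1L) * Ly * Lx + (yl - 1L) * Lx + xl
  cnt <- tabulate(idx, nbins = S * Ly * Lx)
  dim(cnt) <- c(Lx, Ly, S)  # fastest index first

  stat <- 0
  df <- 0L
  for (s in seq_len(S)) {
    O <- t(cnt[, , s])                       # Ly x Lx
    ns <- sum(O)
    if (ns == 0L) next
    rm_ <- rowSums(O); cm <- colSums(O)
    E <- outer(rm_, cm) / ns
    nz <- O > 0
    stat <- stat + 2 * sum(O[nz] * log(O[nz] / E[nz]))
    df <- df + max(sum(rm_ > 0) - 1L, 0L) * max(sum(cm > 0) - 1L, 0L)
  }
  p <- if (df == 0L) 1 else stats::pchisq(stat, df = df, lower.tail = FALSE)
  reliable <- n >= min_avg_cell * Ly * Lx * Lz
  structure(list(statistic = stat, df = df, p_value = p,
                 reliable = reliable,
                 independent = if (reliable) p > alpha else NA,
                 n_used = n, alpha = alpha),
            class = "ci_test")
}

#' @export
print.ci_test <- function(x, ...) {
  cat(sprintf("G2 = %.4f, df = %d, p = %.4g, reliable = %s, independent = %s\n",
              x$statistic, x$df, x$p_value, x$reliable,
              if (is.na(x$independent)) "no decision" else x$independent))
  invisible(x)
}

#' Maximum usable conditioning-set size
#'
#' Largest number of conditioning variables for which the average-cell-count
#' reliability requirement can still be met at sample size `n`:
#' `floor(log_base(n / (min_avg_cell * target_levels * x_levels)))` with
#' `base = cond_levels`, floored at 0. With 1366 subjects, 5 samples per cell,
#' a binary target and ternary SNPs this gives
#' `floor(log3(1366 / (5 * 2 * 3))) = 3`.
#'
#' @param n Sample count.
#' @param min_avg_cell Required average samples per cell.
#' @param target_levels,x_levels,cond_levels Level counts of the target, the
#'   tested variable and each conditioning variable.
#' @return Integer conditioning-set size cap (>= 0).
#' @export
max_conditioning_size <- function(n, min_avg_cell = 5, target_levels = 2,
                                  x_levels = 3, cond_levels = 3) {
  stopifnot(n >= 1, min_avg_cell >= 1, target_levels >= 1, x_levels >= 1,
            cond_levels >= 2)
  ratio <- n / (min_avg_cell * target_levels * x_levels)
  if (ratio < 1) return(0L)
  # tiny epsilon guards floor() against 0.99999... from floating-point logs
  as.integer(floor(log(ratio) / log(cond_levels) + 1e-9))
}

#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' One-degree-of-freedom chi-squared test of observed genotype counts against
#' the Hardy-Weinberg expectations `(p^2, 2pq, q^2) * n`, with the allele
#' frequency estimated by allele counting.
#'
#' @param n_aa Count of minor-allele homozygotes (dosage 2).
#' @param n_het Count of heterozygotes (dosage 1).
#' @param n_AA Count of major-allele homozygotes (dosage 0).
#' @return List with `statistic`, `df` (1) and `p_value`.
#' @export
hwe_test <- function(n_aa, n_het, n_AA) {
  n <- n_aa + n_het + n_AA
  if (n <= 0) stop("no genotype observations")
  q <- (2 * n_aa + n_het) / (2 * n)  # minor-allele frequency
  p <- 1 - q
  E <- n * c(q^2, 2 * p * q, p^2)
  O <- c(n_aa, n_het, n_AA)
  nz <- E > 0
  stat <- sum((O[nz] - E[nz])^2 / E[nz])
  list(statistic = stat, df = 1L,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Minor allele frequency of a genotype column
#'
#' `(2 * n_hom_minor + n_het) / (2 * n_non_missing)`, i.e. the mean dosage
#' halved, for the dataset-oriented minor allele.
#'
#' @param g Dosage vector over \{0, 1, 2, NA\}.
#' @return Allele frequency in `[0, 1]`.
#' @export
maf <- function(g) {
  g <- g[!is.na(g)]
  if (length(g) == 0L) stop("all calls missing")
  sum(g) / (2 * length(g))
}

#' Genotype-dosage linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of the two dosage vectors over jointly
#' non-missing subjects (composite LD). Exact duplicates give 1.
#'
#' @param a,b Dosage vectors over \{0, 1, 2, NA\}.
#' @return r-squared in `[0, 1]`.
#' @export
ld_r2 <- function(a, b) {
  keep <- !is.na(a) & !is.na(b)
  if (sum(keep) < 2L) stop("fewer than two jointly non-missing calls")
  av <- a[keep]; bv <- b[keep]
  if (stats::var(av) == 0 || stats::var(bv) == 0)
    stop("monomorphic column: LD undefined")
  stats::cor(av, bv)^2
}

#' Hypergeometric enrichment test (upper tail)
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of drawing
#' at least `k` marked items in a sample of `n` from a population of `N`
#' containing `K` marked items.
#'
#' @param N Population size.
#' @param K Marked items in the population.
#' @param n Sample size.
#' @param k Observed marked items in the sample.
#' @return Upper-tail p-value.
#' @export
hypergeom_enrichment <- function(N, K, n, k) {
  if (!(k >= 0 && k <= n && n <= N && k <= K && K <= N))
    stop("invalid hypergeometric configuration: need 0 <= k <= n <= N and k <= K <= N")
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR significance mask
#'
#' Step-up procedure at rate `q`; equivalent to thresholding BH-adjusted
#' p-values at `q`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param q Target false discovery rate.
#' @return Logical vector, `TRUE` where the hypothesis is rejected.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  stats::p.adjust(p_values, method = "BH") <= q
}
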