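#' Simulation specification for synthetic case-control genotype data
#'
#' Describes a data-generating process with planted local-causal structure:
#' haplotype-copying linkage disequilibrium within blocks, a logistic
#' phenotype model over a set of causal SNPs, exact-duplicate SNP pairs
#' (complete LD, R^2 = 1), and both missing-completely-at-random and
#' phenotype-dependent (NMAR) missingness.
#'
#' @param n_cases,n_controls Target case and control counts (case-control
#'   ascertainment by rejection sampling).
#' @param n_snps Number of SNPs.
#' @param maf_range Length-2 numeric in (0, 0.5]; per-SNP minor-allele
#'   frequencies are drawn uniformly in this range.
#' @param ld_block_size SNPs per LD block; blocks are independent.
#' @param ld_rho Haplotype copying probability in [0, 1): within a block, each
#'   haplotype allele is copied from the previous SNP with probability
#'   `ld_rho`, else drawn fresh at that SNP's MAF.
#' @param causal_snps Named numeric vector or list mapping SNP index (1-based,
#'   as `"idx"` names or via `indices`/`betas` list) to log-odds effect per
#'   dosage unit. Pass e.g. `list(indices = c(10, 50), betas = c(0.8, 1.0))`.
#' @param beta0 Logistic intercept (log-odds of disease at dosage 0).
#' @param duplicate_pairs Optional list of `c(source, duplicate)` index pairs;
#'   the duplicate column is overwritten with an exact copy of the source
#'   before missingness.
#' @param missing_mcar_rate Probability that any call is set missing,
#'   uniformly at random.
#' @param nmar_snps Optional list with `indices` and `extra_case_rate`: the
#'   listed SNPs receive that much additional missing probability in cases
#'   only (missingness associated with the phenotype).
#' @param seed Integer seed driving the generator's single RNG stream.
#' @return A validated `simulation_spec` list.
#' @export
simulation_spec <- function(n_cases, n_controls, n_snps,
                            maf_range = c(0.1, 0.4),
                            ld_block_size = 10L, ld_rho = 0,
                            causal_snps = list(indices = integer(0),
                                               betas = numeric(0)),
                            beta0 = 0,
                            duplicate_pairs = list(),
                            missing_mcar_rate = 0,
                            nmar_snps = list(indices = integer(0),
                                             extra_case_rate = 0),
                            seed = 1L) {
  stopifnot(n_cases >= 1, n_controls >= 1, n_snps >= 1,
            length(maf_range) == 2L,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            ld_block_size >= 1,
            ld_rho >= 0, ld_rho < 1,
            missing_mcar_rate >= 0, missing_mcar_rate <= 1)
  ci <- as.integer(causal_snps$indices)
  cb <- as.numeric(causal_snps$betas)
  stopifnot(length(ci) == length(cb), !anyDuplicated(ci),
            all(ci >= 1 & ci <= n_snps))
  for (dp in duplicate_pairs)
    stopifnot(length(dp) == 2L, all(dp >= 1 & dp <= n_snps), dp[1] != dp[2])
  ni <- as.integer(nmar_snps$indices)
  nr <- nmar_snps$extra_case_rate
  stopifnot(all(ni >= 1 & ni <= n_snps), nr >= 0, nr <= 1)
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 n_snps = as.integer(n_snps),
                 maf_range = as.numeric(maf_range),
                 ld_block_size = as.integer(ld_block_size),
                 ld_rho = as.numeric(ld_rho),
                 causal_indices = ci, causal_betas = cb,
                 beta0 = as.numeric(beta0),
                 duplicate_pairs = duplicate_pairs,
                 missing_mcar_rate = as.numeric(missing_mcar_rate),
                 nmar_indices = ni, nmar_extra_case_rate = as.numeric(nr),
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

# Draw haplotypes for a batch of subjects: 2n x p binary matrix under the
# first-order copying process within blocks.
draw_haplotypes <- function(n_hap, mafs, block_size, rho) {
  p <- length(mafs)
  fresh <- matrix(stats::runif(n_hap * p), n_hap, p)
  fresh <- sweep(fresh, 2L, mafs, `<`) * 1L
  if (rho <= 0 || p == 1L) return(fresh)
  copy <- matrix(stats::runif(n_hap * p) < rho, n_hap, p)
  block_start <- ((seq_len(p) - 1L) %% block_size) == 0L
  copy[, block_start] <- FALSE
  h <- fresh
  for (j in seq_len(p)[-1L]) {
    cj <- copy[, j]
    if (any(cj)) h[cj, j] <- h[cj, j - 1L]
  }
  h
}

#' Generate a synthetic case-control genotype dataset with ground truth
#'
#' Genotypes are built from two haplotypes per subject drawn by the
#' block-wise copying process of the spec; the phenotype is Bernoulli with
#' success probability `plogis(beta0 + sum(beta_j * g_j))`; subjects are
#' accumulated by rejection sampling until the case and control quotas are
#' both met (case-control ascertainment). Duplicate pairs are then copied
#' exactly, and missingness is applied last: MCAR uniformly over all calls,
#' then the NMAR SNPs gain extra missing probability in cases. A fixed seed
#' reproduces the dataset bit for bit.
#'
#' @param spec A [simulation_spec()].
#' @param max_batches Safety cap on rejection-sampling rounds before erroring
#'   (guards against a degenerate `beta0` making one class unreachable).
#' @return List with `dataset` (a [genotype_dataset()]) and `truth` (a
#'   `synthetic_truth` list: `causal_effects` named by snp_id,
#'   `equivalence_classes`, `true_markov_boundaries`, `mafs`,
#'   `missingness_mechanism`).
#' @export
generate_dataset <- function(spec, max_batches = 200L) {
  stopifnot(inherits(spec, "simulation_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)

  p <- spec$n_snps
  mafs <- stats::runif(p, spec$maf_range[1], spec$maf_range[2])
  n_target <- spec$n_cases + spec$n_controls
  batch <- max(n_target, 500L)

  calls_list <- list()
  pheno_list <- list()
  got_cases <- 0L; got_controls <- 0L
  for (b in seq_len(max_batches)) {
    h1 <- draw_haplotypes(batch, mafs, spec$ld_block_size, spec$ld_rho)
    h2 <- draw_haplotypes(batch, mafs, spec$ld_block_size, spec$ld_rho)
    g <- h1 + h2
    eta <- spec$beta0
    if (length(spec$causal_indices) > 0L)
      eta <- eta + as.vector(g[, spec$causal_indices, drop = FALSE] %*%
                               spec$causal_betas)
    y <- stats::rbinom(batch, 1L, stats::plogis(eta))
    need_cases <- spec$n_cases - got_cases
    need_controls <- spec$n_controls - got_controls
    take_case <- which(y == 1L)[seq_len(min(need_cases, sum(y == 1L)))]
    take_ctrl <- which(y == 0L)[seq_len(min(need_controls, sum(y == 0L)))]
    take <- c(take_case, take_ctrl)
    if (length(take) > 0L) {
      calls_list[[length(calls_list) + 1L]] <- g[take, , drop = FALSE]
      pheno_list[[length(pheno_list) + 1L]] <- y[take]
      got_cases <- got_cases + length(take_case)
      got_controls <- got_controls + length(take_ctrl)
    }
    if (got_cases >= spec$n_cases && got_controls >= spec$n_controls) break
  }
  if (got_cases < spec$n_cases || got_controls < spec$n_controls)
    stop("could not reach ", spec$n_cases, " cases and ", spec$n_controls,
         " controls in ", max_batches,
         " sampling rounds; beta0/betas make a class too rare")

  calls <- do.call(rbind, calls_list)
  phenotype <- unlist(pheno_list)
  # deterministic subject order: cases first, then controls
  ord <- order(-phenotype)
  calls <- calls[ord, , drop = FALSE]
  phenotype <- phenotype[ord]
  n <- nrow(calls)

  for (dp in spec$duplicate_pairs) calls[, dp[2]] <- calls[, dp[1]]

  if (spec$missing_mcar_rate > 0) {
    drop <- matrix(stats::runif(n * p) < spec$missing_mcar_rate, n, p)
    calls[drop] <- NA_integer_
  }
  if (length(spec$nmar_indices) > 0L && spec$nmar_extra_case_rate > 0) {
    case_rows <- which(phenotype == 1L)
    for (j in spec$nmar_indices) {
      hit <- case_rows[stats::runif(length(case_rows)) <
                         spec$nmar_extra_case_rate]
      calls[hit, j] <- NA_integer_
    }
  }

  ids <- sprintf("snp%04d", seq_len(p))
  snps <- data.frame(
    snp_id = ids,
    chromosome = as.character(((seq_len(p) - 1L) %/% spec$ld_block_size) + 1L),
    position = ((seq_len(p) - 1L) %% spec$ld_block_size) * 1000L + 1L,
    allele_minor = "A", allele_major = "G",
    stringsAsFactors = FALSE)
  ds <- genotype_dataset(calls, snps, sprintf("subj%05d", seq_len(n)),
                         phenotype)

  # equivalence classes: each causal SNP together with its exact duplicates
  eq <- lapply(spec$causal_indices, function(ci) {
    members <- ci
    for (dp in spec$duplicate_pairs) {
      if (dp[1] == ci) members <- c(members, dp[2])
      if (dp[2] == ci) members <- c(members, dp[1])
    }
    sort(unique(members))
  })
  truth <- structure(list(
    causal_effects = stats::setNames(spec$causal_betas,
                                     ids[spec$causal_indices]),
    equivalence_classes = lapply(eq, function(m) ids[m]),
    true_markov_boundaries = NULL,
    mafs = stats::setNames(mafs, ids),
    missingness_mechanism = list(
      mcar_rate = spec$missing_mcar_rate,
      nmar_snp_ids = ids[spec$nmar_indices],
      nmar_extra_case_rate = spec$nmar_extra_case_rate)),
    class = "synthetic_truth")
  truth$true_markov_boundaries <- truth_boundaries(truth)
  list(dataset = ds, truth = truth)
}

#' All Markov boundaries implied by the planted equivalence classes
#'
#' Takes the cartesian product over the equivalence classes (one member per
#' class, the remaining causal SNPs fixed), deduplicated. With no equivalence
#' classes beyond singletons this is the single planted causal set.
#'
#' @param truth A `synthetic_truth` as returned by [generate_dataset()].
#' @return List of character vectors (sorted snp_id sets).
#' @export
truth_boundaries <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  base <- sort(names(truth$causal_effects))
  classes <- truth$equivalence_classes
  if (length(base) == 0L) return(list())
  if (length(classes) == 0L) return(list(base))
  grid <- expand.grid(lapply(classes, seq_along))
  boundaries <- lapply(seq_len(nrow(grid)), function(r) {
    b <- base
    for (cl in seq_along(classes)) {
      members <- classes[[cl]]
      if (length(intersect(b, members)) == 0L) next  # class not in this set
      b <- sort(c(setdiff(b, members), members[grid[r, cl]]))
    }
    b
  })
  unique(boundaries)
}
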