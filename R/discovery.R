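#' Discovery configuration for GLL / TIE*
#'
#' @param alpha Significance level of the G2 test (default 0.05).
#' @param max_k Maximum conditioning-set size (default 3; see
#'   [max_conditioning_size()] for the sample-size derivation).
#' @param min_avg_cell Average-cell-count reliability requirement of the G2
#'   test (default 5 samples per contingency cell).
#' @param max_equivalence_subset Cap on the size of the withheld subsets TIE*
#'   explores when searching for information-equivalent boundaries
#'   (default 2).
#' @return A `discovery_config` list.
#' @export
discovery_config <- function(alpha = 0.05, max_k = 3L, min_avg_cell = 5L,
                             max_equivalence_subset = 2L) {
  stopifnot(alpha > 0, alpha < 1, max_k >= 0, min_avg_cell >= 1,
            max_equivalence_subset >= 1)
  structure(list(alpha = alpha, max_k = as.integer(max_k),
                 min_avg_cell = as.integer(min_avg_cell),
                 max_equivalence_subset = as.integer(max_equivalence_subset)),
            class = "discovery_config")
}

# Cached conditional G2 test on dataset columns. `cache` is an environment
# keyed by "x|S"; identical (x, S) queries are answered once per dataset.
g2_cached <- function(calls, y, x_idx, s_idx, cfg, cache) {
  key <- paste(x_idx, paste(sort(s_idx), collapse = ","), sep = "|")
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  res <- g2_test(y, calls[, x_idx],
                 cond = if (length(s_idx) > 0L)
                   calls[, sort(s_idx), drop = FALSE] else NULL,
                 alpha = cfg$alpha, min_avg_cell = cfg$min_avg_cell)
  cache[[key]] <- res
  res
}

# Subsets of `pool` with size 0..kmax, in increasing size then lexicographic
# order of the (sorted) index vectors.
subsets_up_to <- function(pool, kmax, include_empty = TRUE) {
  pool <- sort(pool)
  out <- if (include_empty) list(integer(0)) else list()
  for (k in seq_len(min(kmax, length(pool)))) {
    # combn over positions: a length-1 pool must not be read as seq_len(pool)
    cmb <- utils::combn(length(pool), k, simplify = FALSE)
    out <- c(out, lapply(cmb, function(i) pool[i]))
  }
  out
}

#' Rank candidate SNPs by marginal association with the phenotype
#'
#' The prioritization step of GLL: every SNP is tested marginally against the
#' phenotype with the G2 test; SNPs with a reliable test rejecting
#' independence at `alpha` are returned ordered by ascending p-value, ties
#' broken by ascending (chromosome, position).
#'
#' @param ds A QC'd [genotype_dataset()] with binary phenotype.
#' @param cfg A [discovery_config()].
#' @return Character vector of candidate snp_ids, strongest first.
#' @export
rank_candidates <- function(ds, cfg = discovery_config()) {
  idx <- rank_candidates_idx(ds$calls, ds$phenotype, ds$snps, cfg)
  ds$snps$snp_id[idx]
}

rank_candidates_idx <- function(calls, y, snps, cfg) {
  p <- ncol(calls)
  if (p == 0L) return(integer(0))
  pvals <- rep(NA_real_, p)
  ok <- logical(p)
  for (j in seq_len(p)) {
    g <- calls[, j]
    if (length(unique(g[!is.na(g)])) < 2L) next  # monomorphic: no association
    t <- g2_test(y, g, alpha = cfg$alpha, min_avg_cell = cfg$min_avg_cell)
    if (t$reliable && !t$independent) {
      ok[j] <- TRUE
      pvals[j] <- t$p_value
    }
  }
  cand <- which(ok)
  chrom <- suppressWarnings(as.numeric(snps$chromosome[cand]))
  chrom[is.na(chrom)] <- Inf
  cand[order(pvals[cand], chrom, snps$position[cand])]
}

gll_mb_core <- function(calls, y, snps, cfg, exclude = integer(0),
                        cache = new.env(parent = emptyenv()),
                        ranked = NULL) {
  if (is.null(ranked)) ranked <- rank_candidates_idx(calls, y, snps, cfg)
  ranked <- setdiff(ranked, exclude)
  tpc <- integer(0)         # tentative local-pathway set (column indices)
  removed <- integer(0)     # eliminated, never readmitted
  trace <- list()
  for (cand in ranked) {
    if (cand %in% removed) next
    tpc <- c(tpc, cand)
    # elimination sweep: each current member against subsets of the others
    repeat_sweep <- TRUE
    while (repeat_sweep) {
      repeat_sweep <- FALSE
      for (x in tpc) {
        others <- setdiff(tpc, x)
        sep <- NULL
        for (S in subsets_up_to(others, cfg$max_k)) {
          t <- g2_cached(calls, y, x, S, cfg, cache)
          if (t$reliable && isTRUE(t$independent)) { sep <- S; break }
        }
        if (!is.null(sep)) {
          tpc <- setdiff(tpc, x)
          removed <- c(removed, x)
          trace[[as.character(x)]] <-
            list(eliminated_by = snps$snp_id[sep])
          repeat_sweep <- TRUE
          break
        }
      }
    }
  }
  structure(list(snp_ids = snps$snp_id[sort(tpc)],
                 indices = sort(tpc),
                 trace = trace),
            class = "markov_boundary")
}

#' @export
print.markov_boundary <- function(x, ...) {
  cat("Markov boundary (", length(x$snp_ids), " SNPs): ",
      paste(x$snp_ids, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' GLL-style Markov boundary induction
#'
#' Semi-interleaved inclusion/elimination: candidates enter the tentative
#' local-pathway set in order of marginal association strength; after each
#' admission every current member is tested for conditional independence of
#' the phenotype given every subset (up to size `max_k`) of the other current
#' members, and any member with a reliable test declaring independence is
#' removed permanently. Only reliable tests (average cell count at least
#' `min_avg_cell`) can eliminate, which is the algorithm's guard against
#' false exclusions on thin tables.
#'
#' @param ds A QC'd [genotype_dataset()] with binary phenotype.
#' @param cfg A [discovery_config()].
#' @return A `markov_boundary`: `snp_ids` (genomic column order), `indices`,
#'   and a `trace` of eliminations (separating sets).
#' @export
gll_mb <- function(ds, cfg = discovery_config()) {
  stopifnot(!is.null(ds$phenotype))
  gll_mb_core(ds$calls, ds$phenotype, ds$snps, cfg)
}

#' Check information equivalence of two Markov boundaries
#'
#' `m_new` subsumes `m_ref` when every SNP of `m_ref` absent from `m_new` is
#' rendered conditionally independent of the phenotype by some subset of
#' `m_new` (of size up to `max_k`) under a reliable G2 test.
#'
#' @param m_ref,m_new `markov_boundary` objects (or character vectors of
#'   snp_ids) over SNPs of `ds`.
#' @param ds The dataset both boundaries were discovered in.
#' @param cfg A [discovery_config()].
#' @param cache Optional environment reusing test results across calls.
#' @return `TRUE` when `m_new` carries all of `m_ref`'s information.
#' @export
verify_equivalence <- function(m_ref, m_new, ds, cfg = discovery_config(),
                               cache = new.env(parent = emptyenv())) {
  ref_ids <- if (inherits(m_ref, "markov_boundary")) m_ref$snp_ids else m_ref
  new_ids <- if (inherits(m_new, "markov_boundary")) m_new$snp_ids else m_new
  ref_idx <- match(ref_ids, ds$snps$snp_id)
  new_idx <- match(new_ids, ds$snps$snp_id)
  if (anyNA(ref_idx) || anyNA(new_idx)) stop("boundary SNP not in dataset")
  for (x in setdiff(ref_idx, new_idx)) {
    found <- FALSE
    for (S in subsets_up_to(new_idx, cfg$max_k)) {
      t <- g2_cached(ds$calls, ds$phenotype, x, S, cfg, cache)
      if (t$reliable && isTRUE(t$independent)) { found <- TRUE; break }
    }
    if (!found) return(FALSE)
  }
  TRUE
}

#' TIE*: enumerate all information-equivalent Markov boundaries
#'
#' Runs GLL on the full SNP set to obtain a reference boundary, then
#' repeatedly re-runs it with subsets of the discovered boundaries' union
#' withheld (subset sizes up to `max_equivalence_subset`, explored in
#' increasing size then lexicographic order). A re-discovered boundary is
#' accepted when [verify_equivalence()] confirms it subsumes the reference
#' boundary's information; newly accepted boundaries extend the withheld
#' subset queue. The procedure is deterministic and terminates on the finite
#' capped subset lattice.
#'
#' @param ds A QC'd [genotype_dataset()] with binary phenotype.
#' @param cfg A [discovery_config()].
#' @return A `tie_output`: `boundaries` (list of `markov_boundary`),
#'   `shared_core` (intersection of all boundaries) and
#'   `equivalence_substitutions` (list of `removed` / `replacement` id sets
#'   relative to the reference boundary).
#' @export
tie_star <- function(ds, cfg = discovery_config()) {
  stopifnot(!is.null(ds$phenotype))
  calls <- ds$calls; y <- ds$phenotype; snps <- ds$snps
  cache <- new.env(parent = emptyenv())
  ranked <- rank_candidates_idx(calls, y, snps, cfg)

  m0 <- gll_mb_core(calls, y, snps, cfg, cache = cache, ranked = ranked)
  boundaries <- list(m0)
  seen <- paste(m0$indices, collapse = ",")
  union_idx <- m0$indices

  queue_keys <- character(0)
  enqueue <- function(u) {
    subs <- subsets_up_to(u, cfg$max_equivalence_subset, include_empty = FALSE)
    keys <- vapply(subs, paste, "", collapse = ",")
    new <- setdiff(keys, queue_keys)
    queue_keys <<- c(queue_keys, new)
    new
  }
  pending <- enqueue(union_idx)
  done <- character(0)

  while (length(pending) > 0L) {
    key <- pending[1L]
    pending <- pending[-1L]
    if (key %in% done) next
    done <- c(done, key)
    withheld <- as.integer(strsplit(key, ",")[[1L]])
    # only informative if the withheld set touches some discovered boundary
    if (!any(withheld %in% union_idx)) next
    mg <- gll_mb_core(calls, y, snps, cfg, exclude = withheld, cache = cache,
                      ranked = ranked)
    bkey <- paste(mg$indices, collapse = ",")
    if (bkey %in% seen) next
    if (verify_equivalence(m0$snp_ids, mg$snp_ids, ds, cfg, cache = cache)) {
      boundaries[[length(boundaries) + 1L]] <- mg
      seen <- c(seen, bkey)
      new_union <- sort(union(union_idx, mg$indices))
      if (!identical(new_union, union_idx)) {
        union_idx <- new_union
        pending <- c(pending, setdiff(enqueue(union_idx), done))
      }
    }
  }

  id_sets <- lapply(boundaries, `[[`, "snp_ids")
  core <- Reduce(intersect, id_sets)
  subs <- lapply(id_sets[-1], function(ids)
    list(removed = setdiff(m0$snp_ids, ids),
         replacement = setdiff(ids, m0$snp_ids)))
  structure(list(boundaries = boundaries, shared_core = core,
                 equivalence_substitutions = subs,
                 reference = m0),
            class = "tie_output")
}

#' @export
print.tie_output <- function(x, ...) {
  cat("TIE*:", length(x$boundaries), "information-equivalent Markov",
      if (length(x$boundaries) == 1L) "boundary\n" else "boundaries\n")
  for (i in seq_along(x$boundaries))
    cat(sprintf("  [%d] %s\n", i,
                paste(x$boundaries[[i]]$snp_ids, collapse = ", ")))
  cat("  shared core:", paste(x$shared_core, collapse = ", "), "\n")
  invisible(x)
}
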