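#' Load a run configuration
#'
#' A run configuration is a named list (or a YAML file holding one) with a
#' top-level `out_dir`, `seed`, and one section per stage: `simulate` (or
#' `input`), `qc`, `audit_missing`, `discover`, `fit`, `evaluate`,
#' `robustness`, `audit_ci`. Each stage section may carry `enabled: false` to
#' skip it. Unknown top-level keys are rejected, all at once, so a typo in a
#' stage name cannot silently disable it.
#'
#' @param config A named list or path to a YAML file.
#' @return The validated configuration list.
#' @export
load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  allowed <- c("out_dir", "seed", "simulate", "input", "qc", "audit_missing",
               "discover", "fit", "evaluate", "robustness", "audit_ci")
  unknown <- setdiff(names(config), allowed)
  problems <- character(0)
  if (length(unknown) > 0L)
    problems <- c(problems, paste0("unknown key(s): ",
                                   paste(unknown, collapse = ", ")))
  if (is.null(config$out_dir)) problems <- c(problems, "missing 'out_dir'")
  if (is.null(config$simulate) && is.null(config$input))
    problems <- c(problems, "need either a 'simulate' or an 'input' section")
  if (length(problems) > 0L)
    stop("invalid run config: ", paste(problems, collapse = "; "))
  if (is.null(config$seed)) config$seed <- 1L
  config
}

stage_enabled <- function(section, default = TRUE) {
  if (is.null(section)) return(default)
  if (isFALSE(section$enabled)) return(FALSE)
  TRUE
}

write_artifact <- function(obj, out_dir, name, config_hash) {
  path <- file.path(out_dir, paste0(name, ".json"))
  jsonlite::write_json(c(list(config_hash = config_hash), obj), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  path
}

boundary_list <- function(tie) {
  lapply(tie$boundaries, function(b) b$snp_ids)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in fixed order: simulate (or read input), QC,
#' missingness audit, stratified train/test split, TIE* discovery on the
#' training part, kernel ridge regression fitting per boundary, held-out
#' evaluation, optional resampling robustness, and optional
#' conditional-independence audit of known SNPs. Each stage writes a JSON
#' artifact into `out_dir` stamped with a hash of the configuration, so every
#' number in an artifact is traceable to the run that produced it. Reruns
#' with an identical configuration reproduce the artifacts byte for byte.
#'
#' @param config A run configuration (list or YAML path; see
#'   [load_run_config()]).
#' @return Invisibly, a list with the in-memory stage results and the artifact
#'   paths.
#' @export
run_pipeline <- function(config) {
  config <- load_run_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_file <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, cfg_file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  # hash the configuration content, not its location: identical runs into
  # different directories must produce identical artifacts
  hash_cfg <- config
  hash_cfg$out_dir <- NULL
  hash_file <- tempfile(fileext = ".json")
  jsonlite::write_json(hash_cfg, hash_file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  config_hash <- unname(tools::md5sum(hash_file))
  unlink(hash_file)
  artifacts <- list(config = cfg_file)
  results <- list()
  seed <- as.integer(config$seed)

  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    message(sprintf("[%s] done in %.1fs", name,
                    proc.time()[["elapsed"]] - t0))
    val
  }

  # --- data ------------------------------------------------------------
  if (!is.null(config$simulate) && stage_enabled(config$simulate)) {
    sim <- config$simulate
    spec <- simulation_spec(
      n_cases = sim$n_cases, n_controls = sim$n_controls,
      n_snps = sim$n_snps,
      maf_range = if (is.null(sim$maf_range)) c(0.1, 0.4)
                  else unlist(sim$maf_range),
      ld_block_size = if (is.null(sim$ld_block_size)) 10L
                      else sim$ld_block_size,
      ld_rho = if (is.null(sim$ld_rho)) 0 else sim$ld_rho,
      causal_snps = if (is.null(sim$causal))
        list(indices = integer(0), betas = numeric(0))
        else list(indices = unlist(sim$causal$indices),
                  betas = unlist(sim$causal$betas)),
      beta0 = if (is.null(sim$beta0)) 0 else sim$beta0,
      duplicate_pairs = if (is.null(sim$duplicate_pairs)) list()
                        else lapply(sim$duplicate_pairs, unlist),
      missing_mcar_rate = if (is.null(sim$missing_mcar_rate)) 0
                          else sim$missing_mcar_rate,
      nmar_snps = if (is.null(sim$nmar))
        list(indices = integer(0), extra_case_rate = 0)
        else list(indices = unlist(sim$nmar$indices),
                  extra_case_rate = sim$nmar$extra_case_rate),
      seed = seed)
    gen <- t_stage("simulate", generate_dataset(spec))
    ds <- gen$dataset
    results$truth <- gen$truth
    write_dataset(ds, file.path(out_dir, "dataset.tsv"), "dosage-table")
    artifacts$truth <- write_artifact(
      list(causal_effects = as.list(gen$truth$causal_effects),
           equivalence_classes = gen$truth$equivalence_classes,
           true_markov_boundaries = gen$truth$true_markov_boundaries,
           missingness_mechanism = gen$truth$missingness_mechanism),
      out_dir, "truth", config_hash)
  } else {
    inp <- config$input
    ds <- t_stage("read", read_dataset(inp$path, inp$format))
  }
  results$dataset <- ds

  # --- qc ---------------------------------------------------------------
  if (stage_enabled(config$qc)) {
    qc_cfg <- config$qc
    qc <- t_stage("qc", apply_qc(
      ds,
      min_call_rate = if (is.null(qc_cfg$min_call_rate)) 0.95
                      else qc_cfg$min_call_rate,
      min_maf = if (is.null(qc_cfg$min_maf)) 0.01 else qc_cfg$min_maf,
      hwe_alpha = if (is.null(qc_cfg$hwe_alpha)) 1e-5 else qc_cfg$hwe_alpha,
      hwe_cohort = if (is.null(qc_cfg$hwe_cohort)) "controls"
                   else qc_cfg$hwe_cohort))
    ds <- qc$dataset
    results$qc <- qc$report
    artifacts$qc <- write_artifact(
      list(qc_applied = TRUE,
           n_input = qc$report$n_input,
           removed_call_rate = qc$report$removed_call_rate,
           removed_maf = qc$report$removed_maf,
           removed_hwe = qc$report$removed_hwe,
           n_output = qc$report$n_output),
      out_dir, "qc", config_hash)
  } else {
    artifacts$qc <- write_artifact(
      list(qc_applied = FALSE, n_output = ncol(ds$calls)),
      out_dir, "qc", config_hash)
  }

  # --- missingness audit ------------------------------------------------
  if (!is.null(config$audit_missing) && stage_enabled(config$audit_missing)) {
    am <- config$audit_missing
    rep_m <- t_stage("audit_missing", missingness_analysis(
      ds,
      locus = am$locus,
      fdr_q = if (is.null(am$fdr_q)) 0.05 else am$fdr_q,
      seed = seed))
    results$missingness <- rep_m
    artifacts$missingness <- write_artifact(
      list(n_snps_with_missing = rep_m$n_snps_with_missing,
           n_significant = rep_m$n_significant,
           n_locus_missing = rep_m$n_locus_missing,
           n_locus_significant = rep_m$n_locus_significant,
           enrichment_p = rep_m$enrichment_p,
           classifier_auc = if (is.null(rep_m$classifier)) NA
                            else rep_m$classifier$auc),
      out_dir, "missingness", config_hash)
  }

  # --- split, discovery, fit, evaluate ----------------------------------
  ev <- config$evaluate
  train_fraction <- if (is.null(ev$train_fraction)) 2 / 3 else ev$train_fraction
  sp <- stratified_split(ds, train_fraction, seed = seed)

  dcfg <- discovery_config(
    alpha = if (is.null(config$discover$alpha)) 0.05 else config$discover$alpha,
    max_k = if (is.null(config$discover$max_k)) 3L else config$discover$max_k,
    min_avg_cell = if (is.null(config$discover$min_avg_cell)) 5L
                   else config$discover$min_avg_cell,
    max_equivalence_subset =
      if (is.null(config$discover$max_equivalence_subset)) 2L
      else config$discover$max_equivalence_subset)

  tie <- NULL
  if (stage_enabled(config$discover)) {
    tie <- t_stage("discover", tie_star(sp$train, dcfg))
    results$tie <- tie
    artifacts$tie <- write_artifact(
      list(boundaries = boundary_list(tie),
           shared_core = tie$shared_core),
      out_dir, "tie", config_hash)
  }

  if (!is.null(tie) && stage_enabled(config$fit)) {
    folds <- if (is.null(config$fit$folds)) 10L else config$fit$folds
    models <- t_stage("fit", lapply(tie$boundaries, function(b) {
      if (length(b$snp_ids) == 0L) return(NULL)
      enc <- encode(sp$train, b$snp_ids)
      tuned <- tune_krr(enc$X, sp$train$phenotype, folds = folds, seed = seed)
      krr_fit(enc$X, sp$train$phenotype, tuned$lambda, tuned$gamma,
              snp_ids = b$snp_ids, encode_params = enc$params)
    }))
    results$models <- models
    artifacts$models <- write_artifact(
      list(models = lapply(models, function(m) if (is.null(m)) NULL else
        list(snp_ids = m$snp_ids, lambda = m$lambda, gamma = m$gamma))),
      out_dir, "models", config_hash)

    if (stage_enabled(config$evaluate)) {
      rocs <- t_stage("evaluate", lapply(models, function(m) {
        if (is.null(m)) return(NULL)
        roc_report(predict(m, sp$test), sp$test$phenotype)
      }))
      results$rocs <- rocs
      artifacts$roc <- write_artifact(
        list(per_boundary = lapply(rocs, function(r) if (is.null(r)) NULL else
          list(auc = r$auc, ci_low = r$ci_low, ci_high = r$ci_high,
               n_cases = r$n_cases, n_controls = r$n_controls))),
        out_dir, "roc", config_hash)
    }
  }

  # --- robustness --------------------------------------------------------
  if (!is.null(config$robustness) && stage_enabled(config$robustness, FALSE)) {
    rb <- config$robustness
    rob <- t_stage("robustness", robustness(
      ds,
      n_splits = if (is.null(rb$n_splits)) 1000L else rb$n_splits,
      cfg = dcfg, train_fraction = train_fraction,
      folds = if (is.null(rb$folds)) 10L else rb$folds,
      seed = seed))
    results$robustness <- rob
    artifacts$robustness <- write_artifact(
      list(auc_mean = rob$auc_mean, auc_sd = rob$auc_sd,
           selection_freq = as.list(rob$selection_freq[rob$selection_freq > 0]),
           n_failures = length(rob$failures)),
      out_dir, "robustness", config_hash)
  }

  # --- CI audit ----------------------------------------------------------
  if (!is.null(config$audit_ci) && stage_enabled(config$audit_ci, FALSE) &&
      !is.null(tie) && length(tie$boundaries) > 0L) {
    ac <- config$audit_ci
    audit <- t_stage("audit_ci", ci_audit(
      sp$train, unlist(ac$known_snps), tie$boundaries[[1L]],
      alpha = if (is.null(ac$alpha)) 0.05 else ac$alpha,
      max_subset = if (is.null(ac$max_subset)) 4L else ac$max_subset))
    results$audit_ci <- audit
    artifacts$audit_ci <- write_artifact(
      list(rows = lapply(seq_len(nrow(audit)),
                         function(i) as.list(audit[i, ]))),
      out_dir, "audit_ci", config_hash)
  }

  invisible(list(results = results, artifacts = artifacts))
}
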