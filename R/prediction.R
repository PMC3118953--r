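#' Encode genotype columns for predictive modelling
#'
#' Selects the requested SNPs as a numeric dosage matrix, imputes missing
#' calls to the training-set per-SNP mode (ties broken toward the smaller
#' dosage), and centers/scales each column by training-set statistics
#' (`sd` with the usual n-1 denominator; a constant column's scale is guarded
#' to 1). When `fit_params` is supplied — encoding a test set — the stored
#' modes, means and scales are reused instead of being re-estimated.
#'
#' @param ds A [genotype_dataset()].
#' @param snps Character vector of snp_ids to encode (in this order).
#' @param fit_params Optional parameter set from a previous [encode()] call.
#' @return List with `X` (subjects x SNPs numeric matrix) and `params`
#'   (`snp_ids`, `mode`, `center`, `scale`).
#' @export
encode <- function(ds, snps, fit_params = NULL) {
  idx <- match(snps, ds$snps$snp_id)
  if (anyNA(idx))
    stop("SNP(s) not present in dataset: ",
         paste(snps[is.na(idx)], collapse = ", "))
  X <- ds$calls[, idx, drop = FALSE]
  storage.mode(X) <- "double"
  p <- ncol(X)
  if (is.null(fit_params)) {
    mode_ <- numeric(p); center <- numeric(p); scale_ <- numeric(p)
    for (j in seq_len(p)) {
      col <- X[, j]
      obs <- col[!is.na(col)]
      mode_[j] <- if (length(obs) == 0L) 0 else {
        tab <- table(obs)
        as.numeric(names(tab)[which.max(tab)])  # which.max: first max => smaller dosage
      }
      col[is.na(col)] <- mode_[j]
      center[j] <- mean(col)
      s <- stats::sd(col)
      scale_[j] <- if (is.na(s) || s == 0) 1 else s
      X[, j] <- (col - center[j]) / scale_[j]
    }
    params <- list(snp_ids = snps, mode = mode_, center = center,
                   scale = scale_)
  } else {
    if (!identical(fit_params$snp_ids, snps))
      stop("fit_params were estimated for a different SNP set")
    for (j in seq_len(p)) {
      col <- X[, j]
      col[is.na(col)] <- fit_params$mode[j]
      X[, j] <- (col - fit_params$center[j]) / fit_params$scale[j]
    }
    params <- fit_params
  }
  colnames(X) <- snps
  list(X = X, params = params)
}

rbf_kernel <- function(A, B = NULL, gamma) {
  if (is.null(B)) B <- A
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

#' Fit kernel ridge regression
#'
#' Solves the dual system `(K + lambda I) c = y` with the radial basis kernel
#' `K(x, y) = exp(-gamma * ||x - y||^2)`; binary labels are regressed as real
#' 0/1 and the continuous score is used for ranking/ROC. At `lambda = 0` with
#' distinct rows the fit interpolates the labels exactly; duplicate rows make
#' the system singular, which raises an error advising `lambda > 0`.
#'
#' @param X Encoded training matrix (see [encode()]).
#' @param y Numeric 0/1 labels.
#' @param lambda Ridge penalty, >= 0.
#' @param gamma Kernel width, > 0.
#' @param snp_ids Optional snp_ids recorded on the model.
#' @param encode_params Optional [encode()] parameters recorded on the model.
#' @return A `krr_model` holding the training matrix, dual coefficients and
#'   hyperparameters.
#' @export
krr_fit <- function(X, y, lambda, gamma, snp_ids = colnames(X),
                    encode_params = NULL) {
  stopifnot(lambda >= 0, gamma > 0, nrow(X) >= 2, nrow(X) == length(y))
  K <- rbf_kernel(X, gamma = gamma)
  A <- K + diag(lambda, nrow(X))
  coef <- tryCatch(solve(A, as.numeric(y)),
                   error = function(e)
                     stop("kernel system is singular (duplicate rows at ",
                          "lambda = 0?); use lambda > 0", call. = FALSE))
  structure(list(X = X, coef = as.numeric(coef), lambda = lambda,
                 gamma = gamma, snp_ids = snp_ids,
                 encode_params = encode_params),
            class = "krr_model")
}

#' Predict scores from a kernel ridge regression model
#'
#' @param object A `krr_model`.
#' @param newdata Encoded matrix with the model's columns, or a
#'   [genotype_dataset()] when the model carries `encode_params` (the test
#'   set is then encoded with the stored training parameters).
#' @param ... Unused.
#' @return Numeric score vector (higher = more case-like).
#' @export
predict.krr_model <- function(object, newdata, ...) {
  if (inherits(newdata, "genotype_dataset")) {
    if (is.null(object$encode_params))
      stop("model carries no encoding parameters; pass an encoded matrix")
    newdata <- encode(newdata, object$snp_ids, object$encode_params)$X
  }
  Kz <- rbf_kernel(newdata, object$X, gamma = object$gamma)
  as.numeric(Kz %*% object$coef)
}

#' @export
print.krr_model <- function(x, ...) {
  cat(sprintf("krr_model: %d training subjects, %d features, lambda = %g, gamma = %g\n",
              nrow(x$X), ncol(x$X), x$lambda, x$gamma))
  invisible(x)
}

#' Default hyperparameter grids
#'
#' The ridge grid spans `{1e-10, 1e-8, ..., 1}` (six values, exponents -10 to
#' 0 in steps of 2). The kernel-width grid scales inversely with the number of
#' SNPs in the model: `gamma = 2^j / n_snps` for `j = -3, ..., 3`.
#'
#' @param n_snps Number of SNPs entering the model (for the gamma grid).
#' @return Numeric vector of grid values.
#' @export
default_lambda_grid <- function() 10^seq(-10, 0, by = 2)

#' @rdname default_lambda_grid
#' @export
default_gamma_grid <- function(n_snps) 2^(-3:3) / n_snps

#' Tune kernel ridge regression by stratified k-fold cross-validation
#'
#' Folds are stratified by class from the seed; every (lambda, gamma) pair is
#' scored by mean held-out-fold AUC and the maximizer is returned, with ties
#' resolved toward the smaller gamma and then the larger lambda (the more
#' regularized model). For each (fold, gamma) the kernel is eigendecomposed
#' once and reused across the whole lambda grid.
#'
#' @param X Encoded training matrix.
#' @param y Numeric 0/1 labels.
#' @param lambda_grid,gamma_grid Non-empty hyperparameter grids.
#' @param folds Number of folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @return List with `lambda`, `gamma` and `cv_table` (one row per pair with
#'   the mean fold AUC).
#' @export
tune_krr <- function(X, y, lambda_grid = default_lambda_grid(),
                     gamma_grid = default_gamma_grid(ncol(X)),
                     folds = 10L, seed = 1L) {
  stopifnot(length(lambda_grid) > 0, length(gamma_grid) > 0, folds >= 2)
  y <- as.numeric(y)
  n <- length(y)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  fold_id <- integer(n)
  for (cls in unique(y)) {
    rows <- which(y == cls)
    fold_id[rows] <- sample(rep_len(seq_len(folds), length(rows)))
  }
  for (f in seq_len(folds))
    if (length(unique(y[fold_id != f])) < 2L ||
        length(unique(y[fold_id == f])) < 2L)
      stop("a fold has a single class; use fewer folds")

  lambda_grid <- sort(lambda_grid)
  gamma_grid <- sort(gamma_grid)
  aucs <- array(NA_real_,
                dim = c(length(lambda_grid), length(gamma_grid), folds))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
    Xva <- X[!tr, , drop = FALSE]; yva <- y[!tr]
    for (gi in seq_along(gamma_grid)) {
      K <- rbf_kernel(Xtr, gamma = gamma_grid[gi])
      eig <- eigen(K, symmetric = TRUE)
      Vty <- crossprod(eig$vectors, ytr)
      Kva <- rbf_kernel(Xva, Xtr, gamma = gamma_grid[gi])
      for (li in seq_along(lambda_grid)) {
        coef <- eig$vectors %*% (Vty / (eig$values + lambda_grid[li]))
        scores <- as.numeric(Kva %*% coef)
        aucs[li, gi, f] <- auc(scores, yva)
      }
    }
  }
  mean_auc <- apply(aucs, c(1, 2), mean)
  cv_table <- expand.grid(lambda = lambda_grid, gamma = gamma_grid)
  cv_table$mean_auc <- as.vector(mean_auc)
  # best AUC; ties -> smaller gamma, then larger lambda
  ord <- order(-cv_table$mean_auc, cv_table$gamma, -cv_table$lambda)
  best <- cv_table[ord[1L], ]
  list(lambda = best$lambda, gamma = best$gamma, cv_table = cv_table)
}
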