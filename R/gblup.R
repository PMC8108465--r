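#' Centered genomic relationship matrix
#'
#' `K = W W' / p` where `W` is the dosage matrix with each variant centered by
#' its mean and `p` is the number of variants. Missing dosages are mean-filled
#' per variant for this computation only. `K` is symmetric positive
#' semidefinite; a monomorphic-only input yields the zero matrix with a
#' warning.
#'
#' @param gm A [geno_matrix()] (or plain dosage matrix with sample row names).
#' @return Symmetric numeric matrix with sample IDs as dimnames.
#' @export
#' @examples
#' gm <- geno_matrix(rbind(a = 0, b = 2),
#'                   data.frame(id = "v", chrom = "1", pos = 1L,
#'                              ref = "A", alt = "T"))
#' compute_cgrm(gm)  # [[1, -1], [-1, 1]]
compute_cgrm <- function(gm) {
  d <- if (inherits(gm, "geno_matrix")) gm$dosages else as.matrix(gm)
  if (nrow(d) < 2L) hf_stop("GRM needs >= 2 samples")
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    mu[is.nan(mu)] <- 0  # all-missing variant: centered dosage 0
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2]]
  }
  W <- sweep(d, 2, colMeans(d))
  K <- tcrossprod(W) / ncol(W)
  if (all(abs(K) < .Machine$double.eps * 100)) {
    warning("all variants monomorphic: GRM is the zero matrix")
  }
  dimnames(K) <- list(rownames(d), rownames(d))
  K
}

# Profile REML for y = X beta + u + e, u ~ N(0, sigma_u2 K), e ~ N(0,
# sigma_e2 I), via one spectral decomposition of K and 1-D optimisation of
# the variance ratio lambda = sigma_u2 / sigma_e2 (EMMA-style): rotate by the
# eigenvectors, profile out beta and sigma_e2, grid-search then refine
# log10(lambda). Deterministic.
reml_kernel <- function(y, X, K, eig = NULL, lambda_grid = 10^seq(-6, 6, by = 0.5)) {
  n <- length(y)
  if (is.null(eig)) {
    eig <- eigen(K, symmetric = TRUE)
    tol <- 1e-8 * max(abs(eig$values), 1)
    if (min(eig$values) < -max(1e-8, tol)) {
      hf_stop("kinship matrix is not positive semidefinite (min eigenvalue ",
              format(min(eig$values)), ")")
    }
    eig$values <- pmax(eig$values, 0)
  }
  U <- eig$vectors
  dvals <- eig$values
  q <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < q) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):q]]
    hf_stop("covariate matrix is rank deficient (column ",
            paste(bad, collapse = ", "), ")")
  }
  ys <- crossprod(U, y)
  Xs <- crossprod(U, X)

  nll <- function(log10_lambda) {
    lam <- 10^log10_lambda
    w <- 1 / (lam * dvals + 1)
    XtWX <- crossprod(Xs, w * Xs)
    XtWy <- crossprod(Xs, w * ys)
    ch <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    beta <- backsolve(ch, forwardsolve(t(ch), XtWy))
    r <- ys - Xs %*% beta
    rss <- sum(w * r^2)
    0.5 * ((n - q) * log(rss) + sum(log(lam * dvals + 1)) +
             2 * sum(log(diag(ch))))
  }

  vals <- vapply(log10(lambda_grid), nll, numeric(1))
  # include the boundary lambda -> 0 (pure noise)
  v0 <- nll(-12)
  best <- which.min(vals)
  lo <- log10(lambda_grid[max(1L, best - 1L)])
  hi <- log10(lambda_grid[min(length(lambda_grid), best + 1L)])
  opt <- stats::optimize(nll, lower = lo, upper = hi)
  # ties (e.g. a flat profile when K is the identity) break toward the
  # parsimonious pure-noise boundary
  if (v0 <= opt$objective + 1e-8) {
    log10_lam <- -12; obj <- v0
  } else {
    log10_lam <- opt$minimum; obj <- opt$objective
  }
  lam <- 10^log10_lam
  w <- 1 / (lam * dvals + 1)
  XtWX <- crossprod(Xs, w * Xs)
  beta <- solve(XtWX, crossprod(Xs, w * ys))
  r <- ys - Xs %*% beta
  rss <- sum(w * r^2)
  sigma_e2 <- rss / (n - q)
  sigma_u2 <- lam * sigma_e2
  se_beta <- sqrt(diag(solve(XtWX)) * sigma_e2)
  list(lambda = lam, sigma_u2 = sigma_u2, sigma_e2 = sigma_e2,
       beta = drop(beta), se_beta = se_beta, U = U, d = dvals, w = w,
       ystar = drop(ys), Xstar = Xs, resid_star = drop(r),
       reml_nll = obj, n = n, q = q, eig = eig)
}

#' Fit a gBLUP genomic prediction model
#'
#' Mixed model `y = X beta + u + e` with `u ~ N(0, K sigma_u^2)` defined by a
#' centered genomic relationship matrix and `e ~ N(0, I sigma_e^2)`. Variance
#' components are estimated by REML through a single eigendecomposition of
#' `K` and one-dimensional optimisation of the variance ratio; the fit is
#' deterministic. In NC-II hybrid prediction, `X` carries an intercept plus
#' the maternal and paternal parents' phenotypes of the same trait as fixed
#' covariates and `y` is the within-population z-scored hybrid phenotype.
#'
#' @param y Named numeric vector of phenotypes (training samples).
#' @param K Kinship/GRM matrix covering at least the training samples.
#' @param X Fixed-effect design matrix (default: intercept only). A column of
#'   ones is prepended when absent.
#' @return An object of class `gblup` with components `beta`, `se_beta`,
#'   `sigma_u2`, `sigma_e2`, `h2` (`sigma_u2 * mean(diag(K)) /
#'   (sigma_u2 * mean(diag(K)) + sigma_e2)`), `u_hat` (BLUPs of the training
#'   random effects), `alpha` (weights such that `K[new, train] %*% alpha`
#'   gives new-sample BLUPs), `fitted`, `residuals`, and bookkeeping.
#' @seealso [predict.gblup()], [compute_cgrm()]
#' @export
gblup <- function(y, K, X = NULL) {
  if (is.null(names(y)) && !is.null(rownames(K)) && length(y) == nrow(K)) {
    names(y) <- rownames(K)
  }
  ids <- names(y)
  if (!is.null(rownames(K))) {
    if (!all(ids %in% rownames(K))) hf_stop("samples in y missing from K")
    K_t <- K[ids, ids, drop = FALSE]
  } else {
    K_t <- K
  }
  n <- length(y)
  if (is.null(X)) {
    X <- matrix(1, n, 1, dimnames = list(ids, "(Intercept)"))
  } else {
    X <- as.matrix(X)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    if (!any(apply(X, 2, function(c) all(c == c[1]) && c[1] != 0))) {
      X <- cbind(`(Intercept)` = 1, X)
    }
  }
  fit <- reml_kernel(y, X, K_t)
  # BLUP of training effects: u = lambda K V^{-1} sigma_e2 (y - X beta)
  #                             = U diag(lambda d w) U' r
  u_hat <- drop(fit$U %*% (fit$lambda * fit$d * fit$w * fit$resid_star))
  alpha <- drop(fit$U %*% (fit$lambda * fit$w * fit$resid_star))
  names(u_hat) <- ids; names(alpha) <- ids
  fitted <- drop(X %*% fit$beta) + u_hat
  structure(list(
    beta = stats::setNames(drop(fit$beta), colnames(X)),
    se_beta = stats::setNames(fit$se_beta, colnames(X)),
    sigma_u2 = fit$sigma_u2, sigma_e2 = fit$sigma_e2,
    lambda = fit$lambda,
    h2 = fit$sigma_u2 * mean(diag(K_t)) /
      (fit$sigma_u2 * mean(diag(K_t)) + fit$sigma_e2),
    u_hat = u_hat, alpha = alpha,
    fitted = stats::setNames(fitted, ids),
    residuals = stats::setNames(y - fitted, ids),
    y = y, X = X, training_ids = ids,
    reml_nll = fit$reml_nll
  ), class = "gblup")
}

#' @export
print.gblup <- function(x, ...) {
  cat("gBLUP model\n")
  cat(sprintf("  n = %d training samples\n", length(x$training_ids)))
  cat(sprintf("  sigma_u2 = %.4g, sigma_e2 = %.4g, h2 = %.3f\n",
              x$sigma_u2, x$sigma_e2, x$h2))
  cat("  fixed effects:\n")
  print(round(x$beta, 4))
  invisible(x)
}

#' @export
summary.gblup <- function(object, ...) {
  coefs <- cbind(Estimate = object$beta, `Std. Error` = object$se_beta,
                 `z value` = object$beta / object$se_beta)
  out <- list(coefficients = coefs, sigma_u2 = object$sigma_u2,
              sigma_e2 = object$sigma_e2, h2 = object$h2,
              n = length(object$training_ids))
  class(out) <- "summary.gblup"
  out
}

#' @export
print.summary.gblup <- function(x, ...) {
  cat("gBLUP model summary\n")
  cat(sprintf("  n = %d, sigma_u2 = %.4g, sigma_e2 = %.4g, h2 = %.3f\n\n",
              x$n, x$sigma_u2, x$sigma_e2, x$h2))
  stats::printCoefmat(x$coefficients)
  invisible(x)
}

#' @export
coef.gblup <- function(object, ...) object$beta

#' @export
fitted.gblup <- function(object, ...) object$fitted

#' @export
residuals.gblup <- function(object, ...) object$residuals

#' Predict unphenotyped samples from a gBLUP fit
#'
#' Candidate random effects are `K[candidate, training] %*% alpha`; the
#' prediction adds the fixed-covariate term. When `transform` is given the
#' z-scale prediction is mapped back to absolute trait units with
#' [inverse_zscore()].
#'
#' @param object A [gblup()] fit.
#' @param K_full GRM covering training and candidate samples.
#' @param newX Fixed-effect matrix for the candidates (same columns as the
#'   training `X`; intercept added when absent).
#' @param ids Candidate sample IDs (default: rows of `newX`, else all
#'   non-training rows of `K_full`).
#' @param transform Optional z-score transform for back-conversion.
#' @param ... Ignored.
#' @return Named numeric vector of predictions.
#' @export
predict.gblup <- function(object, K_full, newX = NULL, ids = NULL,
                          transform = NULL, ...) {
  if (is.null(ids)) {
    ids <- if (!is.null(newX) && !is.null(rownames(newX))) rownames(newX)
           else setdiff(rownames(K_full), object$training_ids)
  }
  if (!all(ids %in% rownames(K_full))) {
    hf_stop("candidate sample(s) absent from K_full")
  }
  if (!all(object$training_ids %in% rownames(K_full))) {
    hf_stop("training sample(s) absent from K_full")
  }
  u_c <- drop(K_full[ids, object$training_ids, drop = FALSE] %*% object$alpha)
  if (is.null(newX)) {
    if (ncol(object$X) > 1L) {
      hf_stop("model has covariates: supply newX for the candidates")
    }
    Xc <- matrix(1, length(ids), 1)
  } else {
    Xc <- as.matrix(newX)
    if (ncol(Xc) == ncol(object$X) - 1L) Xc <- cbind(1, Xc)
    if (ncol(Xc) != ncol(object$X)) {
      hf_stop("newX has ", ncol(Xc), " columns, model expects ",
              ncol(object$X))
    }
  }
  pred <- drop(Xc %*% object$beta) + u_c
  names(pred) <- ids
  if (!is.null(transform)) pred <- inverse_zscore(pred, transform)
  stats::setNames(pred, ids)
}

#' Simulate responses from a fitted gBLUP model
#'
#' Draws `y* = X beta + u* + e*` with `u* ~ N(0, sigma_u2 K)` and
#' `e* ~ N(0, sigma_e2 I)` at the fitted parameter values.
#'
#' @param object A [gblup()] fit.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional integer seed.
#' @param K GRM over the training samples (defaults to reconstructing the
#'   random-effect draw from the fit's eigenstructure is not stored; pass the
#'   training GRM used at fit time).
#' @param ... Ignored.
#' @return Data frame with `nsim` columns of simulated responses.
#' @export
simulate.gblup <- function(object, nsim = 1, seed = NULL, K, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(object$training_ids)
  K_t <- K[object$training_ids, object$training_ids, drop = FALSE]
  eig <- eigen(K_t, symmetric = TRUE)
  L <- eig$vectors %*% diag(sqrt(pmax(eig$values, 0)), n)
  mu <- drop(object$X %*% object$beta)
  out <- replicate(nsim, mu + sqrt(object$sigma_u2) * drop(L %*% stats::rnorm(n)) +
                     stats::rnorm(n, sd = sqrt(object$sigma_e2)))
  out <- as.data.frame(out)
  names(out) <- paste0("sim_", seq_len(nsim))
  rownames(out) <- object$training_ids
  out
}

# ---- evaluation schemes ----------------------------------------------------

# Internal: fit on a training cross subset and return predictions for a test
# subset, handling per-population z-scoring and parental covariates.
gblup_fold <- function(K, y, design, train_idx, test_idx,
                       maternal_pheno = NULL, paternal_pheno = NULL) {
  cr <- design$crosses
  ztrain <- numeric(length(train_idx))
  tfs <- list()
  for (t in unique(cr$paternal[train_idx])) {
    sel <- cr$paternal[train_idx] == t
    z <- zscore(y[train_idx][sel])
    ztrain[sel] <- z
    tfs[[t]] <- attr(z, "transform")
  }
  names(ztrain) <- cr$cross[train_idx]
  covar <- function(idx) {
    if (is.null(maternal_pheno)) return(NULL)
    cbind(maternal = unname(maternal_pheno[cr$maternal[idx]]),
          paternal = unname(paternal_pheno[cr$paternal[idx]]))
  }
  fit <- gblup(ztrain, K, X = covar(train_idx))
  Xc <- covar(test_idx)
  if (!is.null(Xc)) rownames(Xc) <- cr$cross[test_idx]
  pred_z <- predict(fit, K, newX = Xc, ids = cr$cross[test_idx])
  list(fit = fit, pred_z = pred_z, transforms = tfs)
}

#' Leave-one-tester-out predictability
#'
#' One fold per tester: the model is trained on all other testers' phenotyped
#' hybrids and predicts the held-out tester's hybrids; the report gives the
#' per-fold Pearson correlation between predicted and observed phenotypes.
#' Folds with fewer than three phenotyped test hybrids are skipped with a
#' warning.
#'
#' @param design A [make_training_split()] design (or full design; only
#'   phenotyped crosses in `y` are used).
#' @param K GRM covering all phenotyped hybrids.
#' @param y Named numeric vector of hybrid phenotypes (absolute scale; z-score
#'   normalisation is applied per population inside each training fold).
#' @param maternal_pheno,paternal_pheno Named vectors of parental phenotypes
#'   of the same trait, used as fixed covariates (optional, used together).
#' @return Data frame of class `predictability_report`: `fold` (held-out
#'   tester), `n_train`, `n_test`, `r`.
#' @export
evaluate_leave_one_tester <- function(design, K, y,
                                      maternal_pheno = NULL,
                                      paternal_pheno = NULL) {
  cr <- design$crosses
  phen <- cr$cross %in% names(y)[!is.na(y)]
  testers <- unique(cr$paternal[phen])
  if (length(testers) < 2L) hf_stop("need >= 2 testers with phenotyped hybrids")
  yy <- y[cr$cross]
  out <- list()
  for (t in testers) {
    test_idx <- which(phen & cr$paternal == t)
    train_idx <- which(phen & cr$paternal != t)
    if (length(test_idx) < 3L) {
      warning("tester ", t, " has < 3 phenotyped hybrids: fold skipped")
      next
    }
    fold <- gblup_fold(K, yy, design, train_idx, test_idx,
                       maternal_pheno, paternal_pheno)
    r <- stats::cor(fold$pred_z, yy[test_idx])
    out[[t]] <- data.frame(fold = t, n_train = length(train_idx),
                           n_test = length(test_idx), r = r,
                           stringsAsFactors = FALSE)
  }
  rep <- do.call(rbind, out)
  rownames(rep) <- NULL
  class(rep) <- c("predictability_report", "data.frame")
  attr(rep, "scheme") <- "leave_one_tester"
  rep
}

#' Tester-swap predictability
#'
#' Mirrors the paired-tester evaluation: the base block is the maternal
#' subset crossed to all testers; training adds tester A's extension hybrids
#' (the remaining maternal lines crossed to A) and the model predicts tester
#' B's extension hybrids, then the roles swap.
#'
#' @param design A [enumerate_crosses()] design.
#' @param K GRM covering all phenotyped hybrids.
#' @param y Named numeric vector of hybrid phenotypes (absolute scale).
#' @param tester_a,tester_b The two full-panel testers.
#' @param maternal_subset Maternal lines forming the base block.
#' @param maternal_pheno,paternal_pheno Optional parental covariates.
#' @return `predictability_report` with one row per direction.
#' @export
evaluate_tester_swap <- function(design, K, y, tester_a, tester_b,
                                 maternal_subset,
                                 maternal_pheno = NULL,
                                 paternal_pheno = NULL) {
  cr <- design$crosses
  yy <- y[cr$cross]
  phen <- !is.na(yy)
  base_idx <- which(phen & cr$maternal %in% maternal_subset)
  ext <- function(t) which(phen & !(cr$maternal %in% maternal_subset) &
                             cr$paternal == t)
  one <- function(train_t, test_t) {
    train_idx <- c(base_idx, ext(train_t))
    test_idx <- ext(test_t)
    if (!length(ext(train_t)) || !length(test_idx)) {
      hf_stop("empty extension set for tester ", train_t, " or ", test_t)
    }
    fold <- gblup_fold(K, yy, design, train_idx, test_idx,
                       maternal_pheno, paternal_pheno)
    data.frame(fold = paste0("train_", train_t, "_predict_", test_t),
               n_train = length(train_idx), n_test = length(test_idx),
               r = stats::cor(fold$pred_z, yy[test_idx]),
               stringsAsFactors = FALSE)
  }
  rep <- rbind(one(tester_a, tester_b), one(tester_b, tester_a))
  class(rep) <- c("predictability_report", "data.frame")
  attr(rep, "scheme") <- "tester_swap"
  rep
}
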