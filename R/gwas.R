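#' Fit the null mixed model of a GWAS scan
#'
#' Eigendecomposes the kinship matrix once, estimates the variance ratio by
#' one-dimensional profile REML, and caches the rotation so that every variant
#' can then be tested by weighted least squares in the rotated space. The
#' variance components estimated here under the null are reused across
#' variants of the scan (the population-parameters-previously-determined
#' approximation).
#'
#' @param y Named numeric phenotype vector.
#' @param K Kinship (GRM) matrix covering the samples, or `NULL` for an
#'   identity kinship (plain linear regression scan).
#' @param covariates Optional covariate matrix (intercept always included).
#' @return An object of class `null_lmm` caching the rotation, the REML
#'   variance components and the derived heritability.
#' @export
fit_null_lmm <- function(y, K = NULL, covariates = NULL) {
  ids <- names(y)
  n <- length(y)
  if (is.null(covariates)) {
    X <- matrix(1, n, 1, dimnames = list(ids, "(Intercept)"))
  } else {
    X <- cbind(`(Intercept)` = 1, as.matrix(covariates))
  }
  if (is.null(K)) {
    fit <- list(lambda = 0, sigma_u2 = 0, sigma_e2 = stats::var(y),
                U = NULL, d = rep(0, n), w = rep(1, n),
                ystar = y, Xstar = X, n = n, q = ncol(X))
    h2 <- 0
  } else {
    if (!is.null(rownames(K)) && !is.null(ids)) {
      K <- K[ids, ids, drop = FALSE]
    }
    fit <- reml_kernel(y, X, K)
    h2 <- fit$sigma_u2 * mean(diag(K)) /
      (fit$sigma_u2 * mean(diag(K)) + fit$sigma_e2)
  }
  structure(list(U = fit$U, d = fit$d, w = fit$w, lambda = fit$lambda,
                 sigma_u2 = fit$sigma_u2, sigma_e2 = fit$sigma_e2, h2 = h2,
                 ystar = drop(fit$ystar), Xstar = fit$Xstar,
                 n = fit$n %||% n, q = ncol(X), ids = ids),
            class = "null_lmm")
}

#' @export
print.null_lmm <- function(x, ...) {
  cat(sprintf("null LMM: n = %d, sigma_u2 = %.4g, sigma_e2 = %.4g, h2 = %.3f\n",
              x$n, x$sigma_u2, x$sigma_e2, x$h2))
  invisible(x)
}

# Core of every scan: given the rotated/weighted null model, test each column
# of G by generalized least squares. Returns beta, se, p (Wald t-test with
# n - q - 1 df). Monomorphic columns get beta 0, se NA, p 1. Missing dosages
# are mean-filled.
scan_kernel <- function(null, G) {
  n <- null$n
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    mu[is.nan(mu)] <- 0  # all-missing variant scans as monomorphic
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mu[idx[, 2]]
  }
  mono <- matrixStats_colVars(G) < .Machine$double.eps * 100
  Gs <- if (is.null(null$U)) G else crossprod(null$U, G)
  sw <- sqrt(null$w)
  yw <- sw * null$ystar
  Xw <- sw * null$Xstar
  Gw <- sw * Gs
  qrx <- qr(Xw)
  yt <- stats::resid(stats::lm.fit(Xw, yw))
  Gt <- qr.resid(qrx, Gw)
  gg <- colSums(Gt^2)
  gy <- colSums(Gt * yt)
  yy <- sum(yt^2)
  df <- n - null$q - 1L
  beta <- gy / gg
  rss <- pmax(yy - beta * gy, 0)
  sigma2 <- rss / df
  se <- sqrt(sigma2 / gg)
  tstat <- beta / se
  p <- 2 * stats::pt(-abs(tstat), df)
  beta[mono] <- 0; se[mono] <- NA_real_; p[mono] <- 1
  p[!mono] <- pmax(p[!mono], .Machine$double.xmin)  # keep p in (0, 1]
  list(beta = beta, se = se, p = p)
}

# colVars without extra dependencies
matrixStats_colVars <- function(G) {
  n <- nrow(G)
  if (n < 2L) return(rep(0, ncol(G)))
  mu <- colMeans(G)
  (colSums(G^2) - n * mu^2) / (n - 1)
}

#' Mixed-model association scan
#'
#' Tests each variant for association with the phenotype under the null
#' model's variance components: generalized least squares in the rotated
#' space, Wald p-values. With identity kinship and no covariates this is
#' exactly the simple-regression t-test at every variant. Monomorphic
#' variants are reported with `p = 1`. Adding a constant to `y` or flipping a
#' variant's allele labels leaves p-values unchanged (the effect sign flips).
#'
#' @param gm A [geno_matrix()] of the scanned samples.
#' @param y Named phenotype vector aligned with `gm` samples.
#' @param K Kinship matrix or `NULL` (identity; plain regression).
#' @param covariates Optional covariates.
#' @param null Optionally a prefitted [fit_null_lmm()] (overrides `K`,
#'   `covariates`).
#' @param population,trait Labels stored on the result.
#' @return A `gwas_result`: data frame `id`, `chrom`, `pos`, `beta`, `se`,
#'   `p` with attributes `population`, `trait`, `n`, `vc`.
#' @export
association_scan <- function(gm, y, K = NULL, covariates = NULL, null = NULL,
                             population = "pop", trait = "trait") {
  ids <- names(y)
  if (is.null(ids)) hf_stop("y must be named by sample ID")
  if (!all(ids %in% sample_ids(gm))) {
    hf_stop("phenotyped samples missing from genotype matrix")
  }
  G <- gm$dosages[ids, , drop = FALSE]
  if (is.null(null)) null <- fit_null_lmm(y, K, covariates)
  res <- scan_kernel(null, G)
  out <- data.frame(id = gm$variants$id, chrom = gm$variants$chrom,
                    pos = gm$variants$pos, beta = res$beta, se = res$se,
                    p = res$p, stringsAsFactors = FALSE)
  structure(out, class = c("gwas_result", "data.frame"),
            population = population, trait = trait, n = length(y),
            vc = c(sigma_u2 = null$sigma_u2, sigma_e2 = null$sigma_e2))
}

#' @export
print.gwas_result <- function(x, ...) {
  cat(sprintf("GWAS result: population %s, trait %s, %d variants, n = %d\n",
              attr(x, "population"), attr(x, "trait"), nrow(x), attr(x, "n")))
  cat(sprintf("  min p = %.3g at %s\n", min(x$p), x$id[which.min(x$p)]))
  invisible(x)
}

#' Write / read a GWAS result TSV
#'
#' Columns `id`, `chrom`, `pos`, `beta`, `se`, `p`.
#'
#' @param gwas A `gwas_result`.
#' @param path File path.
#' @return `path` (write) or a `gwas_result` (read).
#' @export
write_gwas <- function(gwas, path) {
  utils::write.table(as.data.frame(gwas), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_gwas
#' @export
read_gwas <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  structure(out, class = c("gwas_result", "data.frame"))
}

#' Conditional association scan by tag-SNP genotype
#'
#' Splits the samples into the two homozygous classes at a tag variant
#' (heterozygous and missing samples are excluded), then runs an independent
#' scan within each class, re-fitting kinship and null model per subgroup.
#' Classes below `config$min_subgroup` samples are skipped with a warning.
#'
#' @param gm A [geno_matrix()].
#' @param y Named phenotype vector.
#' @param tag_variant Variant ID defining the split.
#' @param with_kinship Recompute a subgroup GRM and fit the mixed model
#'   (default); otherwise plain regression scans.
#' @param config An [hf_config()].
#' @param trait Label stored on the results.
#' @return Named list of `gwas_result` (one per genotype class, e.g.
#'   `"dosage0"`, `"dosage2"`), with attribute `excluded` (het/missing sample
#'   IDs).
#' @export
conditional_scan <- function(gm, y, tag_variant, with_kinship = TRUE,
                             config = hf_config(), trait = "trait") {
  j <- match(tag_variant, gm$variants$id)
  if (is.na(j)) hf_stop("tag variant not found: ", tag_variant)
  tag <- gm$dosages[names(y), j]
  if (length(unique(tag[!is.na(tag)])) < 2L) {
    hf_stop("tag variant is monomorphic among scanned samples")
  }
  excluded <- names(y)[is.na(tag) | tag == 1]
  out <- list()
  for (dos in c(0, 2)) {
    sel <- !is.na(tag) & tag == dos
    label <- paste0("dosage", dos)
    if (sum(sel) < config$min_subgroup) {
      warning("class ", label, " has ", sum(sel), " samples (< ",
              config$min_subgroup, "): skipped")
      next
    }
    sub_ids <- names(y)[sel]
    sub_gm <- gm[sub_ids, ]
    K <- if (with_kinship) compute_cgrm(sub_gm) else NULL
    out[[label]] <- association_scan(sub_gm, y[sub_ids], K = K,
                                     population = label, trait = trait)
  }
  attr(out, "excluded") <- excluded
  out
}

#' Run the full GWAS battery of an NC-II study
#'
#' One scan per (population, trait) cell: the maternal population is scanned
#' for each base trait, and every F1 population (one per tester) is scanned
#' for each base trait and each derived MPH trait, so the number of scans is
#' `T_maternal + P * (T + T_mph)`.
#'
#' @param maternal_gm,f1_gm Genotypes of maternal lines and hybrids.
#' @param maternal_pheno Data frame, one row per maternal line (column
#'   `sample`), one column per trait.
#' @param f1_pheno Data frame, one row per hybrid (column `cross`), one
#'   column per trait (base traits and MPH traits).
#' @param design The [enumerate_crosses()] design.
#' @param traits Base trait names; `mph_traits` the MPH columns.
#' @param with_kinship Fit a per-population cGRM mixed model (default) or
#'   plain regression scans.
#' @return Named list of `gwas_result`, keys `"maternal:TRAIT"` and
#'   `"TESTER:TRAIT"`. Cells whose phenotype column is absent are skipped and
#'   logged.
#' @export
run_gwas_battery <- function(maternal_gm, maternal_pheno, f1_gm, f1_pheno,
                             design, traits, mph_traits = character(),
                             with_kinship = TRUE) {
  out <- list()
  for (tr in traits) {
    if (!tr %in% names(maternal_pheno)) {
      hf_log("maternal trait column missing, cell skipped: ", tr)
      next
    }
    y <- stats::setNames(maternal_pheno[[tr]], maternal_pheno$sample)
    y <- y[!is.na(y)]
    K <- if (with_kinship) compute_cgrm(maternal_gm[names(y), ]) else NULL
    out[[paste0("maternal:", tr)]] <-
      association_scan(maternal_gm, y, K = K, population = "maternal",
                       trait = tr)
  }
  cr <- design$crosses
  for (t in design$paternal_ids) {
    pop_crosses <- cr$cross[cr$paternal == t]
    pop_crosses <- intersect(pop_crosses, f1_pheno$cross)
    pop_crosses <- intersect(pop_crosses, sample_ids(f1_gm))
    if (!length(pop_crosses)) next
    prow <- f1_pheno[match(pop_crosses, f1_pheno$cross), , drop = FALSE]
    gm_pop <- f1_gm[pop_crosses, ]
    K <- if (with_kinship) compute_cgrm(gm_pop) else NULL
    for (tr in c(traits, mph_traits)) {
      if (!tr %in% names(f1_pheno)) {
        hf_log("F1 trait column missing, cell skipped: ", tr)
        next
      }
      y <- stats::setNames(prow[[tr]], prow$cross)
      y <- y[!is.na(y)]
      if (length(y) < 3L) next
      out[[paste0(t, ":", tr)]] <-
        association_scan(gm_pop, y, K = if (is.null(K)) NULL else K,
                         population = t, trait = tr)
    }
  }
  out
}

#' Genomic inflation factor
#'
#' Median-chi-squared definition: `lambda_gc = median(qchisq(1 - p, 1)) /
#' qchisq(0.5, 1)`. Values near 1 indicate a well-calibrated scan.
#'
#' @param p Vector of scan p-values.
#' @return The inflation factor.
#' @export
genomic_inflation <- function(p) {
  stats::median(stats::qchisq(1 - p, df = 1)) / stats::qchisq(0.5, df = 1)
}
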