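#' Enumerate an NC-II factorial cross design
#'
#' Builds the full factorial of maternal lines by paternal testers in
#' deterministic maternal-major order. A line may not appear in both pools
#' (the NC-II pools are disjoint and selfing crosses are undefined).
#'
#' @param maternal_ids Character vector of maternal line IDs.
#' @param paternal_ids Character vector of paternal tester IDs.
#' @return An object of class `cross_design`: list with `maternal_ids`,
#'   `paternal_ids`, `crosses` (data frame `cross`, `maternal`, `paternal`)
#'   and `training` (logical mask, `NA` until a split is made).
#' @export
#' @examples
#' d <- enumerate_crosses(c("m1", "m2", "m3"), c("t1", "t2"))
#' nrow(d$crosses)  # 6
enumerate_crosses <- function(maternal_ids, paternal_ids) {
  if (length(maternal_ids) == 0L || length(paternal_ids) == 0L) {
    hf_stop("both parental ID lists must be non-empty")
  }
  if (anyDuplicated(maternal_ids) || anyDuplicated(paternal_ids)) {
    hf_stop("parental IDs must be unique within each pool")
  }
  overlap <- intersect(maternal_ids, paternal_ids)
  if (length(overlap)) {
    hf_stop("IDs present in both pools (selfing undefined): ",
            paste(overlap, collapse = ", "))
  }
  crosses <- data.frame(
    maternal = rep(maternal_ids, each = length(paternal_ids)),
    paternal = rep(paternal_ids, times = length(maternal_ids)),
    stringsAsFactors = FALSE
  )
  crosses <- cbind(cross = paste(crosses$maternal, crosses$paternal, sep = "_x_"),
                   crosses)
  structure(list(maternal_ids = maternal_ids, paternal_ids = paternal_ids,
                 crosses = crosses,
                 training = rep(NA, nrow(crosses))),
            class = "cross_design")
}

#' @export
print.cross_design <- function(x, ...) {
  cat(sprintf("cross_design: %d maternal x %d paternal = %d crosses\n",
              length(x$maternal_ids), length(x$paternal_ids), nrow(x$crosses)))
  if (!anyNA(x$training)) {
    cat(sprintf("  training %d, candidate %d\n",
                sum(x$training), sum(!x$training)))
  }
  invisible(x)
}

#' Mark the training subset of an NC-II design
#'
#' The training set is the union of (all maternal lines x `full_testers`) and
#' (`maternal_subset` x the remaining testers); everything else is the
#' candidate (to-be-predicted) set.
#'
#' @param design A [enumerate_crosses()] design.
#' @param full_testers Testers crossed to the complete maternal panel.
#' @param maternal_subset Maternal lines phenotyped against the remaining
#'   testers.
#' @return The design with its `training` mask filled in.
#' @export
make_training_split <- function(design, full_testers,
                                maternal_subset = character()) {
  stopifnot(inherits(design, "cross_design"))
  if (!all(full_testers %in% design$paternal_ids)) {
    hf_stop("full_testers must be a subset of the design's paternal IDs")
  }
  if (!all(maternal_subset %in% design$maternal_ids)) {
    hf_stop("maternal_subset must be a subset of the design's maternal IDs")
  }
  mask <- design$crosses$paternal %in% full_testers |
    design$crosses$maternal %in% maternal_subset
  if (!any(mask)) hf_stop("training set is empty")
  design$training <- mask
  design
}

# F1 dosage algebra for homozygous inbred parents: (m + p) / 2 with any
# heterozygous or missing parental call propagated as missing.
f1_dosage <- function(m, p) {
  f1 <- (m + p) / 2
  f1[m == 1 | p == 1] <- NA_real_
  f1
}

#' Apply the five-step parental SNP filter
#'
#' Filters parental genotypes ahead of F1 inference, in fixed order:
#' \enumerate{
#'   \item Heterozygous parental calls are not removed but flagged: each such
#'     call makes the corresponding F1 cell missing (cell-level; reported as a
#'     cell count).
#'   \item Variants with heterozygote rate >= 10\% among maternal lines or
#'     >= 1/30 among paternal testers are removed.
#'   \item Variants monomorphic within the maternal pool or within the
#'     paternal pool are removed.
#'   \item Variants with MAF < 0.02 across all parental lines are removed.
#'   \item Variants whose minor homozygous genotype occurs in fewer than 0.5\%
#'     of the F1 hybrids derived over the full factorial are removed.
#' }
#' Counts in and out of every step are logged and returned; re-running the
#' filter on its own output removes nothing further.
#'
#' @param parents A [geno_matrix()] holding all design parents.
#' @param design A [enumerate_crosses()] design.
#' @param het_rate_maternal,het_rate_paternal Criterion-2 thresholds.
#' @param min_maf Criterion-4 threshold.
#' @param min_hom_frac Criterion-5 threshold (fraction of all hybrids).
#' @return List with `genotypes` (filtered `geno_matrix`) and `report`
#'   (class `filter_report`): per-criterion removal counts, the count of
#'   heterozygous parental cells flagged by criterion 1, and retained count.
#' @export
filter_parent_snps <- function(parents, design,
                               het_rate_maternal = 0.10,
                               het_rate_paternal = 1 / 30,
                               min_maf = 0.02,
                               min_hom_frac = 0.005) {
  stopifnot(inherits(parents, "geno_matrix"), inherits(design, "cross_design"))
  missing_par <- setdiff(c(design$maternal_ids, design$paternal_ids),
                         sample_ids(parents))
  if (length(missing_par)) {
    hf_stop("design parents absent from genotype matrix: ",
            paste(utils::head(missing_par, 5L), collapse = ", "))
  }
  n_in <- ncol(parents$dosages)
  M <- parents$dosages[design$maternal_ids, , drop = FALSE]
  P <- parents$dosages[design$paternal_ids, , drop = FALSE]

  # criterion 1: cell-level flags only
  n_het_cells <- sum(M == 1, na.rm = TRUE) + sum(P == 1, na.rm = TRUE)

  keep <- rep(TRUE, n_in)
  removed <- integer(4)

  het_m <- colMeans(M == 1, na.rm = TRUE)
  het_p <- colMeans(P == 1, na.rm = TRUE)
  het_m[is.nan(het_m)] <- 0; het_p[is.nan(het_p)] <- 0
  r2 <- keep & (het_m >= het_rate_maternal | het_p >= het_rate_paternal)
  removed[1] <- sum(r2); keep <- keep & !r2

  mono_pool <- function(X) {
    mx <- apply(X, 2, function(v) {
      v <- v[!is.na(v)]
      length(unique(v)) <= 1L
    })
    mx
  }
  r3 <- keep & (mono_pool(M) | mono_pool(P))
  removed[2] <- sum(r3); keep <- keep & !r3

  all_par <- rbind(M, P)
  p_freq <- colMeans(all_par, na.rm = TRUE) / 2
  maf <- pmin(p_freq, 1 - p_freq)
  maf[is.nan(maf)] <- 0
  r4 <- keep & (maf < min_maf)
  removed[3] <- sum(r4); keep <- keep & !r4

  # criterion 5 on the full factorial: per-variant homozygote counts among
  # derived F1s follow from parental homozygote counts
  n0m <- colSums(M == 0, na.rm = TRUE); n2m <- colSums(M == 2, na.rm = TRUE)
  n0p <- colSums(P == 0, na.rm = TRUE); n2p <- colSums(P == 2, na.rm = TRUE)
  hom0 <- n0m * n0p
  hom2 <- n2m * n2p
  minor_hom <- pmin(hom0, hom2)
  n_crosses <- nrow(design$crosses)
  r5 <- keep & (minor_hom < min_hom_frac * n_crosses)
  removed[4] <- sum(r5); keep <- keep & !r5

  report <- structure(list(
    n_in = n_in,
    het_cells_flagged = n_het_cells,
    removed = c(criterion2_het_rate = removed[1],
                criterion3_pool_monomorphic = removed[2],
                criterion4_maf = removed[3],
                criterion5_minor_homozygote = removed[4]),
    retained = sum(keep)
  ), class = "filter_report")
  hf_log(sprintf(
    "SNP filter: %d in; removed %d (het rate), %d (pool monomorphic), %d (MAF), %d (minor homozygote); %d retained; %d het parental cells flagged",
    n_in, removed[1], removed[2], removed[3], removed[4], sum(keep), n_het_cells))
  list(genotypes = parents[, which(keep)], report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("SNP filter report\n")
  cat("  variants in:      ", x$n_in, "\n")
  for (nm in names(x$removed)) {
    cat(sprintf("  removed %-28s %d\n", paste0(nm, ":"), x$removed[[nm]]))
  }
  cat("  retained:         ", x$retained, "\n")
  cat("  het cells flagged:", x$het_cells_flagged, "\n")
  invisible(x)
}

#' Derive F1 hybrid genotypes from parental genotypes
#'
#' For homozygous parents the F1 dosage is the mid-parent dosage
#' (0x0 -> 0, 0x2 -> 1, 2x2 -> 2). Any heterozygous or missing parental call
#' makes the hybrid call missing. Flipping the ref/alt labels of a variant
#' flips d -> 2 - d consistently for parents and hybrids.
#'
#' @param parents A [geno_matrix()] (filtered).
#' @param design A [enumerate_crosses()] design.
#' @return A [geno_matrix()] over the design's crosses.
#' @export
infer_f1_genotypes <- function(parents, design) {
  stopifnot(inherits(parents, "geno_matrix"), inherits(design, "cross_design"))
  missing_par <- setdiff(unique(c(design$crosses$maternal, design$crosses$paternal)),
                         sample_ids(parents))
  if (length(missing_par)) {
    hf_stop("cross references unknown parent(s): ",
            paste(utils::head(missing_par, 5L), collapse = ", "))
  }
  M <- parents$dosages[design$crosses$maternal, , drop = FALSE]
  P <- parents$dosages[design$crosses$paternal, , drop = FALSE]
  f1 <- f1_dosage(M, P)
  rownames(f1) <- design$crosses$cross
  geno_matrix(f1, parents$variants)
}

#' Impute missing F1 genotypes by within-tester mode fill
#'
#' Each missing hybrid call is filled with the modal dosage among hybrids
#' sharing the same paternal tester at that variant, ties broken toward the
#' lower dosage. This deterministic mode imputer stands where one would
#' otherwise run a haplotype-based imputer; imputed-cell counts are logged and
#' recorded in the result's `imputed` attribute. Variants missing in all
#' hybrids of a tester are left missing with a warning.
#'
#' @param f1 A [geno_matrix()] of hybrids (rows named by cross ID).
#' @param design The [enumerate_crosses()] design.
#' @return The imputed `geno_matrix`.
#' @export
impute_f1_missing <- function(f1, design) {
  stopifnot(inherits(f1, "geno_matrix"), inherits(design, "cross_design"))
  d <- f1$dosages
  idx <- match(rownames(d), design$crosses$cross)
  if (anyNA(idx)) hf_stop("hybrid rows not present in design")
  tester <- design$crosses$paternal[idx]
  n_imputed <- 0L
  unfillable <- 0L
  for (t in unique(tester)) {
    rows <- which(tester == t)
    sub <- d[rows, , drop = FALSE]
    na_cols <- which(colSums(is.na(sub)) > 0L)
    if (!length(na_cols)) next
    for (j in na_cols) {
      v <- sub[, j]
      cnt <- c(sum(v == 0, na.rm = TRUE), sum(v == 1, na.rm = TRUE),
               sum(v == 2, na.rm = TRUE))
      if (sum(cnt) == 0L) { unfillable <- unfillable + 1L; next }
      mode_dos <- which.max(cnt) - 1L  # first max -> lower dosage on ties
      miss <- is.na(v)
      sub[miss, j] <- mode_dos
      n_imputed <- n_imputed + sum(miss)
    }
    d[rows, ] <- sub
  }
  if (unfillable > 0L) {
    warning(unfillable,
            " variant-by-tester cell group(s) fully missing: left missing")
  }
  hf_log("mode-fill imputation: ", n_imputed, " cell(s) filled")
  out <- geno_matrix(d, f1$variants)
  attr(out, "imputed") <- n_imputed
  out
}
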