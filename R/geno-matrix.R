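#' Genotype matrix container
#'
#' Holds biallelic SNP genotypes as alt-allele dosages together with variant
#' metadata. Dosages are coded 0/1/2 (count of alt alleles) with `NA` for
#' missing calls. Variants are kept sorted by (chromosome, position); positions
#' are 1-based and all intervals in the package are closed, following VCF
#' convention.
#'
#' @param dosages Numeric matrix, samples x variants, entries in
#'   \{0, 1, 2, NA\}. Row names are sample IDs (or supply `sample_ids`).
#' @param variants Data frame with columns `id`, `chrom`, `pos`, `ref`, `alt`
#'   (one row per dosage column).
#' @param sample_ids Optional character vector of sample IDs.
#' @return An object of class `geno_matrix`: a list with elements `dosages`
#'   (matrix with sample row names and variant-id column names) and `variants`.
#' @export
#' @examples
#' gm <- geno_matrix(
#'   dosages = rbind(s1 = c(0, 2), s2 = c(2, NA)),
#'   variants = data.frame(id = c("v1", "v2"), chrom = "1",
#'                         pos = c(100L, 200L), ref = "A", alt = "T")
#' )
#' compute_maf(gm)
geno_matrix <- function(dosages, variants, sample_ids = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (!is.null(sample_ids)) rownames(dosages) <- sample_ids
  if (is.null(rownames(dosages))) {
    hf_stop("sample IDs required (row names of 'dosages' or 'sample_ids')")
  }
  if (anyDuplicated(rownames(dosages))) {
    hf_stop("duplicate sample IDs: ",
            paste(unique(rownames(dosages)[duplicated(rownames(dosages))]),
                  collapse = ", "))
  }
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  req <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(req %in% names(variants))) {
    hf_stop("variants must have columns: ", paste(req, collapse = ", "))
  }
  if (nrow(variants) != ncol(dosages)) {
    hf_stop("variant count (", nrow(variants),
            ") does not match dosage columns (", ncol(dosages), ")")
  }
  variants$pos <- as.integer(variants$pos)
  if (any(variants$pos < 1L)) hf_stop("positions must be >= 1 (1-based)")
  if (any(variants$ref == variants$alt)) hf_stop("ref and alt alleles must differ")
  if (anyDuplicated(variants$id)) hf_stop("duplicate variant IDs")
  bad <- !(dosages %in% c(0, 1, 2) | is.na(dosages))
  if (any(bad)) hf_stop("dosages must be 0, 1, 2 or NA")
  ord <- order(variants$chrom, variants$pos)
  if (any(ord != seq_along(ord))) {
    hf_log("variants reordered by (chrom, pos)")
    variants <- variants[ord, , drop = FALSE]
    dosages <- dosages[, ord, drop = FALSE]
  }
  rownames(variants) <- NULL
  colnames(dosages) <- variants$id
  structure(list(dosages = dosages, variants = variants), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d samples x %d variants (%d chromosome%s), %.2f%% missing\n",
              nrow(x$dosages), ncol(x$dosages),
              length(unique(x$variants$chrom)),
              if (length(unique(x$variants$chrom)) == 1L) "" else "s",
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix
#'
#' @param x A `geno_matrix`.
#' @param i Sample selector (indices or IDs).
#' @param j Variant selector (indices or IDs).
#' @param ... Ignored.
#' @return A `geno_matrix`.
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosages))
  if (missing(j)) j <- seq_len(ncol(x$dosages))
  if (is.character(j)) j <- match(j, x$variants$id)
  if (anyNA(j)) hf_stop("unknown variant selection")
  d <- x$dosages[i, j, drop = FALSE]
  if (anyNA(rownames(d))) hf_stop("unknown sample selection")
  geno_matrix(d, x$variants[j, , drop = FALSE])
}

sample_ids <- function(gm) rownames(gm$dosages)

#' Read genotypes from a VCF file
#'
#' Parses diploid GT fields of a VCF 4.x file into alt-allele dosages.
#' Half-calls and `./.` become missing. Multiallelic records are skipped with
#' a logged count (or rejected, per `config$multiallelic`).
#'
#' @param path Path to a VCF file (plain or gzipped).
#' @param config An [hf_config()].
#' @return A [geno_matrix()].
#' @export
read_vcf <- function(path, config = hf_config()) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (ncol(vcf@gt) < 2L) hf_stop("VCF contains zero samples")
  bi <- vcfR::is.biallelic(vcf)
  if (any(!bi)) {
    if (config$multiallelic == "error") {
      hf_stop(sum(!bi), " multiallelic record(s) in ", path)
    }
    hf_log("skipped ", sum(!bi), " multiallelic record(s)")
    vcf <- vcf[bi, ]
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  # count alt alleles in a diploid GT, tolerating phased separators
  core <- gsub("\\|", "/", gt)
  dos <- matrix(NA_real_, nrow = nrow(core), ncol = ncol(core))
  dos[core %in% c("0/0")] <- 0
  dos[core %in% c("0/1", "1/0")] <- 1
  dos[core %in% c("1/1")] <- 2
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  ids <- fix$ID
  need_id <- is.na(ids) | ids == "."
  ids[need_id] <- paste0(fix$CHROM[need_id], ".s_", fix$POS[need_id])
  variants <- data.frame(id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
                         ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  geno_matrix(t(dos), variants, sample_ids = colnames(gt))
}

#' Write genotypes to a minimal VCF file
#'
#' Emits homozygous/heterozygous diploid GT calls (`0/0`, `0/1`, `1/1`, `./.`)
#' so that [read_vcf()] recovers the dosage matrix exactly.
#'
#' @param gm A [geno_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  gtmap <- c("0/0", "0/1", "1/1")
  d <- gm$dosages
  gt <- matrix("./.", nrow = ncol(d), ncol = nrow(d))
  ok <- !is.na(t(d))
  gt[ok] <- gtmap[t(d)[ok] + 1]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(d)), collapse = "\t")), con)
  v <- gm$variants
  body <- paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT",
                sep = "\t")
  body <- paste(body, apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Read / write the dosage-matrix TSV dialect
#'
#' The TSV layout is one variant per row with columns `id`, `chrom`, `pos`,
#' `ref`, `alt` followed by one dosage column per sample; missing calls are the
#' literal token `NA`. Round trips are lossless. Unsorted variant rows are
#' sorted by (chrom, pos) with a logged note; duplicate sample columns are an
#' error.
#'
#' @param path File path.
#' @return A [geno_matrix()].
#' @export
read_matrix <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = "NA",
                           colClasses = c(id = "character",
                                          chrom = "character",
                                          pos = "integer",
                                          ref = "character",
                                          alt = "character"))
  meta_cols <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(meta_cols %in% names(tab))) {
    hf_stop("matrix TSV must start with columns: ",
            paste(meta_cols, collapse = ", "))
  }
  samp <- names(tab)[!names(tab) %in% meta_cols]
  if (length(samp) == 0L) hf_stop("matrix TSV contains zero sample columns")
  if (anyDuplicated(samp)) hf_stop("duplicate sample ID in matrix TSV header")
  dos <- t(as.matrix(tab[, samp, drop = FALSE]))
  rownames(dos) <- samp
  geno_matrix(dos, tab[, meta_cols], sample_ids = samp)
}

#' @rdname read_matrix
#' @param gm A [geno_matrix()].
#' @export
write_matrix <- function(gm, path) {
  out <- cbind(gm$variants,
               as.data.frame(t(gm$dosages), check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Per-variant minor allele frequency
#'
#' MAF is `min(p, 1 - p)` where `p` is the mean dosage over non-missing calls
#' divided by 2. Variants with no non-missing call get `NA` with a warning.
#' The result is invariant to swapping the ref/alt labels of a variant.
#'
#' @param gm A [geno_matrix()].
#' @return Named numeric vector of MAFs in \[0, 0.5\].
#' @export
compute_maf <- function(gm) {
  n_obs <- colSums(!is.na(gm$dosages))
  p <- colMeans(gm$dosages, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  if (any(n_obs == 0L)) {
    warning(sum(n_obs == 0L), " variant(s) with all calls missing: MAF undefined")
    maf[n_obs == 0L] <- NA_real_
  }
  names(maf) <- gm$variants$id
  maf
}

#' Principal component scores of a genotype matrix
#'
#' Missing dosages are mean-filled (for this computation only), variants are
#' centered, and scores of the leading principal components are returned.
#' Component variances are non-increasing.
#'
#' @param gm A [geno_matrix()].
#' @param n_components Number of components.
#' @return Numeric matrix, samples x components, with an attribute `sdev`
#'   holding the component standard deviations.
#' @export
pca_scores <- function(gm, n_components = 2L) {
  d <- gm$dosages
  if (nrow(d) < 2L || ncol(d) < 2L) hf_stop("PCA needs >= 2 samples and >= 2 variants")
  if (n_components > min(dim(d))) {
    hf_stop("n_components exceeds min(samples, variants)")
  }
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2]]
  }
  pc <- stats::prcomp(d, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  attr(scores, "sdev") <- pc$sdev[seq_len(n_components)]
  scores
}
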