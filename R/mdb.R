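#' Multi-locus haplotype groups
#'
#' Partitions the samples that are homozygous and non-missing at every listed
#' locus into groups by their genotype combination. Groups are labelled
#' `Hap1..HapK` in lexicographic order of the allele combination (dosage-0
#' before dosage-2 at each locus), so labels are canonical for a given locus
#' list. Heterozygous or missing samples are excluded with a logged count.
#'
#' @param gm A [geno_matrix()].
#' @param loci Character vector of variant IDs.
#' @return Data frame of class `haplotype_groups`: `label`, `combo`
#'   (e.g. `"0/2"`), `n`, `members` (list column), with attribute `excluded`.
#' @export
haplotype_groups <- function(gm, loci) {
  j <- match(loci, gm$variants$id)
  if (anyNA(j)) {
    hf_stop("locus not found: ", paste(loci[is.na(j)], collapse = ", "))
  }
  D <- gm$dosages[, j, drop = FALSE]
  hom <- rowSums(is.na(D) | D == 1) == 0L
  if (!any(hom)) hf_stop("no sample is homozygous at all loci")
  excluded <- rownames(D)[!hom]
  hf_log(length(excluded), " sample(s) heterozygous/missing at the loci: excluded")
  combo <- apply(D[hom, , drop = FALSE], 1, paste, collapse = "/")
  combos <- sort(unique(combo))  # lexicographic canonical order
  rows <- lapply(seq_along(combos), function(k) {
    mem <- rownames(D)[hom][combo == combos[k]]
    data.frame(label = paste0("Hap", k), combo = combos[k], n = length(mem),
               members = I(list(mem)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "excluded") <- excluded
  attr(out, "loci") <- loci
  class(out) <- c("haplotype_groups", "data.frame")
  out
}

#' Group-wise trait statistics with a reference comparison
#'
#' Per group and trait: sample size, mean, standard deviation, and the Welch
#' (unequal-variance) two-sample t-test p-value against the reference group.
#' Groups smaller than `min_size` are excluded with a log note; degenerate
#' variance in both groups yields `p = 1` with a flag.
#'
#' @param groups A [haplotype_groups()] table.
#' @param phenotypes Data frame with column `sample` plus one column per
#'   trait.
#' @param reference Label of the reference group.
#' @param min_size Minimum group size retained.
#' @return Data frame of class `group_stats`: `label`, `trait`, `n`, `mean`,
#'   `sd`, `p_vs_ref`, `degenerate`.
#' @export
group_trait_stats <- function(groups, phenotypes, reference = groups$label[1],
                              min_size = 2L) {
  if (!reference %in% groups$label) hf_stop("unknown reference group ", reference)
  traits <- setdiff(names(phenotypes), "sample")
  val <- function(label, tr) {
    mem <- unlist(groups$members[groups$label == label])
    v <- phenotypes[[tr]][match(mem, phenotypes$sample)]
    v[!is.na(v)]
  }
  rows <- list()
  for (lab in groups$label) {
    for (tr in traits) {
      v <- val(lab, tr)
      if (length(v) < min_size) {
        hf_log("group ", lab, " below min size for ", tr, ": excluded")
        next
      }
      ref_v <- val(reference, tr)
      degen <- FALSE
      if (lab == reference) {
        p <- 1
      } else if (stats::sd(v) == 0 && stats::sd(ref_v) == 0) {
        p <- 1; degen <- TRUE
      } else {
        p <- tryCatch(stats::t.test(v, ref_v)$p.value, error = function(e) {
          degen <<- TRUE; 1
        })
      }
      rows[[length(rows) + 1L]] <- data.frame(
        label = lab, trait = tr, n = length(v), mean = mean(v),
        sd = stats::sd(v), p_vs_ref = p, degenerate = degen,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "reference") <- reference
  class(out) <- c("group_stats", "data.frame")
  out
}

#' Two-locus epistasis table
#'
#' Cell means, standard deviations and counts of the phenotype over the
#' observed homozygous genotype combinations of two loci, plus the
#' interaction contrast `(AA,BB) - (AA,bb) - (aa,BB) + (aa,bb)` (dosage-2
#' homozygote written as the capital class) with its standard error. An empty
#' corner cell leaves the contrast undefined (`NA`, flagged).
#'
#' @param gm A [geno_matrix()].
#' @param locus_a,locus_b Variant IDs.
#' @param phenotype Named numeric vector over samples.
#' @return List of class `epistasis_table`: `cells` (data frame `a`, `b`,
#'   `n`, `mean`, `sd`), `contrast`, `contrast_se`, `defined`. Swapping the
#'   locus order leaves the contrast unchanged.
#' @export
two_locus_epistasis_table <- function(gm, locus_a, locus_b, phenotype) {
  ja <- match(locus_a, gm$variants$id); jb <- match(locus_b, gm$variants$id)
  if (is.na(ja) || is.na(jb)) hf_stop("locus not found")
  ids <- intersect(names(phenotype), sample_ids(gm))
  a <- gm$dosages[ids, ja]; b <- gm$dosages[ids, jb]
  y <- phenotype[ids]
  if (length(unique(a[!is.na(a)])) < 2L || length(unique(b[!is.na(b)])) < 2L) {
    hf_stop("both loci must be polymorphic among phenotyped samples")
  }
  keep <- !is.na(a) & !is.na(b) & !is.na(y)
  a <- a[keep]; b <- b[keep]; y <- y[keep]
  cells <- stats::aggregate(y, list(a = a, b = b),
                            function(v) c(n = length(v), mean = mean(v),
                                          sd = stats::sd(v)))
  cells <- data.frame(a = cells$a, b = cells$b,
                      n = cells$x[, "n"], mean = cells$x[, "mean"],
                      sd = cells$x[, "sd"], stringsAsFactors = FALSE)
  cell <- function(da, db) cells[cells$a == da & cells$b == db, , drop = FALSE]
  corner <- list(cell(2, 2), cell(2, 0), cell(0, 2), cell(0, 0))
  defined <- all(vapply(corner, nrow, integer(1)) == 1L) &&
    all(vapply(corner, function(cc) cc$n, numeric(1)) >= 2)
  if (defined) {
    signs <- c(1, -1, -1, 1)
    contrast <- sum(vapply(seq_along(corner),
                           function(k) signs[k] * corner[[k]]$mean, numeric(1)))
    se <- sqrt(sum(vapply(corner, function(cc) {
      s <- cc$sd; if (is.na(s)) 0 else s^2 / cc$n
    }, numeric(1))))
  } else {
    warning("empty or singleton homozygous corner cell: contrast undefined")
    contrast <- NA_real_; se <- NA_real_
  }
  structure(list(cells = cells, contrast = contrast, contrast_se = se,
                 defined = defined, loci = c(locus_a, locus_b)),
            class = "epistasis_table")
}

#' @export
print.epistasis_table <- function(x, ...) {
  cat("two-locus epistasis table:", paste(x$loci, collapse = " x "), "\n")
  print(x$cells)
  cat(sprintf("interaction contrast %.4g (se %.4g)\n",
              x$contrast, x$contrast_se))
  invisible(x)
}

#' Select optimal haplotype combinations under multi-trait criteria
#'
#' Filters out groups that significantly reduce any `protect` trait relative
#' to the reference (mean below the reference and Welch p below
#' `protect_p`), drops groups under `min_size`, then ranks the survivors by
#' the `minimize` trait means in order (lexicographic), ties broken by group
#' label. The result is a permutation of the surviving groups and is stable
#' under input reordering.
#'
#' @param stats A [group_trait_stats()] table.
#' @param minimize Character vector of traits to minimise, in priority order.
#' @param protect Traits that must not be significantly reduced vs the
#'   reference.
#' @param protect_p Significance level of the protection constraint.
#' @param min_size Minimum group size.
#' @return The surviving rows of the per-group trait-mean table, ranked; an
#'   empty data frame (with attribute `reason`) when no group passes.
#' @export
select_optimal <- function(stats, minimize, protect = character(),
                           protect_p = 0.05, min_size = 2L) {
  labs <- unique(stats$label)
  wide <- data.frame(label = labs, stringsAsFactors = FALSE)
  for (tr in unique(stats$trait)) {
    sel <- stats$trait == tr
    wide[[paste0("mean_", tr)]] <- stats$mean[sel][match(labs, stats$label[sel])]
    wide[[paste0("p_", tr)]] <- stats$p_vs_ref[sel][match(labs, stats$label[sel])]
    wide[[paste0("n_", tr)]] <- stats$n[sel][match(labs, stats$label[sel])]
  }
  ref <- attr(stats, "reference")
  ok <- rep(TRUE, nrow(wide))
  for (tr in protect) {
    ref_mean <- stats$mean[stats$label == ref & stats$trait == tr]
    m <- wide[[paste0("mean_", tr)]]
    p <- wide[[paste0("p_", tr)]]
    reduced <- !is.na(m) & m < ref_mean & !is.na(p) & p < protect_p
    ok <- ok & !reduced
  }
  nmin <- do.call(pmin, c(wide[paste0("n_", unique(stats$trait))],
                          na.rm = TRUE))
  ok <- ok & nmin >= min_size & !is.na(nmin)
  out <- wide[ok, , drop = FALSE]
  if (nrow(out) == 0L) {
    attr(out, "reason") <- "no group satisfies the constraints"
    return(out)
  }
  keys <- c(lapply(paste0("mean_", minimize), function(cn) out[[cn]]),
            list(out$label))
  out <- out[do.call(order, keys), , drop = FALSE]
  rownames(out) <- NULL
  out
}
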