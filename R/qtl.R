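#' Pairwise linkage disequilibrium (r-squared)
#'
#' Squared Pearson correlation of the two variants' dosage vectors; samples
#' missing either call are excluded pairwise. Monomorphic input is undefined
#' and treated as 0 (with attribute `undefined = TRUE`).
#'
#' @param gm A [geno_matrix()] (the LD reference panel).
#' @param variant_a,variant_b Variant IDs.
#' @return r-squared in \[0, 1\].
#' @export
pairwise_r2 <- function(gm, variant_a, variant_b) {
  ja <- match(variant_a, gm$variants$id)
  jb <- match(variant_b, gm$variants$id)
  if (is.na(ja) || is.na(jb)) hf_stop("variant not found in LD panel")
  a <- gm$dosages[, ja]; b <- gm$dosages[, jb]
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2L || stats::var(a) == 0 || stats::var(b) == 0) {
    return(structure(0, undefined = TRUE))
  }
  stats::cor(a, b)^2
}

# r2 of one variant column against a set of columns, mean-filled; returns 0
# for monomorphic columns.
r2_vector <- function(D, j, js) {
  a <- D[, j]
  B <- D[, js, drop = FALSE]
  r <- suppressWarnings(stats::cor(a, B, use = "pairwise.complete.obs"))
  r[is.na(r)] <- 0
  drop(r)^2
}

# any cross-locus SNP pair with r2 > thr?
loci_linked <- function(D, idx_a, idx_b, thr) {
  R <- suppressWarnings(stats::cor(D[, idx_a, drop = FALSE],
                                   D[, idx_b, drop = FALSE],
                                   use = "pairwise.complete.obs"))
  R[is.na(R)] <- 0
  any(R^2 > thr)
}

#' Call QTLs from a GWAS scan
#'
#' The three-stage summarisation algorithm:
#' \enumerate{
#'   \item \emph{Grouping}: significant SNPs (`p <= cfg$sig_p`) whose
#'     consecutive gaps are under `cfg$group_dist_bp` on the same chromosome
#'     form seed loci.
#'   \item \emph{LD merging}: two loci on one chromosome are merged when any
#'     cross-locus SNP pair has `r2 > cfg$ld_r2` and the two peak SNPs are
#'     closer than `cfg$merge_dist_bp`; merging repeats until no further pair
#'     qualifies. Because a merged locus re-derives its peak, the outcome can
#'     depend on merge order; the order is therefore fixed canonically: loci
#'     are kept sorted by (chromosome, start) and the first qualifying pair
#'     in that order is merged at each step.
#'   \item \emph{Support}: loci with at least `cfg$min_snps` significant SNPs
#'     are emitted as QTLs (`support = "significant"`). Smaller loci receive a
#'     single extension of `cfg$ext_bp` on both flanks collecting SNPs with
#'     `p <= cfg$suggestive_p`; if the total reaches `cfg$min_snps` they are
#'     emitted with `support = "suggestive"`, otherwise dropped.
#' }
#' The peak SNP is the minimum-p SNP of the locus, ties broken toward the
#' lower position. Variants absent from the LD panel contribute `r2 = 0` with
#' a warning. Emitted intervals are closed and pairwise non-mergeable.
#'
#' @param gwas A `gwas_result` (any data frame with `id`, `chrom`, `pos`,
#'   `p`, optionally `beta`).
#' @param ld_source [geno_matrix()] over the scanned variants, used for r2.
#' @param cfg An [hf_config()].
#' @return Data frame of class `qtl_table`: `chrom`, `start`, `end`,
#'   `peak_id`, `peak_pos`, `peak_p`, `peak_beta`, `n_sig_snps`, `n_snps`,
#'   `support`, `population`, `trait`.
#' @export
call_qtls <- function(gwas, ld_source, cfg = hf_config()) {
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      peak_id = character(), peak_pos = integer(),
                      peak_p = numeric(), peak_beta = numeric(),
                      n_sig_snps = integer(), n_snps = integer(),
                      support = character(), population = character(),
                      trait = character(), stringsAsFactors = FALSE)
  gw <- as.data.frame(gwas)
  gw <- gw[order(gw$chrom, gw$pos), , drop = FALSE]
  sig <- gw[gw$p <= cfg$sig_p, , drop = FALSE]
  if (nrow(sig) == 0L) {
    return(structure(empty, class = c("qtl_table", "data.frame")))
  }
  missing_ld <- setdiff(sig$id, ld_source$variants$id)
  if (length(missing_ld)) {
    warning(length(missing_ld),
            " significant SNP(s) absent from LD panel: r2 treated as 0")
  }
  D <- ld_source$dosages
  colnames(D) <- ld_source$variants$id

  # stage 1: maximal runs of significant SNPs with gaps < group_dist_bp
  loci <- list()
  for (ch in unique(sig$chrom)) {
    s <- sig[sig$chrom == ch, , drop = FALSE]
    gaps <- diff(s$pos)
    grp <- cumsum(c(1L, as.integer(gaps >= cfg$group_dist_bp)))
    for (g in unique(grp)) {
      loci[[length(loci) + 1L]] <- s[grp == g, , drop = FALSE]
    }
  }

  peak_of <- function(loc) {
    cand <- loc[loc$p == min(loc$p), , drop = FALSE]
    cand[which.min(cand$pos), , drop = FALSE]
  }
  ld_cols <- function(ids) intersect(ids, colnames(D))

  # stage 2: merge to fixed point
  repeat {
    merged <- FALSE
    if (length(loci) >= 2L) {
      ord <- order(vapply(loci, function(l) l$chrom[1], character(1)),
                   vapply(loci, function(l) min(l$pos), integer(1)))
      loci <- loci[ord]
      n_loci <- length(loci)
      for (i in seq_len(n_loci - 1L)) {
        for (j in (i + 1L):n_loci) {
          a <- loci[[i]]; b <- loci[[j]]
          if (a$chrom[1] != b$chrom[1]) next
          pa <- peak_of(a)$pos; pb <- peak_of(b)$pos
          if (abs(pa - pb) >= cfg$merge_dist_bp) next
          ca <- ld_cols(a$id); cb <- ld_cols(b$id)
          if (!length(ca) || !length(cb)) next
          if (loci_linked(D, ca, cb, cfg$ld_r2)) {
            loci[[i]] <- rbind(a, b)
            loci[[j]] <- NULL
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
    }
    if (!merged) break
  }

  # stage 3: support rule and emission
  sug <- gw[gw$p <= cfg$suggestive_p, , drop = FALSE]
  rows <- list()
  for (loc in loci) {
    n_sig <- nrow(loc)
    members <- loc
    support <- "significant"
    if (n_sig < cfg$min_snps) {
      support <- "suggestive"
      ok <- FALSE
      lo <- min(loc$pos); hi <- max(loc$pos)
      for (e in seq_len(cfg$max_extensions)) {
        lo <- lo - cfg$ext_bp; hi <- hi + cfg$ext_bp
        members <- sug[sug$chrom == loc$chrom[1] & sug$pos >= lo &
                         sug$pos <= hi, , drop = FALSE]
        if (nrow(members) >= cfg$min_snps) { ok <- TRUE; break }
      }
      if (!ok) next
    }
    pk <- peak_of(members)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = loc$chrom[1], start = min(members$pos), end = max(members$pos),
      peak_id = pk$id, peak_pos = pk$pos, peak_p = pk$p,
      peak_beta = if ("beta" %in% names(pk)) pk$beta else NA_real_,
      n_sig_snps = n_sig, n_snps = nrow(members), support = support,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(structure(empty, class = c("qtl_table", "data.frame")))
  }
  out <- do.call(rbind, rows)
  out$population <- attr(gwas, "population") %||% NA_character_
  out$trait <- attr(gwas, "trait") %||% NA_character_
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("qtl_table", "data.frame"))
}

#' Merge QTL maps across populations
#'
#' Takes per-population QTL tables and merges QTLs whose closed intervals
#' overlap (transitive closure, union-find): the merged interval is the union
#' span, and each merged QTL records its contributing populations, traits,
#' per-population peaks, and a detection count.
#'
#' @param qtl_lists List of `qtl_table`s (all on one coordinate system).
#' @return Data frame of class `merged_qtl_map`: `qtl_id`, `chrom`, `start`,
#'   `end`, `n_detections`, `populations`, `traits`, `peak_ids`, `peak_betas`
#'   (the latter four are comma-separated in print but list columns here).
#' @export
merge_across_populations <- function(qtl_lists) {
  all_q <- do.call(rbind, lapply(qtl_lists, as.data.frame))
  if (is.null(all_q) || nrow(all_q) == 0L) {
    return(structure(data.frame(qtl_id = character(), chrom = character(),
                                start = integer(), end = integer(),
                                n_detections = integer()),
                     class = c("merged_qtl_map", "data.frame")))
  }
  rownames(all_q) <- NULL
  # union-find over interval overlap, per chromosome
  parent <- seq_len(nrow(all_q))
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  for (ch in unique(all_q$chrom)) {
    idx <- which(all_q$chrom == ch)
    idx <- idx[order(all_q$start[idx])]
    if (length(idx) < 2L) next
    # sweep: overlap with running max end implies union (closed intervals)
    cur <- idx[1]; cur_end <- all_q$end[cur]
    for (k in idx[-1]) {
      if (all_q$start[k] <= cur_end) {
        union_(cur, k)
        cur_end <- max(cur_end, all_q$end[k])
      } else {
        cur <- k; cur_end <- all_q$end[k]
      }
    }
  }
  roots <- vapply(seq_len(nrow(all_q)), find, integer(1))
  rows <- lapply(unique(roots), function(r) {
    m <- all_q[roots == r, , drop = FALSE]
    data.frame(chrom = m$chrom[1], start = min(m$start), end = max(m$end),
               n_detections = nrow(m),
               populations = I(list(m$population)),
               traits = I(list(m$trait)),
               peak_ids = I(list(m$peak_id)),
               peak_betas = I(list(m$peak_beta)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out <- cbind(qtl_id = sprintf("mQTL_%s_%d", out$chrom, out$start), out)
  rownames(out) <- NULL
  structure(out, class = c("merged_qtl_map", "data.frame"))
}

#' Classify a QTL's heterotic mode from its detection pattern
#'
#' Pure truth-table function of three booleans: whether the locus was detected
#' in the maternal population, in the F1 populations, and in the derived MPH
#' scans.
#' \itemize{
#'   \item (M, F1, MPH) = (1, 1, 0): additive - both parental alleles
#'     contribute equally, MPH carries no signal.
#'   \item (1, 0, 1): dominant - the paternal allele complements the recessive
#'     maternal allele in hybrids, so the locus vanishes from F1 scans but
#'     surfaces in MPH.
#'   \item (0, 1, 0): epistatic D x A - an additive locus unmasked in hybrids
#'     by dominance complementation of a repressor.
#'   \item (0, 0, 1): epistatic D x D - a dominant locus unmasked in hybrids,
#'     visible only through MPH.
#'   \item (0, 1, 1): epistatic with ambiguous subtype, reported as
#'     `epistatic_DxA` with `ambiguous = TRUE`.
#'   \item (1, 1, 1): `additive` with `ambiguous = TRUE` (additive with a
#'     dominance component).
#'   \item (1, 0, 0): `dominant` with `ambiguous = TRUE` (maternal-only
#'     detection lacks the MPH confirmation).
#'   \item (0, 0, 0): `unclassified`.
#' }
#'
#' @param detected_maternal,detected_f1,detected_mph Logical vectors.
#' @return Data frame with columns `class` (one of `additive`, `dominant`,
#'   `epistatic_DxA`, `epistatic_DxD`, `unclassified`) and `ambiguous`.
#' @export
classify_heterotic_qtl <- function(detected_maternal, detected_f1,
                                   detected_mph) {
  m <- as.logical(detected_maternal)
  f <- as.logical(detected_f1)
  h <- as.logical(detected_mph)
  n <- max(length(m), length(f), length(h))
  m <- rep_len(m, n); f <- rep_len(f, n); h <- rep_len(h, n)
  cls <- character(n); amb <- logical(n)
  for (i in seq_len(n)) {
    key <- paste0(as.integer(m[i]), as.integer(f[i]), as.integer(h[i]))
    res <- switch(key,
      "110" = c("additive", FALSE),
      "111" = c("additive", TRUE),
      "101" = c("dominant", FALSE),
      "100" = c("dominant", TRUE),
      "010" = c("epistatic_DxA", FALSE),
      "011" = c("epistatic_DxA", TRUE),
      "001" = c("epistatic_DxD", FALSE),
      "000" = c("unclassified", FALSE))
    cls[i] <- res[1]; amb[i] <- as.logical(res[2])
  }
  data.frame(class = cls, ambiguous = amb, stringsAsFactors = FALSE)
}

#' Classify a merged QTL map from three detection maps
#'
#' Convenience wrapper: given QTL tables from the maternal scans, the F1
#' scans and the MPH scans of one trait, merges everything into one map and
#' attaches the heterotic class of each merged QTL from its detection pattern.
#'
#' @param maternal_qtls,f1_qtls,mph_qtls `qtl_table`s (or lists of them).
#' @return A `merged_qtl_map` with `detected_maternal`, `detected_f1`,
#'   `detected_mph`, `class` and `ambiguous` columns.
#' @export
classify_merged_map <- function(maternal_qtls, f1_qtls, mph_qtls) {
  as_list <- function(x) if (inherits(x, "qtl_table")) list(x) else x
  tag <- function(lst, src) lapply(as_list(lst), function(q) {
    q <- as.data.frame(q); if (nrow(q)) q$source <- src else q$source <- character(0); q
  })
  all_lists <- c(tag(maternal_qtls, "maternal"), tag(f1_qtls, "f1"),
                 tag(mph_qtls, "mph"))
  keep <- vapply(all_lists, nrow, integer(1)) > 0L
  map <- merge_across_populations(all_lists)
  if (nrow(map) == 0L) return(map)
  all_q <- do.call(rbind, all_lists[keep])
  det <- function(map_row, src) {
    any(all_q$source == src & all_q$chrom == map_row$chrom &
          all_q$start <= map_row$end & all_q$end >= map_row$start)
  }
  dm <- df <- dh <- logical(nrow(map))
  for (i in seq_len(nrow(map))) {
    dm[i] <- det(map[i, ], "maternal")
    df[i] <- det(map[i, ], "f1")
    dh[i] <- det(map[i, ], "mph")
  }
  cl <- classify_heterotic_qtl(dm, df, dh)
  map$detected_maternal <- dm
  map$detected_f1 <- df
  map$detected_mph <- dh
  map$class <- cl$class
  map$ambiguous <- cl$ambiguous
  map
}

#' Cumulative per-class QTL effects
#'
#' For each trait and heterotic class, sums the absolute peak-SNP effects of
#' member QTLs; each merged QTL contributes the mean `|beta|` over the
#' populations in which it was detected. QTLs whose peak effect is missing
#' are skipped with a log note.
#'
#' @param map A classified `merged_qtl_map` (with `class` and `peak_betas`).
#' @param trait Optional trait label filter applied to the map's `traits`.
#' @return Data frame `class`, `cumulative_effect`.
#' @export
cumulative_class_effects <- function(map, trait = NULL) {
  classes <- c("additive", "dominant", "epistatic_DxA", "epistatic_DxD")
  tot <- stats::setNames(numeric(length(classes)), classes)
  for (i in seq_len(nrow(map))) {
    cl <- map$class[i]
    if (!cl %in% classes) next
    betas <- unlist(map$peak_betas[i])
    trs <- unlist(map$traits[i])
    if (!is.null(trait)) betas <- betas[trs == trait | grepl(trait, trs)]
    betas <- betas[!is.na(betas)]
    if (!length(betas)) { hf_log("QTL ", map$qtl_id[i], " skipped: no effect"); next }
    tot[cl] <- tot[cl] + mean(abs(betas))
  }
  data.frame(class = classes, cumulative_effect = unname(tot),
             stringsAsFactors = FALSE)
}

#' Write a QTL table TSV
#'
#' Columns `chrom`, `start`, `end`, `peak_id`, `peak_p`, `n_snps`, `support`.
#'
#' @param qtls A `qtl_table`.
#' @param path File path.
#' @export
write_qtls <- function(qtls, path) {
  utils::write.table(as.data.frame(qtls), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
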