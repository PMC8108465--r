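options(hybridforge.verbose = FALSE)

# quick geno_matrix: dosage matrix plus evenly spaced positions
make_gm <- function(dosages, chrom = "chr1", pos = NULL, ids = NULL) {
  dosages <- as.matrix(dosages)
  m <- ncol(dosages)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  if (is.null(ids)) ids <- sprintf("%s.s_%d", rep_len(chrom, m), pos)
  if (is.null(rownames(dosages))) {
    rownames(dosages) <- sprintf("s%03d", seq_len(nrow(dosages)))
  }
  geno_matrix(dosages,
              data.frame(id = ids, chrom = rep_len(chrom, m), pos = pos,
                         ref = "A", alt = "T", stringsAsFactors = FALSE))
}

# random GWAS fixture for the QTL-caller oracle: positions, p-values and an
# LD panel with blocky correlation
random_qtl_fixture <- function(seed, n_snps = NULL) {
  set.seed(seed)
  n <- if (is.null(n_snps)) sample(20:100, 1) else n_snps
  chrom <- sort(sample(paste0("chr", 1:2), n, replace = TRUE))
  pos <- unlist(lapply(split(seq_len(n), chrom), function(i) {
    sort(sample.int(2e7, length(i)))
  }))
  ns <- 80
  blocks <- cumsum(c(TRUE, runif(n - 1) < 0.25))
  d <- matrix(0, ns, n)
  for (b in unique(blocks)) {
    cols <- which(blocks == b)
    base <- rbinom(ns, 1, runif(1, 0.2, 0.8))
    for (j in cols) {
      flip <- runif(ns) < 0.15
      d[, j] <- 2 * ifelse(flip, 1 - base, base)
    }
  }
  gm <- make_gm(d, chrom = chrom, pos = pos)
  p <- 10^-runif(n, 0, 12)   # plenty of significant SNPs
  gwas <- data.frame(id = gm$variants$id, chrom = gm$variants$chrom,
                     pos = gm$variants$pos, beta = rnorm(n), se = 1, p = p,
                     stringsAsFactors = FALSE)
  list(gwas = gwas, gm = gm)
}

# Independent brute-force QTL caller used as the oracle: single-linkage
# grouping on inter-SNP distance, then exhaustive any-pair merging (scanning
# pairs in reverse order) to closure, then the support rule.
brute_qtls <- function(gwas, gm, cfg) {
  gw <- gwas[order(gwas$chrom, gwas$pos), , drop = FALSE]
  sig <- gw[gw$p <= cfg$sig_p, , drop = FALSE]
  if (nrow(sig) == 0L) return(NULL)
  D <- gm$dosages; colnames(D) <- gm$variants$id
  loci <- lapply(seq_len(nrow(sig)), function(i) sig[i, , drop = FALSE])
  # single-linkage distance grouping to closure
  repeat {
    done <- TRUE
    for (i in rev(seq_along(loci))) {
      for (j in rev(seq_along(loci))) {
        if (j >= i) next
        a <- loci[[i]]; b <- loci[[j]]
        if (a$chrom[1] != b$chrom[1]) next
        mind <- min(abs(outer(a$pos, b$pos, "-")))
        if (mind < cfg$group_dist_bp) {
          loci[[j]] <- rbind(b, a); loci[[i]] <- NULL; done <- FALSE; break
        }
      }
      if (!done) break
    }
    if (done) break
  }
  peak <- function(l) {
    cand <- l[l$p == min(l$p), , drop = FALSE]
    cand[which.min(cand$pos), ]
  }
  # exhaustive LD merging to closure under the canonical order: loci sorted
  # by (chrom, start), first qualifying (i, j) pair merged, then restart
  repeat {
    ord <- order(vapply(loci, function(l) l$chrom[1], character(1)),
                 vapply(loci, function(l) min(l$pos), numeric(1)))
    loci <- loci[ord]
    done <- TRUE
    nl <- length(loci)
    if (nl >= 2L) {
      for (i in seq_len(nl - 1L)) {
        for (j in (i + 1L):nl) {
          a <- loci[[i]]; b <- loci[[j]]
          if (a$chrom[1] != b$chrom[1]) next
          if (abs(peak(a)$pos - peak(b)$pos) >= cfg$merge_dist_bp) next
          R <- suppressWarnings(cor(D[, a$id, drop = FALSE],
                                    D[, b$id, drop = FALSE]))
          R[is.na(R)] <- 0
          if (any(R^2 > cfg$ld_r2)) {
            loci[[i]] <- rbind(a, b); loci[[j]] <- NULL; done <- FALSE; break
          }
        }
        if (!done) break
      }
    }
    if (done) break
  }
  sug <- gw[gw$p <= cfg$suggestive_p, , drop = FALSE]
  rows <- list()
  for (l in loci) {
    members <- l
    support <- "significant"
    if (nrow(l) < cfg$min_snps) {
      support <- "suggestive"
      lo <- min(l$pos) - cfg$ext_bp; hi <- max(l$pos) + cfg$ext_bp
      members <- sug[sug$chrom == l$chrom[1] & sug$pos >= lo & sug$pos <= hi, ]
      if (nrow(members) < cfg$min_snps) next
    }
    pk <- peak(members)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = l$chrom[1], start = min(members$pos), end = max(members$pos),
      peak_id = pk$id, peak_p = pk$p, n_sig_snps = nrow(l),
      n_snps = nrow(members), support = support, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# GRM-correlated trait simulator used across gBLUP tests
sim_gblup_trait <- function(K, h2, n = nrow(K)) {
  eig <- eigen(K, symmetric = TRUE)
  L <- eig$vectors %*% diag(sqrt(pmax(eig$values, 0)), n)
  md <- mean(diag(K))
  su <- if (h2 > 0) h2 / md else 0
  se <- 1 - h2
  y <- sqrt(su) * drop(L %*% rnorm(n)) + rnorm(n, sd = sqrt(se))
  names(y) <- rownames(K)
  y
}
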