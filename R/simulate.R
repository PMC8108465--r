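#' Generate synthetic inbred genotypes with block LD
#'
#' Emulates a resequenced inbred panel: mostly homozygous dosages (0/2 with a
#' small residual heterozygote rate), biallelic SNPs laid out on `n_chrom`
#' chromosomes at fixed spacing, and block-structured linkage disequilibrium.
#' Within a block of `block_len` consecutive variants, alleles are drawn from
#' a Gaussian copula whose latent process is AR(1) with coefficient `rho`, so
#' each variant keeps its own allele frequency exactly while r-squared decays
#' with marker distance; blocks are independent. Allele frequencies are drawn
#' from `maf_spectrum` (uniform bounds on the minor allele frequency, with
#' the minor allele assigned to ref or alt at random). Reproducible by seed.
#'
#' @param n_samples,n_variants Panel dimensions.
#' @param maf_spectrum Length-2 numeric: uniform bounds of the MAF spectrum.
#'   Frequencies are drawn per LD block (with per-variant jitter
#'   `maf_jitter`) because markers on a shared haplotype block carry similar
#'   allele frequencies; the minor-allele orientation is likewise coherent
#'   within a block.
#' @param block_len Variants per LD block.
#' @param rho Latent AR(1) coefficient controlling within-block LD.
#' @param maf_jitter Standard deviation of the per-variant frequency jitter
#'   around the block frequency.
#' @param het_rate Residual heterozygote rate (fraction of calls set to 1).
#' @param n_chrom Number of chromosomes.
#' @param spacing_bp Distance between adjacent variants.
#' @param seed Optional integer seed (set for reproducibility).
#' @return A [geno_matrix()].
#' @export
gen_inbred_genotypes <- function(n_samples, n_variants,
                                 maf_spectrum = c(0.1, 0.4),
                                 block_len = 20L, rho = 0.95,
                                 het_rate = 0.005, n_chrom = 10L,
                                 spacing_bp = 100000L, maf_jitter = 0.01,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_samples > 0, n_variants > 0, block_len > 0)
  block <- (seq_len(n_variants) - 1L) %/% block_len
  n_blocks <- max(block) + 1L
  base <- stats::runif(n_blocks, maf_spectrum[1], maf_spectrum[2])
  maf <- pmin(pmax(base[block + 1L] +
                     stats::rnorm(n_variants, sd = maf_jitter), 0.02), 0.5)
  flip <- (stats::runif(n_blocks) < 0.5)[block + 1L]
  p_alt <- ifelse(flip, 1 - maf, maf)  # alt-allele frequency
  thr <- stats::qnorm(p_alt)

  alle <- matrix(0L, n_samples, n_variants)
  z <- stats::rnorm(n_samples)
  for (j in seq_len(n_variants)) {
    if (j > 1L && block[j] == block[j - 1L]) {
      z <- rho * z + sqrt(1 - rho^2) * stats::rnorm(n_samples)
    } else if (j > 1L) {
      z <- stats::rnorm(n_samples)
    }
    alle[, j] <- as.integer(z < thr[j])
  }
  d <- 2 * alle
  if (het_rate > 0) {
    het <- stats::runif(length(d)) < het_rate
    d[het] <- 1
  }
  per_chrom <- ceiling(n_variants / n_chrom)
  chrom_idx <- rep(seq_len(n_chrom), each = per_chrom)[seq_len(n_variants)]
  within <- stats::ave(seq_len(n_variants), chrom_idx, FUN = seq_along)
  pos <- as.integer(within) * as.integer(spacing_bp)
  chrom <- sprintf("chr%02d", chrom_idx)  # zero-padded: lexicographic = numeric order
  variants <- data.frame(
    id = sprintf("%s.s_%d", chrom, pos), chrom = chrom, pos = pos,
    ref = "A", alt = "T", stringsAsFactors = FALSE)
  rownames(d) <- sprintf("S%04d", seq_len(n_samples))
  geno_matrix(d, variants)
}

#' Spike QTNs into a genotype panel
#'
#' Selects `n` distinct variants uniformly from the mid-frequency stratum
#' (`maf_window`) and assigns exponentially decaying effects by rank:
#' `beta_i = effect_base ^ i` for `i = 1..n`.
#'
#' @param gm A [geno_matrix()].
#' @param n Number of QTNs.
#' @param maf_window MAF interval from which QTNs are drawn.
#' @param effect_base Base of the exponential effect series.
#' @return Data frame of class `qtn_set`: `index`, `id`, `beta`, `freq`
#'   (alt-allele frequency in the panel).
#' @export
spike_in_qtns <- function(gm, n = 20L, maf_window = c(0.25, 0.35),
                          effect_base = 0.96) {
  maf <- compute_maf(gm)
  elig <- which(!is.na(maf) & maf >= maf_window[1] & maf <= maf_window[2])
  if (length(elig) < n) {
    hf_stop("only ", length(elig), " variants in the MAF window, need ", n)
  }
  idx <- sample(elig, n)
  p_alt <- colMeans(gm$dosages[, idx, drop = FALSE], na.rm = TRUE) / 2
  structure(data.frame(index = idx, id = gm$variants$id[idx],
                       beta = effect_base^seq_len(n), freq = unname(p_alt),
                       stringsAsFactors = FALSE),
            class = c("qtn_set", "data.frame"))
}

#' Genetic value of each sample under a QTN set
#'
#' `y = sum_i x_i beta_i` over the spiked QTNs, with no residual noise (the
#' simulated "observed" phenotype is purely genetic). Samples missing a QTN
#' dosage get `NA`.
#'
#' @param gm A [geno_matrix()].
#' @param qtns A [spike_in_qtns()] set.
#' @return Named numeric vector of genetic values.
#' @export
genetic_value <- function(gm, qtns) {
  X <- gm$dosages[, qtns$index, drop = FALSE]
  y <- drop(X %*% qtns$beta)
  y[rowSums(is.na(X)) > 0L] <- NA_real_
  stats::setNames(y, rownames(gm$dosages))
}

#' Classify QTNs by phenotypic variance explained
#'
#' Per-QTN contribution `pve_i = beta_i * f_i * (1 - f_i)` with `f` the
#' allele frequency in the analysed samples. In `"normalized"` mode (default)
#' the raw contributions are divided by their sum so the class thresholds
#' operate on fractions: major `pve >= 0.07`, moderate `0.045 <= pve < 0.07`,
#' minor `pve < 0.045`. `"raw"` thresholds the unnormalised value and
#' `"variance"` uses `beta^2 * 2 f (1 - f)` (the variance contributed by a
#' biallelic additive locus under Hardy-Weinberg), normalised.
#'
#' @param qtns A [spike_in_qtns()] set.
#' @param gm The [geno_matrix()] defining allele frequencies.
#' @param mode One of `"normalized"`, `"raw"`, `"variance"`.
#' @param major_min,moderate_min Class thresholds.
#' @return The `qtn_set` with `pve` and `class` columns added.
#' @export
classify_pve <- function(qtns, gm, mode = c("normalized", "raw", "variance"),
                         major_min = 0.07, moderate_min = 0.045) {
  mode <- match.arg(mode)
  f <- colMeans(gm$dosages[, qtns$index, drop = FALSE], na.rm = TRUE) / 2
  raw <- switch(mode,
                normalized = ,
                raw = qtns$beta * f * (1 - f),
                variance = qtns$beta^2 * 2 * f * (1 - f))
  pve <- if (mode == "raw") raw else raw / sum(raw)
  qtns$pve <- unname(pve)
  qtns$class <- ifelse(pve >= major_min, "major",
                       ifelse(pve >= moderate_min, "moderate", "minor"))
  qtns
}

#' Corrupt a phenotype to a target prediction accuracy
#'
#' Emulates a genomically predicted phenotype: `y' = y + e` with
#' `e ~ N(0, var(y) (1 - r2) / r2)` i.i.d., so the expected squared
#' correlation between `y` and `y'` is `r2`. `r2 = 1` returns `y` exactly.
#'
#' @param y Numeric phenotype vector.
#' @param r2 Target squared correlation in (0, 1\].
#' @return The corrupted phenotype.
#' @export
add_prediction_noise <- function(y, r2) {
  if (!is.numeric(r2) || r2 <= 0 || r2 > 1) hf_stop("r2 must be in (0, 1]")
  if (r2 == 1) return(y)
  y + stats::rnorm(length(y), sd = sqrt(stats::var(y) * (1 - r2) / r2))
}

# Fast no-kinship scan used by the simulation studies: correlation-based
# simple regression of every variant on y. Returns p-values. G must be the
# dosage matrix (no missing values).
fast_scan_p <- function(G, y, center = NULL) {
  n <- length(y)
  Gc <- if (is.null(center)) sweep(G, 2, colMeans(G)) else center
  yc <- y - mean(y)
  sy <- sqrt(sum(yc^2))
  sg <- sqrt(colSums(Gc^2))
  r <- drop(crossprod(Gc, yc)) / (sg * sy)
  r[!is.finite(r)] <- 0
  r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tstat), n - 2)
}

#' Permutation-based significance threshold
#'
#' Shuffles the phenotype `n_perm` times, records the minimum scan p-value of
#' each permutation, and returns the `alpha` quantile of those minima as the
#' genome-wide threshold. Monotone: a stricter `alpha` gives a smaller
#' threshold; `alpha = 1` returns the largest minimum. Deterministic under a
#' fixed seed. Supply a vector `alpha` to get the whole threshold grid from
#' one set of permutations.
#'
#' @param gm A [geno_matrix()] (or plain dosage matrix).
#' @param y Phenotype vector.
#' @param n_perm Number of permutations (>= 100).
#' @param alpha Genome-wide type-I error level(s).
#' @return Named numeric vector of thresholds (one per `alpha`).
#' @export
permutation_threshold <- function(gm, y, n_perm = 1000L, alpha = 0.05) {
  if (n_perm < 100L) hf_stop("n_perm must be >= 100")
  G <- if (inherits(gm, "geno_matrix")) gm$dosages else as.matrix(gm)
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mu[idx[, 2]]
  }
  n <- length(y)
  Gc <- sweep(G, 2, colMeans(G))
  sg <- sqrt(colSums(Gc^2))
  ok <- sg > 0
  # all permutations at once: min p over variants = p of max |cor|
  P <- matrix(y[vapply(seq_len(n_perm), function(i) sample.int(n),
                       integer(n))], n, n_perm)
  Pc <- sweep(P, 2, colMeans(P))
  sp <- sqrt(colSums(Pc^2))
  R <- crossprod(Gc[, ok, drop = FALSE], Pc) / outer(sg[ok], sp)
  rmax <- apply(abs(R), 2, max)
  rmax <- pmin(rmax, 1 - 1e-15)
  tmax <- rmax * sqrt((n - 2) / (1 - rmax^2))
  minp <- sort(2 * stats::pt(-abs(tmax), n - 2))
  thr <- minp[pmax(1L, ceiling(alpha * n_perm))]
  stats::setNames(thr, paste0("alpha", alpha))
}

#' Match significant SNPs to spiked QTNs
#'
#' Clusters the significant variants into loci with the QTL grouping rule
#' (consecutive gaps under `cfg$group_dist_bp` on one chromosome); a locus is
#' a true detection when it contains a QTN or any member SNP with
#' `r2 > cfg$ld_r2` to a QTN. `N0` counts distinct detected QTNs, `N1` false
#' loci, and `FDR = N1 / (N1 + N0)` (0 with `undefined = TRUE` when nothing
#' is significant).
#'
#' @param sig_idx Indices (into `gm`'s variants) of significant SNPs.
#' @param qtns The [spike_in_qtns()] set.
#' @param gm The scanned [geno_matrix()].
#' @param cfg An [hf_config()].
#' @return List: `N0`, `N1`, `fdr`, `detected` (logical per QTN).
#' @export
match_hits_to_qtns <- function(sig_idx, qtns, gm, cfg = hf_config()) {
  detected <- rep(FALSE, nrow(qtns))
  if (length(sig_idx) == 0L) {
    return(list(N0 = 0L, N1 = 0L,
                fdr = structure(0, undefined = TRUE), detected = detected))
  }
  v <- gm$variants[sig_idx, , drop = FALSE]
  ord <- order(v$chrom, v$pos)
  v <- v[ord, , drop = FALSE]
  sidx <- sig_idx[ord]
  newgrp <- c(TRUE, v$chrom[-1] != v$chrom[-nrow(v)] |
                diff(v$pos) >= cfg$group_dist_bp)
  grp <- cumsum(newgrp)
  D <- gm$dosages
  Q <- D[, qtns$index, drop = FALSE]
  N1 <- 0L
  for (g in unique(grp)) {
    members <- sidx[grp == g]
    hit_direct <- qtns$index %in% members
    if (any(hit_direct)) {
      detected <- detected | hit_direct
      linked <- hit_direct
    } else {
      linked <- rep(FALSE, nrow(qtns))
    }
    if (!any(linked)) {
      R <- suppressWarnings(stats::cor(D[, members, drop = FALSE], Q,
                                       use = "pairwise.complete.obs"))
      R[is.na(R)] <- 0
      linked <- apply(R^2 > cfg$ld_r2, 2, any)
    }
    if (any(linked)) detected <- detected | linked else N1 <- N1 + 1L
  }
  N0 <- sum(detected)
  fdr <- if (N0 + N1 == 0L) structure(0, undefined = TRUE) else N1 / (N0 + N1)
  list(N0 = as.integer(N0), N1 = N1, fdr = fdr, detected = detected)
}

#' Configuration of the FDR/power simulation study
#'
#' Defaults are the full study conditions: 20 QTNs with effects `0.96^i`
#' spiked into a 100,000-variant panel, population sizes 207 to the full
#' 1428, six prediction-accuracy levels, 500 repetitions, FDR scored at
#' `p <= 1e-5` and detection power at permutation thresholds. The
#' `reduced = TRUE` preset (2,000 variants, sizes 207/600, r2 1.0/0.6/0.2,
#' 50 reps, 100 permutations) is the desk-scale operating point used by the
#' package's own checks.
#'
#' @param reduced Use the desk-scale preset.
#' @param ... Overrides of individual fields.
#' @return List of class `sim_one_config`.
#' @export
sim_one_config <- function(reduced = FALSE, ...) {
  cfg <- list(
    n_qtns = 20L,
    sizes = c(207L, 400L, 600L, 800L, 1000L, 1428L),
    r2_levels = c(1.0, 0.8, 0.6, 0.4, 0.2, 0.1),
    reps = 500L,
    n_variants = 100000L,
    n_samples = 1428L,
    fdr_p = 1e-5,
    alpha = 0.05,
    n_perm = 1000L,
    maf_window = c(0.25, 0.35),
    effect_base = 0.96,
    seed = 1L
  )
  if (reduced) {
    cfg$sizes <- c(207L, 600L)
    cfg$r2_levels <- c(1.0, 0.6, 0.2)
    cfg$reps <- 50L
    cfg$n_variants <- 2000L
    cfg$n_samples <- 700L
    cfg$n_perm <- 100L
  }
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "sim_one_config")
}

#' Run the spike-in QTN FDR/power simulation
#'
#' For every (population size, prediction accuracy r2) cell: subsample the
#' panel, spike a fresh QTN set, build the purely genetic phenotype, corrupt
#' it to the target accuracy, scan all variants, then score (a) FDR at the
#' fixed `fdr_p` threshold via [match_hits_to_qtns()] and (b) detection power
#' per QTN class at the permutation threshold(s). Cell values are means over
#' `cfg$reps` repetitions; a new QTN set is drawn each repetition.
#'
#' @param cfg A [sim_one_config()].
#' @param gm Optional pre-generated panel (defaults to
#'   [gen_inbred_genotypes()] at the configured size).
#' @return List of class `sim_grid`: `fdr` (data frame size, r2, fdr) and
#'   `power` (data frame size, r2, alpha, class, power), plus the config.
#' @export
run_sim_one <- function(cfg = sim_one_config(reduced = TRUE), gm = NULL) {
  set.seed(cfg$seed)
  if (is.null(gm)) {
    gm <- gen_inbred_genotypes(cfg$n_samples, cfg$n_variants)
  }
  if (max(cfg$sizes) > nrow(gm$dosages)) {
    hf_stop("largest population size exceeds the panel (",
            nrow(gm$dosages), " samples)")
  }
  qcfg <- hf_config(fdr_p = cfg$fdr_p)
  classes <- c("major", "moderate", "minor", "all")
  fdr_rows <- list(); pow_acc <- list()
  for (s in cfg$sizes) {
    for (rep_i in seq_len(cfg$reps)) {
      rows <- sample(nrow(gm$dosages), s)
      sub <- gm[rows, ]
      G <- sub$dosages
      if (anyNA(G)) {
        mu <- colMeans(G, na.rm = TRUE)
        idx <- which(is.na(G), arr.ind = TRUE)
        G[idx] <- mu[idx[, 2]]
      }
      Gc <- sweep(G, 2, colMeans(G))
      qtns <- spike_in_qtns(sub, n = cfg$n_qtns, maf_window = cfg$maf_window,
                            effect_base = cfg$effect_base)
      qtns <- classify_pve(qtns, sub)
      y <- genetic_value(sub, qtns)
      for (r2 in cfg$r2_levels) {
        yp <- add_prediction_noise(y, r2)
        p <- fast_scan_p(G, yp, center = Gc)
        hits <- match_hits_to_qtns(which(p <= cfg$fdr_p), qtns, sub, qcfg)
        fdr_rows[[length(fdr_rows) + 1L]] <-
          data.frame(size = s, r2 = r2, fdr = as.numeric(hits$fdr))
        thr <- permutation_threshold(G, yp, n_perm = cfg$n_perm,
                                     alpha = cfg$alpha)
        for (k in seq_along(thr)) {
          det <- match_hits_to_qtns(which(p <= thr[k]), qtns, sub, qcfg)$detected
          for (cl in classes) {
            sel <- if (cl == "all") rep(TRUE, nrow(qtns)) else qtns$class == cl
            if (!any(sel)) next
            pow_acc[[length(pow_acc) + 1L]] <-
              data.frame(size = s, r2 = r2, alpha = cfg$alpha[k], class = cl,
                         power = mean(det[sel]))
          }
        }
      }
    }
  }
  fdr <- stats::aggregate(fdr ~ size + r2, do.call(rbind, fdr_rows), mean)
  power <- stats::aggregate(power ~ size + r2 + alpha + class,
                            do.call(rbind, pow_acc), mean)
  structure(list(fdr = fdr, power = power, config = cfg), class = "sim_grid")
}

#' @export
print.sim_grid <- function(x, ...) {
  cat("spike-in QTN simulation grid\n")
  cat(sprintf("  %d FDR cell(s), %d power cell(s)\n",
              nrow(x$fdr), nrow(x$power)))
  print(x$fdr)
  invisible(x)
}

#' Configuration of the effect-gradient power simulation
#'
#' Defaults follow the published procedure: 19 effect gradients from 0.1 to
#' 1.9 (in units of the base phenotype's standard deviation), 100 spiked SNPs
#' per gradient, significance at `p = 2.2e-7`, and a comparison across
#' population sizes. The reduced preset trims the gradient grid and SNP count.
#'
#' @param reduced Use the desk-scale preset.
#' @param ... Field overrides.
#' @return List of class `sim_two_config`.
#' @export
sim_two_config <- function(reduced = FALSE, ...) {
  cfg <- list(
    gradients = seq(0.1, 1.9, by = 0.1),
    snps_per_gradient = 100L,
    threshold = 2.2e-7,
    sizes = c(207L, 1428L),
    maf_window = c(0.25, 0.35),
    seed = 1L
  )
  if (reduced) {
    cfg$gradients <- seq(0.2, 1.8, by = 0.4)
    cfg$snps_per_gradient <- 40L
    cfg$sizes <- c(150L, 600L)
  }
  over <- list(...)
  cfg[names(over)] <- over
  if (!length(cfg$gradients)) hf_stop("gradient list must be non-empty")
  structure(cfg, class = "sim_two_config")
}

#' Run the effect-gradient power simulation
#'
#' For each population size and effect gradient: pick `snps_per_gradient`
#' random SNPs from the mid-frequency stratum; for each, shift the base
#' phenotype by `+effect * SD` for the samples carrying the high homozygous
#' genotype and `-effect * SD` for the low homozygous genotype (SD of the
#' base phenotype), test the spiked SNP, and report the fraction passing the
#' significance cutoff as the detection power.
#'
#' @param cfg A [sim_two_config()].
#' @param gm The genotype panel.
#' @param base_phenotype Named base phenotype over the panel's samples (a
#'   synthetic hybrid trait stands in here).
#' @return Data frame `size`, `gradient`, `power`.
#' @export
run_sim_two <- function(cfg = sim_two_config(reduced = TRUE), gm,
                        base_phenotype) {
  set.seed(cfg$seed)
  y_all <- base_phenotype[rownames(gm$dosages)]
  maf <- compute_maf(gm)
  elig <- which(!is.na(maf) & maf >= cfg$maf_window[1] &
                  maf <= cfg$maf_window[2])
  if (length(elig) < cfg$snps_per_gradient) {
    hf_stop("not enough variants in the MAF window")
  }
  out <- list()
  for (s in cfg$sizes) {
    rows <- sample(nrow(gm$dosages), s)
    y0 <- y_all[rows]
    sdev <- stats::sd(y0)
    G <- gm$dosages[rows, , drop = FALSE]
    for (e in cfg$gradients) {
      snps <- sample(elig, cfg$snps_per_gradient)
      hit <- logical(length(snps))
      for (k in seq_along(snps)) {
        g <- G[, snps[k]]
        y <- y0
        y[!is.na(g) & g == 2] <- y[!is.na(g) & g == 2] + e * sdev
        y[!is.na(g) & g == 0] <- y[!is.na(g) & g == 0] - e * sdev
        ok <- !is.na(g)
        p <- fast_scan_p(cbind(g[ok]), y[ok])
        hit[k] <- p <= cfg$threshold
      }
      out[[length(out) + 1L]] <- data.frame(size = s, gradient = e,
                                            power = mean(hit))
    }
  }
  do.call(rbind, out)
}
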