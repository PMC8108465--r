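test_that("pairwise_r2 matches the correlation formula", {
  gm <- make_gm(cbind(c(0, 0, 2, 2), c(0, 2, 0, 2), c(0, 0, 2, 2),
                      c(2, 2, 2, 2)))
  ids <- gm$variants$id
  expect_equal(pairwise_r2(gm, ids[1], ids[3]), 1.0)
  expect_equal(pairwise_r2(gm, ids[1], ids[2]), 0.0)
  r2m <- pairwise_r2(gm, ids[1], ids[4])
  expect_equal(as.numeric(r2m), 0)
  expect_true(attr(r2m, "undefined"))
  set.seed(51)
  d <- matrix(sample(0:2, 400, TRUE), 200, 2)
  rownames(d) <- sprintf("s%03d", 1:200)
  gm2 <- make_gm(d)
  expect_equal(as.numeric(pairwise_r2(gm2, gm2$variants$id[1],
                                      gm2$variants$id[2])),
               (cov(d[, 1], d[, 2]) / (sd(d[, 1]) * sd(d[, 2])))^2,
               tolerance = 1e-12)
})

test_that("call_qtls handles the canonical grouping fixtures", {
  cfg <- hf_config()
  # no SNP below the significance cutoff -> empty table
  fx <- random_qtl_fixture(1, 30)
  fx$gwas$p <- pmax(fx$gwas$p, 1e-5)
  expect_equal(nrow(call_qtls(fx$gwas, fx$gm, cfg)), 0L)

  # 12 significant SNPs in 100 kbp; the 13th is 10 Mbp away and unlinked
  set.seed(52)
  pos <- c(seq(1e6, 1.1e6, length.out = 12), 11.1e6)
  d <- cbind(matrix(rep(sample(c(0, 2), 60, TRUE), 12), 60, 12),
             sample(c(0, 2), 60, TRUE))
  rownames(d) <- sprintf("s%02d", 1:60)
  gm <- make_gm(d, pos = as.integer(pos))
  gwas <- data.frame(id = gm$variants$id, chrom = "chr1",
                     pos = gm$variants$pos, beta = 1, se = 1,
                     p = c(rep(1e-8, 12), 1e-9))
  q <- call_qtls(gwas, gm, cfg)
  expect_equal(nrow(q), 1L)           # lone far SNP lacks support, dropped
  expect_equal(q$n_sig_snps, 12L)
  expect_equal(q$support, "significant")
  expect_equal(q$peak_p, 1e-8)
  expect_equal(q$peak_pos, as.integer(pos[1]))  # tie broken to lowest pos

  # two 6-SNP loci 2 Mbp apart, one cross pair in strong LD -> merged QTL
  pos2 <- c(seq(1e6, 1.05e6, length.out = 6), seq(3e6, 3.05e6, length.out = 6))
  base <- sample(c(0, 2), 80, TRUE)
  d2 <- cbind(matrix(rep(base, 6), 80, 6),
              matrix(rep(base, 6), 80, 6))
  # decorrelate all but one cross pair
  for (j in 7:11) d2[, j] <- sample(c(0, 2), 80, TRUE)
  rownames(d2) <- sprintf("s%02d", 1:80)
  gm2 <- make_gm(d2, pos = as.integer(pos2))
  gwas2 <- data.frame(id = gm2$variants$id, chrom = "chr1",
                      pos = gm2$variants$pos, beta = 1, se = 1, p = 1e-8)
  q2 <- call_qtls(gwas2, gm2, cfg)
  expect_equal(nrow(q2), 1L)
  expect_equal(q2$n_sig_snps, 12L)
  expect_equal(q2$start, 1000000L)
  expect_equal(q2$end, 3050000L)
})

test_that("suggestive support rescues small loci through one extension", {
  cfg <- hf_config()
  set.seed(53)
  pos <- as.integer(c(seq(5e6, 5.02e6, length.out = 4),
                      seq(5.3e6, 5.39e6, length.out = 8)))
  d <- matrix(sample(c(0, 2), 50 * 12, TRUE), 50, 12)
  rownames(d) <- sprintf("s%02d", 1:50)
  gm <- make_gm(d, pos = pos)
  # 4 significant SNPs plus 8 suggestive ones within the 400-kbp extension
  gwas <- data.frame(id = gm$variants$id, chrom = "chr1", pos = pos,
                     beta = 1, se = 1,
                     p = c(rep(1e-8, 4), rep(5e-5, 8)))
  q <- call_qtls(gwas, gm, cfg)
  expect_equal(nrow(q), 1L)
  expect_equal(q$support, "suggestive")
  expect_equal(q$n_sig_snps, 4L)
  expect_equal(q$n_snps, 12L)
  # without the suggestive SNPs the locus is dropped
  gwas2 <- gwas; gwas2$p[5:12] <- 0.5
  expect_equal(nrow(call_qtls(gwas2, gm, cfg)), 0L)
})

test_that("call_qtls agrees with the exhaustive merge-to-closure oracle", {
  cfgs <- list(hf_config(min_snps = 3L, group_dist_bp = 500000L,
                         merge_dist_bp = 3000000L),
               hf_config(min_snps = 5L))
  for (seed in 1:40) {
    fx <- random_qtl_fixture(seed)
    cfg <- cfgs[[seed %% 2 + 1]]
    got <- call_qtls(fx$gwas, fx$gm, cfg)
    want <- brute_qtls(fx$gwas, fx$gm, cfg)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got$start, want$start, info = paste("seed", seed))
      expect_equal(got$end, want$end)
      expect_equal(got$peak_id, want$peak_id)
      expect_equal(got$n_sig_snps, want$n_sig_snps)
      expect_equal(got$support, want$support)
    }
    # invariants: peak inside interval, attaining the interval minimum p
    if (nrow(got)) {
      expect_true(all(got$peak_pos >= got$start & got$peak_pos <= got$end))
      for (k in seq_len(nrow(got))) {
        inside <- fx$gwas$chrom == got$chrom[k] &
          fx$gwas$pos >= got$start[k] & fx$gwas$pos <= got$end[k] &
          fx$gwas$p <= cfg$suggestive_p
        expect_equal(got$peak_p[k], min(fx$gwas$p[inside]))
      }
    }
  }
})

test_that("cross-population merging takes the transitive interval closure", {
  qa <- structure(data.frame(chrom = "chr1", start = 100L, end = 200L,
                             peak_id = "a", peak_pos = 150L, peak_p = 1e-8,
                             peak_beta = 0.3, n_sig_snps = 10L, n_snps = 10L,
                             support = "significant", population = "p1",
                             trait = "tr"),
                  class = c("qtl_table", "data.frame"))
  qb <- qa; qb$start <- 150L; qb$end <- 300L; qb$population <- "p2"
  m <- merge_across_populations(list(qa, qb))
  expect_equal(nrow(m), 1L)
  expect_equal(m$start, 100L)
  expect_equal(m$end, 300L)
  expect_equal(m$n_detections, 2L)

  qc <- qa; qc$start <- 1000L; qc$end <- 1100L
  m2 <- merge_across_populations(list(qa, qc))
  expect_equal(nrow(m2), 2L)

  # chain a-b, b-c with a, c disjoint still merges transitively
  q1 <- qa                              # [100, 200]
  q2 <- qa; q2$start <- 180L; q2$end <- 400L
  q3 <- qa; q3$start <- 390L; q3$end <- 600L
  m3 <- merge_across_populations(list(q1, q2, q3))
  expect_equal(nrow(m3), 1L)
  expect_equal(c(m3$start, m3$end), c(100L, 600L))
})

test_that("heterotic classification covers the full truth table", {
  pat <- expand.grid(m = c(TRUE, FALSE), f = c(TRUE, FALSE),
                     h = c(TRUE, FALSE))
  cl <- classify_heterotic_qtl(pat$m, pat$f, pat$h)
  lookup <- stats::setNames(cl$class,
                            paste0(as.integer(pat$m), as.integer(pat$f),
                                   as.integer(pat$h)))
  expect_equal(unname(lookup["110"]), "additive")
  expect_equal(unname(lookup["101"]), "dominant")
  expect_equal(unname(lookup["010"]), "epistatic_DxA")
  expect_equal(unname(lookup["001"]), "epistatic_DxD")
  expect_equal(unname(lookup["011"]), "epistatic_DxA")
  expect_equal(unname(lookup["111"]), "additive")
  expect_equal(unname(lookup["100"]), "dominant")
  expect_equal(unname(lookup["000"]), "unclassified")
  amb <- stats::setNames(cl$ambiguous,
                         names(lookup))
  expect_true(all(amb[c("011", "111", "100")]))
  expect_false(any(amb[c("110", "101", "010", "001", "000")]))
})

test_that("cumulative class effects sum mean absolute peak betas", {
  mk <- function(start, end, beta, cls, pops = 1) {
    data.frame(qtl_id = paste0("q", start), chrom = "chr1", start = start,
               end = end, n_detections = pops,
               peak_betas = I(list(rep(beta, pops))),
               traits = I(list(rep("tr", pops))),
               class = cls, stringsAsFactors = FALSE)
  }
  map <- rbind(mk(1, 10, 0.3, "additive"), mk(20, 30, 0.2, "additive"),
               mk(40, 50, 0.4, "epistatic_DxA"))
  eff <- cumulative_class_effects(map)
  expect_equal(eff$cumulative_effect[eff$class == "additive"], 0.5)
  expect_equal(eff$cumulative_effect[eff$class == "dominant"], 0)
  expect_equal(eff$cumulative_effect[eff$class == "epistatic_DxA"], 0.4)
  # single QTL detected in several populations contributes its mean |beta|
  map2 <- mk(1, 10, 0.5, "additive", pops = 3)
  expect_equal(cumulative_class_effects(map2)$cumulative_effect[1], 0.5)
  # empty map: all zeros
  empty <- map[0, ]
  expect_true(all(cumulative_class_effects(empty)$cumulative_effect == 0))
})
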