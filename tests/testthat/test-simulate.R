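test_that("genotype generation is seed-reproducible and respects knobs", {
  g1 <- gen_inbred_genotypes(50, 200, seed = 61)
  g2 <- gen_inbred_genotypes(50, 200, seed = 61)
  expect_identical(g1$dosages, g2$dosages)
  g3 <- gen_inbred_genotypes(50, 200, seed = 62)
  expect_false(identical(g1$dosages, g3$dosages))
  # zero residual-het rate: no heterozygous calls
  g0 <- gen_inbred_genotypes(40, 100, het_rate = 0, seed = 63)
  expect_false(any(g0$dosages == 1))
  # chromosomes and spacing laid out as requested
  expect_equal(length(unique(g0$variants$chrom)), 10L)
})

test_that("realized MAF spectrum matches the requested uniform spectrum", {
  gm <- gen_inbred_genotypes(400, 50000, maf_spectrum = c(0.1, 0.4),
                             het_rate = 0, seed = 64)
  maf <- compute_maf(gm)
  ks <- suppressWarnings(ks.test(maf, "punif", 0.1, 0.4))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("within-block LD decays with distance across blocks", {
  gm <- gen_inbred_genotypes(400, 200, block_len = 20L, rho = 0.95,
                             het_rate = 0, seed = 65)
  d <- gm$dosages
  r2_lag <- function(lag) {
    idx <- which((seq_len(200) - 1) %% 20 < 20 - lag)
    mean(vapply(idx[1:100], function(j) {
      suppressWarnings(cor(d[, j], d[, j + lag]))^2
    }, numeric(1)), na.rm = TRUE)
  }
  expect_gt(r2_lag(1), r2_lag(5))
  expect_gt(r2_lag(5), r2_lag(15))
})

test_that("QTN spiking follows the exponential effect series in the MAF window", {
  gm <- gen_inbred_genotypes(300, 2000, seed = 66)
  set.seed(66)
  q <- spike_in_qtns(gm, n = 20)
  expect_equal(q$beta[1], 0.96)
  expect_equal(q$beta[20], 0.96^20)
  expect_equal(round(q$beta[20], 5), 0.442)
  maf <- compute_maf(gm)[q$index]
  expect_true(all(maf >= 0.25 & maf <= 0.35))
  expect_equal(anyDuplicated(q$index), 0L)
  # too few eligible variants is a clear error
  tiny <- gen_inbred_genotypes(30, 10, maf_spectrum = c(0.45, 0.5), seed = 67)
  expect_error(spike_in_qtns(tiny, n = 20), "MAF window")
})

test_that("genetic values sum dosage-weighted effects", {
  gm <- make_gm(cbind(c(0, 1, 2), c(2, 2, 0), c(0, 0, 2)))
  q <- structure(data.frame(index = 1:3, id = gm$variants$id,
                            beta = c(1, 0.5, 2), freq = 0.5),
                 class = c("qtn_set", "data.frame"))
  expect_equal(unname(genetic_value(gm, q)),
               c(0 * 1 + 2 * 0.5 + 0 * 2,
                 1 * 1 + 2 * 0.5 + 0 * 2,
                 2 * 1 + 0 * 0.5 + 2 * 2))
  q1 <- q[1, , drop = FALSE]
  expect_equal(unname(genetic_value(gm, q1)), c(0, 1, 2))
  gm_na <- make_gm(cbind(c(0, NA, 2)))
  expect_true(is.na(genetic_value(gm_na, q1[1, ])[2]))
})

test_that("PVE classification matches a brute-force computation", {
  # equal effects and frequencies: every QTN explains exactly 10%
  gm <- make_gm(matrix(rep(c(0, 0, 2, 2), 10), 4, 10),
                ids = sprintf("v%d", 1:10))
  q <- structure(data.frame(index = 1:10, id = gm$variants$id, beta = 1,
                            freq = 0.5),
                 class = c("qtn_set", "data.frame"))
  cl <- classify_pve(q, gm)
  expect_equal(cl$pve, rep(0.1, 10))
  expect_true(all(cl$class == "major"))
  # a single QTN explains everything
  cl1 <- classify_pve(q[1, ], gm)
  expect_equal(cl1$pve, 1)
  expect_equal(cl1$class, "major")
  # the exponential effect series at realised frequencies, against the
  # brute-force normalised computation
  gm2 <- gen_inbred_genotypes(500, 3000, seed = 68)
  set.seed(68)
  q2 <- spike_in_qtns(gm2, 20)
  cl2 <- classify_pve(q2, gm2)
  f <- colMeans(gm2$dosages[, q2$index]) / 2
  raw <- q2$beta * f * (1 - f)
  want <- raw / sum(raw)
  expect_equal(cl2$pve, unname(want), tolerance = 1e-12)
  expect_equal(cl2$class,
               unname(ifelse(want >= 0.07, "major",
                             ifelse(want >= 0.045, "moderate", "minor"))))
})

test_that("prediction noise hits the target accuracy", {
  set.seed(69)
  y <- rnorm(10000)
  expect_identical(add_prediction_noise(y, 1), y)
  yp <- add_prediction_noise(y, 0.5)
  expect_equal(var(yp - y), var(y), tolerance = 0.05)
  for (r2 in c(0.8, 0.5, 0.2)) {
    ypp <- add_prediction_noise(y, r2)
    expect_equal(cor(y, ypp)^2, r2, tolerance = 0.03)
  }
  expect_error(add_prediction_noise(y, 0), "r2")
})

test_that("permutation thresholds are quantiles of the min-p distribution", {
  gm <- gen_inbred_genotypes(120, 500, seed = 70)
  y <- stats::setNames(rnorm(120), rownames(gm$dosages))
  set.seed(70)
  thr <- permutation_threshold(gm, y, n_perm = 200,
                               alpha = c(0.01, 0.05, 0.5, 1.0))
  expect_true(all(diff(thr) >= 0))       # monotone in alpha
  expect_lt(thr["alpha0.05"], 0.01)      # genome-wide thresholds are small
  set.seed(70)
  thr2 <- permutation_threshold(gm, y, n_perm = 200,
                                alpha = c(0.01, 0.05, 0.5, 1.0))
  expect_identical(thr, thr2)            # bit-exact under a fixed seed
  expect_error(permutation_threshold(gm, y, n_perm = 10), "100")
})

test_that("hit matching scores true and false loci by linkage", {
  gm <- gen_inbred_genotypes(200, 500, seed = 71)
  set.seed(71)
  q <- spike_in_qtns(gm, 5)
  cfg <- hf_config()
  none <- match_hits_to_qtns(integer(), q, gm, cfg)
  expect_equal(none$N0 + none$N1, 0L)
  expect_true(attr(none$fdr, "undefined"))
  only <- match_hits_to_qtns(q$index, q, gm, cfg)
  expect_equal(only$N1, 0L)
  expect_equal(as.numeric(only$fdr), 0)
  expect_equal(only$N0, 5L)
  # one cluster linked to a QTN plus one unlinked cluster far away
  d <- cbind(c(rep(0, 50), rep(2, 50)), c(rep(0, 50), rep(2, 50)),
             rep(c(0, 2), 50))
  rownames(d) <- sprintf("s%03d", 1:100)
  gm2 <- make_gm(d, pos = c(1000000L, 1001000L, 9000000L))
  q2 <- structure(data.frame(index = 1L, id = gm2$variants$id[1],
                             beta = 1, freq = 0.5),
                  class = c("qtn_set", "data.frame"))
  res <- match_hits_to_qtns(c(2L, 3L), q2, gm2, cfg)
  expect_equal(res$N0, 1L)   # SNP 2 tags the QTN via r2 = 1
  expect_equal(res$N1, 1L)   # SNP 3 is an unlinked lone cluster
  expect_equal(as.numeric(res$fdr), 0.5)
})

test_that("the effect-gradient study reproduces its design cardinalities", {
  cfg <- sim_two_config()
  expect_equal(length(cfg$gradients), 19L)
  expect_equal(cfg$gradients[1], 0.1)
  expect_equal(cfg$gradients[19], 1.9)
  expect_equal(cfg$threshold, 2.2e-7)
  expect_error(sim_two_config(gradients = numeric()), "non-empty")
})

test_that("zero effect yields zero power at the stringent cutoff", {
  gm <- gen_inbred_genotypes(250, 400, seed = 72)
  base <- stats::setNames(rnorm(250), rownames(gm$dosages))
  out <- run_sim_two(sim_two_config(reduced = TRUE, gradients = 1e-9,
                                    sizes = 200L, snps_per_gradient = 30L,
                                    seed = 72), gm, base)
  expect_equal(out$power, 0)
})

test_that("full-study bundles are reproducible with a complete truth table", {
  s1 <- suppressWarnings(gen_full_study(seed = 73, n_maternal = 40L, n_testers = 3L,
                       n_variants = 200L))
  s2 <- suppressWarnings(gen_full_study(seed = 73, n_maternal = 40L, n_testers = 3L,
                       n_variants = 200L))
  expect_identical(s1$f1$dosages, s2$f1$dosages)
  expect_identical(s1$pheno_f1$value, s2$pheno_f1$value)
  expect_equal(nrow(s1$truth), 13L)
  expect_true(all(s1$truth$id %in% s1$parents$variants$id))
  # masker fixed for opposite alleles in the two pools
  masker <- s1$truth$id[s1$truth$role == "masker"]
  j <- match(masker, s1$parents$variants$id)
  expect_true(all(s1$parents$dosages[s1$maternal_ids, j] == 0))
  expect_true(all(s1$parents$dosages[s1$tester_ids, j] == 2))
  expect_equal(nrow(s1$design$crosses), 120L)
})
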