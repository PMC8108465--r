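test_that("enumerate_crosses builds the full factorial in maternal-major order", {
  d <- enumerate_crosses(c("m1", "m2", "m3"), c("p1", "p2"))
  expect_equal(nrow(d$crosses), 6L)
  expect_equal(d$crosses$maternal, rep(c("m1", "m2", "m3"), each = 2))
  expect_equal(d$crosses$paternal, rep(c("p1", "p2"), 3))
  expect_equal(nrow(enumerate_crosses("m", "p")$crosses), 1L)
  big <- enumerate_crosses(sprintf("M%04d", 1:1428), sprintf("T%02d", 1:30))
  expect_equal(nrow(big$crosses), 42840L)
  expect_error(enumerate_crosses(c("a", "b"), c("b", "c")), "both pools")
  expect_error(enumerate_crosses(character(), "p"), "non-empty")
})

test_that("make_training_split reproduces the NC-II training arithmetic", {
  mat <- sprintf("M%04d", 1:1428)
  d <- enumerate_crosses(mat, sprintf("T%02d", 1:30))
  d <- make_training_split(d, full_testers = c("T01", "T02"),
                           maternal_subset = mat[1:207])
  expect_equal(sum(d$training), 8652L)          # 2856 + 5796
  expect_equal(sum(!d$training), 34188L)
  expect_equal(sum(d$training) + sum(!d$training), nrow(d$crosses))

  d2 <- enumerate_crosses(c("a", "b"), c("x", "y"))
  d2 <- make_training_split(d2, full_testers = c("x", "y"))
  expect_equal(sum(!d2$training), 0L)           # all testers -> no candidates

  d3 <- enumerate_crosses(sprintf("m%02d", 1:10), c("x", "y"))
  d3 <- make_training_split(d3, full_testers = "x")
  expect_equal(sum(d3$training), 10L)
  expect_equal(sum(!d3$training), 10L)
  expect_error(make_training_split(d3, full_testers = "zz"), "subset")
})

test_that("filter_parent_snps applies the five criteria in order", {
  # 4 maternal + 3 paternal lines, 6 variants:
  # v1/v6 clean; v2 maternal het rate 2/4 >= 10%; v3 maternal-monomorphic;
  # v4 paternal het rate 1/3 >= 1/30; v5 minor homozygote in only 1 of the
  # 12 factorial hybrids (< 10% with the scaled threshold).
  mat <- c("m1", "m2", "m3", "m4"); pat <- c("p1", "p2", "p3")
  d <- enumerate_crosses(mat, pat)
  dos <- rbind(
    m1 = c(0, 1, 0, 0, 0, 0),
    m2 = c(0, 1, 0, 0, 2, 0),
    m3 = c(2, 0, 0, 2, 2, 2),
    m4 = c(2, 0, 0, 2, 2, 2),
    p1 = c(0, 0, 0, 1, 0, 0),
    p2 = c(0, 0, 2, 0, 2, 0),
    p3 = c(2, 2, 2, 2, 2, 2)
  )
  gm <- make_gm(dos)
  res <- filter_parent_snps(gm, d, min_hom_frac = 0.1)
  expect_equal(unname(res$report$removed["criterion2_het_rate"]), 2L)
  expect_equal(unname(res$report$removed["criterion3_pool_monomorphic"]), 1L)
  expect_equal(unname(res$report$removed["criterion4_maf"]), 0L)
  expect_equal(unname(res$report$removed["criterion5_minor_homozygote"]), 1L)
  expect_equal(res$report$retained, 2L)
  expect_equal(res$report$n_in, 6L)
  expect_equal(res$report$retained + sum(res$report$removed), 6L)
  expect_gt(res$report$het_cells_flagged, 0L)

  # idempotence: the filter is a no-op on its own output
  res2 <- filter_parent_snps(res$genotypes, d, min_hom_frac = 0.1)
  expect_equal(sum(res2$report$removed), 0L)
  expect_equal(res2$genotypes$dosages, res$genotypes$dosages)

  expect_error(filter_parent_snps(gm[c("m1", "m2"), ], d), "absent")
})

test_that("criterion 4 removes rare alleles at realistic panel sizes", {
  # at 100 maternal + 2 paternal lines, a variant with one minor homozygote
  # in each pool is polymorphic in both pools yet has MAF 4/204 < 0.02
  mat <- sprintf("m%03d", 1:100); pat <- c("p1", "p2")
  d <- enumerate_crosses(mat, pat)
  dos <- matrix(0, 102, 2, dimnames = list(c(mat, pat), NULL))
  dos[, 1] <- c(rep(0, 50), rep(2, 50), 0, 2)   # common variant
  dos[1, 2] <- 2; dos[102, 2] <- 2              # rare allele
  gm <- make_gm(dos)
  res <- filter_parent_snps(gm, d, min_hom_frac = 0)
  expect_equal(unname(res$report$removed["criterion4_maf"]), 1L)
  expect_equal(res$report$retained, 1L)
})

test_that("infer_f1_genotypes follows Mendelian dosage algebra", {
  d <- enumerate_crosses(c("m1", "m2"), c("p1", "p2"))
  gm <- make_gm(rbind(m1 = c(0, 1, 2), m2 = c(2, 0, 2),
                      p1 = c(2, 0, 2), p2 = c(0, NA, 2)))
  f1 <- infer_f1_genotypes(gm, d)
  expect_equal(unname(f1$dosages["m1_x_p1", ]), c(1, NA, 2))  # het -> NA
  expect_equal(unname(f1$dosages["m1_x_p2", ]), c(0, NA, 2))
  expect_equal(unname(f1$dosages["m2_x_p1", ]), c(2, 0, 2))
  expect_equal(unname(f1$dosages["m2_x_p2", ]), c(1, NA, 2))  # missing -> NA
  expect_error(infer_f1_genotypes(gm[c("m1", "p1"), ], d), "unknown parent")
})

test_that("F1 inference is symmetric under allele-label flips", {
  set.seed(11)
  mat <- sprintf("m%d", 1:8); pat <- c("p1", "p2")
  d <- enumerate_crosses(mat, pat)
  dos <- matrix(sample(c(0, 2), 50, TRUE), 10, 5,
                dimnames = list(c(mat, pat), NULL))
  gm <- make_gm(dos)
  f1 <- infer_f1_genotypes(gm, d)
  gm_flip <- make_gm(2 - dos)
  f1_flip <- infer_f1_genotypes(gm_flip, d)
  expect_equal(f1_flip$dosages, 2 - f1$dosages)
})

test_that("impute_f1_missing mode-fills within tester groups", {
  d <- enumerate_crosses(sprintf("m%d", 1:4), c("p1", "p2"))
  f1_dos <- matrix(NA_real_, 8, 2,
                   dimnames = list(d$crosses$cross, NULL))
  # tester p1 group: dosages 1,1,NA,1 -> mode 1; tester p2: tie 0/0/2/2+NA
  f1_dos[d$crosses$paternal == "p1", 1] <- c(1, 1, NA, 1)
  f1_dos[d$crosses$paternal == "p2", 1] <- c(0, 0, 2, 2)
  f1_dos[d$crosses$paternal == "p1", 2] <- c(0, 0, 2, 2)
  f1_dos[d$crosses$paternal == "p2", 2] <- c(NA, 0, 2, 2)
  f1 <- make_gm(f1_dos)
  imp <- impute_f1_missing(f1, d)
  filled <- imp$dosages[d$crosses$cross[d$crosses$paternal == "p1"][3], 1]
  expect_equal(unname(filled), 1)
  # tie between dosage 0 (count 1) and 2 (count 2): mode is 2 here; craft an
  # exact tie in column 2 of tester p2: counts 1 zero vs 2 twos -> not a tie.
  # exact tie: tester p1 column 2 fully observed stays unchanged
  expect_equal(unname(imp$dosages[d$crosses$paternal == "p1", 2]),
               c(0, 0, 2, 2))
  expect_equal(attr(imp, "imputed"), 2L)
})

test_that("mode-fill ties break toward the lower dosage", {
  d <- enumerate_crosses(sprintf("m%d", 1:5), "p1")
  f1_dos <- matrix(c(0, 0, 2, 2, NA), 5, 1,
                   dimnames = list(d$crosses$cross, NULL))
  imp <- impute_f1_missing(make_gm(f1_dos), d)
  expect_equal(unname(imp$dosages[5, 1]), 0)
  # fully observed matrix unchanged
  full <- make_gm(matrix(c(0, 0, 2, 2, 2), 5, 1,
                         dimnames = list(d$crosses$cross, NULL)))
  expect_equal(impute_f1_missing(full, d)$dosages, full$dosages)
})
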