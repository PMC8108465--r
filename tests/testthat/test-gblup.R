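test_that("compute_cgrm matches hand arithmetic and basic symmetries", {
  gm <- make_gm(matrix(c(0, 2), 2, 1, dimnames = list(c("a", "b"), NULL)))
  expect_equal(unname(compute_cgrm(gm)),
               matrix(c(1, -1, -1, 1), 2))
  expect_warning(K0 <- compute_cgrm(make_gm(matrix(2, 3, 4))), "monomorphic")
  expect_equal(unname(K0), matrix(0, 3, 3))
  # duplicated samples give identical rows/columns
  d <- matrix(sample(c(0, 2), 30, TRUE), 6, 5)
  d[2, ] <- d[1, ]
  rownames(d) <- letters[1:6]
  K <- compute_cgrm(make_gm(d))
  expect_equal(K[1, ], K[2, ], ignore_attr = TRUE)
  # variant permutation leaves K unchanged; duplicating all variants does too
  # (W W' and p both double)
  set.seed(8)
  d2 <- matrix(sample(c(0, 1, 2), 60, TRUE), 6, 10,
               dimnames = list(letters[1:6], NULL))
  K1 <- compute_cgrm(make_gm(d2))
  perm <- sample(10)
  K2 <- compute_cgrm(make_gm(d2[, perm]))
  expect_equal(K1, K2, tolerance = 1e-10)
  K3 <- compute_cgrm(make_gm(cbind(d2, d2)))
  expect_equal(K3, K1, tolerance = 1e-10)
})

test_that("gblup recovers an exact linear fit with vanishing noise", {
  set.seed(21)
  n <- 60
  d <- matrix(sample(c(0, 2), n * 50, TRUE), n, 50,
              dimnames = list(sprintf("s%02d", 1:n), NULL))
  K <- compute_cgrm(make_gm(d))
  X <- cbind(cov1 = rnorm(n), cov2 = runif(n))
  y <- stats::setNames(drop(2 + 3 * X[, 1] - X[, 2]), rownames(d))
  fit <- gblup(y, K, X = X)
  expect_lt(fit$sigma_e2, 1e-8)
  expect_equal(unname(fit$beta), c(2, 3, -1), tolerance = 1e-5)
})

test_that("gblup flags rank-deficient covariates by name", {
  set.seed(22)
  n <- 40
  d <- matrix(sample(c(0, 2), n * 30, TRUE), n, 30,
              dimnames = list(sprintf("s%02d", 1:n), NULL))
  K <- compute_cgrm(make_gm(d))
  X <- cbind(a = rnorm(n))
  X <- cbind(X, b = 2 * X[, "a"])
  y <- stats::setNames(rnorm(n), rownames(d))
  expect_error(gblup(y, K, X = X), "rank deficient")
})

test_that("variance-ratio estimates track the simulation truth", {
  set.seed(23)
  gm <- gen_inbred_genotypes(300, 400, seed = 23)
  K <- compute_cgrm(gm)
  # equal variance components: ratio near 1/2
  y <- sim_gblup_trait(K, 0.5)
  fit <- gblup(y, K)
  ratio <- fit$h2
  expect_gt(ratio, 0.35)
  expect_lt(ratio, 0.65)
  # pure noise: estimated heritability small
  y0 <- stats::setNames(rnorm(300), rownames(K))
  expect_lt(gblup(y0, K)$h2, 0.15)
})

test_that("predictions respect GRM geometry and covariate-only limits", {
  set.seed(24)
  gm <- gen_inbred_genotypes(120, 300, seed = 24)
  d <- gm$dosages
  d <- rbind(d, clone = d[1, ])  # candidate identical to training sample 1
  K <- compute_cgrm(make_gm(d))
  train <- rownames(gm$dosages)
  y <- sim_gblup_trait(K[train, train], 0.8)
  fit <- gblup(y, K[train, train])
  pred <- predict(fit, K, ids = c("clone", train[1]))
  expect_equal(unname(pred["clone"]), unname(pred[train[1]]), tolerance = 1e-8)

  # with sigma_u2 = 0 the prediction is the covariate term alone
  fit0 <- fit
  fit0$alpha[] <- 0
  pred0 <- predict(fit0, K, ids = "clone")
  expect_equal(unname(pred0), unname(fit$beta["(Intercept)"]))
})

test_that("gBLUP predicts a heritable trait out of sample", {
  set.seed(25)
  gm <- gen_inbred_genotypes(700, 500, seed = 25)
  K <- compute_cgrm(gm)
  y <- sim_gblup_trait(K, 0.8)
  train <- rownames(K)[1:500]
  test <- rownames(K)[501:700]
  fit <- gblup(y[train], K[train, train])
  pred <- predict(fit, K, ids = test)
  expect_gt(cor(pred, y[test]), 0.6)
})

test_that("leave-one-tester evaluation does its fold bookkeeping", {
  set.seed(26)
  n_mat <- 40; n_t <- 5
  study_par <- gen_inbred_genotypes(n_mat + n_t, 200, seed = 26)
  mat <- sprintf("m%02d", 1:n_mat); pat <- sprintf("t%d", 1:n_t)
  rownames(study_par$dosages) <- c(mat, pat)
  des <- enumerate_crosses(mat, pat)
  f1 <- suppressWarnings(impute_f1_missing(infer_f1_genotypes(study_par, des), des))
  K <- compute_cgrm(f1)
  y <- sim_gblup_trait(K, 0.7)
  rep <- evaluate_leave_one_tester(des, K, y)
  expect_equal(nrow(rep), 5L)
  expect_setequal(rep$fold, pat)
  expect_equal(rep$n_train, rep(n_mat * (n_t - 1L), 5L))
  expect_equal(rep$n_test, rep(n_mat, 5L))
  expect_true(all(rep$r >= -1 & rep$r <= 1))
})

test_that("leave-one-tester r is near zero for a pure-noise trait", {
  set.seed(27)
  n_mat <- 50; n_t <- 4
  par <- gen_inbred_genotypes(n_mat + n_t, 150, seed = 27)
  mat <- sprintf("m%02d", 1:n_mat); pat <- sprintf("t%d", 1:n_t)
  rownames(par$dosages) <- c(mat, pat)
  des <- enumerate_crosses(mat, pat)
  f1 <- suppressWarnings(impute_f1_missing(infer_f1_genotypes(par, des), des))
  K <- compute_cgrm(f1)
  y <- stats::setNames(rnorm(nrow(K)), rownames(K))
  rep <- evaluate_leave_one_tester(des, K, y)
  expect_lt(abs(mean(rep$r)), 0.25)
})

test_that("tester-swap evaluation trains on base plus extension blocks", {
  set.seed(28)
  n_mat <- 40; n_t <- 4
  par <- gen_inbred_genotypes(n_mat + n_t, 300, seed = 28)
  mat <- sprintf("m%02d", 1:n_mat); pat <- sprintf("t%d", 1:n_t)
  rownames(par$dosages) <- c(mat, pat)
  des <- enumerate_crosses(mat, pat)
  f1 <- suppressWarnings(impute_f1_missing(infer_f1_genotypes(par, des), des))
  K <- compute_cgrm(f1)
  y <- sim_gblup_trait(K, 0.9)
  subset <- mat[1:10]
  rep <- evaluate_tester_swap(des, K, y, "t1", "t2", subset)
  expect_equal(nrow(rep), 2L)
  # training = subset x all testers + extension x one tester
  expect_equal(rep$n_train, rep(10L * n_t + 30L, 2L))
  expect_equal(rep$n_test, rep(30L, 2L))
  # symmetric architecture: both directions predict comparably well
  expect_true(all(rep$r > 0.4))
  expect_lt(abs(rep$r[1] - rep$r[2]), 0.25)
})
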