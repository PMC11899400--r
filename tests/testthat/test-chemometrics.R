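test_that("PCA matches the SVD/eigendecomposition definition", {
  # rank-1: all variance in one feature
  x <- cbind(a = c(1, 2, 3, 4), b = rep(5, 4), c = rep(-1, 4))
  pc <- fit_pca(x, 1)
  expect_equal(pc$explained_variance[1], 1)
  # reconstruction with all components reproduces the matrix
  set.seed(1)
  x2 <- matrix(rnorm(24), 6, 4)
  pc2 <- fit_pca(x2, 4)
  rec <- sweep(pc2$scores %*% t(pc2$loadings), 2, pc2$center, `+`)
  expect_equal(rec, x2, tolerance = 1e-10, ignore_attr = TRUE)
  # autoscaled input: total variance equals the number of features
  sim <- generate_feature_table(n_groups = 2, n_reps = 4, n_qc = 4,
                                n_features = 10, n_dam = 2, seed = 6)
  auto <- intensity_matrix(run_preprocess(sim$table)$autoscaled)
  expect_equal(fit_pca(auto, 2)$total_variance, ncol(auto),
               tolerance = 1e-8)
  expect_error(fit_pca(x2, 7), class = "invalid_argument")
})

test_that("PCA components follow the positive-loading sign convention", {
  set.seed(4)
  x <- matrix(rnorm(40), 8, 5)
  pc <- fit_pca(x, 3)
  for (a in 1:3) {
    expect_gt(pc$loadings[which.max(abs(pc$loadings[, a])), a], 0)
  }
})

test_that("PLS-DA fits separable data and reduces to least squares", {
  # perfectly separable two-group data
  set.seed(2)
  x <- rbind(matrix(rnorm(40, 5), 8, 5), matrix(rnorm(40, -5), 8, 5))
  lab <- rep(c("A", "B"), each = 8)
  m <- fit_plsda(x, lab, 2)
  expect_gte(m$R2Y, 0.99)
  # component scores mutually orthogonal (NIPALS deflation)
  expect_equal(crossprod(m$T)[1, 2], 0, tolerance = 1e-8)
  # one feature, one component: prediction equals univariate least squares
  x1 <- matrix(c(1, 2, 3, 5, 6, 9), ncol = 1)
  lab1 <- c("A", "A", "A", "B", "B", "B")
  m1 <- fit_plsda(x1, lab1, 1)
  y <- as.numeric(lab1 == "B")
  ls <- fitted(lm(y ~ x1))
  expect_equal(unname(predict(m1, x1)$y_hat[, "B"]), unname(ls),
               tolerance = 1e-10)
  expect_error(fit_plsda(x1, rep("A", 6), 1), class = "invalid_argument")
})

test_that("OPLS-DA separates predictive from orthogonal variation", {
  set.seed(8)
  n <- 16; p <- 12
  lab <- factor(rep(c("A", "B"), each = n / 2))
  y <- as.numeric(lab == "B") - 0.5
  # data with injected label-orthogonal structure
  x <- outer(y, rnorm(p)) + outer(rnorm(n), rnorm(p)) +
    matrix(rnorm(n * p, sd = 0.1), n, p)
  o <- fit_oplsda(x, lab, n_orthogonal = 1)
  p2 <- fit_plsda(x, lab, 2)
  expect_equal(unname(predict(o, x)$y_hat),
               unname(predict(p2, x)$y_hat[, "B"]), tolerance = 1e-6)
  # n_orthogonal = 0 reduces to 1-component PLS
  o0 <- fit_oplsda(x, lab, n_orthogonal = 0)
  p1 <- fit_plsda(x, lab, 1)
  expect_equal(unname(predict(o0, x)$y_hat),
               unname(predict(p1, x)$y_hat[, "B"]), tolerance = 1e-10)
  # predictive and orthogonal scores uncorrelated
  expect_equal(cor(o$t, o$T_ortho[, 1]), 0, tolerance = 1e-8)
  expect_error(fit_oplsda(x, rep(c("A", "B", "C"), length.out = n), 1),
               class = "invalid_argument")
})

test_that("VIP follows the closed form and its normalization identity", {
  # weights proportional to (2, 1, 0): VIP = sqrt(3) * |w| / ||w||
  yv <- c(-3, -1, 1, 3)
  x <- outer(yv, c(2, 1, 0))
  m <- fit_oplsda(x, factor(c("A", "A", "B", "B")), 0)
  expect_equal(unname(m$vip), sqrt(3) * c(2, 1, 0) / sqrt(5),
               tolerance = 1e-10)
  # single-feature model: VIP forced to 1
  m1 <- fit_oplsda(matrix(yv, ncol = 1), factor(c("A", "A", "B", "B")), 0)
  expect_equal(unname(m1$vip), 1)
  # sum of VIP^2 = number of features, for PLS-DA too
  set.seed(3)
  xr <- matrix(rnorm(60), 10, 6)
  labr <- rep(c("A", "B"), 5)
  for (model in list(fit_plsda(xr, labr, 2), fit_oplsda(xr, labr, 1))) {
    expect_equal(sum(compute_vip(model)^2), 6, tolerance = 1e-8)
  }
  expect_error(compute_vip(list()), class = "invalid_state")
})

test_that("cross-validated Q2 rewards signal and penalizes noise", {
  set.seed(5)
  x <- rbind(matrix(rnorm(35, 4, 0.1), 7, 5), matrix(rnorm(35, -4, 0.1), 7, 5))
  lab <- rep(c("A", "B"), each = 7)
  q2 <- cross_validate_q2(x, lab, model_spec("plsda", 1), k = 7, seed = 1)
  expect_gte(q2, 0.95)
  expect_identical(formals(cross_validate_q2)$k, 7)
  # null data: mean Q2 over repeats is not positive
  q2_null <- vapply(1:50, function(i) {
    set.seed(100 + i)
    xn <- matrix(rnorm(12 * 6), 12, 6)
    cross_validate_q2(xn, rep(c("A", "B"), each = 6),
                      model_spec("plsda", 1), k = 6, seed = i)
  }, numeric(1))
  expect_lte(mean(q2_null), 0)
  expect_error(cross_validate_q2(x, lab, k = 20, seed = 1),
               class = "invalid_argument")
})

test_that("fits are deterministic given seed and input order", {
  set.seed(12)
  x <- matrix(rnorm(80), 10, 8)
  lab <- rep(c("A", "B"), 5)
  expect_identical(fit_plsda(x, lab, 2), fit_plsda(x, lab, 2))
  expect_identical(
    cross_validate_q2(x, lab, model_spec("oplsda", n_orthogonal = 1),
                      k = 5, seed = 42),
    cross_validate_q2(x, lab, model_spec("oplsda", n_orthogonal = 1),
                      k = 5, seed = 42))
})

test_that("permutation testing uses the add-one convention and defaults", {
  set.seed(9)
  x <- rbind(matrix(rnorm(20, 3, 0.2), 4, 5), matrix(rnorm(20, -3, 0.2), 4, 5))
  lab <- rep(c("A", "B"), each = 4)
  pr <- permutation_test(x, lab, model_spec("plsda", 1), n_perm = 19,
                         k = 4, seed = 2)
  expect_equal(nrow(pr$permuted), 19)
  expect_gte(pr$p_value$Q2, 1 / 20)   # minimum attainable p = 1/(n_perm+1)
  expect_lte(pr$p_value$Q2, 1)
  expect_identical(formals(permutation_test)$n_perm, 200)
  # strongly separated data: observed Q2 beats every permutation
  expect_equal(pr$p_value$Q2, 1 / 20)
})
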