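test_that("PCA matches the covariance eigendecomposition", {
  set.seed(42)
  x <- scale(matrix(rnorm(60), 10L, 6L), scale = FALSE)
  fit <- fit_pca(x, 4L)
  eig <- eigen(cov(x))
  # explained variance equals eigenvalue fractions
  expect_equal(fit$explained_variance,
               (eig$values / sum(eig$values))[1:4], tolerance = 1e-10)
  # loadings span the same directions (up to sign)
  for (a in 1:4) {
    expect_equal(abs(sum(fit$loadings[, a] * eig$vectors[, a])), 1,
                 tolerance = 1e-8)
  }
  # orthonormal loadings, non-increasing variance
  expect_equal(crossprod(fit$loadings), diag(4), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(diff(fit$explained_variance) <= 1e-12))
})

test_that("rank-1 matrix loads on a single component", {
  u <- rnorm(8); v <- rnorm(5)
  x <- outer(u - mean(u), v)
  fit <- suppressWarnings(fit_pca(x, 3L))
  expect_equal(fit$explained_variance[1L], 1, tolerance = 1e-10)
  expect_warning(fit_pca(x, 3L), "rank")
})

test_that("OPLS-DA with n_orth = 0 equals the NIPALS PLS1 oracle", {
  set.seed(7)
  x <- matrix(rnorm(200), 20L, 10L)
  x[1:10, 1:3] <- x[1:10, 1:3] + 1.5
  y <- rep(c("a", "b"), each = 10L)
  fit <- fit_oplsda(x, y, n_orth = 0L, scale = "uv")

  sc <- scale_center(x, "uv")
  ynum <- ifelse(y == "b", 1, -1)
  oracle <- pls1_oracle(sc$x, ynum - mean(ynum))
  expect_equal(abs(sum(fit$w * oracle$w)), 1, tolerance = 1e-8)
  expect_equal(fit$t_p * fit$q, oracle$yhat, tolerance = 1e-8,
               ignore_attr = TRUE)
  pred <- predict(fit, x)
  expect_equal(pred$y_hat, oracle$yhat + mean(ynum), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("noise-free class-aligned variation gives R2Y = 1", {
  # every column proportional to the class vector: the predictive score
  # reproduces the class exactly
  y <- rep(c("a", "b"), each = 6L)
  ynum <- ifelse(y == "b", 1, -1)
  x <- cbind(ynum, 2 * ynum, -0.5 * ynum)
  fit <- fit_oplsda(x, y, n_orth = 0L, scale = "none")
  expect_equal(fit$r2y, 1, tolerance = 1e-10)
})

test_that("an added class-orthogonal direction is absorbed by n_orth = 1", {
  # plant strong structured variation along a sample direction orthogonal
  # to the class vector and to the clean predictive scores, loading on a
  # feature direction in the clean matrix's null space: one orthogonal
  # component removes it and restores the clean predictive scores
  set.seed(9)
  n <- 24L; p <- 30L
  y <- rep(c("a", "b"), each = n / 2L)
  ynum <- ifelse(y == "b", 1, -1)
  x_clean <- matrix(rnorm(n * p), n, p)
  x_clean[y == "b", 1:3] <- x_clean[y == "b", 1:3] + 2
  f0 <- fit_oplsda(x_clean, y, n_orth = 0L, scale = "none")

  xc <- scale(x_clean, scale = FALSE)
  sv <- svd(xc, nv = p)
  vnull <- sv$v[, sum(sv$d > 1e-8) + 1L] # feature direction unseen by xc
  v <- vnull + 0.5 * f0$w
  v <- v / sqrt(sum(v^2))
  conf <- qr.resid(qr(cbind(1, ynum, f0$t_p)), rnorm(n))
  x_aug <- x_clean + 1e4 * conf %*% t(v)

  f1 <- fit_oplsda(x_aug, y, n_orth = 1L, scale = "none")
  expect_gt(abs(cor(f0$t_p, f1$t_p)), 1 - 1e-6)
  # without the orthogonal filter the planted direction wrecks the scores
  fa0 <- fit_oplsda(x_aug, y, n_orth = 0L, scale = "none")
  expect_lt(abs(cor(f0$t_p, fa0$t_p)), 0.5)
})

test_that("predictive scores are orthogonal to every orthogonal score", {
  set.seed(10)
  x <- matrix(rnorm(30L * 12L), 30L, 12L)
  x[1:15, 1:4] <- x[1:15, 1:4] + 1
  y <- rep(c("a", "b"), each = 15L)
  for (k in 1:3) {
    fit <- fit_oplsda(x, y, n_orth = k)
    for (j in seq_len(k)) {
      dot <- abs(sum(fit$t_p * fit$T_o[, j]))
      expect_lt(dot, 1e-8 * sqrt(sum(fit$t_p^2) * sum(fit$T_o[, j]^2)))
    }
    expect_true(fit$r2y >= 0 && fit$r2y <= 1)
    expect_equal(sum(fit$w^2), 1, tolerance = 1e-10)
  }
})

test_that("OPLS-DA input contracts", {
  x <- matrix(rnorm(40), 10L, 4L)
  expect_error(fit_oplsda(x, rep("a", 10L)), "2 classes")
  expect_error(fit_oplsda(x, c("a", rep("b", 9L))), "2 samples per class")
  expect_error(fit_oplsda(x, rep(c("a", "b"), 5L), n_orth = 4L), "rank")
})

test_that("VIP normalization and closed-form cases", {
  set.seed(11)
  x <- matrix(rnorm(26L * 16L), 26L, 16L)
  x[1:13, 1:5] <- x[1:13, 1:5] + 1.2
  y <- rep(c("a", "b"), each = 13L)
  fit <- fit_oplsda(x, y, n_orth = 1L)
  vip <- compute_vip(fit)
  # mean squared VIP = 1 for any fitted model
  expect_equal(mean(vip$vip^2), 1, tolerance = 1e-8)

  # equal absolute weights -> all VIP = 1
  mock <- structure(list(w = rep(c(1, -1), 8L) / 4, component_ids = NULL),
                    class = "oplsda")
  expect_equal(compute_vip(mock)$vip, rep(1, 16L))

  # single nonzero weight among p = 16 -> VIP = 4 there, 0 elsewhere
  mock$w <- c(1, rep(0, 15L))
  v <- compute_vip(mock)$vip
  expect_equal(v[1L], 4)
  expect_equal(v[-1L], rep(0, 15L))
})

test_that("S-plot coordinates agree with direct covariance/correlation", {
  set.seed(12)
  x <- matrix(rnorm(20L * 6L), 20L, 6L)
  x[1:10, 1L] <- x[1:10, 1L] + 3
  colnames(x) <- sprintf("C%d", 1:6)
  y <- rep(c("a", "b"), each = 10L)
  fit <- fit_oplsda(x, y, n_orth = 0L)
  sp <- splot_coordinates(fit, x)
  xs <- apply_scaling(x, fit$scaling)
  for (j in 1:6) {
    expect_equal(sp$covariance[j], cov(fit$t_p, xs[, j]), tolerance = 1e-10)
    expect_equal(sp$correlation[j], cor(fit$t_p, xs[, j]), tolerance = 1e-10)
  }
  # sign(cov) == sign(corr); correlations bounded
  expect_true(all(sign(sp$covariance) == sign(sp$correlation)))
  expect_true(all(abs(sp$correlation) <= 1 + 1e-12))

  # zero-variance column flagged with correlation 0 (scale = "none")
  x2 <- cbind(x, C7 = 5)
  fit2 <- fit_oplsda(x2, y, n_orth = 0L, scale = "none")
  sp2 <- splot_coordinates(fit2, x2)
  expect_true(sp2$zero_variance[7L])
  expect_equal(sp2$correlation[7L], 0)
})

test_that("pure-noise components have vanishing S-plot correlation", {
  set.seed(13)
  n <- 400L
  y <- rep(c("a", "b"), each = n / 2L)
  x <- cbind(sig = ifelse(y == "b", 1, -1) + rnorm(n, sd = 0.3),
             matrix(rnorm(n * 5L), n, 5L))
  fit <- fit_oplsda(x, y, n_orth = 0L)
  sp <- splot_coordinates(fit, x)
  expect_true(all(abs(sp$correlation[-1L]) < 3 / sqrt(n)))
  expect_gt(sp$correlation[1L], 0.9)
})
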