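test_that("two symmetric points recover the analytic max-margin solution", {
  K <- compute_gram(matrix(c(-1, 1), 2, 1), spec = kernel_spec("linear"))
  fit <- solve_svm_dual(K, c(-1, 1), C = 10, tol = 1e-10)
  expect_equal(fit$alpha, c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(fit$b, 0, tolerance = 1e-6)
  expect_equal(fit$objective, 0.5, tolerance = 1e-6)
  # induced decision function is f(x) = x
  p <- svm_predict(fit, matrix(c(-2, 2), 1, 2))  # K(2, x_i) = (-2, 2)
  expect_equal(unname(p$decision), 2)
  expect_equal(unname(p$labels), 1)
  # tie at f = 0 goes to the positive class
  p0 <- svm_predict(fit, matrix(c(0, 0), 1, 2))
  expect_equal(unname(p0$decision), 0)
  expect_equal(unname(p0$labels), 1)
})

test_that("degenerate label inputs are rejected", {
  K <- random_psd(6, seed = 1)
  expect_error(solve_svm_dual(K, rep(1, 6), C = 1), "single-class")
  expect_error(solve_svm_dual(K, c(1, 1, 1, 2, 2, 3), C = 1), "two classes")
  expect_error(solve_svm_dual(K, c(-1, 1, -1, 1, -1, 1), C = -2), "positive")
  expect_error(no_information_rate(integer(0)), "empty")
})

test_that("no-information rate is the majority-class proportion", {
  expect_equal(no_information_rate(c(rep(1, 7), rep(-1, 3))), 0.7)
  expect_equal(no_information_rate(c(-1, -1, 1, 1)), 0.5)
  expect_equal(no_information_rate("a"), 1.0)
})

test_that("dual objective matches a brute-force interior-point QP oracle", {
  # XOR: not linearly separable, all points support vectors
  Xxor <- matrix(c(0, 0, 1, 1, 0, 1, 1, 0), 4, 2, byrow = TRUE)
  yxor <- c(-1, -1, 1, 1)
  Kxor <- tcrossprod(Xxor) + diag(1e-6, 4)
  expect_equal(solve_svm_dual(Kxor, yxor, C = 1, tol = 1e-8)$objective,
               ipop_dual_objective(Kxor, yxor, 1), tolerance = 1e-6)
  set.seed(7)
  for (i in 1:20) {
    n <- sample(10:20, 1)
    K <- random_psd(n)
    y <- sample(c(-1, 1), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1] <- -y[1]
    C <- sample(c(0.1, 1, 10), 1)
    expect_equal(solve_svm_dual(K, y, C = C, tol = 1e-8)$objective,
                 ipop_dual_objective(K, y, C), tolerance = 1e-6,
                 label = sprintf("instance %d (n=%d, C=%g)", i, n, C))
  }
})

test_that("solution satisfies the dual feasibility invariants", {
  set.seed(3)
  for (i in 1:5) {
    d <- make_blobs(12, shift = 1.5, seed = i)
    K <- compute_gram(d$X, d$X, kernel_spec("radial", sigma = 0.5))
    fit <- solve_svm_dual(K, d$y, C = 2)
    expect_true(all(fit$alpha >= -1e-8 & fit$alpha <= 2 + 1e-8))
    expect_lt(abs(sum(fit$alpha * fit$y)), 1e-6)
    expect_lte(fit$gap, fit$tol)
  }
})

test_that("training error is non-increasing in C on a separable toy", {
  d <- make_blobs(15, shift = 4, seed = 9)
  K <- compute_gram(d$X, d$X, kernel_spec("linear"))
  errs <- vapply(c(0.01, 0.1, 1, 10), function(C) {
    fit <- solve_svm_dual(K, d$y, C = C)
    mean(svm_predict(fit, K)$labels != d$y)
  }, 0)
  expect_true(all(diff(errs) <= 1e-12))
  expect_equal(errs[4], 0)  # margin property: separable data fit perfectly
})

test_that("scaling the Gram by c and the cost by 1/c leaves predictions unchanged", {
  d <- make_blobs(12, shift = 2, seed = 21)
  K <- as.matrix(compute_gram(d$X, d$X, kernel_spec("radial", sigma = 0.3)))
  f1 <- solve_svm_dual(K, d$y, C = 1)
  f2 <- solve_svm_dual(5 * K, d$y, C = 1 / 5)
  expect_equal(svm_predict(f1, K)$labels, svm_predict(f2, 5 * K)$labels)
})

test_that("cross-validation is stratified, deterministic, and finds separable structure", {
  d <- make_blobs(20, shift = 5, seed = 13)
  specs <- list(kernel_spec("radial", sigma = 0.1),
                kernel_spec("radial", sigma = 1))
  cv1 <- cross_validate_svm(d$X, d$y, specs, C_grid = c(0.1, 1), k = 5, seed = 42)
  cv2 <- cross_validate_svm(d$X, d$y, specs, C_grid = c(0.1, 1), k = 5, seed = 42)
  expect_identical(cv1$grid, cv2$grid)
  expect_identical(cv1$folds, cv2$folds)
  expect_equal(cv1$grid$mean_acc[cv1$best], 1.0)
  # stratification: class counts per fold differ by at most one
  tab <- table(cv1$folds, d$y)
  expect_lte(max(tab) - min(tab), 1)
  expect_true(all(cv1$grid$mean_acc >= 0 & cv1$grid$mean_acc <= 1))
  expect_error(cross_validate_svm(d$X[1:8, ], d$y[1:8], specs, k = 5),
               "n >= 2k")
})

test_that("shuffled labels cannot be classified above chance", {
  d <- make_blobs(20, shift = 5, seed = 3)
  accs <- vapply(1:10, function(r) {
    set.seed(100 + r)
    ysh <- sample(d$y)
    cv <- cross_validate_svm(d$X, ysh, kernel_spec("radial", sigma = 0.5),
                             C_grid = c(0.1, 1), k = 5, seed = r)
    cv$grid$mean_acc[cv$best]
  }, 0)
  # mean best-cell accuracy stays within a few sd of the 0.5 NIR
  expect_lt(mean(accs), 0.5 + 3 * max(sd(accs), 0.02))
})
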