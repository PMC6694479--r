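# Helper: radial kernels on disjoint feature blocks, a few carrying signal.
block_kernel_data <- function(n, n_signal_blocks, n_noise_blocks, seed,
                              block_width = 4, shift = 1.6) {
  set.seed(seed)
  M <- n_signal_blocks + n_noise_blocks
  p <- M * block_width
  X <- matrix(rnorm(n * p), n, p)
  y <- rep(c(-1, 1), length.out = n)
  sig_cols <- seq_len(n_signal_blocks * block_width)
  X[y == 1, sig_cols] <- X[y == 1, sig_cols] + shift
  colnames(X) <- paste0("f", seq_len(p))
  blocks <- split(colnames(X), rep(seq_len(M), each = block_width))
  grams <- lapply(blocks, function(feats)
    compute_gram(X, X, kernel_spec("radial",
                                   sigma = median_heuristic_sigma(X[, feats]),
                                   features = feats)))
  list(grams = unname(grams), y = y,
       signal = seq_len(n_signal_blocks),
       noise = n_signal_blocks + seq_len(n_noise_blocks))
}

test_that("single-kernel DAL reduces to the SVM at the mapped cost", {
  d <- make_blobs(20, shift = 3, seed = 17)
  K <- compute_gram(d$X, d$X, kernel_spec("radial", sigma = 0.5))
  dal <- dalmkl_fit(list(K), d$y, dal_config("hinge", C = 0.05))
  expect_equal(dal$weights, 1.0)
  mapped <- estimate_wrapper_cost(dal)
  expect_equal(mapped, max(abs(dal$alpha)))
  svm <- solve_svm_dual(K, d$y, C = mapped)
  expect_equal(mkl_predict(dal, list(K))$labels,
               svm_predict(svm, K)$labels)
})

test_that("inactive kernel blocks are exactly zero, not merely small", {
  d <- block_kernel_data(50, n_signal_blocks = 2, n_noise_blocks = 4, seed = 2)
  for (loss in c("hinge", "logistic")) {
    fit <- dalmkl_fit(d$grams, d$y, dal_config(loss, C = 0.05))
    inactive <- setdiff(seq_along(d$grams), fit$active)
    expect_gt(length(inactive), 0)
    for (m in inactive) {
      expect_identical(fit$beta[[m]], numeric(length(d$y)))
      expect_identical(fit$weights[m], 0)
    }
    expect_equal(sum(fit$weights), 1, tolerance = 1e-12)
    expect_true(all(fit$weights >= 0))
  }
})

test_that("the outer objective decreases monotonically along the trace", {
  inst <- rand_mkl_instance(n = 25, M = 3, seed = 12)
  for (loss in c("hinge", "logistic")) {
    fit <- dalmkl_fit(inst$mats, inst$y, dal_config(loss, C = 0.05))
    expect_true(all(diff(fit$trace$primal) <= 1e-8))
    expect_true(fit$converged)
  }
})

test_that("noise kernels are pruned while informative kernels survive", {
  zeroed <- informative_kept <- logical(5)
  for (s in 1:5) {
    d <- block_kernel_data(60, n_signal_blocks = 2, n_noise_blocks = 8,
                           seed = 100 + s)
    fit <- dalmkl_fit(d$grams, d$y, dal_config("hinge", C = 0.05))
    zeroed[s] <- sum(!(d$noise %in% fit$active)) >= 6
    informative_kept[s] <- all(d$signal %in% fit$active)
  }
  expect_gte(mean(zeroed & informative_kept), 0.8)
})

test_that("stronger penalties keep fewer kernels active", {
  n_active <- sapply(1:3, function(s) {
    d <- block_kernel_data(50, n_signal_blocks = 2, n_noise_blocks = 6,
                           seed = 200 + s)
    vapply(c(0.005, 0.05, 0.5), function(C)
      length(dalmkl_fit(d$grams, d$y, dal_config("hinge", C = C))$active), 0L)
  })
  # monotone trend in the mean over seeds as C (the effective
  # regularization strength) grows
  expect_true(all(diff(rowMeans(n_active)) <= 0))
})

test_that("DAL hinge and SimpleMKL agree on held-out labels at matched cost", {
  agree <- vapply(1:10, function(s) {
    set.seed(400 + s)
    tr <- make_blobs(15, d = 2, shift = 2, seed = 400 + s)
    te <- make_blobs(10, d = 2, shift = 2, seed = 900 + s)
    specs <- list(kernel_spec("radial", sigma = 1), kernel_spec("linear"),
                  kernel_spec("radial", sigma = 0.1))
    Ktr <- lapply(specs, function(sp) compute_gram(tr$X, tr$X, sp))
    Kte <- lapply(specs, function(sp) compute_gram(te$X, tr$X, sp))
    dal <- dalmkl_fit(Ktr, tr$y, dal_config("hinge", C = 0.05))
    wrap <- simplemkl_fit(Ktr, tr$y, C = estimate_wrapper_cost(dal))
    mean(mkl_predict(dal, Kte)$labels == mkl_predict(wrap, Kte)$labels)
  }, 0)
  expect_gte(mean(agree), 0.95)
})

test_that("degenerate DAL inputs are rejected", {
  inst <- rand_mkl_instance(n = 10, M = 2, seed = 3)
  expect_error(dalmkl_fit(inst$mats, rep(1, 10), dal_config("hinge")),
               "single-class")
  expect_error(dal_config("hinge", C = -1))
  expect_error(dal_config("hinge", gamma_growth = 0.5))
  fake <- structure(list(alpha = rep(0, 5)), class = "dal_model")
  expect_error(estimate_wrapper_cost(fake), "degenerate")
})
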