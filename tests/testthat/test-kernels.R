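test_that("kernel formulas match hand-computed values", {
  expect_equal(as.matrix(compute_gram(matrix(c(1, 2), 1), matrix(c(3, 4), 1),
                                      kernel_spec("linear")))[1, 1], 11)
  expect_equal(as.matrix(compute_gram(matrix(c(1, 0), 1), matrix(c(1, 0), 1),
                                      kernel_spec("polynomial", degree = 2,
                                                  scale = 1, offset = 1)))[1, 1], 4)
  # radial: self-similarity 1 for any sigma; off-diagonal exp(-sigma d^2 / 2)
  X <- matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE)
  K <- as.matrix(compute_gram(X, X, kernel_spec("radial", sigma = 2)))
  expect_equal(unname(diag(K)), c(1, 1))
  expect_equal(K[1, 2], exp(-2 * 2 / 2))
  # the alternative convention drops the /2
  K2 <- as.matrix(compute_gram(X, X, kernel_spec("radial", sigma = 2,
                                                 rbf_half = FALSE)))
  expect_equal(K2[1, 2], exp(-2 * 2))
  # ordinal: (r - |x - y|) / r
  expect_equal(as.matrix(compute_gram(matrix(1), matrix(3),
                                      kernel_spec("clinical_ordinal",
                                                  range = 4)))[1, 1], 0.5)
  # nominal: exact match indicator
  stg <- data.frame(stage = c("IIIC", "IV"))
  Kn <- as.matrix(compute_gram(stg, stg, kernel_spec("clinical_nominal")))
  expect_equal(Kn, matrix(c(1, 0, 0, 1), 2, dimnames = dimnames(Kn)))
})

test_that("every kernel family yields a symmetric Gram with the declared range", {
  set.seed(11)
  X <- data.frame(f1 = rnorm(15), f2 = rnorm(15),
                  stage = sample(c("I", "II", "III"), 15, replace = TRUE),
                  grade = sample(1:4, 15, replace = TRUE))
  rownames(X) <- paste0("p", 1:15)
  specs <- list(kernel_spec("linear", features = c("f1", "f2")),
                kernel_spec("polynomial", degree = 3, features = c("f1", "f2")),
                kernel_spec("polynomial", degree = 2, normalize = TRUE,
                            features = c("f1", "f2")),
                kernel_spec("radial", sigma = 0.7, features = c("f1", "f2")),
                kernel_spec("clinical_nominal", features = "stage"),
                kernel_spec("clinical_ordinal", range = 3, features = "grade"))
  for (sp in specs) {
    K <- as.matrix(compute_gram(X, X, sp))
    expect_lt(max(abs(K - t(K))), 1e-10)
    if (sp$kind %in% c("radial", "clinical_nominal", "clinical_ordinal")) {
      expect_true(all(K >= 0 & K <= 1 + 1e-12))
      if (sp$kind == "radial") expect_equal(unname(diag(K)), rep(1, 15))
    }
    if (isTRUE(sp$normalize)) expect_true(all(abs(K) <= 1 + 1e-12))
  }
})

test_that("restricting via feature_subset equals projecting the table first", {
  set.seed(4)
  X <- matrix(rnorm(60), 12, 5, dimnames = list(paste0("s", 1:12),
                                                paste0("f", 1:5)))
  sub <- c("f2", "f4")
  for (sp in list(kernel_spec("linear", features = sub),
                  kernel_spec("radial", sigma = 1.3, features = sub))) {
    sp_all <- sp
    sp_all$features <- NULL
    expect_equal(as.matrix(compute_gram(X, X, sp)),
                 as.matrix(compute_gram(X[, sub], X[, sub], sp_all)))
  }
})

test_that("combining Grams is the weighted sum and preserves PSD", {
  K1 <- compute_gram(matrix(rnorm(20), 10, 2), spec = kernel_spec("linear"))
  K2 <- compute_gram(matrix(rnorm(20), 10, 2), spec = kernel_spec("linear"))
  expect_equal(as.matrix(combine_grams(list(K1, K2), c(1, 0))), as.matrix(K1))
  expect_equal(as.matrix(combine_grams(list(K1, K1), c(0.5, 0.5))),
               as.matrix(K1))
  # convexity closure: eigenvalue check on random PSD pairs
  for (s in 1:20) {
    A <- random_psd(15, seed = s, ridge = 0)
    B <- random_psd(15, seed = s + 100, ridge = 0)
    Kc <- combine_grams(list(A, B), c(0.3, 0.7))
    expect_gte(min_eigenvalue(as.matrix(Kc)),
               -1e-8 * max(abs(eigen(as.matrix(Kc), only.values = TRUE)$values)))
  }
  expect_error(combine_grams(list(K1, K2), c(-1, 2)), "nonnegative")
  expect_error(combine_grams(list(K1, matrix(0, 3, 3)), c(1, 1)), "mismatch")
})

test_that("validate_psd leaves PSD inputs alone and repairs indefinite ones", {
  I5 <- diag(5)
  out <- validate_psd(I5)
  expect_false(attr(out, "psd_repaired"))
  expect_equal(out, I5, ignore_attr = TRUE)
  # slightly negative eigenvalue: repaired with jitter on the diagonal
  neg <- diag(c(1, -1e-12))
  expect_message(rep_out <- validate_psd(neg), "jitter")
  expect_true(attr(rep_out, "psd_repaired"))
  expect_gte(min_eigenvalue(matrix(rep_out, 2, 2)), 0)
  # exact rank-1 outer product is PSD (eigenvalues {||v||^2, 0, ...})
  v <- rnorm(8)
  out2 <- validate_psd(tcrossprod(v))
  expect_false(attr(out2, "psd_repaired"))
  expect_error(validate_psd(matrix(1:6, 2, 3)), "square")
})

test_that("kernel_spec rejects mismatched or invalid hyperparameters", {
  expect_error(kernel_spec("radial"), "requires 'sigma'")
  expect_error(kernel_spec("radial", sigma = -1), "positive")
  expect_error(kernel_spec("linear", sigma = 2), "not used")
  expect_error(kernel_spec("clinical_ordinal", range = 0), "positive")
  expect_error(kernel_spec("polynomial", degree = 0.5), "positive integer")
  expect_error(kernel_spec("radial", sigma = 1, normalize = TRUE),
               "only available")
  expect_error(compute_gram(matrix(1, 2, 2), spec = kernel_spec("linear",
                                                                features = "nope")),
               "not found")
  # ordinal codes outside the declared range are a contract violation
  expect_error(compute_gram(matrix(c(1, 9), 2, 1), spec =
                              kernel_spec("clinical_ordinal", range = 3)),
               "range")
  # level labels map to consecutive codes; r defaults to L - 1
  sp <- kernel_spec("clinical_ordinal", levels = c("I", "II", "III", "IV"))
  expect_equal(sp$range, 3)
  K <- as.matrix(compute_gram(data.frame(s = "I"), data.frame(s = "IV"), sp))
  expect_equal(K[1, 1], 0)
})

test_that("composite kernels equal the weighted sum of their members", {
  set.seed(2)
  X <- data.frame(stage = sample(1:4, 10, replace = TRUE), age = rnorm(10))
  s1 <- kernel_spec("clinical_ordinal", range = 3, features = "stage")
  s2 <- kernel_spec("radial", sigma = 1, features = "age")
  combo <- kernel_combo(list(s1, s2))
  expect_equal(as.matrix(compute_gram(X, X, combo)),
               0.5 * as.matrix(compute_gram(X, X, s1)) +
               0.5 * as.matrix(compute_gram(X, X, s2)))
})

test_that("Gram matrices and feature tables round-trip through CSV", {
  X <- matrix(rnorm(20), 10, 2, dimnames = list(paste0("s", 1:10), c("a", "b")))
  K <- compute_gram(X, X, kernel_spec("radial", sigma = 1))
  f <- tempfile(fileext = ".csv")
  write_gram(K, f)
  K2 <- read_gram(f)
  expect_equal(K2$values, K$values, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(K2$row_ids, K$row_ids)
  ft <- tempfile(fileext = ".csv")
  write.csv(data.frame(sample_id = rownames(X), X), ft, row.names = FALSE)
  tab <- read_feature_table(ft)
  expect_equal(as.matrix(tab), X)
})
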