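test_that("feature ranking orders by evidence and flags constants", {
  set.seed(1)
  y <- rep(c(-1, 1), each = 10)
  X <- cbind(perfect = 2 * y, const = rep(3, 20),
             noise1 = rnorm(20), noise2 = rnorm(20))
  for (method in c("ttest", "wilcoxon")) {
    rk <- rank_features(X, y, method = method)
    expect_equal(rk$feature[1], "perfect")
    expect_lt(rk$p_value[1], 1e-6)
    const_row <- rk[rk$feature == "const", ]
    expect_equal(const_row$p_value, 1)
    expect_equal(const_row$flag, "constant")
    expect_true(all(diff(rk$p_value) >= 0))
    expect_true(all(rk$p_value >= 0 & rk$p_value <= 1))
  }
  expect_error(rank_features(X[c(1, 11), ], y[c(1, 11)]),
               "two samples per class")
})

test_that("informative features are recovered among many nulls", {
  recall <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 100
    y <- rep(c(-1, 1), each = n / 2)
    X <- matrix(rnorm(n * 500), n, 500,
                dimnames = list(NULL, paste0("g", 1:500)))
    X[y == 1, 1:5] <- X[y == 1, 1:5] + 1.5
    rk <- rank_features(X, y)
    mean(paste0("g", 1:5) %in% select_top_features(rk, 10))
  }, 0)
  expect_gte(mean(recall), 0.8)
})

test_that("top-k selection is prefix-consistent and validated", {
  set.seed(5)
  y <- rep(c(-1, 1), each = 15)
  X <- matrix(rnorm(30 * 100), 30, 100,
              dimnames = list(NULL, paste0("g", 1:100)))
  rk <- rank_features(X, y)
  top65 <- select_top_features(rk, 65)
  expect_length(top65, 65)
  expect_identical(select_top_features(rk, 10), top65[1:10])
  expect_identical(select_top_features(rk, 100), rk$feature)
  expect_error(select_top_features(rk, 0), "between 1 and")
  expect_error(select_top_features(rk, 101), "between 1 and")
})

test_that("ranking on training rows only differs from ranking with test rows leaked", {
  set.seed(77)
  n <- 60
  y <- rep(c(-1, 1), each = n / 2)
  X <- matrix(rnorm(n * 80), n, 80, dimnames = list(NULL, paste0("g", 1:80)))
  X[y == 1, 1:4] <- X[y == 1, 1:4] + 0.8
  tr <- c(1:20, 31:50)
  top_train <- select_top_features(rank_features(X[tr, ], y[tr]), 10)
  top_leaked <- select_top_features(rank_features(X, y), 10)
  expect_false(identical(top_train, top_leaked))
})

test_that("kernel screening eliminates uninformative candidates by the NIR rule", {
  hits <- vapply(1:5, function(s) {
    set.seed(s)
    n <- 60
    # imbalanced labels: a kernel with no signal can at best match the NIR
    y <- c(rep(-1, 21), rep(1, 39))
    X <- data.frame(inf1 = rnorm(n) + ifelse(y > 0, 2.5, 0),
                    inf2 = rnorm(n) + ifelse(y > 0, 2.5, 0),
                    noise1 = rnorm(n), noise2 = rnorm(n))
    cand <- list(kernel_spec("radial", sigma = 0.5,
                             features = c("inf1", "inf2"), name = "informative"),
                 kernel_spec("radial", sigma = 0.5,
                             features = c("noise1", "noise2"), name = "noise"))
    scr <- screen_kernels(X, y, cand, C_grid = c(0.1, 1, 10), folds = 5, seed = s)
    kept <- vapply(scr$survivors, `[[`, "", "name")
    ("informative" %in% kept) && !("noise" %in% kept)
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("accuracy equal to the NIR is not enough to survive", {
  # constant feature -> constant Gram -> the SVM can only predict the
  # majority class, so CV accuracy equals the NIR exactly
  set.seed(9)
  n <- 40
  y <- c(rep(1, 28), rep(-1, 12))
  X <- data.frame(flat = rep(1, n), noise = rnorm(n))
  cand <- kernel_spec("linear", features = "flat", name = "flat")
  expect_error(screen_kernels(X, y, list(cand), C_grid = 1, folds = 5, seed = 1),
               class = "no_surviving_kernels")
  # a single candidate above the NIR is returned unchanged
  set.seed(10)
  X$good <- rnorm(n) + ifelse(y > 0, 3, 0)
  good <- kernel_spec("radial", sigma = 1, features = "good", name = "good")
  scr <- screen_kernels(X, y, list(good), C_grid = c(0.1, 1), folds = 5, seed = 1)
  expect_length(scr$survivors, 1)
  expect_equal(scr$survivors[[1]]$name, "good")
  expect_true(!is.null(attr(scr$survivors[[1]], "best_C")))
})

test_that("GMT collections expand to per-set kernel specs", {
  gmt_file <- tempfile(fileext = ".gmt")
  writeLines(c("SET_A\tfirst pathway\tg1\tg2\tg3",
               "SET_B\tsecond pathway\tg2\tg4",
               "SET_C\tunmeasured pathway\tzz1\tzz2"), gmt_file)
  gmt <- read_gmt(gmt_file)
  expect_named(gmt$sets, c("SET_A", "SET_B", "SET_C"))
  measured <- c("g1", "g2", "g3", "g4", "g5")
  expect_warning(specs <- geneset_kernel_specs(measured, gmt,
                                               kernel_spec("linear")),
                 "dropped")
  expect_named(specs, c("SET_A", "SET_B"))
  expect_equal(specs$SET_B$features, c("g2", "g4"))
  expect_equal(attr(specs, "n_dropped"), 1L)
  # restriction consistency: per-set gram equals gram on the projected table
  set.seed(3)
  X <- matrix(rnorm(50), 10, 5, dimnames = list(NULL, measured))
  expect_equal(as.matrix(compute_gram(X, X, specs$SET_A)),
               as.matrix(compute_gram(X[, c("g1", "g2", "g3")], spec =
                                        kernel_spec("linear"))))
  writeLines("BAD\tonly two fields", gmt_file)
  expect_error(read_gmt(gmt_file), "malformed")
})

test_that("survival dichotomization respects the band and exclusion rules", {
  out <- dichotomize_survival(1:10, rep(1, 10), lo = 0.4, hi = 0.6)
  expect_equal(out$cutoff, 5.5)
  expect_equal(out$proportion, 0.5)
  expect_equal(sum(out$labels == 1), 5)
  # censored patients are excluded before anything else
  ev <- c(rep(1, 7), rep(0, 3))
  out2 <- dichotomize_survival(1:10, ev)
  expect_length(out2$kept, 7)
  expect_identical(out2$kept, which(ev == 1))
  expect_error(dichotomize_survival(rep(5, 10), rep(1, 10)), "same time")
  expect_error(dichotomize_survival(1:10, rep(1, 10), lo = 0.49, hi = 0.495),
               "proportion in")
  expect_error(dichotomize_survival(1:10, rep(0, 10)), "uncensored")
})

test_that("dichotomization always lands in the band or fails explicitly", {
  for (s in 1:20) {
    set.seed(s)
    time <- rlnorm(40, 5, 1)
    event <- rbinom(40, 1, 0.8)
    res <- tryCatch(dichotomize_survival(time, event), error = identity)
    if (!inherits(res, "error")) {
      expect_gte(res$proportion, 0.4)
      expect_lte(res$proportion, 0.6)
      expect_equal(unname(res$labels),
                   ifelse(time[res$kept] > res$cutoff, 1, -1))
    }
  }
})

test_that("the median heuristic returns a usable radial bandwidth", {
  set.seed(2)
  X <- matrix(rnorm(40), 20, 2)
  sig <- median_heuristic_sigma(X)
  expect_gt(sig, 0)
  expect_error(median_heuristic_sigma(matrix(1, 5, 2)), "undefined")
  menu <- ovarian_preset(paste0("g", 1:10), age_sigma = sig)
  expect_length(menu$expression, 4)
  expect_length(menu$clinical, 3)
  expect_s3_class(menu$clinical[[3]], "kernel_combo")
})
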