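# Independent oracles and small fixture generators shared across tests.

# Brute-force solution of the soft-margin SVM dual by a generic
# interior-point QP (kernlab::ipop) -- independent of the SMO path.
ipop_dual_objective <- function(K, y, C) {
  Q <- K * tcrossprod(y)
  ip <- kernlab::ipop(c = rep(-1, length(y)), H = Q,
                      A = matrix(as.numeric(y), 1), b = 0,
                      l = rep(0, length(y)), u = rep(C, length(y)),
                      r = 0, sigf = 8)
  a <- kernlab::primal(ip)
  sum(a) - 0.5 * drop(crossprod(a, Q %*% a))
}

# All simplex grid points with the given step for M kernels.
simplex_grid <- function(M, step = 0.05) {
  k <- round(1 / step)
  if (M == 1) return(matrix(1, 1, 1))
  pts <- list()
  rec <- function(prefix, left) {
    if (length(prefix) == M - 1) {
      pts[[length(pts) + 1L]] <<- c(prefix, left) * step
      return()
    }
    for (i in 0:left) rec(c(prefix, i), left - i)
  }
  rec(integer(0), k)
  do.call(rbind, pts)
}

# Best (smallest) combined-kernel SVM dual value over a coarse simplex grid:
# the brute-force oracle the MKL solvers must not be beaten by.
grid_best_objective <- function(mats, y, C, step = 0.05, tol = 1e-8) {
  W <- simplex_grid(length(mats), step)
  best <- Inf
  for (i in seq_len(nrow(W))) {
    K <- Reduce(`+`, Map(`*`, mats, W[i, ]))
    o <- solve_svm_dual(K, y, C = C, tol = tol)$objective
    if (o < best) best <- o
  }
  best
}

# Two Gaussian blobs in d dimensions, shifted by `shift` along every axis.
make_blobs <- function(n_per, d = 2, shift = 3, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * d), n_per, d),
             matrix(rnorm(n_per * d, mean = shift), n_per, d))
  colnames(X) <- paste0("f", seq_len(d))
  rownames(X) <- paste0("s", seq_len(2 * n_per))
  list(X = X, y = rep(c(-1, 1), each = n_per))
}

random_psd <- function(n, seed = NULL, ridge = 1e-6) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(n * n), n)
  crossprod(A) / n + diag(ridge, n)
}

# Random small MKL instance: M full-rank PSD grams + balanced-ish labels.
rand_mkl_instance <- function(n, M, seed) {
  set.seed(seed)
  mats <- replicate(M, random_psd(n), simplify = FALSE)
  y <- sample(c(-1, 1), n, replace = TRUE)
  if (length(unique(y)) < 2) y[1] <- -y[1]
  list(mats = mats, y = y)
}

min_eigenvalue <- function(M) {
  min(eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values)
}
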