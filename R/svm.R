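# Soft-margin SVM on a precomputed Gram matrix: dual solver, prediction,
# stratified cross-validation over kernel/cost grids, no-information rate.

# Map arbitrary two-class labels to {-1, +1}. Classes are sorted
# lexicographically; the first becomes -1, the second +1. Numeric -1/+1
# input is passed through unchanged.
encode_labels <- function(y) {
  if (!length(y)) stop("empty labels", call. = FALSE)
  if (is.numeric(y) && all(y %in% c(-1, 1))) {
    if (length(unique(y)) < 2L) stop("single-class labels", call. = FALSE)
    return(list(y = as.numeric(y), classes = c("-1", "1")))
  }
  cl <- sort(unique(as.character(y)))
  if (length(cl) < 2L) stop("single-class labels", call. = FALSE)
  if (length(cl) > 2L)
    stop("more than two classes; this is a binary classifier", call. = FALSE)
  list(y = ifelse(as.character(y) == cl[1], -1, 1), classes = cl)
}

decode_labels <- function(signs, classes) {
  out <- ifelse(signs >= 0, classes[2], classes[1])
  if (identical(classes, c("-1", "1"))) out <- as.numeric(out)
  out
}

#' Solve the soft-margin SVM dual for a fixed Gram matrix
#'
#' Maximizes the standard dual
#' \deqn{\sum_i \alpha_i - \tfrac12 \sum_{ij} \alpha_i\alpha_j y_i y_j K_{ij}}
#' subject to \eqn{0 \le \alpha_i \le C} and \eqn{\sum_i \alpha_i y_i = 0},
#' by sequential minimal optimization with maximal-violating-pair selection.
#' The cost `C` bounds the dual coefficients and so penalizes
#' misclassification (soft margin). The bias is recovered from unbounded
#' support vectors (averaged), or from the KKT interval midpoint when every
#' support vector sits on the box.
#'
#' @param gram square training Gram (a `gram` object or plain matrix),
#'   positive semidefinite.
#' @param y two-class labels; arbitrary labels are encoded lexicographically
#'   (first class \eqn{-1}, second \eqn{+1}).
#' @param C positive cost parameter.
#' @param tol KKT violation tolerance of the solver.
#' @param max_iter iteration safeguard.
#' @return An `svm_solution`: `alpha`, `b`, `objective` (attained dual
#'   value), `support_idx`, `C`, encoded `y`, class mapping, training ids,
#'   and solver diagnostics (`iterations`, `gap`, `converged`).
#' @examples
#' K <- compute_gram(matrix(c(-1, 1), 2, 1), spec = kernel_spec("linear"))
#' fit <- solve_svm_dual(K, c(-1, 1), C = 10)
#' fit$alpha  # the analytic max-margin solution (0.5, 0.5)
#' @export
solve_svm_dual <- function(gram, y, C = 1, tol = 1e-6, max_iter = 200000L) {
  V <- gram_values(gram)
  if (nrow(V) != ncol(V)) stop("training Gram must be square", call. = FALSE)
  enc <- encode_labels(y)
  if (length(enc$y) != nrow(V)) stop("labels do not match Gram size", call. = FALSE)
  if (!is.numeric(C) || length(C) != 1L || C <= 0)
    stop("'C' must be a single positive number", call. = FALSE)
  sol <- .smo_solve(V, enc$y, C, tol, as.integer(max_iter))
  if (!sol$converged)
    warning(sprintf("SMO stopped at max_iter with KKT gap %.3g (tol %.3g)",
                    sol$gap, tol))
  structure(list(alpha = sol$alpha, b = sol$b, objective = sol$objective,
                 support_idx = which(sol$alpha > 1e-8),
                 C = C, y = enc$y, classes = enc$classes,
                 ids = if (is_gram(gram)) gram$row_ids
                       else as.character(seq_len(nrow(V))),
                 iterations = sol$iterations, gap = sol$gap,
                 converged = sol$converged, tol = tol),
            class = "svm_solution")
}

#' @export
print.svm_solution <- function(x, ...) {
  cat(sprintf("<svm_solution> n = %d, C = %g, %d support vectors, dual objective %.6g\n",
              length(x$alpha), x$C, length(x$support_idx), x$objective))
  invisible(x)
}

#' Predict with a fitted SVM
#'
#' Decision values \eqn{f(x) = \sum_i \alpha_i y_i K(x, x_i) + b}; the label
#' is the sign of \eqn{f}, with ties (\eqn{f = 0}) mapped to the positive
#' class.
#'
#' @param model an [solve_svm_dual()] fit.
#' @param cross_gram rectangular Gram between new samples (rows) and the
#'   training samples (columns, in training order).
#' @return list with `decision` (numeric) and `labels` (on the original
#'   label scale).
#' @export
svm_predict <- function(model, cross_gram) {
  V <- gram_values(cross_gram)
  if (ncol(V) != length(model$alpha))
    stop("cross Gram columns do not match the training set", call. = FALSE)
  if (is_gram(cross_gram) && !identical(cross_gram$col_ids, model$ids))
    stop("cross Gram column ids do not match training ids", call. = FALSE)
  f <- drop(V %*% (model$alpha * model$y)) + model$b
  list(decision = f, labels = decode_labels(f, model$classes))
}

#' No-information rate
#'
#' The accuracy of always predicting the majority class; the baseline used
#' to screen candidate kernels.
#'
#' @param y nonempty label vector.
#' @return proportion of the majority class.
#' @export
no_information_rate <- function(y) {
  if (!length(y)) stop("empty labels", call. = FALSE)
  max(table(y)) / length(y)
}

# Stratified fold assignment: shuffle within class, deal round-robin, so
# class counts per fold differ by at most one.
make_folds <- function(y, k, seed) {
  if (k < 2) stop("need at least 2 folds", call. = FALSE)
  fold <- integer(length(y))
  set.seed(seed)
  for (cl in unique(as.character(y))) {
    idx <- which(as.character(y) == cl)
    idx <- if (length(idx) > 1) sample(idx) else idx
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validate SVM over a kernel / cost grid
#'
#' Stratified k-fold cross-validation of [solve_svm_dual()] for every
#' combination of candidate kernel and cost. The full Gram on `X` is
#' computed once per kernel and subset per fold (all kernels here are
#' pairwise, so this is leak-free).
#'
#' @param X sample-by-feature table.
#' @param y two-class labels.
#' @param specs list of [kernel_spec()] / [kernel_combo()] candidates (a
#'   single spec is accepted).
#' @param C_grid cost values to try; default `c(0.01, 0.1, 1, 10, 100)`.
#' @param k number of folds (default 10).
#' @param seed integer seed controlling fold assignment.
#' @param tol SVM solver tolerance.
#' @return A `cv_result`: `grid` (one row per spec x C with mean/sd
#'   accuracy), `best` (row index of the best cell; ties go to the first,
#'   i.e. smaller C), `folds`, `seed`, `specs`.
#' @export
cross_validate_svm <- function(X, y, specs, C_grid = c(0.01, 0.1, 1, 10, 100),
                               k = 10, seed = 1, tol = 1e-6) {
  if (inherits(specs, c("kernel_spec", "kernel_combo"))) specs <- list(specs)
  n <- nrow(X)
  if (n < 2 * k) stop("need n >= 2k samples for k-fold CV", call. = FALSE)
  enc <- encode_labels(y)
  fold <- make_folds(enc$y, k, seed)
  acc <- array(NA_real_, dim = c(length(specs), length(C_grid), k))
  correct <- array(NA_real_, dim = dim(acc))
  for (s in seq_along(specs)) {
    Kfull <- gram_values(compute_gram(X, X, specs[[s]]))
    for (f in seq_len(k)) {
      tr <- which(fold != f)
      te <- which(fold == f)
      if (length(unique(enc$y[tr])) < 2)
        stop("a class is absent from a training fold; n is too small for k folds",
             call. = FALSE)
      for (ci in seq_along(C_grid)) {
        m <- solve_svm_dual(Kfull[tr, tr, drop = FALSE], enc$y[tr],
                            C = C_grid[ci], tol = tol)
        p <- svm_predict(m, Kfull[te, tr, drop = FALSE])
        correct[s, ci, f] <- sum(p$labels == enc$y[te])
        acc[s, ci, f] <- correct[s, ci, f] / length(te)
      }
    }
  }
  grid <- expand.grid(spec = seq_along(specs), C = C_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$spec_name <- vapply(specs, function(s) s$name %||% "kernel", "")[grid$spec]
  # cell accuracy is POOLED over folds (total correct / n): with unequal
  # fold sizes the plain mean of fold accuracies is biased, e.g. a
  # majority-class predictor would not score exactly the NIR
  grid$mean_acc <- mapply(function(s, ci) sum(correct[s, ci, ]) / n,
                          grid$spec, match(grid$C, C_grid))
  grid$sd_acc <- mapply(function(s, ci) sd(acc[s, ci, ]),
                        grid$spec, match(grid$C, C_grid))
  structure(list(grid = grid, best = which.max(grid$mean_acc),
                 folds = fold, seed = seed, specs = specs, k = k),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  b <- x$grid[x$best, ]
  cat(sprintf("<cv_result> %d kernels x %d costs, %d folds; best: %s, C = %g, accuracy %.3f\n",
              length(x$specs), length(unique(x$grid$C)), x$k,
              b$spec_name, b$C, b$mean_acc))
  invisible(x)
}
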