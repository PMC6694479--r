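# Wrapper-method MKL: alternate full SVM solves with kernel-weight updates
# on the probability simplex. Both solvers minimize, over the simplex,
# J(eta) = max_alpha { sum(alpha) - 0.5 alpha' (yy' * sum_m eta_m K_m) alpha },
# the optimal SVM dual value of the combined kernel.

# Shared state for one wrapper fit: aligned matrices + encoded labels.
mkl_setup <- function(grams, y) {
  al <- align_grams(grams)
  if (length(unique(c(vapply(al$mats, nrow, 0L), vapply(al$mats, ncol, 0L)))) != 1)
    stop("training Gram matrices must be square and aligned", call. = FALSE)
  enc <- encode_labels(y)
  if (length(enc$y) != nrow(al$mats[[1]]))
    stop("labels do not match Gram size", call. = FALSE)
  specs <- lapply(grams, function(g)
    if (is_gram(g) && is.list(g$spec)) g$spec else list(kind = "matrix", name = "matrix"))
  c(al, list(enc = enc, specs = specs, M = length(al$mats)))
}

combined_solve <- function(st, eta, C, tol) {
  V <- matrix(0, length(st$enc$y), length(st$enc$y))
  for (m in seq_len(st$M)) if (eta[m] > 0) V <- V + eta[m] * st$mats[[m]]
  sol <- solve_svm_dual(V, st$enc$y, C = C, tol = tol)
  sol$ids <- st$row_ids
  sol
}

# S_m = (alpha*y)' K_m (alpha*y); the per-kernel quadratic forms behind both
# the SEMKL norm update and the SimpleMKL gradient g_m = -S_m / 2.
kernel_quadforms <- function(st, svm) {
  v <- svm$alpha * st$enc$y
  vapply(st$mats, function(K) drop(crossprod(v, K %*% v)), 0)
}

# Zero numerically dead weights and renormalize onto the simplex.
clean_weights <- function(eta, floor = 1e-8) {
  eta[eta < floor] <- 0
  if (sum(eta) <= 0) stop("all kernel weights collapsed to zero", call. = FALSE)
  eta / sum(eta)
}

new_mkl_model <- function(method, weights, svm, st, trace, converged) {
  structure(list(method = method, weights = weights, svm = svm,
                 specs = st$specs, ids = st$row_ids, classes = st$enc$classes,
                 trace = trace, converged = converged),
            class = "mkl_model")
}

#' @export
print.mkl_model <- function(x, ...) {
  cat(sprintf("<mkl_model> %s, %d kernels, %d samples, objective %.6g, converged: %s\n",
              x$method, length(x$weights), length(x$svm$alpha),
              x$svm$objective, x$converged))
  cat("weights:", paste(sprintf("%.4f", x$weights), collapse = " "), "\n")
  invisible(x)
}

#' SEMKL: closed-form kernel-weight updates
#'
#' Simple and efficient MKL. Alternates (i) a soft-margin SVM solve on the
#' combined kernel \eqn{K(\eta) = \sum_m \eta_m K_m} and (ii) the explicit
#' weight update derived from the Cauchy-Schwarz inequality,
#' \deqn{\eta_m \leftarrow \|f_m\| / \sum_k \|f_k\|, \qquad
#'       \|f_m\|^2 = \eta_m^2\, \alpha^T (yy^T \circ K_m)\, \alpha,}
#' which keeps the weights on the probability simplex and drives the
#' combined dual objective downhill without any line search.
#'
#' @param grams list of aligned square training Gram matrices (`gram`
#'   objects or plain matrices).
#' @param y two-class labels.
#' @param C positive SVM cost.
#' @param max_iter iteration cap (default 100).
#' @param tol stop when `max(abs(diff(eta)))` falls below this (default 1e-4).
#' @param svm_tol tolerance passed to the inner SVM solver.
#' @return An `mkl_model` with simplex `weights`, the embedded
#'   `svm_solution` for the final combined kernel, a per-iteration `trace`
#'   (weights, objective, weight change) and an honest `converged` flag.
#' @references Xu et al. (2010), "Simple and efficient multiple kernel
#'   learning by group lasso"-style closed-form updates.
#' @export
semkl_fit <- function(grams, y, C = 1, max_iter = 100, tol = 1e-4,
                      svm_tol = 1e-6) {
  st <- mkl_setup(grams, y)
  eta <- rep(1 / st$M, st$M)
  trace <- vector("list", 0L)
  converged <- FALSE
  svm <- combined_solve(st, eta, C, svm_tol)
  for (it in seq_len(max_iter)) {
    S <- kernel_quadforms(st, svm)
    norms <- eta * sqrt(pmax(S, 0))          # ||f_m|| = eta_m sqrt(S_m)
    if (sum(norms) <= 0)
      stop("degenerate SVM solution: all per-kernel function norms are zero",
           call. = FALSE)
    eta_new <- clean_weights(norms / sum(norms))
    delta <- max(abs(eta_new - eta))
    eta <- eta_new
    svm <- combined_solve(st, eta, C, svm_tol)
    trace[[it]] <- data.frame(iter = it, objective = svm$objective,
                              delta = delta,
                              t(setNames(eta, paste0("eta", seq_len(st$M)))))
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!length(trace))  # M = 1 or max_iter = 0 corner: record the fit as-is
    trace[[1]] <- data.frame(iter = 0L, objective = svm$objective, delta = 0,
                             t(setNames(eta, paste0("eta", seq_len(st$M)))))
  if (st$M == 1L) converged <- TRUE
  new_mkl_model("semkl", eta, svm, st, do.call(rbind, trace), converged)
}

#' SimpleMKL: reduced-gradient descent with line search
#'
#' Minimizes the combined SVM dual value \eqn{J(\eta)} over the probability
#' simplex. At the current weights the SVM is solved once, giving the
#' gradient \eqn{g_m = -\tfrac12 \alpha^T (yy^T \circ K_m) \alpha}; the
#' gradient is reduced against the largest-weight component (ties broken by
#' lowest index) so that steps stay on the simplex, descent components that
#' would drive a zero weight negative are clipped, and a line search along
#' the resulting direction (golden section on the feasible segment, falling
#' back to backtracking where the first improving step is accepted) picks
#' the step size. Each line-search candidate requires one SVM solve.
#' Terminates when the relative duality gap
#' \eqn{(\max_m S_m/2 - \sum_m \eta_m S_m/2)/|J|} drops below `tol_gap`, the
#' direction vanishes, or the SVM-solve budget is exhausted.
#'
#' @inheritParams semkl_fit
#' @param max_iter maximum number of inner SVM solves (default 200).
#' @param tol_gap relative duality-gap tolerance (default 0.01).
#' @return An `mkl_model`; `trace` reports weights, objective and gap per
#'   outer iteration, `converged` is `FALSE` on budget exhaustion or
#'   line-search failure.
#' @references Rakotomamonjy et al. (2008), "SimpleMKL", JMLR 9.
#' @export
simplemkl_fit <- function(grams, y, C = 1, max_iter = 200, tol_gap = 0.01,
                          svm_tol = 1e-6) {
  st <- mkl_setup(grams, y)
  M <- st$M
  eta <- rep(1 / M, M)
  solves <- 0L
  solve_at <- function(eta) {
    solves <<- solves + 1L
    combined_solve(st, eta, C, svm_tol)
  }
  svm <- solve_at(eta)
  trace <- list()
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    S <- kernel_quadforms(st, svm)
    J <- svm$objective
    gap <- (max(S) / 2 - sum(eta * S) / 2) / max(abs(J), 1e-12)
    trace[[it]] <- data.frame(iter = it, solves = solves, objective = J,
                              gap = gap,
                              t(setNames(eta, paste0("eta", seq_len(M)))))
    if (M == 1L || gap <= tol_gap) { converged <- TRUE; break }
    if (solves >= max_iter) break

    g <- -S / 2
    reduced_dir <- function(eta) {
      mu <- which.max(eta)                    # ties -> lowest index (which.max)
      D <- -(g - g[mu])
      D[eta <= 1e-12 & D < 0] <- 0            # don't push dead weights negative
      D[mu] <- 0
      D[mu] <- -sum(D)
      D
    }
    max_step <- function(eta, D) {
      neg <- which(D < -1e-15)
      if (length(neg)) max(min(-eta[neg] / D[neg]), 0) else 1
    }
    proj <- function(eta, gam, D) {
      w <- pmax(eta + gam * D, 0)
      w[w < 1e-12] <- 0                       # boundary steps land exactly on 0
      clean_weights(w, floor = 0)
    }

    # descent-direction update: take full steps while they keep improving,
    # zeroing the weight that saturates and re-reducing the direction
    eta_cur <- eta; J_cur <- J; svm_cur <- svm
    improved <- FALSE
    D <- reduced_dir(eta_cur)
    while (max(abs(D)) > 1e-12 && solves < max_iter) {
      gamma_max <- max_step(eta_cur, D)
      if (gamma_max <= 0) break
      cand_eta <- proj(eta_cur, gamma_max, D)
      cand <- solve_at(cand_eta)
      if (cand$objective < J_cur - 1e-12) {
        eta_cur <- cand_eta; J_cur <- cand$objective; svm_cur <- cand
        improved <- TRUE
        D <- reduced_dir(eta_cur)
      } else break
    }
    if (max(abs(D)) < 1e-12 && !improved) { converged <- TRUE; break }

    # golden-section line search along the last direction on [0, gamma_max]
    gamma_max <- max_step(eta_cur, D)
    if (max(abs(D)) > 1e-12 && gamma_max > 0 && solves < max_iter) {
      phi <- function(gam) {
        s <- solve_at(proj(eta_cur, gam, D))
        list(J = s$objective, svm = s, gam = gam)
      }
      gr <- (sqrt(5) - 1) / 2
      a <- 0; bnd <- gamma_max
      x1 <- bnd - gr * (bnd - a); x2 <- a + gr * (bnd - a)
      f1 <- phi(x1); f2 <- phi(x2)
      for (ls in seq_len(8)) {
        if (solves >= max_iter) break
        if (f1$J <= f2$J) { bnd <- x2; x2 <- x1; f2 <- f1
                            x1 <- bnd - gr * (bnd - a); f1 <- phi(x1) }
        else              { a <- x1; x1 <- x2; f1 <- f2
                            x2 <- a + gr * (bnd - a); f2 <- phi(x2) }
      }
      best <- if (f1$J <= f2$J) f1 else f2
      if (best$J < J_cur - 1e-12) {
        eta_cur <- proj(eta_cur, best$gam, D); J_cur <- best$J
        svm_cur <- best$svm
        improved <- TRUE
      } else if (!improved) {
        # fallback: backtracking from the maximal step, first improvement wins
        gam <- gamma_max
        for (bt in seq_len(12)) {
          if (solves >= max_iter) break
          cand <- phi(gam)
          if (cand$J < J_cur - 1e-12) {
            eta_cur <- proj(eta_cur, gam, D); J_cur <- cand$J
            svm_cur <- cand$svm
            improved <- TRUE
            break
          }
          gam <- gam / 2
        }
      }
    }
    if (!improved) break                      # line-search failure: stop, not converged
    eta <- eta_cur
    svm <- svm_cur
    if (solves >= max_iter) break
  }
  eta <- clean_weights(eta)
  new_mkl_model("simplemkl", eta, svm, st, do.call(rbind, trace), converged)
}

#' Predict with a fitted MKL model
#'
#' Combines the rectangular test-by-train Gram matrices with the learned
#' kernel weights and applies the embedded SVM (wrapper methods), or sums
#' the per-kernel function blocks (DAL models).
#'
#' @param model an `mkl_model` ([semkl_fit()], [simplemkl_fit()]) or
#'   `dal_model` ([dalmkl_fit()]).
#' @param cross_grams list of rectangular Gram matrices, aligned with the
#'   training kernels (same order) and training sample ids.
#' @return list with `decision` values and `labels`.
#' @export
mkl_predict <- function(model, cross_grams) UseMethod("mkl_predict")

#' @export
mkl_predict.mkl_model <- function(model, cross_grams) {
  al <- align_grams(cross_grams)
  if (length(al$mats) != length(model$weights))
    stop("need one cross Gram per training kernel", call. = FALSE)
  if (!identical(al$col_ids, model$ids) &&
      !identical(al$col_ids, as.character(seq_along(model$ids))))
    stop("cross Gram column ids do not match training ids", call. = FALSE)
  K <- combine_grams(al$mats, model$weights)
  p <- svm_predict(model$svm, gram_values(K))
  p$labels <- decode_labels(p$decision, model$classes)
  p
}
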