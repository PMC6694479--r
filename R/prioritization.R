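# Workflow stages upstream of the MKL fit: rank features by two-group
# tests, keep the top k, screen candidate kernels against the
# no-information rate, expand gene-set collections into per-set kernels,
# and dichotomize survival into a binary outcome.

#' Rank features by two-group differential tests
#'
#' Per-feature Welch t-test (unequal variances) or Wilcoxon rank-sum test
#' between the two label groups; features are ordered by ascending p-value,
#' ties broken by feature id. Features that are constant across all samples
#' cannot be tested: they are kept with p-value 1 and flagged, never
#' silently dropped.
#'
#' @param X sample-by-feature numeric table.
#' @param y two-class labels, at least two samples per class.
#' @param method `"ttest"` (Welch) or `"wilcoxon"`.
#' @return A `feature_ranking`: data frame with `feature`, `statistic`,
#'   `p_value`, `flag` (`"constant"` where untestable), sorted by p-value;
#'   attribute `method`.
#' @export
rank_features <- function(X, y, method = c("ttest", "wilcoxon")) {
  method <- match.arg(method)
  enc <- encode_labels(y)
  if (min(table(enc$y)) < 2)
    stop("need at least two samples per class", call. = FALSE)
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("features must be numeric", call. = FALSE)
  if (nrow(X) != length(enc$y)) stop("labels do not match table rows", call. = FALSE)
  feats <- colnames(X) %||% as.character(seq_len(ncol(X)))
  g1 <- enc$y < 0
  res <- vapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    if (var(x) == 0) return(c(NA_real_, 1, 1))       # constant overall
    if (var(x[g1]) == 0 && var(x[!g1]) == 0)          # constant within groups
      return(c(Inf, 0, 0))                            # but separated: p -> 0
    out <- if (method == "ttest")
      tryCatch(t.test(x[g1], x[!g1]),
               error = function(e) list(statistic = NA_real_, p.value = 1))
    else
      suppressWarnings(wilcox.test(x[g1], x[!g1], exact = FALSE))
    c(unname(out$statistic), out$p.value, 0)
  }, numeric(3))
  df <- data.frame(feature = feats, statistic = res[1, ], p_value = res[2, ],
                   flag = ifelse(res[3, ] == 1, "constant", ""),
                   stringsAsFactors = FALSE)
  df <- df[order(df$p_value, df$feature), ]
  rownames(df) <- NULL
  structure(df, class = c("feature_ranking", "data.frame"), method = method)
}

#' Keep the top-ranked features
#'
#' @param ranking a [rank_features()] result.
#' @param k number of features to keep, `1 <= k <= nrow(ranking)`.
#' @return character vector of the first `k` feature ids in ranking order
#'   (prefix-consistent: the top 10 are the first 10 of the top 65).
#' @export
select_top_features <- function(ranking, k) {
  stopifnot(inherits(ranking, "feature_ranking"))
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > nrow(ranking))
    stop(sprintf("'k' must be between 1 and %d", nrow(ranking)), call. = FALSE)
  ranking$feature[seq_len(as.integer(k))]
}

#' Screen candidate kernels against the no-information rate
#'
#' Runs [cross_validate_svm()] for each candidate over the cost grid and
#' keeps, per candidate, the best (spec, C) cell by cross-validated
#' accuracy. Candidates whose best accuracy does not exceed the
#' no-information rate are eliminated: a kernel that merely reproduces the
#' majority-class guess (accuracy equal to the NIR) carries no usable
#' signal. Survivors carry their selected cost into MKL via the
#' `"best_C"` attribute on each spec.
#'
#' @inheritParams cross_validate_svm
#' @param candidates list of [kernel_spec()] / [kernel_combo()] candidates.
#' @param folds number of CV folds (default 10).
#' @return A `kernel_screen`: `table` (one row per candidate: name, best C,
#'   CV accuracy, survived), `survivors` (list of surviving specs with
#'   `best_C` attributes), `nir`, `seed`. Raises a condition of class
#'   `no_surviving_kernels` when every candidate is eliminated.
#' @export
screen_kernels <- function(X, y, candidates, C_grid = c(0.01, 0.1, 1, 10, 100),
                           folds = 10, seed = 1) {
  if (inherits(candidates, c("kernel_spec", "kernel_combo")))
    candidates <- list(candidates)
  nir <- no_information_rate(y)
  rows <- vector("list", length(candidates))
  survivors <- list()
  for (i in seq_along(candidates)) {
    cv <- cross_validate_svm(X, y, candidates[[i]], C_grid = C_grid,
                             k = folds, seed = seed)
    best <- cv$grid[cv$best, ]
    survived <- best$mean_acc > nir
    rows[[i]] <- data.frame(candidate = candidates[[i]]$name %||% paste0("k", i),
                            best_C = best$C, cv_acc = best$mean_acc,
                            survived = survived, stringsAsFactors = FALSE)
    if (survived) {
      sp <- candidates[[i]]
      attr(sp, "best_C") <- best$C
      survivors[[length(survivors) + 1L]] <- sp
    }
  }
  tab <- do.call(rbind, rows)
  if (!length(survivors))
    stop(structure(class = c("no_surviving_kernels", "error", "condition"),
                   list(message = sprintf(
                     "no candidate kernel beat the no-information rate (%.3f)", nir),
                     call = sys.call())))
  structure(list(table = tab, survivors = survivors, nir = nir, seed = seed),
            class = "kernel_screen")
}

#' @export
print.kernel_screen <- function(x, ...) {
  cat(sprintf("<kernel_screen> NIR %.3f: %d of %d candidates survived\n",
              x$nir, length(x$survivors), nrow(x$table)))
  print(x$table)
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Tab-separated, one set per line: name, description, then gene ids.
#'
#' @param path GMT file path.
#' @return A `gene_set_collection`: named list `sets` of gene-id vectors
#'   plus a parallel `description` vector. Set names must be unique.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 0L) < 3L
  if (any(bad))
    stop(sprintf("malformed GMT line(s): %s", paste(which(bad), collapse = ", ")),
         call. = FALSE)
  nm <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(nm)) stop("duplicated gene-set names in GMT", call. = FALSE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  names(sets) <- nm
  if (any(!lengths(sets))) stop("empty gene set(s) in GMT", call. = FALSE)
  structure(list(sets = sets,
                 description = setNames(vapply(parts, `[[`, "", 2L), nm)),
            class = "gene_set_collection")
}

#' One kernel spec per gene set
#'
#' Intersects each gene set with the measured genes and instantiates the
#' base kernel restricted to that subset, so that each pathway contributes
#' one candidate kernel. Sets with no measured genes are dropped with a
#' warning (the count is reported in the `"n_dropped"` attribute).
#'
#' @param expression_genes character vector of measured gene ids.
#' @param sets a [read_gmt()] collection (or named list of gene-id vectors).
#' @param base a [kernel_spec()] template; its `features` field is replaced
#'   per set.
#' @return named list of `kernel_spec`s, one per nonempty intersection.
#' @export
geneset_kernel_specs <- function(expression_genes, sets, base) {
  if (inherits(sets, "gene_set_collection")) sets <- sets$sets
  stopifnot(inherits(base, "kernel_spec"), length(sets) > 0)
  out <- list()
  dropped <- 0L
  for (nm in names(sets)) {
    feats <- intersect(sets[[nm]], expression_genes)
    if (!length(feats)) { dropped <- dropped + 1L; next }
    sp <- base
    sp$features <- feats
    sp$name <- paste0(nm, " [", base$kind, ", ", length(feats), " genes]")
    out[[nm]] <- sp
  }
  if (dropped)
    warning(sprintf("%d gene set(s) had no measured genes and were dropped", dropped))
  if (!length(out))
    stop("no gene set intersects the measured genes", call. = FALSE)
  attr(out, "n_dropped") <- dropped
  out
}

#' Median-heuristic radial bandwidth
#'
#' A rule-of-thumb bandwidth for radial kernels,
#' \eqn{\sigma = 1 / \mathrm{median}(\|x_i - x_j\|^2)}, computed on the
#' training rows only.
#'
#' @param X numeric sample-by-feature table.
#' @return positive `sigma` for [kernel_spec()].
#' @export
median_heuristic_sigma <- function(X) {
  d2 <- as.numeric(dist(as.matrix(X)))^2
  m <- median(d2[d2 > 0])
  if (!is.finite(m) || m <= 0)
    stop("median heuristic undefined: all pairwise distances are zero", call. = FALSE)
  1 / m
}

#' Dichotomize survival into a binary outcome
#'
#' Right-censored patients are excluded first (their class at any cutoff is
#' unknown). A cutoff is then chosen among midpoints of consecutive distinct
#' observed event times such that the proportion surviving past the cutoff
#' lies within `[lo, hi]`; among feasible cutoffs the one whose proportion
#' is closest to 0.5 is selected (ties: the smaller cutoff). Note the
#' resulting analysis ignores the censoring mechanism entirely and is in
#' that sense biased; it trades that bias for a simple binary target.
#'
#' @param time positive survival/follow-up times.
#' @param event event indicator, 1 = death observed, 0 = right-censored.
#' @param lo,hi admissible band for the survivor proportion
#'   (defaults 0.4, 0.6).
#' @param min_kept minimum number of uncensored patients required.
#' @return list with `labels` (+1 survived past the cutoff, -1 otherwise),
#'   `cutoff`, `kept` (indices of uncensored patients), and `proportion`
#'   (survivor proportion among kept patients).
#' @export
dichotomize_survival <- function(time, event, lo = 0.4, hi = 0.6,
                                 min_kept = 2) {
  stopifnot(length(time) == length(event))
  if (any(time <= 0)) stop("survival times must be positive", call. = FALSE)
  if (!(lo < hi && lo > 0 && hi < 1))
    stop("need 0 < lo < hi < 1", call. = FALSE)
  kept <- which(event == 1)
  if (length(kept) < min_kept)
    stop(sprintf("only %d uncensored patients (< %d required)",
                 length(kept), min_kept), call. = FALSE)
  t_kept <- time[kept]
  ut <- sort(unique(t_kept))
  if (length(ut) < 2)
    stop("no feasible cutoff: all events occur at the same time", call. = FALSE)
  cutoffs <- (ut[-length(ut)] + ut[-1]) / 2
  props <- vapply(cutoffs, function(ct) mean(t_kept > ct), 0)
  feasible <- props >= lo & props <= hi
  if (!any(feasible))
    stop(sprintf("no cutoff gives a survivor proportion in [%.2f, %.2f]", lo, hi),
         call. = FALSE)
  pick <- which(feasible)[order(abs(props[feasible] - 0.5),
                                cutoffs[feasible])][1]
  list(labels = ifelse(t_kept > cutoffs[pick], 1, -1),
       cutoff = cutoffs[pick], kept = kept, proportion = props[pick])
}

#' Ovarian-style kernel menu preset
#'
#' The candidate menu used in the worked clinical + expression example: for
#' the expression block a linear kernel and three radial kernels
#' (\eqn{\sigma \in \{10^{-4}, 10^{-3}, 10^{-2}\}}); for the clinical block
#' an ordinal kernel on tumour stage, a radial kernel on standardized age
#' with a median-heuristic bandwidth, and their equal-weight average as a
#' third candidate.
#'
#' @param expression_features feature ids of the expression block.
#' @param stage_levels ordered stage labels (default `I < II < III < IV`).
#' @param age_sigma radial bandwidth for the (standardized) age kernel;
#'   compute it on the training ages with [median_heuristic_sigma()].
#' @param stage_col,age_col clinical column names.
#' @return named list with `expression` and `clinical` candidate lists.
#' @export
ovarian_preset <- function(expression_features,
                           stage_levels = c("I", "II", "III", "IV"),
                           age_sigma = 1, stage_col = "stage",
                           age_col = "age") {
  expr <- c(list(kernel_spec("linear", features = expression_features)),
            lapply(c(1e-4, 1e-3, 1e-2), function(s)
              kernel_spec("radial", sigma = s, features = expression_features)))
  stage <- kernel_spec("clinical_ordinal", levels = stage_levels,
                       features = stage_col, name = "stage ordinal")
  age <- kernel_spec("radial", sigma = age_sigma, features = age_col,
                     name = "age radial")
  list(expression = expr,
       clinical = list(stage, age, kernel_combo(list(stage, age),
                                                name = "stage+age average")))
}
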