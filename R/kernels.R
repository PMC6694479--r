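#' Declare a kernel
#'
#' A `kernel_spec` is a declarative description of one similarity measure:
#' its family, the hyperparameters of that family, and the feature subset it
#' reads. Five families are supported:
#'
#' * `linear`: \eqn{K(x,y) = x^T y}
#' * `polynomial`: \eqn{K(x,y) = (\nu x^T y + c)^a} with degree `a`,
#'   scale \eqn{\nu} and offset `c`
#' * `radial`: \eqn{K(x,y) = \exp(-\sigma \|x-y\|^2 / 2)}; `sigma` controls
#'   the smoothness of the induced decision boundary (small `sigma`, smooth
#'   boundary). Set `rbf_half = FALSE` for the alternative convention
#'   \eqn{\exp(-\sigma \|x-y\|^2)} used by some kernel libraries.
#' * `clinical_nominal`: per feature, 1 if the two values are equal and 0
#'   otherwise; with several features the indicator is averaged.
#' * `clinical_ordinal`: per feature, \eqn{(r - |x - y|)/r} on integer level
#'   codes, where `r` is the range of the ordinal levels; averaged across
#'   features. Supply either `range` directly (numeric codes expected) or
#'   `levels` (character data mapped to codes `1..L`, `r` defaults to
#'   `L - 1`).
#'
#' @param kind kernel family, one of `"linear"`, `"polynomial"`, `"radial"`,
#'   `"clinical_nominal"`, `"clinical_ordinal"`.
#' @param sigma positive bandwidth of the radial kernel.
#' @param degree,scale,offset polynomial hyperparameters: positive integer
#'   degree \eqn{a \ge 1}, positive scale \eqn{\nu} (default 1), real offset
#'   (default 1).
#' @param range positive range `r` of the ordinal levels.
#' @param levels ordered level labels for ordinal/nominal features; ordinal
#'   data are mapped to consecutive integer codes in this order.
#' @param features character vector (or integer indices) of the columns this
#'   kernel reads; `NULL` means all columns of the table it is applied to.
#' @param normalize cosine-normalize the Gram matrix,
#'   \eqn{K_{ij}/\sqrt{K_{ii} K_{jj}}}; only meaningful (and only allowed)
#'   for linear and polynomial kernels.
#' @param rbf_half logical; keep the `/2` in the radial exponent (default
#'   `TRUE`).
#' @param name optional label used in reports; auto-generated otherwise.
#'
#' @return An object of class `kernel_spec`.
#' @examples
#' kernel_spec("radial", sigma = 2)
#' kernel_spec("clinical_ordinal", levels = c("I", "II", "III", "IV"))
#' @export
kernel_spec <- function(kind = c("linear", "polynomial", "radial",
                                 "clinical_nominal", "clinical_ordinal"),
                        sigma = NULL, degree = NULL, scale = NULL,
                        offset = NULL, range = NULL, levels = NULL,
                        features = NULL, normalize = FALSE, rbf_half = TRUE,
                        name = NULL) {
  kind <- match.arg(kind)
  chk_pos <- function(x, what) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
      stop(sprintf("'%s' must be a single positive number", what), call. = FALSE)
    x
  }
  forbid <- function(vals, names) {
    bad <- names[!vapply(vals, is.null, logical(1))]
    if (length(bad))
      stop(sprintf("hyperparameter(s) %s not used by kernel kind '%s'",
                   paste(sQuote(bad), collapse = ", "), kind), call. = FALSE)
  }
  spec <- list(kind = kind, features = features,
               normalize = isTRUE(normalize), levels = levels)
  switch(kind,
    linear = {
      forbid(list(sigma, degree, scale, offset, range, levels),
             c("sigma", "degree", "scale", "offset", "range", "levels"))
    },
    polynomial = {
      forbid(list(sigma, range, levels), c("sigma", "range", "levels"))
      if (is.null(degree)) stop("polynomial kernel requires 'degree'", call. = FALSE)
      chk_pos(degree, "degree")
      if (degree != round(degree) || degree < 1)
        stop("'degree' must be a positive integer (a >= 1)", call. = FALSE)
      spec$degree <- as.integer(degree)
      spec$scale <- if (is.null(scale)) 1 else chk_pos(scale, "scale")
      spec$offset <- if (is.null(offset)) 1 else {
        if (!is.numeric(offset) || length(offset) != 1L || !is.finite(offset))
          stop("'offset' must be a single real number", call. = FALSE)
        offset
      }
    },
    radial = {
      forbid(list(degree, scale, offset, range, levels),
             c("degree", "scale", "offset", "range", "levels"))
      if (is.null(sigma)) stop("radial kernel requires 'sigma'", call. = FALSE)
      spec$sigma <- chk_pos(sigma, "sigma")
      spec$rbf_half <- isTRUE(rbf_half)
    },
    clinical_nominal = {
      forbid(list(sigma, degree, scale, offset, range),
             c("sigma", "degree", "scale", "offset", "range"))
    },
    clinical_ordinal = {
      forbid(list(sigma, degree, scale, offset),
             c("sigma", "degree", "scale", "offset"))
      if (is.null(range) && is.null(levels))
        stop("clinical_ordinal kernel requires 'range' or 'levels'", call. = FALSE)
      if (!is.null(levels) && length(levels) < 2L)
        stop("'levels' must list at least two ordered levels", call. = FALSE)
      spec$range <- if (!is.null(range)) chk_pos(range, "range")
                    else length(levels) - 1
    }
  )
  if (spec$normalize && !kind %in% c("linear", "polynomial"))
    stop("'normalize' is only available for linear and polynomial kernels",
         call. = FALSE)
  spec$name <- if (!is.null(name)) as.character(name) else default_spec_name(spec)
  structure(spec, class = "kernel_spec")
}

default_spec_name <- function(spec) {
  base <- switch(spec$kind,
    linear = "linear",
    polynomial = sprintf("polynomial(a=%d,scale=%g,offset=%g)",
                         spec$degree, spec$scale, spec$offset),
    radial = sprintf("radial(sigma=%g)", spec$sigma),
    clinical_nominal = "nominal",
    clinical_ordinal = sprintf("ordinal(r=%g)", spec$range))
  if (!is.null(spec$features))
    base <- paste0(base, "[", length(spec$features), " features]")
  base
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat("<kernel_spec>", x$name,
      if (x$normalize) "(cosine-normalized)" else "", "\n")
  invisible(x)
}

#' Combine several kernels into one composite candidate
#'
#' A composite kernel is the weighted sum of its member kernels' Gram
#' matrices (a convex combination of kernels is again a kernel). It can be
#' used anywhere a [kernel_spec()] is accepted, e.g. the equal-weight average
#' of a stage kernel and an age kernel as a single clinical candidate.
#'
#' @param specs list of [kernel_spec()] objects.
#' @param weights nonnegative weights, recycled to `length(specs)`;
#'   default equal weights.
#' @param name optional label.
#' @return An object of class `kernel_combo`.
#' @export
kernel_combo <- function(specs, weights = NULL, name = NULL) {
  if (!length(specs) || !all(vapply(specs, inherits, logical(1), "kernel_spec")))
    stop("'specs' must be a nonempty list of kernel_spec objects", call. = FALSE)
  if (is.null(weights)) weights <- rep(1 / length(specs), length(specs))
  if (length(weights) != length(specs) || any(weights < 0))
    stop("'weights' must be nonnegative, one per spec", call. = FALSE)
  structure(list(kind = "combined", specs = specs, weights = weights,
                 name = if (is.null(name))
                   paste0("avg(", paste(vapply(specs, `[[`, "", "name"),
                                        collapse = " + "), ")")
                 else as.character(name)),
            class = "kernel_combo")
}

#' @export
print.kernel_combo <- function(x, ...) {
  cat("<kernel_combo>", x$name, "\n")
  invisible(x)
}

sample_ids <- function(tab) {
  rn <- rownames(tab)
  if (is.null(rn)) as.character(seq_len(nrow(tab))) else rn
}

resolve_features <- function(tab, features) {
  if (is.null(features)) return(colnames(tab) %||% seq_len(ncol(tab)))
  if (is.numeric(features)) {
    if (any(features < 1 | features > ncol(tab)))
      stop("feature indices out of range", call. = FALSE)
    return(features)
  }
  missing <- setdiff(features, colnames(tab))
  if (length(missing))
    stop(sprintf("features not found in table: %s",
                 paste(head(missing, 5), collapse = ", ")), call. = FALSE)
  features
}

`%||%` <- function(a, b) if (is.null(a)) b else a

numeric_block <- function(tab, features, what) {
  x <- as.matrix(as.data.frame(tab)[, features, drop = FALSE])
  if (!is.numeric(x))
    stop(sprintf("%s kernels require numeric features", what), call. = FALSE)
  storage.mode(x) <- "double"
  x
}

#' Compute a Gram matrix
#'
#' Evaluates the kernel declared by `spec` between every row of `rows` and
#' every row of `cols`, restricted to the spec's feature subset. With
#' `cols = rows` the result is the square, symmetric training Gram; with a
#' held-out table in `rows` it is the rectangular test-by-train matrix used
#' for prediction.
#'
#' @param rows,cols sample-by-feature tables (matrix or data frame; row
#'   names are used as sample identifiers).
#' @param spec a [kernel_spec()] or [kernel_combo()].
#' @return A `gram` object: the numeric matrix plus row/column identifiers
#'   and the generating spec. Use [as.matrix()] to extract the values.
#' @examples
#' X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("f1", "f2")))
#' K <- compute_gram(X, spec = kernel_spec("radial", sigma = 2))
#' dim(K)
#' @export
compute_gram <- function(rows, cols = rows, spec) {
  UseMethod("compute_gram", spec)
}

#' @export
compute_gram.kernel_combo <- function(rows, cols = rows, spec) {
  grams <- lapply(spec$specs, function(s) compute_gram(rows, cols, s))
  out <- combine_grams(grams, spec$weights)
  out$spec <- spec
  out
}

#' @export
compute_gram.kernel_spec <- function(rows, cols = rows, spec) {
  if (is.null(dim(rows)) || is.null(dim(cols)))
    stop("'rows' and 'cols' must be matrices or data frames", call. = FALSE)
  feats <- resolve_features(rows, spec$features)
  resolve_features(cols, spec$features)
  same <- identical(dim(rows), dim(cols)) && isTRUE(all.equal(rows, cols))

  K <- switch(spec$kind,
    linear = {
      X <- numeric_block(rows, feats, "linear")
      Y <- numeric_block(cols, feats, "linear")
      V <- tcrossprod(X, Y)
      if (spec$normalize) V <- cosine_normalize(V, rowSums(X^2), rowSums(Y^2))
      V
    },
    polynomial = {
      X <- numeric_block(rows, feats, "polynomial")
      Y <- numeric_block(cols, feats, "polynomial")
      V <- (spec$scale * tcrossprod(X, Y) + spec$offset)^spec$degree
      if (spec$normalize)
        V <- cosine_normalize(V,
                              (spec$scale * rowSums(X^2) + spec$offset)^spec$degree,
                              (spec$scale * rowSums(Y^2) + spec$offset)^spec$degree)
      V
    },
    radial = {
      X <- numeric_block(rows, feats, "radial")
      Y <- numeric_block(cols, feats, "radial")
      d2 <- pmax(outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y), 0)
      exp(-spec$sigma * d2 / (if (spec$rbf_half) 2 else 1))
    },
    clinical_nominal = gram_categorical(rows, cols, feats, spec, ordinal = FALSE),
    clinical_ordinal = gram_categorical(rows, cols, feats, spec, ordinal = TRUE)
  )
  if (same) K <- (K + t(K)) / 2   # kill floating-point asymmetry
  new_gram(K, sample_ids(rows), sample_ids(cols), spec)
}

cosine_normalize <- function(V, kr, kc) {
  if (any(kr <= 0) || any(kc <= 0))
    stop("cosine normalization undefined: zero self-similarity", call. = FALSE)
  V / sqrt(outer(kr, kc))
}

gram_categorical <- function(rows, cols, feats, spec, ordinal) {
  rows <- as.data.frame(rows)[, feats, drop = FALSE]
  cols <- as.data.frame(cols)[, feats, drop = FALSE]
  acc <- 0
  for (j in seq_along(feats)) {
    x <- rows[[j]]
    y <- cols[[j]]
    if (ordinal) {
      if (!is.null(spec$levels)) {
        x <- level_codes(x, spec$levels)
        y <- level_codes(y, spec$levels)
      } else if (!is.numeric(x) || !is.numeric(y)) {
        stop("ordinal kernel without 'levels' requires numeric level codes",
             call. = FALSE)
      }
      span <- max(x, y) - min(x, y)
      if (span > spec$range + 1e-8)
        stop(sprintf("ordinal codes span %.3g, larger than range r = %g",
                     span, spec$range), call. = FALSE)
      acc <- acc + (spec$range - abs(outer(x, y, "-"))) / spec$range
    } else {
      acc <- acc + (outer(as.character(x), as.character(y), "==")) * 1
    }
  }
  acc / length(feats)
}

level_codes <- function(x, levels) {
  codes <- match(as.character(x), levels)
  if (anyNA(codes))
    stop(sprintf("value(s) not in declared levels: %s",
                 paste(unique(x[is.na(codes)]), collapse = ", ")), call. = FALSE)
  as.numeric(codes)
}

new_gram <- function(values, row_ids, col_ids, spec) {
  stopifnot(nrow(values) == length(row_ids), ncol(values) == length(col_ids))
  dimnames(values) <- list(row_ids, col_ids)
  structure(list(values = values, row_ids = row_ids, col_ids = col_ids,
                 spec = spec),
            class = "gram")
}

#' @export
as.matrix.gram <- function(x, ...) x$values

#' @export
dim.gram <- function(x) dim(x$values)

#' @export
print.gram <- function(x, ...) {
  nm <- if (is.list(x$spec) && !is.null(x$spec$name)) x$spec$name else "combined"
  cat(sprintf("<gram> %d x %d, kernel: %s\n", nrow(x$values), ncol(x$values), nm))
  invisible(x)
}

is_gram <- function(x) inherits(x, "gram")

gram_values <- function(x) if (is_gram(x)) x$values else as.matrix(x)

#' Weighted sum of Gram matrices
#'
#' Forms \eqn{\sum_m \eta_m K_m}. A convex combination of positive
#' semidefinite kernels is again positive semidefinite, so the result is a
#' valid kernel whenever the inputs are.
#'
#' @param grams list of [compute_gram()] results (or plain matrices) sharing
#'   identical row and column identifiers.
#' @param weights nonnegative weights, one per Gram matrix.
#' @return A `gram` object whose spec records the weights used.
#' @export
combine_grams <- function(grams, weights) {
  al <- align_grams(grams)
  if (length(weights) != length(grams))
    stop("need one weight per Gram matrix", call. = FALSE)
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("weights must be finite and nonnegative", call. = FALSE)
  V <- matrix(0, length(al$row_ids), length(al$col_ids))
  for (m in seq_along(al$mats)) V <- V + weights[m] * al$mats[[m]]
  new_gram(V, al$row_ids, al$col_ids,
           list(kind = "combined", weights = weights, name = "combined",
                members = lapply(grams, function(g)
                  if (is_gram(g) && is.list(g$spec)) g$spec$name %||% "combined"
                  else "matrix")))
}

# Check a list of grams/matrices is mutually aligned; return plain matrices.
align_grams <- function(grams) {
  if (!length(grams)) stop("empty list of Gram matrices", call. = FALSE)
  if (is_gram(grams) || is.matrix(grams)) grams <- list(grams)
  mats <- lapply(grams, gram_values)
  d <- dim(mats[[1]])
  row_ids <- if (is_gram(grams[[1]])) grams[[1]]$row_ids
             else rownames(mats[[1]]) %||% as.character(seq_len(d[1]))
  col_ids <- if (is_gram(grams[[1]])) grams[[1]]$col_ids
             else colnames(mats[[1]]) %||% as.character(seq_len(d[2]))
  for (g in grams) {
    if (!identical(dim(gram_values(g)), d))
      stop("Gram matrices have mismatched dimensions", call. = FALSE)
    if (is_gram(g) &&
        (!identical(g$row_ids, row_ids) || !identical(g$col_ids, col_ids)))
      stop("Gram matrices have mismatched sample identifiers", call. = FALSE)
  }
  list(mats = mats, row_ids = row_ids, col_ids = col_ids)
}

#' Check (and repair) positive semidefiniteness
#'
#' Verifies that a square symmetric Gram matrix is positive semidefinite up
#' to numerical tolerance (smallest eigenvalue no less than
#' `-tol` times the largest). If it is not, `jitter` is added to the
#' diagonal and the repair is reported via a message and the
#' `"psd_repaired"` attribute.
#'
#' @param gram square `gram` object or matrix.
#' @param jitter diagonal ridge added when the check fails.
#' @param tol relative eigenvalue tolerance: eigenvalues above `-tol` times
#'   the spectral scale are attributed to floating-point rounding of an
#'   exactly-PSD matrix and left alone.
#' @return The (possibly repaired) `gram`, with attribute `psd_repaired`.
#' @export
validate_psd <- function(gram, jitter = 1e-8, tol = 1e-13) {
  V <- gram_values(gram)
  if (nrow(V) != ncol(V)) stop("Gram matrix must be square", call. = FALSE)
  if (max(abs(V - t(V))) > 1e-8) stop("Gram matrix is not symmetric", call. = FALSE)
  ev <- eigen((V + t(V)) / 2, symmetric = TRUE, only.values = TRUE)$values
  scale <- max(abs(ev), 1)
  repaired <- min(ev) < -tol * scale
  if (repaired) {
    message(sprintf("Gram not PSD (min eigenvalue %.3g); adding jitter %g to diagonal",
                    min(ev), jitter))
    V <- V + diag(jitter, nrow(V))
    if (is_gram(gram)) gram$values <- V else gram <- V
  }
  attr(gram, "psd_repaired") <- repaired
  gram
}

#' Read a sample-by-feature table
#'
#' CSV/TSV with a header row of feature names and the sample identifier in
#' the first column.
#'
#' @param path file path; fields separated by comma (`.csv`) or tab
#'   otherwise.
#' @return data frame with sample ids as row names.
#' @export
read_feature_table <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- read.csv(path, sep = sep, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) stop("duplicated sample identifiers in ", path, call. = FALSE)
  out <- tab[, -1, drop = FALSE]
  rownames(out) <- ids
  out
}

#' Write / read a Gram matrix as CSV
#'
#' Sample identifiers are stored as header (columns) and first column (rows).
#'
#' @param gram a `gram` object.
#' @param path output file.
#' @return `write_gram` returns `path` invisibly; `read_gram` returns a
#'   `gram` object (spec recorded as `"deserialized"`).
#' @export
write_gram <- function(gram, path) {
  stopifnot(is_gram(gram))
  df <- data.frame(sample_id = gram$row_ids, gram$values, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gram
#' @export
read_gram <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  V <- as.matrix(df[, -1, drop = FALSE])
  new_gram(V, as.character(df[[1]]), colnames(df)[-1],
           list(kind = "deserialized", name = "deserialized"))
}
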