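# End-to-end workflow: validate a YAML/JSON run configuration, then execute
# split -> feature ranking/selection -> kernel menu -> NIR screening ->
# MKL fit -> held-out evaluation, writing all artifacts and a log that makes
# the run reproducible from its manifest alone.

run_config_defaults <- list(
  method = "semkl",
  train_frac = 0.7,
  folds = 10,
  C_grid = c(0.01, 0.1, 1, 10, 100),
  C = 1,
  dal_loss = "hinge",
  dal_C = 0.05,
  top_features = NULL,
  rank_method = "ttest",
  survival_band = c(0.4, 0.6),
  out_dir = "mkl_run"
)

#' Validate and resolve a workflow configuration
#'
#' Reads a YAML or JSON configuration (or takes a list), fills in declared
#' defaults, validates every kernel entry through [kernel_spec()], and
#' records the provenance (`"user"` or `"default"`) of every field. A seed
#' is generated and recorded when absent, so every accepted configuration is
#' fully reproducible.
#'
#' Schema (fields under `kernels` are passed to [kernel_spec()]):
#' ```
#' data:
#'   expression: expr.csv      # sample-by-feature table(s)
#'   clinical: clinical.csv    # optional
#'   labels: labels.csv        # two columns: sample_id, label
#'   survival: surv.csv        # optional: sample_id, time, event
#'   gmt: sets.gmt             # optional gene sets
#' kernels:
#'   - {kind: radial, sigma: 0.01, source: expression}
#'   - {kind: clinical_ordinal, levels: [I, II, III, IV], features: [stage],
#'      source: clinical}
#' method: semkl               # semkl | simplemkl | dalmkl
#' train_frac: 0.7
#' folds: 10
#' seed: 42
#' out_dir: run1/
#' ```
#'
#' @param config path to a `.yml`/`.yaml`/`.json` file, or a list.
#' @return A `run_config` with attribute `provenance`.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a file path or a list", call. = FALSE)
  known <- c(names(run_config_defaults), "data", "kernels", "seed")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "), call. = FALSE)

  provenance <- setNames(rep("user", length(names(config))), names(config))
  for (f in names(run_config_defaults)) {
    if (is.null(config[[f]])) {
      config[[f]] <- run_config_defaults[[f]]
      provenance[f] <- "default"
    }
  }
  if (is.null(config$seed)) {
    config$seed <- sample.int(1e6, 1)
    provenance["seed"] <- "generated"
  }
  if (!config$method %in% c("semkl", "simplemkl", "dalmkl"))
    stop("field 'method': must be semkl, simplemkl or dalmkl", call. = FALSE)
  if (!is.numeric(config$train_frac) || config$train_frac <= 0 ||
      config$train_frac >= 1)
    stop("field 'train_frac': must be in (0, 1)", call. = FALSE)
  if (!is.numeric(config$folds) || config$folds < 2)
    stop("field 'folds': must be an integer >= 2", call. = FALSE)

  if (!is.null(config$data)) {
    for (f in intersect(names(config$data),
                        c("expression", "clinical", "labels", "survival", "gmt")))
      if (!file.exists(config$data[[f]]))
        stop(sprintf("field 'data.%s': file not found: %s", f, config$data[[f]]),
             call. = FALSE)
  }
  if (!is.null(config$kernels)) {
    config$kernels <- lapply(seq_along(config$kernels), function(i) {
      k <- config$kernels[[i]]
      src <- k$source %||% "expression"
      k$source <- NULL
      if (!is.null(k$features)) k$features <- unlist(k$features)
      if (!is.null(k$levels)) k$levels <- unlist(k$levels)
      sp <- tryCatch(do.call(kernel_spec, k), error = function(e)
        stop(sprintf("field 'kernels[%d]': %s", i, conditionMessage(e)),
             call. = FALSE))
      attr(sp, "source") <- src
      sp
    })
  }
  structure(config, class = "run_config", provenance = provenance)
}

#' Serialize a run configuration to YAML
#'
#' Round-trips with [validate_config()]: validating the serialized file
#' yields an equivalent configuration.
#'
#' @param config a `run_config`.
#' @param path output `.yml` path.
#' @return `path`, invisibly.
#' @export
serialize_config <- function(config, path) {
  out <- unclass(config)
  if (!is.null(out$kernels))
    out$kernels <- lapply(out$kernels, function(sp) {
      k <- Filter(Negate(is.null),
                  sp[setdiff(names(sp), c("name", "rbf_half"))])
      k$normalize <- if (isTRUE(sp$normalize)) TRUE else NULL
      k$source <- attr(sp, "source")
      Filter(Negate(is.null), k)
    })
  yaml::write_yaml(out, path)
  invisible(path)
}

workflow_log <- function(lines, path) {
  writeLines(lines, path)
  invisible(path)
}

#' Run the full MKL workflow
#'
#' Executes the recommended MKL experiment end to end on the configured
#' data: stratified train/test split, feature ranking and selection on the
#' training rows only, kernel menu construction (including gene-set kernels
#' when a GMT file is configured), per-kernel SVM screening against the
#' no-information rate, MKL fit on the survivors, and held-out evaluation.
#'
#' Artifacts written to `out_dir`: `model.json` (weights, dual
#' coefficients, bias, specs, trace), `weights.csv` (kernel importance),
#' `metrics.json` (held-out accuracy, NIR, sizes), `screening.csv`,
#' `manifest.yml` (the fully resolved configuration, seeds included) and
#' `log.txt` (label encoding, NIR, eliminated kernels, PSD repairs, final
#' weights).
#'
#' @param config a [validate_config()] result (or anything it accepts).
#' @param data optionally, an in-memory list with elements `tables` (named
#'   list of sample-by-feature tables), `labels`, and optionally `gmt`;
#'   bypasses the file paths in `config$data`.
#' @return list with the fitted `model`, `screen`, `metrics`, `split`, and
#'   `artifact` paths, invisibly.
#' @export
run_workflow <- function(config, data = NULL) {
  config <- validate_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("seed: %d", config$seed),
                 sprintf("method: %s", config$method))

  # ---- assemble data
  if (is.null(data)) {
    if (is.null(config$data))
      stop("no data configured and none supplied", call. = FALSE)
    tables <- list()
    for (src in intersect(names(config$data), c("expression", "clinical")))
      tables[[src]] <- read_feature_table(config$data[[src]])
    gmt <- if (!is.null(config$data$gmt)) read_gmt(config$data$gmt)
    if (!is.null(config$data$labels)) {
      lab <- read.csv(config$data$labels, stringsAsFactors = FALSE)
      labels <- setNames(lab[[2]], as.character(lab[[1]]))
      keep_ids <- rownames(tables[[1]])
    } else if (!is.null(config$data$survival)) {
      surv <- read.csv(config$data$survival, stringsAsFactors = FALSE)
      ds <- dichotomize_survival(surv$time, surv$event,
                                 lo = config$survival_band[1],
                                 hi = config$survival_band[2])
      keep_ids <- as.character(surv[[1]][ds$kept])
      labels <- setNames(ds$labels, keep_ids)
      log_lines <- c(log_lines,
                     sprintf("survival dichotomized at %.4g (survivor proportion %.3f); %d censored patients excluded",
                             ds$cutoff, ds$proportion, nrow(surv) - length(ds$kept)))
    } else stop("config$data needs 'labels' or 'survival'", call. = FALSE)
    tables <- lapply(tables, function(tb) tb[keep_ids, , drop = FALSE])
    y <- unname(labels[keep_ids])
  } else {
    tables <- data$tables
    y <- data$labels
    gmt <- data$gmt
    keep_ids <- rownames(tables[[1]])
  }
  enc <- encode_labels(y)
  log_lines <- c(log_lines,
                 sprintf("label encoding: %s -> -1, %s -> +1",
                         enc$classes[1], enc$classes[2]))

  # ---- stratified split
  n <- length(y)
  set.seed(config$seed)
  tr <- sort(unlist(lapply(unique(enc$y), function(cl) {
    idx <- which(enc$y == cl)
    sample(idx, round(length(idx) * config$train_frac))
  })))
  te <- setdiff(seq_len(n), tr)
  log_lines <- c(log_lines, sprintf("split: %d train / %d test (train_frac %.2f)",
                                    length(tr), length(te), config$train_frac))

  # ---- feature selection on training rows only
  specs <- config$kernels %||%
    list(structure(kernel_spec("linear"), source = "expression"))
  if (!is.null(config$top_features) && !is.null(tables$expression)) {
    rk <- rank_features(tables$expression[tr, , drop = FALSE], y[tr],
                        method = config$rank_method)
    top <- select_top_features(rk, min(config$top_features, nrow(rk)))
    log_lines <- c(log_lines, sprintf("feature ranking (%s): kept top %d of %d",
                                      config$rank_method, length(top), nrow(rk)))
    specs <- lapply(specs, function(sp) {
      if (identical(attr(sp, "source"), "expression") &&
          !inherits(sp, "kernel_combo") && is.null(sp$features))
        sp$features <- top
      sp
    })
  }
  if (!is.null(gmt) && !is.null(tables$expression)) {
    base <- kernel_spec("linear")
    gs <- geneset_kernel_specs(colnames(tables$expression), gmt, base)
    gs <- lapply(gs, function(sp) { attr(sp, "source") <- "expression"; sp })
    specs <- c(specs, gs)
  }

  # ---- screening against the NIR (training rows only)
  source_table <- function(sp) tables[[attr(sp, "source") %||% "expression"]]
  Xtr_for <- function(sp) source_table(sp)[tr, , drop = FALSE]
  screen_rows <- list(); survivors <- list()
  nir <- no_information_rate(y[tr])
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    res <- tryCatch(screen_kernels(Xtr_for(sp), y[tr], sp,
                                   C_grid = config$C_grid,
                                   folds = config$folds, seed = config$seed),
                    no_surviving_kernels = function(e) e)
    if (inherits(res, "no_surviving_kernels")) {
      cv <- cross_validate_svm(Xtr_for(sp), y[tr], sp, C_grid = config$C_grid,
                               k = config$folds, seed = config$seed)
      best <- cv$grid[cv$best, ]
      screen_rows[[i]] <- data.frame(candidate = sp$name, best_C = best$C,
                                     cv_acc = best$mean_acc, survived = FALSE,
                                     stringsAsFactors = FALSE)
    } else {
      screen_rows[[i]] <- res$table
      sv <- res$survivors[[1]]
      attr(sv, "source") <- attr(sp, "source")
      survivors[[length(survivors) + 1L]] <- sv
    }
  }
  screen_tab <- do.call(rbind, screen_rows)
  screen_tab$nir <- nir
  eliminated <- screen_tab$candidate[!screen_tab$survived]
  log_lines <- c(log_lines, sprintf("no-information rate: %.4f", nir),
                 if (length(eliminated))
                   paste0("eliminated: ",
                          paste(sprintf("%s (acc %.3f)", eliminated,
                                        screen_tab$cv_acc[!screen_tab$survived]),
                                collapse = "; "))
                 else "eliminated: none")
  if (!length(survivors))
    stop(structure(class = c("no_surviving_kernels", "error", "condition"),
                   list(message = "no surviving kernels after screening; not fitting MKL",
                        call = sys.call())))

  # ---- Gram construction (with PSD validation) and MKL fit
  psd_repairs <- 0L
  train_grams <- lapply(survivors, function(sp) {
    g <- compute_gram(source_table(sp)[tr, , drop = FALSE], spec = sp)
    g <- withCallingHandlers(validate_psd(g),
      message = function(m) invokeRestart("muffleMessage"))
    if (isTRUE(attr(g, "psd_repaired"))) psd_repairs <<- psd_repairs + 1L
    g
  })
  cross_grams <- lapply(survivors, function(sp)
    compute_gram(source_table(sp)[te, , drop = FALSE],
                 source_table(sp)[tr, , drop = FALSE], sp))
  log_lines <- c(log_lines, sprintf("PSD repairs: %d", psd_repairs))

  model <- switch(config$method,
    semkl = semkl_fit(train_grams, y[tr], C = config$C),
    simplemkl = simplemkl_fit(train_grams, y[tr], C = config$C),
    dalmkl = dalmkl_fit(train_grams, y[tr],
                        dal_config(config$dal_loss, C = config$dal_C)))

  pred <- mkl_predict(model, cross_grams)
  acc <- mean(pred$labels == y[te])
  metrics <- list(test_accuracy = acc, nir_train = nir,
                  n_train = length(tr), n_test = length(te),
                  n_kernels = length(survivors), method = config$method,
                  converged = model$converged, seed = config$seed)
  log_lines <- c(log_lines,
                 sprintf("final weights: %s",
                         paste(sprintf("%s=%.6f",
                                       vapply(survivors, `[[`, "", "name"),
                                       model$weights), collapse = ", ")),
                 sprintf("held-out accuracy: %.4f", acc))

  # ---- artifacts
  weights_df <- data.frame(kernel = vapply(survivors, `[[`, "", "name"),
                           weight = round(model$weights, 6))
  paths <- list(model = file.path(out_dir, "model.json"),
                weights = file.path(out_dir, "weights.csv"),
                metrics = file.path(out_dir, "metrics.json"),
                screening = file.path(out_dir, "screening.csv"),
                manifest = file.path(out_dir, "manifest.yml"),
                log = file.path(out_dir, "log.txt"))
  jsonlite::write_json(model_to_json(model, survivors), paths$model,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write.csv(weights_df, paths$weights, row.names = FALSE)
  jsonlite::write_json(metrics, paths$metrics, auto_unbox = TRUE, digits = NA)
  write.csv(screen_tab, paths$screening, row.names = FALSE)
  serialize_config(config, paths$manifest)
  workflow_log(log_lines, paths$log)

  invisible(list(model = model, screen = screen_tab, metrics = metrics,
                 split = list(train = keep_ids[tr], test = keep_ids[te]),
                 artifacts = paths))
}

# Versioned JSON view of a fitted model (schema_version bumps on change).
model_to_json <- function(model, specs) {
  base <- list(schema_version = 1L, method = model$method,
               weights = round(model$weights, 6),
               kernels = vapply(specs, `[[`, "", "name"),
               classes = model$classes, ids = model$ids,
               converged = model$converged,
               trace = model$trace)
  if (inherits(model, "dal_model")) {
    base$bias <- model$b
    base$alpha <- model$alpha
    base$active <- model$active
    base$beta <- model$beta
  } else {
    base$bias <- model$svm$b
    base$alpha <- model$svm$alpha
    base$objective <- model$svm$objective
  }
  base
}
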