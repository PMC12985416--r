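# Tree-ensemble pathogenicity classifiers: final fits, nested
# cross-validation with TPE hyperparameter search, and the
# full-vs-reduced feature ablation.

as_binary_label <- function(label) {
  if (is.logical(label)) return(as.integer(label))
  if (is.numeric(label) && all(label %in% c(0, 1))) return(as.integer(label))
  x <- toupper(as.character(label))
  if (!all(x %in% c("PATHOGENIC", "BENIGN"))) {
    abort("labels must be PATHOGENIC/BENIGN (or 0/1)")
  }
  as.integer(x == "PATHOGENIC")
}

feature_columns <- function(data) {
  setdiff(names(data), c("variant_id", "gene", "label", "accession",
                         "position", "wt_aa", "var_aa"))
}

# stratified k-fold assignment, deterministic given the RNG state
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Default hyperparameter search space
#'
#' Random forest: number of trees 100-1000, maximum depth 3-30 or
#' unlimited, minimum node size 1-10, feature-subset rule sqrt/log2 or a
#' fraction in 0.3-1. Gradient boosting: rounds 100-1000, learning rate
#' log-uniform in 0.001-0.3, depth 2-10, row subsample 0.5-1, column
#' subsample 0.5-1.
#'
#' @param algorithm `"rf"` or `"xgb"`.
#' @return Named list of [param_def()]s.
#' @export
default_search_space <- function(algorithm = c("rf", "xgb")) {
  algorithm <- arg_match(algorithm)
  if (algorithm == "rf") {
    list(
      num_trees = param_def("int", 100, 1000),
      max_depth = param_def("int", 3, 31), # 31 means unlimited
      min_node_size = param_def("int", 1, 10),
      mtry_mode = param_def("categorical", values = c("sqrt", "log2", "frac")),
      mtry_frac = param_def("uniform", 0.3, 1.0)
    )
  } else {
    list(
      nrounds = param_def("int", 100, 1000),
      eta = param_def("loguniform", 0.001, 0.3),
      max_depth = param_def("int", 2, 10),
      subsample = param_def("uniform", 0.5, 1.0),
      colsample_bytree = param_def("uniform", 0.5, 1.0)
    )
  }
}

resolve_mtry <- function(mode, frac, p) {
  switch(mode %||% "sqrt",
         sqrt = max(1L, floor(sqrt(p))),
         log2 = max(1L, floor(log2(p))),
         frac = max(1L, round((frac %||% 0.5) * p)))
}

fit_engine <- function(X, y, algorithm, hp, seed) {
  if (algorithm == "rf") {
    depth <- hp$max_depth %||% 31
    ranger::ranger(
      x = X, y = factor(y, levels = c(0, 1)),
      probability = TRUE,
      num.trees = hp$num_trees %||% 500,
      max.depth = if (depth >= 31) 0 else depth,
      min.node.size = hp$min_node_size %||% 5,
      mtry = resolve_mtry(hp$mtry_mode, hp$mtry_frac, ncol(X)),
      importance = "impurity",
      seed = seed, num.threads = 1
    )
  } else {
    set.seed(seed)
    xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    eta = hp$eta %||% 0.1,
                    max_depth = hp$max_depth %||% 6,
                    subsample = hp$subsample %||% 1,
                    colsample_bytree = hp$colsample_bytree %||% 1,
                    nthread = 1, base_score = 0.5),
      data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
      nrounds = hp$nrounds %||% 300, verbose = 0
    )
  }
}

predict_engine <- function(fit, algorithm, X) {
  if (algorithm == "rf") {
    unname(predict(fit, data = as.data.frame(X),
                   num.threads = 1)$predictions[, "1"])
  } else {
    as.numeric(predict(fit, xgboost::xgb.DMatrix(X, nthread = 1)))
  }
}

#' Fit a final pathogenicity classifier
#'
#' Refits the chosen algorithm on the full supplied training data (typically
#' after hyperparameter selection by [nested_cv()]) and returns a model
#' bundle carrying the feature schema, hyperparameters and a training
#' manifest.
#'
#' @param data Feature tibble with a `label` column (PATHOGENIC/BENIGN or
#'   0/1) and feature columns; id columns (`variant_id`, `gene`) are
#'   ignored for fitting.
#' @param algorithm `"rf"` (random forest, ranger) or `"xgb"` (gradient
#'   boosting, xgboost).
#' @param hyperparameters Named list within [default_search_space()];
#'   missing entries take defaults.
#' @param seed Integer seed; the fit is deterministic given it.
#' @param decision_threshold Probability cutoff for binary calls
#'   (default 0.5).
#' @return A `pathopred_model` bundle.
#' @export
fit_final <- function(data, algorithm = c("rf", "xgb"),
                      hyperparameters = list(), seed = 1L,
                      decision_threshold = 0.5) {
  algorithm <- arg_match(algorithm)
  if (nrow(data) == 0) abort("empty training data")
  if (decision_threshold <= 0 || decision_threshold >= 1) {
    abort("`decision_threshold` must lie in (0, 1)")
  }
  y <- as_binary_label(data$label)
  feats <- feature_columns(data)
  X <- as.matrix(data[, feats])
  fit <- fit_engine(X, y, algorithm, hyperparameters, seed)
  structure(
    list(algorithm = algorithm, fit = fit, feature_schema = feats,
         schema_name = attr(data, "schema") %||% NA_character_,
         hyperparameters = hyperparameters,
         decision_threshold = decision_threshold,
         manifest = list(n_train = nrow(data),
                         class_counts = as.list(table(y)),
                         seed = as.integer(seed))),
    class = "pathopred_model"
  )
}

#' @export
print.pathopred_model <- function(x, ...) {
  cat(sprintf("<pathopred_model> %s on %d features (n_train = %d, seed = %d)\n",
              x$algorithm, length(x$feature_schema), x$manifest$n_train,
              x$manifest$seed))
  invisible(x)
}

#' Predict pathogenicity probabilities
#'
#' @param model A `pathopred_model`.
#' @param newdata Tibble or matrix carrying at least the model's feature
#'   columns; a missing feature column is a schema-mismatch error.
#' @return Numeric vector of scores in \[0, 1\], one per row. Calls are
#'   `score > decision_threshold`.
#' @export
predict_proba <- function(model, newdata) {
  stopifnot(inherits(model, "pathopred_model"))
  missing <- setdiff(model$feature_schema, colnames(newdata))
  if (length(missing) > 0) {
    abort(sprintf("feature schema mismatch: missing column(s) %s",
                  paste(missing, collapse = ", ")))
  }
  X <- as.matrix(as.data.frame(newdata)[, model$feature_schema, drop = FALSE])
  predict_engine(model$fit, model$algorithm, X)
}

#' @export
predict.pathopred_model <- function(object, newdata,
                                    type = c("prob", "class"), ...) {
  type <- arg_match(type)
  p <- predict_proba(object, newdata)
  if (type == "prob") p else as.integer(p > object$decision_threshold)
}

#' Serialize / restore a model bundle
#'
#' Writes the bundle as a directory holding a JSON manifest (algorithm,
#' schema, hyperparameters, training manifest) alongside the estimator
#' blob. Gradient-boosting estimators are stored via xgboost's own raw
#' format so they survive across sessions.
#'
#' @param model A `pathopred_model`.
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(algorithm = model$algorithm, feature_schema = model$feature_schema,
         schema_name = model$schema_name,
         hyperparameters = model$hyperparameters,
         decision_threshold = model$decision_threshold,
         manifest = model$manifest),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  if (model$algorithm == "xgb") {
    writeBin(xgboost::xgb.save.raw(model$fit), file.path(dir, "estimator.bin"))
  } else {
    saveRDS(model$fit, file.path(dir, "estimator.rds"))
  }
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  fit <- if (man$algorithm == "xgb") {
    path <- file.path(dir, "estimator.bin")
    xgboost::xgb.load.raw(readBin(path, "raw", file.size(path)))
  } else {
    readRDS(file.path(dir, "estimator.rds"))
  }
  structure(
    list(algorithm = man$algorithm, fit = fit,
         feature_schema = man$feature_schema,
         schema_name = man$schema_name,
         hyperparameters = as.list(man$hyperparameters),
         decision_threshold = man$decision_threshold,
         manifest = as.list(man$manifest)),
    class = "pathopred_model"
  )
}

#' Nested cross-validation with Bayesian hyperparameter search
#'
#' A stratified outer loop estimates generalization performance; inside
#' every outer training fold a stratified inner loop drives a TPE search
#' (objective: mean inner-fold AUROC). The winning configuration is refit
#' on the outer training fold and scored once on the outer test fold.
#' Hyperparameter search never touches outer-test rows.
#'
#' @inheritParams fit_final
#' @param outer_k Outer folds (default 5).
#' @param inner_k Inner folds (default 3).
#' @param n_trials Search trials per outer fold (default 150).
#' @param search_space Named list of [param_def()]s; defaults to
#'   [default_search_space()] for the algorithm.
#' @return A `nested_cv` object: `fold_metrics` tibble (one row per outer
#'   fold), `summary` (mean and sd per metric), `best_params` per fold,
#'   `outer_fold` assignment vector, plus the call settings.
#' @export
nested_cv <- function(data, algorithm = c("rf", "xgb"), outer_k = 5L,
                      inner_k = 3L, n_trials = 150L, seed = 1L,
                      search_space = NULL) {
  algorithm <- arg_match(algorithm)
  if (n_trials < 1) abort("`n_trials` must be at least 1")
  y <- as_binary_label(data$label)
  if (min(table(y)) < outer_k) {
    abort("fewer samples in a class than outer folds; cannot stratify")
  }
  space <- search_space %||% default_search_space(algorithm)
  feats <- feature_columns(data)
  X <- as.matrix(data[, feats])

  set.seed(seed)
  outer_fold <- stratified_folds(y, outer_k)
  fold_rows <- vector("list", outer_k)
  best_params <- vector("list", outer_k)
  inner_indices <- vector("list", outer_k)

  for (k in seq_len(outer_k)) {
    tr <- which(outer_fold != k)
    te <- which(outer_fold == k)
    ytr <- y[tr]

    objective <- function(hp) {
      set.seed(seed * 131L + k)
      inner <- stratified_folds(ytr, inner_k)
      aucs <- map_dbl(seq_len(inner_k), function(j) {
        itr <- tr[inner != j]
        ite <- tr[inner == j]
        inner_indices[[k]] <<- sort(unique(c(inner_indices[[k]], itr, ite)))
        fit <- fit_engine(X[itr, , drop = FALSE], y[itr], algorithm, hp,
                          seed = seed * 977L + k * 31L + j)
        auroc(y[ite], predict_engine(fit, algorithm, X[ite, , drop = FALSE]))
      })
      -mean(aucs)
    }
    res <- tpe_optimize(objective, space, n_trials,
                        seed = seed * 7919L + k,
                        n_startup = min(10L, max(1L, n_trials %/% 3L)))
    best_params[[k]] <- res$best_params

    fit <- fit_engine(X[tr, , drop = FALSE], y[tr], algorithm,
                      res$best_params, seed = seed * 104729L %% 2147483L + k)
    scores <- predict_engine(fit, algorithm, X[te, , drop = FALSE])
    m <- compute_metrics(y[te], scores)
    fold_rows[[k]] <- bind_cols(tibble(fold = k), m)
  }

  fold_metrics <- list_rbind(fold_rows)
  met_cols <- c("auroc", "f1", "precision", "recall", "mcc", "accuracy")
  summ <- tibble(
    metric = met_cols,
    mean = map_dbl(met_cols, ~ mean(fold_metrics[[.x]])),
    sd = map_dbl(met_cols, ~ sd(fold_metrics[[.x]]))
  )
  structure(
    list(fold_metrics = fold_metrics, summary = summ,
         best_params = best_params, outer_fold = outer_fold,
         inner_indices = inner_indices,
         algorithm = algorithm, outer_k = outer_k, inner_k = inner_k,
         n_trials = n_trials, seed = as.integer(seed)),
    class = "nested_cv"
  )
}

#' @export
print.nested_cv <- function(x, ...) {
  cat(sprintf("<nested_cv> %s, %d x %d folds, %d trials/fold\n",
              x$algorithm, x$outer_k, x$inner_k, x$n_trials))
  auc <- x$summary[x$summary$metric == "auroc", ]
  cat(sprintf("  mean outer AUROC %.3f +/- %.3f\n", auc$mean, auc$sd))
  invisible(x)
}

#' Full-vs-reduced feature ablation under identical folds
#'
#' Runs the same cross-validation procedure — identical outer fold
#' assignment, identical search settings — on a full and a reduced feature
#' matrix and reports the AUROC difference attributable to the extra
#' features.
#'
#' @param data_full,data_reduced Feature tibbles over the same rows in the
#'   same order; the reduced columns must be a subset of the full columns.
#' @inheritParams nested_cv
#' @return List with `auc_full`, `auc_reduced`, `delta`
#'   (`auc_full - auc_reduced`) and both `nested_cv` reports.
#' @export
ablation_compare <- function(data_full, data_reduced,
                             algorithm = c("rf", "xgb"), outer_k = 5L,
                             inner_k = 3L, n_trials = 20L, seed = 1L,
                             search_space = NULL) {
  algorithm <- arg_match(algorithm)
  if (nrow(data_full) != nrow(data_reduced)) {
    abort("fold mismatch: full and reduced matrices differ in rows")
  }
  if (!all(feature_columns(data_reduced) %in% feature_columns(data_full))) {
    abort("reduced feature columns must be a subset of the full columns")
  }
  if (!identical(as_binary_label(data_full$label),
                 as_binary_label(data_reduced$label))) {
    abort("fold mismatch: labels differ between matrices")
  }
  cv_full <- nested_cv(data_full, algorithm, outer_k, inner_k, n_trials,
                       seed = seed, search_space = search_space)
  cv_red <- nested_cv(data_reduced, algorithm, outer_k, inner_k, n_trials,
                      seed = seed, search_space = search_space)
  stopifnot(identical(cv_full$outer_fold, cv_red$outer_fold))
  auc_full <- cv_full$summary$mean[cv_full$summary$metric == "auroc"]
  auc_red <- cv_red$summary$mean[cv_red$summary$metric == "auroc"]
  list(auc_full = auc_full, auc_reduced = auc_red,
       delta = auc_full - auc_red, cv_full = cv_full, cv_reduced = cv_red)
}
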