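# broom-style accessors for the package's fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.pathopred_model <- function(x, ...) {
  if (x$algorithm == "rf") {
    imp <- x$fit$variable.importance
    tibble(feature = names(imp), importance = unname(imp)) |>
      arrange(dplyr::desc(importance))
  } else {
    imp <- xgboost::xgb.importance(model = x$fit)
    tibble(feature = imp$Feature, importance = imp$Gain)
  }
}

#' @export
glance.pathopred_model <- function(x, ...) {
  tibble(algorithm = x$algorithm, n_features = length(x$feature_schema),
         n_train = x$manifest$n_train,
         decision_threshold = x$decision_threshold,
         seed = x$manifest$seed)
}

#' @export
tidy.nested_cv <- function(x, ...) {
  tidyr::pivot_longer(x$fold_metrics, -c(fold, dplyr::any_of("n")),
                      names_to = "metric", values_to = "value")
}

#' @export
glance.nested_cv <- function(x, ...) {
  auc <- x$summary[x$summary$metric == "auroc", ]
  tibble(algorithm = x$algorithm, outer_k = x$outer_k, inner_k = x$inner_k,
         n_trials = x$n_trials, mean_auroc = auc$mean, sd_auroc = auc$sd,
         seed = x$seed)
}

#' @export
tidy.shap_explanation <- function(x, ...) {
  x$ranking
}

#' @export
tidy.reclassification <- function(x, ...) {
  count(as_tibble(x), assigned, name = "n")
}

#' @export
glance.reclassification <- function(x, ...) {
  thr <- attr(x, "thresholds")
  tibble(n = nrow(x),
         n_likely_pathogenic = sum(x$assigned == "LIKELY_PATHOGENIC"),
         n_likely_benign = sum(x$assigned == "LIKELY_BENIGN"),
         n_unchanged = sum(x$assigned == "UNCHANGED"),
         hi = thr[["hi"]], lo = thr[["lo"]])
}
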