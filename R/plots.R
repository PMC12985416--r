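# ggplot2 views of the package's result objects.

#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point geom_jitter
#'   geom_histogram geom_vline geom_boxplot coord_flip labs theme_minimal
#'   facet_wrap
#' @export
ggplot2::autoplot

#' @export
autoplot.nested_cv <- function(object, ...) {
  tidy(object) |>
    ggplot(aes(x = metric, y = value)) +
    geom_boxplot(outlier.shape = NA, colour = "grey40") +
    geom_jitter(width = 0.1, height = 0, aes(colour = factor(fold))) +
    labs(y = "outer-fold value", x = NULL, colour = "fold",
         title = sprintf("Nested CV (%s, %dx%d)", object$algorithm,
                         object$outer_k, object$inner_k)) +
    theme_minimal()
}

#' @export
autoplot.shap_explanation <- function(object, top_n = 10, ...) {
  dat <- head(object$ranking, top_n)
  dat$feature <- factor(dat$feature, levels = rev(dat$feature))
  ggplot(dat, aes(x = feature, y = mean_abs_shap)) +
    geom_col(fill = "steelblue") +
    coord_flip() +
    labs(x = NULL, y = "mean |SHAP|",
         title = "Global feature importance") +
    theme_minimal()
}

#' @export
autoplot.reclassification <- function(object, ...) {
  thr <- attr(object, "thresholds")
  ggplot(as_tibble(object), aes(x = mean_score, fill = assigned)) +
    geom_histogram(bins = 50, boundary = 0) +
    geom_vline(xintercept = c(thr[["lo"]], thr[["hi"]]), linetype = 2) +
    labs(x = "mean consensus score", y = "variants",
         title = "Consensus reclassification") +
    theme_minimal()
}

#' Feature distributions of successful vs failed predictions
#'
#' Mirrors the failure-mode view: for each listed feature, the
#' distribution over variants the model called correctly vs incorrectly,
#' split by truth label.
#'
#' @param strata A `failure_strata` from [stratify_failures()].
#' @param features Feature columns to show (default pLDDT, delta-PSIC,
#'   SASA).
#' @return A ggplot object.
#' @export
plot_failure_features <- function(strata,
                                  features = c("plddt", "delta_psic",
                                               "sasa")) {
  dat <- strata$bins |>
    tidyr::pivot_longer(dplyr::all_of(features), names_to = "feature",
                        values_to = "value")
  ggplot(dat, aes(x = label, y = value, fill = model_success)) +
    geom_boxplot() +
    facet_wrap(~feature, scales = "free_y") +
    labs(x = NULL, y = NULL, fill = "correct",
         title = "Feature distributions of successes vs failures") +
    theme_minimal()
}

#' @export
autoplot.failure_strata <- function(object, feature = "plddt", ...) {
  ggplot(object$bins, aes(x = bin, y = .data[[feature]], fill = label)) +
    geom_boxplot() +
    labs(x = "correct comparator predictions", y = feature,
         title = "Prediction consistency by structural confidence") +
    theme_minimal()
}
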