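# Classification metrics, bootstrap confidence intervals, comparator
# benchmarking, and failure-mode stratification.

#' Rank-based AUROC
#'
#' Mann-Whitney formulation with midrank tie correction; constant scores
#' give exactly 0.5.
#'
#' @param y_true Binary truth (PATHOGENIC/BENIGN or 0/1).
#' @param scores Numeric scores, larger = more pathogenic.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(y_true, scores) {
  y <- as_binary_label(y_true)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) abort("both classes required for AUROC")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

confusion_counts <- function(y, calls) {
  c(tp = sum(y == 1 & calls == 1), fp = sum(y == 0 & calls == 1),
    fn = sum(y == 1 & calls == 0), tn = sum(y == 0 & calls == 0))
}

metrics_from_confusion <- function(cc) {
  tp <- cc[["tp"]]; fp <- cc[["fp"]]; fn <- cc[["fn"]]; tn <- cc[["tn"]]
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  denom <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  accuracy <- (tp + tn) / sum(cc)
  c(f1 = f1, precision = precision, recall = recall, mcc = mcc,
    accuracy = accuracy)
}

#' Classification metrics from scores and calls
#'
#' AUROC by the rank (Mann-Whitney) formulation with tie correction;
#' F1, MCC, precision, recall and accuracy from the confusion matrix.
#' When `calls` is absent, calls are `scores > threshold`.
#'
#' @inheritParams auroc
#' @param calls Optional binary calls (1 = damaging).
#' @param threshold Score cutoff used when `calls` is absent.
#' @return One-row tibble: `auroc`, `f1`, `precision`, `recall`, `mcc`,
#'   `accuracy`, `n`.
#' @export
compute_metrics <- function(y_true, scores, calls = NULL, threshold = 0.5) {
  y <- as_binary_label(y_true)
  if (length(unique(y)) < 2) abort("both classes required in `y_true`")
  if (is.null(calls)) calls <- as.integer(scores > threshold)
  cm <- metrics_from_confusion(confusion_counts(y, as.integer(calls)))
  tibble(auroc = auroc(y, scores), f1 = cm[["f1"]],
         precision = cm[["precision"]], recall = cm[["recall"]],
         mcc = cm[["mcc"]], accuracy = cm[["accuracy"]], n = length(y))
}

#' Bootstrap percentile confidence intervals for classification metrics
#'
#' Resamples the evaluation set with replacement at its original size;
#' resamples lacking one of the classes are excluded from the interval and
#' counted in `n_excluded`. Percentile 2.5/97.5 bounds over the retained
#' resamples; deterministic for a fixed seed.
#'
#' @inheritParams compute_metrics
#' @param metrics Which metrics to bootstrap.
#' @param n_boot Number of resamples (default 1000).
#' @param seed Integer seed.
#' @return Tibble: `metric`, `estimate`, `lo`, `hi`, `n_boot`,
#'   `n_excluded`. The drawn index matrix is attached as attribute
#'   `"indices"` for auditability.
#' @export
bootstrap_ci <- function(y_true, scores, calls = NULL,
                         metrics = c("auroc", "f1", "precision", "recall",
                                     "mcc", "accuracy"),
                         n_boot = 1000L, seed = 1L, threshold = 0.5) {
  y <- as_binary_label(y_true)
  n <- length(y)
  if (n < 2 || length(unique(y)) < 2) {
    abort("need at least two observations covering both classes")
  }
  if (is.null(calls)) calls <- as.integer(scores > threshold)
  metrics <- match.arg(metrics, several.ok = TRUE)

  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
  keep <- apply(idx, 1, function(ii) length(unique(y[ii])) == 2)
  n_excluded <- sum(!keep)
  if (!any(keep)) abort("all bootstrap resamples were single-class")

  boot_vals <- matrix(NA_real_, sum(keep), length(metrics),
                      dimnames = list(NULL, metrics))
  rows <- which(keep)
  for (r in seq_along(rows)) {
    ii <- idx[rows[r], ]
    yb <- y[ii]; sb <- scores[ii]; cb <- calls[ii]
    vals <- c()
    if ("auroc" %in% metrics) vals <- c(vals, auroc = auroc(yb, sb))
    cm <- metrics_from_confusion(confusion_counts(yb, cb))
    boot_vals[r, ] <- c(vals, cm)[metrics]
  }

  est <- compute_metrics(y, scores, calls)
  tibble(
    metric = metrics,
    estimate = as.numeric(est[1, metrics]),
    lo = unname(apply(boot_vals, 2, quantile, 0.025, names = FALSE)),
    hi = unname(apply(boot_vals, 2, quantile, 0.975, names = FALSE)),
    n_boot = as.integer(n_boot),
    n_excluded = as.integer(n_excluded)
  ) -> out
  attr(out, "indices") <- idx
  out
}

#' Benchmark external predictors against shared truth labels
#'
#' Evaluates each comparator tool on the variants it actually scored:
#' rows missing a tool's score are dropped for that tool only, so per-tool
#' `n` varies. Tools whose orientation says smaller = more damaging are
#' flipped before AUROC. Tools without binary calls are evaluated by AUROC
#' alone; tools with calls get the full metric set. Tools left with a
#' single truth class after dropping are skipped with a warning.
#'
#' @param truth Tibble with `variant_id` and `label` (PATHOGENIC/BENIGN).
#' @param comparators Long tibble: `variant_id`, `tool`, `score`
#'   (numeric, `NA` = not scored) and optionally `call`
#'   (`"damaging"`/`"tolerated"` or 1/0, `NA` allowed).
#' @param manifest Tibble with `tool`, `higher_is_damaging` (logical),
#'   `has_calls` (logical).
#' @param n_boot Bootstrap resamples for CIs (0 = none).
#' @param seed Seed for the bootstrap.
#' @return Tibble, one row per evaluated tool: `tool`, `n`, `auroc`,
#'   (`auroc_lo`, `auroc_hi` when `n_boot > 0`), `f1`, `precision`,
#'   `recall`, `mcc`, `accuracy` (NA for score-only tools).
#' @export
benchmark_comparators <- function(truth, comparators, manifest,
                                  n_boot = 0L, seed = 1L) {
  rows <- lapply(manifest$tool, function(tl) {
    meta <- manifest[manifest$tool == tl, ]
    dat <- comparators[comparators$tool == tl, ]
    dat <- dplyr::inner_join(truth, dat, by = "variant_id")
    dat <- dat[!is.na(dat$score), ]
    if (nrow(dat) == 0) {
      warn(sprintf("tool %s has no scored variants; skipped", tl))
      return(NULL)
    }
    y <- as_binary_label(dat$label)
    if (length(unique(y)) < 2) {
      warn(sprintf("tool %s covers a single class after dropping; skipped", tl))
      return(NULL)
    }
    sc <- if (isTRUE(meta$higher_is_damaging)) dat$score else -dat$score
    out <- tibble(tool = tl, n = nrow(dat), auroc = auroc(y, sc))
    if (n_boot > 0) {
      ci <- bootstrap_ci(y, sc, calls = as.integer(sc > mean(range(sc))),
                         metrics = "auroc", n_boot = n_boot, seed = seed)
      out$auroc_lo <- ci$lo; out$auroc_hi <- ci$hi
    }
    if (isTRUE(meta$has_calls) && "call" %in% names(dat) &&
        any(!is.na(dat$call))) {
      calls <- dat$call
      if (is.character(calls)) {
        calls <- dplyr::case_match(tolower(calls), "damaging" ~ 1L,
                                   "tolerated" ~ 0L, .default = NA_integer_)
      }
      keep <- !is.na(calls)
      cm <- metrics_from_confusion(confusion_counts(y[keep],
                                                    as.integer(calls[keep])))
      out$f1 <- cm[["f1"]]; out$precision <- cm[["precision"]]
      out$recall <- cm[["recall"]]; out$mcc <- cm[["mcc"]]
      out$accuracy <- cm[["accuracy"]]
    } else {
      out$f1 <- NA_real_; out$precision <- NA_real_; out$recall <- NA_real_
      out$mcc <- NA_real_; out$accuracy <- NA_real_
    }
    out
  })
  list_rbind(purrr::compact(rows))
}

#' Per-class accuracy of binary predictors
#'
#' The accuracy of a predictor restricted to one truth class, i.e. its
#' recall on that class (sensitivity for pathogenic, specificity for
#' benign).
#'
#' @param truth Tibble with `variant_id`, `label`.
#' @param calls Long tibble: `variant_id`, `predictor`, `call` (1 =
#'   damaging).
#' @return Tibble: `predictor`, `label`, `accuracy`, `n`.
#' @export
per_class_accuracy <- function(truth, calls) {
  dat <- dplyr::inner_join(truth, calls, by = "variant_id")
  dat$correct <- as_binary_label(dat$label) == as.integer(dat$call)
  dat |>
    group_by(predictor, label) |>
    summarise(accuracy = mean(correct), n = dplyr::n(), .groups = "drop")
}

correct_count_bin <- function(n, n_predictors = 12L) {
  hi2 <- 2L * pmax(1L, ceiling(n / 2))
  hi2 <- pmin(hi2, n_predictors)
  sprintf("[%d-%d]", hi2 - 1L, hi2)
}

#' Stratify prediction successes and failures by structural features
#'
#' Flags, per variant and predictor, whether the call matched the truth
#' label; counts how many comparator predictors got each variant right;
#' and joins the per-variant feature values so success/failure feature
#' distributions can be summarized or plotted. Correct counts are binned
#' in pairs (`[1-2]` ... `[11-12]`; a count of zero folds into the lowest
#' band).
#'
#' @param truth Tibble with `variant_id`, `label`.
#' @param features Tibble with `variant_id` and feature columns (typically
#'   `plddt`, `delta_psic`, `sasa`).
#' @param model_calls Tibble `variant_id`, `call` for the model under
#'   study (flagged success/failure per variant).
#' @param comparator_calls Long tibble `variant_id`, `predictor`, `call`
#'   for the call-producing comparators.
#' @return A `failure_strata` list: `success` (long per-predictor success
#'   flags, model included as predictor `"model"`), `bins` (per variant:
#'   `correct_n`, `bin`, model success, label, features).
#' @export
stratify_failures <- function(truth, features, model_calls,
                              comparator_calls) {
  all_calls <- bind_rows(
    tibble(variant_id = model_calls$variant_id, predictor = "model",
           call = model_calls$call),
    comparator_calls
  )
  dat <- dplyr::inner_join(truth, all_calls, by = "variant_id")
  dat$success <- as_binary_label(dat$label) == as.integer(dat$call)

  n_comp <- length(unique(comparator_calls$predictor))
  counts <- dat |>
    filter(predictor != "model") |>
    group_by(variant_id) |>
    summarise(correct_n = sum(success), .groups = "drop")
  counts$bin <- correct_count_bin(counts$correct_n, n_comp)

  bins <- truth |>
    dplyr::left_join(counts, by = "variant_id") |>
    dplyr::left_join(dat |> filter(predictor == "model") |>
                       select(variant_id, model_success = success),
                     by = "variant_id") |>
    dplyr::left_join(features, by = "variant_id")

  structure(list(success = dat |> select(variant_id, label, predictor,
                                         success),
                 bins = bins, n_comparators = n_comp),
            class = "failure_strata")
}

#' @export
print.failure_strata <- function(x, ...) {
  cat(sprintf("<failure_strata> %d variants, %d comparators\n",
              nrow(x$bins), x$n_comparators))
  print(count(x$bins, bin))
  invisible(x)
}
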