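test_that("metrics reproduce closed forms and tie handling", {
  # perfect separation
  y <- rep(c(1, 0), each = 10)
  s <- c(runif(10, 0.8, 1), runif(10, 0, 0.2))
  m <- compute_metrics(y, s)
  expect_equal(m$auroc, 1)
  expect_equal(m$mcc, 1)
  expect_equal(m$f1, 1)

  # constant scores: AUROC exactly 0.5 by midrank ties
  expect_equal(compute_metrics(y, rep(0.7, 20))$auroc, 0.5)

  # TP=50 FP=10 FN=10 TN=30 -> F1 = 100/120
  y2 <- rep(c(1, 0), c(60, 40))
  calls <- c(rep(1, 50), rep(0, 10), rep(1, 10), rep(0, 30))
  m2 <- compute_metrics(y2, calls, calls = calls)
  expect_equal(m2$f1, 100 / 120)
  expect_equal(m2$precision, 50 / 60)
  expect_equal(m2$recall, 50 / 60)
  expect_equal(m2$accuracy, 0.8)

  expect_error(compute_metrics(rep(1, 5), runif(5)), "both classes")
})

test_that("rank AUROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(21)
  for (i in 1:5) {
    y <- rbinom(80, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- rnorm(80) + y
    s[sample(80, 10)] <- round(s[sample(80, 10)], 1) # inject ties
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auroc(y, s), ref, tolerance = 1e-12)
  }
})

test_that("score negation and label swaps behave symmetrically", {
  set.seed(3)
  y <- rbinom(100, 1, 0.5)
  s <- rnorm(100) # tie-free
  expect_equal(auroc(y, s) + auroc(y, -s), 1)

  calls <- as.integer(s > 0)
  m <- compute_metrics(y, s, calls)
  m_sw <- compute_metrics(1 - y, -s, 1 - calls)
  expect_equal(m_sw$mcc, m$mcc)
})

test_that("bootstrap intervals are percentile-based with exclusion bookkeeping", {
  set.seed(10)
  y <- rep(c(1, 0), each = 100)
  s <- c(runif(100, 0.7, 1), runif(100, 0, 0.3))
  ci <- bootstrap_ci(y, s, n_boot = 200, seed = 4, metrics = "auroc")
  expect_equal(ci$lo, 1)
  expect_equal(ci$hi, 1)
  expect_equal(ci$n_excluded, 0L)

  # heavily imbalanced n = 4: excluded count matches the drawn indices
  y2 <- c(1, 0, 0, 0)
  s2 <- c(0.9, 0.2, 0.3, 0.1)
  ci2 <- bootstrap_ci(y2, s2, n_boot = 500, seed = 7, metrics = "auroc")
  idx <- attr(ci2, "indices")
  manual_excluded <- sum(apply(idx, 1, function(ii) length(unique(y2[ii])) < 2))
  expect_gt(ci2$n_excluded, 0)
  expect_equal(ci2$n_excluded, manual_excluded)

  # n_boot = 1: the interval degenerates to a hand-computable resample
  ci3 <- bootstrap_ci(y, s, n_boot = 1, seed = 12, metrics = "auroc")
  ii <- attr(ci3, "indices")[1, ]
  expect_equal(ci3$lo, auroc(y[ii], s[ii]))
  expect_equal(ci3$hi, ci3$lo)

  # determinism
  ci4 <- bootstrap_ci(y2, s2, n_boot = 500, seed = 7, metrics = "auroc")
  expect_identical(as.data.frame(ci2), as.data.frame(ci4))
})

test_that("comparator benchmarking drops missing rows per tool", {
  set.seed(8)
  truth <- tibble::tibble(variant_id = paste0("v", 1:20),
                          label = rep(c("PATHOGENIC", "BENIGN"), 10))
  y <- as.integer(truth$label == "PATHOGENIC")
  comp <- dplyr::bind_rows(
    tibble::tibble(variant_id = truth$variant_id, tool = "caller",
                   score = y + rnorm(20, 0, 0.3), call = y),
    tibble::tibble(variant_id = truth$variant_id, tool = "score_only",
                   score = y + rnorm(20, 0, 0.3), call = NA_integer_),
    tibble::tibble(variant_id = truth$variant_id, tool = "gappy",
                   score = replace(y + rnorm(20, 0, 0.3),
                                   1:3, NA_real_), call = NA_integer_),
    tibble::tibble(variant_id = truth$variant_id, tool = "inverted",
                   score = -(y + rnorm(20, 0, 0.3)), call = NA_integer_))
  manifest <- tibble::tibble(
    tool = c("caller", "score_only", "gappy", "inverted"),
    higher_is_damaging = c(TRUE, TRUE, TRUE, FALSE),
    has_calls = c(TRUE, FALSE, FALSE, FALSE))
  bench <- benchmark_comparators(truth, comp, manifest)
  expect_equal(bench$n[bench$tool == "caller"], 20L)
  expect_equal(bench$n[bench$tool == "gappy"], 17L)
  expect_false(is.na(bench$f1[bench$tool == "caller"]))
  expect_true(is.na(bench$f1[bench$tool == "score_only"]))
  expect_gt(bench$auroc[bench$tool == "inverted"], 0.5) # orientation applied

  # single-class after dropping -> skipped with a warning
  comp_bad <- tibble::tibble(variant_id = truth$variant_id[y == 1],
                             tool = "halfcov", score = runif(10))
  mani_bad <- tibble::tibble(tool = "halfcov", higher_is_damaging = TRUE,
                             has_calls = FALSE)
  expect_warning(out <- benchmark_comparators(truth, comp_bad, mani_bad),
                 "single class")
  expect_equal(nrow(out), 0)
})

test_that("failure stratification bins correct-predictor counts", {
  truth <- tibble::tibble(variant_id = paste0("v", 1:10),
                          label = rep(c("PATHOGENIC", "BENIGN"), 5))
  y <- as.integer(truth$label == "PATHOGENIC")
  # 12 comparators; variant v1 correct by all 12, v2 correct by 3, ...
  correct_n <- c(12L, 3L, 7L, 1L, 0L, 9L, 12L, 5L, 2L, 11L)
  comp <- purrr::list_rbind(purrr::map(1:12, function(t) {
    tibble::tibble(
      variant_id = truth$variant_id, predictor = sprintf("tool%02d", t),
      call = ifelse(t <= correct_n, y, 1L - y))
  }))
  model_calls <- tibble::tibble(variant_id = truth$variant_id, call = y)
  feats <- tibble::tibble(variant_id = truth$variant_id,
                          plddt = runif(10, 30, 95),
                          delta_psic = rnorm(10), sasa = runif(10, 0, 200))
  st <- stratify_failures(truth, feats, model_calls, comp)
  expect_equal(st$bins$correct_n, correct_n)
  expect_equal(st$bins$bin[1], "[11-12]")
  expect_equal(st$bins$bin[2], "[3-4]")
  expect_equal(st$bins$bin[5], "[1-2]") # zero folds into the lowest band
  expect_equal(unname(table(st$bins$bin)[c("[1-2]", "[11-12]")]),
               c(3L, 3L), ignore_attr = TRUE)
  expect_true(all(st$success$success[st$success$predictor == "model"]))

  # per-class accuracy of a tool equals its recall on that class
  acc <- per_class_accuracy(truth, comp)
  t3 <- comp[comp$predictor == "tool03", ]
  path_ids <- truth$variant_id[truth$label == "PATHOGENIC"]
  recall_path <- mean(t3$call[t3$variant_id %in% path_ids] == 1)
  expect_equal(acc$accuracy[acc$predictor == "tool03" &
                              acc$label == "PATHOGENIC"], recall_path)
})
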