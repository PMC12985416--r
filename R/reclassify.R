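# Consensus mean-score reclassification of VUS/conflicting variants.

#' Normalize heterogeneous predictor scores onto \[0, 1\]
#'
#' Monotone rescaling so that scores from different tools share a common
#' damaging-high orientation and range. Scores whose orientation says
#' smaller = more damaging are inverted first. `minmax` applies an affine
#' map onto \[0, 1\]; `rank_percentile` maps to midrank / n (robust for
#' unbounded scores such as CADD).
#'
#' @param x Numeric scores (`NA` passed through).
#' @param method `"minmax"` or `"rank_percentile"`.
#' @param higher_is_damaging Orientation flag; `FALSE` inverts first.
#' @return Numeric vector in \[0, 1\].
#' @export
normalize_tool_scores <- function(x, method = c("minmax", "rank_percentile"),
                                  higher_is_damaging = TRUE) {
  method <- arg_match(method)
  if (!higher_is_damaging) x <- -x
  obs <- x[!is.na(x)]
  if (length(obs) < 2) abort("need at least 2 observed scores to normalize")
  if (method == "minmax") {
    rng <- range(obs)
    if (rng[1] == rng[2]) {
      abort("constant scores cannot be min-max normalized; use rank_percentile")
    }
    (x - rng[1]) / (rng[2] - rng[1])
  } else {
    out <- rep(NA_real_, length(x))
    out[!is.na(x)] <- rank(obs, ties.method = "average") / length(obs)
    out
  }
}

#' Consensus reclassification by mean predictor score
#'
#' Averages the configured tools' normalized scores per variant and
#' reassigns variants whose mean is strictly above `hi` as likely
#' pathogenic or strictly below `lo` as likely benign; everything else —
#' including means exactly at a threshold — stays unchanged. Variants with
#' fewer than `min_tools` available scores are left unchanged and flagged
#' as insufficient evidence.
#'
#' @param scores Tibble with `variant_id`, optional metadata columns
#'   (`gene`, `prior_label`, `review_status`), and one numeric column per
#'   tool, all values in \[0, 1\] (or `NA`).
#' @param tools Character vector of tool column names; default: every
#'   numeric non-metadata column.
#' @param hi,lo Upper/lower mean-score thresholds (defaults 0.95 / 0.05;
#'   `hi` must exceed `lo`).
#' @param min_tools Minimum number of available scores required; default:
#'   all configured tools.
#' @return A `reclassification` tibble: metadata columns plus `n_tools`,
#'   `mean_score`, `assigned` (`LIKELY_PATHOGENIC` / `LIKELY_BENIGN` /
#'   `UNCHANGED`), `insufficient_evidence`.
#' @export
consensus_reclassify <- function(scores, tools = NULL, hi = 0.95, lo = 0.05,
                                 min_tools = NULL) {
  if (hi <= lo) abort("`hi` must be greater than `lo`")
  meta_cols <- intersect(c("variant_id", "gene", "prior_label",
                           "review_status"), names(scores))
  if (is.null(tools)) {
    tools <- setdiff(names(scores)[vapply(scores, is.numeric, TRUE)],
                     meta_cols)
  }
  if (length(tools) == 0) abort("no tool score columns found")
  sm <- as.matrix(scores[, tools])
  if (any(sm < 0 | sm > 1, na.rm = TRUE)) {
    abort("tool scores must lie in [0, 1]; normalize first")
  }
  if (is.null(min_tools)) min_tools <- length(tools)

  n_avail <- rowSums(!is.na(sm))
  mean_score <- rowMeans(sm, na.rm = TRUE)
  mean_score[n_avail == 0] <- NA_real_
  insufficient <- n_avail < min_tools
  assigned <- dplyr::case_when(
    insufficient ~ "UNCHANGED",
    mean_score > hi ~ "LIKELY_PATHOGENIC",
    mean_score < lo ~ "LIKELY_BENIGN",
    TRUE ~ "UNCHANGED"
  )
  out <- bind_cols(
    scores[, meta_cols],
    tibble(n_tools = as.integer(n_avail), mean_score = mean_score,
           assigned = assigned, insufficient_evidence = insufficient)
  )
  class(out) <- c("reclassification", class(out))
  attr(out, "thresholds") <- c(hi = hi, lo = lo)
  attr(out, "tools") <- tools
  out
}

#' Summarize consensus reclassification decisions
#'
#' Cross-tabulates reassignments by gene, prior clinical label and ClinVar
#' review status (whichever columns are present), conserving totals:
#' per-group counts of each assignment sum to the overall count.
#'
#' @param decisions A `reclassification` tibble.
#' @return List of tibbles: `totals` (per assigned class), and where the
#'   metadata exist `by_gene`, `by_prior_label`, `by_review_status`
#'   (reassigned variants only, i.e. `assigned != "UNCHANGED"`).
#' @export
summarize_reclassification <- function(decisions) {
  out <- list(totals = count(decisions, assigned, name = "n"))
  reassigned <- filter(decisions, assigned != "UNCHANGED")
  if ("gene" %in% names(decisions)) {
    out$by_gene <- count(reassigned, gene, assigned, name = "n")
  }
  if ("prior_label" %in% names(decisions)) {
    out$by_prior_label <- count(reassigned, prior_label, assigned, name = "n")
  }
  if ("review_status" %in% names(decisions)) {
    out$by_review_status <- count(reassigned, review_status, assigned,
                                  name = "n")
  }
  out
}
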