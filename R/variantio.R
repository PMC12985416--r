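# Reading, harmonizing, filtering and splitting missense-variant tables.

CLIN_LABELS <- c("PATHOGENIC", "BENIGN", "VUS", "CONFLICTING", "UNKNOWN")

#' Column dialect for variant tables
#'
#' Maps the canonical field names onto the column names of a foreign
#' delimited file. Set `protein_change` to the name of an HGVS-style
#' protein-change column (e.g. `p.Arg1699Trp`) when the file does not carry
#' explicit `position`/`wt_aa`/`var_aa` columns.
#'
#' @param gene,accession,position,wt_aa,var_aa,raw_label,review_stars,origin
#'   Column names in the input file.
#' @param protein_change Optional column holding HGVS `p.` strings; when
#'   given it overrides `position`, `wt_aa` and `var_aa`.
#' @return A named list usable as the `dialect` argument of
#'   [read_variant_table()].
#' @export
variant_dialect <- function(gene = "gene", accession = "accession",
                            position = "position", wt_aa = "wt_aa",
                            var_aa = "var_aa", raw_label = "raw_label",
                            review_stars = "review_stars", origin = "origin",
                            protein_change = NULL) {
  list(gene = gene, accession = accession, position = position,
       wt_aa = wt_aa, var_aa = var_aa, raw_label = raw_label,
       review_stars = review_stars, origin = origin,
       protein_change = protein_change)
}

#' Parse HGVS protein-change strings
#'
#' Accepts `p.Arg1699Trp` and one-letter `p.R1699W` forms (the `p.` prefix
#' is optional). Unparseable strings yield `NA` fields rather than an error.
#'
#' @param x Character vector of protein-change strings.
#' @return Tibble with columns `wt_aa`, `position`, `var_aa` (`NA` where
#'   parsing failed).
#' @export
parse_protein_change <- function(x) {
  x <- stringr::str_trim(stringr::str_remove(x, "^p\\."))
  m3 <- stringr::str_match(x, "^([A-Z][a-z]{2})(\\d+)([A-Z][a-z]{2})$")
  m1 <- stringr::str_match(x, "^([A-Z])(\\d+)([A-Z])$")
  wt <- if_else(!is.na(m3[, 1]), unname(AA_THREE_TO_ONE[m3[, 2]]), m1[, 2])
  vr <- if_else(!is.na(m3[, 1]), unname(AA_THREE_TO_ONE[m3[, 4]]), m1[, 4])
  pos <- if_else(!is.na(m3[, 1]), m3[, 3], m1[, 3])
  wt[!wt %in% AA_ALPHABET] <- NA_character_
  vr[!vr %in% AA_ALPHABET] <- NA_character_
  tibble(wt_aa = wt, position = as.integer(pos), var_aa = vr)
}

#' Harmonize free-text clinical-significance labels
#'
#' Collapses ClinVar-style clinical-significance strings into the four
#' working classes. Pathogenic and likely-pathogenic entries (including the
#' slash-combined spellings) merge into `PATHOGENIC`, benign analogously;
#' any string starting with "conflicting" becomes `CONFLICTING`; matching is
#' case-insensitive. Out-of-vocabulary strings map to the explicit
#' `UNKNOWN` sentinel, never silently to a class.
#'
#' @param raw_label Character vector of raw labels.
#' @return Character vector over
#'   `c("PATHOGENIC","BENIGN","VUS","CONFLICTING","UNKNOWN")`.
#' @export
harmonize_label <- function(raw_label) {
  x <- stringr::str_to_lower(stringr::str_trim(as.character(raw_label)))
  dplyr::case_when(
    x %in% c("pathogenic", "likely pathogenic",
             "pathogenic/likely pathogenic",
             "likely pathogenic/pathogenic") ~ "PATHOGENIC",
    x %in% c("benign", "likely benign", "benign/likely benign",
             "likely benign/benign") ~ "BENIGN",
    x %in% c("uncertain significance", "vus",
             "variant of uncertain significance") ~ "VUS",
    stringr::str_starts(x, "conflicting") ~ "CONFLICTING",
    TRUE ~ "UNKNOWN"
  )
}

#' Read and harmonize a delimited missense-variant table
#'
#' Reads a CSV/TSV variant table, maps columns through `dialect`, harmonizes
#' clinical labels and validates each row against the missense-variant
#' invariants. Rows that are not missense (wild-type equals variant), carry
#' an unparseable protein change, a non-positive position, or residues
#' outside the 20-letter alphabet are counted and skipped, not fatal; the
#' per-reason counts are attached as the `"skipped"` attribute and reported
#' via a message.
#'
#' @param path Path to a delimited file (delimiter auto-detected from the
#'   extension: `.tsv`/`.txt` tab, otherwise comma).
#' @param dialect Column mapping from [variant_dialect()].
#' @return Tibble with columns `variant_id`, `gene`, `accession`,
#'   `position`, `wt_aa`, `var_aa`, `raw_label`, `label`, `review_stars`,
#'   `origin`, plus a `"skipped"` attribute (named integer vector).
#' @export
read_variant_table <- function(path, dialect = variant_dialect()) {
  if (!file.exists(path)) abort(sprintf("variant table not found: %s", path))
  delim <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (nrow(raw) == 0) {
    warn("variant table is empty")
    out <- tibble(variant_id = character(), gene = character(),
                  accession = character(), position = integer(),
                  wt_aa = character(), var_aa = character(),
                  raw_label = character(), label = character(),
                  review_stars = integer(), origin = character())
    attr(out, "skipped") <- c(not_missense = 0L, unparseable = 0L)
    return(out)
  }
  need <- c("gene", "accession", "raw_label", "review_stars", "origin")
  need <- c(need, if (is.null(dialect$protein_change))
    c("position", "wt_aa", "var_aa") else "protein_change")
  for (field in need) {
    col <- dialect[[field]]
    if (is.null(col) || !col %in% names(raw)) {
      abort(sprintf("required column missing from variant table: `%s` (field `%s`)",
                    col %||% field, field))
    }
  }

  if (!is.null(dialect$protein_change)) {
    pc <- parse_protein_change(raw[[dialect$protein_change]])
    raw$position <- pc$position
    raw$wt_aa <- pc$wt_aa
    raw$var_aa <- pc$var_aa
  } else {
    raw$position <- suppressWarnings(as.integer(raw[[dialect$position]]))
    raw$wt_aa <- as.character(raw[[dialect$wt_aa]])
    raw$var_aa <- as.character(raw[[dialect$var_aa]])
  }

  out <- tibble(
    gene = as.character(raw[[dialect$gene]]),
    accession = as.character(raw[[dialect$accession]]),
    position = raw$position,
    wt_aa = raw$wt_aa,
    var_aa = raw$var_aa,
    raw_label = as.character(raw[[dialect$raw_label]]),
    review_stars = suppressWarnings(as.integer(raw[[dialect$review_stars]])),
    origin = toupper(as.character(raw[[dialect$origin]]))
  )
  out$origin[!out$origin %in% c("GERMLINE", "SOMATIC")] <-
    ifelse(is.na(out$origin[!out$origin %in% c("GERMLINE", "SOMATIC")]),
           NA, "OTHER")

  unparseable <- is.na(out$position) | is.na(out$wt_aa) | is.na(out$var_aa) |
    !out$wt_aa %in% AA_ALPHABET | !out$var_aa %in% AA_ALPHABET |
    (!is.na(out$position) & out$position < 1)
  not_missense <- !unparseable & out$wt_aa == out$var_aa
  skipped <- c(not_missense = sum(not_missense),
               unparseable = sum(unparseable))
  if (sum(skipped) > 0) {
    inform(sprintf("skipped %d row(s): %d not missense, %d unparseable",
                   sum(skipped), skipped[["not_missense"]],
                   skipped[["unparseable"]]))
  }
  out <- out[!unparseable & !not_missense, , drop = FALSE]
  out$label <- harmonize_label(out$raw_label)
  out$variant_id <- paste0(out$accession, ":", out$wt_aa, out$position,
                           out$var_aa)
  out <- out[, c("variant_id", "gene", "accession", "position", "wt_aa",
                 "var_aa", "raw_label", "label", "review_stars", "origin")]
  attr(out, "skipped") <- skipped
  out
}

#' Write a harmonized variant table as canonical CSV
#'
#' @param variants Tibble as returned by [read_variant_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  readr::write_csv(variants, path, progress = FALSE)
  invisible(path)
}

#' Filter variants by review confidence and origin
#'
#' Keeps records with at least `min_stars` ClinVar review stars and, by
#' default, germline origin (somatic and other origins removed). Row order
#' is preserved and the operation is idempotent.
#'
#' @param variants Variant tibble.
#' @param min_stars Minimum review stars (default 1).
#' @param require_germline Drop non-germline records (default `TRUE`).
#' @return Filtered tibble.
#' @export
filter_variants <- function(variants, min_stars = 1, require_germline = TRUE) {
  keep <- !is.na(variants$review_stars) & variants$review_stars >= min_stars
  if (require_germline) keep <- keep & variants$origin %in% "GERMLINE"
  variants[keep, , drop = FALSE]
}

#' Check variant positions against protein sequences
#'
#' A variant maps consistently when its position lies within the protein and
#' the sequence carries the annotated wild-type residue at that (1-based)
#' position. Inconsistent records signal `FALSE`, never an error.
#'
#' @param variants Variant tibble.
#' @param sequences Named character vector (or `Biostrings::AAStringSet`)
#'   of protein sequences keyed by accession.
#' @return Logical vector, one element per variant row.
#' @export
validate_mapping <- function(variants, sequences) {
  if (inherits(sequences, "AAStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  seqs <- unname(sequences[variants$accession])
  found <- !is.na(seqs)
  ok <- found & variants$position >= 1 & variants$position <= nchar(seqs)
  at <- rep(NA_character_, nrow(variants))
  at[ok] <- substr(seqs[ok], variants$position[ok], variants$position[ok])
  ok & at == variants$wt_aa & !is.na(at)
}

#' Stratified train/test partition of a labeled variant pool
#'
#' Splits a pathogenic/benign pool into train and test sets stratified by
#' label. The overall sizes are `round(N * (1 - test_fraction))` and the
#' remainder, independent of the seed; per-class test counts are allocated
#' by largest remainder so class proportions match the pool within rounding.
#'
#' @param variants Tibble whose `label` column contains only `PATHOGENIC`
#'   and `BENIGN` (both present).
#' @param test_fraction Fraction held out, in (0, 1). Default 0.2.
#' @param seed Integer seed controlling which records land in which side.
#' @return An object of class `labeled_split`: list with tibbles `train`
#'   and `test` plus `seed` and `test_fraction`.
#' @export
split_train_test <- function(variants, test_fraction = 0.2, seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    abort("`test_fraction` must lie strictly between 0 and 1")
  }
  labs <- unique(variants$label)
  if (!all(labs %in% c("PATHOGENIC", "BENIGN"))) {
    abort("pool must contain only PATHOGENIC/BENIGN labels; filter first")
  }
  if (length(labs) < 2) {
    abort("pool contains a single class; stratified splitting is impossible")
  }
  n <- nrow(variants)
  n_train <- round(n * (1 - test_fraction))
  n_test <- n - n_train

  counts <- table(variants$label)
  ideal <- as.numeric(counts) * n_test / n
  base <- floor(ideal)
  rem <- n_test - sum(base)
  ord <- order(ideal - base, decreasing = TRUE)
  base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  test_per_class <- setNames(as.integer(base), names(counts))

  set.seed(seed)
  test_idx <- unlist(lapply(names(counts), function(cl) {
    idx <- which(variants$label == cl)
    sample(idx, test_per_class[[cl]])
  }), use.names = FALSE)
  test_idx <- sort(test_idx)

  structure(
    list(train = variants[-test_idx, , drop = FALSE],
         test = variants[test_idx, , drop = FALSE],
         seed = as.integer(seed), test_fraction = test_fraction),
    class = "labeled_split"
  )
}

#' @export
print.labeled_split <- function(x, ...) {
  cat(sprintf("<labeled_split> train: %d, test: %d (test_fraction = %g, seed = %d)\n",
              nrow(x$train), nrow(x$test), x$test_fraction, x$seed))
  invisible(x)
}

#' Write a split manifest as JSON
#'
#' Records the ids assigned to each partition together with the seed and
#' fraction, so a partition can be reproduced or audited.
#'
#' @param split A `labeled_split`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_split_manifest <- function(split, path) {
  jsonlite::write_json(
    list(seed = split$seed, test_fraction = split$test_fraction,
         train_ids = split$train$variant_id, test_ids = split$test$variant_id),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
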