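test_that("variant tables parse with field mapping and row skipping", {
  rows <- tibble::tibble(
    gene = c("BRCA1", "TP53", "MLH1", "ATM", "PTEN"),
    accession = c("P38398", "P04637", "P40692", "Q13315", "P60484"),
    position = c(1699L, 175L, 384L, 2891L, 130L),
    wt_aa = c("R", "R", "V", "A", "R"),
    var_aa = c("W", "H", "D", "A", "X"), # row 4 synonymous, row 5 bad code
    raw_label = c("Pathogenic", "Likely pathogenic", "Benign",
                  "Uncertain significance", "Benign"),
    review_stars = c(3L, 2L, 1L, 1L, 1L),
    origin = "germline")
  path <- write_variant_fixture(rows)
  v <- suppressMessages(read_variant_table(path))
  expect_equal(nrow(v), 3)
  expect_equal(sum(attr(v, "skipped")), 2)
  expect_equal(v$label[v$gene == "BRCA1"], "PATHOGENIC")
  expect_equal(v$variant_id[1], "P38398:R1699W")

  # round trip is bit-identical on every field
  out <- tempfile(fileext = ".csv")
  write_variant_table(v, out)
  v2 <- read_variant_table(out)
  for (col in names(v)) expect_identical(v[[col]], v2[[col]])
})

test_that("HGVS protein-change dialect is parsed with 3->1 letter mapping", {
  rows <- tibble::tibble(
    gene = c("BRCA1", "BRCA1", "BRCA1"),
    accession = "P38398",
    protein_change = c("p.Arg1699Trp", "p.R71G", "p.Bad999"),
    raw_label = "Pathogenic", review_stars = 2L, origin = "germline")
  path <- write_variant_fixture(rows)
  v <- suppressMessages(read_variant_table(
    path, variant_dialect(protein_change = "protein_change")))
  expect_equal(nrow(v), 2)
  expect_equal(v$wt_aa, c("R", "R"))
  expect_equal(v$position, c(1699L, 71L))
  expect_equal(v$var_aa, c("W", "G"))
})

test_that("missing required columns and empty files are handled explicitly", {
  rows <- tibble::tibble(gene = "BRCA1", accession = "P38398",
                         position = 1L, wt_aa = "M", var_aa = "T",
                         review_stars = 1L, origin = "germline")
  path <- write_variant_fixture(rows)
  expect_error(read_variant_table(path), "raw_label")

  empty <- tempfile(fileext = ".csv")
  writeLines("gene,accession,position,wt_aa,var_aa,raw_label,review_stars,origin",
             empty)
  expect_warning(v <- read_variant_table(empty), "empty")
  expect_equal(nrow(v), 0)
})

test_that("clinical labels harmonize case-insensitively into five classes", {
  expect_equal(harmonize_label("Likely pathogenic"), "PATHOGENIC")
  expect_equal(harmonize_label("Pathogenic/Likely pathogenic"), "PATHOGENIC")
  expect_equal(harmonize_label("benign/likely benign"), "BENIGN")
  expect_equal(harmonize_label("LIKELY BENIGN"), "BENIGN")
  expect_equal(harmonize_label("Uncertain significance"), "VUS")
  expect_equal(harmonize_label("Conflicting interpretations of pathogenicity"),
               "CONFLICTING")
  expect_equal(harmonize_label("drug response"), "UNKNOWN")
  expect_equal(harmonize_label("Pathogenicity unknown thing"), "UNKNOWN")
})

test_that("filtering keeps >= min-star germline records, preserves order, idempotent", {
  v <- tibble::tibble(
    variant_id = paste0("v", 1:10),
    review_stars = c(1L, 4L, 0L, 2L, 0L, 3L, 1L, 2L, 4L, 1L),
    origin = c("GERMLINE", "SOMATIC", "GERMLINE", "GERMLINE", "GERMLINE",
               "SOMATIC", "GERMLINE", "GERMLINE", "SOMATIC", "GERMLINE"))
  kept <- filter_variants(v)
  # 3 somatic and 2 zero-star germline rows drop
  expect_equal(nrow(kept), 5)
  expect_equal(kept$variant_id, c("v1", "v4", "v7", "v8", "v10"))
  expect_identical(filter_variants(kept), kept)
  # somatic with 4 stars is removed; germline 1 star kept
  expect_false("v2" %in% kept$variant_id)
  expect_true("v1" %in% kept$variant_id)
  # stars-only filtering when germline not required
  expect_equal(nrow(filter_variants(v, require_germline = FALSE)), 8)
})

test_that("mapping validation checks position range and wild-type residue", {
  v <- tibble::tibble(accession = c("A1", "A1", "A1", "A2"),
                      position = c(3L, 3L, 99L, 1L),
                      wt_aa = c("R", "K", "A", "M"))
  seqs <- c(A1 = "MARK", A2 = "MKV")
  expect_equal(validate_mapping(v, seqs), c(TRUE, FALSE, FALSE, TRUE))
  # unknown accession is a mapping failure, not an error
  v2 <- tibble::tibble(accession = "NOPE", position = 1L, wt_aa = "M")
  expect_false(validate_mapping(v2, seqs))
})

test_that("stratified splitting reproduces pool proportions and exact sizes", {
  pool <- tibble::tibble(
    variant_id = paste0("v", 1:3091),
    label = rep(c("PATHOGENIC", "BENIGN"), c(1100, 1991)))
  sp <- split_train_test(pool, test_fraction = 0.2, seed = 9)
  expect_equal(nrow(sp$train), 2473)
  expect_equal(nrow(sp$test), 618)
  expect_equal(length(intersect(sp$train$variant_id, sp$test$variant_id)), 0)

  # sizes depend only on N and fraction, never the seed
  for (s in c(1, 77, 2024)) {
    sp2 <- split_train_test(pool, 0.2, seed = s)
    expect_equal(c(nrow(sp2$train), nrow(sp2$test)), c(2473, 618))
  }

  # stratified rounding: 30/70 mix at N = 100 gives 6 + 14 test rows
  pool2 <- tibble::tibble(variant_id = paste0("w", 1:100),
                          label = rep(c("PATHOGENIC", "BENIGN"), c(30, 70)))
  sp3 <- split_train_test(pool2, 0.2, seed = 3)
  expect_equal(sum(sp3$test$label == "PATHOGENIC"), 6)
  expect_equal(sum(sp3$test$label == "BENIGN"), 14)

  # determinism: identical membership for a fixed seed
  sp4 <- split_train_test(pool2, 0.2, seed = 3)
  expect_identical(sp3$test$variant_id, sp4$test$variant_id)

  expect_error(split_train_test(pool2[1:30, ], 0.2, seed = 1),
               "single class")
  expect_error(split_train_test(dplyr::mutate(pool2, label = "VUS"), 0.2, 1),
               "PATHOGENIC/BENIGN")

  # split manifest records the partition
  mf <- tempfile(fileext = ".json")
  write_split_manifest(sp3, mf)
  js <- jsonlite::read_json(mf, simplifyVector = TRUE)
  expect_setequal(js$test_ids, sp3$test$variant_id)
})
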