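uniform_bg <- setNames(rep(0.05, 20), AA_ALPHABET)

test_that("PSIC scores follow the independent-counts formula", {
  # single row, uniform background: n_eff = 1 everywhere and the observed
  # residue scores ln((1 + w*bg)/((1 + w)*bg)) = ln(10.5) at w = 1
  msa <- pathopred:::msa_from_strings("ACDE")
  prof <- psic_profile(msa, background = uniform_bg)
  expect_equal(prof$n_eff, rep(1, 4))
  expect_equal(unname(prof$scores[1, "A"]), log(1.05 / (2 * 0.05)))
  expect_true(all(prof$scores[1, setdiff(AA_ALPHABET, "A")] < 0))

  # column of 50 identical residues: observed residue strictly highest
  msa2 <- pathopred:::msa_from_strings(rep("AAAA", 50))
  prof2 <- psic_profile(msa2, background = uniform_bg)
  expect_true(all(prof2$scores[1, "A"] > prof2$scores[1, -1]))

  # columns renormalize: sum_a f(j, a) == 1
  msa3 <- gen_msa(strsplit("MKVLAWGRQN", "")[[1]],
                  conservation = seq(0.1, 1, length.out = 10),
                  depth = 30, seed = 2)
  prof3 <- psic_profile(msa3)
  f <- exp(prof3$scores) * matrix(prof3$background, nrow(prof3$scores), 20,
                                  byrow = TRUE)
  expect_equal(rowSums(f), rep(1, 10), tolerance = 1e-12)
})

test_that("duplicate sequences collapse into one independent count", {
  # 50 exact duplicates carry no more evidence than the sequence itself
  prof_many <- psic_profile(pathopred:::msa_from_strings(rep("MKVL", 50)),
                            background = uniform_bg)
  prof_one <- psic_profile(pathopred:::msa_from_strings("MKVL"),
                           background = uniform_bg)
  expect_equal(prof_many$scores, prof_one$scores, tolerance = 1e-12)
  expect_equal(prof_many$n_eff, rep(1, 4))

  # two distant sequences stay in separate clusters: two counts
  prof_two <- psic_profile(pathopred:::msa_from_strings(c("MKVL", "AWGH")),
                           background = uniform_bg)
  expect_equal(prof_two$n_eff, rep(2, 4))
})

test_that("columns with no usable residues fall back to pseudo-counts, flagged", {
  # query carries a non-standard residue at column 2 and every other row a
  # gap there: no independent counts, scores stay at the background (zero)
  msa <- pathopred:::msa_from_strings(c("MXVL", "M-V-", "M-VK"))
  prof <- suppressMessages(psic_profile(msa, background = uniform_bg))
  expect_equal(unname(prof$scores[2, ]), rep(0, 20))
  expect_equal(attr(prof$scores, "flagged"), 2L)
  expect_true(all(is.finite(prof$scores)))
})

test_that("delta-PSIC is the wt-minus-variant score difference, antisymmetric", {
  msa <- pathopred:::msa_from_strings(rep("AAAA", 30))
  prof <- psic_profile(msa, background = uniform_bg)
  d <- delta_psic(prof, 2, "A", "W")
  expect_gt(d, 2) # conserved position, disruptive substitution
  expect_equal(delta_psic(prof, 2, "W", "A"), -d)
  expect_equal(delta_psic(prof, 2, "W", "W"), 0)

  # one singleton cluster per residue type: all frequencies equal, deltas vanish
  msa2 <- pathopred:::msa_from_strings(AA_ALPHABET)
  prof2 <- psic_profile(msa2, background = uniform_bg,
                        clustering_identity = 1.01) # force singleton clusters
  expect_equal(delta_psic(prof2, 1, "C", "Y"), 0, tolerance = 1e-12)
  expect_error(delta_psic(prof, 9, "A", "W"), "position")
})

test_that("BLOSUM62 lookups are the standard matrix and symmetric", {
  expect_equal(substitution_score("A", "A"), 4L)
  expect_equal(substitution_score("W", "C"), -2L)
  grid <- expand.grid(a = AA_ALPHABET, b = AA_ALPHABET,
                      stringsAsFactors = FALSE)
  expect_equal(substitution_score(grid$a, grid$b),
               substitution_score(grid$b, grid$a))
  expect_error(substitution_score("A", "Z"), "amino-acid")
})

test_that("physicochemical deltas are antisymmetric on fixed scales", {
  self <- physchem_features("G", "G")
  expect_equal(self$d_hydrophobicity, 0)
  expect_equal(self$d_volume, 0)
  expect_gt(physchem_features("G", "W")$d_volume, 0)
  ab <- physchem_features("A", "K")
  ba <- physchem_features("K", "A")
  expect_equal(ab$d_volume, -ba$d_volume)
  expect_equal(ab$d_hydrophobicity, -ba$d_hydrophobicity)
  expect_equal(ab$wt_helix_prop, ba$var_helix_prop)
})

test_that("aligned FASTA round-trips through read_msa", {
  msa <- gen_msa("MKVLAW", conservation = rep(0.5, 6), depth = 8, seed = 3)
  path <- tempfile(fileext = ".afa")
  write_msa_fasta(msa, path)
  back <- read_msa(path)
  expect_equal(back$rows, msa$rows)
  expect_equal(back$column_map, msa$column_map)
})

test_that("feature assembly is deterministic, schema-aware and complete", {
  sf <- small_fixture()
  feat_full <- sf$features
  feat_red <- suppressMessages(fixture_features(sf$fix, "reduced",
                                                n_points = 120))
  expect_equal(ncol(feat_full), ncol(feat_red) + 2)
  expect_setequal(setdiff(names(feat_full), names(feat_red)),
                  c("protein_length", "go_term_count"))
  expect_equal(names(feat_full)[-(1:3)], feature_schema("full"))
  expect_false(anyNA(feat_full))

  # determinism and order independence
  again <- suppressMessages(fixture_features(sf$fix, "full", n_points = 120))
  expect_identical(as.data.frame(feat_full), as.data.frame(again))

  shuf <- sf$fix
  set.seed(1)
  shuf$variants <- shuf$variants[sample(nrow(shuf$variants)), ]
  feat_shuf <- suppressMessages(fixture_features(shuf, "full",
                                                 n_points = 120))
  expect_identical(
    as.data.frame(dplyr::arrange(feat_full, variant_id)),
    as.data.frame(dplyr::arrange(feat_shuf, variant_id)))

  # a hand-assembled vector matches the pipeline's row
  v <- sf$fix$variants[1, ]
  row <- feat_full[feat_full$variant_id == v$variant_id, ]
  expect_equal(row$blosum62, as.numeric(substitution_score(v$wt_aa, v$var_aa)))
  pc <- physchem_features(v$wt_aa, v$var_aa)
  expect_equal(row$d_volume, pc$d_volume)
  prof <- psic_profile(sf$fix$msas[[v$accession]])
  expect_equal(row$delta_psic,
               delta_psic(prof, v$position, v$wt_aa, v$var_aa))
  expect_equal(row$psic_wt - row$psic_var, row$delta_psic)

  # missing constituents are named errors
  expect_error(
    assemble_features(v, sf$fix$contexts,
                      tibble::tibble(accession = "other", index = 1,
                                     plddt = 1, sasa = 1, rasa = 1),
                      setNames(list(prof), v$accession), "full"),
    "structural")
  expect_error(
    fixture_features(within(sf$fix, msas <- msas[-1]), "full",
                     n_points = 120),
    "PSIC profile")
})
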