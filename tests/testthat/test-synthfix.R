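small_cfg <- function(seed = 7) {
  synthetic_config(seed = seed, n_proteins = 3, length_range = c(40, 50),
                   n_variants = 60, msa_depth = 15, vus_fraction = 0.2)
}

test_that("generators are pure functions of (config, seed)", {
  cfg <- small_cfg()
  p1 <- gen_protein(cfg, 2)
  p2 <- gen_protein(cfg, 2)
  expect_identical(p1, p2)
  expect_false(identical(gen_protein(cfg, 1)$sequence, p1$sequence))

  d1 <- tempfile(); d2 <- tempfile()
  suppressMessages(generate_fixture(cfg, d1))
  suppressMessages(generate_fixture(cfg, d2))
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  md5_1 <- unname(tools::md5sum(file.path(d1, f1)))
  md5_2 <- unname(tools::md5sum(file.path(d2, f1)))
  expect_identical(md5_1, md5_2)
})

test_that("toy proteins have exposed low-confidence termini and buried cores", {
  cfg <- small_cfg()
  p <- gen_protein(cfg, 1)
  expect_true(all(p$plddt >= 0 & p$plddt <= 100))
  expect_gt(mean(p$plddt[p$core]), mean(p$plddt[!p$core]))

  sf <- suppressMessages(residue_struct_features(p$model, n_points = 240))
  expect_gt(mean(sf$sasa[!p$core]), mean(sf$sasa[p$core]))
})

test_that("alignment columns track the requested conservation", {
  seq <- strsplit(paste(rep("MKVLAWGRQN", 3), collapse = ""), "")[[1]]
  cons <- rep(c(1, 0.05), length.out = 30)
  msa <- gen_msa(seq, cons, depth = 200, seed = 9)
  expect_equal(dim(msa$rows), c(200, 30))

  # fully conserved column: all rows identical
  expect_equal(length(unique(msa$rows[, 1])), 1)

  # weakly conserved column: homolog query-residue frequency in the
  # binomial band around 0.05 plus background mass
  freq <- mean(msa$rows[-1, 2] == seq[2])
  expect_gte(freq, 0)
  expect_lte(freq, 0.25)

  # PSIC scores the query residue strictly highest at a conserved column
  prof <- psic_profile(msa)
  qi <- match(seq[1], AA_ALPHABET)
  expect_true(all(prof$scores[1, qi] > prof$scores[1, -qi]))

  expect_error(gen_msa(seq, cons[1:3], 10), "match the sequence")
})

test_that("variant sets plant the documented class structure", {
  cfg <- small_cfg()
  proteins <- lapply(1:3, function(i) gen_protein(cfg, i))
  vs <- gen_variant_set(cfg, proteins)
  expect_equal(nrow(vs$variants), 60 + round(60 * 0.2))
  expect_true(all(vs$variants$wt_aa != vs$variants$var_aa))

  man <- vs$manifest
  expect_gt(mean(man$conservation[man$planted_label == 1]),
            mean(man$conservation[man$planted_label == 0]))
  expect_gt(mean(man$core[man$planted_label == 1]),
            mean(man$core[man$planted_label == 0]))
  expect_gt(mean(man$plddt[man$planted_label == 1]),
            mean(man$plddt[man$planted_label == 0]))

  # noise-free config: emitted labels equal the manifest labels
  cfg0 <- synthetic_config(seed = 3, n_proteins = 3,
                           length_range = c(40, 50), n_variants = 60,
                           msa_depth = 15, label_noise = 0,
                           vus_fraction = 0)
  vs0 <- gen_variant_set(cfg0, lapply(1:3, function(i) gen_protein(cfg0, i)))
  expect_identical(harmonize_label(vs0$variants$raw_label),
                   ifelse(vs0$manifest$planted_label == 1, "PATHOGENIC",
                          "BENIGN"))

  # over-subscription is an error
  cfg_big <- synthetic_config(seed = 1, n_proteins = 1,
                              length_range = c(40, 40), n_variants = 200,
                              msa_depth = 5)
  expect_error(gen_variant_set(cfg_big, list(gen_protein(cfg_big, 1))),
               "positions available")
})

test_that("binormal comparator scores hit the target separability", {
  y <- rep(c(1, 0), each = 500)
  null_tools <- gen_comparator_scores(y, paste0("v", 1:1000),
                                      target_auc = 0.5, n_tools = 1,
                                      seed = 5)
  a0 <- auroc(y, null_tools$scores$score)
  expect_gte(a0, 0.45); expect_lte(a0, 0.55)

  mid <- gen_comparator_scores(y, paste0("v", 1:1000), target_auc = 0.8,
                               n_tools = 2, seed = 6, has_calls = c(TRUE,
                                                                    FALSE))
  for (tl in unique(mid$scores$tool)) {
    a <- auroc(y, mid$scores$score[mid$scores$tool == tl])
    expect_gte(a, 0.76); expect_lte(a, 0.84)
  }
  expect_true(all(mid$scores$score >= 0 & mid$scores$score <= 1))
  expect_true(all(is.na(mid$scores$call[mid$scores$tool == "tool02"])))
  expect_false(anyNA(mid$scores$call[mid$scores$tool == "tool01"]))
  expect_error(gen_comparator_scores(y, paste0("v", 1:1000), 0.3), "target_auc")
})
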