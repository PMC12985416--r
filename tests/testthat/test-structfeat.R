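test_that("Shrake-Rupley SASA matches sphere geometry", {
  # isolated atom: exact expanded-sphere area
  m <- atom_model(radius = 1.7)
  s <- compute_sasa(m, probe_radius = 1.4, n_points = 960)
  analytic <- 4 * pi * 3.1^2
  expect_lt(abs(s$sasa - analytic) / analytic, 0.01)

  # two coincident identical atoms fully occlude each other
  m2 <- atom_model(coords = matrix(0, 2, 3))
  s2 <- compute_sasa(m2, n_points = 240)
  expect_equal(sum(s2$sasa), 0)

  # separation beyond the sum of expanded radii: no occlusion
  m3 <- atom_model(coords = rbind(c(0, 0, 0), c(6.3, 0, 0)))
  s3 <- compute_sasa(m3, n_points = 240)
  expect_equal(unname(s3$sasa), rep(4 * pi * 3.1^2, 2), tolerance = 1e-10)

  expect_error(compute_sasa(m, n_points = 5), "n_points")
})

test_that("two-sphere SASA converges to the analytic cap area", {
  # equal spheres, centers 3 A apart: exposed = 4*pi*R^2 - 2*pi*R*(R - d/2)
  coords <- rbind(c(0, 0, 0), c(3, 0, 0))
  R <- 1.7 + 1.4
  analytic <- 4 * pi * R^2 - 2 * pi * R * (R - 3 / 2)
  errs <- sapply(c(96, 960), function(np) {
    s <- compute_sasa(atom_model(coords = coords), n_points = np)
    abs(s$sasa[1] - analytic)
  })
  expect_lt(errs[2], errs[1] + 1e-9)
  expect_lt(errs[2] / analytic, 0.01)
})

test_that("SASA is rigid-motion invariant and monotone under atom addition", {
  set.seed(5)
  coords <- matrix(rnorm(30, sd = 3), 10, 3)
  base <- compute_sasa(atom_model(coords = coords), n_points = 480)

  # random rotation + translation
  qr_rot <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  moved <- sweep(coords %*% qr_rot, 2, c(5, -3, 11), "+")
  rot <- compute_sasa(atom_model(coords = moved), n_points = 480)
  expect_equal(sum(rot$sasa), sum(base$sasa),
               tolerance = 0.01)

  # adding atoms never increases total SASA of the original set
  for (i in 1:5) {
    extra <- rbind(coords, matrix(rnorm(6, sd = 2), 2, 3))
    bigger <- compute_sasa(atom_model(coords = extra), n_points = 480)
    expect_lte(sum(bigger$sasa[1:10]), sum(base$sasa) + 1e-9)
  }
})

test_that("rASA is the max-ASA ratio, unclamped but flagged when extreme", {
  expect_equal(compute_rasa(0, "A"), 0)
  expect_equal(compute_rasa(unname(MAX_ASA_TIEN2013["W"]), "W"), 1)
  expect_equal(compute_rasa(64.5, "A", c(A = 129.0)), 0.5)
  # linear in sasa for fixed residue type
  s <- c(0, 10, 20, 40)
  expect_equal(compute_rasa(2 * s, "G"), 2 * compute_rasa(s, "G"))
  expect_error(compute_rasa(10, "B"), "amino-acid")
  expect_error(compute_rasa(-1, "A"), "non-negative")
  expect_message(compute_rasa(1000, "A"), "rASA > 1.2")
})

test_that("PDB structures round-trip with pLDDT read from the B-factor column", {
  cfg <- synthetic_config(seed = 5, n_proteins = 1,
                          length_range = c(30, 30), n_variants = 5,
                          msa_depth = 5, vus_fraction = 0)
  p <- gen_protein(cfg, 1)
  path <- tempfile(fileext = ".pdb")
  write_structure_pdb(p$model, path)
  m <- read_structure(path)
  expect_equal(nrow(m$residues), 30)
  expect_equal(m$residues$aa, p$sequence)
  expect_equal(m$residues$plddt, round(p$plddt, 2))
  expect_equal(m$atoms$x, round(p$model$atoms$x, 3))
  expect_true(all(m$atoms$radius > 0))
})

test_that("structures with chain breaks or no B-factors are rejected", {
  lines <- sprintf(
    "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    1:3, c(1L, 3L, 4L), c(0, 4, 8), 0, 0, 1, 91.3)
  path <- tempfile(fileext = ".pdb")
  writeLines(c(lines, "END"), path)
  expect_error(read_structure(path), "missing residue index\\(es\\) 2")

  # a single-residue file reads the stated B-factor as pLDDT
  path2 <- tempfile(fileext = ".pdb")
  writeLines(c(lines[1], "END"), path2)
  m <- read_structure(path2)
  expect_equal(m$residues$plddt, 91.3)

  # B-factor outside [0, 100] is not a pLDDT channel
  bad <- sub("91.30", "250.0", lines[1])
  path3 <- tempfile(fileext = ".pdb")
  writeLines(c(bad, "END"), path3)
  expect_error(read_structure(path3), "pLDDT")
})

test_that("per-residue feature table combines pLDDT, SASA and rASA", {
  cfg <- synthetic_config(seed = 8, n_proteins = 1,
                          length_range = c(40, 40), n_variants = 5,
                          msa_depth = 5, vus_fraction = 0)
  p <- gen_protein(cfg, 1)
  rf <- suppressMessages(residue_struct_features(p$model, n_points = 240))
  expect_equal(nrow(rf), 40)
  expect_equal(rf$rasa,
               rf$sasa / unname(MAX_ASA_TIEN2013[rf$aa]))
  expect_true(all(rf$sasa >= 0))
  expect_equal(rf$plddt, p$plddt)
})
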