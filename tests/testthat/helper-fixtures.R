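# Shared in-code fixtures. Everything is generated at test time; the only
# cross-test cache is a small planted-signal fixture reused where a full
# feature table is needed.

.fixture_cache <- new.env(parent = emptyenv())

# small planted fixture + features, built once per test run
small_fixture <- function() {
  if (is.null(.fixture_cache$fix)) {
    cfg <- synthetic_config(seed = 42L, n_proteins = 8L,
                            length_range = c(60L, 80L), n_variants = 300L,
                            msa_depth = 25L, vus_fraction = 0.2)
    dir <- file.path(tempdir(), "pathopred_small_fixture")
    .fixture_cache$fix <- suppressMessages(generate_fixture(cfg, dir))
    .fixture_cache$features <- suppressMessages(
      fixture_features(.fixture_cache$fix, "full", n_points = 120))
  }
  list(fix = .fixture_cache$fix, features = .fixture_cache$features)
}

small_pool <- function() {
  feat <- small_fixture()$features
  feat[feat$label %in% c("PATHOGENIC", "BENIGN"), ]
}

# single-atom structure model
atom_model <- function(x = 0, y = 0, z = 0, radius = 1.7, n = 1,
                       coords = NULL) {
  if (is.null(coords)) coords <- matrix(c(x, y, z), ncol = 3)
  n <- nrow(coords)
  structure(list(
    accession = "toy",
    residues = tibble::tibble(index = seq_len(n),
                              aa = rep("A", n), plddt = rep(90, n)),
    atoms = tibble::tibble(residue_index = seq_len(n), element = "C",
                           x = coords[, 1], y = coords[, 2],
                           z = coords[, 3], radius = radius)),
    class = "structure_model")
}

# canonical-dialect variant CSV writer
write_variant_fixture <- function(rows, path = tempfile(fileext = ".csv")) {
  readr::write_csv(rows, path, progress = FALSE)
  path
}

# quick gaussian classification table for model-structure tests
gaussian_data <- function(n = 200, p = 5, informative = 2, seed = 1,
                          prefix = "f") {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0(prefix, seq_len(p))))
  lin <- X[, seq_len(informative), drop = FALSE] %*%
    rep(1.5, informative)
  y <- as.integer(lin + rnorm(n, 0, 0.8) > 0)
  out <- tibble::as_tibble(as.data.frame(X))
  out$label <- y
  out
}

# narrowed random-forest space to keep search loops quick in tests
small_rf_space <- function() {
  list(num_trees = param_def("int", 50, 150),
       max_depth = param_def("int", 3, 15),
       min_node_size = param_def("int", 1, 10),
       mtry_mode = param_def("categorical",
                             values = c("sqrt", "log2", "frac")),
       mtry_frac = param_def("uniform", 0.3, 1.0))
}
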