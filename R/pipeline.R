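# End-to-end orchestration: config validation, feature building over a
# fixture directory, staged execution with a checksummed run manifest.

PIPELINE_STAGES <- c("simulate", "prepare", "features", "train",
                     "benchmark", "reclassify")

default_config <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    stages = PIPELINE_STAGES,
    synth = list(n_proteins = 60L, length_range = c(100L, 160L),
                 n_variants = 2000L, pathogenic_fraction = 0.5,
                 effect = list(conservation_gap = 0.9, burial_gap = 0.8,
                               plddt_gap = 40),
                 label_noise = 0.02, msa_depth = 50L, vus_fraction = 0.2,
                 target_auc = 0.9, n_tools = 4L),
    prepare = list(min_stars = 1L, require_germline = TRUE,
                   test_fraction = 0.2),
    features = list(schema = "full", probe_radius = 1.4, n_points = 240L),
    train = list(algorithm = "rf", outer_k = 5L, inner_k = 3L,
                 n_trials = 150L),
    reclassify = list(hi = 0.95, lo = 0.05, min_tools = NULL)
  )
}

merge_checked <- function(defaults, given, path = "") {
  unknown <- setdiff(names(given), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s)%s: %s",
                  if (nzchar(path)) paste0(" in ", path) else "",
                  paste(unknown, collapse = ", ")))
  }
  for (k in names(given)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(given[[k]]) &&
                         !is.null(names(defaults[[k]]))) {
      merge_checked(defaults[[k]], given[[k]],
                    paste0(path, if (nzchar(path)) ".", k))
    } else {
      given[[k]]
    }
  }
  defaults
}

#' Validate and normalize a pipeline configuration
#'
#' Accepts a JSON/YAML file path or a list; injects defaults for missing
#' keys, rejects unknown keys by name, and cross-checks fields (stage list
#' must be a prefix of the stage order; reclassification thresholds must
#' satisfy `hi > lo`). An empty file yields the all-defaults config.
#'
#' @param config Path to a JSON or YAML file, or a (possibly empty) list.
#' @return Normalized config list (class `pathopred_config`).
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    txt <- readLines(config, warn = FALSE)
    config <- if (all(!nzchar(trimws(txt)))) list()
    else if (grepl("\\.ya?ml$", config)) yaml::yaml.load(paste(txt, collapse = "\n"))
    else jsonlite::fromJSON(paste(txt, collapse = "\n"),
                            simplifyVector = TRUE)
    config <- config %||% list()
  }
  cfg <- merge_checked(default_config(), config)
  if (!all(cfg$stages %in% PIPELINE_STAGES) ||
      !identical(cfg$stages, PIPELINE_STAGES[seq_along(cfg$stages)])) {
    abort("`stages` must be a prefix of: simulate, prepare, features, train, benchmark, reclassify")
  }
  if (cfg$reclassify$hi <= cfg$reclassify$lo) {
    abort(sprintf("reclassification thresholds out of order: hi = %g <= lo = %g",
                  cfg$reclassify$hi, cfg$reclassify$lo))
  }
  if (cfg$features$n_points < 10) abort("features.n_points must be >= 10")
  if (!cfg$train$algorithm %in% c("rf", "xgb")) {
    abort("train.algorithm must be 'rf' or 'xgb'")
  }
  structure(cfg, class = "pathopred_config")
}

#' Build the feature table for an in-memory fixture
#'
#' Convenience wrapper running structural feature extraction and PSIC
#' profiling over the objects returned by [generate_fixture()], then
#' assembling the requested schema for the fixture's variants.
#'
#' @param fix List returned by [generate_fixture()].
#' @param schema `"full"` or `"reduced"`.
#' @param probe_radius,n_points SASA settings (see [compute_sasa()]).
#' @return Feature tibble from [assemble_features()], with harmonized
#'   `label` column.
#' @export
fixture_features <- function(fix, schema = c("full", "reduced"),
                             probe_radius = 1.4, n_points = 240) {
  schema <- arg_match(schema)
  struct <- list_rbind(map(fix$proteins, function(p) {
    residue_struct_features(p$model, probe_radius = probe_radius,
                            n_points = n_points)
  }))
  profiles <- map(fix$msas, psic_profile)
  variants <- fix$variants
  variants$label <- harmonize_label(variants$raw_label)
  assemble_features(variants, fix$contexts, struct, profiles,
                    schema = schema)
}

read_fixture_dir <- function(dir) {
  pdbs <- list.files(file.path(dir, "pdb"), full.names = TRUE,
                     pattern = "\\.pdb$")
  proteins <- map(pdbs, function(p) {
    model <- read_structure(p)
    list(accession = model$accession, model = model,
         sequence = model$residues$aa)
  })
  names(proteins) <- map_chr(proteins, "accession")
  msas <- map(proteins, function(p) {
    read_msa(file.path(dir, "msa", paste0(p$accession, ".afa")))
  })
  list(
    proteins = proteins, msas = msas,
    contexts = readr::read_csv(file.path(dir, "contexts.csv"),
                               show_col_types = FALSE, progress = FALSE),
    variants_path = file.path(dir, "variants.csv"),
    comparators = readr::read_csv(file.path(dir, "comparators.csv"),
                                  show_col_types = FALSE, progress = FALSE),
    comparator_manifest = readr::read_csv(
      file.path(dir, "comparator_manifest.csv"), show_col_types = FALSE,
      progress = FALSE)
  )
}

checksum_files <- function(paths) {
  paths <- paths[file.exists(paths)]
  sums <- tools::md5sum(paths)
  setNames(as.list(unname(sums)), basename(paths))
}

#' Run the pipeline end-to-end
#'
#' Executes simulate, prepare, features, train, benchmark and reclassify
#' (or any leading subset per `config$stages`), logging per-stage
#' input/output counts and recording md5 checksums of every artifact in a
#' run manifest. Inputs are never mutated; all outputs land under
#' `config$out_dir`. A failing stage aborts with the stage named; partial
#' outputs are retained.
#'
#' @param config A [validate_config()] result, or anything it accepts.
#' @return A `run_manifest`: list with `config_hash`, per-stage output
#'   checksums, `seed` and package version.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pathopred_config")) config
         else validate_config(config)
  out_dir <- cfg$out_dir %||% tempfile("pathopred_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(cfg), cfg_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  manifest <- list(config_hash = unname(tools::md5sum(cfg_path)),
                   seed = cfg$seed,
                   version = as.character(utils::packageVersion("pathopred")),
                   stages = list())
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    if (!name %in% cfg$stages) return(invisible(NULL))
    inform(sprintf("[%s] starting", name))
    outputs <- tryCatch(fun(), error = function(e) {
      abort(sprintf("pipeline stage `%s` failed: %s", name,
                    conditionMessage(e)), parent = e)
    })
    manifest$stages[[name]] <<- list(outputs = checksum_files(outputs))
    inform(sprintf("[%s] done (%d artifact(s))", name, length(outputs)))
  }

  run_stage("simulate", function() {
    sy <- cfg$synth
    sc <- synthetic_config(
      seed = cfg$seed, n_proteins = sy$n_proteins,
      length_range = sy$length_range, n_variants = sy$n_variants,
      pathogenic_fraction = sy$pathogenic_fraction, effect = sy$effect,
      label_noise = sy$label_noise, msa_depth = sy$msa_depth,
      vus_fraction = sy$vus_fraction)
    fix_dir <- file.path(out_dir, "fixture")
    generate_fixture(sc, fix_dir, target_auc = sy$target_auc,
                     n_tools = sy$n_tools)
    state$fix <- read_fixture_dir(fix_dir)
    list.files(fix_dir, recursive = TRUE, full.names = TRUE)
  })

  run_stage("prepare", function() {
    fx <- state$fix
    variants <- read_variant_table(fx$variants_path)
    inform(sprintf("[prepare] parsed %d variants", nrow(variants)))
    variants <- filter_variants(variants, cfg$prepare$min_stars,
                                cfg$prepare$require_germline)
    seqs <- setNames(map_chr(fx$proteins,
                             ~ paste(.x$sequence, collapse = "")),
                     names(fx$proteins))
    ok <- validate_mapping(variants, seqs)
    if (any(!ok)) inform(sprintf("[prepare] dropped %d mapping failures",
                                 sum(!ok)))
    variants <- variants[ok, ]
    state$variants <- variants
    pool <- filter(variants, label %in% c("PATHOGENIC", "BENIGN"))
    state$split <- split_train_test(pool, cfg$prepare$test_fraction,
                                    seed = cfg$seed)
    p1 <- file.path(out_dir, "variants_harmonized.csv")
    p2 <- file.path(out_dir, "split_manifest.json")
    write_variant_table(variants, p1)
    write_split_manifest(state$split, p2)
    c(p1, p2)
  })

  run_stage("features", function() {
    fx <- state$fix
    struct <- list_rbind(map(fx$proteins, function(p) {
      residue_struct_features(p$model,
                              probe_radius = cfg$features$probe_radius,
                              n_points = cfg$features$n_points)
    }))
    profiles <- map(fx$msas, psic_profile)
    state$features <- assemble_features(
      state$variants, fx$contexts, struct, profiles,
      schema = cfg$features$schema)
    state$struct <- struct
    p <- file.path(out_dir, "features.csv")
    readr::write_csv(state$features, p, progress = FALSE)
    p
  })

  run_stage("train", function() {
    feat <- state$features
    train_feat <- feat[feat$variant_id %in% state$split$train$variant_id, ]
    test_feat <- feat[feat$variant_id %in% state$split$test$variant_id, ]
    cv <- nested_cv(train_feat, cfg$train$algorithm,
                    outer_k = cfg$train$outer_k,
                    inner_k = cfg$train$inner_k,
                    n_trials = cfg$train$n_trials, seed = cfg$seed)
    best_fold <- which.max(cv$fold_metrics$auroc)
    model <- fit_final(train_feat, cfg$train$algorithm,
                       hyperparameters = cv$best_params[[best_fold]],
                       seed = cfg$seed)
    state$cv <- cv
    state$model <- model
    state$test_feat <- test_feat
    model_dir <- file.path(out_dir, "model")
    save_model(model, model_dir)
    p_cv <- file.path(out_dir, "cv_report.json")
    jsonlite::write_json(
      list(fold_metrics = cv$fold_metrics, summary = cv$summary,
           n_trials = cv$n_trials),
      p_cv, auto_unbox = TRUE, digits = NA)
    c(list.files(model_dir, full.names = TRUE), p_cv)
  })

  run_stage("benchmark", function() {
    fx <- state$fix
    test_feat <- state$test_feat
    truth <- select(test_feat, variant_id, label)
    scores <- predict_proba(state$model, test_feat)
    own <- compute_metrics(truth$label, scores)
    comp <- benchmark_comparators(truth, fx$comparators,
                                  fx$comparator_manifest)
    bench <- bind_rows(
      bind_cols(tibble(tool = paste0("model_", state$model$algorithm)),
                own |> select(-n), tibble(n = own$n)),
      comp)
    state$benchmark <- bench
    p <- file.path(out_dir, "benchmark.csv")
    readr::write_csv(bench, p, progress = FALSE)
    p
  })

  run_stage("reclassify", function() {
    fx <- state$fix
    feat <- state$features
    vus_feat <- feat[feat$label %in% c("VUS", "CONFLICTING"), ]
    if (nrow(vus_feat) == 0) {
      inform("[reclassify] no VUS/conflicting variants; nothing to do")
      return(character())
    }
    model_scores <- tibble(variant_id = vus_feat$variant_id,
                           model = predict_proba(state$model, vus_feat))
    comp_wide <- fx$comparators |>
      select(variant_id, tool, score) |>
      tidyr::pivot_wider(names_from = tool, values_from = score)
    meta <- state$variants |>
      filter(variant_id %in% vus_feat$variant_id) |>
      mutate(prior_label = label,
             review_status = c("SINGLE_SUBMITTER", "MULTIPLE_NO_CONSENSUS",
                               "EXPERT")[pmin(review_stars, 3)]) |>
      select(variant_id, gene, prior_label, review_status)
    score_tab <- meta |>
      dplyr::inner_join(model_scores, by = "variant_id") |>
      dplyr::inner_join(comp_wide, by = "variant_id")
    decisions <- consensus_reclassify(
      score_tab, hi = cfg$reclassify$hi, lo = cfg$reclassify$lo,
      min_tools = cfg$reclassify$min_tools)
    state$decisions <- decisions
    p1 <- file.path(out_dir, "reclassification.csv")
    readr::write_csv(as_tibble(decisions), p1, progress = FALSE)
    p2 <- file.path(out_dir, "reclassification_summary.json")
    jsonlite::write_json(summarize_reclassification(decisions), p2,
                         auto_unbox = TRUE, digits = NA)
    c(p1, p2)
  })

  manifest$out_dir <- out_dir
  manifest$results <- as.list(state)
  structure(manifest, class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> %d stage(s) completed under %s\n",
              length(x$stages), x$out_dir))
  for (nm in names(x$stages)) {
    cat(sprintf("  %-10s %d artifact(s)\n", nm,
                length(x$stages[[nm]]$outputs)))
  }
  invisible(x)
}
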