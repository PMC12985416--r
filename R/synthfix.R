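# Seeded synthetic fixtures: toy proteins (sequence + helical structure +
# pLDDT profile), alignments with controlled per-position conservation,
# labeled variant tables with planted class structure, and binormal
# comparator score tables. Everything is a pure function of (config, seed).

AA_ONE_TO_THREE <- toupper(setNames(names(AA_THREE_TO_ONE), AA_THREE_TO_ONE))

derive_seed <- function(seed, index, salt = 0L) {
  as.integer((as.numeric(seed) * 7919 + index * 104729 + salt * 131) %%
               2147483647)
}

#' Configuration for synthetic fixture generation
#'
#' The defaults define the simulated study conditions: a panel of toy
#' proteins whose ordered core is an alpha-helix (high pLDDT, buried) and
#' whose termini are extended and disordered (low pLDDT, exposed), with
#' pathogenic variants planted preferentially at conserved, buried,
#' high-confidence positions and benign variants at the opposite.
#'
#' @param seed Integer master seed.
#' @param n_proteins Number of proteins (default 60).
#' @param length_range Min/max residues per protein (default 100-160;
#'   minimum allowed is 20).
#' @param n_variants Pathogenic/benign variants to plant (default 2000).
#' @param pathogenic_fraction Fraction of planted pathogenic labels
#'   (default 0.5).
#' @param effect Planted effect sizes: `conservation_gap` and `burial_gap`
#'   (differences between the probabilities that a pathogenic vs benign
#'   variant lands on a conserved / buried position, each in \[0, 1\]) and
#'   `plddt_gap` (mean pLDDT difference between core and terminal
#'   segments, points).
#' @param label_noise Probability of flipping an emitted label
#'   (in \[0, 0.5)).
#' @param msa_depth Alignment rows per protein, query included
#'   (default 50).
#' @param vus_fraction Extra variants emitted as VUS/conflicting, as a
#'   fraction of `n_variants` (default 0.2); their latent planted label is
#'   recorded only in the manifest.
#' @return Validated `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L, n_proteins = 60L,
                             length_range = c(100L, 160L),
                             n_variants = 2000L, pathogenic_fraction = 0.5,
                             effect = list(conservation_gap = 0.9,
                                           burial_gap = 0.8,
                                           plddt_gap = 40),
                             label_noise = 0.02, msa_depth = 50L,
                             vus_fraction = 0.2) {
  if (length_range[1] < 20) abort("minimum protein length is 20")
  if (length_range[1] > length_range[2]) abort("bad length_range")
  if (pathogenic_fraction <= 0 || pathogenic_fraction >= 1) {
    abort("pathogenic_fraction must lie in (0, 1)")
  }
  if (label_noise < 0 || label_noise >= 0.5) {
    abort("label_noise must lie in [0, 0.5)")
  }
  effect <- modifyList(list(conservation_gap = 0.9, burial_gap = 0.8,
                            plddt_gap = 40), effect)
  for (g in c("conservation_gap", "burial_gap")) {
    if (effect[[g]] < 0 || effect[[g]] > 1) abort(sprintf("%s must lie in [0,1]", g))
  }
  structure(list(seed = as.integer(seed), n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 n_variants = as.integer(n_variants),
                 pathogenic_fraction = pathogenic_fraction, effect = effect,
                 label_noise = label_noise, msa_depth = as.integer(msa_depth),
                 vus_fraction = vus_fraction),
            class = "synthetic_config")
}

#' Generate one synthetic protein
#'
#' Random sequence (BLOSUM62 background frequencies); backbone on an ideal
#' alpha-helix (2.3 A radius, 1.5 A rise, 100 degrees per residue) for the
#' core segment, with the dummy side-chain sphere tucked toward the helix
#' axis so core residues are occluded, and a sparse extended arc
#' (6.5 A rise, far from the axis, side chains outward) for the terminal
#' ~15% at each end so terminal residues are exposed. pLDDT is high in
#' the core and low in the terminal segments; per-position conservation
#' mixes conserved (0.85-0.99) and variable (0.10-0.40) positions.
#'
#' @param config A `synthetic_config`.
#' @param index Protein index (1-based); output is deterministic per
#'   (seed, index).
#' @return List with `accession`, `sequence`, `core` (logical per
#'   residue), `conserved` (logical), `conservation` (numeric), `plddt`,
#'   and `model` (a ready `structure_model`).
#' @export
gen_protein <- function(config, index) {
  set.seed(derive_seed(config$seed, index, 1L))
  lens <- seq(config$length_range[1], config$length_range[2])
  len <- lens[sample.int(length(lens), 1)]
  sequence <- sample(AA_ALPHABET, len, replace = TRUE,
                     prob = BLOSUM62_FREQ)
  n_term <- max(3L, round(0.15 * len))
  core <- rep(TRUE, len)
  core[seq_len(n_term)] <- FALSE
  core[seq(len - n_term + 1, len)] <- FALSE

  gap <- config$effect$plddt_gap
  plddt <- ifelse(core, 70 + gap / 2, 70 - gap / 2) + rnorm(len, 0, 3)
  plddt <- pmin(100, pmax(0, plddt))

  conserved <- runif(len) < 0.5
  conservation <- ifelse(conserved, runif(len, 0.85, 0.99),
                         runif(len, 0.10, 0.40))

  # geometry: compact helix core with side chains tucked toward the axis
  # (buried), sparse extended termini far from the axis (exposed); z
  # advances along the chain
  xyz <- matrix(0, len, 3)
  side <- matrix(0, len, 3)
  z <- 0
  for (i in seq_len(len)) {
    theta <- i * 100 * pi / 180
    if (core[i]) {
      xyz[i, ] <- c(2.3 * cos(theta), 2.3 * sin(theta), z)
      side[i, ] <- c(0.4 * cos(theta), 0.4 * sin(theta), z)
      z <- z + 1.5
    } else {
      xyz[i, ] <- c(9 * cos(theta), 9 * sin(theta), z)
      side[i, ] <- c(12 * cos(theta), 12 * sin(theta), z)
      z <- z + 6.5
    }
  }

  atoms <- tibble(
    residue_index = rep(seq_len(len), each = 2),
    element = rep(c("C", "C"), len),
    x = as.numeric(rbind(xyz[, 1], side[, 1])),
    y = as.numeric(rbind(xyz[, 2], side[, 2])),
    z = as.numeric(rbind(xyz[, 3], side[, 3])),
    radius = unname(VDW_RADII["C"])
  )
  accession <- sprintf("SYN%04d", index)
  model <- structure(
    list(accession = accession,
         residues = tibble(index = seq_len(len), aa = sequence,
                           plddt = plddt),
         atoms = atoms),
    class = "structure_model")
  list(accession = accession, sequence = sequence, core = core,
       conserved = conserved, conservation = conservation, plddt = plddt,
       model = model)
}

#' Write a structure model as a PDB file with pLDDT in the B-factor column
#'
#' @param model A `structure_model` (atom names CA and CB are emitted for
#'   the backbone and dummy side-chain spheres).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(model, path) {
  res <- model$residues
  at <- model$atoms
  plddt <- setNames(res$plddt, res$index)
  aa3 <- AA_ONE_TO_THREE[setNames(res$aa, res$index)[as.character(at$residue_index)]]
  name <- rep(c("CA", "CB"), length.out = nrow(at))
  lines <- sprintf(
    "ATOM  %5d  %-3s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(at)), name, aa3, at$residue_index, at$x, at$y, at$z, 1,
    plddt[as.character(at$residue_index)], at$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Generate a synthetic alignment with controlled conservation
#'
#' Row 1 is the (ungapped) query; each additional row emits the query
#' residue at position j with probability `conservation[j]` and otherwise
#' a non-query substitution drawn from the BLOSUM62 conditional
#' distribution given the query residue (so homolog rows carry realistic
#' conservative substitutions). No gaps are produced.
#'
#' @param sequence Query residues (character vector or single string).
#' @param conservation Per-position conservation probabilities in
#'   \[0, 1\], one per residue.
#' @param depth Total rows including the query.
#' @param seed Integer seed.
#' @return An `msa` object.
#' @export
gen_msa <- function(sequence, conservation, depth, seed = 1L) {
  if (length(sequence) == 1) sequence <- strsplit(sequence, "")[[1]]
  if (length(conservation) != length(sequence)) {
    abort("`conservation` must match the sequence length")
  }
  set.seed(seed)
  len <- length(sequence)
  # substitution model: p(a | wt) proportional to
  # freq[a] * 2^(blosum62[wt, a] / 2) over a != wt, so `conservation` is
  # exactly the per-position query-residue emission probability
  b62 <- blosum62_matrix()
  cond <- sweep(2^(b62 / 2), 2, BLOSUM62_FREQ, "*")
  diag(cond) <- 0
  cond <- cond / rowSums(cond)
  rows <- matrix("", depth, len)
  rows[1, ] <- sequence
  for (r in seq(2, length.out = depth - 1)) {
    keep <- runif(len) < conservation
    sub <- vapply(sequence, function(wt) {
      sample(AA_ALPHABET, 1, prob = cond[wt, ])
    }, "")
    rows[r, ] <- ifelse(keep, sequence, sub)
  }
  msa_from_strings(apply(rows, 1, paste, collapse = ""))
}

#' Write an `msa` as aligned FASTA
#' @param msa An `msa` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_msa_fasta <- function(msa, path) {
  seqs <- apply(msa$rows, 1, paste, collapse = "")
  writeLines(as.vector(rbind(paste0(">", rownames(msa$rows)), seqs)), path)
  invisible(path)
}

pick_variant_aa <- function(wt, damaging) {
  m <- blosum62_matrix()
  sc <- m[wt, setdiff(AA_ALPHABET, wt)]
  pool <- if (damaging) names(sort(sc))[1:4] else
    names(sort(sc, decreasing = TRUE))[1:2]
  sample(pool, 1)
}

#' Generate a labeled variant table with planted class structure
#'
#' Pathogenic variants are sampled preferentially at conserved, buried
#' (core), high-pLDDT positions — the gaps set by `config$effect` — with
#' dissimilar substitutions (low BLOSUM62), and benign variants at the
#' opposite, with conservative substitutions. Emitted labels flip with
#' probability `label_noise`; a further `vus_fraction` of variants is
#' emitted as VUS/conflicting with the latent label recorded only in the
#' manifest. Positions are drawn without replacement; requesting more
#' variants than available positions is an error.
#'
#' @param config A `synthetic_config`.
#' @param proteins List of proteins from [gen_protein()].
#' @return List with `variants` (tibble: `variant_id`, `gene`,
#'   `accession`, `position`, `wt_aa`, `var_aa`, `raw_label`,
#'   `review_stars`, `review_status`, `origin`) and `manifest` (tibble of
#'   planted truths plus the planted directions as attribute
#'   `"directions"`).
#' @export
gen_variant_set <- function(config, proteins) {
  set.seed(derive_seed(config$seed, 0L, 2L))
  pos_tab <- list_rbind(map(proteins, function(p) {
    tibble(accession = p$accession, position = seq_along(p$sequence),
           wt_aa = p$sequence, core = p$core, conserved = p$conserved,
           conservation = p$conservation, plddt = p$plddt)
  }))
  n_vus <- round(config$n_variants * config$vus_fraction)
  n_total <- config$n_variants + n_vus
  if (n_total > nrow(pos_tab)) {
    abort(sprintf("requested %d variants but only %d positions available",
                  n_total, nrow(pos_tab)))
  }

  n_path <- round(config$n_variants * config$pathogenic_fraction)
  planted <- c(rep(1L, n_path), rep(0L, config$n_variants - n_path),
               rbinom(n_vus, 1, config$pathogenic_fraction))
  is_vus <- c(rep(FALSE, config$n_variants), rep(TRUE, n_vus))

  cg <- config$effect$conservation_gap
  bg <- config$effect$burial_gap
  w_path <- (0.5 + cg / 2)^pos_tab$conserved *
    (0.5 - cg / 2)^(!pos_tab$conserved) *
    (0.5 + bg / 2)^pos_tab$core * (0.5 - bg / 2)^(!pos_tab$core)
  w_ben <- (0.5 - cg / 2)^pos_tab$conserved *
    (0.5 + cg / 2)^(!pos_tab$conserved) *
    (0.5 - bg / 2)^pos_tab$core * (0.5 + bg / 2)^(!pos_tab$core)

  avail <- rep(TRUE, nrow(pos_tab))
  rows <- integer(n_total)
  for (i in seq_len(n_total)) {
    w <- if (planted[i] == 1) w_path else w_ben
    idx <- which(avail)
    j <- idx[sample.int(length(idx), 1, prob = w[idx])]
    rows[i] <- j
    avail[j] <- FALSE
  }
  vt <- pos_tab[rows, ]
  vt$planted_label <- planted
  vt$is_vus <- is_vus
  vt$var_aa <- vapply(seq_len(n_total), function(i) {
    pick_variant_aa(vt$wt_aa[i], planted[i] == 1)
  }, "")

  flip <- runif(n_total) < config$label_noise
  emitted <- ifelse(flip, 1L - planted, planted)
  raw_label <- ifelse(
    is_vus,
    sample(c("Uncertain significance",
             "Conflicting interpretations of pathogenicity"),
           n_total, replace = TRUE, prob = c(0.85, 0.15)),
    ifelse(emitted == 1,
           sample(c("Pathogenic", "Likely pathogenic"), n_total,
                  replace = TRUE),
           sample(c("Benign", "Likely benign"), n_total, replace = TRUE)))

  stars <- sample(1:3, n_total, replace = TRUE, prob = c(0.6, 0.3, 0.1))
  variants <- tibble(
    variant_id = paste0(vt$accession, ":", vt$wt_aa, vt$position, vt$var_aa),
    gene = sub("SYN", "GENE", vt$accession),
    accession = vt$accession, position = vt$position, wt_aa = vt$wt_aa,
    var_aa = vt$var_aa, raw_label = raw_label, review_stars = stars,
    review_status = c("SINGLE_SUBMITTER", "MULTIPLE_NO_CONSENSUS",
                      "EXPERT")[stars],
    origin = "germline"
  )
  manifest <- tibble(variant_id = variants$variant_id,
                     planted_label = planted, emitted_flipped = flip,
                     is_vus = is_vus, conserved = vt$conserved,
                     core = vt$core, conservation = vt$conservation,
                     plddt = vt$plddt)
  attr(manifest, "directions") <- list(
    pathogenic_at_conserved = TRUE, pathogenic_at_buried = TRUE,
    pathogenic_at_high_plddt = TRUE, effect = config$effect)
  list(variants = variants, manifest = manifest)
}

#' Generate comparator predictor scores from a binormal model
#'
#' Positives draw from Normal(mu, 1) and negatives from Normal(0, 1) with
#' `mu = sqrt(2) * qnorm(target_auc)`, independently per tool, then squash
#' to \[0, 1\] through the logistic map (a monotone transform, so the AUROC
#' is preserved). Tools flagged with calls threshold the latent score at
#' mu / 2.
#'
#' @param labels Binary truth (1 = pathogenic) or PATHOGENIC/BENIGN.
#' @param variant_id Ids aligned with `labels`.
#' @param target_auc Population AUROC in \[0.5, 1).
#' @param n_tools Number of tools.
#' @param seed Integer seed.
#' @param has_calls Logical vector (recycled) marking call-producing tools.
#' @param tool_names Optional tool names (default tool01, tool02, ...).
#' @return List with `scores` (long tibble: `variant_id`, `tool`, `score`,
#'   `call`) and `manifest` (tibble: `tool`, `higher_is_damaging`,
#'   `has_calls`).
#' @export
gen_comparator_scores <- function(labels, variant_id, target_auc = 0.9,
                                  n_tools = 4L, seed = 1L, has_calls = TRUE,
                                  tool_names = NULL) {
  if (target_auc < 0.5 || target_auc >= 1) {
    abort("target_auc must lie in [0.5, 1)")
  }
  y <- as_binary_label(labels)
  mu <- sqrt(2) * qnorm(target_auc)
  has_calls <- rep_len(has_calls, n_tools)
  tool_names <- tool_names %||% sprintf("tool%02d", seq_len(n_tools))
  set.seed(seed)
  scores <- list_rbind(map(seq_len(n_tools), function(t) {
    latent <- rnorm(length(y), mean = mu * y, sd = 1)
    tibble(variant_id = variant_id, tool = tool_names[t],
           score = plogis(latent - mu / 2),
           call = if (has_calls[t]) as.integer(latent > mu / 2)
                  else NA_integer_)
  }))
  list(scores = scores,
       manifest = tibble(tool = tool_names, higher_is_damaging = TRUE,
                         has_calls = has_calls))
}

#' Generate a complete fixture directory
#'
#' Writes, for every protein, a FASTA sequence, a PDB structure (pLDDT in
#' the B-factor column) and an aligned-FASTA alignment; plus the variant
#' table CSV, a protein-context CSV (accession, length, GO term count), a
#' long comparator-score CSV with its tool manifest, and a JSON manifest of
#' every planted quantity. Byte-identical across repeated calls with the
#' same config.
#'
#' @param config A `synthetic_config`.
#' @param dir Output directory (created).
#' @param target_auc,n_tools,has_calls Passed to
#'   [gen_comparator_scores()] (scores are simulated from the latent
#'   planted labels).
#' @return Invisibly, a list with the in-memory `proteins`, `variants`,
#'   `manifest`, `comparators` and the directory path.
#' @export
generate_fixture <- function(config, dir, target_auc = 0.9, n_tools = 4L,
                             has_calls = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sub in c("fasta", "pdb", "msa")) {
    dir.create(file.path(dir, sub), showWarnings = FALSE)
  }
  proteins <- map(seq_len(config$n_proteins), ~ gen_protein(config, .x))
  contexts <- list_rbind(map(proteins, function(p) {
    tibble(accession = p$accession, length = length(p$sequence),
           go_term_count = 0L)
  }))
  set.seed(derive_seed(config$seed, 0L, 3L))
  contexts$go_term_count <- sample(5:120, nrow(contexts), replace = TRUE)

  msas <- list()
  for (p in proteins) {
    writeLines(c(paste0(">", p$accession), paste(p$sequence, collapse = "")),
               file.path(dir, "fasta", paste0(p$accession, ".fasta")))
    write_structure_pdb(p$model, file.path(dir, "pdb",
                                           paste0(p$accession, ".pdb")))
    msa <- gen_msa(p$sequence, p$conservation, config$msa_depth,
                   seed = derive_seed(config$seed, match(p$accession,
                                                         contexts$accession),
                                      4L))
    msas[[p$accession]] <- msa
    write_msa_fasta(msa, file.path(dir, "msa", paste0(p$accession, ".afa")))
  }

  vs <- gen_variant_set(config, proteins)
  readr::write_csv(vs$variants, file.path(dir, "variants.csv"),
                   progress = FALSE)
  readr::write_csv(contexts, file.path(dir, "contexts.csv"), progress = FALSE)

  comp <- gen_comparator_scores(
    vs$manifest$planted_label, vs$variants$variant_id,
    target_auc = target_auc, n_tools = n_tools, has_calls = has_calls,
    seed = derive_seed(config$seed, 0L, 5L))
  readr::write_csv(comp$scores, file.path(dir, "comparators.csv"),
                   progress = FALSE)
  readr::write_csv(comp$manifest, file.path(dir, "comparator_manifest.csv"),
                   progress = FALSE)

  jsonlite::write_json(
    list(config = unclass(config),
         directions = attr(vs$manifest, "directions"),
         variants = vs$manifest),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(proteins = proteins, msas = msas, contexts = contexts,
                 variants = vs$variants, manifest = vs$manifest,
                 comparators = comp, dir = dir))
}
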