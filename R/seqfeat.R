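# Sequence-derived features: PSIC conservation profiles, BLOSUM62 and
# physicochemical substitution features, and feature-vector assembly.

#' Read an aligned FASTA multiple sequence alignment
#'
#' The first record is taken as the query unless `query_id` names another.
#' All rows must share one alignment length; the map from alignment columns
#' to (1-based) query positions is derived from the query row's gaps.
#'
#' @param path Aligned FASTA file.
#' @param query_id Optional id of the query row.
#' @return An `msa` object: list with `query_id`, `rows` (character matrix,
#'   sequences by alignment columns) and `column_map` (alignment column of
#'   each query position).
#' @export
read_msa <- function(path, query_id = NULL) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0) abort("empty alignment")
  rows <- as.character(seqs)
  if (length(unique(nchar(rows))) != 1) {
    abort("alignment rows differ in length; not an aligned FASTA")
  }
  ids <- sub("\\s.*$", "", names(seqs))
  qi <- if (is.null(query_id)) 1L else match(query_id, ids)
  if (is.na(qi)) abort(sprintf("query id not found in alignment: %s", query_id))
  rows <- rows[c(qi, setdiff(seq_along(rows), qi))]
  ids <- ids[c(qi, setdiff(seq_along(ids), qi))]
  mat <- do.call(rbind, strsplit(toupper(rows), ""))
  rownames(mat) <- ids
  column_map <- which(!mat[1, ] %in% c("-", "."))
  structure(list(query_id = ids[1], rows = mat,
                 column_map = as.integer(column_map)),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> query %s: %d rows x %d columns (%d query positions)\n",
              x$query_id, nrow(x$rows), ncol(x$rows), length(x$column_map)))
  invisible(x)
}

msa_from_strings <- function(rows, query_id = "query") {
  # internal helper for tests/generators: first string is the query
  mat <- do.call(rbind, strsplit(toupper(rows), ""))
  rownames(mat) <- c(query_id, sprintf("row%d", seq_len(nrow(mat) - 1)))
  structure(list(query_id = query_id, rows = mat,
                 column_map = which(!mat[1, ] %in% c("-", "."))),
            class = "msa")
}

# fraction of identical residues over columns where at least one row is
# ungapped (the greedy-clustering identity measure)
pair_identity <- function(a, b) {
  informative <- !(a %in% c("-", ".")) | !(b %in% c("-", "."))
  if (!any(informative)) return(0)
  sum(a == b & informative) / sum(informative)
}

#' Position-specific independent counts (PSIC) conservation profile
#'
#' Redundancy-corrected conservation log-odds. Sequences are greedily
#' clustered at an identity threshold; at every column each cluster
#' contributes one independent count, split equally over its members'
#' (ungapped) residues. Observed frequencies are smoothed with a
#' background pseudo-count and converted to natural-log odds against the
#' background:
#' `score(j, a) = ln((counts(j, a) + w * bg[a]) / ((n_eff(j) + w) * bg[a]))`.
#'
#' @param msa An `msa` object.
#' @param background Strictly positive 20-vector of background frequencies
#'   (normalized internally). Default: pooled residue frequencies of the
#'   alignment with Laplace smoothing, or uniform for tiny alignments
#'   (< 100 residue cells).
#' @param clustering_identity Greedy-clustering identity threshold
#'   (default 0.62).
#' @param pseudo_weight Background pseudo-count weight `w` (default 1).
#' @return A `psic_profile`: list with `scores` (query positions x 20
#'   matrix), `n_eff` (effective cluster count per position) and
#'   `background`. Positions whose column is all-gap get zero scores and
#'   are listed in the `"flagged"` attribute of `scores`.
#' @export
psic_profile <- function(msa, background = NULL, clustering_identity = 0.62,
                         pseudo_weight = 1.0) {
  stopifnot(inherits(msa, "msa"))
  mat <- msa$rows
  n_rows <- nrow(mat)

  if (is.null(background)) {
    cells <- mat[mat %in% AA_ALPHABET]
    if (length(cells) < 100) {
      background <- setNames(rep(1 / 20, 20), AA_ALPHABET)
    } else {
      tab <- table(factor(cells, levels = AA_ALPHABET))
      background <- (as.numeric(tab) + 1) / (sum(tab) + 20)
      names(background) <- AA_ALPHABET
    }
  }
  background <- background[AA_ALPHABET]
  if (any(is.na(background)) || any(background <= 0)) {
    abort("`background` must be strictly positive over the 20 amino acids")
  }
  background <- background / sum(background)

  # greedy clustering against cluster representatives (first member)
  cluster <- integer(n_rows)
  reps <- integer(0)
  for (i in seq_len(n_rows)) {
    assigned <- FALSE
    for (k in seq_along(reps)) {
      if (pair_identity(mat[i, ], mat[reps[k], ]) >= clustering_identity) {
        cluster[i] <- k
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      reps <- c(reps, i)
      cluster[i] <- length(reps)
    }
  }

  cols <- msa$column_map
  n_pos <- length(cols)
  scores <- matrix(0, n_pos, 20, dimnames = list(NULL, AA_ALPHABET))
  n_eff <- numeric(n_pos)
  flagged <- integer(0)
  w <- pseudo_weight
  for (p in seq_len(n_pos)) {
    col <- mat[, cols[p]]
    counts <- setNames(numeric(20), AA_ALPHABET)
    eff <- 0
    for (k in seq_along(reps)) {
      res <- col[cluster == k]
      res <- res[res %in% AA_ALPHABET]
      if (length(res) == 0) next
      eff <- eff + 1
      tab <- table(res) / length(res)
      counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
    }
    n_eff[p] <- eff
    if (eff == 0) {
      flagged <- c(flagged, p)
      next # pseudo-counts only: f == background, scores stay 0
    }
    f <- (counts + w * background) / (eff + w)
    scores[p, ] <- log(f / background)
  }
  if (length(flagged) > 0) {
    inform(sprintf("%d all-gap column(s): scores from pseudo-counts only",
                   length(flagged)))
  }
  attr(scores, "flagged") <- flagged
  structure(list(scores = scores, n_eff = n_eff, background = background),
            class = "psic_profile")
}

#' @export
print.psic_profile <- function(x, ...) {
  cat(sprintf("<psic_profile> %d positions, mean n_eff %.1f\n",
              nrow(x$scores), mean(x$n_eff)))
  invisible(x)
}

#' PSIC score difference between wild-type and variant residues
#'
#' `delta_psic = score(position, wt) - score(position, var)`; large positive
#' values mark disruptive substitutions at conserved positions. Antisymmetric
#' in (wt, var). Vectorized over positions and residues.
#'
#' @param profile A `psic_profile`.
#' @param position 1-based query position(s).
#' @param wt_aa,var_aa One-letter residue codes.
#' @return Numeric vector.
#' @export
delta_psic <- function(profile, position, wt_aa, var_aa) {
  stopifnot(inherits(profile, "psic_profile"))
  if (any(position < 1 | position > nrow(profile$scores))) {
    abort("`position` outside the profile")
  }
  check_aa(wt_aa, "wt_aa"); check_aa(var_aa, "var_aa")
  profile$scores[cbind(position, match(wt_aa, AA_ALPHABET))] -
    profile$scores[cbind(position, match(var_aa, AA_ALPHABET))]
}

#' BLOSUM62 substitution score
#'
#' Symmetric lookup in the standard BLOSUM62 matrix (from Biostrings).
#'
#' @param wt_aa,var_aa One-letter residue codes (vectorized).
#' @return Integer vector of substitution scores.
#' @export
substitution_score <- function(wt_aa, var_aa) {
  check_aa(wt_aa, "wt_aa"); check_aa(var_aa, "var_aa")
  m <- blosum62_matrix()
  as.integer(m[cbind(wt_aa, var_aa)])
}

#' Physicochemical and propensity features of a substitution
#'
#' Emits variant-minus-wild-type deltas on fixed per-residue scales
#' (Kyte-Doolittle hydropathy, Zamyatnin volume) plus per-residue
#' Chou-Fasman helix/sheet/turn propensities and background amino-acid
#' frequencies for both residues.
#'
#' @param wt_aa,var_aa One-letter residue codes (vectorized).
#' @param scales Scale tables, see [default_scales()].
#' @return Tibble with columns `d_hydrophobicity`, `d_volume`,
#'   `wt_helix_prop`, `var_helix_prop`, `wt_sheet_prop`, `var_sheet_prop`,
#'   `wt_turn_prop`, `var_turn_prop`, `wt_frequency`, `var_frequency`.
#' @export
physchem_features <- function(wt_aa, var_aa, scales = default_scales()) {
  check_aa(wt_aa, "wt_aa"); check_aa(var_aa, "var_aa")
  tibble(
    d_hydrophobicity = unname(scales$hydropathy[var_aa] -
                                scales$hydropathy[wt_aa]),
    d_volume = unname(scales$volume[var_aa] - scales$volume[wt_aa]),
    wt_helix_prop = unname(scales$helix[wt_aa]),
    var_helix_prop = unname(scales$helix[var_aa]),
    wt_sheet_prop = unname(scales$sheet[wt_aa]),
    var_sheet_prop = unname(scales$sheet[var_aa]),
    wt_turn_prop = unname(scales$turn[wt_aa]),
    var_turn_prop = unname(scales$turn[var_aa]),
    wt_frequency = unname(scales$frequency[wt_aa]),
    var_frequency = unname(scales$frequency[var_aa])
  )
}

#' Ordered feature names of a schema
#'
#' The `reduced` schema carries only variant-local sequence and structure
#' features; `full` appends the two gene-level features (`protein_length`,
#' `go_term_count`).
#'
#' @param schema `"full"` or `"reduced"`.
#' @return Character vector of feature names in canonical order.
#' @export
feature_schema <- function(schema = c("full", "reduced")) {
  schema <- arg_match(schema)
  reduced <- c("psic_wt", "psic_var", "delta_psic", "blosum62",
               "d_hydrophobicity", "d_volume",
               "wt_helix_prop", "var_helix_prop",
               "wt_sheet_prop", "var_sheet_prop",
               "wt_turn_prop", "var_turn_prop",
               "wt_frequency", "var_frequency",
               "plddt", "sasa", "rasa")
  if (schema == "reduced") reduced else
    c(reduced, "protein_length", "go_term_count")
}

#' Assemble the model feature matrix for a variant table
#'
#' Joins conservation, substitution, physicochemical and structural
#' constituents into one deterministic feature table under the requested
#' schema. Every variant must have passed [validate_mapping()]; a missing
#' constituent (no profile, no structural row, no context row) is an error
#' naming the variant and the missing piece, never a silent `NA`.
#'
#' @param variants Variant tibble (needs `variant_id`, `accession`,
#'   `position`, `wt_aa`, `var_aa`; `label` and `gene` are carried through
#'   when present).
#' @param contexts Protein-context tibble: `accession`, `length`,
#'   `go_term_count` (required for the full schema).
#' @param struct_features Per-residue structural features as from
#'   [residue_struct_features()], covering all proteins.
#' @param profiles Named list of `psic_profile` objects keyed by accession.
#' @param schema `"full"` or `"reduced"`.
#' @param scales Scale tables for [physchem_features()].
#' @return Tibble: `variant_id` (+ `gene`, `label` if present) followed by
#'   the schema's feature columns in canonical order. The schema name is
#'   attached as attribute `"schema"`.
#' @export
assemble_features <- function(variants, contexts, struct_features, profiles,
                              schema = c("full", "reduced"),
                              scales = default_scales()) {
  schema <- arg_match(schema)
  cols <- feature_schema(schema)

  miss_prof <- setdiff(unique(variants$accession), names(profiles))
  if (length(miss_prof) > 0) {
    abort(sprintf("missing PSIC profile for accession(s): %s",
                  paste(miss_prof, collapse = ", ")))
  }

  psic_wt <- numeric(nrow(variants))
  psic_var <- numeric(nrow(variants))
  for (acc in unique(variants$accession)) {
    sel <- which(variants$accession == acc)
    prof <- profiles[[acc]]
    if (any(variants$position[sel] > nrow(prof$scores))) {
      abort(sprintf("variant position beyond PSIC profile for %s", acc))
    }
    ai_wt <- match(variants$wt_aa[sel], AA_ALPHABET)
    ai_var <- match(variants$var_aa[sel], AA_ALPHABET)
    psic_wt[sel] <- prof$scores[cbind(variants$position[sel], ai_wt)]
    psic_var[sel] <- prof$scores[cbind(variants$position[sel], ai_var)]
  }

  st <- struct_features[, c("accession", "index", "plddt", "sasa", "rasa")]
  key <- match(paste(variants$accession, variants$position),
               paste(st$accession, st$index))
  if (any(is.na(key))) {
    bad <- variants$variant_id[is.na(key)][1]
    abort(sprintf("missing structural features (plddt/sasa/rasa) for %s", bad))
  }

  out <- tibble(variant_id = variants$variant_id)
  if ("gene" %in% names(variants)) out$gene <- variants$gene
  if ("label" %in% names(variants)) out$label <- variants$label
  out$psic_wt <- psic_wt
  out$psic_var <- psic_var
  out$delta_psic <- psic_wt - psic_var
  out$blosum62 <- as.numeric(substitution_score(variants$wt_aa,
                                                variants$var_aa))
  out <- bind_cols(out, physchem_features(variants$wt_aa, variants$var_aa,
                                          scales))
  out$plddt <- st$plddt[key]
  out$sasa <- st$sasa[key]
  out$rasa <- st$rasa[key]

  if (schema == "full") {
    ck <- match(variants$accession, contexts$accession)
    if (any(is.na(ck))) {
      abort(sprintf("missing protein context (protein_length/go_term_count) for %s",
                    variants$accession[is.na(ck)][1]))
    }
    out$protein_length <- as.numeric(contexts$length[ck])
    out$go_term_count <- as.numeric(contexts$go_term_count[ck])
  }

  if (anyNA(out[cols])) {
    nac <- cols[colSums(is.na(out[cols])) > 0]
    abort(sprintf("missing values in assembled feature(s): %s",
                  paste(nac, collapse = ", ")))
  }
  keep <- c(intersect(c("variant_id", "gene", "label"), names(out)), cols)
  out <- out[, keep]
  attr(out, "schema") <- schema
  out
}
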