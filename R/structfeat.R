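# Predicted-structure parsing and per-residue structural features:
# pLDDT (AF2 convention: stored in the B-factor field), Shrake-Rupley SASA,
# and relative solvent accessibility (rASA).

#' Parse a predicted protein structure
#'
#' Reads a PDB or mmCIF file following the AlphaFold2 conventions: one chain,
#' complete residue coverage, and the per-residue pLDDT confidence stored in
#' the temperature-factor (B) column, constant within a residue; the
#' C-alpha value is taken. Van der Waals radii are attached per atom from an
#' element-keyed table.
#'
#' @param path Path to a `.pdb` or `.cif` file.
#' @param accession Accession to record; defaults to the file base name.
#' @param vdw_radii Element-keyed radius table (Angstrom); see [VDW_RADII].
#' @return A `structure_model`: list with `accession`, tibble `residues`
#'   (`index`, `aa`, `plddt`) and tibble `atoms` (`residue_index`,
#'   `element`, `x`, `y`, `z`, `radius`).
#' @export
read_structure <- function(path, accession = NULL, vdw_radii = VDW_RADII) {
  if (!file.exists(path)) abort(sprintf("structure file not found: %s", path))
  pdb <- if (grepl("\\.cif$", path, ignore.case = TRUE)) {
    bio3d::read.cif(path, verbose = FALSE)
  } else {
    bio3d::read.pdb(path, verbose = FALSE)
  }
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) abort("no ATOM records in structure")
  if (all(is.na(at$b))) abort("no pLDDT channel: temperature factors missing")

  elem <- at$elesy
  if (any(is.na(elem) | elem == "")) {
    # fall back on the first letter of the atom name
    elem <- ifelse(is.na(elem) | elem == "",
                   substr(gsub("[0-9]", "", at$elety), 1, 1), elem)
  }
  elem <- toupper(elem)
  unknown <- setdiff(unique(elem), names(vdw_radii))
  if (length(unknown) > 0) {
    abort(sprintf("no van der Waals radius for element(s): %s",
                  paste(unknown, collapse = ", ")))
  }

  idx <- sort(unique(at$resno))
  missing <- setdiff(seq(min(idx), max(idx)), idx)
  if (length(missing) > 0) {
    abort(sprintf("chain break: missing residue index(es) %s",
                  paste(missing, collapse = ", ")))
  }

  ca <- at[at$elety == "CA", , drop = FALSE]
  ca <- ca[match(idx, ca$resno), , drop = FALSE]
  aa1 <- unname(AA_THREE_TO_ONE[stringr::str_to_title(ca$resid)])
  plddt <- ca$b
  if (any(is.na(plddt))) abort("no pLDDT channel: C-alpha B-factor missing")
  if (any(plddt < 0 | plddt > 100)) {
    abort("temperature-factor values outside [0, 100]; not a pLDDT channel")
  }

  structure(
    list(accession = accession %||%
           tools::file_path_sans_ext(basename(path)),
         residues = tibble(index = as.integer(idx), aa = aa1, plddt = plddt),
         atoms = tibble(residue_index = as.integer(at$resno), element = elem,
                        x = at$x, y = at$y, z = at$z,
                        radius = unname(vdw_radii[elem]))),
    class = "structure_model"
  )
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %s: %d residues, %d atoms, mean pLDDT %.1f\n",
              x$accession, nrow(x$residues), nrow(x$atoms),
              mean(x$residues$plddt)))
  invisible(x)
}

# Quasi-uniform unit sphere points by the Fibonacci (golden-angle) lattice.
# A fixed, seedless construction keeps SASA fully deterministic.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (3 - sqrt(5)) * (i - 0.5)
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Shrake-Rupley solvent accessible surface area
#'
#' Numerical SASA by the Shrake-Rupley method: each atom's sphere is
#' expanded by the probe radius and covered with a deterministic Fibonacci
#' point lattice; the exposed fraction (points not inside any other
#' expanded sphere) times the expanded-sphere area is the atom's SASA, and
#' residue SASA sums its atoms.
#'
#' @param model A `structure_model`.
#' @param probe_radius Solvent probe radius in Angstrom (default 1.4, water).
#' @param n_points Sphere sample points per atom (default 960; at least 10).
#' @return Tibble with `residue_index` and `sasa` (square Angstrom), one row
#'   per residue, in residue order.
#' @export
compute_sasa <- function(model, probe_radius = 1.4, n_points = 960) {
  if (n_points < 10) abort("`n_points` must be at least 10 for usable sampling")
  atoms <- if (inherits(model, "structure_model")) model$atoms else model
  n_atoms <- nrow(atoms)
  if (n_atoms == 0) abort("structure has no atoms")
  pts <- fibonacci_sphere(n_points)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rad <- atoms$radius + probe_radius

  atom_sasa <- numeric(n_atoms)
  for (i in seq_len(n_atoms)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (rad + rad[i])^2 & seq_len(n_atoms) != i)
    if (length(nb) == 0) {
      exposed <- n_points
    } else {
      sp <- pts * rad[i]
      sp <- sweep(sp, 2, xyz[i, ], "+")
      covered <- rep(FALSE, n_points)
      for (j in nb) {
        dj2 <- (sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 +
          (sp[, 3] - xyz[j, 3])^2
        # tiny relative tolerance so exactly coincident spheres occlude
        covered <- covered | dj2 < rad[j]^2 * (1 + 1e-9)
        if (all(covered)) break
      }
      exposed <- sum(!covered)
    }
    atom_sasa[i] <- exposed / n_points * 4 * pi * rad[i]^2
  }
  res <- tapply(atom_sasa, atoms$residue_index, sum)
  tibble(residue_index = as.integer(names(res)), sasa = as.numeric(res)) |>
    arrange(residue_index)
}

#' Relative solvent accessibility
#'
#' Divides observed residue SASA by the maximum attainable SASA for the
#' residue type. Values are reported unclamped — with theoretical maxima a
#' ratio slightly above 1 is legitimate — but values above 1.2 trigger a
#' diagnostic message as likely geometry problems.
#'
#' @param sasa Numeric vector of residue SASA values (square Angstrom).
#' @param aa One-letter residue codes, recycled against `sasa`.
#' @param max_asa_table Named max-ASA table; default [MAX_ASA_TIEN2013].
#' @return Numeric vector of rASA values.
#' @export
compute_rasa <- function(sasa, aa, max_asa_table = MAX_ASA_TIEN2013) {
  check_aa(aa)
  if (any(sasa < 0)) abort("`sasa` must be non-negative")
  miss <- setdiff(unique(aa), names(max_asa_table))
  if (length(miss) > 0) {
    abort(sprintf("no max-ASA reference for residue type(s): %s",
                  paste(miss, collapse = ", ")))
  }
  rasa <- sasa / unname(max_asa_table[aa])
  n_high <- sum(rasa > 1.2)
  if (n_high > 0) {
    inform(sprintf("%d residue(s) with rASA > 1.2 (kept unclamped)", n_high))
  }
  rasa
}

#' Per-residue structural feature table
#'
#' Convenience wrapper combining pLDDT extraction, [compute_sasa()] and
#' [compute_rasa()] for one structure.
#'
#' @inheritParams compute_sasa
#' @param max_asa_table Max-ASA normalization table.
#' @return Tibble with `accession`, `index`, `aa`, `plddt`, `sasa`, `rasa`.
#' @export
residue_struct_features <- function(model, probe_radius = 1.4,
                                    n_points = 960,
                                    max_asa_table = MAX_ASA_TIEN2013) {
  stopifnot(inherits(model, "structure_model"))
  s <- compute_sasa(model, probe_radius = probe_radius, n_points = n_points)
  res <- model$residues
  stopifnot(identical(res$index, s$residue_index))
  tibble(accession = model$accession, index = res$index, aa = res$aa,
         plddt = res$plddt, sasa = s$sasa,
         rasa = compute_rasa(s$sasa, res$aa, max_asa_table))
}
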