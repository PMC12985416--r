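# Amino-acid reference tables. All per-residue scales are keyed by the 20
# standard one-letter codes and shipped editable as inst/extdata/scales.json;
# the in-source copies below are the defaults.

#' The 20 standard amino acids (one-letter codes)
#' @export
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# three-letter -> one-letter, for HGVS protein-change parsing
AA_THREE_TO_ONE <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
  Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
  Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
  Tyr = "Y", Val = "V"
)

# Kyte-Doolittle hydropathy index
KD_HYDROPATHY <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I =  4.5, L =  3.8, K = -3.9, M =  1.9, F =  2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

# Zamyatnin residue volumes (A^3)
AA_VOLUME <- c(
  A =  88.6, R = 173.4, N = 114.1, D = 111.1, C = 108.5, Q = 143.8,
  E = 138.4, G =  60.1, H = 153.2, I = 166.7, L = 166.7, K = 168.6,
  M = 162.9, F = 189.9, P = 112.7, S =  89.0, T = 116.1, W = 227.8,
  Y = 193.6, V = 140.0
)

# Chou-Fasman secondary-structure propensities
CF_HELIX <- c(
  A = 1.42, R = 0.98, N = 0.67, D = 1.01, C = 0.70, Q = 1.11, E = 1.51,
  G = 0.57, H = 1.00, I = 1.08, L = 1.21, K = 1.16, M = 1.45, F = 1.13,
  P = 0.57, S = 0.77, T = 0.83, W = 1.08, Y = 0.69, V = 1.06
)
CF_SHEET <- c(
  A = 0.83, R = 0.93, N = 0.89, D = 0.54, C = 1.19, Q = 1.10, E = 0.37,
  G = 0.75, H = 0.87, I = 1.60, L = 1.30, K = 0.74, M = 1.05, F = 1.38,
  P = 0.55, S = 0.75, T = 1.19, W = 1.37, Y = 1.47, V = 1.70
)
CF_TURN <- c(
  A = 0.66, R = 0.95, N = 1.56, D = 1.46, C = 1.19, Q = 0.98, E = 0.74,
  G = 1.56, H = 0.95, I = 0.47, L = 0.59, K = 1.01, M = 0.60, F = 0.60,
  P = 1.52, S = 1.43, T = 0.96, W = 0.96, Y = 1.14, V = 0.50
)

# BLOSUM62 background amino-acid frequencies (Henikoff & Henikoff)
BLOSUM62_FREQ <- c(
  A = 0.074, R = 0.052, N = 0.045, D = 0.054, C = 0.025, Q = 0.034,
  E = 0.054, G = 0.074, H = 0.026, I = 0.068, L = 0.099, K = 0.058,
  M = 0.025, F = 0.047, P = 0.039, S = 0.057, T = 0.051, W = 0.013,
  Y = 0.032, V = 0.073
)

#' Theoretical maximum solvent accessibility per residue type
#'
#' The Tien et al. (2013) "theoretical" maximum accessible surface areas
#' (in square Angstrom), used to normalize residue SASA into relative
#' solvent accessibility (rASA). Values above 1 are possible for observed
#' conformations and are deliberately not clamped.
#'
#' @format Named numeric vector over the 20 one-letter codes.
#' @export
MAX_ASA_TIEN2013 <- c(
  A = 129.0, R = 274.0, N = 195.0, D = 193.0, C = 167.0, Q = 225.0,
  E = 223.0, G = 104.0, H = 224.0, I = 197.0, L = 201.0, K = 236.0,
  M = 224.0, F = 240.0, P = 159.0, S = 155.0, T = 172.0, W = 285.0,
  Y = 263.0, V = 174.0
)

#' Van der Waals radii by element (Angstrom)
#' @export
VDW_RADII <- c(C = 1.7, N = 1.55, O = 1.52, S = 1.8, H = 1.2, P = 1.8)

# BLOSUM62 substitution matrix, restricted to the 20 standard residues
blosum62_matrix <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62[AA_ALPHABET, AA_ALPHABET]
    }
    m
  }
})

#' Default per-residue scale tables
#'
#' Returns the physicochemical and propensity scales used by
#' [physchem_features()] and the structural normalization tables, as one
#' editable list. Pass a modified copy to the feature functions to swap
#' scales.
#'
#' @return Named list with elements `hydropathy`, `volume`, `helix`,
#'   `sheet`, `turn`, `frequency`, `max_asa`, `vdw_radii`.
#' @export
default_scales <- function() {
  list(
    hydropathy = KD_HYDROPATHY,
    volume     = AA_VOLUME,
    helix      = CF_HELIX,
    sheet      = CF_SHEET,
    turn       = CF_TURN,
    frequency  = BLOSUM62_FREQ,
    max_asa    = MAX_ASA_TIEN2013,
    vdw_radii  = VDW_RADII
  )
}

check_aa <- function(aa, arg = "aa") {
  bad <- !aa %in% AA_ALPHABET
  if (any(bad)) {
    abort(sprintf("unknown amino-acid code(s) in `%s`: %s",
                  arg, paste(unique(aa[bad]), collapse = ", ")))
  }
  invisible(aa)
}
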