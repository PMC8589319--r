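#' Monoisotopic mass of an elemental composition
#'
#' Computes the monoisotopic mass (in Da) of a molecule or modification given
#' as a named count vector of element symbols. Heavy isotopes used by
#' isobaric/AQUA labelling are written `"13C"` and `"15N"`.
#'
#' @param composition Named numeric vector or list of integer element counts,
#'   e.g. `c(C = 4, H = 6, N = 2, O = 2)` for the GlyGly remnant. Counts may
#'   be negative (mass differences such as deamidation). An empty composition
#'   has mass 0.
#' @return Mass in Da (double scalar).
#' @examples
#' monoisotopic_mass(c(C = 4, H = 6, N = 2, O = 2)) # GlyGly remnant, 114.0429
#' monoisotopic_mass(c(H = 2, O = 1))               # water
#' @export
monoisotopic_mass <- function(composition) {
  composition <- unlist(composition)
  if (length(composition) == 0) return(0)
  if (is.null(names(composition)) || any(!nzchar(names(composition)))) {
    stop("`composition` must be a named vector of element counts", call. = FALSE)
  }
  if (any(composition != round(composition))) {
    stop("element counts must be integers", call. = FALSE)
  }
  unknown <- setdiff(names(composition), names(.element_masses))
  if (length(unknown) > 0) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sum(composition * .element_masses[names(composition)])
}

# IUPAC monoisotopic masses; 13C/15N are the stable heavy labels used in
# TMT reagents and AQUA reference peptides.
.element_masses <- c(
  H = 1.0078250319,
  C = 12.0,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.97207069,
  P = 30.97376151,
  `13C` = 13.0033548378,
  `15N` = 15.0001088984
)

#' Elemental compositions of common search modifications
#'
#' The variable and static modifications used in a TMT diGLY search:
#' the GlyGly remnant left on ubiquitylated lysines after tryptic digestion,
#' the TMT label (four 13C and one 15N), carbamidomethylation of cysteine,
#' methionine oxidation, serine/threonine phosphorylation, and
#' asparagine/glutamine deamidation (a mass difference: +O, -N, -H).
#'
#' @return Named list of compositions suitable for [monoisotopic_mass()].
#' @examples
#' sapply(modification_compositions(), monoisotopic_mass)
#' @export
modification_compositions <- function() {
  list(
    glygly          = c(C = 4, H = 6, N = 2, O = 2),
    tmt             = c(C = 8, `13C` = 4, H = 20, N = 1, `15N` = 1, O = 2),
    carbamidomethyl = c(C = 2, H = 3, N = 1, O = 1),
    oxidation       = c(O = 1),
    phospho         = c(H = 1, P = 1, O = 3),
    deamidation     = c(O = 1, N = -1, H = -1)
  )
}

# average residue masses (Da) for molecular-weight estimation of proteins
# on the g/mol scale used by the proteomic ruler
.avg_residue_masses <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)

#' Protein molecular weight from sequence
#'
#' Average molecular weight (g/mol): sum of average residue masses plus one
#' water. A convenience helper for the proteomic ruler; residues outside the
#' 20 standard amino acids are an error.
#'
#' @param sequence Character vector of amino-acid sequences.
#' @return Numeric vector of molecular weights (g/mol).
#' @export
protein_molecular_weight <- function(sequence) {
  vapply(sequence, function(s) {
    aa <- strsplit(toupper(s), "")[[1]]
    bad <- setdiff(aa, names(.avg_residue_masses))
    if (length(bad) > 0) {
      stop("non-standard residue(s): ", paste(unique(bad), collapse = ", "),
           call. = FALSE)
    }
    sum(.avg_residue_masses[aa]) + 18.01528
  }, numeric(1), USE.NAMES = FALSE)
}
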