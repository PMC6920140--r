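# Monoisotopic atomic masses: CODATA/AME2020 values, >= 7 decimal digits.
# Average masses are IUPAC standard atomic weights (used for documentation
# and the legacy hydrogen constant only; all workflows here are monoisotopic).
.ATOMIC_MASSES <- data.frame(
  element = c("H", "C", "N", "O", "S"),
  monoisotopic = c(1.00782503207, 12.0, 14.0030740048, 15.9949146196, 31.97207100),
  average = c(1.00794, 12.0107, 14.0067, 15.9994, 32.065),
  stringsAsFactors = FALSE
)

.PROTON_MASS <- 1.00727646688

# Average-mass hydrogen used by the 2004-era ISB calculators; retained for
# provenance, selectable via constants_mode = "legacy" where it matters.
.LEGACY_HYDROGEN <- 1.00794

# Residue (amino acid minus water) elemental formulas, standard 20.
.RESIDUE_FORMULAS <- list(
  G = c(C = 2, H = 3, N = 1, O = 1),
  A = c(C = 3, H = 5, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2),
  P = c(C = 5, H = 7, N = 1, O = 1),
  V = c(C = 5, H = 9, N = 1, O = 1),
  T = c(C = 4, H = 7, N = 1, O = 2),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1),
  I = c(C = 6, H = 11, N = 1, O = 1),
  N = c(C = 4, H = 6, N = 2, O = 2),
  D = c(C = 4, H = 5, N = 1, O = 3),
  Q = c(C = 5, H = 8, N = 2, O = 2),
  K = c(C = 6, H = 12, N = 2, O = 1),
  E = c(C = 5, H = 7, N = 1, O = 3),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1),
  F = c(C = 9, H = 9, N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1),
  Y = c(C = 9, H = 9, N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1)
)

.WATER <- c(H = 2, O = 1)

#' Amino acid and atomic constants table
#'
#' Returns the constants behind every mass computed by the package: residue
#' elemental formulas (amino acid minus water) for the 20 standard residues,
#' the water formula, monoisotopic and average atomic masses, the proton
#' mass, and the legacy average-mass hydrogen constant (1.00794 Da) that
#' older web calculators used for per-cysteine corrections.
#'
#' @return A list with elements `residue_formulas` (named list of named
#'   integer vectors), `water`, `atomic_masses` (data frame with columns
#'   `element`, `monoisotopic`, `average`), `proton_mass`, and
#'   `legacy_hydrogen`.
#' @export
#' @examples
#' tab <- amino_acid_table()
#' tab$residue_formulas$G
amino_acid_table <- function() {
  list(
    residue_formulas = lapply(.RESIDUE_FORMULAS, elemental_composition),
    water = elemental_composition(.WATER),
    atomic_masses = .ATOMIC_MASSES,
    proton_mass = .PROTON_MASS,
    legacy_hydrogen = .LEGACY_HYDROGEN
  )
}

#' Elemental composition objects
#'
#' An elemental composition is a named integer vector of element counts
#' (e.g. `c(C = 117, H = 172, ...)`). Zero counts are dropped; negative
#' counts are an error. Compositions add with `+` and subtract with `-`
#' (element-wise; subtraction below zero is an error).
#'
#' @param counts Named numeric vector of non-negative integer counts.
#' @return An object of class `elemental_composition`.
#' @export
#' @examples
#' elemental_composition(c(H = 2, O = 1))
elemental_composition <- function(counts) {
  if (length(counts) == 0) {
    x <- integer(0)
    names(x) <- character(0)
    class(x) <- "elemental_composition"
    return(x)
  }
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("composition counts must be named by element symbol")
  }
  if (any(counts < 0)) stop("element counts must be non-negative")
  if (any(counts != round(counts))) stop("element counts must be integers")
  counts <- tapply(counts, names(counts), sum)  # merge duplicates
  counts <- counts[counts > 0]
  x <- as.integer(counts)
  names(x) <- names(counts)
  x <- x[order(match(names(x), c("C", "H"), nomatch = 3L), names(x))]
  class(x) <- "elemental_composition"
  x
}

#' @export
`+.elemental_composition` <- function(e1, e2) {
  all_el <- union(names(e1), names(e2))
  a <- structure(unclass(e1)[all_el], names = all_el)
  b <- structure(unclass(e2)[all_el], names = all_el)
  a[is.na(a)] <- 0L
  b[is.na(b)] <- 0L
  elemental_composition(a + b)
}

#' @export
`-.elemental_composition` <- function(e1, e2) {
  if (missing(e2)) stop("unary minus is not defined for compositions")
  all_el <- union(names(e1), names(e2))
  a <- structure(unclass(e1)[all_el], names = all_el)
  b <- structure(unclass(e2)[all_el], names = all_el)
  a[is.na(a)] <- 0L
  b[is.na(b)] <- 0L
  if (any(a - b < 0)) stop("composition subtraction below zero")
  elemental_composition(a - b)
}

#' @export
format.elemental_composition <- function(x, ...) {
  paste0(names(x), unclass(x), collapse = "")
}

#' @export
print.elemental_composition <- function(x, ...) {
  cat("<elemental composition>", format(x), "\n")
  invisible(x)
}

#' Construct a peptide
#'
#' A peptide is a one-letter amino acid sequence together with a count of
#' intramolecular disulfide bridges. Each disulfide bridge removes two
#' hydrogen atoms from the molecule, so `2 * n_disulfides` must not exceed
#' the number of cysteines. Termini are free amine / free acid.
#'
#' @param sequence One-letter amino acid string (standard 20 residues), or a
#'   path to a single-record amino-acid FASTA file.
#' @param n_disulfides Number of intramolecular S-S bridges (default 0).
#' @return An object of class `peptide` with fields `sequence`,
#'   `n_disulfides`, `termini`.
#' @export
#' @examples
#' peptide("DTHFPICIFCCGCCKTPKCGFCCRT", n_disulfides = 4)
peptide <- function(sequence, n_disulfides = 0L) {
  if (length(sequence) != 1 || !is.character(sequence)) {
    stop("sequence must be a single character string")
  }
  if (file.exists(sequence) && grepl("\\.(fa|fasta|faa)$", sequence, ignore.case = TRUE)) {
    aa <- Biostrings::readAAStringSet(sequence)
    if (length(aa) != 1) stop("FASTA peptide input must contain exactly one record")
    sequence <- as.character(aa[[1]])
  }
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0) stop("empty peptide sequence")
  letters <- strsplit(sequence, "")[[1]]
  bad <- setdiff(letters, names(.RESIDUE_FORMULAS))
  if (length(bad) > 0) {
    stop("invalid residue letter(s): ", paste(unique(bad), collapse = ", "))
  }
  n_disulfides <- as.integer(n_disulfides)
  if (is.na(n_disulfides) || n_disulfides < 0) stop("n_disulfides must be >= 0")
  n_cys <- sum(letters == "C")
  if (2L * n_disulfides > n_cys) {
    stop("2 * n_disulfides (", 2L * n_disulfides,
         ") exceeds cysteine count (", n_cys, ")")
  }
  structure(
    list(sequence = sequence, n_disulfides = n_disulfides,
         termini = c(N = "free amine", C = "free acid")),
    class = "peptide"
  )
}

#' @export
print.peptide <- function(x, ...) {
  cat("<peptide> ", x$sequence, "  (", nchar(x$sequence), " aa, ",
      x$n_disulfides, " disulfide bridge", if (x$n_disulfides != 1) "s",
      ")\n", sep = "")
  invisible(x)
}

.as_peptide <- function(x, n_disulfides = 0L) {
  if (inherits(x, "peptide")) x else peptide(x, n_disulfides)
}

#' Elemental composition of a peptide
#'
#' Sums the residue formulas, adds one water for the termini, and removes
#' two hydrogen atoms per disulfide bridge (S-S bond formation oxidises two
#' cysteine thiols, losing 2 H).
#'
#' @param pep A [peptide()] object, or a sequence string.
#' @param n_disulfides Used only when `pep` is a string.
#' @return An `elemental_composition`.
#' @export
#' @examples
#' composition_of(peptide("DTHFPICIFCCGCCKTPKCGFCCRT", 4))
#' # C117H172N32O31S8
composition_of <- function(pep, n_disulfides = 0L) {
  pep <- .as_peptide(pep, n_disulfides)
  letters <- strsplit(pep$sequence, "")[[1]]
  counts <- Reduce(`+`, lapply(.RESIDUE_FORMULAS[letters], function(f) {
    full <- c(C = 0, H = 0, N = 0, O = 0, S = 0)
    full[names(f)] <- f
    full
  }))
  counts["H"] <- counts["H"] + 2 - 2 * pep$n_disulfides
  counts["O"] <- counts["O"] + 1
  if (counts["H"] < 0) stop("disulfide hydrogen removal below zero")
  elemental_composition(counts)
}

#' Monoisotopic mass of an elemental composition
#'
#' @param comp An `elemental_composition`, a [peptide()] (its composition is
#'   computed first), or a named count vector.
#' @return Mass in Da: sum over elements of count times the monoisotopic
#'   atomic mass.
#' @export
#' @examples
#' monoisotopic_mass(elemental_composition(c(H = 2, O = 1)))  # 18.01056
monoisotopic_mass <- function(comp) {
  if (inherits(comp, "peptide")) comp <- composition_of(comp)
  if (!inherits(comp, "elemental_composition")) comp <- elemental_composition(comp)
  idx <- match(names(comp), .ATOMIC_MASSES$element)
  if (anyNA(idx)) {
    stop("no atomic mass for element(s): ",
         paste(names(comp)[is.na(idx)], collapse = ", "))
  }
  sum(unclass(comp) * .ATOMIC_MASSES$monoisotopic[idx])
}

#' m/z of a protonated ion
#'
#' `mz_of` computes the mass-to-charge ratio of `[M + zH]^z+`:
#' `(M + z * m_proton) / z`. `neutral_mass_from_mz` is its exact inverse.
#'
#' @param neutral_mass Neutral monoisotopic mass M in Da.
#' @param z Positive integer charge.
#' @return m/z in Th (Da per unit charge).
#' @export
#' @examples
#' mz_of(2777.0632, 5)
mz_of <- function(neutral_mass, z) {
  z <- as.integer(z)
  if (any(is.na(z)) || any(z < 1)) stop("charge z must be a positive integer")
  if (any(neutral_mass <= 0)) stop("neutral mass must be positive")
  (neutral_mass + z * .PROTON_MASS) / z
}

#' @rdname mz_of
#' @param mz Observed m/z; must exceed the proton mass.
#' @export
neutral_mass_from_mz <- function(mz, z) {
  z <- as.integer(z)
  if (any(is.na(z)) || any(z < 1)) stop("charge z must be a positive integer")
  if (any(mz <= .PROTON_MASS)) stop("m/z must exceed the proton mass")
  z * mz - z * .PROTON_MASS
}
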