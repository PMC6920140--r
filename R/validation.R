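#' Reported canine hepcidin-25 candidate sequences
#'
#' The published translations of the canine hepcidin-25 peptide: the
#' earlier cDNA-derived records carrying leucine/isoleucine/lysine at
#' positions 21 and 24, the commercial recombinant standard, and the
#' genome-, mRNA- and serum-peptide-derived sequence with phenylalanine-21
#' and arginine-24.
#'
#' @return Data frame with columns `id`, `sequence`, `provenance`.
#' @export
hepcidin_candidates <- function() {
  data.frame(
    id = c("AAT95397.1", "AAW82336.1", "AAV40979.1", "recombinant",
           "this-study-DNA", "this-study-mRNA", "this-study-peptide"),
    sequence = c("DTHFPICIFCCGCCKTPKCGLCCIT",
                 "DTHFPICIFCCGCCKTPKCGFCCKT",
                 "DTHFPICIFCCGCCKTPKCGLCCKT",
                 "DTHFPICIFCCGCCKTPKCGLCCKT",
                 "DTHFPICIFCCGCCKTPKCGFCCRT",
                 "DTHFPICIFCCGCCKTPKCGFCCRT",
                 "DTHFPICIFCCGCCKTPKCGFCCRT"),
    provenance = c("mRNA", "mRNA", "mRNA", "recombinant",
                   "DNA", "mRNA", "peptide"),
    stringsAsFactors = FALSE
  )
}

# Disulfide count used when scoring a candidate: hepcidin-like peptides
# carry 4 bridges; entries with fewer than 8 cysteines are scored with
# floor(nCys / 2) so that malformed database records still get a score.
.candidate_disulfides <- function(sequence) {
  n_cys <- vapply(strsplit(sequence, ""), function(l) sum(l == "C"), integer(1))
  pmin(4L, n_cys %/% 2L)
}

#' Filter candidate sequences by precursor mass
#'
#' Computes each candidate's disulfide-corrected monoisotopic mass and its
#' signed ppm error against an observed neutral mass, and flags candidates
#' within tolerance.
#'
#' @param candidates Data frame with columns `id` and `sequence` (and
#'   optionally `provenance`), e.g. [hepcidin_candidates()], or a path to
#'   a CSV/FASTA candidate file (see [read_candidates()]).
#' @param observed_mass Observed neutral monoisotopic mass in Da.
#' @param tol_ppm Tolerance in ppm (default 20).
#' @return The candidate data frame with added columns `n_disulfides`,
#'   `mass`, `precursor_ppm`, `passes_precursor`.
#' @export
#' @examples
#' precursor_filter(hepcidin_candidates(), 2777.0632)
precursor_filter <- function(candidates, observed_mass, tol_ppm = 20) {
  candidates <- .as_candidates(candidates)
  if (observed_mass <= 0) stop("observed mass must be positive")
  nd <- .candidate_disulfides(candidates$sequence)
  mass <- mapply(function(s, d) monoisotopic_mass(composition_of(peptide(s, d))),
                 candidates$sequence, nd)
  ppm <- (observed_mass - mass) / mass * 1e6
  candidates$n_disulfides <- nd
  candidates$mass <- unname(mass)
  candidates$precursor_ppm <- unname(ppm)
  candidates$passes_precursor <- abs(candidates$precursor_ppm) <= tol_ppm
  candidates
}

#' Rank candidate sequences against precursor mass and MS/MS evidence
#'
#' Scores each candidate by (1) precursor mass agreement and (2) fragment
#' evidence from an observed MS/MS spectrum, then orders by: passes the
#' precursor filter, higher bond coverage, more matched ions, smaller
#' absolute precursor ppm; remaining ties broken lexicographically by id.
#'
#' @inheritParams precursor_filter
#' @param msms A [mass_spectrum()] of observed fragment ions, or `NULL`
#'   (ranking then falls back to precursor evidence only).
#' @param precursor_tol_ppm Precursor tolerance in ppm (default 20).
#' @param fragment_tol_ppm MS/MS match tolerance in ppm (default 10).
#' @param cys_correction Apply the per-cysteine hydrogen subtraction when
#'   predicting fragments (default `TRUE`, appropriate for
#'   disulfide-bonded peptides).
#' @return Data frame of candidate scores ordered by rank, with columns
#'   `rank`, `id`, `sequence`, `mass`, `precursor_ppm`, `passes_precursor`,
#'   `fragment_coverage`, `matched_ion_count`.
#' @export
rank_candidates <- function(candidates, observed_mass, msms = NULL,
                            precursor_tol_ppm = 20, fragment_tol_ppm = 10,
                            cys_correction = TRUE) {
  candidates <- .as_candidates(candidates)
  if (nrow(candidates) == 0) stop("empty candidate list")
  scored <- precursor_filter(candidates, observed_mass, precursor_tol_ppm)
  if (!is.null(msms) && nrow(.as_spectrum(msms)) > 0) {
    frag <- lapply(seq_len(nrow(scored)), function(i) {
      a <- annotate_spectrum(msms, peptide(scored$sequence[i],
                                           scored$n_disulfides[i]),
                             tol_ppm = fragment_tol_ppm,
                             cys_correction = cys_correction)
      c(coverage = a$coverage, count = a$matched_ion_count)
    })
    scored$fragment_coverage <- vapply(frag, `[[`, numeric(1), "coverage")
    scored$matched_ion_count <- vapply(frag, `[[`, numeric(1), "count")
    scored$msms_used <- TRUE
  } else {
    scored$fragment_coverage <- 0
    scored$matched_ion_count <- 0
    scored$msms_used <- FALSE
  }
  ord <- order(-scored$passes_precursor, -scored$fragment_coverage,
               -scored$matched_ion_count, abs(scored$precursor_ppm),
               scored$id)
  scored <- scored[ord, ]
  scored$rank <- seq_len(nrow(scored))
  rownames(scored) <- NULL
  scored[, c("rank", "id", "sequence", "provenance", "mass", "precursor_ppm",
             "passes_precursor", "fragment_coverage", "matched_ion_count",
             "msms_used")]
}

.as_candidates <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    return(read_candidates(x))
  }
  x <- as.data.frame(x)
  if (!all(c("id", "sequence") %in% names(x))) {
    stop("candidates need 'id' and 'sequence' columns")
  }
  if (is.null(x$provenance)) x$provenance <- NA_character_
  x$sequence <- toupper(x$sequence)
  x
}
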