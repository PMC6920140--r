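# Residue monoisotopic masses, derived once from the residue formulas.
.residue_masses <- function() {
  vapply(.RESIDUE_FORMULAS, function(f) {
    idx <- match(names(f), .ATOMIC_MASSES$element)
    sum(f * .ATOMIC_MASSES$monoisotopic[idx])
  }, numeric(1))
}

.H_MONO <- 1.00782503207
.WATER_MONO <- 2 * 1.00782503207 + 15.9949146196

.cys_h <- function(constants_mode) {
  switch(constants_mode,
         modern = .H_MONO,
         legacy = .LEGACY_HYDROGEN,
         stop("constants_mode must be 'modern' or 'legacy'"))
}

#' m/z of a single b or y fragment ion
#'
#' Standard CID backbone fragments: `b_i` is the N-terminal piece of `i`
#' residues (sum of residue masses), `y_i` the C-terminal piece of `i`
#' residues plus water. Protonation adds `z` proton masses and divides by
#' `z`. With `cys_correction = TRUE`, one hydrogen mass is subtracted per
#' cysteine contained in the fragment - a uniform approximation for
#' fragments of a fully disulfide-bonded peptide, in which every cysteine
#' has lost the thiol hydrogen to an S-S bond.
#'
#' @param pep A [peptide()] or sequence string.
#' @param series `"b"` or `"y"`.
#' @param index Number of residues in the fragment, `1 <= index < n`.
#' @param z Charge (default 1).
#' @param cys_correction Subtract one H per contained cysteine
#'   (default `FALSE`).
#' @param constants_mode `"modern"` (monoisotopic H, 1.0078250) or
#'   `"legacy"` (average-mass H, 1.00794, for bit-compatibility with older
#'   web calculators).
#' @return m/z in Th.
#' @export
#' @examples
#' fragment_mz("DTHFPICIFCCGCCKTPKCGFCCRT", "b", 2)  # ~217.082
fragment_mz <- function(pep, series = c("b", "y"), index, z = 1L,
                        cys_correction = FALSE, constants_mode = "modern") {
  pep <- .as_peptide(pep)
  series <- match.arg(series)
  n <- nchar(pep$sequence)
  index <- as.integer(index)
  if (any(index < 1) || any(index > n - 1)) {
    stop("fragment index must be in 1..", n - 1)
  }
  z <- as.integer(z)
  if (any(z < 1)) stop("charge must be >= 1")
  letters <- strsplit(pep$sequence, "")[[1]]
  rm <- .residue_masses()
  frag_letters <- if (series == "b") {
    lapply(index, function(i) letters[seq_len(i)])
  } else {
    lapply(index, function(i) letters[seq.int(n - i + 1, n)])
  }
  neutral <- vapply(frag_letters, function(l) sum(rm[l]), numeric(1))
  if (series == "y") neutral <- neutral + .WATER_MONO
  if (cys_correction) {
    n_cys <- vapply(frag_letters, function(l) sum(l == "C"), numeric(1))
    neutral <- neutral - n_cys * .cys_h(constants_mode)
  }
  (neutral + z * .PROTON_MASS) / z
}

#' Theoretical fragment-ion spectrum
#'
#' All `b_i` / `y_i` ions for `i = 1 .. n-1` across the requested series and
#' charges, with unit intensities, sorted by m/z.
#'
#' @inheritParams fragment_mz
#' @param series_set Character vector of series (default `c("b", "y")`).
#' @param z_set Integer charges (default 1).
#' @return A [mass_spectrum()] with extra columns `series`, `index`, `z`,
#'   `n_cys` (cysteines contained in the fragment).
#' @export
theoretical_spectrum <- function(pep, series_set = c("b", "y"), z_set = 1L,
                                 cys_correction = FALSE,
                                 constants_mode = "modern") {
  pep <- .as_peptide(pep)
  n <- nchar(pep$sequence)
  if (n < 2) stop("peptide must have at least 2 residues")
  letters <- strsplit(pep$sequence, "")[[1]]
  grid <- expand.grid(index = seq_len(n - 1), series = series_set, z = z_set,
                      stringsAsFactors = FALSE)
  grid <- grid[!duplicated(grid), ]
  mz <- mapply(function(s, i, z) {
    fragment_mz(pep, s, i, z, cys_correction, constants_mode)
  }, grid$series, grid$index, grid$z)
  n_cys <- mapply(function(s, i) {
    l <- if (s == "b") letters[seq_len(i)] else letters[seq.int(n - i + 1, n)]
    sum(l == "C")
  }, grid$series, grid$index)
  out <- data.frame(mz = mz, intensity = 1,
                    series = grid$series, index = grid$index, z = grid$z,
                    n_cys = as.integer(n_cys))
  out <- out[order(out$mz), ]
  rownames(out) <- NULL
  attr(out, "source_id") <- paste0("theoretical:", pep$sequence)
  attr(out, "rt") <- NA_real_
  class(out) <- c("mass_spectrum", "data.frame")
  out
}

#' Annotate an observed MS/MS spectrum against a candidate sequence
#'
#' Matches observed peaks to the theoretical b/y ions of `pep` within a ppm
#' tolerance. Each theoretical ion is assigned at most one peak (smallest
#' absolute ppm error; ties toward higher intensity) and each peak is
#' annotated at most once per (series, index, z). Bond coverage is the
#' fraction of the `n - 1` inter-residue bonds supported by at least one
#' annotated ion (`b_i` or `y_(n-i)` both support bond `i`). Isobaric
#' leucine/isoleucine are indistinguishable at this level.
#'
#' @inheritParams fragment_mz
#' @param observed A [mass_spectrum()].
#' @param tol_ppm Match tolerance in ppm (default 10).
#' @param z_set Charges of the theoretical ions (default 1).
#' @return A list of class `annotated_spectrum`: `spectrum`, `annotations`
#'   (data frame: peak, series, index, z, mz_theoretical, ppm),
#'   `coverage`, `matched_ion_count`.
#' @export
annotate_spectrum <- function(observed, pep, tol_ppm = 10,
                              series_set = c("b", "y"), z_set = 1L,
                              cys_correction = FALSE,
                              constants_mode = "modern") {
  observed <- .as_spectrum(observed)
  if (nrow(observed) == 0) stop("observed spectrum is empty")
  pep <- .as_peptide(pep)
  n <- nchar(pep$sequence)
  theo <- theoretical_spectrum(pep, series_set, z_set, cys_correction,
                               constants_mode)
  ann <- vector("list", nrow(theo))
  for (i in seq_len(nrow(theo))) {
    d_ppm <- (observed$mz - theo$mz[i]) / theo$mz[i] * 1e6
    ok <- which(abs(d_ppm) <= tol_ppm)
    if (length(ok) == 0) next
    best <- ok[order(abs(d_ppm[ok]), -observed$intensity[ok])][1]
    ann[[i]] <- data.frame(peak = best, series = theo$series[i],
                           index = theo$index[i], z = theo$z[i],
                           mz_theoretical = theo$mz[i], ppm = d_ppm[best])
  }
  ann <- do.call(rbind, ann[!vapply(ann, is.null, logical(1))])
  if (is.null(ann)) {
    ann <- data.frame(peak = integer(0), series = character(0),
                      index = integer(0), z = integer(0),
                      mz_theoretical = numeric(0), ppm = numeric(0))
  }
  bonds <- unique(c(ann$index[ann$series == "b"],
                    n - ann$index[ann$series == "y"]))
  bonds <- bonds[bonds >= 1 & bonds <= n - 1]
  structure(
    list(spectrum = observed, annotations = ann,
         coverage = length(bonds) / (n - 1),
         matched_ion_count = nrow(ann)),
    class = "annotated_spectrum"
  )
}

#' @export
print.annotated_spectrum <- function(x, ...) {
  cat("<annotated spectrum> ", x$matched_ion_count, " matched ion(s), bond coverage ",
      sprintf("%.1f%%", 100 * x$coverage), "\n", sep = "")
  invisible(x)
}
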