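# Isotope abundance tables (IUPAC 2021 representative values).
# Each element: matrix with columns mass (Da), abundance (fraction),
# rows ordered by nucleon number starting at the most-common-lightest isotope.
.ISOTOPES <- list(
  H = cbind(mass = c(1.00782503207, 2.01410177785),
            abundance = c(0.999885, 0.000115)),
  C = cbind(mass = c(12.0, 13.00335483507),
            abundance = c(0.9893, 0.0107)),
  N = cbind(mass = c(14.0030740048, 15.0001088989),
            abundance = c(0.99636, 0.00364)),
  O = cbind(mass = c(15.9949146196, 16.9991317565, 17.9991596129),
            abundance = c(0.99757, 0.00038, 0.00205)),
  S = cbind(mass = c(31.97207100, 32.97145876, 33.96786690, NA, 35.96708076),
            abundance = c(0.9499, 0.0075, 0.0425, 0, 0.0001))
)

# C13 - C12; the nucleon spacing used for charge recognition.
.NEUTRON_SPACING <- 1.00335483507

#' Mass spectrum container
#'
#' A centroided peak list: a data frame with columns `mz` and `intensity`,
#' sorted by m/z, with optional metadata attributes.
#'
#' @param mz,intensity Numeric vectors of equal length; intensities >= 0.
#' @param source_id,rt Optional metadata (free-text id, retention time in
#'   minutes) stored as attributes.
#' @return A data frame of class `mass_spectrum`.
#' @export
mass_spectrum <- function(mz, intensity, source_id = NA_character_, rt = NA_real_) {
  if (length(mz) != length(intensity)) stop("mz and intensity lengths differ")
  if (any(intensity < 0)) stop("intensities must be >= 0")
  ord <- order(mz)
  out <- data.frame(mz = as.numeric(mz[ord]), intensity = as.numeric(intensity[ord]))
  attr(out, "source_id") <- source_id
  attr(out, "rt") <- rt
  class(out) <- c("mass_spectrum", "data.frame")
  out
}

.as_spectrum <- function(x) {
  if (inherits(x, "mass_spectrum")) return(x)
  if (is.data.frame(x) && all(c("mz", "intensity") %in% names(x))) {
    return(mass_spectrum(x$mz, x$intensity))
  }
  stop("cannot interpret input as a mass spectrum")
}

# Convolve two (offset -> abundance/mass-centroid) isotope vectors.
# Representation: data.frame(offset, mass, abundance) with offset = nucleon
# shift from the all-lightest isotopologue; mass = abundance-weighted
# centroid within the bin.
.iso_convolve <- function(a, b, cap) {
  n_off <- outer(a$offset, b$offset, `+`)
  n_ab <- outer(a$abundance, b$abundance)
  n_mass <- outer(a$mass, b$mass, `+`)
  keep <- n_off <= cap
  off <- n_off[keep]; ab <- n_ab[keep]; ms <- n_mass[keep]
  agg_ab <- tapply(ab, off, sum)
  agg_m <- tapply(ab * ms, off, sum) / agg_ab
  data.frame(offset = as.integer(names(agg_ab)),
             mass = as.numeric(agg_m),
             abundance = as.numeric(agg_ab))
}

.iso_element <- function(element) {
  tab <- .ISOTOPES[[element]]
  if (is.null(tab)) stop("no isotope data for element: ", element)
  keep <- tab[, "abundance"] > 0
  data.frame(offset = which(keep) - 1L,
             mass = tab[keep, "mass"],
             abundance = tab[keep, "abundance"])
}

# Distribution of n atoms of one element, by binary exponentiation.
.iso_power <- function(base, n, cap) {
  result <- data.frame(offset = 0L, mass = 0, abundance = 1)
  sq <- base
  while (n > 0) {
    if (n %% 2 == 1) result <- .iso_convolve(result, sq, cap)
    n <- n %/% 2
    if (n > 0) sq <- .iso_convolve(sq, sq, cap)
  }
  result
}

#' Predict an aggregated isotope pattern
#'
#' Computes the isotopologue distribution of an elemental composition by
#' iterative convolution of per-element isotope vectors, aggregated per
#' nucleon number (unit-mass binning; each bin's mass is the
#' abundance-weighted centroid). This matches what a ~30,000-resolution
#' TOF instrument resolves: isotopologue peaks, not isotope fine structure.
#'
#' @param comp An `elemental_composition` (or named count vector, or
#'   [peptide()]).
#' @param z Charge; 0 (default) keeps neutral masses, z >= 1 converts each
#'   isotopologue mass to the `[M + zH]^z+` m/z.
#' @param abundance_floor Entries below this relative abundance (after the
#'   envelope-length cap) are dropped; the pattern is then renormalized to
#'   sum to 1. Default 1e-4.
#' @param max_isotopologues Envelope length cap (default 12).
#' @return A data frame of class `isotope_pattern` with columns `mz`
#'   (neutral mass when `z = 0`) and `abundance` (summing to 1), and a
#'   `charge` attribute.
#' @export
#' @examples
#' isotope_pattern(elemental_composition(c(C = 1)))
isotope_pattern <- function(comp, z = 0L, abundance_floor = 1e-4,
                            max_isotopologues = 12L) {
  if (inherits(comp, "peptide")) comp <- composition_of(comp)
  if (!inherits(comp, "elemental_composition")) comp <- elemental_composition(comp)
  if (length(comp) == 0) stop("empty composition")
  if (abundance_floor < 0 || abundance_floor >= 1) stop("abundance_floor must be in [0, 1)")
  cap <- as.integer(max_isotopologues) - 1L
  dist <- data.frame(offset = 0L, mass = 0, abundance = 1)
  for (el in names(comp)) {
    dist <- .iso_convolve(dist, .iso_power(.iso_element(el), unclass(comp)[[el]], cap), cap)
  }
  dist <- dist[dist$abundance >= abundance_floor, , drop = FALSE]
  dist$abundance <- dist$abundance / sum(dist$abundance)
  mz <- dist$mass
  z <- as.integer(z)
  if (z > 0) mz <- mz_of(mz, z)
  out <- data.frame(mz = mz, abundance = dist$abundance)
  out <- out[order(out$mz), ]
  rownames(out) <- NULL
  attr(out, "charge") <- z
  class(out) <- c("isotope_pattern", "data.frame")
  out
}

#' Compare a theoretical envelope with an observed spectrum
#'
#' Greedily pairs each theoretical isotopologue with the nearest observed
#' peak within a ppm tolerance (most abundant theoretical entries paired
#' first; each observed peak used at most once) and scores the agreement as
#' the cosine similarity between the paired intensity vectors, with
#' unpaired theoretical entries contributing zeros.
#'
#' @param theoretical An [isotope_pattern()].
#' @param observed A [mass_spectrum()] (or data frame with `mz`,
#'   `intensity`).
#' @param match_tol_ppm Pairing tolerance in ppm (default 10).
#' @return A list with `similarity` (in `[0, 1]`), `ppm_errors` (signed,
#'   observed vs theoretical, `NA` for unpaired entries), and `pairs`
#'   (data frame of matched indices).
#' @export
envelope_similarity <- function(theoretical, observed, match_tol_ppm = 10) {
  observed <- .as_spectrum(observed)
  if (nrow(theoretical) == 0 || nrow(observed) == 0) stop("empty inputs")
  n <- nrow(theoretical)
  matched_obs <- rep(NA_integer_, n)
  used <- rep(FALSE, nrow(observed))
  for (i in order(theoretical$abundance, decreasing = TRUE)) {
    d_ppm <- (observed$mz - theoretical$mz[i]) / theoretical$mz[i] * 1e6
    ok <- which(abs(d_ppm) <= match_tol_ppm & !used)
    if (length(ok) == 0) next
    # nearest in ppm; ties toward higher intensity
    best <- ok[order(abs(d_ppm[ok]), -observed$intensity[ok])][1]
    matched_obs[i] <- best
    used[best] <- TRUE
  }
  t_vec <- theoretical$abundance
  o_vec <- ifelse(is.na(matched_obs), 0, observed$intensity[matched_obs])
  ppm <- ifelse(is.na(matched_obs), NA_real_,
                (observed$mz[matched_obs] - theoretical$mz) / theoretical$mz * 1e6)
  denom <- sqrt(sum(t_vec^2)) * sqrt(sum(o_vec^2))
  sim <- if (denom == 0) 0 else sum(t_vec * o_vec) / denom
  list(similarity = sim, ppm_errors = ppm,
       pairs = data.frame(theoretical = seq_len(n), observed = matched_obs))
}

#' Deconvolute a charge-state series to a neutral mass
#'
#' Converts each `(m/z, z)` observation to a neutral mass and reports the
#' arithmetic mean together with the spread of the individual estimates in
#' ppm. A spread above `max_ppm_spread` flags the series as inconsistent
#' (it is reported, not an error).
#'
#' @param observations A data frame (or 2-column matrix) with columns `mz`
#'   and `z`.
#' @param max_ppm_spread Consistency limit in ppm (default 20).
#' @return A list of class `charge_state_series`: `observations`,
#'   `neutral_masses`, `inferred_neutral_mass`, `ppm_spread`, `consistent`.
#' @export
#' @examples
#' deconvolute(data.frame(mz = c(556.420376, 695.273485, 926.695333),
#'                        z = c(5, 4, 3)))
deconvolute <- function(observations, max_ppm_spread = 20) {
  observations <- as.data.frame(observations)
  if (!all(c("mz", "z") %in% names(observations))) {
    names(observations)[1:2] <- c("mz", "z")
  }
  if (nrow(observations) < 1) stop("need at least one (mz, z) observation")
  if (anyDuplicated(observations$z)) stop("charge states must be distinct")
  masses <- neutral_mass_from_mz(observations$mz, observations$z)
  m_mean <- mean(masses)
  spread <- if (length(masses) > 1) (max(masses) - min(masses)) / m_mean * 1e6 else 0
  structure(
    list(observations = observations,
         neutral_masses = masses,
         inferred_neutral_mass = m_mean,
         ppm_spread = spread,
         consistent = spread <= max_ppm_spread),
    class = "charge_state_series"
  )
}

#' @export
print.charge_state_series <- function(x, ...) {
  cat("<charge-state series> ", nrow(x$observations), " observation(s)\n",
      "  inferred neutral mass: ", sprintf("%.5f", x$inferred_neutral_mass),
      " Da\n  ppm spread: ", sprintf("%.3f", x$ppm_spread),
      if (!x$consistent) "  [INCONSISTENT]", "\n", sep = "")
  invisible(x)
}

#' Assign charge states to isotopic envelopes in a spectrum
#'
#' Splits the peak list into clusters separated by more than one nucleon
#' spacing, then, for each cluster with at least three peaks, picks the
#' candidate charge whose isotope spacing (1.00335/z) best matches the
#' median observed spacing between consecutive peaks. Clusters where no
#' candidate fits within `max_rel_err` are skipped. The median spacing makes
#' the assignment robust to moderate contaminant peaks inside a cluster.
#'
#' @param spectrum A [mass_spectrum()].
#' @param z_candidates Integer charges to consider (default 1:6).
#' @param max_rel_err Maximum relative deviation between observed and
#'   predicted spacing (default 0.15).
#' @return Data frame with columns `mz` (lowest-mass peak of the cluster,
#'   the monoisotopic peak when the envelope is complete) and `z`.
#' @export
assign_charges <- function(spectrum, z_candidates = 1:6, max_rel_err = 0.15) {
  spectrum <- .as_spectrum(spectrum)
  if (nrow(spectrum) == 0) {
    return(data.frame(mz = numeric(0), z = integer(0)))
  }
  gaps <- diff(spectrum$mz)
  cluster <- cumsum(c(0, gaps > .NEUTRON_SPACING * 1.25))
  out <- list()
  for (cl in unique(cluster)) {
    idx <- which(cluster == cl)
    if (length(idx) < 3) next
    d <- diff(spectrum$mz[idx])
    # weight each consecutive gap by the weaker flanking peak, so sparse
    # low-intensity contaminant peaks cannot outvote the true spacing
    w <- pmin(spectrum$intensity[idx[-length(idx)]], spectrum$intensity[idx[-1]])
    pred <- .NEUTRON_SPACING / z_candidates
    score <- vapply(pred, function(p) sum(w[abs(d - p) / p <= max_rel_err]),
                    numeric(1))
    if (max(score) <= 0) next
    out[[length(out) + 1]] <- data.frame(
      mz = spectrum$mz[idx[1]],
      z = z_candidates[which.max(score)]
    )
  }
  if (length(out) == 0) return(data.frame(mz = numeric(0), z = integer(0)))
  do.call(rbind, out)
}
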