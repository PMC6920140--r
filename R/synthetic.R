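# The sequence this package was built around: the Canidae hepcidin-25,
# 8 cysteines engaged in 4 disulfide bridges.
.HEPCIDIN_SEQ <- "DTHFPICIFCCGCCKTPKCGFCCRT"

#' The Canidae hepcidin-25 peptide
#'
#' Convenience constructor for the 25-residue, 4-disulfide Canidae
#' hepcidin (DTHFPICIFCCGCCKTPKCGFCCRT).
#'
#' @return A [peptide()].
#' @export
hepcidin_peptide <- function() peptide(.HEPCIDIN_SEQ, n_disulfides = 4L)

# Multiplicative lognormal noise with coefficient of variation cv.
.lognoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Uniform m/z jitter of +/- ppm.
.jitter_mz <- function(mz, ppm) {
  if (ppm <= 0) return(mz)
  mz * (1 + stats::runif(length(mz), -ppm, ppm) * 1e-6)
}

#' Simulate a multi-charge precursor spectrum
#'
#' Renders the theoretical isotope envelopes of a disulfide-bonded peptide
#' at the requested charge states, then applies multiplicative lognormal
#' intensity noise, uniform ppm jitter on m/z, optional peak dropout, and
#' optionally a co-eluting contaminant overlapping the high-mass isotopes
#' of the lowest charge state (as seen for real serum isolates).
#'
#' @param pep A [peptide()] (default [hepcidin_peptide()]).
#' @param charges Charge states to render (default `c(5, 4, 3)`).
#' @param intensity_cv Coefficient of variation of multiplicative
#'   intensity noise (default 0.05).
#' @param jitter_ppm Half-width of uniform m/z jitter in ppm (default 2).
#' @param dropout Fraction of peaks randomly removed (default 0).
#' @param contaminant Add contaminant peaks over the lowest-charge
#'   envelope (default `FALSE`).
#' @param contaminant_rel Contaminant intensity relative to that
#'   envelope's base peak (default 0.4).
#' @param seed Optional integer seed for reproducibility.
#' @return A list: `spectrum` (a [mass_spectrum()]), `truth` (list with
#'   `mass`, `charges`, `envelopes` = per-charge monoisotopic m/z).
#' @export
simulate_precursor_spectrum <- function(pep = hepcidin_peptide(),
                                        charges = c(5L, 4L, 3L),
                                        intensity_cv = 0.05,
                                        jitter_ppm = 2,
                                        dropout = 0,
                                        contaminant = FALSE,
                                        contaminant_rel = 0.4,
                                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  comp <- composition_of(pep)
  M <- monoisotopic_mass(comp)
  peaks <- list()
  mono_mz <- numeric(0)
  base_by_z <- c("5" = 1.0, "4" = 0.8, "3" = 0.5)  # arbitrary envelope scaling
  for (z in charges) {
    pat <- isotope_pattern(comp, z = z)
    base <- if (as.character(z) %in% names(base_by_z)) base_by_z[[as.character(z)]] else 1
    inten <- pat$abundance * 1e5 * base * .lognoise(nrow(pat), intensity_cv)
    mz <- .jitter_mz(pat$mz, jitter_ppm)
    keep <- stats::runif(length(mz)) >= dropout
    peaks[[length(peaks) + 1]] <- data.frame(mz = mz[keep], intensity = inten[keep])
    mono_mz <- c(mono_mz, mz_of(M, z))
  }
  if (contaminant) {
    zc <- min(charges)
    pat <- isotope_pattern(comp, z = zc)
    base_int <- max(pat$abundance) * 1e5 *
      (if (as.character(zc) %in% names(base_by_z)) base_by_z[[as.character(zc)]] else 1)
    # contaminant envelope overlapping the high-mass isotopes, offset by
    # half a nucleon spacing so its peaks interleave
    cont_mz <- pat$mz[nrow(pat) %/% 2 + seq_len(min(4, nrow(pat) %/% 2))] +
      0.5 * 1.00335483507 / zc
    cont_int <- base_int * contaminant_rel * rev(seq_along(cont_mz)) / length(cont_mz)
    peaks[[length(peaks) + 1]] <- data.frame(mz = cont_mz, intensity = cont_int)
  }
  all_peaks <- do.call(rbind, peaks)
  spec <- mass_spectrum(all_peaks$mz, all_peaks$intensity, source_id = "simulated")
  list(spectrum = spec,
       truth = list(mass = M, charges = charges,
                    envelopes = stats::setNames(mono_mz, charges)))
}

#' Simulate an MS/MS fragment spectrum
#'
#' The theoretical singly-charged b/y spectrum of the peptide (with the
#' per-cysteine hydrogen correction, as appropriate for a fully
#' disulfide-bonded precursor), with random peak dropout, ppm jitter, and
#' lognormal intensity variation.
#'
#' @inheritParams simulate_precursor_spectrum
#' @param dropout Fraction of fragment peaks removed (default 0.2).
#' @param jitter_ppm m/z jitter half-width in ppm (default 5).
#' @param cys_correction Passed to [theoretical_spectrum()] (default
#'   `TRUE`).
#' @return A list: `spectrum`, `truth` (list with `sequence`,
#'   `n_disulfides`).
#' @export
simulate_fragment_spectrum <- function(pep = hepcidin_peptide(),
                                       dropout = 0.2,
                                       jitter_ppm = 5,
                                       intensity_cv = 0.3,
                                       cys_correction = TRUE,
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  pep <- .as_peptide(pep)
  theo <- theoretical_spectrum(pep, cys_correction = cys_correction)
  keep <- stats::runif(nrow(theo)) >= dropout
  if (!any(keep)) keep[sample.int(nrow(theo), 1)] <- TRUE
  mz <- .jitter_mz(theo$mz[keep], jitter_ppm)
  inten <- 1e4 * .lognoise(sum(keep), intensity_cv)
  list(spectrum = mass_spectrum(mz, inten, source_id = "simulated-msms"),
       truth = list(sequence = pep$sequence, n_disulfides = pep$n_disulfides))
}

#' Simulate a genome with a planted peptide-coding gene
#'
#' Generates uniform-random DNA and plants the coding sequence of a
#' peptide (codons sampled uniformly from each residue's synonymous set)
#' as 1-3 exons, in order, on a chosen or random strand, separated by
#' random intron-like gaps. Ground-truth exon intervals are returned in
#' forward-strand 0-based half-open coordinates.
#'
#' @param pep Peptide whose coding sequence is planted (default
#'   [hepcidin_peptide()]).
#' @param genome_length Total genome length in nt (default 100000).
#' @param n_exons Number of coding segments, 1-3 (default 3).
#' @param strand `"+"`, `"-"`, or `"random"` (default).
#' @param min_exon_codons Minimum codons per exon (default 4).
#' @param intron_range Min/max intron length in nt (default
#'   `c(100, 5000)`).
#' @param seed Optional integer seed.
#' @return A list: `genome` (a [nuc_seq()]), `truth` (list with `strand`,
#'   `exons` data frame in forward coordinates, `cds` the planted coding
#'   sequence, `sequence` the peptide).
#' @export
simulate_genome_with_gene <- function(pep = hepcidin_peptide(),
                                      genome_length = 100000L,
                                      n_exons = 3L,
                                      strand = c("random", "+", "-"),
                                      min_exon_codons = 4L,
                                      intron_range = c(100L, 5000L),
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  strand <- match.arg(strand)
  if (strand == "random") strand <- sample(c("+", "-"), 1)
  pep <- .as_peptide(pep)
  n_res <- nchar(pep$sequence)
  n_exons <- as.integer(n_exons)
  if (n_exons < 1 || n_exons * min_exon_codons > n_res) {
    stop("exon plan incompatible with peptide length")
  }
  tab <- .codon_table()
  letters <- strsplit(pep$sequence, "")[[1]]
  cds <- paste(vapply(letters, function(a) {
    codons <- tab[[a]]
    codons[sample.int(length(codons), 1)]
  }, character(1)), collapse = "")

  # split residue count into n_exons parts, each >= min_exon_codons
  extra <- n_res - n_exons * min_exon_codons
  parts <- min_exon_codons +
    as.vector(stats::rmultinom(1, extra, rep(1, n_exons)))
  stopifnot(sum(parts) == n_res, all(parts >= min_exon_codons))
  exon_nt <- 3L * parts
  introns <- if (n_exons > 1) {
    sample(intron_range[1]:intron_range[2], n_exons - 1, replace = TRUE)
  } else integer(0)
  gene_span <- sum(exon_nt) + sum(introns)
  if (gene_span + 2 > genome_length) stop("exon plan longer than genome")

  bases <- c("A", "C", "G", "T")
  gene_start <- sample.int(genome_length - gene_span + 1L, 1) - 1L  # 0-based
  genome <- sample(bases, genome_length, replace = TRUE)
  cds_chars <- strsplit(cds, "")[[1]]
  pos <- gene_start
  offset <- 0L
  exons_fwd <- data.frame(start = integer(n_exons), end = integer(n_exons))
  for (i in seq_len(n_exons)) {
    seg <- cds_chars[(offset + 1L):(offset + exon_nt[i])]
    genome[(pos + 1L):(pos + exon_nt[i])] <- seg
    exons_fwd$start[i] <- pos
    exons_fwd$end[i] <- pos + exon_nt[i]
    offset <- offset + exon_nt[i]
    if (i < n_exons) pos <- pos + exon_nt[i] + introns[i]
  }
  genome_str <- paste(genome, collapse = "")
  if (strand == "-") {
    genome_str <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(genome_str)))
    exons_fwd <- data.frame(start = genome_length - exons_fwd$end,
                            end = genome_length - exons_fwd$start)
    exons_fwd <- exons_fwd[order(exons_fwd$start), , drop = FALSE]
    rownames(exons_fwd) <- NULL
  }
  list(genome = nuc_seq(genome_str, id = "synthetic-genome"),
       truth = list(strand = strand, exons = exons_fwd, cds = cds,
                    sequence = pep$sequence))
}

#' Simulate a quantitation study
#'
#' Generates (a) an 8-point calibration series spanning 0.6-75 nM with
#' proportional response and multiplicative noise, (b) internal-standard
#' peak areas across an injection sequence, (c) unknown samples spiked at
#' a known concentration, and (d) a subjects x timepoints time-course for
#' hepcidin (rising after transfusion) and total serum iron (immediate
#' rise then decline) with lognormal between-subject and within-subject
#' noise - the design of a 10-greyhound, 4-timepoint transfusion study.
#'
#' @param calibration_nM Calibration levels in nM (default an 8-point
#'   doubling series spanning 0.6 to 75 nM).
#' @param response_per_nM True response slope (default 1000 area units
#'   per nM).
#' @param calibration_cv Multiplicative noise CV on calibration responses
#'   (default 0.05).
#' @param is_nM Internal-standard concentration (default 18.75).
#' @param n_injections Length of the injection sequence for IS areas
#'   (default 117).
#' @param is_cv CV of IS areas across the sequence (default 0.14).
#' @param spike_nM True concentration of the unknown samples (default
#'   18.75), `n_spike` replicates.
#' @param n_spike Number of unknown replicates (default 6).
#' @param n_subjects,timepoints Time-course design (default 10 subjects at
#'   0, 2, 4, 6 h).
#' @param hepcidin_median,iron_median Per-timepoint median trajectories
#'   (defaults: hepcidin 4, 6, 9, 12 nM rising; iron 20, 45, 38, 30 uM
#'   jumping at 2 h then declining).
#' @param subject_cv Between-subject lognormal CV (default 0.25).
#' @param residual_cv Within-subject lognormal CV (default 0.15).
#' @param seed Optional integer seed.
#' @return A list: `calibration` (data frame `nM`, `response`),
#'   `is_areas` (numeric, length `n_injections`), `spike_responses`
#'   (numeric), `hepcidin`, `iron` (subjects x timepoints matrices with
#'   timepoint column names), `truth` (list of the generating
#'   parameters).
#' @export
simulate_quant_study <- function(calibration_nM = c(0.6, 1.17, 2.34, 4.69,
                                                    9.38, 18.75, 37.5, 75),
                                 response_per_nM = 1000,
                                 calibration_cv = 0.05,
                                 is_nM = 18.75,
                                 n_injections = 117L,
                                 is_cv = 0.14,
                                 spike_nM = 18.75,
                                 n_spike = 6L,
                                 n_subjects = 10L,
                                 timepoints = c(0, 2, 4, 6),
                                 hepcidin_median = c(4, 6, 9, 12),
                                 iron_median = c(20, 45, 38, 30),
                                 subject_cv = 0.25,
                                 residual_cv = 0.15,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(hepcidin_median) != length(timepoints) ||
      length(iron_median) != length(timepoints)) {
    stop("median trajectories must match the timepoints")
  }
  calibration <- data.frame(
    nM = calibration_nM,
    response = response_per_nM * calibration_nM *
      .lognoise(length(calibration_nM), calibration_cv)
  )
  is_areas <- response_per_nM * is_nM * .lognoise(n_injections, is_cv)
  spike_responses <- response_per_nM * spike_nM * .lognoise(n_spike, calibration_cv)
  k <- length(timepoints)
  make_course <- function(medians) {
    subj <- .lognoise(n_subjects, subject_cv)
    m <- outer(subj, medians) * matrix(.lognoise(n_subjects * k, residual_cv),
                                       n_subjects, k)
    colnames(m) <- timepoints
    rownames(m) <- paste0("subject", seq_len(n_subjects))
    m
  }
  list(calibration = calibration,
       is_areas = is_areas,
       spike_responses = spike_responses,
       hepcidin = make_course(hepcidin_median),
       iron = make_course(iron_median),
       truth = list(response_per_nM = response_per_nM, is_nM = is_nM,
                    spike_nM = spike_nM, timepoints = timepoints,
                    hepcidin_median = hepcidin_median,
                    iron_median = iron_median))
}
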