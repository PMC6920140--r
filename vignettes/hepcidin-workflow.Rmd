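---
title: "Identifying and quantifying a disulfide-rich peptide hormone: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying and quantifying a disulfide-rich peptide hormone: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peptigen)
```

# The problem

Hepcidin-25 is the 25-residue, liver-derived hormone that controls systemic
iron homeostasis by binding and degrading the iron exporter ferroportin. The
mature peptide carries eight cysteines locked into four intramolecular
disulfide bridges, which makes its intact mass *smaller* than a naive residue
sum: every S-S bond forms by oxidation of two thiols and removes two hydrogen
atoms. Database records for the canine ortholog long disagreed about the
residues at positions 21 and 24 (leucine/lysine in the older cDNA-derived
records versus phenylalanine/arginine in curated genome translations), a
62 Da discrepancy large enough that a targeted assay built on the wrong
sequence would simply never see the real hormone.

`peptigen` implements the peptidogenomic workflow that resolves such
disagreements: compute what each candidate sequence *should* weigh and
fragment into, compare against what the mass spectrometer *measured*, and
cross-validate the winning sequence against nucleotide evidence and
ortholog conservation. A synthetic-data module generates every input with
known ground truth, so the full chain is testable without instrument data.

# Intact mass with disulfide accounting

For a peptide with sequence $a_1 \dots a_n$ and $d$ disulfide bridges the
elemental composition is

$$\mathrm{comp} = \sum_{i=1}^{n} \mathrm{residue}(a_i) + \mathrm{H_2O} - 2d\,\mathrm{H},$$

and the monoisotopic mass is the count-weighted sum of monoisotopic atomic
masses (CODATA/AME values hard-coded to at least 7 decimals). For the
serum-measured Canidae sequence with $d = 4$ this yields
C117H172N32O31S8:

```{r mass}
hep <- hepcidin_peptide()
comp <- composition_of(hep)
comp
M <- monoisotopic_mass(comp)
M
```

Electrospray charging is pure algebra: $m/z = (M + z\,m_p)/z$ with the
proton mass $m_p = 1.007276$ Da, and deconvolution inverts it, averaging
the per-charge-state mass estimates and reporting their spread in ppm:

```{r charges}
mz_of(M, c(5, 4, 3))
deconvolute(data.frame(mz = c(556.420376, 695.273485, 926.695333),
                       z = c(5, 4, 3)))
```

Two constant choices deserve a note. Hydrogen removal and the per-cysteine
fragment correction use the monoisotopic H *atom* mass (1.0078250 Da);
charging uses the proton mass. Older web calculators used the average-mass
hydrogen (1.00794 Da) for the cysteine correction; that legacy constant is
retained (`amino_acid_table()$legacy_hydrogen`, `constants_mode = "legacy"`)
for bit-compatibility, and the difference (< 0.001 Da per cysteine) sits far
below the 10 ppm matching tolerance. Published monoisotopic predictions made
with 2004-era atomic-mass tables differ from ours by about 1 mDa on a
2.8 kDa peptide; we use current constants and do not attempt to
reverse-engineer historical tables. Disulfide *connectivity* (which cysteine
pairs with which) is deliberately not modeled: only the count affects the
intact mass, and it is rarely known experimentally.

# Isotope envelopes

`isotope_pattern()` computes the isotopologue distribution by iterative
convolution of per-element isotope vectors (binary exponentiation over atom
counts), aggregated per nucleon number with abundance-weighted centroid
masses. Unit-mass binning is the right granularity for a ~30,000-resolution
TOF instrument, which resolves isotopologue peaks but not isotope fine
structure. Defaults: envelope capped at 12 isotopologues, entries below a
relative abundance of 1e-4 dropped, then renormalized to sum to 1. The
neutron spacing constant used for charge recognition is 1.00335 Da
(13C - 12C).

```{r envelope}
pat5 <- isotope_pattern(comp, z = 5)
head(pat5, 4)
```

For a ~2.8 kDa peptide the most abundant isotopologue is no longer the
monoisotopic peak - an envelope shape the tests verify against a
full-enumeration oracle.

`envelope_similarity()` pairs theoretical isotopologues with observed peaks
greedily (most abundant first, nearest in ppm, ties toward higher
intensity, each observed peak used once) and scores the paired intensity
vectors by cosine similarity, counting unpaired theoretical entries as
zeros - so a missing isotope hurts the score rather than being ignored.

`assign_charges()` splits a peak list into clusters separated by more than
1.25 nucleon spacings and votes on each cluster's charge: every consecutive
gap votes for the charge whose predicted spacing ($1.00335/z$) it matches
within 15%, weighted by the weaker flanking peak's intensity. The weighting
is the design choice that matters: a co-eluting contaminant interleaved at
half-spacing would win a plain median-spacing vote (suggesting $2z$), but
its low-intensity gaps are outvoted by the intense true-spacing gaps in the
lower envelope.

# Fragment ions and the cysteine correction

Backbone CID fragments follow the standard b/y algebra ($b_i$: N-terminal
residue sum; $y_i$: C-terminal residue sum plus water; plus $z$ protons
over $z$). For a fully disulfide-bonded peptide the package offers the
uniform approximation of subtracting one hydrogen per cysteine *contained
in the fragment*, reflecting that every thiol has lost its hydrogen to an
S-S bond. This is an approximation - real disulfide-linked fragments can
remain tethered across the bridge - but it is the convention under which
the reference b/y predictions for hepcidins were generated, and the
complementarity identity $b_i + y_{n-i} - 2m_p = M$ holds exactly in the
uncorrected case (a property test). Only b/y at $z = 1$ are produced by
default, matching predictions "from an assumed singly-protonated
precursor"; other series and charges sit behind arguments. Leucine and
isoleucine are isobaric: annotation cannot distinguish them, and the
workflow resolves such positions genomically, not spectrally.

Annotation coverage is reported per inter-residue bond: bond $i$ is
supported if $b_i$ or $y_{n-i}$ matched within tolerance (10 ppm default).

# Candidate ranking

`rank_candidates()` scores each candidate sequence by precursor agreement
(signed ppm against the deconvoluted mass; pass/fail at 20 ppm default -
generous against observed sub-2-ppm errors, and configurable) and by MS/MS
bond coverage and matched-ion count. The sort key is: passes precursor,
higher coverage, more matched ions, smaller |ppm|, then id
lexicographically so reports are reproducible. Candidates with fewer than
eight cysteines are scored with $\lfloor n_{\mathrm{Cys}}/2 \rfloor$
bridges instead of erroring, so malformed database entries still appear,
ranked, in the report. The published record set is bundled as
`hepcidin_candidates()`:

```{r rank}
rank_candidates(hepcidin_candidates(), 2777.0632)[, 1:6]
```

No ppm threshold for "consistent" was ever printed alongside the original
measurements; 20 ppm is this package's default, chosen as roughly ten times
the instrument-level error so that a true sequence is never rejected while
a 28 Da (10,000 ppm) wrong residue never passes.

# Nucleotide cross-validation

`translate_nuc()` wraps the standard codon table (Biostrings; stops as
`*`, N-containing codons as `X`, leading CTG/TTG treated as ordinary
codons, trailing partial codons dropped). `reverse_translate_pattern()`
emits a regular expression of per-residue synonymous-codon alternations -
exact by construction, since split codon families (leucine, serine,
arginine) cannot be expressed as single IUPAC triplets.
`find_coding_matches()` scans both strands for contiguous coding matches
and, with `max_exons > 1`, chains up to three in-order coding segments
(each at least 4 codons, gaps at most 50 kb, splits only at codon
boundaries) - a deliberate simplification of spliced alignment that is
exactly what a compact three-exon gene needs, with backtracking over the
split point in case random sequence happens to extend an exon. Coordinates
follow the BED convention: 0-based half-open on the forward strand, with
minus-strand hits reported in forward coordinates plus a strand flag.

One subtlety encoded in the tests: the published 23-mer
`ATGCAGATGGGGAAGTGGGTGTC`, described as the "reverse translation" of the
conserved N-terminus DTHFPIC, is in fact the *antisense* strand of the
coding sequence (it translates to MQMGKWV on its own strand). The package
treats it as antisense rather than "correcting" it.

`conservation()` compares equal-length peptides column-wise (pairwise
percent identity, variant columns); unequal lengths are first aligned
globally with match 1 / mismatch 0 / gap -1 - an explicit, documented
stand-in for a full multiple-alignment tool, adequate for the
nearly-identical orthologs this analysis concerns.

# Quantitation and the time-course test

`align_features()` clusters peaks across samples greedily in decreasing
area order within retention-time and mass tolerances (defaults 0.10 min,
0.05 Da - the alignment settings of the source instrument software;
upstream peak-integration settings of that software concern profile data
and do not apply to the centroided peak lists this package accepts).
Reproducibility of an internal standard is summarized by
`percent_rsd()` = sd/mean x 100. Calibration is ordinary least squares of
response on concentration over an 8-point, 0.6-75 nM doubling series;
`quantify()` inverts it and flags extrapolation outside the calibrated
range. Responses may be internal-standard area ratios or raw areas - the
original normalization was never specified beyond the standard's purpose,
so both are accepted.

`friedman_test()` is implemented from the rank formula: within-subject
mid-ranks, tie-corrected statistic

$$Q = \frac{(k-1)\sum_j \left(R_j - n(k+1)/2\right)^2}{\sum_{ij} r_{ij}^2 - nk(k+1)^2/4},$$

referred to $\chi^2_{k-1}$, with an exact mode that enumerates all
$(k!)^n$ within-subject permutations (feasible to about $n \le 6$,
$k \le 4$; it conditions on each row's observed tie pattern). All-constant
rows yield $Q = 0$, $p = 1$ by definition. The chi-square route matches
`stats::friedman.test` to machine precision and the exact route matches an
independent enumeration oracle in the test suite; incomplete blocks are an
error, never silently dropped.

# What the synthetic data does and does not emulate

The generator defaults *are* the study conditions of the motivating
experiment: 5+/4+/3+ charge states of the 4-disulfide 25-mer; 8-point
0.6-75 nM calibration; an 18.75 nM internal standard across a 117-injection
sequence with 14% area CV (the level consistent with the reported ~14%
RSD); 10 subjects sampled at 0, 2, 4 and 6 hours. Median trajectories -
hepcidin rising 4, 6, 9, 12 nM; iron jumping 20 to 45 then declining 38, 30 -
are qualitative reconstructions of the published figure's shape (no numeric
medians were printed); they were fixed once as plausible physiology and are
configuration, not claims. Noise models are the simplest that match TOF
behavior: multiplicative lognormal intensities, uniform ppm jitter,
Bernoulli peak dropout, an optional interleaved contaminant at 40% of base
peak. Not emulated: chromatographic peak shapes, profile-mode (continuum)
spectra, detector saturation, correlated matrix interferences, real
between-dog biology. Passing tests therefore demonstrate the *algorithms*
are correct under controlled conditions, not that instrument data of any
quality will yield the same numbers.

Problem sizes used in the shipped tests were chosen to keep the full suite
fast on a laptop while leaving the statistics meaningful: 100-seed ranking
recovery, 4000-replicate null calibration of the Friedman test, 100 kb
planted-genome searches. All are parameters, not limits.

# Known limitations

* Average-mass workflows, non-proton adducts and negative mode are out of
  scope; peak lists must be centroided.
* The fragment model does not represent disulfide-tethered internal
  fragments; the uniform per-cysteine correction is an approximation.
* The exon-chaining search is not a spliced aligner (no splice-site model,
  codon-boundary splits only) and reports the first chain found per strand.
* Conservation analysis is pairwise identity, not a phylogeny-aware
  multiple alignment.
* The chi-square Friedman p-value is approximate for small $n$; use
  `exact = TRUE` there.
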