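# peptigen

Peptidogenomic identification and quantitation of disulfide-rich peptides,
built around the Canidae iron-regulatory hormone hepcidin-25.

## The problem

Hepcidin-25 is the master regulator of iron homeostasis: a 25-residue,
liver-derived peptide whose eight cysteines form four intramolecular
disulfide bridges. Database records of the canine ortholog disagreed for
years about residues 21 and 24 (leucine/lysine in cDNA-derived entries,
phenylalanine/arginine in curated genome translations) — a 62 Da
difference, so an assay targeting the wrong sequence can never detect the
real hormone. Resolving such conflicts takes a *peptidogenomics* loop:

1. compute each candidate sequence's disulfide-corrected intact mass and
   theoretical spectra,
2. compare them against the measured charge-state series, isotope
   envelopes and MS/MS fragments,
3. cross-validate the winner against nucleotide evidence (frame
   translation, degenerate reverse translation, exon-split coding-sequence
   search) and ortholog conservation,
4. quantify the peptide by internal-standard LC-MS calibration and test
   its time-course (Friedman rank test).

`peptigen` implements all four stages for R users (with a thin CLI in
`inst/scripts/peptigen`), plus a synthetic-data module that generates
spectra, genomes, calibration series and time-courses with known ground
truth so the entire pipeline is testable offline.

## The model in brief

For sequence $a_1\dots a_n$ with $d$ disulfide bridges:

- composition: $\sum_i \mathrm{residue}(a_i) + \mathrm{H_2O} - 2d\,\mathrm{H}$
  (each S–S bond removes two hydrogens);
- monoisotopic mass $M$: count-weighted sum of monoisotopic atomic masses;
- charging: $m/z = (M + z\,m_p)/z$, $m_p = 1.007276$ Da; deconvolution
  inverts and averages over observed charge states;
- isotope envelope: per-element isotope vectors convolved and aggregated
  per nucleon (unit-mass binning, as resolved by a ~30,000-resolution TOF);
- fragments: standard $b_i$/$y_i$ ions, optionally minus one hydrogen per
  contained cysteine (the disulfide-engaged approximation);
- Friedman statistic, tie-corrected:
  $Q = (k-1)\sum_j (R_j - n(k+1)/2)^2 \big/ (\sum_{ij} r_{ij}^2 - nk(k+1)^2/4)$
  against $\chi^2_{k-1}$, with an exact enumeration mode for small designs.

## Worked example

```r
library(peptigen)

hep <- hepcidin_peptide()            # DTHFPICIFCCGCCKTPKCGFCCRT, 4 bridges
composition_of(hep)
#> <elemental composition> C117H172N32O31S8

M <- monoisotopic_mass(composition_of(hep))
#> 2777.06319

round(mz_of(M, c(5, 4, 3)), 4)
#> [1] 556.4199 695.2731 926.6950
```

The three m/z values sit within 1 ppm of the ions observed in greyhound
serum (556.420376, 695.273485, 926.695333). Deconvoluting those observed
ions back to a neutral mass:

```r
d <- deconvolute(data.frame(mz = c(556.420376, 695.273485, 926.695333),
                            z = c(5, 4, 3)))
d
#> <charge-state series> 3 observation(s)
#>   inferred neutral mass: 2777.06483 Da
#>   ppm spread: 0.478
```

i.e. a 2,777 Da peptide with sub-ppm internal consistency — 62 Da heavier
than the 2,715 Da L21/K24 sequence the older records predicted. Ranking
all published candidate sequences against this mass and a (here simulated)
MS/MS spectrum:

```r
msms <- simulate_fragment_spectrum(seed = 7)   # truth: the F/R sequence
rank_candidates(hepcidin_candidates(), d$inferred_neutral_mass, msms$spectrum)
#>   rank                 id precursor_ppm passes_precursor fragment_coverage
#> 1    1     this-study-DNA     5.902e-01             TRUE            0.9583
#> 2    2    this-study-mRNA     5.902e-01             TRUE            0.9583
#> 3    3 this-study-peptide     5.902e-01             TRUE            0.9583
#> 4    4         AAW82336.1     1.019e+04            FALSE            0.7500
#> 5    5         AAV40979.1     2.283e+04            FALSE            0.6250
#> 6    6        recombinant     2.283e+04            FALSE            0.6250
#> 7    7         AAT95397.1     2.852e+04            FALSE            0.6250
```

Only the genome-consistent F21/R24 sequence passes the precursor filter
(0.6 ppm); every historical variant misses by thousands of ppm and
annotates fewer fragment bonds. `run_identify()` chains this with the
coding-sequence search and conservation analysis into one report; see the
vignette (`vignettes/hepcidin-workflow.Rmd`) for the methods behind each
stage.

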