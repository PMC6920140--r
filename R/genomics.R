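.as_dna_string <- function(nuc) {
  if (inherits(nuc, "DNAString")) return(nuc)
  if (inherits(nuc, "nuc_seq")) return(Biostrings::DNAString(nuc$sequence))
  if (is.character(nuc) && length(nuc) == 1) {
    if (file.exists(nuc) && grepl("\\.(fa|fasta|fna)$", nuc, ignore.case = TRUE)) {
      set <- Biostrings::readDNAStringSet(nuc)
      if (length(set) != 1) stop("FASTA nucleotide input must contain exactly one record")
      return(set[[1]])
    }
    return(Biostrings::DNAString(toupper(nuc)))
  }
  stop("cannot interpret input as a nucleotide sequence")
}

#' Nucleotide sequence record
#'
#' Light container for a named nucleotide sequence over the alphabet
#' A/C/G/T/N.
#'
#' @param sequence Nucleotide string.
#' @param id Sequence identifier.
#' @return An object of class `nuc_seq`.
#' @export
nuc_seq <- function(sequence, id = "seq") {
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0) stop("empty nucleotide sequence")
  if (grepl("[^ACGTN]", sequence)) stop("alphabet must be A/C/G/T/N")
  structure(list(id = id, sequence = sequence), class = "nuc_seq")
}

#' Translate a nucleotide sequence in a given frame and strand
#'
#' Standard nuclear codon table. For the minus strand the sequence is
#' reverse-complemented first, then the frame offset applied. A trailing
#' partial codon is dropped; stop codons translate to `*` and codons
#' containing N to `X`.
#'
#' @param nuc Nucleotide input: string, `DNAString`, [nuc_seq()], or a
#'   single-record FASTA path.
#' @param frame Frame offset 0, 1 or 2.
#' @param strand `"+"` or `"-"`.
#' @return Peptide string.
#' @export
#' @examples
#' translate_nuc("ATGCAGATGGGGAAGTGGGTGTC", strand = "-")  # "DTHFPIC"
translate_nuc <- function(nuc, frame = 0L, strand = c("+", "-")) {
  strand <- match.arg(strand)
  frame <- as.integer(frame)
  if (!frame %in% 0:2) stop("frame must be 0, 1 or 2")
  dna <- .as_dna_string(nuc)
  if (strand == "-") dna <- Biostrings::reverseComplement(dna)
  len <- length(dna)
  start <- frame + 1L
  n_codons <- (len - frame) %/% 3L
  if (n_codons < 1) return("")
  dna <- Biostrings::subseq(dna, start, start + 3L * n_codons - 1L)
  # no.init.codon: a leading CTG/TTG is an ordinary codon here, not a start
  as.character(Biostrings::translate(dna, if.fuzzy.codon = "X",
                                     no.init.codon = TRUE))
}

.codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), gc)
}

#' Degenerate reverse translation of a peptide
#'
#' Builds a regular expression that matches exactly the DNA sequences
#' coding for the given peptide under the standard codon table: one
#' alternation group of synonymous codons per residue. (A single IUPAC
#' triplet cannot express split codon families such as leucine's
#' TTA/TTG/CTN, so alternation is used throughout.)
#'
#' @param pep Peptide string (standard 20 residues).
#' @return A single regex string (non-capturing groups), suitable for
#'   `gregexpr(..., perl = TRUE)`.
#' @export
#' @examples
#' reverse_translate_pattern("M")  # matches exactly "ATG"
reverse_translate_pattern <- function(pep) {
  if (inherits(pep, "peptide")) pep <- pep$sequence
  pep <- toupper(pep)
  letters <- strsplit(pep, "")[[1]]
  bad <- setdiff(letters, names(.RESIDUE_FORMULAS))
  if (length(bad)) stop("invalid residue letter(s): ", paste(unique(bad), collapse = ", "))
  tab <- .codon_table()
  groups <- vapply(letters, function(a) {
    codons <- tab[[a]]
    if (length(codons) == 1) codons else
      paste0("(?:", paste(codons, collapse = "|"), ")")
  }, character(1))
  paste0(groups, collapse = "")
}

# Longest run of residues of `pep` coded at oriented 0-based position p0.
.extend_match <- function(seq_chars, p0, pep_letters, tab) {
  n_max <- min(length(pep_letters), (length(seq_chars) - p0) %/% 3L)
  i <- 0L
  while (i < n_max) {
    codon <- paste(seq_chars[(p0 + 3L * i + 1L):(p0 + 3L * i + 3L)], collapse = "")
    if (!codon %in% tab[[pep_letters[i + 1L]]]) break
    i <- i + 1L
  }
  i
}

# Chained (exon-split) search on one oriented sequence. Returns list of
# segment data.frames (oriented 0-based half-open) or NULL.
.find_chain <- function(seq_str, seq_chars, pep_letters, from, exons_left,
                        min_codons, max_gap, tab, first = TRUE) {
  n_pep <- length(pep_letters)
  anchor_len <- min(min_codons, n_pep)
  anchor_pat <- reverse_translate_pattern(
    paste(pep_letters[seq_len(anchor_len)], collapse = ""))
  window_end <- if (first) nchar(seq_str) else min(nchar(seq_str), from + max_gap)
  if (from >= window_end) return(NULL)
  m <- gregexpr(anchor_pat, substr(seq_str, from + 1L, window_end), perl = TRUE)[[1]]
  if (m[1] == -1) return(NULL)
  starts <- from + as.integer(m) - 1L  # oriented 0-based
  for (a in starts) {
    e <- .extend_match(seq_chars, a, pep_letters, tab)
    if (e < anchor_len) next
    if (e == n_pep) {
      return(list(data.frame(start = a, end = a + 3L * n_pep)))
    }
    if (exons_left <= 1) next
    for (j in seq.int(e, min_codons)) {
      remaining <- n_pep - j
      if (remaining < min_codons) next
      rest <- .find_chain(seq_str, seq_chars, pep_letters[(j + 1L):n_pep],
                          from = a + 3L * j, exons_left = exons_left - 1L,
                          min_codons = min_codons, max_gap = max_gap,
                          tab = tab, first = FALSE)
      if (!is.null(rest)) {
        return(c(list(data.frame(start = a, end = a + 3L * j)), rest))
      }
    }
  }
  NULL
}

#' Find coding matches for a peptide in a nucleotide sequence
#'
#' Scans both strands for stretches of DNA whose translation equals the
#' query peptide. With `max_exons > 1` the peptide may be split, in order,
#' across up to that many non-overlapping coding segments separated by
#' gaps of at most `max_gap` nucleotides (a simple chained search along the
#' coding strand, not a spliced aligner; splits are only considered at
#' codon boundaries). Each segment must span at least `min_exon_codons`
#' codons.
#'
#' Coordinates are 0-based half-open on the forward strand (BED
#' convention); minus-strand hits are reported in forward coordinates with
#' the strand flag set, exons ordered by forward position.
#'
#' @param pep Peptide string (length >= 4).
#' @param nuc Nucleotide input (see [translate_nuc()]).
#' @param max_exons Maximum number of coding segments (default 3).
#' @param min_exon_codons Minimum codons per segment (default 4).
#' @param max_gap Maximum intron-like gap in nucleotides (default 50000).
#' @param seq_id Identifier recorded in hits.
#' @return A list of hits; each hit is a list with `seq_id`, `strand`,
#'   `frame` (0-2, on the coding strand), `exons` (data frame `start`,
#'   `end`), `translated`. Empty list when the peptide is absent.
#' @export
find_coding_matches <- function(pep, nuc, max_exons = 3L, min_exon_codons = 4L,
                                max_gap = 50000L, seq_id = NULL) {
  if (inherits(pep, "peptide")) pep <- pep$sequence
  pep <- toupper(pep)
  if (nchar(pep) < 4) stop("peptide must be at least 4 residues")
  if (is.null(seq_id)) {
    seq_id <- if (inherits(nuc, "nuc_seq")) nuc$id else "seq"
  }
  dna <- .as_dna_string(nuc)
  L <- length(dna)
  pep_letters <- strsplit(pep, "")[[1]]
  tab <- .codon_table()
  hits <- list()
  for (strand in c("+", "-")) {
    oriented <- if (strand == "+") dna else Biostrings::reverseComplement(dna)
    seq_str <- as.character(oriented)
    seq_chars <- strsplit(seq_str, "")[[1]]

    # contiguous matches: full-peptide regex
    full_pat <- reverse_translate_pattern(pep)
    m <- gregexpr(full_pat, seq_str, perl = TRUE)[[1]]
    contig_starts <- if (m[1] == -1) integer(0) else as.integer(m) - 1L
    for (a in contig_starts) {
      seg <- data.frame(start = a, end = a + 3L * length(pep_letters))
      hits[[length(hits) + 1]] <- .make_hit(seq_id, strand, seg, L, pep)
    }

    # chained multi-exon matches (>= 2 segments, skipping contiguous ones)
    if (max_exons > 1) {
      chain <- .find_chain(seq_str, seq_chars, pep_letters, from = 0L,
                           exons_left = as.integer(max_exons),
                           min_codons = as.integer(min_exon_codons),
                           max_gap = as.integer(max_gap), tab = tab)
      if (!is.null(chain) && length(chain) > 1) {
        segs <- do.call(rbind, chain)
        hits[[length(hits) + 1]] <- .make_hit(seq_id, strand, segs, L, pep)
      }
    }
  }
  hits
}

.make_hit <- function(seq_id, strand, segs_oriented, L, pep) {
  frame <- segs_oriented$start[1] %% 3L
  if (strand == "+") {
    exons <- segs_oriented
  } else {
    exons <- data.frame(start = L - segs_oriented$end,
                        end = L - segs_oriented$start)
    exons <- exons[order(exons$start), , drop = FALSE]
  }
  rownames(exons) <- NULL
  structure(list(seq_id = seq_id, strand = strand, frame = frame,
                 exons = exons, translated = pep),
            class = "genomic_hit")
}

#' @export
print.genomic_hit <- function(x, ...) {
  cat("<genomic hit> ", x$seq_id, " (", x$strand, ") frame ", x$frame,
      ": ", paste(sprintf("[%d,%d)", x$exons$start, x$exons$end), collapse = " + "),
      " -> ", x$translated, "\n", sep = "")
  invisible(x)
}

#' Write coding-match hits as BED-like TSV
#'
#' One row per exon: seq id, start, end (0-based half-open, forward
#' strand), hit name, score placeholder, strand.
#'
#' @param hits List of hits from [find_coding_matches()].
#' @param path Output file.
#' @export
write_hits_bed <- function(hits, path) {
  rows <- do.call(rbind, lapply(seq_along(hits), function(i) {
    h <- hits[[i]]
    data.frame(chrom = h$seq_id, start = h$exons$start, end = h$exons$end,
               name = paste0("hit", i, ":", h$translated), score = 0,
               strand = h$strand)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Pairwise identity and conservation-column analysis
#'
#' For a set of peptide sequences, computes the matrix of pairwise percent
#' identities and lists the variant columns (positions at which any pair of
#' sequences differs). Equal-length inputs are compared column-wise;
#' unequal lengths are first globally aligned pairwise (match 1, mismatch
#' 0, gap -1) and identity taken over alignment columns, in which case
#' variant columns are reported only for the equal-length subset.
#'
#' @param sequences Named character vector (or named list) of peptide
#'   sequences, or a peptide FASTA path; at least 2 sequences.
#' @return A list of class `conservation_report`: `sequences`,
#'   `identity_matrix` (symmetric, diagonal 100), `variant_columns`.
#' @export
#' @examples
#' conservation(c(a = "DTHFPICIFCCGCCKTPKCGFCCRT",
#'                b = "DTHFPICIFCCGCCKTPKCGLCCIT"))
conservation <- function(sequences) {
  if (is.character(sequences) && length(sequences) == 1 && file.exists(sequences)) {
    set <- Biostrings::readAAStringSet(sequences)
    sequences <- stats::setNames(as.character(set), names(set))
  }
  sequences <- unlist(as.list(sequences))
  if (length(sequences) < 2) stop("need at least 2 sequences")
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    names(sequences) <- paste0("seq", seq_along(sequences))
  }
  sequences <- toupper(sequences)
  n <- length(sequences)
  ids <- names(sequences)
  lens <- nchar(sequences)
  mat <- matrix(100, n, n, dimnames = list(ids, ids))
  equal_len <- length(unique(lens)) == 1
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      if (lens[i] == lens[j]) {
        a <- strsplit(sequences[[i]], "")[[1]]
        b <- strsplit(sequences[[j]], "")[[1]]
        ident <- sum(a == b) / lens[i] * 100
      } else {
        ident <- .aligned_identity(sequences[[i]], sequences[[j]])
      }
      mat[i, j] <- mat[j, i] <- ident
    }
  }
  variant <- integer(0)
  if (equal_len) {
    cols <- do.call(rbind, strsplit(sequences, ""))
    variant <- which(apply(cols, 2, function(col) length(unique(col)) > 1))
  }
  structure(list(sequences = sequences, identity_matrix = mat,
                 variant_columns = variant),
            class = "conservation_report")
}

# Global alignment, match 1 / mismatch 0 / gap -1; identity over columns.
.aligned_identity <- function(a, b) {
  letters_all <- unique(c(strsplit(a, "")[[1]], strsplit(b, "")[[1]]))
  sub <- matrix(0, length(letters_all), length(letters_all),
                dimnames = list(letters_all, letters_all))
  diag(sub) <- 1
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = sub, gapOpening = 0, gapExtension = 1,
    type = "global")
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  ps <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  sum(pa == ps & pa != "-") / length(pa) * 100
}

#' @export
print.conservation_report <- function(x, ...) {
  cat("<conservation report> ", length(x$sequences), " sequences\n", sep = "")
  print(round(x$identity_matrix, 1))
  cat("variant columns:",
      if (length(x$variant_columns)) paste(x$variant_columns, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}
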