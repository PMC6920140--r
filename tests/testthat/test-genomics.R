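test_that("frame/strand translation follows the standard code", {
  expect_identical(translate_nuc("ATG"), "M")
  expect_identical(translate_nuc("ATGAAATAG"), "MK*")
  expect_identical(translate_nuc("ATGAANTAG"), "MX*")
  expect_identical(translate_nuc("CATGGG", frame = 1), "M")  # partial codon dropped
  # the published antisense 23-mer codes DTHFPIC on its reverse complement
  expect_identical(substr(translate_nuc("ATGCAGATGGGGAAGTGGGTGTC",
                                        strand = "-"), 1, 7), "DTHFPIC")
  expect_error(translate_nuc("ATG", frame = 3), "frame")
})

test_that("minus-strand translation equals plus-strand on the reverse complement", {
  set.seed(7)
  for (i in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    for (f in 0:2) {
      expect_identical(translate_nuc(s, frame = f, strand = "-"),
                       translate_nuc(rc, frame = f, strand = "+"))
    }
  }
})

test_that("reverse-translation patterns match exactly the coding DNA", {
  expect_identical(reverse_translate_pattern("M"), "ATG")
  expect_identical(reverse_translate_pattern("W"), "TGG")
  pat <- reverse_translate_pattern("DTHFPIC")
  expect_true(grepl(paste0("^", pat, "$"), "GACACCCACTTCCCCATCTGC", perl = TRUE))
  # exhaustive exactness for a dipeptide: every matching 6-mer translates
  # back to it, and every coding 6-mer matches
  pat2 <- paste0("^", reverse_translate_pattern("MF"), "$")
  bases <- c("A", "C", "G", "T")
  kmers <- do.call(paste0, expand.grid(rep(list(bases), 6)))
  hits <- kmers[grepl(pat2, kmers, perl = TRUE)]
  # independent oracle: one vectorized Biostrings translation of all 6-mers
  aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(kmers),
                                           no.init.codon = TRUE))
  expect_identical(sort(hits), sort(kmers[aa == "MF"]))
})

test_that("reverse translation round-trips through translation", {
  set.seed(11)
  tab <- Biostrings::GENETIC_CODE
  for (i in 1:10) {
    pep <- paste(sample(names(peptigen::amino_acid_table()$residue_formulas),
                        8, replace = TRUE), collapse = "")
    # one random codon realization per residue
    dna <- paste(vapply(strsplit(pep, "")[[1]], function(a) {
      cods <- names(tab)[tab == a]
      sample(cods, 1)
    }, character(1)), collapse = "")
    expect_identical(translate_nuc(dna), pep)
    expect_true(grepl(paste0("^", reverse_translate_pattern(pep), "$"),
                      dna, perl = TRUE))
  }
})

test_that("contiguous coding matches are found on the antisense strand", {
  nuc <- paste0("AAATTTCCC", "ATGCAGATGGGGAAGTGGGTGTC", "GGGTTTAAA")
  hits <- find_coding_matches("DTHFPIC", nuc)
  expect_length(hits, 1)
  expect_identical(hits[[1]]$strand, "-")
  expect_equal(nrow(hits[[1]]$exons), 1)
  # the 21 coding nt sit at forward offset 11..32 (0-based half-open)
  expect_identical(hits[[1]]$exons$start, 11L)
  expect_identical(hits[[1]]$exons$end, 32L)
  expect_length(find_coding_matches("WWWWWW", nuc), 0)
})

test_that("planted multi-exon genes are recovered with exact intervals", {
  for (seed in c(3, 14, 25)) {
    g <- simulate_genome_with_gene(genome_length = 30000L, n_exons = 3L,
                                   seed = seed)
    hits <- find_coding_matches(g$truth$sequence, g$genome, max_exons = 3)
    expect_gte(length(hits), 1)
    match_truth <- vapply(hits, function(h) {
      h$strand == g$truth$strand && nrow(h$exons) == nrow(g$truth$exons) &&
        all(h$exons$start == g$truth$exons$start) &&
        all(h$exons$end == g$truth$exons$end)
    }, logical(1))
    expect_true(any(match_truth))
  }
})

test_that("random DNA yields no spurious hits for a 7+ residue query", {
  set.seed(21)
  for (i in 1:3) {
    s <- paste(sample(c("A", "C", "G", "T"), 50000, replace = TRUE),
               collapse = "")
    expect_length(find_coding_matches(substr(HEP_SEQ, 1, 9), s,
                                      max_exons = 1), 0)
  }
})

test_that("conservation reproduces the published pairwise identities", {
  cons <- conservation(c(
    this_study = HEP_SEQ,
    AAT95397.1 = "DTHFPICIFCCGCCKTPKCGLCCIT",
    AAW82336.1 = "DTHFPICIFCCGCCKTPKCGFCCKT"
  ))
  m <- cons$identity_matrix
  expect_equal(unname(m["this_study", "AAT95397.1"]), 92)
  expect_equal(unname(m["this_study", "AAW82336.1"]), 96)
  expect_true(isSymmetric(m))
  expect_true(all(diag(m) == 100))
  expect_identical(cons$variant_columns, c(21L, 24L))
  ident <- conservation(c(a = HEP_SEQ, b = HEP_SEQ))
  expect_true(all(ident$identity_matrix == 100))
  expect_length(ident$variant_columns, 0)
})

test_that("identity matrix is invariant under sequence reordering", {
  seqs <- c(a = HEP_SEQ, b = "DTHFPICIFCCGCCKTPKCGLCCIT",
            c = "DTHFPICIFCCGCCKTPKCGLCCKT")
  m1 <- conservation(seqs)$identity_matrix
  m2 <- conservation(rev(seqs))$identity_matrix
  expect_equal(m1[names(seqs), names(seqs)], m2[names(seqs), names(seqs)])
})

test_that("unequal-length sequences are aligned before identity", {
  cons <- conservation(c(full = HEP_SEQ, short = substr(HEP_SEQ, 1, 20)))
  expect_equal(unname(cons$identity_matrix["full", "short"]), 20 / 25 * 100,
               tolerance = 0.01)
  expect_error(conservation(c(a = HEP_SEQ)), "at least 2")
})
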