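test_that("codon translation resolves assignable ambiguity codes", {
  expect_equal(translate_codon("YTR"), "L")   # all 4 expansions are Leu
  expect_equal(translate_codon("RCT"), "?")   # ACT=Thr vs GCT=Ala
  expect_equal(translate_codon("ATG"), "M")
  expect_equal(translate_codon("AC"), "?")    # incomplete triplet
  expect_equal(translate_codon("GCN"), "A")   # 4-fold degenerate Ala
  expect_equal(translate_codon("---"), "-")
  expect_equal(translate_codon("A-G"), "?")   # mixed gap is unresolvable
  expect_equal(translate_codon("TAR"), "*")   # TAA/TAG both stop
  expect_equal(translate_codon("GC?"), "A")   # '?' expands like N
  expect_error(translate_codon("AXG"), "invalid")
})

test_that("codon translation matches brute-force expansion on sampled triplets", {
  skip_if_not_installed("seqinr")
  set.seed(11)
  codes <- names(ORACLE_IUPAC)
  trips <- replicate(300, paste(sample(codes, 3, replace = TRUE),
                                collapse = ""))
  for (tr in unique(trips)) {
    expect_identical(translate_codon(tr), oracle_translate_triplet(tr),
                     label = tr)
  }
})

test_that("alignment translation runs frame +1 and flags odd lengths", {
  a <- alignment(c("s1", "s2"), c("ATGGCN", "ATGTAA"), source = "g.fas")
  res <- translate_nt_to_aa(a)
  expect_equal(res$alignment$seqs, c("MA", "M*"))
  expect_length(res$warnings, 0)

  b <- alignment("s1", "ATGGC", source = "g.fas")
  res2 <- translate_nt_to_aa(b)
  expect_equal(res2$alignment$seqs, "M?")
  expect_match(res2$warnings, "multiple of three")

  aa <- alignment(c("s1", "s2"), c("MKLF", "MKLW"), source = "p.fas")
  res3 <- translate_nt_to_aa(aa)
  expect_identical(res3$alignment, aa)  # pass-through for unsuitable input
})

test_that("reverse translation emits compressed IUPAC codons", {
  expect_equal(reverse_translate_aa("M"), "ATG")
  expect_equal(reverse_translate_aa("W"), "TGG")
  # six Leu codons: pos1 {T,C}=Y, pos2 {T}, pos3 {A,C,G,T}=N
  expect_equal(reverse_translate_aa("L"), "YTN")
  expect_equal(reverse_translate_aa("-"), "---")
  expect_equal(reverse_translate_aa("X"), "NNN")
  expect_equal(reverse_translate_aa("?"), "NNN")
  expect_error(reverse_translate_aa("O"), "unknown")
})

test_that("every concrete codon of an amino acid sits inside its compression", {
  gc <- Biostrings::GENETIC_CODE
  for (aa in unique(gc)) {
    comp <- strsplit(reverse_translate_aa(aa), "", fixed = TRUE)[[1]]
    for (codon in names(gc)[gc == aa]) {
      bases <- strsplit(codon, "", fixed = TRUE)[[1]]
      for (j in 1:3) {
        expect_true(bases[j] %in% ORACLE_IUPAC[[comp[j]]],
                    label = paste(aa, codon, j))
      }
    }
  }
})

test_that("reverse-translating an alignment triples its length", {
  a <- alignment(c("s1", "s2"), c("MW-L", "MWFL"), source = "p.fas",
                 types = c("amino_acid", "amino_acid"))
  out <- reverse_translate_alignment(a)
  expect_equal(nchar(out$seqs), c(12L, 12L))
  expect_equal(out$seqs[1], "ATGTGG---YTN")
  expect_equal(out$seqtype, "nucleotide")

  nt <- alignment("s1", "ACGT", source = "g.fas")
  expect_identical(reverse_translate_alignment(nt), nt)
})

test_that("translating a compressed codon recovers unambiguous residues", {
  p <- alignment(c("s1", "s2"), c("MWMW", "WMWM"), source = "p.fas",
                 types = rep("amino_acid", 2))
  back <- translate_nt_to_aa(reverse_translate_alignment(p))
  expect_identical(back$alignment$seqs, p$seqs)
})
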