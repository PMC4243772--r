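test_that("iupac_union is the inverse of the ambiguity expansion", {
  expect_equal(iupac_union("A"), "A")
  expect_equal(iupac_union(c("A", "C")), "M")
  expect_equal(iupac_union(c("A", "C", "G", "T")), "N")
  expect_equal(iupac_union(c("T", "U")), "T")
  expect_error(iupac_union(character()), "non-empty")
  # round-trip through every code in the hand-written oracle table
  for (code in setdiff(names(ORACLE_IUPAC), "U")) {
    expect_equal(iupac_union(ORACLE_IUPAC[[code]]), code)
  }
})

test_that("most-frequent consensus: plurality wins, base ties compress", {
  expect_equal(consensus_column(c("A", "A", "C"), "mostfreq",
                                "nucleotide"), "A")
  expect_equal(consensus_column(c("A", "C"), "mostfreq",
                                "nucleotide"), "M")
  # ties involving an ambiguity code, or amino-acid ties, give '?'
  expect_equal(consensus_column(c("A", "R"), "mostfreq",
                                "nucleotide"), "?")
  expect_equal(consensus_column(c("K", "R"), "mostfreq",
                                "amino_acid"), "?")
  expect_equal(consensus_column(c("-", "-", "?"), "mostfreq",
                                "nucleotide"), "?")
})

test_that("majority rule needs strictly more than half of the block", {
  expect_equal(consensus_column(c("A", "A", "C", "C", "G"), "majority",
                                "nucleotide"), "?")   # 40% max
  expect_equal(consensus_column(c("A", "A", "A", "C"), "majority",
                                "nucleotide"), "A")   # 75%
  expect_equal(consensus_column(c("K", "K", "R"), "majority",
                                "amino_acid"), "K")   # 2/3
  # exactly 50% is not a majority; gap rows stay in the denominator
  expect_equal(consensus_column(c("A", "A", "C", "G"), "majority",
                                "nucleotide"), "?")
  expect_equal(consensus_column(c("A", "A", "-", "-"), "majority",
                                "nucleotide"), "?")
  expect_equal(consensus_column(c("A", "A", "A", "-"), "majority",
                                "nucleotide"), "A")
})

test_that("strict consensus compresses all bases, ignoring gaps", {
  expect_equal(consensus_column(c("A", "G", "-"), "strict",
                                "nucleotide"), "R")
  expect_equal(consensus_column(c("-", "?", "-"), "strict",
                                "nucleotide"), "?")
  # input ambiguity codes are expanded before the union
  expect_equal(consensus_column(c("R", "C"), "strict", "nucleotide"), "V")
  expect_equal(consensus_column(c("K", "K"), "strict", "amino_acid"), "K")
  expect_equal(consensus_column(c("K", "R"), "strict", "amino_acid"), "X")
})

test_that("strict nucleotide consensus expands to a superset of the column", {
  set.seed(5)
  for (i in 1:300) {
    n <- sample(2:8, 1)
    states <- sample(c("A", "C", "G", "T", "R", "Y", "N", "-", "?"),
                     n, replace = TRUE)
    out <- consensus_column(states, "strict", "nucleotide")
    observed <- unlist(ORACLE_IUPAC[states[!states %in% c("-", "?")]])
    if (length(observed) == 0) {
      expect_equal(out, "?")
    } else {
      expect_true(all(observed %in% ORACLE_IUPAC[[out]]))
    }
  }
})

test_that("column order of the block never matters", {
  set.seed(6)
  for (method in c("mostfreq", "majority", "strict")) {
    for (i in 1:50) {
      states <- sample(c("A", "C", "G", "T", "-", "?"), 6, replace = TRUE)
      expect_identical(consensus_column(states, method, "nucleotide"),
                       consensus_column(sample(states), method,
                                        "nucleotide"))
    }
  }
})

test_that("block files parse and misassignments are refused", {
  f <- tempfile()
  writeLines(c("popA : s1, s2", "popB : s3,s4"), f)
  blocks <- parse_block_file(f)
  expect_equal(blocks, list(popA = c("s1", "s2"), popB = c("s3", "s4")))

  writeLines("no separator here", f)
  expect_error(parse_block_file(f), "block_name")
  writeLines(c("a : s1", "a : s2"), f)
  expect_error(parse_block_file(f), "duplicate block")
  writeLines(c("a : s1", "b : s1"), f)
  expect_error(parse_block_file(f), "more than one")
})

test_that("build_consensus replaces blocks and passes the rest through", {
  a <- alignment(c("s1", "s2", "s3"), c("AC", "AG", "TT"),
                 source = "g.fas")
  out <- build_consensus(a, list(pop = c("s1", "s2")), "strict")
  expect_equal(out$names, c("pop", "s3"))
  expect_equal(out$seqs, c("AS", "TT"))

  # identical sequences: consensus equals the sequence under all methods
  b <- alignment(c("s1", "s2"), c("ACGT", "ACGT"), source = "g.fas")
  for (m in c("mostfreq", "majority", "strict")) {
    expect_equal(build_consensus(b, list(x = c("s1", "s2")), m)$seqs,
                 "ACGT")
  }

  expect_error(build_consensus(a, list(pop = c("s1", "zz")), "strict"),
               "zz")
})
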