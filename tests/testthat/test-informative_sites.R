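test_that("the two-states-twice rule classifies the worked examples", {
  expect_true(is_parsimony_informative(c("A", "A", "C", "C"),
                                       "nucleotide"))
  expect_false(is_parsimony_informative(c("A", "A", "A", "C"),
                                        "nucleotide"))
  expect_false(is_parsimony_informative(c("A", "C", "G", "T"),
                                        "nucleotide"))
  # gaps and ambiguity codes are not character states
  expect_true(is_parsimony_informative(c("A", "A", "-", "-", "C", "C"),
                                       "nucleotide"))
  expect_false(is_parsimony_informative(c("R", "R", "C", "C"),
                                        "nucleotide"))
  expect_true(is_parsimony_informative(c("K", "K", "R", "R"),
                                       "amino_acid"))
})

test_that("classification agrees with the direct-count oracle", {
  set.seed(21)
  for (i in 1:400) {
    col <- sample(c("A", "C", "G", "T", "U", "R", "N", "-", "?"),
                  sample(2:10, 1), replace = TRUE)
    expect_identical(is_parsimony_informative(col, "nucleotide"),
                     oracle_informative(col, ORACLE_NT_STATES),
                     label = paste(col, collapse = ""))
  }
  for (i in 1:200) {
    col <- sample(c(ORACLE_AA_STATES, "X", "-", "?"),
                  sample(2:10, 1), replace = TRUE)
    expect_identical(is_parsimony_informative(col, "amino_acid"),
                     oracle_informative(col, ORACLE_AA_STATES),
                     label = paste(col, collapse = ""))
  }
})

test_that("classification is row-permutation invariant and monotone under duplication", {
  set.seed(22)
  for (i in 1:100) {
    col <- sample(c("A", "C", "G", "-"), 6, replace = TRUE)
    v <- is_parsimony_informative(col, "nucleotide")
    expect_identical(is_parsimony_informative(sample(col), "nucleotide"), v)
    if (v) {
      expect_true(is_parsimony_informative(rep(col, 2), "nucleotide"))
    }
  }
})

test_that("two-taxon alignments can never hold informative sites", {
  set.seed(23)
  for (i in 1:20) {
    a <- random_test_alignment(n = 2, len = 40)
    expect_length(extract_informative(a)$indices, 0)
  }
})

test_that("extraction keeps exactly the informative columns in order", {
  a <- alignment(c("t1", "t2", "t3", "t4"),
                 c("AACC", "AACC", "GGCC", "GGTT"),
                 source = "g.fas")
  res <- extract_informative(a)
  mat <- do.call(rbind, strsplit(c("AACC", "AACC", "GGCC", "GGTT"), ""))
  expected <- which(vapply(1:4, function(j) {
    oracle_informative(mat[, j], ORACLE_NT_STATES)
  }, logical(1)))
  expect_equal(res$indices, expected)
  expect_equal(nchar(res$alignment$seqs[1]), length(expected))

  same <- alignment(c("t1", "t2", "t3", "t4"), rep("ACGT", 4),
                    source = "g.fas")
  expect_length(extract_informative(same)$indices, 0)
})

test_that("fixture-planted informative columns are recovered", {
  fx <- generate_fixture(99, n_taxa = 6, n_genes = 2,
                         missing_fraction = 0, plant_informative = TRUE)
  for (p in fx$paths) {
    res <- extract_informative(read_alignment(p))
    expect_true(1 %in% res$indices)
  }
})
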