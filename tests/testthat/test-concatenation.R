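test_that("concatenation pads missing taxa by sequence type", {
  g1 <- alignment(c("a", "b"), c("ACGT", "ACGA"), source = "g1.fas")
  g2 <- alignment(c("a", "c"), c("GG", "GC"), source = "g2.fas")
  sm <- concatenate(list(g1, g2))

  expect_equal(sm$alignment$names, c("a", "b", "c"))
  expect_equal(sm$alignment$seqs,
               c("ACGTGG", "ACGANN", "NNNNGC"))
  expect_equal(sm$partitions$gene, c("g1", "g2"))
  expect_equal(sm$partitions$start, c(1L, 5L))
  expect_equal(sm$partitions$end, c(4L, 6L))
  expect_equal(sm$padded,
               data.frame(taxon = c("c", "b"), gene = c("g1", "g2")))
})

test_that("amino-acid and structure genes pad with X and dots", {
  aa <- alignment(c("a", "b"), c("MKL", "MKW"), source = "prot.fas",
                  types = rep("amino_acid", 2))
  nt <- alignment(c("a", "c"), c("ACGT", "ACGA"), source = "nt.fas")
  st <- alignment(c("struct1"), "((.))", source = "rna.fas",
                  types = "structure")
  sm <- concatenate(list(nt, aa, st))
  rows <- sm$alignment$seqs
  names(rows) <- sm$alignment$names
  expect_equal(unname(rows["c"]), paste0("ACGA", "XXX", "....."))
  expect_equal(unname(rows["struct1"]), paste0("....", "...", "((.))"))
  expect_equal(sm$partitions$seqtype,
               c("nucleotide", "amino_acid", "structure"))
})

test_that("a single input concatenates to itself with one partition", {
  g <- random_test_alignment(n = 4, len = 12)
  sm <- concatenate(list(g))
  expect_identical(sm$alignment$seqs, g$seqs)
  expect_equal(nrow(sm$partitions), 1L)
  expect_equal(sm$partitions$start, 1L)
  expect_equal(sm$partitions$end, 12L)
  expect_equal(nrow(sm$padded), 0L)
})

test_that("supermatrix length is the sum of gene lengths", {
  set.seed(13)
  for (i in 1:10) {
    alns <- lapply(1:3, function(g) {
      a <- random_test_alignment(n = sample(3:6, 1),
                                 len = sample(6:30, 1))
      a$source <- paste0("g", g, ".fas")
      a
    })
    sm <- concatenate(alns)
    expect_equal(nchar(sm$alignment$seqs[1]),
                 sum(vapply(alns, function(a) nchar(a$seqs[1]),
                            integer(1))))
    expect_equal(sm$partitions$end[3], nchar(sm$alignment$seqs[1]))
  }
})

test_that("slicing a partition reconstructs the gene exactly", {
  set.seed(14)
  for (i in 1:10) {
    taxa <- sprintf("t%02d", 1:6)
    alns <- lapply(1:3, function(g) {
      keep <- sort(sample(6, sample(3:6, 1)))
      a <- random_test_alignment(n = length(keep), len = 3 * g + 3)
      a$names <- taxa[keep]
      a$source <- paste0("g", g, ".fas")
      a
    })
    sm <- concatenate(alns)
    for (g in 1:3) {
      back <- extract_partition(sm, paste0("g", g))
      # row order follows the supermatrix; compare record-by-record
      ord <- match(alns[[g]]$names, back$names)
      expect_false(anyNA(ord))
      expect_identical(back$seqs[ord], alns[[g]]$seqs)
    }
  }
})

test_that("taxon order inside an input does not change row content", {
  g1 <- alignment(c("a", "b", "c"), c("ACGT", "ACGA", "ACGC"),
                  source = "g1.fas")
  g2 <- alignment(c("c", "a"), c("GT", "GA"), source = "g2.fas")
  g2r <- alignment(c("a", "c"), c("GA", "GT"), source = "g2.fas")
  s1 <- concatenate(list(g1, g2))
  s2 <- concatenate(list(g1, g2r))
  expect_identical(s1$alignment$names, s2$alignment$names)
  expect_identical(s1$alignment$seqs, s2$alignment$seqs)
})

test_that("duplicate gene stems get distinguishing suffixes", {
  g1 <- alignment("a", "ACGT", source = "dir1/g.fas")
  g2 <- alignment("a", "GGCC", source = "dir2/g.fas")
  sm <- concatenate(list(g1, g2))
  expect_equal(anyDuplicated(sm$partitions$gene), 0L)
})

test_that("input order resolution is deterministic", {
  d <- tempfile(); dir.create(d)
  file.create(file.path(d, c("b.fas", "a.fas")))
  expect_equal(basename(resolve_input_order(d)), c("a.fas", "b.fas"))
  expect_equal(resolve_input_order(c("b.fas", "a.fas")),
               c("b.fas", "a.fas"))
  expect_error(resolve_input_order(c("x.fas", "x.fas")), "duplicate")
})
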