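# Independent oracles and random-case builders shared across tests.
# The oracles deliberately avoid the package's own code paths: the
# IUPAC table below is written out by hand and concrete codons are
# translated through seqinr.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# concrete-codon table translated once through seqinr (built lazily so
# the helper loads even where seqinr is absent)
.oracle_codon_aa <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      bases <- c("A", "C", "G", "T")
      codons <- as.vector(outer(as.vector(outer(bases, bases, paste0)),
                                bases, paste0))
      tab <<- vapply(codons, function(cd) {
        seqinr::translate(tolower(strsplit(cd, "", fixed = TRUE)[[1L]]))
      }, character(1L))
    }
    tab
  }
})

# brute-force ambiguity translation: enumerate every concrete codon in
# the expansion, translate each with seqinr, demand a unique amino acid
oracle_translate_triplet <- function(triplet) {
  tab <- .oracle_codon_aa()
  chars <- strsplit(toupper(triplet), "", fixed = TRUE)[[1L]]
  sets <- ORACLE_IUPAC[chars]
  grid <- expand.grid(sets, stringsAsFactors = FALSE)
  aas <- unique(tab[paste0(grid[[1L]], grid[[2L]], grid[[3L]])])
  if (length(aas) == 1L) unname(aas) else "?"
}

# direct per-column state count straight from the printed definition
oracle_informative <- function(column, states) {
  col <- toupper(column)
  col[col == "U"] <- "T"
  counts <- table(col[col %in% states])
  sum(counts >= 2) >= 2
}

ORACLE_NT_STATES <- c("A", "C", "G", "T")
ORACLE_AA_STATES <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# random gap-bearing alignment for round-trip and property tests
random_test_alignment <- function(n = 4, len = 20, seqtype = "nucleotide",
                                  gap_prob = 0.1) {
  pool <- if (seqtype == "nucleotide") ORACLE_NT_STATES else ORACLE_AA_STATES
  seqs <- vapply(seq_len(n), function(i) {
    chars <- sample(pool, len, replace = TRUE)
    gaps <- runif(len) < gap_prob
    chars[gaps] <- sample(c("-", "?"), sum(gaps), replace = TRUE)
    paste(chars, collapse = "")
  }, character(1))
  alignment(sprintf("tx_%02d", seq_len(n)), seqs,
            source = "random.fas",
            types = rep(seqtype, n))
}

# balanced dot-bracket string built by random insertion of "()" / "."
random_balanced_structure <- function(n_pairs = 5, n_dots = 5,
                                      n_ignored = 2) {
  s <- character(0)
  insert <- function(s, piece) {
    at <- sample(0:length(s), 1)
    append(s, piece, after = at)
  }
  for (i in seq_len(n_pairs)) s <- insert(s, c("(", ")"))
  for (i in seq_len(n_dots)) s <- insert(s, ".")
  for (i in seq_len(n_ignored)) s <- insert(s, sample(c("-", "?"), 1))
  paste(s, collapse = "")
}

# drop the balance: insert one surplus bracket somewhere
random_unbalanced_structure <- function() {
  s <- strsplit(random_balanced_structure(sample(1:6, 1), 3, 1),
                "", fixed = TRUE)[[1]]
  extra <- sample(c("(", ")"), 1)
  at <- sample(0:length(s), 1)
  paste(append(s, extra, after = at), collapse = "")
}

# check the proper-nesting invariant of a pairing table: any two pairs
# are either disjoint or strictly nested
pairs_properly_nested <- function(pairs) {
  if (nrow(pairs) < 2) return(TRUE)
  for (i in seq_len(nrow(pairs) - 1)) {
    for (j in (i + 1):nrow(pairs)) {
      a <- pairs[i, ]; b <- pairs[j, ]
      disjoint <- a["close"] < b["open"] || b["close"] < a["open"]
      nested <- (a["open"] < b["open"] && b["close"] < a["close"]) ||
                (b["open"] < a["open"] && a["close"] < b["close"])
      if (!disjoint && !nested) return(FALSE)
    }
  }
  TRUE
}
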