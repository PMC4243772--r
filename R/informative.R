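# Parsimony-informative site classification and extraction. A site is
# parsimony-informative when it shows at least two character states
# that each occur at least twice; only such sites can discriminate
# tree topologies under parsimony.

informative_state_set <- function(seqtype) {
  nt <- c("A", "C", "G", "T")
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  switch(seqtype,
    nucleotide = nt,
    amino_acid = aa,
    mixed      = union(nt, aa),
    structure  = character()
  )
}

#' Is an alignment column parsimony-informative?
#'
#' Counts concrete character states only: gaps, `?` and ambiguity
#' codes are not treated as states (standard practice in phylogenetics
#' tools); `U` is counted as `T`. The column is informative when at
#' least two distinct states each reach a count of two.
#'
#' @param column character vector, one state per taxon.
#' @param seqtype `"nucleotide"`, `"amino_acid"` or `"mixed"`.
#' @return logical scalar.
#' @examples
#' is_parsimony_informative(c("A", "A", "C", "C"), "nucleotide")  # TRUE
#' is_parsimony_informative(c("A", "A", "A", "C"), "nucleotide")  # FALSE
#' @export
is_parsimony_informative <- function(column, seqtype = "nucleotide") {
  if (!length(column)) stop("column must be non-empty")
  states <- toupper(column)
  states[states == "U"] <- "T"
  states <- states[states %in% informative_state_set(seqtype)]
  if (length(states) < 4L) return(FALSE)
  tab <- tabulate(factor(states))
  sum(tab >= 2L) >= 2L
}

#' Extract the parsimony-informative columns of an alignment
#'
#' @param aln an [alignment()] or the alignment inside a supermatrix.
#' @return list with `alignment` (only the informative columns, in
#'   original order; possibly zero columns) and `indices` (1-based
#'   column positions).
#' @export
extract_informative <- function(aln) {
  if (inherits(aln, "supermatrix")) aln <- aln$alignment
  mat <- aln_matrix(aln)
  idx <- which(vapply(seq_len(ncol(mat)), function(j) {
    is_parsimony_informative(mat[, j], aln$seqtype)
  }, logical(1L)))
  out <- aln_from_matrix(mat[, idx, drop = FALSE], aln)
  list(alignment = out, indices = idx)
}
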