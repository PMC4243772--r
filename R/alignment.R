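# Core domain model: sequence records, alignments, type detection.

SEQTYPES <- c("nucleotide", "amino_acid", "structure", "mixed")

NT_ALPHABET <- c("A", "C", "G", "T", "U",
                 "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N",
                 "-", "?")
AA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                 "B", "Z", "J", "X", "*", "-", "?")
STRUCT_ALPHABET <- c("(", ")", ".", "-", "?")

seqtype_alphabet <- function(seqtype) {
  switch(seqtype,
    nucleotide = NT_ALPHABET,
    amino_acid = AA_ALPHABET,
    structure  = STRUCT_ALPHABET,
    mixed      = unique(c(NT_ALPHABET, AA_ALPHABET, STRUCT_ALPHABET)),
    stop("unknown seqtype: ", seqtype)
  )
}

#' Detect the sequence type of a residue string
#'
#' Classifies a residue string as `"structure"` (dot-bracket),
#' `"nucleotide"` or `"amino_acid"`. Detection is case-insensitive and
#' ignores gap (`-`) and missing (`?`) characters. A string whose
#' informative characters are all drawn from `(`, `)`, `.` is a
#' secondary-structure string; otherwise the string is called nucleotide
#' when at least 95\% of its informative characters are in
#' `A,C,G,T,U,N`, and amino acid otherwise. The 95\% threshold tolerates
#' occasional IUPAC ambiguity codes in DNA without misclassifying
#' protein sequences; it is a heuristic, documented rather than derived.
#'
#' @param residues single non-empty character string.
#' @return one of `"nucleotide"`, `"amino_acid"`, `"structure"`.
#' @examples
#' detect_seqtype("ACGTACGT")
#' detect_seqtype("MKLFEQW")
#' detect_seqtype("((..))")
#' @export
detect_seqtype <- function(residues) {
  if (!is.character(residues) || length(residues) != 1L || is.na(residues) ||
      !nzchar(residues)) {
    stop("residues must be a single non-empty character string")
  }
  chars <- strsplit(toupper(residues), "", fixed = TRUE)[[1L]]
  informative <- chars[!chars %in% c("-", "?")]
  if (length(informative) == 0L) {
    # nothing but gaps/missing: call it nucleotide by convention
    return("nucleotide")
  }
  if (all(informative %in% c("(", ")", "."))) {
    return("structure")
  }
  frac_nt <- mean(informative %in% c("A", "C", "G", "T", "U", "N"))
  if (frac_nt >= 0.95) "nucleotide" else "amino_acid"
}

# seqtype shared by the non-structure records; "structure" if all records
# are structure strings; "mixed" only when explicitly constructed so
# (supermatrices); a file mixing nucleotide and amino-acid records is
# rejected by the alignment constructor.
infer_alignment_seqtype <- function(types) {
  if (any(types == "mixed")) return("mixed")
  non_struct <- unique(types[types != "structure"])
  if (length(non_struct) == 0L) return("structure")
  if (length(non_struct) > 1L) {
    stop("alignment mixes nucleotide and amino-acid records; ",
         "input files must be type-homogeneous")
  }
  non_struct
}

#' Construct an alignment of named, equal-length sequences
#'
#' @param names character vector of unique, non-empty record names.
#' @param seqs character vector of residue strings (upper-cased on
#'   construction), all of identical length.
#' @param source label for the origin of the alignment (file name or a
#'   synthetic tag).
#' @param types optional per-record sequence types; detected with
#'   [detect_seqtype()] when omitted.
#' @return an object of class `"alignment"` with fields `names`, `seqs`,
#'   `types`, `seqtype` (alignment-level type) and `source`.
#' @export
alignment <- function(names, seqs, source = "<memory>", types = NULL) {
  names <- as.character(names)
  seqs <- toupper(as.character(seqs))
  if (length(names) != length(seqs)) {
    stop("names and seqs must have the same length")
  }
  if (length(seqs) == 0L) stop("an alignment needs at least one record")
  if (is.null(types)) {
    types <- vapply(seqs, function(s) {
      if (nzchar(s)) detect_seqtype(s) else "nucleotide"
    }, character(1L), USE.NAMES = FALSE)
  }
  obj <- structure(
    list(names = names, seqs = seqs, types = types,
         seqtype = infer_alignment_seqtype(types), source = source),
    class = "alignment"
  )
  issues <- validate_alignment(obj)
  if (length(issues)) {
    stop("invalid alignment (", source, "): ",
         paste(issues, collapse = "; "))
  }
  obj
}

#' Validate alignment invariants
#'
#' Checks equal residue-string lengths, unique non-empty record names
#' and per-record alphabet membership. Violations are reported, not
#' thrown, so callers can present them all at once.
#'
#' @param x an object shaped like an [alignment()].
#' @return character vector of violation messages; empty when valid.
#' @export
validate_alignment <- function(x) {
  issues <- character()
  if (any(!nzchar(x$names) | is.na(x$names))) {
    issues <- c(issues, "record names must be non-empty")
  }
  if (any(grepl("[\r\n]", x$names))) {
    issues <- c(issues, "record names must not contain newlines")
  }
  dup <- unique(x$names[duplicated(x$names)])
  if (length(dup)) {
    issues <- c(issues, paste0("duplicate record name(s): ",
                               paste(dup, collapse = ", ")))
  }
  lens <- nchar(x$seqs)
  if (length(unique(lens)) > 1L) {
    ref <- lens[1L]
    off <- x$names[lens != ref]
    issues <- c(issues, paste0("length mismatch for record(s): ",
                               paste(off, collapse = ", ")))
  }
  for (i in seq_along(x$seqs)) {
    if (!nzchar(x$seqs[i])) next
    chars <- unique(strsplit(x$seqs[i], "", fixed = TRUE)[[1L]])
    bad <- setdiff(chars, seqtype_alphabet(x$types[i]))
    if (length(bad)) {
      issues <- c(issues, paste0("record '", x$names[i], "': character(s) ",
                                 paste(bad, collapse = ""),
                                 " outside the ", x$types[i], " alphabet"))
    }
  }
  issues
}

#' @export
print.alignment <- function(x, ...) {
  cat("Alignment:", x$source, "\n")
  cat(" ", length(x$names), "records,", nchar(x$seqs[1L]), "columns,",
      x$seqtype, "\n")
  shown <- utils::head(seq_along(x$names), 6L)
  for (i in shown) {
    s <- x$seqs[i]
    if (nchar(s) > 50L) s <- paste0(substr(s, 1L, 50L), "...")
    cat("  ", format(x$names[i], width = 12L), " ", s, "\n", sep = "")
  }
  if (length(x$names) > 6L) cat("  ...\n")
  invisible(x)
}

n_records <- function(x) length(x$names)
aln_length <- function(x) nchar(x$seqs[1L])

# alignment columns as an n_records x L character matrix
aln_matrix <- function(x) {
  if (aln_length(x) == 0L) {
    return(matrix(character(), nrow = n_records(x), ncol = 0L))
  }
  do.call(rbind, strsplit(x$seqs, "", fixed = TRUE))
}

# rebuild an alignment from a character matrix, keeping metadata
aln_from_matrix <- function(mat, template, types = template$types) {
  seqs <- if (ncol(mat) == 0L) rep("", nrow(mat)) else
    apply(mat, 1L, paste, collapse = "")
  alignment(template$names, seqs, source = template$source, types = types)
}

file_stem <- function(path) {
  sub("\\.[^.]*$", "", basename(path))
}
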