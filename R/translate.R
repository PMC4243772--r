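# Nucleotide <-> amino-acid translation under the standard genetic
# code, with IUPAC ambiguity resolution in the forward direction and
# compressed (position-wise IUPAC union) codons in reverse.

GENETIC_CODE_TABLE <- Biostrings::GENETIC_CODE

# memo cache: ambiguity triplets recur constantly in real alignments
.codon_cache <- new.env(parent = emptyenv())

#' Translate one (possibly ambiguous) codon
#'
#' Each position is expanded through the IUPAC ambiguity map and the
#' Cartesian set of concrete codons is formed. If every concrete codon
#' encodes the same amino acid the triplet is assignable and that amino
#' acid is returned (so `"YTR"` gives `L`); otherwise `?` (so `"RCT"`
#' gives `?`). Incomplete triplets (fewer than 3 characters) give `?`.
#' A `?` position is expanded like `N`; a triplet containing `-` is
#' unresolvable (`?`) unless it is all gaps, in which case the gap is
#' preserved (`-`). Ambiguity sets mixing stop and sense codons give
#' `?`; pure stop codons give `*`.
#'
#' @param triplet string of 1--3 nucleotide characters (IUPAC codes,
#'   `-`, `?` allowed).
#' @return single amino-acid character, `?`, `*` or `-`.
#' @examples
#' translate_codon("ATG")  # M
#' translate_codon("YTR")  # L
#' translate_codon("RCT")  # ?
#' translate_codon("GCN")  # A
#' @export
translate_codon <- function(triplet) {
  triplet <- toupper(triplet)
  if (!is.character(triplet) || length(triplet) != 1L ||
      nchar(triplet) < 1L || nchar(triplet) > 3L) {
    stop("triplet must be a string of 1 to 3 characters")
  }
  hit <- get0(triplet, envir = .codon_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  chars <- strsplit(triplet, "", fixed = TRUE)[[1L]]
  ok <- chars %in% c(names(IUPAC_SETS), "-", "?")
  if (!all(ok)) {
    stop("invalid nucleotide character(s) in codon: ",
         paste(chars[!ok], collapse = ""))
  }
  aa <- translate_codon_impl(chars)
  assign(triplet, aa, envir = .codon_cache)
  aa
}

translate_codon_impl <- function(chars) {
  if (length(chars) < 3L) return("?")
  if (all(chars == "-")) return("-")
  if (any(chars == "-")) return("?")
  sets <- lapply(chars, function(ch) {
    if (ch == "?") c("A", "C", "G", "T") else IUPAC_SETS[[ch]]
  })
  codons <- as.vector(outer(
    as.vector(outer(sets[[1L]], sets[[2L]], paste0)),
    sets[[3L]], paste0))
  aas <- unique(unname(GENETIC_CODE_TABLE[codons]))
  if (length(aas) == 1L) aas else "?"
}

#' Translate a nucleotide alignment to amino acids
#'
#' Translates codon-wise in frame +1 (no reading-frame inference is
#' attempted). The output has `floor(L/3)` columns, plus one `?` column
#' when a trailing incomplete triplet exists; a warning is recorded
#' when the alignment length is not a multiple of 3. Alignments that
#' are not nucleotide (amino acid, structure, or nucleotide files
#' carrying a secondary-structure row) pass through untouched, so mixed
#' input sets can be translated in one run.
#'
#' @param aln an [alignment()].
#' @return list with `alignment` (translated or passed through) and
#'   `warnings` (character vector).
#' @export
translate_nt_to_aa <- function(aln) {
  warnings <- character()
  if (aln$seqtype != "nucleotide") {
    return(list(alignment = aln, warnings = warnings))
  }
  if (any(aln$types == "structure")) {
    warnings <- paste0(aln$source, ": contains secondary-structure ",
                       "records; alignment not translated")
    return(list(alignment = aln, warnings = warnings))
  }
  L <- aln_length(aln)
  if (L %% 3L != 0L) {
    warnings <- paste0(aln$source, ": length ", L,
                       " is not a multiple of three; trailing incomplete ",
                       "triplet translated to '?'")
  }
  starts <- seq(1L, L, by = 3L)
  seqs <- vapply(aln$seqs, function(s) {
    codons <- substring(s, starts, pmin(starts + 2L, L))
    paste(vapply(codons, translate_codon, character(1L)), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
  out <- alignment(aln$names, seqs, source = aln$source,
                   types = rep("amino_acid", length(seqs)))
  list(alignment = out, warnings = warnings)
}

#' Reverse-translate an amino acid into a compressed IUPAC codon
#'
#' The compressed codon carries, at each of the three positions, the
#' IUPAC code for the union of bases observed at that position across
#' all codons of the amino acid; e.g. leucine gives `"YTN"`. The
#' compression is lossy by construction: its expansion is a superset
#' of, never smaller than, the amino acid's codon set. `B`, `Z` and `J`
#' compress the unions of their member amino acids' codons; `X` and `?`
#' give `"NNN"`; `-` gives `"---"`; `*` compresses the stop codons.
#'
#' @param aa single amino-acid character (standard 20, `B`, `Z`, `J`,
#'   `X`, `*`, `-`, `?`).
#' @return 3-character nucleotide string.
#' @examples
#' reverse_translate_aa("M")  # ATG
#' reverse_translate_aa("L")  # YTN
#' @export
reverse_translate_aa <- function(aa) {
  aa <- toupper(aa)
  if (!is.character(aa) || length(aa) != 1L || nchar(aa) != 1L) {
    stop("aa must be a single character")
  }
  if (aa == "-") return("---")
  if (aa %in% c("?", "X")) return("NNN")
  members <- switch(aa,
    B = c("N", "D"), Z = c("Q", "E"), J = c("I", "L"), aa)
  codons <- names(GENETIC_CODE_TABLE)[GENETIC_CODE_TABLE %in% members]
  if (!length(codons)) stop("unknown amino-acid character: '", aa, "'")
  mat <- do.call(rbind, strsplit(codons, "", fixed = TRUE))
  paste(vapply(1:3, function(j) iupac_union(unique(mat[, j])),
               character(1L)), collapse = "")
}

#' Reverse-translate an amino-acid alignment to compressed codons
#'
#' Each residue becomes its compressed IUPAC codon, so the output is
#' three times the input length. Non-amino-acid alignments pass through
#' untouched.
#'
#' @param aln an [alignment()].
#' @return an [alignment()] of nucleotide type (or the input,
#'   unchanged).
#' @export
reverse_translate_alignment <- function(aln) {
  if (aln$seqtype != "amino_acid" || any(aln$types == "structure")) {
    return(aln)
  }
  cache <- new.env(parent = emptyenv())
  rt <- function(ch) {
    hit <- get0(ch, envir = cache, inherits = FALSE)
    if (!is.null(hit)) return(hit)
    v <- reverse_translate_aa(ch)
    assign(ch, v, envir = cache)
    v
  }
  seqs <- vapply(aln$seqs, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    paste(vapply(chars, rt, character(1L)), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
  types <- ifelse(aln$types == "amino_acid", "nucleotide", aln$types)
  alignment(aln$names, seqs, source = aln$source, types = types)
}
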