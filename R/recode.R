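# RY recoding (purines -> R, pyrimidines -> Y) and third-codon-position
# exclusion. Both assume in-frame (+1) protein-coding nucleotide input;
# no reading-frame inference is attempted.

RY_MAP <- c(A = "R", G = "R", R = "R",
            C = "Y", T = "Y", U = "Y", Y = "Y",
            "-" = "-", "?" = "?",
            S = "?", W = "?", K = "?", M = "?",
            B = "?", D = "?", H = "?", V = "?", N = "?")

#' RY-recode a single nucleotide character
#'
#' Purines (`A`, `G`, `R`) become `R`; pyrimidines (`C`, `T`, `U`, `Y`)
#' become `Y`. Gap and missing characters pass through. Ambiguity codes
#' spanning both classes (`W`, `S`, `K`, `M`, `B`, `D`, `H`, `V`, `N`)
#' have no unique purine/pyrimidine assignment and become `?`.
#'
#' @param chars character vector of nucleotide characters.
#' @return recoded character vector of the same length.
#' @export
ry_encode_char <- function(chars) {
  chars <- toupper(chars)
  out <- RY_MAP[chars]
  if (anyNA(out)) {
    stop("invalid nucleotide character(s) for RY coding: ",
         paste(unique(chars[is.na(out)]), collapse = ""))
  }
  unname(out)
}

#' RY-recode a nucleotide alignment
#'
#' Recodes either every column or only every third column (positions
#' 3, 6, 9, ... in frame +1). Amino-acid and structure alignments pass
#' through unchanged, as do secondary-structure rows inside nucleotide
#' alignments.
#'
#' @param aln an [alignment()].
#' @param mode `"all"` or `"third"`.
#' @return the recoded [alignment()].
#' @export
ry_encode <- function(aln, mode = c("all", "third")) {
  mode <- match.arg(mode)
  if (aln$seqtype != "nucleotide") return(aln)
  L <- aln_length(aln)
  idx <- if (mode == "all") seq_len(L) else which(seq_len(L) %% 3L == 0L)
  if (!length(idx)) return(aln)
  seqs <- aln$seqs
  for (i in seq_along(seqs)) {
    if (aln$types[i] != "nucleotide") next
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    chars[idx] <- ry_encode_char(chars[idx])
    seqs[i] <- paste(chars, collapse = "")
  }
  alignment(aln$names, seqs, source = aln$source, types = aln$types)
}

#' Drop every third column of a nucleotide alignment
#'
#' Removes columns 3, 6, 9, ... (1-based, frame +1) from every record,
#' including any secondary-structure row, so that record lengths stay
#' equal. Non-nucleotide alignments pass through unchanged. The output
#' length is `L - floor(L/3)`.
#'
#' @param aln an [alignment()].
#' @return the reduced [alignment()].
#' @export
exclude_third_positions <- function(aln) {
  if (aln$seqtype != "nucleotide") return(aln)
  L <- aln_length(aln)
  keep <- which(seq_len(L) %% 3L != 0L)
  if (length(keep) == L) return(aln)
  mat <- aln_matrix(aln)[, keep, drop = FALSE]
  aln_from_matrix(mat, aln)
}
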