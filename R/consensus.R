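# Consensus sequences for defined sequence blocks under three column
# rules: most frequent, majority rule (> 50% of the block), and strict
# (IUPAC union for nucleotides, 'X' for amino acids).

CONSENSUS_METHODS <- c("mostfreq", "majority", "strict")

#' Consensus character for one alignment column
#'
#' Rules per method, with gaps (`-`) and missing data (`?`) never
#' eligible as consensus states:
#' \describe{
#'   \item{mostfreq}{the most frequent informative state wins; a tie
#'     among concrete nucleotide bases yields their IUPAC union, any
#'     other tie (ambiguity codes involved, or amino-acid data) yields
#'     `?`.}
#'   \item{majority}{the state present in strictly more than 50\% of
#'     the block's sequences (gap-bearing sequences count in the
#'     denominator); otherwise `?`. A state at exactly 50\% is not a
#'     majority.}
#'   \item{strict}{nucleotide: the IUPAC union of all bases present,
#'     with input ambiguity codes expanded and `-`/`?` ignored as long
#'     as any base exists at the site; amino acid: `X` when more than
#'     one state is present. A column of only `-` and `?` yields `?`.}
#' }
#' In the frequency-based methods input ambiguity codes count as their
#' own states and are not expanded.
#'
#' @param states character vector, one state per block sequence.
#' @param method one of `"mostfreq"`, `"majority"`, `"strict"`.
#' @param seqtype `"nucleotide"` or `"amino_acid"`.
#' @return single consensus character.
#' @export
consensus_column <- function(states, method = CONSENSUS_METHODS,
                             seqtype = c("nucleotide", "amino_acid")) {
  method <- match.arg(method)
  seqtype <- match.arg(seqtype)
  states <- toupper(states)
  if (!length(states)) stop("states must be non-empty")
  informative <- states[!states %in% c("-", "?")]

  if (method == "mostfreq") {
    if (!length(informative)) return("?")
    tab <- table(informative)
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1L) return(top)
    if (seqtype == "nucleotide" && all(top %in% c("A", "C", "G", "T", "U"))) {
      return(iupac_union(top))
    }
    return("?")
  }

  if (method == "majority") {
    if (!length(informative)) return("?")
    tab <- table(informative)
    if (max(tab) > length(states) / 2) {
      return(names(tab)[which.max(tab)])
    }
    return("?")
  }

  # strict
  if (seqtype == "nucleotide") {
    if (!length(informative)) return("?")
    bases <- unique(unlist(lapply(informative, expand_iupac)))
    return(iupac_union(bases))
  }
  u <- unique(informative)
  if (!length(u)) "?" else if (length(u) == 1L) u else "X"
}

#' Parse a consensus block definition file
#'
#' One block per non-blank line, in the form
#' `block_name : member1,member2,...`. Block names must be unique and a
#' sequence name may appear in at most one block.
#'
#' @param path path to the block file.
#' @return named list mapping block name to a character vector of
#'   member sequence names.
#' @export
parse_block_file <- function(path) {
  if (!file.exists(path)) stop("no such block file: ", path)
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  blocks <- list()
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line)) next
    pos <- regexpr(":", line, fixed = TRUE)
    if (pos < 0L) {
      stop("block file ", path, ", line ", i,
           ": expected 'block_name : member1,member2,...'")
    }
    name <- trimws(substr(line, 1L, pos - 1L))
    members <- trimws(strsplit(substr(line, pos + 1L, nchar(line)),
                               ",", fixed = TRUE)[[1L]])
    members <- members[nzchar(members)]
    if (!nzchar(name) || !length(members)) {
      stop("block file ", path, ", line ", i,
           ": block name and members must be non-empty")
    }
    if (name %in% names(blocks)) {
      stop("block file ", path, ": duplicate block name '", name, "'")
    }
    blocks[[name]] <- members
  }
  all_members <- unlist(blocks, use.names = FALSE)
  if (anyDuplicated(all_members)) {
    stop("block file ", path, ": sequence(s) assigned to more than one ",
         "block: ", paste(unique(all_members[duplicated(all_members)]),
                          collapse = ", "))
  }
  blocks
}

#' Build block consensus sequences within an alignment
#'
#' Replaces each defined block of sequences by one consensus record
#' (named after the block), computed column-by-column with
#' [consensus_column()]. Records not assigned to any block pass through
#' unchanged, after the consensus records.
#'
#' @param aln an [alignment()] of nucleotide or amino-acid type.
#' @param blocks named list of member-name vectors, as from
#'   [parse_block_file()].
#' @param method consensus method, see [consensus_column()].
#' @return an [alignment()] with one record per block plus the
#'   unassigned records.
#' @export
build_consensus <- function(aln, blocks, method = CONSENSUS_METHODS) {
  method <- match.arg(method)
  if (!length(blocks)) return(aln)
  if (aln$seqtype == "structure" || aln$seqtype == "mixed") {
    stop("consensus requires a nucleotide or amino-acid alignment")
  }
  missing <- setdiff(unlist(blocks, use.names = FALSE), aln$names)
  if (length(missing)) {
    stop("block member(s) absent from ", aln$source, ": ",
         paste(missing, collapse = ", "))
  }
  mat <- aln_matrix(aln)
  cons_seqs <- vapply(blocks, function(members) {
    rows <- mat[match(members, aln$names), , drop = FALSE]
    paste(apply(rows, 2L, consensus_column, method = method,
                seqtype = aln$seqtype), collapse = "")
  }, character(1L))
  keep <- !aln$names %in% unlist(blocks, use.names = FALSE)
  out_names <- c(names(blocks), aln$names[keep])
  out_seqs <- c(unname(cons_seqs), aln$seqs[keep])
  out_types <- c(rep(aln$seqtype, length(blocks)), aln$types[keep])
  alignment(out_names, out_seqs, source = aln$source, types = out_types)
}
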