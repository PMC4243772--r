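# IUPAC nucleotide ambiguity codes: expansion and unique inverse lookup.
# The code <-> base-set tables come from Biostrings; 'U' is folded into
# 'T' wherever sets of bases are compared.

# named list: code -> character vector of concrete bases (A/C/G/T)
IUPAC_SETS <- local({
  m <- strsplit(Biostrings::IUPAC_CODE_MAP, "", fixed = TRUE)
  m[["U"]] <- "T"
  m
})

# sorted base-set string -> code ("ACGT" -> "N", "AG" -> "R", ...)
IUPAC_INVERSE <- local({
  m <- strsplit(Biostrings::IUPAC_CODE_MAP, "", fixed = TRUE)
  keys <- vapply(m, function(b) paste(sort(b), collapse = ""), character(1L))
  stats::setNames(names(m), keys)
})

#' Expand an IUPAC nucleotide code into its concrete bases
#'
#' @param code single IUPAC nucleotide character (`A`, `C`, `G`, `T`,
#'   `U` or an ambiguity code `R,Y,S,W,K,M,B,D,H,V,N`).
#' @return character vector of bases from `A,C,G,T`; `U` expands to `T`.
#' @export
expand_iupac <- function(code) {
  code <- toupper(code)
  set <- IUPAC_SETS[[code]]
  if (is.null(set)) stop("not an IUPAC nucleotide code: '", code, "'")
  set
}

#' IUPAC code for a set of nucleotide bases
#'
#' Returns the unique single-letter IUPAC ambiguity code whose expansion
#' equals the given base set, e.g. `{A,C}` is `M` and `{A,C,G,T}` is
#' `N`. Singletons map to themselves; `U` is treated as `T`.
#'
#' @param bases non-empty character vector with elements from
#'   `A,C,G,T,U`.
#' @return single IUPAC character.
#' @examples
#' iupac_union(c("A", "C"))
#' iupac_union(c("A", "C", "G", "T"))
#' @export
iupac_union <- function(bases) {
  bases <- toupper(bases)
  bases[bases == "U"] <- "T"
  bases <- unique(bases)
  if (length(bases) == 0L) stop("iupac_union needs a non-empty base set")
  if (!all(bases %in% c("A", "C", "G", "T"))) {
    stop("iupac_union accepts concrete bases only, got: ",
         paste(setdiff(bases, c("A", "C", "G", "T")), collapse = ","))
  }
  unname(IUPAC_INVERSE[paste(sort(bases), collapse = "")])
}
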