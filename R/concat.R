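# Supermatrix concatenation: gene alignments are joined column-wise,
# keyed by taxon name, with taxa missing from a gene padded by
# 'N' (nucleotide), 'X' (amino acid) or '.' (dot-bracket structure),
# and per-gene coordinates recorded in a partition map.

pad_char_for <- function(seqtype) {
  switch(seqtype,
    nucleotide = "N",
    amino_acid = "X",
    structure  = ".",
    stop("no padding character for seqtype: ", seqtype)
  )
}

#' Deterministic input ordering
#'
#' Paths are kept in the order given; a directory argument expands to
#' its files in lexicographic order. Duplicate paths are rejected.
#'
#' @param paths character vector of file and/or directory paths.
#' @return ordered character vector of file paths.
#' @export
resolve_input_order <- function(paths) {
  if (!length(paths)) stop("no input paths given")
  out <- unlist(lapply(paths, function(p) {
    if (dir.exists(p)) {
      files <- list.files(p, full.names = TRUE)
      files[order(basename(files), method = "radix")]
    } else {
      p
    }
  }))
  if (anyDuplicated(out)) {
    stop("duplicate input path(s): ",
         paste(unique(out[duplicated(out)]), collapse = ", "))
  }
  out
}

#' Concatenate gene alignments into a supermatrix
#'
#' The taxon set of the supermatrix is the union over all inputs,
#' ordered by first appearance. For each taxon and gene, the taxon's
#' sequence is used when present; otherwise a replacement string of the
#' gene's length is inserted: `N` for nucleotide genes, `X` for
#' amino-acid genes and `.` for structure strings (a taxon whose own
#' records are structure strings is always padded with `.`). Nucleotide
#' and amino-acid genes may be mixed in one supermatrix. Gene names are
#' the input source stems; duplicate stems get a numeric suffix.
#'
#' @param alignments ordered list of [alignment()] objects.
#' @return object of class `"supermatrix"`: a list with `alignment`
#'   (the concatenated alignment), `partitions` (data frame `gene`,
#'   `start`, `end`, `seqtype` with 1-based inclusive, contiguous
#'   coordinates) and `padded` (data frame `taxon`, `gene` of inserted
#'   replacement strings).
#' @export
concatenate <- function(alignments) {
  if (!length(alignments)) stop("need at least one alignment")
  if (!all(vapply(alignments, inherits, logical(1L), "alignment"))) {
    stop("all inputs must be alignment objects")
  }
  genes <- vapply(alignments, function(a) file_stem(a$source), character(1L))
  if (anyDuplicated(genes)) {
    genes <- make.unique(genes, sep = "_")
  }

  taxa <- character()
  taxon_type <- character()
  for (a in alignments) {
    new <- !a$names %in% taxa
    taxa <- c(taxa, a$names[new])
    taxon_type <- c(taxon_type, a$types[new])
  }

  lens <- vapply(alignments, aln_length, integer(1L))
  starts <- cumsum(c(1L, lens[-length(lens)]))
  partitions <- data.frame(
    gene = genes,
    start = starts,
    end = starts + lens - 1L,
    seqtype = vapply(alignments, function(a) a$seqtype, character(1L)),
    stringsAsFactors = FALSE
  )

  rows <- stats::setNames(rep("", length(taxa)), taxa)
  pad_taxon <- character()
  pad_gene <- character()
  for (g in seq_along(alignments)) {
    a <- alignments[[g]]
    idx <- match(taxa, a$names)
    for (t in seq_along(taxa)) {
      if (is.na(idx[t])) {
        pad_type <- if (taxon_type[t] == "structure") "structure"
                    else partitions$seqtype[g]
        rows[t] <- paste0(rows[t],
                          strrep(pad_char_for(pad_type), lens[g]))
        pad_taxon <- c(pad_taxon, taxa[t])
        pad_gene <- c(pad_gene, genes[g])
      } else {
        rows[t] <- paste0(rows[t], a$seqs[idx[t]])
      }
    }
  }

  # every gene contributes a cell to every row, so a row's alphabet is
  # governed by the full set of gene types
  gene_types <- unique(partitions$seqtype)
  row_types <- vapply(seq_along(taxa), function(t) {
    if (taxon_type[t] == "structure") return("structure")
    if (length(gene_types) == 1L) gene_types else "mixed"
  }, character(1L))

  sm_aln <- alignment(taxa, unname(rows), source = "supermatrix",
                      types = row_types)
  structure(
    list(alignment = sm_aln,
         partitions = partitions,
         padded = data.frame(taxon = pad_taxon, gene = pad_gene,
                             stringsAsFactors = FALSE)),
    class = "supermatrix"
  )
}

#' @export
print.supermatrix <- function(x, ...) {
  cat("Supermatrix:", length(x$alignment$names), "taxa x",
      aln_length(x$alignment), "columns,",
      nrow(x$partitions), "partitions\n")
  pm <- x$partitions
  for (i in seq_len(nrow(pm))) {
    cat("  ", pm$gene[i], ": ", pm$start[i], "-", pm$end[i],
        " (", pm$seqtype[i], ")\n", sep = "")
  }
  cat(" ", nrow(x$padded), "replacement strings inserted\n")
  invisible(x)
}

#' Extract one gene's columns from a supermatrix
#'
#' Slices the partition's coordinate range and drops the rows that
#' were inserted as replacement (padding) strings for that gene,
#' reconstructing the original gene alignment.
#'
#' @param sm a supermatrix from [concatenate()].
#' @param gene gene (partition) name.
#' @return an [alignment()] holding the gene's original records.
#' @export
extract_partition <- function(sm, gene) {
  pm <- sm$partitions
  i <- match(gene, pm$gene)
  if (is.na(i)) stop("no partition named '", gene, "'")
  padded_taxa <- sm$padded$taxon[sm$padded$gene == gene]
  keep <- !sm$alignment$names %in% padded_taxa
  seqs <- substr(sm$alignment$seqs[keep], pm$start[i], pm$end[i])
  alignment(sm$alignment$names[keep], seqs,
            source = paste0("supermatrix:", gene))
}
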