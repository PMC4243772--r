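# Alignment file I/O: FASTA / CLUSTAL / PHYLIP readers with format
# auto-detection, FASTA / PHYLIP / NEXUS writers, RAxML partition file
# and the plain-text info report.
#
# PHYLIP is handled in its relaxed dialect: names of any length
# delimited by whitespace, sequential single-line layout on write;
# single-line sequential or classic interleaved accepted on read.

OUTPUT_FORMATS <- c("fasta", "phylip", "nexus")

format_extension <- c(fasta = ".fas", phylip = ".phy", nexus = ".nex")

#' Read an alignment from FASTA, CLUSTAL or PHYLIP
#'
#' The format is auto-detected from the first non-blank line unless a
#' hint is given: `>` starts FASTA, a `CLUSTAL` header starts CLUSTAL,
#' and a leading `ntax nchar` integer pair starts PHYLIP. Residues are
#' upper-cased; CR/LF line endings are normalised.
#'
#' @param path path to the alignment file.
#' @param format optional format hint: `"fasta"`, `"clustal"` or
#'   `"phylip"`.
#' @return a validated [alignment()].
#' @export
read_alignment <- function(path, format = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  if (is.null(format)) {
    format <- sniff_format(lines, path)
  } else {
    format <- match.arg(tolower(format), c("fasta", "clustal", "phylip"))
  }
  rec <- switch(format,
    fasta   = parse_fasta(lines, path),
    clustal = parse_clustal(lines, path),
    phylip  = parse_phylip(lines, path)
  )
  alignment(rec$names, rec$seqs, source = path)
}

sniff_format <- function(lines, path) {
  idx <- which(nzchar(trimws(lines)))
  if (!length(idx)) stop("empty file: ", path)
  first <- trimws(lines[idx[1L]])
  if (startsWith(first, ">")) return("fasta")
  if (grepl("^CLUSTAL", first, ignore.case = TRUE)) return("clustal")
  if (grepl("^[0-9]+\\s+[0-9]+$", first)) return("phylip")
  stop("cannot determine alignment format of ", path,
       " (line ", idx[1L], ": '", substr(first, 1L, 30L), "')")
}

parse_fasta <- function(lines, path) {
  names <- character()
  seqs <- character()
  cur <- 0L
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line)) next
    if (startsWith(line, ">")) {
      cur <- cur + 1L
      names[cur] <- trimws(sub("^>", "", line))
      seqs[cur] <- ""
    } else {
      if (cur == 0L) {
        stop("FASTA parse error in ", path, " at line ", i,
             ": sequence data before the first '>' header")
      }
      seqs[cur] <- paste0(seqs[cur], gsub("\\s", "", line))
    }
  }
  if (cur == 0L) stop("no FASTA records found in ", path)
  list(names = names, seqs = seqs)
}

parse_clustal <- function(lines, path) {
  if (!grepl("^\\s*CLUSTAL", lines[which(nzchar(trimws(lines)))[1L]],
             ignore.case = TRUE)) {
    stop("missing CLUSTAL header in ", path)
  }
  body <- lines[-which(nzchar(trimws(lines)))[1L]]
  seqs <- list()
  order <- character()
  for (i in seq_along(body)) {
    line <- body[i]
    if (!nzchar(trimws(line))) next
    # conservation lines start with whitespace and hold only * : . and blanks
    if (grepl("^[ \t]", line)) next
    toks <- strsplit(trimws(line), "\\s+")[[1L]]
    if (length(toks) < 2L) {
      stop("CLUSTAL parse error in ", path, " at body line ", i,
           ": expected '<name> <sequence>'")
    }
    # drop a trailing cumulative-count column if present
    if (grepl("^[0-9]+$", toks[length(toks)])) toks <- toks[-length(toks)]
    nm <- toks[1L]
    chunk <- paste(toks[-1L], collapse = "")
    if (is.null(seqs[[nm]])) {
      seqs[[nm]] <- chunk
      order <- c(order, nm)
    } else {
      seqs[[nm]] <- paste0(seqs[[nm]], chunk)
    }
  }
  if (!length(order)) stop("no sequences found in CLUSTAL file ", path)
  list(names = order, seqs = unlist(seqs[order], use.names = FALSE))
}

parse_phylip <- function(lines, path) {
  idx <- which(nzchar(trimws(lines)))
  if (!length(idx)) stop("empty PHYLIP file: ", path)
  hdr <- strsplit(trimws(lines[idx[1L]]), "\\s+")[[1L]]
  if (length(hdr) != 2L || anyNA(suppressWarnings(as.integer(hdr)))) {
    stop("PHYLIP parse error in ", path, " at line ", idx[1L],
         ": expected '<ntax> <nchar>' header")
  }
  ntax <- as.integer(hdr[1L])
  nchar_expected <- as.integer(hdr[2L])
  body <- lines[idx[-1L]]
  if (length(body) < ntax) {
    stop("PHYLIP file ", path, " declares ", ntax,
         " taxa but holds only ", length(body), " sequence lines")
  }
  names <- character(ntax)
  seqs <- character(ntax)
  for (i in seq_len(ntax)) {
    toks <- strsplit(trimws(body[i]), "\\s+")[[1L]]
    if (length(toks) < 2L) {
      stop("PHYLIP parse error in ", path, ": line '", body[i],
           "' lacks a sequence after the name")
    }
    names[i] <- toks[1L]
    seqs[i] <- paste(toks[-1L], collapse = "")
  }
  # interleaved continuation blocks cycle through the taxa in order;
  # a leading repeated name is tolerated and dropped
  rest <- body[-seq_len(ntax)]
  slot <- 0L
  for (line in rest) {
    slot <- slot %% ntax + 1L
    toks <- strsplit(trimws(line), "\\s+")[[1L]]
    if (length(toks) > 1L && toks[1L] == names[slot]) toks <- toks[-1L]
    seqs[slot] <- paste0(seqs[slot], paste(toks, collapse = ""))
  }
  if (any(nchar(seqs) != nchar_expected)) {
    off <- names[nchar(seqs) != nchar_expected]
    stop("PHYLIP file ", path, ": sequence length disagrees with header (",
         nchar_expected, ") for: ", paste(off, collapse = ", "))
  }
  list(names = names, seqs = seqs)
}

#' Write an alignment or supermatrix in one or more formats
#'
#' Writes one file per requested format. FASTA wraps sequences at 60
#' columns; PHYLIP uses the relaxed sequential dialect; NEXUS emits a
#' `DATA` block with `MISSING=?` and `GAP=-`. For a supermatrix with
#' partitions of mixed type the NEXUS `DATATYPE` uses the MrBayes
#' `MIXED(...)` syntax. With `mrbayes_block = TRUE` and a partition map
#' present, a `mrbayes` block with one `charset` per partition and a
#' combined `partition` statement is appended to the NEXUS file.
#'
#' @param x an [alignment()] or a supermatrix from [concatenate()].
#' @param out_dir output directory (created if needed).
#' @param formats subset of `"fasta"`, `"phylip"`, `"nexus"`; FASTA is
#'   the default.
#' @param mrbayes_block embed a MrBayes charset/partition block in the
#'   NEXUS output.
#' @param base_name file stem for the outputs; defaults to the source
#'   stem, or `"supermatrix"` for a supermatrix.
#' @return character vector of written file paths.
#' @export
write_alignment <- function(x, out_dir, formats = "fasta",
                            mrbayes_block = FALSE, base_name = NULL) {
  partitions <- NULL
  if (inherits(x, "supermatrix")) {
    partitions <- x$partitions
    if (is.null(base_name)) base_name <- "supermatrix"
    x <- x$alignment
  }
  if (!inherits(x, "alignment")) stop("x must be an alignment or supermatrix")
  if (is.null(base_name)) base_name <- file_stem(x$source)
  formats <- match.arg(tolower(formats), OUTPUT_FORMATS, several.ok = TRUE)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory: ", out_dir)
  }
  paths <- character()
  for (fmt in unique(formats)) {
    path <- file.path(out_dir, paste0(base_name, format_extension[[fmt]]))
    txt <- switch(fmt,
      fasta  = format_fasta(x),
      phylip = format_phylip(x),
      nexus  = format_nexus(x, partitions, mrbayes_block)
    )
    writeLines(txt, path)
    paths <- c(paths, path)
  }
  paths
}

format_fasta <- function(x, width = 60L) {
  unlist(lapply(seq_along(x$names), function(i) {
    s <- x$seqs[i]
    n <- nchar(s)
    body <- if (n == 0L) character() else {
      starts <- seq(1L, n, by = width)
      substring(s, starts, pmin(starts + width - 1L, n))
    }
    c(paste0(">", x$names[i]), body)
  }))
}

format_phylip <- function(x) {
  pad <- max(nchar(x$names)) + 2L
  c(paste(" ", length(x$names), aln_length(x)),
    paste0(formatC(x$names, width = -pad), x$seqs))
}

format_clustal <- function(x) {
  pad <- max(nchar(x$names)) + 3L
  c("CLUSTAL W (phyloconcat)", "",
    paste0(formatC(x$names, width = -pad), x$seqs))
}

nexus_datatype <- function(x, partitions) {
  if (!is.null(partitions) &&
      length(unique(partitions$seqtype[partitions$seqtype != "structure"])) > 1L) {
    spans <- vapply(seq_len(nrow(partitions)), function(i) {
      dt <- switch(partitions$seqtype[i],
                   nucleotide = "DNA", amino_acid = "PROTEIN",
                   structure = "STANDARD")
      paste0(dt, ":", partitions$start[i], "-", partitions$end[i])
    }, character(1L))
    return(paste0("MIXED(", paste(spans, collapse = ","), ")"))
  }
  switch(x$seqtype,
    nucleotide = "DNA",
    amino_acid = "PROTEIN",
    structure  = "STANDARD",
    mixed      = "STANDARD"
  )
}

format_nexus <- function(x, partitions, mrbayes_block) {
  pad <- max(nchar(x$names)) + 2L
  out <- c(
    "#NEXUS",
    "BEGIN DATA;",
    paste0("  DIMENSIONS NTAX=", length(x$names),
           " NCHAR=", aln_length(x), ";"),
    paste0("  FORMAT DATATYPE=", nexus_datatype(x, partitions),
           " MISSING=? GAP=- INTERLEAVE=NO;"),
    "  MATRIX",
    paste0("    ", formatC(x$names, width = -pad), x$seqs),
    "  ;",
    "END;"
  )
  if (isTRUE(mrbayes_block) && !is.null(partitions) && nrow(partitions) > 0L) {
    charsets <- paste0("  charset ", partitions$gene, " = ",
                       partitions$start, "-", partitions$end, ";")
    out <- c(out,
      "BEGIN MRBAYES;",
      charsets,
      paste0("  partition combined = ", nrow(partitions), ": ",
             paste(partitions$gene, collapse = ", "), ";"),
      "  set partition = combined;",
      "END;"
    )
  }
  out
}

#' Write a RAxML-style partition file
#'
#' One line per partition, `"<MODEL>, <gene> = <start>-<end>"` with
#' 1-based inclusive coordinates. Nucleotide partitions are labelled
#' `DNA`; amino-acid partitions carry a placeholder substitution model
#' (default `WAG`) since model selection is delegated to external
#' tools. Structure partitions are skipped (no RAxML model exists for
#' them).
#'
#' @param partitions partition map data frame with columns `gene`,
#'   `start`, `end`, `seqtype` (as produced by [concatenate()]).
#' @param path output file path.
#' @param aa_model model label for amino-acid partitions.
#' @return `path`, invisibly.
#' @export
write_partitions_raxml <- function(partitions, path, aa_model = "WAG") {
  check_partition_map(partitions)
  keep <- partitions$seqtype != "structure"
  labels <- ifelse(partitions$seqtype[keep] == "nucleotide", "DNA", aa_model)
  writeLines(paste0(labels, ", ", partitions$gene[keep], " = ",
                    partitions$start[keep], "-", partitions$end[keep]),
             path)
  invisible(path)
}

check_partition_map <- function(partitions) {
  if (is.null(partitions) || nrow(partitions) == 0L) {
    stop("empty partition map")
  }
  if (partitions$start[1L] != 1L) {
    stop("partition map must start at column 1")
  }
  if (any(partitions$end < partitions$start)) {
    stop("partition with end < start: ",
         partitions$gene[which(partitions$end < partitions$start)[1L]])
  }
  if (nrow(partitions) > 1L) {
    gaps <- partitions$start[-1L] != partitions$end[-nrow(partitions)] + 1L
    if (any(gaps)) {
      stop("partitions not contiguous at gene ",
           partitions$gene[-1L][which(gaps)[1L]])
    }
  }
  invisible(TRUE)
}

# character composition of an alignment, over all residues
composition_counts <- function(x) {
  tab <- table(unlist(strsplit(x$seqs, "", fixed = TRUE)))
  tab[order(names(tab))]
}

# GC fraction over unambiguous bases only: (G+C) / (A+C+G+T+U)
gc_content <- function(x) {
  tab <- composition_counts(x)
  gc <- sum(tab[names(tab) %in% c("G", "C")])
  acgtu <- sum(tab[names(tab) %in% c("A", "C", "G", "T", "U")])
  if (acgtu == 0L) return(NA_real_)
  gc / acgtu
}

report_block <- function(x, heading) {
  lines <- c(
    heading,
    paste0("  taxa:          ", length(x$names)),
    paste0("  length:        ", aln_length(x)),
    paste0("  sequence type: ", x$seqtype)
  )
  tab <- composition_counts(x)
  lines <- c(lines, "  composition:",
             paste0("    ", names(tab), ": ", as.integer(tab)))
  if (x$seqtype == "nucleotide") {
    gc <- gc_content(x)
    lines <- c(lines, paste0("  GC content:    ",
                             ifelse(is.na(gc), "NA",
                                    sprintf("%.2f%%", 100 * gc))))
  }
  lines
}

#' Write the plain-text info report
#'
#' Summarises every input alignment (taxon count, length, sequence
#' type, character composition, GC content for nucleotide data) and,
#' when a supermatrix is given, its partition coordinates and the
#' replacement (padding) sequences inserted for taxa missing from
#' individual genes. `fast = TRUE` drops the per-fragment coordinate
#' and replacement listings, trading detail for speed on large runs.
#'
#' @param alignments list of [alignment()] objects.
#' @param supermatrix optional supermatrix from [concatenate()].
#' @param path output file path.
#' @param fast reduced report without per-fragment details.
#' @return `path`, invisibly.
#' @export
write_info_report <- function(alignments, supermatrix = NULL, path,
                              fast = FALSE) {
  if (!length(alignments)) stop("need at least one alignment")
  lines <- c("phyloconcat info report",
             paste0("inputs: ", length(alignments)), "")
  for (a in alignments) {
    lines <- c(lines, report_block(a, paste0("== infile: ", a$source)), "")
  }
  if (!is.null(supermatrix)) {
    lines <- c(lines,
               report_block(supermatrix$alignment, "== supermatrix"), "")
    if (!fast) {
      pm <- supermatrix$partitions
      lines <- c(lines, "  fragment positions:",
                 paste0("    ", pm$gene, ": ", pm$start, "-", pm$end,
                        " (", pm$seqtype, ")"))
      pad <- supermatrix$padded
      lines <- c(lines, "  inserted replacement strings:")
      if (nrow(pad) == 0L) {
        lines <- c(lines, "    (none)")
      } else {
        lines <- c(lines, paste0("    ", pad$taxon, " in ", pad$gene))
      }
      lines <- c(lines, "")
    }
  }
  writeLines(lines, path)
  invisible(path)
}
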