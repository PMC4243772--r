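# Synthetic alignment generator. Emulates the shape of multi-gene
# phylogenetic data sets: several gene alignments over a shared taxon
# set, some taxa missing from some genes, files rotating through the
# three accepted input formats, and optionally a planted
# parsimony-informative column per gene for classifier checks.

random_seq <- function(len, seqtype) {
  pool <- switch(seqtype,
    nucleotide = c("A", "C", "G", "T"),
    amino_acid = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  )
  paste(sample(pool, len, replace = TRUE), collapse = "")
}

#' Generate a synthetic multi-gene alignment fixture
#'
#' Writes `n_genes` alignment files in rotating formats (FASTA, PHYLIP,
#' CLUSTAL) over a common taxon set, deterministically for a given
#' seed. Each gene omits each taxon with probability
#' `missing_fraction`, subject to at least two taxa per gene and each
#' taxon appearing in at least one gene. With `plant_informative`,
#' column 1 of every gene is overwritten with an A/C (nucleotide) or
#' K/R (amino acid) half-and-half pattern, which is
#' parsimony-informative whenever at least four taxa are present.
#'
#' @param seed integer seed; equal seeds give byte-identical files.
#' @param dir output directory for the gene files.
#' @param n_taxa number of taxa in the shared set.
#' @param n_genes number of gene alignments.
#' @param lengths integer vector of gene lengths, recycled.
#' @param seqtypes per-gene types (`"nucleotide"`/`"amino_acid"`),
#'   recycled.
#' @param missing_fraction probability that a taxon is absent from a
#'   gene (0 <= f < 1).
#' @param plant_informative plant a known informative column per gene.
#' @return list with `paths` (ordered file paths) and `truth`: `taxa`,
#'   `present` (taxa x genes logical matrix), `genes`, `lengths`,
#'   `seqtypes`, `planted` (per-gene planted column states or `NULL`).
#' @export
generate_fixture <- function(seed, dir = tempfile("fixture"),
                             n_taxa = 6L, n_genes = 3L,
                             lengths = c(60L, 45L, 30L),
                             seqtypes = "nucleotide",
                             missing_fraction = 0.2,
                             plant_informative = FALSE) {
  stopifnot(n_taxa >= 2L, n_genes >= 1L,
            missing_fraction >= 0, missing_fraction < 1)
  set.seed(as.integer(seed))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  lengths <- rep_len(as.integer(lengths), n_genes)
  seqtypes <- rep_len(seqtypes, n_genes)
  taxa <- sprintf("taxon%02d", seq_len(n_taxa))
  formats <- rep_len(c("fasta", "phylip", "clustal"), n_genes)
  ext <- c(fasta = ".fas", phylip = ".phy", clustal = ".aln")

  present <- matrix(TRUE, n_taxa, n_genes,
                    dimnames = list(taxa, sprintf("gene%02d",
                                                  seq_len(n_genes))))
  if (missing_fraction > 0) {
    present[] <- stats::runif(n_taxa * n_genes) >= missing_fraction
    for (g in seq_len(n_genes)) {          # at least two taxa per gene
      if (sum(present[, g]) < 2L) {
        present[sample(n_taxa, 2L), g] <- TRUE
      }
    }
    for (t in seq_len(n_taxa)) {           # every taxon somewhere
      if (!any(present[t, ])) present[t, sample(n_genes, 1L)] <- TRUE
    }
  }

  paths <- character(n_genes)
  planted <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    keep <- taxa[present[, g]]
    seqs <- vapply(keep, function(t) random_seq(lengths[g], seqtypes[g]),
                   character(1L))
    if (plant_informative) {
      half <- rep(switch(seqtypes[g], nucleotide = c("A", "C"),
                         amino_acid = c("K", "R")),
                  length.out = length(keep))
      half <- sort(half)
      substr(seqs, 1L, 1L) <- half
      planted[[g]] <- half
    }
    a <- alignment(keep, unname(seqs), source = colnames(present)[g],
                   types = rep(seqtypes[g], length(keep)))
    path <- file.path(dir, paste0(colnames(present)[g],
                                  ext[[formats[g]]]))
    txt <- switch(formats[g],
      fasta   = format_fasta(a),
      phylip  = format_phylip(a),
      clustal = format_clustal(a)
    )
    writeLines(txt, path)
    paths[g] <- path
  }
  list(paths = paths,
       truth = list(taxa = taxa, present = present,
                    genes = colnames(present), lengths = lengths,
                    seqtypes = seqtypes,
                    planted = if (plant_informative) planted else NULL))
}
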