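Package: phyloconcat
Title: Multiple Sequence Alignment Processing and Supermatrix
    Concatenation for Phylogenetics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Prepares multiple sequence alignments for phylogenetic and
    population genetic analyses in a single composable run: reading of
    FASTA, CLUSTAL and PHYLIP alignments; writing of FASTA, PHYLIP and
    NEXUS (optionally with an embedded MrBayes block); sequence renaming
    from tab-delimited maps; ambiguity-aware translation between
    nucleotide and amino acid states with compressed IUPAC reverse
    translation; consensus sequences for defined sequence blocks (most
    frequent, majority rule, strict); RY recoding; third-codon-position
    exclusion; extraction of parsimony-informative sites; concatenation
    of gene alignments into a partitioned supermatrix with RAxML
    partition files; and plain-text reports of base composition, GC
    content and RNA secondary-structure stem/loop positions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    ape,
    seqinr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
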