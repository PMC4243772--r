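# phyloconcat

Phylogenetic and population genetic studies routinely juggle dozens to
thousands of per-gene multiple sequence alignments that need renaming,
format conversion, translation, consensus building, recoding and — above
all — concatenation into a single partitioned supermatrix before a tree
can be inferred. `phyloconcat` is an R package (plus a thin command-line
front end) that performs all of these preparation steps in one
composable run, for nucleotide, amino-acid and RNA secondary-structure
(dot-bracket) alignments in any mixture of FASTA, CLUSTAL and PHYLIP
input files.

Processing stages always execute in one fixed hierarchical order, so
that combinations stay well-defined:

1. sequence renaming (tab-delimited map)
2. translation (nucleotide → amino acid, or reverse translation to
   compressed IUPAC codons)
3. consensus of defined sequence blocks (most frequent / majority rule /
   strict)
4. RY coding (whole sequences or third codon positions)
5. exclusion of every third codon position
6. concatenation into a supermatrix, padding missing taxa with
   `N`/`X`/`.` and recording per-gene partitions
7. extraction of parsimony-informative sites
8. output: FASTA / PHYLIP / NEXUS (optionally with a MrBayes block),
   RAxML partition files, and plain-text info and stem/loop reports

Chains that contradict this flow (e.g. RY coding *before* translation)
are rejected at configuration time and require two runs.

## The rules at the core

* **Ambiguity-aware translation.** A codon containing IUPAC ambiguity
  codes is expanded into its Cartesian set of concrete codons; if every
  expansion encodes the same amino acid the codon is assignable
  (`YTR → L`, since TTA/TTG/CTA/CTG are all leucine), otherwise it
  translates to `?` (`RCT → ?`, since ACT is Thr but GCT is Ala).
  Incomplete triplets give `?`; `---` stays `-`. Reverse translation
  emits the position-wise IUPAC union of an amino acid's codons
  (`L → YTN`).
* **Consensus.** *Most frequent*: plurality state; ties among concrete
  bases compress to their IUPAC code, other ties give `?`. *Majority
  rule*: the state held by strictly more than 50 % of the block's
  sequences, else `?`. *Strict*: the IUPAC union of all bases at the
  site (`X` for amino acids with >1 state), ignoring `-`/`?` unless the
  column holds nothing else, in which case `?`.
* **Parsimony-informative site**: a column with at least two character
  states that each occur at least twice; gaps, `?` and ambiguity codes
  are not states.
* **RY coding**: purines (`A`,`G`,`R`) → `R`, pyrimidines
  (`C`,`T`,`U`,`Y`) → `Y`; gap/missing preserved; ambiguity codes
  spanning both classes → `?`.
* **Concatenation**: taxa are matched by exact name across genes; a
  taxon absent from a gene receives a replacement string (`N`×len,
  `X`×len or `.`×len by type), and every gene's 1-based inclusive
  coordinate range is recorded for RAxML/MrBayes partition output.

## Worked example

```r
library(phyloconcat)

cox1 <- alignment(c("Homo", "Pan"), c("ATGGCNTAY", "ATGGCCTAC"),
                  source = "cox1.fas", types = rep("nucleotide", 2))
rag1 <- alignment(c("Homo", "Gorilla"), c("MKW", "MKF"),
                  source = "rag1.fas", types = rep("amino_acid", 2))

tr <- translate_nt_to_aa(cox1)
tr$alignment$seqs
#> [1] "MAY" "MAY"

sm <- concatenate(list(tr$alignment, rag1))
sm
#> Supermatrix: 3 taxa x 6 columns, 2 partitions
#>   cox1: 1-3 (amino_acid)
#>   rag1: 4-6 (amino_acid)
#>   2 replacement strings inserted
sm$alignment$seqs
#> [1] "MAYMKW" "MAYXXX" "XXXMKF"
```

`GCN` translates cleanly to alanine (`MAY` in both taxa: `ATG`→M,
`GCN`/`GCC`→A, `TAY`/`TAC`→Y). After concatenation, Pan (absent from
rag1) and Gorilla (absent from cox1) carry `XXX` replacement strings,
and the partition table records where each gene sits — exactly what a
partitioned RAxML or MrBayes analysis consumes.

```r
extract_informative(alignment(paste0("t", 1:4),
                    c("AACC", "AACC", "GGCC", "GGTT"),
                    source = "demo"))$indices
#> [1] 1 2
```

Columns 1 and 2 each hold A,A,G,G — two states, both twice — so they
are parsimony-informative. Columns 3 and 4 hold C,C,C,T: the T is a
singleton, which no parsimony step can use, so they are excluded.

The same pipeline is available from a shell:

```sh
Rscript "$(Rscript -e 'cat(system.file("exec/phyloconcat", package="phyloconcat"))')" \
  -i genes/ --concat --partitions --out-format fasta,nexus --mrbayes-block --out-dir out/
```

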