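---
title: "Alignment processing and supermatrix construction with phyloconcat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment processing and supermatrix construction with phyloconcat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloconcat)
```

## The problem

Supermatrix phylogenetics concatenates many per-gene alignments —
often mixing ribosomal RNA with secondary-structure annotation,
protein-coding DNA and amino-acid data — into one matrix whose columns
are assigned per-gene substitution models. Getting from a directory of
heterogeneous gene files to that matrix involves a series of small,
error-prone manipulations: renaming taxa to a common vocabulary,
translating coding DNA, summarising populations into consensus rows,
recoding to reduce compositional bias, dropping saturated third codon
positions, padding taxa that were never sequenced for a gene, and
emitting the formats and partition files the inference programs expect.
`phyloconcat` implements each manipulation as an exported function and
composes them in one fixed order.

## The fixed process order

`run_pipeline()` always executes

renaming → translation → block consensus → RY coding → third-position
exclusion → concatenation → informative-site extraction → output,

with disabled stages acting as identities. The order is not arbitrary:
renaming must precede concatenation because taxa are matched by exact
name; translation must precede third-position handling because an
amino-acid matrix has no codon structure; and consensus rows must exist
before concatenation so they can be matched like any taxon. Requests
that would need a *later* stage to run first — RY coding or
third-position exclusion combined with nucleotide-to-amino-acid
translation, or third-position exclusion together with third-position
RY coding — are rejected by `run_config()` before any file is read;
such chains need two successive runs. The order genuinely matters:
strict consensus of an `{A, C}` column is `M`, which RY-codes to `?`,
while RY coding first would give `{R, Y}` and a strict consensus of
`N`. The pipeline produces the former, and a test asserts it.

## Sequence types and detection

Each record is classified as nucleotide, amino acid or dot-bracket
structure. Characters `-` and `?` are ignored; a string whose remaining
characters are all `(`, `)`, `.` is structure; otherwise the string is
nucleotide when at least **95 %** of its informative characters fall in
`A,C,G,T,U,N`, else amino acid. The threshold is a heuristic chosen to
tolerate occasional ambiguity codes in DNA without misreading proteins
(which typically contain far more than 5 % non-ACGTUN letters). It can
misfire on very short sequences — nine bases with one `Y` sit at 89 % —
so every constructor and reader accepts explicit per-record types, and
files mixing nucleotide with amino-acid records are rejected as
ambiguous rather than guessed at. Since any DNA string is also a legal
protein string character-wise, detection applies the
structure → nucleotide → amino-acid priority deterministically.

## Translation

Forward translation uses the standard genetic code (frame +1 only; the
reading frame is taken as given, never inferred) and resolves IUPAC
ambiguity codes by full expansion: a codon is translated iff every
concrete codon in its expansion encodes the same amino acid, e.g.
`YTR → L` but `RCT → ?`. `?` positions expand like `N`; a codon
containing `-` is unresolvable (`?`) unless it is entirely gaps, which
preserves the indel (`-`). Expansions mixing stop and sense give `?`;
pure stops give `*`. Alignment lengths not divisible by 3 trigger a
recorded warning and a trailing `?` column. Alignments that are not
suitable — amino-acid files, or nucleotide files carrying a structure
row (whose length could not shrink consistently) — pass through
untouched, which is what makes mixed input sets translatable in one
run.

Reverse translation emits *compressed IUPAC codons*: at each codon
position, the IUPAC code of the union of bases across the amino acid's
codons (`M → ATG`, `L → YTN`). The convention is position-wise and
therefore lossy — `YTN` also covers two phenylalanine codons — but it
is guaranteed (and property-tested) to be a superset of the true codon
set, never a subset. `B`, `Z`, `J` use the union of their member amino
acids' codons; `X`/`?` give `NNN`, `-` gives `---`.

## Consensus methods

Blocks of sequences (defined one per line as
`block_name : member1,member2,...`) are replaced by single consensus
rows. Per column:

* **most frequent** — plurality among informative states; ties of
  concrete bases compress to their IUPAC union, any tie involving
  ambiguity codes, and amino-acid ties, give `?`;
* **majority rule** — the state carried by strictly more than 50 % of
  the block's sequences; the denominator is the block size including
  gap-bearing rows, and exactly 50 % is not a majority;
* **strict** — nucleotide: IUPAC union of all bases present, expanding
  input ambiguity codes, ignoring `-`/`?` while any base exists;
  amino acid: `X` for more than one state.

A column consisting solely of `-` and `?` yields `?` under every
method; a consensus state is never a gap. In the frequency-based
methods, input ambiguity codes count as their own states — expanding
them would make "frequency" ill-defined. Consensus is computed per
input file, and block members missing from a file are an error rather
than silently skipped, so a typo in a block file cannot produce a
half-empty consensus.

## RY coding, third positions

`A,G,R → R` and `C,T,U,Y → Y`, either across the whole sequence or at
positions 3, 6, 9, … only. Gap and missing characters are preserved;
ambiguity codes spanning both classes (e.g. `W` = {A,T}) are recoded to
`?`, since a downstream two-state model cannot interpret them and no
unique assignment exists. Third-position exclusion removes columns
3, 6, 9, … from all rows (structure rows included, to keep lengths
equal — note this can unbalance a bracket string, one reason the two
third-position operations are nucleotide-alignment operations first).
Both interpret "third position" in frame +1 of each input alignment.

## Concatenation and padding

Taxa are matched by exact, case-sensitive name; the supermatrix taxon
set is the union over inputs, ordered by first appearance (a
deterministic choice; alphabetical ordering would work equally but
reorder user input). A taxon absent from a gene receives a replacement
string: `N`×len for nucleotide genes, `X`×len for amino-acid genes and
`.`×len for structure strings. Every insertion is recorded in the
`padded` table and listed in the info report. Partition coordinates are
1-based, inclusive, contiguous and checked as such before any partition
file is written. Gene names are input file stems; duplicate stems are
disambiguated with a numeric suffix. Slicing a partition's range and
dropping its padded rows reconstructs the original gene exactly — this
round-trip is the module's central invariant and is tested on 100
random fixtures.

## File formats

FASTA (wrapped at 60 columns), CLUSTAL and PHYLIP are read with
auto-detection from the first non-blank line; FASTA, PHYLIP and NEXUS
are written. PHYLIP follows the relaxed dialect — names of any length
up to whitespace — because strict 10-character names truncate modern
taxon identifiers. The reader accepts single-line sequential and
classic interleaved layouts; multi-line sequential *without* repeated
names is indistinguishable from interleaved and is not supported (the
writer only emits single-line sequential, so package round-trips are
exact). NEXUS output is a `DATA` block with `MISSING=?` and `GAP=-`;
mixed-type supermatrices use the MrBayes `MIXED(DNA:…,PROTEIN:…)`
datatype, and `mrbayes_block = TRUE` appends a minimal block of one
`charset` per partition plus a combined `partition`/`set` statement —
deliberately no model (`lset`/`prset`) commands, which belong to the
analyst. RAxML partition files label nucleotide partitions `DNA` and
amino-acid partitions with a placeholder model (default `WAG`), since
best-fit protein model selection is delegated to external tools;
structure partitions are skipped, as no RAxML model exists for them.

Composition reporting counts all characters; GC content is
(G+C)/(A+C+G+T+U), ignoring ambiguity codes, gaps and `?` — an
unambiguous, reproducible denominator.

## Informative sites and structure report

A column is parsimony-informative when at least two character states
each occur at least twice; gaps, `?` and ambiguity codes are not
counted as states, matching common practice (an indel "state" cannot
support a parsimony step under the substitution-only models these
matrices feed). `U` is counted as `T`. Extraction preserves column
order and may legitimately return zero columns.

Dot-bracket strings are parsed by stack matching — each `)` pairs with
the most recent unmatched `(` — with `-`/`?` as ignored positions and
pseudoknot alphabets rejected. The parse asserts proper nesting.
Supermatrix stem/loop coordinates are obtained by parsing the
concatenated structure row, which equals the per-gene pairing tables
shifted by each partition's offset; `.`-padding inserted for taxa
missing a structure gene consequently shows up as loop positions of the
pad, which the report documents rather than hides.

## The synthetic-data generator

`generate_fixture()` emulates the shape of a multi-gene data set: a
shared taxon set, several genes of differing length and type, files
rotating through FASTA/PHYLIP/CLUSTAL, each taxon missing from each
gene with probability `missing_fraction` (default 0.2, a typical
missing-data level in supermatrix studies), subject to ≥ 2 taxa per
gene and every taxon present somewhere. Optionally it plants a known
parsimony-informative column. It is seed-deterministic and returns its
ground truth (presence matrix, planted states) for tests. What it does
*not* emulate: phylogenetic signal (sites are i.i.d. uniform),
alignment error, indel structure beyond uniform gap sprinkling, or
compositional bias. Passing tests therefore demonstrate the
*bookkeeping* correctness of the pipeline — coordinates, padding,
round-trips, rule boundaries — not inference quality on real data,
which is the appropriate claim for an alignment editor.

Test and acceptance problem sizes (100 fixtures for round-trips, 1000
random columns/strings for property suites, all 4096 ambiguity
triplets) were chosen so the full suite completes in about a minute on
one core while still exercising every rule boundary.

## Known limitations

* One genetic code (the standard one); no mitochondrial or plastid
  variants, no ORF search, no frame correction.
* NEXUS is write-only; interleaved NEXUS and Stockholm are out of
  scope.
* Consensus blocks apply per file and must be fully present in every
  file processed.
* The 95 % type-detection threshold is heuristic on short sequences;
  pass explicit types where files are tiny.
* No ortholog selection, chimera construction or missing-data gene
  filtering — this package prepares matrices, it does not choose their
  contents.
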