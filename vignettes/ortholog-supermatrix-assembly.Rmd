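---
title: "Assembling BUSCO ortholog supermatrices: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembling BUSCO ortholog supermatrices: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthomatrix)
```

## The problem

Public transcriptome assemblies (NCBI nucleotide and TSA records) are a
cheap, rapidly growing source of phylogenetic markers, but they arrive as
per-species bags of transcripts with no ortholog labels. BUSCO annotates
each transcriptome against a lineage-specific OrthoDB catalogue of
near-universal single-copy orthologs, reporting every candidate locus as
Complete, Duplicated, Fragmented or Missing together with the matching
transcript, a bit score and a match length. orthomatrix turns a directory
of such per-species BUSCO results plus the underlying
`genus_species.fasta` transcriptomes into the inputs a partitioned
maximum-likelihood analysis needs: per-locus alignments in relaxed phylip,
a concatenated supermatrix, and a nexus `sets` block of charset
coordinates that IQ-TREE reads directly. Around that core it quantifies
missing-data structure (which, for transcriptomes, reflects tissue- and
lineage-specific expression as much as sequencing depth) and lets the user
rebuild the matrix under explicit occupancy thresholds.

## The selection model

For one species, the full table is reduced to at most one transcript per
BUSCO locus:

1. `Missing` rows contribute nothing.
2. `Fragmented` rows are retained by default, reflecting the view that a
   partial transcript is still usable phylogenetic signal; a minimum match
   length (`min_fragment_length`, in the units of the table's Length
   column) may be required. The threshold is *inclusive* (`length >=
   threshold`), the least surprising reading of a minimum. The filter runs
   *before* duplicate resolution, so a long low-scoring fragment can never
   be displaced by a fragment that the filter already removed; whether the
   original tooling orders these two steps the same way is not documented,
   so we state our order rather than claim it.
3. Among the surviving rows of a locus (typically a `Duplicated` group,
   but also the malformed case of mixed Complete/Duplicated rows, which we
   resolve by the same rule rather than reject), the highest bit score
   wins; equal scores fall back to the earliest row in the table. This
   makes selection a pure function of the file content — no hash-order or
   locale dependence — which the test suite checks against an independent
   brute-force oracle on randomized tables.

## Alignment and orientation

Assembled transcripts land on either strand, so homologous sequences may
arrive reverse-complemented. The alignment step is deliberately
*delegated*: the package owns a backend contract, not an MSA algorithm.
The default backend shells out to `mafft --adjustdirection --quiet`, which
both aligns and flips opposite-strand rows, marking flipped records with a
leading `_R_` on the name; `align_locus()` strips exactly one such marker
(a genuine taxon label may not begin with `_R_`, and a post-strip
collision is an error) and verifies that the output rows are exactly the
input species at equal length. No further MAFFT strategy flags are set;
defaults are used and recorded in the manifest log. A deterministic
`pad_aligner()` — right-pad every sequence with gaps to the longest record
— stands in for MAFFT in tests and anywhere reproducible bytes matter
more than alignment quality. Single-sequence bins bypass the backend
entirely.

## Supermatrix conventions

`concatenate()` takes the union of taxa (sorted, unless an explicit order
is supplied) and fills each absent (taxon, locus) cell with `?` to the
locus length. `?` rather than `-` keeps occupancy-driven absence
distinguishable from within-alignment gaps; IQ-TREE treats both as
missing data. Loci are ordered lexicographically by BUSCO id by default
for determinism. Partition coordinates are 1-based inclusive (the nexus
convention), always contiguous, non-overlapping and covering — invariants
re-validated on every construction and on every `partitions.nex` read and
write. Charset names are sanitized to `[A-Za-z0-9_]` for nexus token
safety. `split_supermatrix()` is the exact inverse of `concatenate()`,
which gives the test suite a round-trip identity to hold on random input.

The relaxed phylip dialect written is sequential, unwrapped, one
`name<space>sequence` row per taxon with a `<ntaxa> <ncolumns>` header;
names are length-unrestricted but whitespace-free. This is the most
permissive dialect IQ-TREE's reader accepts, and round-trips exactly.

## Occupancy, thresholds, reassembly

The occupancy matrix holds one of `complete`, `fragmented`, `missing` per
taxon x locus; `Duplicated` winners count as complete (a resolved
duplicate is a usable full-length sequence), and a fragment removed by the
length filter becomes missing — once filtered it contributes no data, so
counting it as fragmented would overstate occupancy. Filtering order is
taxa first (`min_loci_per_taxon` present loci, where fragmented cells
count as present by default, toggleable), then loci on the reduced matrix
(`min_taxa_per_locus`). The taxon rule mirrors common practice of, e.g.,
keeping only taxa with at least 1000 of several thousand candidate
orthologs. Both rules are monotone in their thresholds, a property the
tests assert alongside a brute-force counting oracle.

Reassembly after filtering *re-aligns* each kept locus from its surviving
raw sequences rather than slicing columns out of the old alignment:
dropping a taxon can change the optimal alignment of those that remain. A
kept locus with no surviving taxa is dropped with a warning; a locus down
to one taxon is retained as a singleton row.

Occupancy can also be built without BUSCO at all: from any directory of
per-locus FASTA files (anchored hybrid enrichment, ultraconserved
elements, ...), where presence means at least one non-gap character, or
from any delimited presence/absence table (behavioural, phenotypic,
expression data) with configurable present/absent tokens — both two-state
modes that never assign `fragmented`.

## GO categories

Orthologs map to Gene Ontology categories through a user-supplied
two-column table rather than a live OrthoDB/GO pipeline, keeping the test
suite offline; the category vocabulary is free (slim labels or GO ids). A
tiny synthetic example ships in `inst/extdata/synthetic_go_mapping.tsv`.
`intersection_counts()` reports the upset-plot decomposition: each
annotated locus contributes to exactly one exclusive combination (its full
category set), so the combination counts partition the annotated loci;
non-exclusive per-category set sizes and the unannotated count are
reported alongside. `relative_percent_sampled()` gives, per taxon and
category, 100 x (present member loci) / (member loci in the matrix);
categories with no member loci in the matrix are excluded with a warning
rather than reported as 0/0. Rendering (upset, circle-pack, barplots) is
left to plotting front ends; the package guarantees the tidy tables.

## The synthetic fixture: what it emulates, what it does not

`generate_fixture()` plants a fully known world: per locus a random master
sequence (default 300-900 nt, the span of typical BUSCO transcript
matches), per species a 2%-substituted copy — enough divergence that a
real aligner does nontrivial work, close enough that homology is
unambiguous — with independent Bernoulli draws for missingness,
fragmentation (a random subsequence of 30-80% of full length),
duplication (a second variant transcript whose score either trails the
winner or ties it exactly, the tie winner being the first-listed row), and
reverse complementation; plus a few decoy transcripts per species.
Default rates in the pipeline tests (30% missing, 15-20% fragmented, 20%
duplicated, 20% reverse-complemented) are deliberately harsher than the
mostly >70%-representation datasets the method targets, to exercise every
code path. Everything derives from one seed and regenerates byte for
byte.

What a green fixture test establishes: the plumbing — parsing, selection,
harvest, binning, alignment contract, concatenation, occupancy — is
exact. What it does not establish: anything about real BUSCO search
behaviour (HMMER/BLAST sensitivity, true score distributions), real
evolutionary divergence (no substitution model, no tree), chimeric or
mis-assembled transcripts, or isoform structure. The emulated full tables
are format-faithful to BUSCO v3's five-column transcriptome layout only.

## Numerical and degenerate-input choices

* Score comparison is exact floating-point; the tie-break rule makes
  equality well-defined behaviour rather than a hazard.
* Sorting uses radix order throughout, so output order is
  locale-independent.
* Empty selections, all-missing species, empty bins after filtering and
  one-taxon loci all have defined non-fatal behaviour (empty mapping,
  all-missing occupancy row, warned drop, singleton pass-through); an
  empty alignment list is the one hard error in concatenation, since a
  supermatrix of zero loci is meaningless.
* A transcript id missing from its FASTA is a warning, not an error: one
  corrupt species should not abort a 50-species harvest.

## Known limitations

BUSCO v4/v5 table dialects are rejected, not guessed. No codon-aware
alignment, trimming or masking. No within-locus codon partitioning and no
model selection — the output is the *input* to IQ-TREE, which owns those.
The live NCBI transport groups one query into one label and is unsuitable
for multi-species queries; query per species, or supply a custom
transport. Matrix decisiveness and phylogenetic information content
metrics are out of scope.
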