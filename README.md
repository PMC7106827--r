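# orthomatrix

Assembly of BUSCO single-copy-ortholog supermatrices from transcriptomes,
for phylogeneticists who want to turn per-species transcriptome FASTA
files plus BUSCO v3 results into partitioned, IQ-TREE-ready alignments —
and to see, quantify and filter the missing-data structure of the result
before inferring anything from it.

## What it does

Given per-species transcriptomes (`genus_species.fasta`) annotated with
BUSCO v3 against an OrthoDB lineage set (e.g. `laurasiatheria_odb9`),
each species' full table reports every candidate locus as Complete,
Duplicated, Fragmented or Missing with a matching transcript, bit score
and match length. orthomatrix:

1. **Selects** one transcript per locus per species: Missing rows yield
   nothing; Fragmented hits are kept (optionally above an inclusive
   length threshold ℓ ≥ ℓ_min); Duplicated groups resolve to
   argmax score, equal scores to the first row encountered.
2. **Harvests and bins** the winning sequences into per-locus FASTA
   files keyed by BUSCO id.
3. **Aligns** each locus through a pluggable backend — by default
   `mafft --adjustdirection`, which also reverse-complements
   opposite-strand transcripts (the `_R_` marker MAFFT adds is stripped
   from taxon names) — and writes relaxed phylip.
4. **Concatenates** the loci over the union of taxa into a supermatrix
   `M` (absent cells filled with `?`), with charsets
   `charset locus_i = start_i-end_i;` (1-based, inclusive, contiguous,
   covering) in a nexus `sets` block IQ-TREE reads directly.
5. **Quantifies occupancy**: the taxon × locus state matrix over
   {complete, fragmented, missing}, long-format summaries at any
   hierarchical grouping, and threshold filtering (keep taxa with at
   least *m* present loci; then loci with at least *t* present taxa)
   followed by reassembly that *re-aligns* every kept locus from its
   surviving raw sequences.
6. **Maps loci to GO categories** from a two-column table, reporting
   upset-style exclusive intersection counts (which partition the
   annotated loci) and the relative percent of each category sampled per
   taxon.

Occupancy tools also work without BUSCO: on any directory of per-locus
FASTA files (AHE, UCE, ...) or any delimited presence/absence table. A
synthetic-fixture generator plants known ortholog structure (controlled
missingness, fragmentation, duplication, reverse complementation, score
ties) with emulated BUSCO tables, so the whole pipeline is testable
offline; `planted_truth_check()` diffs pipeline output against the
planted truth.

## Worked example

```r
library(orthomatrix)

dir <- tempfile("demo_")
fx <- generate_fixture(fixture_spec(n_species = 4, n_loci = 10,
  p_missing = 0.25, p_fragment = 0.15, p_duplicate = 0.2,
  p_reverse_complement = 0.2, seed = 42), dir)

pipe <- run_fixture_pipeline(dir)   # parse -> select -> harvest -> align -> concat
pipe$supermatrix
#> Supermatrix: 4 taxa x 4977 columns, 10 loci
pipe$occupancy
#> Occupancy: 4 taxa x 10 loci ( 67.5% complete, 15.0% fragmented, 17.5% missing )
head(pipe$supermatrix$partitions, 3)
#>         locus start  end
#> 1 EOG09F00001     1  860
#> 2 EOG09F00002   861 1480
#> 3 EOG09F00003  1481 1932

planted_truth_check(pipe, fx$truth)$ok   # selections, occupancy, membership
#> [1] TRUE

# keep taxa with >= 7 of the 10 loci present, rebuild the matrix
kept <- apply_thresholds(pipe$occupancy, threshold_spec(min_loci_per_taxon = 7))
kept$kept_taxa
#> [1] "Genus01_species01" "Genus03_species03" "Genus04_species04"
reassemble(kept$kept_taxa, kept$kept_loci, pipe$bins)
#> Supermatrix: 3 taxa x 4977 columns, 10 loci

# GO category intersections (upset decomposition)
m <- load_go_mapping(system.file("extdata", "synthetic_go_mapping.tsv",
                                 package = "orthomatrix"))
intersection_counts(m)$intersections
#>                    combination count
#> 1                  Development     2
#> 2 Development+Immune+Signaling     1
#> 3       Development+Metabolism     1
#> ...
```

The 4977-column supermatrix is the sum of the ten per-locus alignment
lengths; the partition table gives each locus's 1-based column range.
`TRUE` from `planted_truth_check()` means every selection, harvested
sequence, occupancy state and supermatrix cell matched the planted
ground truth. After thresholding, `Genus02_species02` (fewer than 7
present loci) is dropped and the matrix is rebuilt by realignment over
the 3 survivors. Each GO intersection count is the number of loci whose
*exact* category set is that combination, so the counts sum to the
number of annotated loci.

Real data follows the same calls with your own directories:
`read_busco_results_dir()` + `select_best_hits()` +
`extract_sequences()` / `bin_by_locus()` + `align_locus(...,
mafft_aligner())` + `concatenate()` + `write_partition_nexus()`. A
stage-wise command-line front end is installed at
`system.file("cli", "orthomatrix", package = "orthomatrix")`:

```sh
Rscript inst/cli/orthomatrix parse   --output-dir out --busco-results-dir busco
Rscript inst/cli/orthomatrix harvest --output-dir out --fasta-dir fastas
Rscript inst/cli/orthomatrix align   --output-dir out --aligner mafft
Rscript inst/cli/orthomatrix concat  --output-dir out
```

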