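Package: orthomatrix
Title: Assembly of BUSCO Ortholog Supermatrices from Transcriptomes
Version: 1.0.0
Authors@R: person("Dana", "Willoughby", email = "dwilloughby@example.org",
    role = c("aut", "cre"))
Description: Assembles phylogenomics-ready multiple sequence alignments of
    BUSCO single-copy orthologs from per-species transcriptome FASTA files.
    Parses BUSCO v3 full-table results, resolves duplicated hits by bit
    score, harvests the winning transcript per locus per species, bins
    sequences into per-locus FASTA files, aligns each locus through a
    pluggable aligner backend (MAFFT with direction adjustment by default),
    and concatenates loci into a supermatrix with a nexus charset partition
    block readable by IQ-TREE. Occupancy tools quantify complete, fragmented
    and missing states per taxon and locus, summarize them at user-defined
    hierarchical levels, and drive threshold-based filtering with full
    realignment on reassembly. Orthologs can be mapped to Gene Ontology
    categories to compute upset-style intersection counts and relative
    percent sampled per taxon. A synthetic-fixture generator plants ortholog
    structure with controlled missingness, fragmentation, duplication and
    reverse complementation, with emulated BUSCO full tables, for fully
    offline end-to-end testing.
License: GPL-3
Encoding: UTF-8
Imports:
    Biostrings,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
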