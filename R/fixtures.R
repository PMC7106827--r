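# Synthetic fixture generator: multi-species transcriptomes with planted
# ortholog structure plus emulated BUSCO v3 full tables, giving the whole
# pipeline a known ground truth without BUSCO, MAFFT or network access.
# Ortholog copies of a locus are mutated variants of a shared master
# sequence, so real aligners also produce sensible alignments; decoy
# transcripts are independent random sequences.

#' Specification for a synthetic transcriptome fixture
#'
#' All randomness derives from `seed`, making generated files reproducible
#' byte for byte.
#'
#' @param n_species,n_loci Positive counts.
#' @param locus_length_range Min/max master-sequence length (nucleotides).
#' @param p_missing Probability a (species, locus) cell is missing.
#' @param p_fragment Probability a non-missing cell is a fragment.
#' @param fragment_length_fraction_range Fraction of the full length a
#'   fragment retains, drawn uniformly in this subrange of (0, 1].
#' @param p_duplicate Probability a complete cell carries a duplicated
#'   second transcript.
#' @param p_reverse_complement Probability a written transcript is
#'   reverse-complemented (opposite strand).
#' @param n_decoy_transcripts Non-ortholog transcripts per species.
#' @param substitution_rate Per-site substitution probability applied to
#'   each species' copy of the master sequence.
#' @param seed Integer random seed.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_species, n_loci,
                         locus_length_range = c(300L, 900L),
                         p_missing = 0, p_fragment = 0,
                         fragment_length_fraction_range = c(0.3, 0.8),
                         p_duplicate = 0, p_reverse_complement = 0,
                         n_decoy_transcripts = 3L,
                         substitution_rate = 0.02,
                         seed = 1L) {
  probs <- c(p_missing = p_missing, p_fragment = p_fragment,
             p_duplicate = p_duplicate,
             p_reverse_complement = p_reverse_complement)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  stopifnot(n_species >= 1L, n_loci >= 1L,
            length(locus_length_range) == 2L,
            locus_length_range[1] >= 1,
            locus_length_range[1] <= locus_length_range[2],
            length(fragment_length_fraction_range) == 2L,
            fragment_length_fraction_range[1] > 0,
            fragment_length_fraction_range[1] <=
              fragment_length_fraction_range[2],
            fragment_length_fraction_range[2] <= 1,
            n_decoy_transcripts >= 0L,
            substitution_rate >= 0, substitution_rate <= 1)
  structure(list(n_species = as.integer(n_species),
                 n_loci = as.integer(n_loci),
                 locus_length_range = as.integer(locus_length_range),
                 p_missing = p_missing, p_fragment = p_fragment,
                 fragment_length_fraction_range =
                   as.numeric(fragment_length_fraction_range),
                 p_duplicate = p_duplicate,
                 p_reverse_complement = p_reverse_complement,
                 n_decoy_transcripts = as.integer(n_decoy_transcripts),
                 substitution_rate = substitution_rate,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

.random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

.mutate_dna <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic fixture with planted ground truth
#'
#' Writes one `genus_species.fasta` per species (ortholog transcripts plus
#' decoys, in shuffled order, some reverse-complemented), an emulated
#' BUSCO v3 full table per species under
#' `<busco_dir>/run_<species>/full_table_<species>.tsv` (scores arranged
#' so the planted winner is the maximum, with controlled equal-score
#' ties), and a ground-truth TSV recording the expected winning transcript
#' and state per (species, locus).
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory for the FASTA files and the truth table.
#' @param busco_dir Directory for the emulated BUSCO results (default
#'   `<dir>/busco_results`).
#' @return Invisibly, a list with `spec`, `dir`, `busco_dir`, `species`,
#'   `loci`, `fasta_paths`, `truth` (data frame: `species`, `busco_id`,
#'   `state`, `sequence_id`, `orientation`, `sequence`) and `truth_path`.
#' @export
generate_fixture <- function(spec, dir,
                             busco_dir = file.path(dir, "busco_results")) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)

  species <- sprintf("Genus%02d_species%02d", seq_len(spec$n_species),
                     seq_len(spec$n_species))
  loci <- sprintf("EOG09F%05d", seq_len(spec$n_loci))
  master_len <- sample(seq(spec$locus_length_range[1],
                           spec$locus_length_range[2]),
                       spec$n_loci, replace = TRUE)
  master <- vapply(master_len, .random_dna, character(1))
  names(master) <- loci

  truth <- list()
  fasta_paths <- character(0)

  for (sp in species) {
    run_dir <- file.path(busco_dir, paste0("run_", sp))
    dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
    transcripts <- character(0)   # id -> written sequence
    rows <- character(0)          # full-table data rows
    k <- 0L
    new_id <- function() {
      k <<- k + 1L
      sprintf("tr%04d", k)
    }
    orient <- function(seq) {
      if (stats::runif(1) < spec$p_reverse_complement) {
        list(seq = .revcomp(seq), strand = "-")
      } else {
        list(seq = seq, strand = "+")
      }
    }
    for (locus in loci) {
      if (stats::runif(1) < spec$p_missing) {
        rows <- c(rows, paste(locus, "Missing", sep = "\t"))
        truth[[length(truth) + 1L]] <- data.frame(
          species = sp, busco_id = locus, state = "missing",
          sequence_id = NA_character_, orientation = NA_character_,
          sequence = NA_character_, stringsAsFactors = FALSE)
        next
      }
      full <- .mutate_dna(master[[locus]], spec$substitution_rate)
      fragmented <- stats::runif(1) < spec$p_fragment
      if (fragmented) {
        frac <- stats::runif(1, spec$fragment_length_fraction_range[1],
                             spec$fragment_length_fraction_range[2])
        flen <- max(1L, as.integer(round(frac * nchar(full))))
        start <- sample(nchar(full) - flen + 1L, 1L)
        full <- substr(full, start, start + flen - 1L)
      }
      o <- orient(full)
      id <- new_id()
      transcripts[[id]] <- o$seq
      score <- round(stats::runif(1, 400, 950), 1)
      status <- if (fragmented) "Fragmented" else "Complete"
      duplicated_cell <- !fragmented && stats::runif(1) < spec$p_duplicate
      if (duplicated_cell) {
        dup_seq <- .mutate_dna(master[[locus]], spec$substitution_rate)
        o2 <- orient(dup_seq)
        id2 <- new_id()
        transcripts[[id2]] <- o2$seq
        tie <- stats::runif(1) < 0.5
        if (tie) {
          # equal scores, distinct transcripts: winner is the first row
          rows <- c(rows,
                    sprintf("%s\tDuplicated\t%s\t%.1f\t%d", locus, id,
                            score, nchar(o$seq)),
                    sprintf("%s\tDuplicated\t%s\t%.1f\t%d", locus, id2,
                            score, nchar(o2$seq)))
        } else {
          loser_score <- max(0, score - round(stats::runif(1, 10, 100), 1))
          # losing row listed first so argmax (not order) decides
          rows <- c(rows,
                    sprintf("%s\tDuplicated\t%s\t%.1f\t%d", locus, id2,
                            loser_score, nchar(o2$seq)),
                    sprintf("%s\tDuplicated\t%s\t%.1f\t%d", locus, id,
                            score, nchar(o$seq)))
        }
        truth[[length(truth) + 1L]] <- data.frame(
          species = sp, busco_id = locus, state = "complete",
          sequence_id = id, orientation = o$strand, sequence = o$seq,
          stringsAsFactors = FALSE)
      } else {
        rows <- c(rows, sprintf("%s\t%s\t%s\t%.1f\t%d", locus, status, id,
                                score, nchar(o$seq)))
        truth[[length(truth) + 1L]] <- data.frame(
          species = sp, busco_id = locus,
          state = if (fragmented) "fragmented" else "complete",
          sequence_id = id, orientation = o$strand, sequence = o$seq,
          stringsAsFactors = FALSE)
      }
    }
    for (j in seq_len(spec$n_decoy_transcripts)) {
      dlen <- sample(seq(spec$locus_length_range[1],
                         spec$locus_length_range[2]), 1L)
      transcripts[[sprintf("decoy%03d", j)]] <- .random_dna(dlen)
    }
    tbl <- c("# BUSCO version is: 3.0.2",
             "# The lineage dataset is: synthetic_odb9",
             "# Busco id\tStatus\tSequence\tScore\tLength",
             rows)
    writeLines(tbl, file.path(run_dir, paste0("full_table_", sp, ".tsv")))
    fasta_path <- file.path(dir, paste0(sp, ".fasta"))
    if (length(transcripts) > 0L) {
      transcripts <- transcripts[sample(length(transcripts))]
      write_fasta(transcripts, fasta_path)
    } else {
      writeLines(character(0), fasta_path)
    }
    fasta_paths <- c(fasta_paths, fasta_path)
  }

  truth <- do.call(rbind, truth)
  truth_path <- file.path(dir, "truth.tsv")
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(list(spec = spec, dir = dir, busco_dir = busco_dir,
                 species = species, loci = loci,
                 fasta_paths = fasta_paths, truth = truth,
                 truth_path = truth_path))
}

#' Run the harvest-to-supermatrix pipeline over a fixture
#'
#' Convenience driver (also used by the command-line stages): parses the
#' BUSCO results, selects best hits, harvests and bins sequences, aligns
#' each bin and concatenates, and builds the occupancy matrix over the
#' full locus universe found in the tables.
#'
#' @param dir Directory of per-species FASTA files.
#' @param busco_dir Directory of BUSCO run results (default
#'   `<dir>/busco_results`).
#' @param aligner Aligner backend (default the deterministic
#'   [pad_aligner()]).
#' @param policy A [selection_policy()].
#' @return List with `selections`, `bins`, `alignments`, `supermatrix`
#'   (`NULL` when no locus has any sequence) and `occupancy`.
#' @export
run_fixture_pipeline <- function(dir,
                                 busco_dir = file.path(dir, "busco_results"),
                                 aligner = pad_aligner(),
                                 policy = selection_policy()) {
  results <- read_busco_results_dir(busco_dir)
  selections <- lapply(results, select_best_hits, policy = policy)
  per_species <- lapply(names(results), function(sp) {
    fasta <- file.path(dir, paste0(sp, ".fasta"))
    extract_sequences(fasta, selections[[sp]], species = sp)
  })
  names(per_species) <- names(results)
  bins <- bin_by_locus(per_species)
  alignments <- lapply(bins, align_locus, aligner = aligner)
  sm <- if (length(alignments) > 0L) concatenate(unname(alignments))
        else NULL
  universe <- unique(unlist(lapply(results, function(r) r$hits$busco_id),
                            use.names = FALSE))
  occ <- build_occupancy(selections, universe)
  list(selections = selections, bins = bins, alignments = alignments,
       supermatrix = sm, occupancy = occ)
}

.truth_diff <- function(species, locus, field, expected, observed) {
  data.frame(species = species, locus = locus, field = field,
             expected = as.character(expected),
             observed = as.character(observed), stringsAsFactors = FALSE)
}

#' Check pipeline output against a fixture's planted ground truth
#'
#' Verifies selections (winning transcript id and status class), harvested
#' bin sequences (exactly the planted as-written sequences), occupancy
#' states, and supermatrix membership (a (taxon, locus) slice holds data
#' characters iff the planted state is non-missing). Every mismatch is
#' named by (species, locus).
#'
#' @param pipeline Output of [run_fixture_pipeline()].
#' @param truth Ground-truth data frame from [generate_fixture()] (or read
#'   from its `truth.tsv`).
#' @return List with `ok` (logical) and `diff` (data frame `species`,
#'   `locus`, `field`, `expected`, `observed`; zero rows when `ok`).
#' @export
planted_truth_check <- function(pipeline, truth) {
  stopifnot(is.data.frame(truth))
  diffs <- list()
  note <- function(d) diffs[[length(diffs) + 1L]] <<- d
  occ <- pipeline$occupancy
  sm <- pipeline$supermatrix

  for (i in seq_len(nrow(truth))) {
    sp <- truth$species[i]
    locus <- truth$busco_id[i]
    state <- truth$state[i]
    sel <- pipeline$selections[[sp]]
    row <- if (!is.null(sel)) sel[sel$busco_id == locus, , drop = FALSE]
           else sel
    if (state == "missing") {
      if (!is.null(row) && nrow(row) > 0L) {
        note(.truth_diff(sp, locus, "selection", "<absent>",
                         row$sequence_id[1]))
      }
    } else {
      if (is.null(row) || nrow(row) == 0L) {
        note(.truth_diff(sp, locus, "selection", truth$sequence_id[i],
                         "<absent>"))
      } else {
        if (row$sequence_id[1] != truth$sequence_id[i]) {
          note(.truth_diff(sp, locus, "selection", truth$sequence_id[i],
                           row$sequence_id[1]))
        }
        ok_status <- switch(state,
          complete = row$status[1] %in% c("Complete", "Duplicated"),
          fragmented = row$status[1] == "Fragmented",
          FALSE)
        if (!ok_status) {
          note(.truth_diff(sp, locus, "status", state, row$status[1]))
        }
        rec <- pipeline$bins[[locus]]$records
        got <- if (!is.null(rec) && sp %in% names(rec)) rec[[sp]]
               else "<absent>"
        if (!identical(got, toupper(truth$sequence[i]))) {
          note(.truth_diff(sp, locus, "sequence", truth$sequence[i], got))
        }
      }
    }
    # occupancy state
    if (!is.null(occ) && sp %in% occ$taxa && locus %in% occ$loci) {
      got <- occ$state[sp, locus]
      if (got != state) note(.truth_diff(sp, locus, "occupancy", state, got))
    } else {
      note(.truth_diff(sp, locus, "occupancy", state, "<absent>"))
    }
    # supermatrix membership
    if (!is.null(sm) && locus %in% sm$partitions$locus) {
      p <- sm$partitions[sm$partitions$locus == locus, ]
      if (sp %in% sm$taxa) {
        slice <- substr(sm$matrix[[sp]], p$start, p$end)
        has_data <- grepl("[^-?]", slice)
        if (has_data != (state != "missing")) {
          note(.truth_diff(sp, locus, "supermatrix",
                           if (state != "missing") "data" else "filler",
                           if (has_data) "data" else "filler"))
        }
      } else if (state != "missing") {
        note(.truth_diff(sp, locus, "supermatrix", "data", "<taxon absent>"))
      }
    } else if (state != "missing") {
      note(.truth_diff(sp, locus, "supermatrix", "data", "<locus absent>"))
    }
  }
  diff <- if (length(diffs) > 0L) do.call(rbind, diffs)
          else .truth_diff(character(0), character(0), character(0),
                           character(0), character(0))
  list(ok = nrow(diff) == 0L, diff = diff)
}
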