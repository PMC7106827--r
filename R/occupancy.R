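# Occupancy: complete / fragmented / missing states per taxon x locus,
# hierarchical summaries, threshold filtering, and reassembly of the
# supermatrix after taxa are dropped.

.occ_states <- c("complete", "fragmented", "missing")

#' Construct a validated occupancy matrix
#'
#' @param state Character matrix with taxa as rownames, loci as colnames,
#'   and cells in `complete`, `fragmented`, `missing`.
#' @return An object of class `occupancy_matrix` with fields `taxa`,
#'   `loci`, `state`.
#' @export
occupancy_matrix <- function(state) {
  stopifnot(is.matrix(state), is.character(state),
            !is.null(rownames(state)), !is.null(colnames(state)))
  if (anyDuplicated(rownames(state)) || anyDuplicated(colnames(state))) {
    stop("duplicate taxon or locus labels")
  }
  if (!all(state %in% .occ_states)) {
    stop("occupancy cells must be one of: ",
         paste(.occ_states, collapse = ", "))
  }
  structure(list(taxa = rownames(state), loci = colnames(state),
                 state = state),
            class = "occupancy_matrix")
}

#' Build the occupancy matrix from per-species selections
#'
#' A cell is `complete` when the winning hit's status is Complete or
#' Duplicated, `fragmented` for Fragmented, and `missing` when the species
#' selected nothing for that locus (including fragments removed by the
#' selection policy).
#'
#' @param selections Named list `species -> selection data frame` from
#'   [select_best_hits()] (columns `busco_id`, `status`).
#' @param locus_universe Character vector of all candidate loci; must
#'   contain every selected locus.
#' @return An `occupancy_matrix` (taxa and loci sorted).
#' @export
build_occupancy <- function(selections, locus_universe) {
  stopifnot(is.list(selections), !is.null(names(selections)),
            is.character(locus_universe), length(locus_universe) >= 1L)
  taxa <- sort(names(selections), method = "radix")
  loci <- sort(unique(locus_universe), method = "radix")
  state <- matrix("missing", nrow = length(taxa), ncol = length(loci),
                  dimnames = list(taxa, loci))
  for (sp in taxa) {
    sel <- selections[[sp]]
    if (is.null(sel) || nrow(sel) == 0L) next
    outside <- setdiff(sel$busco_id, loci)
    if (length(outside) > 0L) {
      stop("species '", sp, "': selected locus outside universe: ",
           paste(outside, collapse = ", "))
    }
    cell <- ifelse(sel$status %in% c("Complete", "Duplicated"),
                   "complete",
                   ifelse(sel$status == "Fragmented", "fragmented",
                          "missing"))
    state[sp, sel$busco_id] <- cell
  }
  occupancy_matrix(state)
}

#' Build an occupancy matrix from a directory of per-locus FASTA files
#'
#' Works for any marker set (anchored hybrid enrichment, ultraconserved
#' elements, ...): each file is one locus, record names are taxon labels.
#' A taxon is `complete` at a locus when its record has at least one
#' non-gap, non-missing character; `fragmented` is never assigned in this
#' mode (two-state data).
#'
#' @param dir Directory of `.fa`/`.fas`/`.fasta` files.
#' @param taxa Optional explicit taxon list; defaults to the union of
#'   record names across files.
#' @return An `occupancy_matrix`.
#' @export
build_occupancy_from_fasta_dir <- function(dir, taxa = NULL) {
  if (!dir.exists(dir)) stop("directory not found: ", dir)
  files <- sort(list.files(dir, pattern = "\\.(fa|fas|fasta)$",
                           full.names = TRUE), method = "radix")
  if (length(files) == 0L) stop("no FASTA files found in: ", dir)
  per_locus <- lapply(files, function(f) {
    seqs <- read_fasta(f, on_duplicate = "error")
    names(seqs)[grepl("[^-?]", seqs)]   # taxa with >= 1 data character
  })
  loci <- sub("\\.(fa|fas|fasta)$", "", basename(files))
  if (is.null(taxa)) {
    all_names <- lapply(files, function(f) names(read_fasta(f,
                                                on_duplicate = "error")))
    taxa <- sort(unique(unlist(all_names, use.names = FALSE)),
                 method = "radix")
  }
  state <- matrix("missing", nrow = length(taxa), ncol = length(loci),
                  dimnames = list(taxa, loci))
  for (i in seq_along(loci)) {
    present <- intersect(per_locus[[i]], taxa)
    state[present, loci[i]] <- "complete"
  }
  occupancy_matrix(state)
}

#' Read a delimited presence/absence table as an occupancy matrix
#'
#' Accepts any rectangular delimited file of presence/absence data
#' (behavioural, phenotypic, gene expression, ...). Row labels are taxa
#' (first column), column labels are loci/characters (header). Tokens are
#' mapped to the two-state `complete`/`missing` coding; a token in neither
#' set is an error naming the offending cell.
#'
#' @param x File path, a single string of content, or a character vector
#'   of lines.
#' @param present_tokens Tokens coding presence (default `"1"`).
#' @param absent_tokens Tokens coding absence (default `"0"`).
#' @param sep Field delimiter (default `","`).
#' @return An `occupancy_matrix`.
#' @export
read_presence_absence <- function(x, present_tokens = "1",
                                  absent_tokens = "0", sep = ",") {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    x <- readLines(x, warn = FALSE)
  } else if (length(x) == 1L) {
    x <- strsplit(x, "\n", fixed = TRUE)[[1]]
  }
  x <- x[nzchar(trimws(x))]
  if (length(x) < 2L) stop("presence/absence table needs a header and rows")
  fields <- strsplit(x, sep, fixed = TRUE)
  header <- trimws(fields[[1]])
  loci <- header[-1]
  if (length(loci) == 0L) stop("presence/absence table has no data columns")
  ncol_expect <- length(header)
  taxa <- character(length(fields) - 1L)
  state <- matrix("missing", nrow = length(fields) - 1L, ncol = length(loci))
  for (i in seq_along(fields)[-1]) {
    f <- trimws(fields[[i]])
    if (length(f) != ncol_expect) {
      stop("ragged row at line ", i, ": expected ", ncol_expect,
           " fields, found ", length(f))
    }
    taxa[i - 1L] <- f[1]
    for (j in seq_along(loci)) {
      tok <- f[j + 1L]
      if (tok %in% present_tokens) {
        state[i - 1L, j] <- "complete"
      } else if (tok %in% absent_tokens) {
        state[i - 1L, j] <- "missing"
      } else {
        stop("unmapped token '", tok, "' at (", f[1], ", ", loci[j], ")")
      }
    }
  }
  dimnames(state) <- list(taxa, loci)
  occupancy_matrix(state)
}

#' Summarize occupancy states in long format
#'
#' Counts and percentages of each state per taxon and per locus, plus an
#' aggregation per group when a taxon grouping (e.g. taxonomy at a chosen
#' hierarchical level) is supplied. The long table feeds barplot,
#' circle-pack or upset front ends directly.
#'
#' @param occ An `occupancy_matrix`.
#' @param grouping Optional named character vector `taxon -> group`; must
#'   cover every taxon.
#' @return Data frame with columns `scope` (`taxon`, `locus` or `group`),
#'   `unit`, `state`, `count`, `percent`.
#' @export
summarize_occupancy <- function(occ, grouping = NULL) {
  stopifnot(inherits(occ, "occupancy_matrix"))
  tally <- function(scope, unit, cells) {
    counts <- vapply(.occ_states, function(s) sum(cells == s), integer(1))
    data.frame(scope = scope, unit = unit, state = .occ_states,
               count = unname(counts),
               percent = unname(100 * counts / length(cells)),
               stringsAsFactors = FALSE)
  }
  out <- list()
  for (tx in occ$taxa) {
    out[[length(out) + 1L]] <- tally("taxon", tx, occ$state[tx, ])
  }
  for (lc in occ$loci) {
    out[[length(out) + 1L]] <- tally("locus", lc, occ$state[, lc])
  }
  if (!is.null(grouping)) {
    absent <- setdiff(occ$taxa, names(grouping))
    if (length(absent) > 0L) {
      stop("taxa absent from grouping: ", paste(absent, collapse = ", "))
    }
    for (g in sort(unique(grouping[occ$taxa]), method = "radix")) {
      members <- occ$taxa[grouping[occ$taxa] == g]
      out[[length(out) + 1L]] <-
        tally("group", g, occ$state[members, , drop = FALSE])
    }
  }
  do.call(rbind, out)
}

#' Thresholds for occupancy-based filtering
#'
#' @param min_loci_per_taxon Keep a taxon only if it has at least this many
#'   present loci (e.g. 1000 of ~6000 candidate orthologs is a workable
#'   starting point for transcriptome-derived datasets).
#' @param min_taxa_per_locus Keep a locus only if, after the taxon filter,
#'   at least this many kept taxa have it present.
#' @param count_fragmented_as_present Count `fragmented` cells as present?
#'   Default `TRUE`, matching the retention of fragmented hits upstream.
#' @return An object of class `threshold_spec`.
#' @export
threshold_spec <- function(min_loci_per_taxon = 0L, min_taxa_per_locus = 0L,
                           count_fragmented_as_present = TRUE) {
  min_loci_per_taxon <- as.integer(min_loci_per_taxon)
  min_taxa_per_locus <- as.integer(min_taxa_per_locus)
  stopifnot(length(min_loci_per_taxon) == 1L, !is.na(min_loci_per_taxon),
            min_loci_per_taxon >= 0L,
            length(min_taxa_per_locus) == 1L, !is.na(min_taxa_per_locus),
            min_taxa_per_locus >= 0L,
            is.logical(count_fragmented_as_present),
            length(count_fragmented_as_present) == 1L,
            !is.na(count_fragmented_as_present))
  structure(list(min_loci_per_taxon = min_loci_per_taxon,
                 min_taxa_per_locus = min_taxa_per_locus,
                 count_fragmented_as_present = count_fragmented_as_present),
            class = "threshold_spec")
}

.presence <- function(occ, count_fragmented_as_present) {
  occ$state == "complete" |
    (count_fragmented_as_present & occ$state == "fragmented")
}

#' Filter taxa and loci by occupancy thresholds
#'
#' Taxa are filtered first (present-locus count at least
#' `min_loci_per_taxon`); loci are then filtered on the taxon-reduced
#' matrix (present-taxon count at least `min_taxa_per_locus`).
#' Deterministic; raising a threshold never adds members to a kept set.
#'
#' @param occ An `occupancy_matrix`.
#' @param spec A [threshold_spec()].
#' @return List with `kept_taxa` and `kept_loci` (character vectors in the
#'   matrix's order).
#' @export
apply_thresholds <- function(occ, spec = threshold_spec()) {
  stopifnot(inherits(occ, "occupancy_matrix"),
            inherits(spec, "threshold_spec"))
  present <- .presence(occ, spec$count_fragmented_as_present)
  kept_taxa <- occ$taxa[rowSums(present) >= spec$min_loci_per_taxon]
  sub <- present[kept_taxa, , drop = FALSE]
  kept_loci <- occ$loci[colSums(sub) >= spec$min_taxa_per_locus]
  list(kept_taxa = kept_taxa, kept_loci = kept_loci)
}

#' Reassemble a filtered supermatrix by realigning each kept locus
#'
#' After taxa are dropped, every kept locus is re-aligned from its
#' surviving raw (unaligned) sequences -- not column-sliced from the old
#' alignment -- and the loci are concatenated afresh with a regenerated
#' partition scheme. A kept locus left with zero surviving taxa is dropped
#' with a warning; a locus reduced to one taxon is retained as a singleton
#' row.
#'
#' @param kept_taxa Character vector of taxa to retain.
#' @param kept_loci Character vector of loci to retain; bins must exist
#'   for all of them.
#' @param bins Named list of [locus_bin()] objects (raw sequences).
#' @param aligner Aligner backend, see [align_locus()].
#' @param taxon_order Optional explicit taxon ordering for the new matrix.
#' @return A `supermatrix` over the surviving taxa and loci.
#' @export
reassemble <- function(kept_taxa, kept_loci, bins, aligner = pad_aligner(),
                       taxon_order = NULL) {
  absent <- setdiff(kept_loci, names(bins))
  if (length(absent) > 0L) {
    stop("no bins available for kept loci: ", paste(absent, collapse = ", "))
  }
  kept_loci <- sort(kept_loci, method = "radix")
  alignments <- list()
  for (locus in kept_loci) {
    recs <- bins[[locus]]$records
    recs <- recs[names(recs) %in% kept_taxa]
    if (length(recs) == 0L) {
      warning("locus '", locus,
              "' has no surviving taxa after filtering; dropped")
      next
    }
    alignments[[locus]] <- align_locus(locus_bin(locus, recs), aligner)
  }
  if (length(alignments) == 0L) {
    stop("no loci survived filtering; nothing to reassemble")
  }
  concatenate(unname(alignments), taxon_order = taxon_order)
}

#' Write an occupancy matrix as CSV
#'
#' Taxa as rows, loci as columns, cells the state strings. Read back with
#' [read_occupancy_csv()].
#'
#' @param occ An `occupancy_matrix`.
#' @param path Destination file.
#' @return Invisibly, `path`.
#' @export
write_occupancy_csv <- function(occ, path) {
  stopifnot(inherits(occ, "occupancy_matrix"))
  utils::write.csv(as.data.frame(occ$state), path)
  invisible(path)
}

#' Read an occupancy matrix written by [write_occupancy_csv()]
#'
#' @param path CSV file.
#' @return An `occupancy_matrix`.
#' @export
read_occupancy_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE,
                        colClasses = "character")
  occupancy_matrix(as.matrix(df))
}

#' @export
print.occupancy_matrix <- function(x, ...) {
  n <- length(x$state)
  cat("Occupancy:", length(x$taxa), "taxa x", length(x$loci), "loci (",
      sprintf("%.1f%% complete, %.1f%% fragmented, %.1f%% missing",
              100 * sum(x$state == "complete") / n,
              100 * sum(x$state == "fragmented") / n,
              100 * sum(x$state == "missing") / n), ")\n")
  invisible(x)
}
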