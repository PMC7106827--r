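# Parsing of BUSCO v3 full tables and resolution of each species' hits to at
# most one transcript per BUSCO locus.

.busco_statuses <- c("Complete", "Duplicated", "Fragmented", "Missing")

#' Selection policy for resolving BUSCO hits
#'
#' Controls which hits are eligible to represent a locus for a species.
#' Fragmented hits are retained by default; a minimum match length (in the
#' units of the full table's Length column, i.e. nucleotides for
#' transcriptome mode) can be required of them. The threshold is inclusive:
#' a fragment of exactly `min_fragment_length` is kept.
#'
#' @param keep_fragmented Logical; retain hits with status `Fragmented`?
#' @param min_fragment_length Non-negative integer; minimum Length column
#'   value a fragmented hit must reach to be retained. Ignored when
#'   `keep_fragmented` is `FALSE`.
#' @return An object of class `selection_policy`.
#' @export
#' @examples
#' selection_policy(keep_fragmented = TRUE, min_fragment_length = 200)
selection_policy <- function(keep_fragmented = TRUE, min_fragment_length = 0L) {
  stopifnot(is.logical(keep_fragmented), length(keep_fragmented) == 1L,
            !is.na(keep_fragmented))
  min_fragment_length <- suppressWarnings(as.integer(min_fragment_length))
  if (length(min_fragment_length) != 1L || is.na(min_fragment_length) ||
      min_fragment_length < 0L) {
    stop("`min_fragment_length` must be a single non-negative integer")
  }
  structure(
    list(keep_fragmented = keep_fragmented,
         min_fragment_length = min_fragment_length),
    class = "selection_policy"
  )
}

.check_species_label <- function(species) {
  if (!is.character(species) || length(species) != 1L || is.na(species) ||
      !nzchar(species) || grepl("[[:space:]]", species)) {
    stop("species label must be a non-empty string without whitespace")
  }
  species
}

#' Parse a BUSCO v3 full table
#'
#' Reads the tab-separated `full_table_*.tsv` that BUSCO v3 writes for each
#' run. Lines starting with `#` are comments and are skipped. Data rows carry
#' `busco_id<TAB>status` and, for any status other than `Missing`, three
#' further columns: matching sequence id, bit score and match length.
#' Trailing extra columns are tolerated; other layouts are rejected.
#' Status strings are matched case-insensitively after trimming. Row order
#' is preserved exactly as read, which the duplicate tie-break rule relies
#' on.
#'
#' @param text Either the path of a full-table file, a single string holding
#'   its whole content, or a character vector of lines.
#' @param species Taxon label for this table (conventionally
#'   `genus_species`, taken from the input file name).
#' @return An object of class `species_result`: a list with elements
#'   `species` and `hits`, the latter a data frame with columns `busco_id`,
#'   `status`, `sequence_id`, `score`, `length` and `line` (source line
#'   number). Absent fields of `Missing` rows are `NA`.
#' @seealso [select_best_hits()], [read_full_table()]
#' @export
parse_full_table <- function(text, species) {
  .check_species_label(species)
  if (!is.character(text)) stop("`text` must be character")
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    text <- readLines(text, warn = FALSE)
  } else if (length(text) == 1L) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  lineno <- seq_along(text)
  keep <- !grepl("^[[:space:]]*(#|$)", text)
  text <- text[keep]
  lineno <- lineno[keep]
  if (length(text) == 0L) {
    stop("full table for '", species, "' contains no data rows")
  }

  fields <- strsplit(text, "\t", fixed = TRUE)
  n <- length(fields)
  busco_id <- character(n)
  status <- character(n)
  sequence_id <- rep(NA_character_, n)
  score <- rep(NA_real_, n)
  length_ <- rep(NA_integer_, n)

  for (i in seq_len(n)) {
    f <- trimws(fields[[i]])
    if (length(f) < 2L || !nzchar(f[1]) || !nzchar(f[2])) {
      stop("malformed full-table row at line ", lineno[i],
           ": expected at least busco_id and status")
    }
    st <- .busco_statuses[match(tolower(f[2]), tolower(.busco_statuses))]
    if (is.na(st)) {
      stop("unknown BUSCO status '", f[2], "' at line ", lineno[i])
    }
    busco_id[i] <- f[1]
    status[i] <- st
    if (st == "Missing") next
    if (length(f) < 5L) {
      stop("malformed full-table row at line ", lineno[i], ": status '", st,
           "' requires sequence, score and length columns")
    }
    sc <- suppressWarnings(as.numeric(f[4]))
    ln <- suppressWarnings(as.numeric(f[5]))
    if (is.na(sc) || sc < 0) {
      stop("non-numeric or negative score '", f[4], "' at line ", lineno[i])
    }
    if (is.na(ln) || ln < 1 || ln != round(ln)) {
      stop("invalid length '", f[5], "' at line ", lineno[i])
    }
    sequence_id[i] <- f[3]
    score[i] <- sc
    length_[i] <- as.integer(ln)
  }

  structure(
    list(species = species,
         hits = data.frame(busco_id = busco_id, status = status,
                           sequence_id = sequence_id, score = score,
                           length = length_, line = lineno,
                           stringsAsFactors = FALSE)),
    class = "species_result"
  )
}

#' Read a BUSCO full table from disk
#'
#' Convenience wrapper around [parse_full_table()] that derives the species
#' label from the file name (`full_table_<species>.tsv` or
#' `<species>.tsv`) when not given.
#'
#' @param path Path to a BUSCO v3 full-table TSV.
#' @param species Optional explicit taxon label.
#' @return A `species_result`; see [parse_full_table()].
#' @export
read_full_table <- function(path, species = NULL) {
  if (!file.exists(path)) stop("full table not found: ", path)
  if (is.null(species)) {
    species <- sub("\\.tsv$", "", basename(path))
    species <- sub("^full_table_", "", species)
  }
  parse_full_table(readLines(path, warn = FALSE), species)
}

#' Resolve a species' BUSCO hits to one transcript per locus
#'
#' Applies the selection rules: `Missing` rows never produce an entry;
#' fragmented hits are kept only if the policy allows them and their match
#' length reaches the threshold; among the surviving hits of a locus
#' (typically a `Duplicated` group) the best-scoring sequence wins, and
#' equal scores are broken in favour of the first sequence encountered in
#' the table. The fragment-length filter is applied before duplicate
#' resolution.
#'
#' @param result A `species_result` from [parse_full_table()].
#' @param policy A [selection_policy()].
#' @return A data frame with one row per selected locus and columns
#'   `busco_id`, `sequence_id` and `status` (the winning hit's status),
#'   sorted by `busco_id`. Zero rows when nothing survives.
#' @export
#' @examples
#' tbl <- parse_full_table(paste(
#'   "L1\tDuplicated\ttrA\t500\t900",
#'   "L1\tDuplicated\ttrB\t500\t880", sep = "\n"), "Genus_species")
#' select_best_hits(tbl, selection_policy())  # trA wins the tie (first row)
select_best_hits <- function(result, policy = selection_policy()) {
  stopifnot(inherits(result, "species_result"),
            inherits(policy, "selection_policy"))
  h <- result$hits
  h <- h[h$status != "Missing", , drop = FALSE]
  if (!policy$keep_fragmented) {
    h <- h[h$status != "Fragmented", , drop = FALSE]
  } else if (policy$min_fragment_length > 0L) {
    drop <- h$status == "Fragmented" & h$length < policy$min_fragment_length
    h <- h[!drop, , drop = FALSE]
  }
  if (nrow(h) == 0L) {
    return(data.frame(busco_id = character(), sequence_id = character(),
                      status = character(), stringsAsFactors = FALSE))
  }
  # max score per locus, ties broken by original row order (h preserves it)
  ord <- order(h$busco_id, -h$score, seq_len(nrow(h)), method = "radix")
  h <- h[ord, , drop = FALSE]
  win <- h[!duplicated(h$busco_id), c("busco_id", "sequence_id", "status"),
           drop = FALSE]
  win <- win[order(win$busco_id, method = "radix"), , drop = FALSE]
  rownames(win) <- NULL
  win
}

#' Discover and parse BUSCO results for a directory of runs
#'
#' Looks for the BUSCO v3 layout `<results_dir>/run_<species>/
#' full_table_<species>.tsv`; falls back to any `*.tsv` directly inside
#' `results_dir`, using the file name (sans `full_table_` prefix and
#' extension) as the species label.
#'
#' @param results_dir Directory holding BUSCO run outputs.
#' @return Named list of `species_result` objects, sorted by species label.
#' @export
read_busco_results_dir <- function(results_dir) {
  if (!dir.exists(results_dir)) {
    stop("BUSCO results directory not found: ", results_dir)
  }
  runs <- list.dirs(results_dir, recursive = FALSE)
  runs <- runs[grepl("^run_", basename(runs))]
  tables <- character(0)
  if (length(runs) > 0L) {
    for (r in runs) {
      ft <- list.files(r, pattern = "^full_table.*\\.tsv$", full.names = TRUE)
      if (length(ft) == 0L) {
        stop("no full_table tsv inside BUSCO run directory: ", r)
      }
      tables <- c(tables, ft[1])
    }
  } else {
    tables <- list.files(results_dir, pattern = "\\.tsv$", full.names = TRUE)
  }
  if (length(tables) == 0L) {
    stop("no BUSCO full tables found under: ", results_dir)
  }
  res <- lapply(tables, read_full_table)
  names(res) <- vapply(res, function(x) x$species, character(1))
  if (anyDuplicated(names(res))) {
    stop("duplicate species labels among BUSCO results: ",
         paste(unique(names(res)[duplicated(names(res))]), collapse = ", "))
  }
  res[order(names(res), method = "radix")]
}

#' Run BUSCO v3 over every FASTA in a directory (optional external driver)
#'
#' Thin subprocess wrapper invoking `run_BUSCO.py -i <fasta> -l <lineage>
#' -m tran` per species FASTA, writing results under `out_dir`. Requires a
#' working BUSCO v3 installation on the PATH; intended for opt-in use only,
#' never exercised by the test suite.
#'
#' @param fasta_dir Directory of `genus_species.fasta` files.
#' @param lineage Path to an OrthoDB lineage dataset (e.g.
#'   `laurasiatheria_odb9`).
#' @param out_dir Output directory for the per-species run folders.
#' @param busco Executable name or path of the BUSCO v3 entry point.
#' @return Invisibly, the vector of run directories created.
#' @export
run_busco_dir <- function(fasta_dir, lineage, out_dir,
                          busco = "run_BUSCO.py") {
  if (Sys.which(busco) == "") {
    stop("BUSCO executable '", busco, "' not found on PATH")
  }
  fastas <- list.files(fasta_dir, pattern = "\\.(fa|fas|fasta)$",
                       full.names = TRUE)
  if (length(fastas) == 0L) stop("no FASTA files in ", fasta_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  made <- character(0)
  for (f in fastas) {
    sp <- sub("\\.(fa|fas|fasta)$", "", basename(f))
    status <- system2(busco, c("-i", shQuote(f), "-l", shQuote(lineage),
                               "-m", "tran", "-o", shQuote(sp)),
                      stdout = FALSE, stderr = FALSE)
    if (status != 0L) stop("BUSCO failed for species '", sp, "'")
    made <- c(made, file.path(out_dir, paste0("run_", sp)))
  }
  invisible(made)
}
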