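# Per-locus alignment through a pluggable backend, plus the alignment
# formats the pipeline reads and writes (FASTA intermediates, relaxed
# phylip). The alignment step is delegated -- MAFFT by default -- so what
# this module owns is the contract: same taxa in, equal-length rows out,
# orientation markers stripped from labels.

#' Construct a validated per-locus alignment
#'
#' @param busco_id Locus identifier.
#' @param sequences Named character vector `taxon -> aligned sequence`; all
#'   sequences must have equal length >= 1 over the nucleotide alphabet
#'   plus `-` (gap) and `?` (missing filler). Taxon labels must be unique
#'   and must not begin with the `_R_` orientation marker.
#' @return An object of class `locus_alignment` with fields `busco_id`,
#'   `taxa`, `sequences` and `length`.
#' @export
locus_alignment <- function(busco_id, sequences) {
  stopifnot(is.character(busco_id), length(busco_id) == 1L, nzchar(busco_id),
            is.character(sequences), length(sequences) >= 1L,
            !is.null(names(sequences)), all(nzchar(names(sequences))))
  taxa <- names(sequences)
  if (anyDuplicated(taxa)) {
    stop("locus '", busco_id, "': duplicate taxon labels")
  }
  if (any(startsWith(taxa, "_R_"))) {
    stop("locus '", busco_id,
         "': taxon label carries a residual orientation marker (_R_)")
  }
  widths <- nchar(sequences)
  if (widths[1] < 1L || any(widths != widths[1])) {
    stop("locus '", busco_id, "': rows are not of equal positive length")
  }
  sequences <- toupper(sequences)
  bad <- grepl("[^ACGTUNRYSWKMBDHV?-]", sequences)
  if (any(bad)) {
    stop("locus '", busco_id, "': invalid characters in row(s) ",
         paste(taxa[bad], collapse = ", "))
  }
  structure(list(busco_id = busco_id, taxa = taxa, sequences = sequences,
                 length = unname(widths[1])),
            class = "locus_alignment")
}

#' Deterministic test aligner: right-pad with gaps
#'
#' A stand-in backend that makes the full pipeline runnable without any
#' external binary: each sequence is padded on the right with `-` to the
#' length of the longest record. Deterministic and alignment-free; real
#' analyses should use [mafft_aligner()].
#'
#' @return An aligner backend object.
#' @export
pad_aligner <- function() {
  structure(list(), class = c("pad_aligner", "aligner"))
}

#' MAFFT aligner backend with strand orientation adjustment
#'
#' Invokes `mafft --adjustdirection --quiet <in.fasta>` and captures the
#' aligned FASTA from stdout. `--adjustdirection` reverse-complements
#' sequences found on the opposite strand so every row is oriented 5'->3';
#' MAFFT flags such rows by prefixing `_R_` to their name, which
#' [align_locus()] strips afterwards.
#'
#' @param exe MAFFT executable name or path.
#' @param flags Character vector of command-line flags.
#' @return An aligner backend object.
#' @export
mafft_aligner <- function(exe = "mafft",
                          flags = c("--adjustdirection", "--quiet")) {
  structure(list(exe = exe, flags = flags),
            class = c("mafft_aligner", "aligner"))
}

# Backend dispatch: records in (named, unaligned), records out (named,
# aligned, possibly with orientation markers on the names).
run_aligner <- function(aligner, records, busco_id) {
  UseMethod("run_aligner")
}

#' @export
run_aligner.pad_aligner <- function(aligner, records, busco_id) {
  w <- max(nchar(records))
  vapply(records, function(s) {
    paste0(s, strrep("-", w - nchar(s)))
  }, character(1))
}

#' @export
run_aligner.mafft_aligner <- function(aligner, records, busco_id) {
  if (Sys.which(aligner$exe) == "") {
    stop("locus '", busco_id, "': MAFFT executable '", aligner$exe,
         "' not found on PATH")
  }
  infile <- tempfile(fileext = ".fasta")
  on.exit(unlink(infile))
  write_fasta(records, infile)
  out <- suppressWarnings(
    system2(aligner$exe, c(aligner$flags, shQuote(infile)),
            stdout = TRUE, stderr = FALSE)
  )
  status <- attr(out, "status")
  if (!is.null(status) && status != 0L) {
    stop("locus '", busco_id, "': MAFFT exited with status ", status)
  }
  tmp <- tempfile(fileext = ".fasta")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(out, tmp)
  aligned <- tryCatch(read_fasta(tmp), error = function(e) {
    stop("locus '", busco_id, "': unparsable MAFFT output: ",
         conditionMessage(e))
  })
  aligned
}

#' Strip aligner orientation markers from taxon labels
#'
#' Direction-adjusting aligners mark reverse-complemented rows by
#' prefixing `_R_` to the record name. This removes one leading marker and
#' leaves every other character intact. Two labels collapsing onto the
#' same name after stripping is an error.
#'
#' @param labels Character vector of taxon labels.
#' @return The labels with any leading `_R_` removed.
#' @export
strip_orientation_markers <- function(labels) {
  stopifnot(is.character(labels))
  out <- sub("^_R_", "", labels)
  if (anyDuplicated(out)) {
    stop("taxon label collision after stripping orientation markers: ",
         paste(unique(out[duplicated(out)]), collapse = ", "))
  }
  out
}

#' Align one locus bin
#'
#' Runs the backend on the bin's records, strips orientation markers from
#' the output labels, and checks the contract: the alignment contains
#' exactly the bin's species, all rows of equal length. A single-record bin
#' bypasses the backend and passes through as a one-row alignment of the
#' raw sequence.
#'
#' @param bin A [locus_bin()].
#' @param aligner Backend object; [pad_aligner()] (deterministic, no
#'   external binary) or [mafft_aligner()].
#' @return A [locus_alignment()].
#' @export
align_locus <- function(bin, aligner = pad_aligner()) {
  stopifnot(inherits(bin, "locus_bin"))
  if (length(bin$records) == 1L) {
    return(locus_alignment(bin$busco_id, toupper(bin$records)))
  }
  aligned <- run_aligner(aligner, bin$records, bin$busco_id)
  names(aligned) <- strip_orientation_markers(names(aligned))
  if (!setequal(names(aligned), names(bin$records)) ||
      length(aligned) != length(bin$records)) {
    stop("locus '", bin$busco_id,
         "': aligner output taxa do not match the input bin")
  }
  aligned <- aligned[names(bin$records)]
  locus_alignment(bin$busco_id, aligned)
}

#' Write an alignment in relaxed phylip format
#'
#' Relaxed dialect: header `<ntaxa> <ncolumns>`, then one sequential
#' (non-interleaved, unwrapped) row per taxon with the name and the
#' sequence separated by a single space. Names are unrestricted in length
#' (no 10-character truncation) but must be whitespace-free. Sequences are
#' uppercased on write. Compatible with IQ-TREE's reader.
#'
#' @param x A [locus_alignment()], a supermatrix, or a named character
#'   vector of equal-length sequences.
#' @param path Destination file.
#' @return Invisibly, `path`.
#' @export
write_relaxed_phylip <- function(x, path) {
  seqs <- if (inherits(x, "locus_alignment")) x$sequences
          else if (inherits(x, "supermatrix")) x$matrix
          else x
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  widths <- nchar(seqs)
  if (any(widths != widths[1])) stop("rows are not of equal length")
  if (any(grepl("[[:space:]]", names(seqs)))) {
    stop("taxon names must be whitespace-free")
  }
  lines <- c(paste(length(seqs), widths[1]),
             paste(names(seqs), toupper(seqs)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a relaxed phylip alignment
#'
#' Inverse of [write_relaxed_phylip()]: `read(write(x))` reproduces `x`
#' (labels, sequences, order). Header/row-count mismatches, ragged rows
#' and duplicate names are errors.
#'
#' @param path Source file.
#' @param busco_id Locus identifier for the returned alignment; defaults to
#'   the file basename without extension.
#' @return A [locus_alignment()].
#' @export
read_relaxed_phylip <- function(path, busco_id = NULL) {
  if (!file.exists(path)) stop("phylip file not found: ", path)
  if (is.null(busco_id)) {
    busco_id <- sub("\\.(phy|phylip)$", "", basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("phylip file too short: ", path)
  hdr <- suppressWarnings(as.integer(strsplit(trimws(lines[1]),
                                              "[[:space:]]+")[[1]]))
  if (length(hdr) != 2L || anyNA(hdr) || any(hdr < 1L)) {
    stop("malformed phylip header in ", path)
  }
  rows <- lines[-1]
  if (length(rows) != hdr[1]) {
    stop("phylip header declares ", hdr[1], " taxa but file has ",
         length(rows), " rows: ", path)
  }
  parts <- regmatches(rows, regexpr("[[:space:]]+", rows), invert = TRUE)
  bad <- vapply(parts, function(p) length(p) != 2L || !all(nzchar(p)),
                logical(1))
  if (any(bad)) stop("malformed phylip row(s) in ", path)
  seqs <- vapply(parts, `[`, character(1), 2L)
  names(seqs) <- vapply(parts, `[`, character(1), 1L)
  if (anyDuplicated(names(seqs))) stop("duplicate taxon names in ", path)
  if (any(nchar(seqs) != hdr[2])) {
    stop("ragged rows or wrong column count in ", path)
  }
  locus_alignment(busco_id, seqs)
}
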