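# Concatenation of per-locus alignments into a supermatrix over the union
# of taxa, with a nexus charset partition scheme for IQ-TREE.

# Missing-taxon filler: '?', not '-', so data absent by occupancy stays
# distinguishable from alignment gaps. IQ-TREE treats both as missing.
.fill_char <- "?"

.validate_partitions <- function(partitions, total_length = NULL) {
  stopifnot(is.data.frame(partitions),
            all(c("locus", "start", "end") %in% names(partitions)))
  if (nrow(partitions) == 0L) stop("empty partition scheme")
  if (anyDuplicated(partitions$locus)) {
    stop("duplicate locus names in partition scheme")
  }
  if (partitions$start[1] != 1L) stop("first partition must start at 1")
  if (any(partitions$end < partitions$start)) {
    stop("partition with end < start")
  }
  if (nrow(partitions) > 1L) {
    nxt <- partitions$start[-1]
    prv <- partitions$end[-nrow(partitions)]
    if (any(nxt != prv + 1L)) {
      stop("partitions are not contiguous and non-overlapping")
    }
  }
  if (!is.null(total_length) &&
      partitions$end[nrow(partitions)] != total_length) {
    stop("partitions do not cover the matrix length")
  }
  invisible(partitions)
}

#' Concatenate per-locus alignments into a supermatrix
#'
#' Taxa are the union over all alignments, sorted unless an explicit order
#' is given. A taxon absent from a locus receives an all-`?` filler row of
#' that locus's length. Partition coordinates are 1-based inclusive and
#' follow the input locus order; total length equals the sum of locus
#' lengths.
#'
#' @param alignments List of [locus_alignment()] objects with unique locus
#'   names.
#' @param taxon_order Optional explicit taxon ordering; must contain every
#'   taxon seen in the alignments.
#' @return An object of class `supermatrix`: list with `taxa`, `matrix`
#'   (taxon-keyed concatenated sequences) and `partitions` (data frame
#'   `locus`, `start`, `end`).
#' @export
concatenate <- function(alignments, taxon_order = NULL) {
  if (length(alignments) == 0L) stop("no alignments to concatenate")
  stopifnot(all(vapply(alignments, inherits, logical(1), "locus_alignment")))
  ids <- unname(vapply(alignments, `[[`, character(1), "busco_id"))
  if (anyDuplicated(ids)) {
    stop("duplicate locus name(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  all_taxa <- sort(unique(unlist(lapply(alignments, `[[`, "taxa"),
                                 use.names = FALSE)), method = "radix")
  if (!is.null(taxon_order)) {
    if (!setequal(taxon_order, all_taxa) ||
        length(taxon_order) != length(all_taxa)) {
      stop("`taxon_order` must be a permutation of the union of taxa")
    }
    all_taxa <- taxon_order
  }
  lens <- vapply(alignments, `[[`, integer(1), "length")
  ends <- cumsum(lens)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  pieces <- lapply(alignments, function(a) {
    rows <- a$sequences[all_taxa]
    rows[is.na(rows)] <- strrep(.fill_char, a$length)
    unname(rows)
  })
  mat <- do.call(paste0, pieces)
  names(mat) <- all_taxa
  partitions <- data.frame(locus = ids, start = as.integer(starts),
                           end = as.integer(ends), stringsAsFactors = FALSE)
  .validate_partitions(partitions, total_length = sum(lens))
  structure(list(taxa = all_taxa, matrix = mat, partitions = partitions),
            class = "supermatrix")
}

#' Split a supermatrix back into per-locus alignments
#'
#' Inverse of [concatenate()]: slicing each partition's column range
#' reproduces the per-locus alignments, filler rows included, so
#' `concatenate(split_supermatrix(sm))` equals `sm`.
#'
#' @param sm A `supermatrix`.
#' @return List of [locus_alignment()] objects in partition order.
#' @export
split_supermatrix <- function(sm) {
  stopifnot(inherits(sm, "supermatrix"))
  p <- sm$partitions
  lapply(seq_len(nrow(p)), function(i) {
    rows <- substr(sm$matrix, p$start[i], p$end[i])
    names(rows) <- sm$taxa
    locus_alignment(p$locus[i], rows)
  })
}

.sanitize_charset_name <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

#' Write a partition scheme as a nexus sets block
#'
#' Emits `#nexus`, a `begin sets;` block with one
#' `charset <name> = <start>-<end>;` line per partition, and `end;`.
#' Charset names are sanitized to `[A-Za-z0-9_]`. Output is byte-stable
#' for a given scheme and is readable by IQ-TREE (`-p`/`-spp`).
#'
#' @param partitions Data frame with columns `locus`, `start`, `end`
#'   (1-based inclusive), e.g. the `partitions` element of a supermatrix.
#' @param path Destination file.
#' @return Invisibly, `path`.
#' @export
write_partition_nexus <- function(partitions, path) {
  .validate_partitions(partitions)
  nm <- .sanitize_charset_name(partitions$locus)
  if (anyDuplicated(nm)) stop("charset names collide after sanitization")
  lines <- c("#nexus",
             "begin sets;",
             sprintf("  charset %s = %d-%d;", nm,
                     partitions$start, partitions$end),
             "end;")
  writeLines(lines, path)
  invisible(path)
}

#' Read a nexus sets block back into a partition scheme
#'
#' @param path Nexus file written by [write_partition_nexus()].
#' @return Data frame with columns `locus`, `start`, `end`.
#' @export
read_partition_nexus <- function(path) {
  if (!file.exists(path)) stop("nexus file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  cs <- grep("^\\s*charset\\s", lines, ignore.case = TRUE, value = TRUE)
  if (length(cs) == 0L) stop("no charset lines in ", path)
  m <- regmatches(cs, regexec(
    "charset\\s+(\\S+)\\s*=\\s*([0-9]+)\\s*-\\s*([0-9]+)\\s*;", cs,
    ignore.case = TRUE))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) stop("malformed charset line(s) in ", path)
  partitions <- data.frame(
    locus = vapply(m, `[`, character(1), 2L),
    start = as.integer(vapply(m, `[`, character(1), 3L)),
    end = as.integer(vapply(m, `[`, character(1), 4L)),
    stringsAsFactors = FALSE)
  .validate_partitions(partitions)
}

#' @export
print.supermatrix <- function(x, ...) {
  cat("Supermatrix:", length(x$taxa), "taxa x",
      x$partitions$end[nrow(x$partitions)], "columns,",
      nrow(x$partitions), "loci\n")
  invisible(x)
}
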