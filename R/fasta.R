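# FASTA input/output. Record identity is the first whitespace-delimited
# token of the description line, matching how BUSCO reports transcript ids.

#' Read a FASTA file as a named character vector
#'
#' Sequences are uppercased; record names are the first whitespace-delimited
#' token of each description line. Duplicate ids keep the first record
#' (with a warning) or raise an error, depending on `on_duplicate`.
#'
#' @param path FASTA file (wrapped or unwrapped lines).
#' @param on_duplicate `"first"` (default; warn and keep the first record)
#'   or `"error"`.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, on_duplicate = c("first", "error")) {
  on_duplicate <- match.arg(on_duplicate)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(x), "[ \t]+"), `[`, character(1), 1L)
  seqs <- toupper(as.character(x))
  names(seqs) <- ids
  dup <- duplicated(ids)
  if (any(dup)) {
    if (on_duplicate == "error") {
      stop("duplicate record id(s) in ", path, ": ",
           paste(unique(ids[dup]), collapse = ", "))
    }
    warning("duplicate record id(s) in ", basename(path), " (",
            paste(unique(ids[dup]), collapse = ", "),
            "); first record kept")
    seqs <- seqs[!dup]
  }
  seqs
}

#' Write a named character vector of sequences to FASTA
#'
#' @param seqs Named character vector (names become record ids).
#' @param path Destination file.
#' @param width Line-wrap width for sequence lines.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)), all(nzchar(names(seqs))))
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

# Reverse complement of plain DNA strings (fixture plumbing; uppercase in,
# uppercase out, ACGTN only).
.revcomp <- function(s) {
  vapply(s, function(x) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
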