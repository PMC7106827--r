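# Gene Ontology category mapping: upset-style intersection counts and
# relative percent of categories sampled per taxon.

#' Load an ortholog-to-GO-category mapping
#'
#' Two-column delimited input (busco_id, category), one pair per row, any
#' row order; repeated busco_ids union their categories. The delimiter is
#' sniffed (tab if the first data row contains one, comma otherwise)
#' unless given. The category vocabulary is free: GO slim labels like
#' "Development" or full GO ids both work.
#'
#' @param x File path, single content string, or character vector of lines.
#' @param sep Optional explicit delimiter.
#' @return An object of class `go_mapping`: named list
#'   `busco_id -> character vector of categories`.
#' @export
load_go_mapping <- function(x, sep = NULL) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    x <- readLines(x, warn = FALSE)
  } else if (length(x) == 1L) {
    x <- strsplit(x, "\n", fixed = TRUE)[[1]]
  }
  lineno <- seq_along(x)
  keep <- nzchar(trimws(x)) & !grepl("^[[:space:]]*#", x)
  x <- x[keep]
  lineno <- lineno[keep]
  entries <- list()
  if (length(x) == 0L) {
    return(structure(entries, class = "go_mapping"))
  }
  if (is.null(sep)) sep <- if (grepl("\t", x[1], fixed = TRUE)) "\t" else ","
  fields <- strsplit(x, sep, fixed = TRUE)
  for (i in seq_along(fields)) {
    f <- trimws(fields[[i]])
    if (length(f) != 2L || !all(nzchar(f))) {
      stop("malformed GO mapping row at line ", lineno[i],
           ": expected exactly (busco_id, category)")
    }
    entries[[f[1]]] <- union(entries[[f[1]]], f[2])
  }
  structure(entries, class = "go_mapping")
}

#' Exclusive intersection counts of GO categories across loci
#'
#' Every annotated locus contributes to exactly one exclusive combination:
#' its full category set. These counts partition the annotated loci, as in
#' the intersection-size histogram of an upset plot; per-category set
#' sizes (non-exclusive) are reported alongside, as are loci with an empty
#' category set (unannotated).
#'
#' @param mapping A `go_mapping`.
#' @return List with `intersections` (data frame `combination`, `count`,
#'   combinations as sorted `+`-joined category labels, ordered by
#'   decreasing count then label), `set_sizes` (data frame `category`,
#'   `count`), and `n_unannotated`.
#' @export
intersection_counts <- function(mapping) {
  stopifnot(inherits(mapping, "go_mapping"))
  sizes <- vapply(mapping, length, integer(1))
  annotated <- mapping[sizes > 0L]
  n_unannotated <- sum(sizes == 0L)
  if (length(annotated) == 0L) {
    return(list(
      intersections = data.frame(combination = character(),
                                 count = integer(),
                                 stringsAsFactors = FALSE),
      set_sizes = data.frame(category = character(), count = integer(),
                             stringsAsFactors = FALSE),
      n_unannotated = n_unannotated))
  }
  combo <- vapply(annotated, function(s) {
    paste(sort(unique(s), method = "radix"), collapse = "+")
  }, character(1))
  tab <- table(combo)
  inter <- data.frame(combination = names(tab),
                      count = as.integer(tab), stringsAsFactors = FALSE)
  inter <- inter[order(-inter$count, inter$combination, method = "radix"), ,
                 drop = FALSE]
  rownames(inter) <- NULL
  cat_tab <- table(unlist(lapply(annotated, unique), use.names = FALSE))
  set_sizes <- data.frame(category = names(cat_tab),
                          count = as.integer(cat_tab),
                          stringsAsFactors = FALSE)
  set_sizes <- set_sizes[order(-set_sizes$count, set_sizes$category,
                               method = "radix"), , drop = FALSE]
  rownames(set_sizes) <- NULL
  list(intersections = inter, set_sizes = set_sizes,
       n_unannotated = n_unannotated)
}

#' Relative percent of each GO category sampled per taxon
#'
#' For each taxon (or sample, e.g. a species-tissue combination) and
#' category: `100 * present loci in the category / category members among
#' the occupancy matrix's loci`. Presence honours the fragmented toggle.
#' Categories with zero member loci in the matrix are excluded with a
#' warning.
#'
#' @param mapping A `go_mapping`.
#' @param occ An `occupancy_matrix` whose loci are drawn from the mapping
#'   domain (unannotated loci are allowed and simply ignored).
#' @param count_fragmented_as_present Count `fragmented` cells as present?
#' @return Data frame `taxon`, `category`, `percent`, with percent in
#'   `[0, 100]`.
#' @export
relative_percent_sampled <- function(mapping, occ,
                                     count_fragmented_as_present = TRUE) {
  stopifnot(inherits(mapping, "go_mapping"),
            inherits(occ, "occupancy_matrix"))
  categories <- sort(unique(unlist(mapping, use.names = FALSE)),
                     method = "radix")
  members <- lapply(categories, function(cat) {
    loci <- names(mapping)[vapply(mapping, function(s) cat %in% s,
                                  logical(1))]
    intersect(loci, occ$loci)
  })
  names(members) <- categories
  empty <- vapply(members, length, integer(1)) == 0L
  if (any(empty)) {
    warning("categor(ies) with zero member loci in the matrix excluded: ",
            paste(categories[empty], collapse = ", "))
    members <- members[!empty]
    categories <- categories[!empty]
  }
  present <- .presence(occ, count_fragmented_as_present)
  out <- expand.grid(taxon = occ$taxa, category = categories,
                     stringsAsFactors = FALSE)
  out$percent <- mapply(function(tx, cat) {
    m <- members[[cat]]
    100 * sum(present[tx, m]) / length(m)
  }, out$taxon, out$category, USE.NAMES = FALSE)
  out <- out[order(out$taxon, out$category, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
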