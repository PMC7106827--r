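# Shared generators and independent brute-force oracles. The oracles are
# deliberately naive (explicit loops, no shared code with the package
# internals) so they stay an independent check.

random_hits <- function(n_loci = 5, max_dup = 3) {
  loci <- sprintf("L%02d", seq_len(n_loci))
  rows <- list()
  for (locus in loci) {
    k <- sample(0:max_dup, 1)
    if (k == 0) {
      rows[[length(rows) + 1L]] <- paste(locus, "Missing", sep = "\t")
      next
    }
    status <- if (k > 1) "Duplicated"
              else sample(c("Complete", "Fragmented"), 1)
    for (j in seq_len(k)) {
      # coarse score grid so equal-score ties actually happen
      score <- sample(seq(100, 900, by = 100), 1)
      len <- sample(50:1200, 1)
      rows[[length(rows) + 1L]] <- sprintf(
        "%s\t%s\ttr_%s_%d\t%d\t%d", locus, status, locus, j, score, len)
    }
  }
  rows <- unlist(rows)
  sample(rows)  # shuffle row order across loci
}

# Brute-force selection: group by locus, drop Missing, filter fragments,
# argmax score with lowest-row-index tie-break.
oracle_select <- function(lines, keep_fragmented = TRUE,
                          min_fragment_length = 0) {
  parts <- strsplit(lines, "\t", fixed = TRUE)
  out <- list()
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (p[2] == "Missing") next
    if (p[2] == "Fragmented") {
      if (!keep_fragmented) next
      if (as.numeric(p[5]) < min_fragment_length) next
    }
    locus <- p[1]
    cand <- list(id = p[3], score = as.numeric(p[4]), row = i,
                 status = p[2])
    best <- out[[locus]]
    if (is.null(best) || cand$score > best$score ||
        (cand$score == best$score && cand$row < best$row)) {
      out[[locus]] <- cand
    }
  }
  if (length(out) == 0) {
    return(data.frame(busco_id = character(), sequence_id = character(),
                      status = character(), stringsAsFactors = FALSE))
  }
  df <- data.frame(busco_id = names(out),
                   sequence_id = vapply(out, `[[`, "", "id"),
                   status = vapply(out, `[[`, "", "status"),
                   stringsAsFactors = FALSE)
  df <- df[order(df$busco_id, method = "radix"), ]
  rownames(df) <- NULL
  df
}

random_occupancy <- function(n_taxa = 6, n_loci = 10,
                             p = c(0.5, 0.2, 0.3)) {
  state <- matrix(sample(c("complete", "fragmented", "missing"),
                         n_taxa * n_loci, replace = TRUE, prob = p),
                  nrow = n_taxa,
                  dimnames = list(sprintf("t%02d", seq_len(n_taxa)),
                                  sprintf("L%02d", seq_len(n_loci))))
  occupancy_matrix(state)
}

# Brute-force threshold filter by explicit counting loops.
oracle_thresholds <- function(occ, min_loci_per_taxon, min_taxa_per_locus,
                              frag_present = TRUE) {
  is_present <- function(s) {
    s == "complete" || (frag_present && s == "fragmented")
  }
  kept_taxa <- character(0)
  for (tx in occ$taxa) {
    n <- 0
    for (lc in occ$loci) if (is_present(occ$state[tx, lc])) n <- n + 1
    if (n >= min_loci_per_taxon) kept_taxa <- c(kept_taxa, tx)
  }
  kept_loci <- character(0)
  for (lc in occ$loci) {
    n <- 0
    for (tx in kept_taxa) if (is_present(occ$state[tx, lc])) n <- n + 1
    if (n >= min_taxa_per_locus) kept_loci <- c(kept_loci, lc)
  }
  list(kept_taxa = kept_taxa, kept_loci = kept_loci)
}

random_alignment <- function(id = "L1", max_taxa = 8, max_len = 40) {
  n <- sample(1:max_taxa, 1)
  len <- sample(1:max_len, 1)
  taxa <- paste0(sample(c("Tursiops_truncatus", "Orcinus_orca",
                          "Amia_calva", "Polypterus_bichir",
                          "Camelus_bactrianus", "Megalops_cyprinoides",
                          "Lipotes_vexillifer", "Physeter_catodon")),
                 sprintf("_%02d", seq_len(8)))[seq_len(n)]
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T", "N", "-", "?"), len,
                 replace = TRUE, prob = c(rep(0.2, 4), 0.05, 0.1, 0.05)),
          collapse = "")
  }, character(1))
  # guarantee at least one non-filler character per row
  seqs <- vapply(seqs, function(s) {
    if (!grepl("[^-?]", s)) sub(".", "A", s) else s
  }, character(1), USE.NAMES = FALSE)
  names(seqs) <- taxa
  locus_alignment(id, seqs)
}

# Brute-force GO intersection enumeration over all category combinations.
oracle_intersections <- function(mapping_list) {
  categories <- sort(unique(unlist(mapping_list)))
  counts <- list()
  annotated <- 0
  for (locus in names(mapping_list)) {
    s <- sort(unique(mapping_list[[locus]]))
    if (length(s) == 0) next
    annotated <- annotated + 1
    key <- paste(s, collapse = "+")
    counts[[key]] <- (counts[[key]] %||% 0) + 1
  }
  # check against full 2^k enumeration
  full <- list()
  if (length(categories) <= 12) {
    combos <- unlist(lapply(seq_along(categories), function(k) {
      apply(utils::combn(categories, k), 2, paste, collapse = "+")
    }))
    for (key in combos) {
      set <- strsplit(key, "+", fixed = TRUE)[[1]]
      n <- 0
      for (locus in names(mapping_list)) {
        if (setequal(mapping_list[[locus]], set)) n <- n + 1
      }
      if (n > 0) full[[key]] <- n
    }
    stopifnot(identical(counts[sort(names(counts))],
                        full[sort(names(full))]))
  }
  list(counts = counts, annotated = annotated)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

small_fixture <- function(dir, seed = 42L, n_species = 3L, n_loci = 8L,
                          ...) {
  generate_fixture(
    fixture_spec(n_species = n_species, n_loci = n_loci, seed = seed, ...),
    dir)
}
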