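# Occupancy construction, summaries, thresholds, reassembly.

sel_df <- function(ids, statuses) {
  data.frame(busco_id = ids,
             sequence_id = if (length(ids)) paste0("tr_", ids)
                           else character(0),
             status = statuses, stringsAsFactors = FALSE)
}

test_that("build_occupancy maps winning statuses to cell states", {
  occ <- build_occupancy(
    list(sp1 = sel_df(c("L1", "L2"), c("Complete", "Fragmented"))),
    c("L1", "L2", "L3"))
  expect_identical(unname(occ$state["sp1", ]),
                   c("complete", "fragmented", "missing"))

  # Duplicated winners are complete cells
  occ <- build_occupancy(list(sp1 = sel_df("L1", "Duplicated")), "L1")
  expect_identical(unname(occ$state["sp1", "L1"]), "complete")

  # empty selection -> all-missing row
  occ <- build_occupancy(list(sp1 = sel_df(character(0), character(0))),
                         c("L1", "L2"))
  expect_true(all(occ$state == "missing"))

  expect_error(build_occupancy(list(sp1 = sel_df("L9", "Complete")),
                               c("L1")), "outside universe")
})

test_that("per-taxon state counts always sum to the locus count", {
  set.seed(5)
  for (i in 1:5) {
    occ <- random_occupancy(sample(2:8, 1), sample(3:15, 1))
    sums <- rowSums(occ$state == "complete") +
      rowSums(occ$state == "fragmented") + rowSums(occ$state == "missing")
    expect_true(all(sums == length(occ$loci)))
  }
})

test_that("build_occupancy_from_fasta_dir marks presence by data chars", {
  dir <- withr::local_tempdir()
  writeLines(c(">sp1", "ACGT", ">sp2", "GG--"), file.path(dir, "L1.fasta"))
  writeLines(c(">sp1", "AC", ">sp3", "--"), file.path(dir, "L2.fasta"))
  occ <- build_occupancy_from_fasta_dir(dir)
  expect_identical(occ$taxa, c("sp1", "sp2", "sp3"))
  expect_identical(unname(occ$state["sp2", ]), c("complete", "missing"))
  # all-gap record counts as missing; fragmented never assigned here
  expect_identical(unname(occ$state["sp3", "L2"]), "missing")
  expect_false(any(occ$state == "fragmented"))

  expect_error(build_occupancy_from_fasta_dir(withr::local_tempdir()),
               "no FASTA")
  writeLines(c(">sp1", "AC", ">sp1", "GG"), file.path(dir, "L3.fasta"))
  expect_error(build_occupancy_from_fasta_dir(dir), "duplicate")
})

test_that("read_presence_absence maps tokens and flags bad cells", {
  occ <- read_presence_absence("t,L1,L2\na,1,0\nb,0,1")
  expect_identical(unname(occ$state["a", ]), c("complete", "missing"))
  expect_error(read_presence_absence("t,L1,L2\na,1"), "ragged")
  expect_error(read_presence_absence("t,L1,L2\na,1,NA"),
               "\\(a, L2\\)")
  # configurable tokens and delimiter
  occ <- read_presence_absence("t\tL1\nx\tyes", present_tokens = "yes",
                               sep = "\t")
  expect_identical(unname(occ$state["x", "L1"]), "complete")
})

test_that("summarize_occupancy produces per-unit and grouped tallies", {
  state <- rbind(a = rep("complete", 4),
                 b = c("complete", "missing", "missing", "missing"))
  colnames(state) <- paste0("L", 1:4)
  occ <- occupancy_matrix(state)
  s <- summarize_occupancy(occ, grouping = c(a = "G", b = "G"))
  a_missing <- s[s$scope == "taxon" & s$unit == "a" &
                   s$state == "missing", ]
  expect_equal(a_missing$percent, 0)
  b_missing <- s[s$scope == "taxon" & s$unit == "b" &
                   s$state == "missing", ]
  expect_equal(b_missing$percent, 75)
  g <- s[s$scope == "group" & s$unit == "G", ]
  expect_equal(sum(g$count), 8)
  expect_error(summarize_occupancy(occ, grouping = c(a = "G")),
               "absent from grouping")
})

test_that("apply_thresholds matches the oracle and is monotone", {
  set.seed(77)
  for (i in 1:20) {
    occ <- random_occupancy(sample(3:9, 1), sample(4:16, 1))
    frag <- sample(c(TRUE, FALSE), 1)
    mt <- sample(0:length(occ$loci), 1)
    ml <- sample(0:length(occ$taxa), 1)
    got <- apply_thresholds(occ, threshold_spec(mt, ml, frag))
    want <- oracle_thresholds(occ, mt, ml, frag)
    expect_identical(got, want)
  }
  occ <- random_occupancy(8, 12)
  prev <- NULL
  for (mt in 0:length(occ$loci)) {
    kept <- apply_thresholds(occ, threshold_spec(mt, 0))$kept_taxa
    if (!is.null(prev)) expect_true(all(kept %in% prev))
    prev <- kept
  }
  # boundary semantics
  expect_identical(apply_thresholds(occ, threshold_spec(0, 0)),
                   list(kept_taxa = occ$taxa, kept_loci = occ$loci))
  full <- apply_thresholds(
    occ, threshold_spec(0, length(occ$taxa), FALSE))$kept_loci
  expect_identical(full,
                   occ$loci[colSums(occ$state == "complete") ==
                              length(occ$taxa)])
})

test_that("thresholds separate taxa by present-locus counts", {
  state <- rbind(
    A = c(rep("complete", 12), rep("missing", 8)),
    B = c(rep("complete", 9), rep("missing", 11)))
  colnames(state) <- sprintf("L%02d", 1:20)
  occ <- occupancy_matrix(state)
  kept <- apply_thresholds(occ, threshold_spec(10, 0))
  expect_identical(kept$kept_taxa, "A")
})

test_that("reassemble realigns surviving sequences and regenerates partitions", {
  bins <- bin_by_locus(list(sp1 = c(L1 = "ACGTAA", L2 = "GGG"),
                            sp2 = c(L1 = "ACG", L2 = "GGT"),
                            sp3 = c(L1 = "ACGTAA")))
  # drop sp3: L1 realigns to the max surviving length (6), L2 unchanged
  sm <- reassemble(c("sp1", "sp2"), c("L1", "L2"), bins)
  expect_identical(sm$taxa, c("sp1", "sp2"))
  expect_identical(sm$partitions$end[2] , 9L)

  # drop nothing: equals the straight pipeline result
  full <- concatenate(lapply(bins, align_locus))
  expect_identical(reassemble(c("sp1", "sp2", "sp3"), c("L1", "L2"), bins),
                   full)

  # locus reduced to one taxon is retained as a singleton row
  sm <- reassemble("sp3", c("L1"), bins)
  expect_identical(sm$taxa, "sp3")

  # kept locus with zero surviving taxa is dropped with a warning
  expect_warning(sm <- reassemble("sp3", c("L1", "L2"), bins),
                 "no surviving taxa")
  expect_identical(sm$partitions$locus, "L1")
  expect_error(suppressWarnings(reassemble("sp3", "L2", bins)),
               "nothing to reassemble")
  expect_error(reassemble("sp1", "L9", bins), "no bins")
})

test_that("occupancy CSV round-trips", {
  occ <- random_occupancy(4, 6)
  f <- withr::local_tempfile(fileext = ".csv")
  write_occupancy_csv(occ, f)
  back <- read_occupancy_csv(f)
  expect_identical(back$state, occ$state)
})
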