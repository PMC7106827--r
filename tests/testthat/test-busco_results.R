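# BUSCO v3 full-table parsing and best-hit selection.

test_that("parse_full_table maps rows to hits and preserves order", {
  txt <- paste(
    "# BUSCO version is: 3.0.2",
    "EOG090W00BB\tComplete\ttr_12\t850.3\t1200",
    "EOG090W00CC\tMissing",
    "EOG090W00DD\tFragmented\ttr_7\t120.0\t300",
    sep = "\n")
  res <- parse_full_table(txt, "Tursiops_truncatus")
  expect_s3_class(res, "species_result")
  expect_identical(res$species, "Tursiops_truncatus")
  h <- res$hits
  expect_identical(h$busco_id,
                   c("EOG090W00BB", "EOG090W00CC", "EOG090W00DD"))
  expect_identical(h$status, c("Complete", "Missing", "Fragmented"))
  expect_identical(h$sequence_id[1], "tr_12")
  expect_equal(h$score[1], 850.3)
  expect_identical(h$length[1], 1200L)
  # Missing row: all three optional fields absent
  expect_true(is.na(h$sequence_id[2]) && is.na(h$score[2]) &&
                is.na(h$length[2]))
})

test_that("parse_full_table tolerates case, trailing columns and comments", {
  txt <- paste(
    "#comment",
    "L1\tcomplete\ttrA\t10\t100\textra\tcols",
    "L2\tMISSING",
    sep = "\n")
  h <- parse_full_table(txt, "sp")$hits
  expect_identical(h$status, c("Complete", "Missing"))
})

test_that("parse_full_table rejects malformed input with line numbers", {
  expect_error(parse_full_table("L1\tComplete\ttr\tNaNX\t700", "sp"),
               "line 1")
  expect_error(parse_full_table("ok\tMissing\nL2\tComplete\ttr\t5", "sp"),
               "line 2")
  expect_error(parse_full_table("L1\tWeird\ttr\t5\t10", "sp"),
               "unknown BUSCO status")
  expect_error(parse_full_table("L1\tComplete\ttr\t-4\t10", "sp"), "line 1")
  expect_error(parse_full_table("L1\tComplete\ttr\t4\t0", "sp"), "length")
  expect_error(parse_full_table("# only comments\n", "sp"), "no data rows")
  expect_error(parse_full_table("L1\tMissing", "bad label"), "whitespace")
})

test_that("select_best_hits resolves duplicates by score then row order", {
  txt <- paste(
    "L1\tDuplicated\tA\t500\t900",
    "L1\tDuplicated\tB\t450\t880",
    sep = "\n")
  sel <- select_best_hits(parse_full_table(txt, "sp"))
  expect_identical(sel$sequence_id, "A")
  expect_identical(sel$status, "Duplicated")

  tie <- paste(
    "L1\tDuplicated\tA\t500\t900",
    "L1\tDuplicated\tB\t500\t880",
    sep = "\n")
  expect_identical(select_best_hits(parse_full_table(tie, "sp"))$sequence_id,
                   "A")
  # lower-scoring row first: argmax, not first-encountered, must win
  rev_order <- paste(
    "L1\tDuplicated\tB\t450\t880",
    "L1\tDuplicated\tA\t500\t900",
    sep = "\n")
  expect_identical(
    select_best_hits(parse_full_table(rev_order, "sp"))$sequence_id, "A")
})

test_that("fragment filtering honours the inclusive length threshold", {
  res <- parse_full_table("L2\tFragmented\tC\t100\t150", "sp")
  expect_identical(
    nrow(select_best_hits(res, selection_policy(TRUE, 200))), 0L)
  expect_identical(
    select_best_hits(res, selection_policy(TRUE, 150))$sequence_id, "C")
  expect_identical(
    select_best_hits(res, selection_policy(TRUE, 100))$sequence_id, "C")
  expect_identical(
    nrow(select_best_hits(res, selection_policy(FALSE, 0))), 0L)
})

test_that("Missing rows never produce selections", {
  res <- parse_full_table("L3\tMissing", "sp")
  expect_identical(nrow(select_best_hits(res)), 0L)
})

test_that("select_best_hits agrees with the brute-force oracle", {
  set.seed(101)
  for (rep in 1:60) {
    lines <- random_hits(n_loci = sample(1:8, 1))
    keep <- sample(c(TRUE, FALSE), 1)
    minlen <- sample(c(0, 100, 600), 1)
    got <- select_best_hits(parse_full_table(lines, "sp"),
                            selection_policy(keep, minlen))
    want <- oracle_select(lines, keep, minlen)
    expect_identical(got, want)
    expect_lte(nrow(got), length(unique(sub("\t.*", "", lines))))
    # determinism on identical text
    expect_identical(got, select_best_hits(parse_full_table(lines, "sp"),
                                           selection_policy(keep, minlen)))
  }
})

test_that("read_busco_results_dir discovers the run_<species> layout", {
  root <- withr::local_tempdir()
  for (sp in c("Amia_calva", "Polyodon_spathula")) {
    d <- file.path(root, paste0("run_", sp))
    dir.create(d, recursive = TRUE)
    writeLines(c("# header", "L1\tComplete\ttr1\t10\t100"),
               file.path(d, paste0("full_table_", sp, ".tsv")))
  }
  res <- read_busco_results_dir(root)
  expect_identical(names(res), c("Amia_calva", "Polyodon_spathula"))
  expect_error(read_busco_results_dir(file.path(root, "nope")),
               "not found")
})
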