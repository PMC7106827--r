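# Concatenation, partition schemes, nexus output, split round-trips.

two_locus_sm <- function() {
  concatenate(list(
    locus_alignment("L1", c(sp1 = "ACGT", sp2 = "AC-T")),
    locus_alignment("L2", c(sp1 = "GGG"))))
}

test_that("concatenate unions taxa, fills absences with ?, sets partitions", {
  sm <- two_locus_sm()
  expect_identical(sm$taxa, c("sp1", "sp2"))
  expect_identical(unname(nchar(sm$matrix)), c(7L, 7L))
  expect_identical(unname(sm$matrix[["sp2"]]), "AC-T???")
  expect_identical(sm$partitions$locus, c("L1", "L2"))
  expect_identical(sm$partitions$start, c(1L, 5L))
  expect_identical(sm$partitions$end, c(4L, 7L))
})

test_that("single-locus concatenation is the identity plus one partition", {
  aln <- locus_alignment("L9", c(a = "ACGT", b = "TTTT"))
  sm <- concatenate(list(aln))
  expect_identical(sm$matrix, aln$sequences)
  expect_identical(sm$partitions,
                   data.frame(locus = "L9", start = 1L, end = 4L,
                              stringsAsFactors = FALSE))
})

test_that("concatenate rejects duplicates, empties, bad taxon orders", {
  a <- locus_alignment("L1", c(x = "AA"))
  expect_error(concatenate(list()), "no alignments")
  expect_error(concatenate(list(a, a)), "duplicate")
  expect_error(concatenate(list(a), taxon_order = c("x", "y")),
               "permutation")
})

test_that("length conservation and split round-trip hold on random loci", {
  set.seed(23)
  for (rep in 1:10) {
    n <- sample(2:10, 1)
    alns <- lapply(seq_len(n), function(i) {
      random_alignment(sprintf("LOC%03d", i))
    })
    sm <- concatenate(alns)
    lens <- vapply(alns, `[[`, integer(1), "length")
    expect_identical(sm$partitions$end[n], sum(lens))
    expect_identical(sm$partitions$end - sm$partitions$start + 1L, lens)
    expect_true(all(nchar(sm$matrix) == sum(lens)))
    # split inverts concatenate (fillers included)
    back <- concatenate(split_supermatrix(sm))
    expect_identical(back, sm)
  }
})

test_that("concatenate is permutation-safe over locus order", {
  set.seed(31)
  alns <- lapply(1:5, function(i) random_alignment(sprintf("P%d", i)))
  sm <- concatenate(alns)
  perm <- sample(5)
  sm2 <- concatenate(alns[perm])
  expect_identical(sm2$partitions$locus,
                   vapply(alns[perm], `[[`, character(1), "busco_id"))
  for (i in seq_along(alns)) {
    id <- alns[[i]]$busco_id
    p1 <- sm$partitions[sm$partitions$locus == id, ]
    p2 <- sm2$partitions[sm2$partitions$locus == id, ]
    expect_identical(substr(sm$matrix, p1$start, p1$end),
                     substr(sm2$matrix, p2$start, p2$end))
  }
})

test_that("nexus charset output matches the documented format", {
  f <- withr::local_tempfile(fileext = ".nex")
  parts <- data.frame(locus = c("L1", "L2"), start = c(1L, 501L),
                      end = c(500L, 800L), stringsAsFactors = FALSE)
  write_partition_nexus(parts, f)
  lines <- readLines(f)
  expect_identical(lines[1], "#nexus")
  expect_true("  charset L1 = 1-500;" %in% lines)
  expect_true("  charset L2 = 501-800;" %in% lines)
  expect_identical(lines[length(lines)], "end;")
  expect_identical(read_partition_nexus(f), parts)

  # cumulative coordinates from lengths 2,3,4
  sm <- concatenate(list(locus_alignment("a", c(x = "AA")),
                         locus_alignment("b", c(x = "AAA")),
                         locus_alignment("c", c(x = "AAAA"))))
  expect_identical(sm$partitions$start, c(1L, 3L, 6L))
  expect_identical(sm$partitions$end, c(2L, 5L, 9L))

  # invalid schemes are rejected before writing
  bad <- data.frame(locus = c("L1", "L2"), start = c(1L, 10L),
                    end = c(5L, 12L))
  expect_error(write_partition_nexus(bad, f), "contiguous")
  expect_error(write_partition_nexus(
    data.frame(locus = "L1", start = 2L, end = 5L), f), "start at 1")
})

test_that("nexus writing is byte-stable and charset names are sanitized", {
  f1 <- withr::local_tempfile(fileext = ".nex")
  f2 <- withr::local_tempfile(fileext = ".nex")
  parts <- data.frame(locus = c("EOG:09.1", "B"), start = c(1L, 4L),
                      end = c(3L, 6L), stringsAsFactors = FALSE)
  write_partition_nexus(parts, f1)
  write_partition_nexus(parts, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_true(any(grepl("charset EOG_09_1 ", readLines(f1))))
})
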