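# Deletion calling from linked null evidence at adjacent markers.

# two-marker fixture: same four F2 individuals missing at both markers with
# homozygous parents (the class-5 linked pattern)
linked_class5_fixture <- function() {
  off1 <- c(rep("--", 6), rep("11", 18))
  fam_fixture(p1 = list("11", "11"), p2 = list("11", "11"),
              off = list(off1, off1),
              gp1 = list(c("11", "12"), c("11", "12")),
              gp2 = list(c("--", "11"), c("--", "11")),
              marker = c("mA", "mB"), pos = c(1000L, 5000L))
}

test_that("adjacent class-5 markers with shared missing F2 yield one deletion call", {
  fx <- linked_class5_fixture()
  fc <- classify_families(fx$geno, fx$pedigree)
  expect_true(all(fc$category == "class5"))
  calls <- call_deletions(fc, fx$map)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$marker1, "mA")
  expect_equal(calls$marker2, "mB")
  expect_equal(calls$size_kb, 4)
  expect_setequal(calls$shared_f2[[1]], sprintf("O%02d", 1:6))
  expect_equal(calls$families[[1]], "1")
  expect_false(calls$run)
})

test_that("nulls in different families at the two markers do not support a call", {
  off_null <- c(rep("--", 6), rep("11", 18))
  off_clean <- rep("11", 24)
  # family 1 shows the pattern only at mA, family 2 only at mB
  fx1 <- fam_fixture(p1 = list("11", "11"), p2 = list("11", "11"),
                     off = list(off_null, off_clean),
                     gp1 = list(c("11", "12"), c("11", "12")),
                     gp2 = list(c("--", "11"), c("--", "11")),
                     marker = c("mA", "mB"), pos = c(1000L, 5000L))
  fc1 <- classify_families(fx1$geno, fx1$pedigree)
  fc2 <- classify_families(fx1$geno, fx1$pedigree)
  fc2$family <- "2"
  fc2$category <- rev(fc2$category)
  fc2$hypotheses <- rev(fc2$hypotheses)
  calls <- call_deletions(dplyr::bind_rows(fc1, fc2), fx1$map)
  # family 1 supports only mA, family 2 only mB: no family links both
  expect_equal(nrow(calls), 0L)
})

test_that("too few shared carriers blocks the call and the knob relaxes it", {
  off1 <- c(rep("--", 6), rep("11", 18))
  off2 <- c(rep("--", 2), rep("11", 4), rep("--", 4), rep("11", 14))
  # markers share only O01 and O02 as missing F2
  fx <- fam_fixture(p1 = list("11", "11"), p2 = list("11", "11"),
                    off = list(off1, off2),
                    gp1 = list(c("11", "12"), c("11", "12")),
                    gp2 = list(c("--", "11"), c("--", "11")),
                    marker = c("mA", "mB"), pos = c(1000L, 5000L))
  fc <- classify_families(fx$geno, fx$pedigree)
  expect_equal(nrow(call_deletions(fc, fx$map)), 0L)
  expect_equal(nrow(call_deletions(fc, fx$map, min_f2_carriers = 2L)), 1L)
})

test_that("three linked markers give two pairwise calls flagged as a run", {
  off1 <- c(rep("--", 6), rep("11", 18))
  fx <- fam_fixture(p1 = list("11", "11", "11"), p2 = list("11", "11", "11"),
                    off = list(off1, off1, off1),
                    gp1 = list(c("11", "12"), c("11", "12"), c("11", "12")),
                    gp2 = list(c("--", "11"), c("--", "11"), c("--", "11")),
                    marker = c("mA", "mB", "mC"), pos = c(1000L, 5000L, 9000L))
  fc <- classify_families(fx$geno, fx$pedigree)
  calls <- call_deletions(fc, fx$map)
  expect_equal(nrow(calls), 2L)
  expect_true(all(calls$run))
  expect_equal(calls$marker1, c("mA", "mB"))
})

test_that("calls never span a chromosome boundary", {
  off1 <- c(rep("--", 6), rep("11", 18))
  fx <- fam_fixture(p1 = list("11", "11"), p2 = list("11", "11"),
                    off = list(off1, off1),
                    gp1 = list(c("11", "12"), c("11", "12")),
                    gp2 = list(c("--", "11"), c("--", "11")),
                    marker = c("mA", "mB"), chrom = c("1", "2"),
                    pos = c(1000L, 1000L))
  fc <- classify_families(fx$geno, fx$pedigree)
  expect_equal(nrow(call_deletions(fc, fx$map)), 0L)
})

test_that("an unsorted map is rejected", {
  fx <- linked_class5_fixture()
  fc <- classify_families(fx$geno, fx$pedigree)
  bad_map <- fx$map[2:1, ]
  expect_error(call_deletions(fc, bad_map), "not sorted")
})

test_that("region writer uses 0-based half-open BED and a region table TSV", {
  fx <- linked_class5_fixture()
  fx$map$pos <- c(1000L, 5000L)
  fc <- classify_families(fx$geno, fx$pedigree)
  calls <- call_deletions(fc, fx$map)
  bed <- withr::local_tempfile(); tsv <- withr::local_tempfile()
  write_regions(calls, bed_path = bed, tsv_path = tsv)
  expect_equal(readLines(bed), "1\t999\t5000\tregion1")
  tab <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(tab$size_kb, 4)
  expect_equal(tab$snps, "mA,mB")
  # empty call set -> valid empty files
  write_regions(calls[0, ], bed_path = bed, tsv_path = tsv)
  expect_equal(length(readLines(bed)), 0L)
  expect_equal(nrow(readr::read_tsv(tsv, show_col_types = FALSE)), 0L)
})

test_that("deletion calls on multi-chromosome fixtures sort by position", {
  off1 <- c(rep("--", 6), rep("11", 18))
  fx <- fam_fixture(
    p1 = replicate(4, "11", simplify = FALSE),
    p2 = replicate(4, "11", simplify = FALSE),
    off = replicate(4, off1, simplify = FALSE),
    gp1 = replicate(4, c("11", "12"), simplify = FALSE),
    gp2 = replicate(4, c("--", "11"), simplify = FALSE),
    marker = c("mA", "mB", "mC", "mD"), chrom = c("1", "1", "2", "2"),
    pos = c(1000L, 5000L, 2000L, 8000L))
  fc <- classify_families(fx$geno, fx$pedigree)
  calls <- call_deletions(fc, fx$map)
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$chrom, c("1", "2"))
  expect_equal(calls$region, 1:2)
  expect_false(any(calls$run))
})
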