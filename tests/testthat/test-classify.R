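# Single-marker fixtures mirroring the worked examples of the five
# null-allele classes, each checked against the per-family classifier.

test_that("the five null-allele classes are assigned from their signature patterns", {
  cls <- function(fx) classify_family(fx$geno, fx$pedigree, "m1")$category

  # class 1: offspring conflict with both homozygous parents; grandparents
  # homozygous/missing, so one genotyping error cannot explain the marker
  fx <- fam_fixture("11", "22", c(rep("11", 5), rep("22", 5)),
                    gp1 = c("11", "11"), gp2 = c("22", "--"))
  expect_equal(cls(fx), "class1")

  # class 2: several conflicts, but recalling parent 1 as heterozygous
  # would explain them all
  fx <- fam_fixture("11", "22", c(rep("12", 8), rep("22", 6)),
                    gp1 = c("11", "12"), gp2 = c("12", "22"))
  expect_equal(cls(fx), "class2")

  # class 3: single F0-F1 conflict; both F1 parents the same homozygote, so
  # no F2 incompatibility could ever appear
  fx <- fam_fixture("11", "11", rep("11", 10),
                    gp1 = c("11", "12"), gp2 = c("22", "11"))
  expect_equal(cls(fx), "class3")

  # class 4: one conflicting offspring where a real null should have hit more
  fx <- fam_fixture("11", "12", c("22", rep("11", 5), rep("12", 5)),
                    gp1 = c("11", "12"), gp2 = c("11", "12"))
  expect_equal(cls(fx), "class4")

  # class 5 (missing pattern): 8 of 24 offspring missing, parents homozygous
  fx <- fam_fixture("11", "11", c(rep("--", 8), rep("11", 16)),
                    gp1 = c("11", "12"), gp2 = c("--", "11"))
  expect_equal(cls(fx), "class5")

  # class 5 (het absence): both homozygotes, no heterozygote, one parent
  # missing (two nulls) and the other heterozygous
  fx <- fam_fixture("--", "12", c(rep("11", 4), rep("22", 5)),
                    gp1 = c("--", "11"), gp2 = c("12", "12"))
  expect_equal(cls(fx), "class5")
})

test_that("non-null-explainable conflicts fall into the error categories", {
  # different homozygotes but heterozygous grandparents: grandparent filter
  # fails, no null hypothesis remains
  fx <- fam_fixture("11", "11", c(rep("11", 6), "22"),
                    gp1 = c("12", "12"), gp2 = c("12", "12"))
  res <- classify_family(fx$geno, fx$pedigree, "m1")
  expect_equal(res$category, "err_diffhom")
  expect_equal(nrow(res$hypotheses[[1]]$states %||% data.frame()), 0L)

  # trio-level conflict without any different-homozygote pair
  fx <- fam_fixture("11", "11", c(rep("11", 6), "12"),
                    gp1 = c("12", "12"), gp2 = c("12", "12"))
  expect_equal(classify_family(fx$geno, fx$pedigree, "m1")$category,
               "err_other")
})

test_that("class-5 assay-failure filter excludes near-total missingness", {
  # all F2 missing
  fx <- fam_fixture("11", "11", rep("--", 24),
                    gp1 = c("11", "12"), gp2 = c("11", "12"))
  expect_equal(classify_family(fx$geno, fx$pedigree, "m1")$category,
               "consistent")
  # all but one missing
  fx <- fam_fixture("11", "11", c(rep("--", 23), "11"),
                    gp1 = c("11", "12"), gp2 = c("11", "12"))
  expect_equal(classify_family(fx$geno, fx$pedigree, "m1")$category,
               "consistent")
  # two called is enough again
  fx <- fam_fixture("11", "11", c(rep("--", 22), "11", "11"),
                    gp1 = c("11", "12"), gp2 = c("11", "12"))
  expect_equal(classify_family(fx$geno, fx$pedigree, "m1")$category,
               "class5")
})

test_that("the min_missing threshold is a strict boundary", {
  mk <- function(n_miss) {
    fam_fixture("11", "11", c(rep("--", n_miss), rep("11", 24 - n_miss)),
                gp1 = c("11", "12"), gp2 = c("11", "12"))
  }
  fx5 <- mk(5); fx6 <- mk(6)
  expect_equal(classify_family(fx5$geno, fx5$pedigree, "m1")$category,
               "consistent")
  expect_equal(classify_family(fx6$geno, fx6$pedigree, "m1")$category,
               "class5")
  # lowering the knob moves the boundary
  fx4 <- mk(4)
  expect_equal(classify_family(fx4$geno, fx4$pedigree, "m1",
                               min_missing = 3L)$category, "class5")
})

test_that("classes 1 and 2 are separated by the one-error criterion", {
  withr::local_seed(505)
  found <- c(class1 = 0L, class2 = 0L)
  for (i in 1:250) {
    fx <- random_fixture(n_off = 6)
    res <- classify_family(fx$geno, fx$pedigree, "m1")
    if (res$category %in% c("class1", "class2")) {
      found[res$category] <- found[res$category] + 1L
      me <- o_min_edits(fixture_to_list(fx), cap = 2L)
      if (res$category == "class2") expect_equal(me, 1L)
      else expect_gte(me, 2L)
      expect_gt(res$n_incompat, 1L)
    }
  }
  expect_true(all(found > 0L))
})

test_that("expected_more_incompatibilities follows the co-parent's alleles", {
  expect_true(expected_more_incompatibilities("11", "12"))
  expect_false(expected_more_incompatibilities("11", "11"))
  expect_true(expected_more_incompatibilities("11", "22"))
  expect_true(expected_more_incompatibilities("22", "12"))
  expect_false(expected_more_incompatibilities("22", "22"))
  expect_true(expected_more_incompatibilities("11", "--"))
  expect_error(expected_more_incompatibilities("12", "11"), "homozygous")
})

test_that("categories are mutually exclusive and exhaustive under fuzzing", {
  withr::local_seed(606)
  for (i in 1:300) {
    fx <- random_fixture(n_off = sample(c(3L, 8L, 24L), 1))
    res <- classify_family(fx$geno, fx$pedigree, "m1")
    expect_equal(nrow(res), 1L)
    expect_true(res$category %in% c(paste0("class", 1:5), "err_diffhom",
                                    "err_other", "consistent"))
    # error categories admit no null hypothesis
    if (startsWith(res$category, "err")) {
      expect_equal(length(res$hypotheses[[1]]), 0L)
      expect_gte(res$n_incompat, 1L)
    }
  }
})

test_that("family integration follows the cross-family rules and is symmetric", {
  expect_equal(integrate_categories("class2", "class4"), "class2")
  expect_equal(integrate_categories("class4", "class5"), "class5")
  expect_equal(integrate_categories("err_other", "err_diffhom"), "err_diffhom")
  expect_equal(integrate_categories("class5", "consistent"), "class5")
  expect_equal(integrate_categories("class3", "err_diffhom"), "class3")
  expect_equal(integrate_categories("err_other", "consistent"), "err_other")
  expect_equal(integrate_categories("class1", "class3"), "class1")
  expect_equal(integrate_categories("class2", "class5"), "class2")
  cats <- c(paste0("class", 1:5), "err_diffhom", "err_other", "consistent")
  for (a in cats) {
    for (b in cats) {
      expect_equal(integrate_categories(a, b), integrate_categories(b, a))
      expect_true(integrate_categories(a, b) %in% cats)
    }
  }
})

test_that("integrate_families records the both-family flag and rejects marker mismatches", {
  a <- tibble::tibble(marker = "m1", category = "class5")
  b <- tibble::tibble(marker = "m1", category = "consistent")
  res <- integrate_families(a, b)
  expect_equal(res$category, "class5")
  expect_false(res$both_families)
  b2 <- tibble::tibble(marker = "m2", category = "class5")
  expect_error(integrate_families(a, b2), "different markers")
  res2 <- integrate_families(a, dplyr::mutate(b, category = "class4"))
  expect_true(res2$both_families)
})

test_that("classify_all integrates simulated families and keeps clean markers consistent", {
  cfg <- sim_config(n_markers = 80, null_rate = 0, error_rate = 0,
                    missing_rate = 0, assay_fail_rate = 0, seed = 9)
  sim <- simulate_intercross(cfg)
  res <- classify_all(sim$geno, sim$pedigree)
  expect_equal(nrow(res), 80L)
  expect_true(all(res$category == "consistent"))
  expect_true(all(c("chrom", "pos") %in% names(res)))
})
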