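# Per-SNP per-family classification into null-allele classes, genotyping
# error categories, or "consistent", and integration across families.
#
# The five null-allele classes grade the evidence:
#   class1  >1 incompatibility, not explainable by one genotyping error
#   class2  >1 incompatibility, explainable by one genotyping error
#   class3  one incompatibility (F0-F1) where no more are expected, because
#           both F1 parents are called the same homozygote
#   class4  one incompatibility where more would be expected under a null
#   class5  many missing F2 with homozygous-or-missing parents, or both
#           homozygotes but no heterozygote among the F2 with one parent
#           missing and the other heterozygous (a two-null parent)
# Incompatibilities that no null-allele assignment can explain are genotyping
# errors, split by whether a different-homozygote pair occurred.

classify_one <- function(cd, fam, min_missing = 5L) {
  inc <- incompat_pairs_one(cd, fam)
  n_inc <- nrow(inc)
  n_dh <- sum(inc$kind == "different_homozygotes")
  nm <- sum(cd$o == 0L)
  nn <- length(cd$o) - nm
  res <- list(n_incompat = n_inc, n_diffhom = n_dh, n_missing_f2 = nm,
              one_error_explains = NA, hypotheses = list())

  if (n_inc > 0L) {
    hyps <- enumerate_hypotheses_one(cd, fam)
    res$hypotheses <- hyps
    if (length(hyps) == 0L) {
      res$category <- if (n_dh > 0L) "err_diffhom" else "err_other"
      return(res)
    }
    if (n_inc > 1L) {
      one <- min_edits_one(cd, fam, cap = 1L) == 1L
      res$one_error_explains <- one
      res$category <- if (one) "class2" else "class1"
      return(res)
    }
    # a single incompatibility: class3 when it sits between an F1 parent and
    # a grandparent and the two F1 parents share the same homozygous call, so
    # no F2 incompatibility could ever surface; otherwise class4
    same_hom <- cd$p[[1L]] == cd$p[[2L]] && cd$p[[1L]] %in% c(1L, 3L)
    res$category <- if (inc$level[[1L]] == "F0-F1" && same_hom) "class3"
                    else "class4"
    return(res)
  }

  # no incompatibilities: check the class-5 patterns
  missing_pre <- hom_or_missing(cd$p[[1L]]) && hom_or_missing(cd$p[[2L]]) &&
    nm > min_missing && nn > 1L
  hetabs_pre <- sum(cd$o == 1L) > 1L && sum(cd$o == 3L) > 1L &&
    sum(cd$o == 2L) == 0L &&
    ((cd$p[[1L]] == 0L && cd$p[[2L]] == 2L) ||
     (cd$p[[2L]] == 0L && cd$p[[1L]] == 2L))
  if (missing_pre || hetabs_pre) {
    hyps <- enumerate_hypotheses_one(cd, fam)
    keep <- if (missing_pre) {
      # the missing F2 are read as null homozygotes, so both parents must
      # admit a null-carrying state consistent with their F0 pairs
      Filter(function(h) all(h$states$type != "none"), hyps)
    } else {
      Filter(function(h) any(h$states$type == "twonull"), hyps)
    }
    if (length(keep) > 0L) {
      res$hypotheses <- keep
      res$category <- "class5"
      return(res)
    }
  }
  res$category <- "consistent"
  res
}

#' Classify every SNP in every family
#'
#' Assigns each (marker, family) pair to one of the five null-allele classes,
#' one of the two genotyping-error categories, or `consistent`. Classes 1 and
#' 2 are separated by whether a single genotyping error could explain all the
#' marker's conflicts; class 5 requires more than `min_missing` F2 offspring
#' with missing calls (with both parents homozygous or missing, more than one
#' F2 genotyped, and not all-but-one missing — whole-assay failures are not
#' evidence), or the two-null-parent pattern of both homozygotes with no
#' heterozygote among the F2.
#'
#' @inheritParams find_incompatibilities
#' @param min_missing Minimum number of missing F2 calls (exclusive) for the
#'   class-5 missing-value pattern. The default 5 requires more than five
#'   missing offspring.
#' @return A tibble with one row per (marker, family): `marker`, `family`,
#'   `category`, `n_incompat`, `n_diffhom`, `n_missing_f2`,
#'   `one_error_explains` (logical, evaluated only when more than one
#'   incompatibility exists), and a `hypotheses` list-column of null-allele
#'   hypothesis tables (see [null_hypotheses()]).
#' @export
classify_families <- function(geno, pedigree, min_missing = 5L) {
  fams <- build_families(pedigree)
  markers <- unique(geno$marker)
  M <- geno_code_matrix(geno, markers = markers,
                        individuals = union(unique(geno$individual),
                                            pedigree$individual))
  out <- vector("list", nrow(fams))
  for (i in seq_len(nrow(fams))) {
    fam <- fam_ctx(fams[i, ])
    counts <- incompat_counts_matrix(M, fam)
    P1 <- M[, fam$p[[1L]]]; P2 <- M[, fam$p[[2L]]]
    O <- M[, fam$off, drop = FALSE]
    nm <- rowSums(O == 0L)
    nn <- ncol(O) - nm
    missing_pre <- hom_or_missing(P1) & hom_or_missing(P2) &
      nm > min_missing & nn > 1L
    hetabs_pre <- rowSums(O == 1L) > 1L & rowSums(O == 3L) > 1L &
      rowSums(O == 2L) == 0L &
      ((P1 == 0L & P2 == 2L) | (P2 == 0L & P1 == 2L))
    candidate <- counts$n_incompat > 0L | missing_pre | hetabs_pre
    cat <- rep("consistent", length(markers))
    details <- vector("list", length(markers))
    one_err <- rep(NA, length(markers))
    for (mi in which(candidate)) {
      res <- classify_one(fam_codes(M, fam, markers[[mi]]), fam,
                          min_missing = min_missing)
      cat[[mi]] <- res$category
      details[[mi]] <- res$hypotheses
      one_err[[mi]] <- res$one_error_explains
    }
    details[vapply(details, is.null, logical(1))] <- list(list())
    out[[i]] <- tibble::tibble(
      marker = markers, family = fam$id, category = cat,
      n_incompat = counts$n_incompat, n_diffhom = counts$n_diffhom,
      n_missing_f2 = as.integer(nm), one_error_explains = one_err,
      hypotheses = details)
  }
  dplyr::bind_rows(out)
}

#' Classify a single SNP in a single family
#'
#' Convenience wrapper around [classify_families()] for one marker.
#'
#' @inheritParams null_hypotheses
#' @inheritParams classify_families
#' @return A one-row classification tibble (see [classify_families()]).
#' @export
classify_family <- function(geno, pedigree, marker, family = NULL,
                            min_missing = 5L) {
  fam <- get_family(pedigree, family)
  M <- geno_code_matrix(geno, markers = marker,
                        individuals = union(unique(geno$individual),
                                            pedigree$individual))
  res <- classify_one(fam_codes(M, fam, marker), fam, min_missing = min_missing)
  tibble::tibble(marker = marker, family = fam$id, category = res$category,
                 n_incompat = res$n_incompat, n_diffhom = res$n_diffhom,
                 n_missing_f2 = res$n_missing_f2,
                 one_error_explains = res$one_error_explains,
                 hypotheses = list(res$hypotheses))
}

#' Would a null allele be expected to cause further incompatibilities?
#'
#' Under a single-carrier hypothesis, an F2 offspring inheriting the null is
#' called homozygous for whichever allele the co-parent transmitted. More
#' incompatibilities are therefore expected whenever the co-parent carries an
#' allele different from the carrier parent's visible allele; when both F1
#' parents share the same homozygous call none are expected (the class-3
#' configuration). A missing co-parent could carry either allele, so more
#' incompatibilities are treated as possible.
#'
#' @param carrier Genotype call of the carrier parent as a string (`"11"`,
#'   `"22"`; the visible homozygote).
#' @param co_parent Genotype call of the other parent (`"11"`, `"12"`,
#'   `"22"`, or `"--"` for missing).
#' @return Logical, vectorised over the inputs.
#' @export
#' @examples
#' expected_more_incompatibilities("11", "12")  # TRUE
#' expected_more_incompatibilities("11", "11")  # FALSE
expected_more_incompatibilities <- function(carrier, co_parent) {
  cg <- parse_call(carrier)
  og <- parse_call(co_parent)
  if (any(!cg %in% c(1L, 3L))) {
    abort("`carrier` must be a homozygous call (\"11\" or \"22\")")
  }
  vis <- ifelse(cg == 1L, 1L, 2L)
  other <- 3L - vis
  og == 0L | mapply(function(g, a) a %in% ALLELE_SETS[[g + 1L]], og, other)
}

parse_call <- function(x) {
  lut <- c("--" = 0L, "00" = 0L, "11" = 1L, "12" = 2L, "21" = 2L, "22" = 3L)
  g <- lut[x]
  if (anyNA(g)) abort(paste0("unparseable genotype call: ",
                             paste(x[is.na(g)], collapse = ", ")))
  unname(g)
}

#' Integrate per-family categories into an overall category
#'
#' Applies the cross-family rules: two different null classes among 1-4 give
#' the numerically lower class; class 4 with class 5 gives class 5 (class 4
#' carries the weakest evidence); a null class beats an error category or a
#' consistent result; two error categories give `err_diffhom` if either
#' family showed a different-homozygote error; identical categories stand.
#'
#' @param a,b Category strings (vectorised).
#' @return The integrated category vector.
#' @export
integrate_categories <- function(a, b) {
  stopifnot(all(a %in% CATEGORIES), all(b %in% CATEGORIES))
  mapply(function(x, y) {
    if (x == y) return(x)
    xn <- x %in% NULL_CLASSES
    yn <- y %in% NULL_CLASSES
    if (xn && yn) {
      if (setequal(c(x, y), c("class4", "class5"))) return("class5")
      return(min(x, y))  # class labels sort numerically
    }
    if (xn) return(x)
    if (yn) return(y)
    xe <- x %in% ERR_CLASSES
    ye <- y %in% ERR_CLASSES
    if (xe && ye) {
      return(if ("err_diffhom" %in% c(x, y)) "err_diffhom" else "err_other")
    }
    if (xe) return(x)
    if (ye) return(y)
    "consistent"
  }, a, b, USE.NAMES = FALSE)
}

#' Integrate two per-family classifications of the same SNP
#'
#' @param a,b One-row classification tibbles for the same marker in two
#'   families (rows of [classify_families()] output).
#' @return A one-row tibble: `marker`, `category`, `both_families` (both
#'   families independently show a null-allele class), and the two per-family
#'   categories.
#' @export
integrate_families <- function(a, b) {
  if (!identical(a$marker, b$marker)) {
    abort("classifications are for different markers")
  }
  tibble::tibble(
    marker = a$marker,
    category = integrate_categories(a$category, b$category),
    both_families = a$category %in% NULL_CLASSES & b$category %in% NULL_CLASSES,
    category_a = a$category, category_b = b$category)
}

#' Integrate per-family classifications across all families
#'
#' Reduces the per-(marker, family) categories of [classify_families()] to
#' one overall category per marker, recording how many families showed
#' null-allele or error evidence.
#'
#' @param fam_cls Output of [classify_families()].
#' @return A tibble with one row per marker: `marker`, `category`,
#'   `both_families` (at least two families with a null class),
#'   `n_fam_null`, `n_fam_err`, and a `family_categories` list-column of
#'   named per-family category vectors.
#' @export
integrate_classifications <- function(fam_cls) {
  fam_cls |>
    dplyr::group_by(.data$marker) |>
    dplyr::summarise(
      family_categories = list(setNames(.data$category, .data$family)),
      n_fam_null = sum(.data$category %in% NULL_CLASSES),
      n_fam_err = sum(.data$category %in% ERR_CLASSES),
      both_families = .data$n_fam_null >= 2L,
      category = Reduce(integrate_categories, .data$category),
      .groups = "drop") |>
    dplyr::select("marker", "category", "both_families", "n_fam_null",
                  "n_fam_err", "family_categories")
}

#' Scan genotypes for null alleles: classify and integrate in one step
#'
#' Runs [classify_families()] then [integrate_classifications()] and joins
#' the marker map when present.
#'
#' @inheritParams classify_families
#' @param map Optional marker map (`marker`, `chrom`, `pos`); taken from
#'   `geno` columns when present.
#' @return The integrated per-marker tibble, with `chrom`/`pos` when a map
#'   is available. The per-family table is attached as attribute
#'   `"family_classifications"`.
#' @export
classify_all <- function(geno, pedigree, min_missing = 5L, map = NULL) {
  fam_cls <- classify_families(geno, pedigree, min_missing = min_missing)
  res <- integrate_classifications(fam_cls)
  if (is.null(map) && all(c("chrom", "pos") %in% names(geno))) {
    map <- dplyr::distinct(geno, .data$marker, .data$chrom, .data$pos)
  }
  if (!is.null(map)) {
    res <- dplyr::left_join(res, map, by = "marker") |>
      dplyr::relocate("chrom", "pos", .after = "marker")
  }
  attr(res, "family_classifications") <- fam_cls
  res
}
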