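# Cross-family summary of null-allele classes and the family-ratio mixture
# model for the error fraction.
#
# In a design where the families share founders, true null alleles should be
# found at similar rates in both families, while sporadic genotyping errors
# are family-specific. Treating a null-allele class as a mixture of true
# nulls (family ratio 1) and a fraction x of error SNPs occurring at the
# family ratio r_e observed for different-homozygote errors, the class ratio
# is r = (1 - x) + x * r_e, so x = (r - 1) / (r_e - 1).

#' Family-ratio mixture estimate of the error fraction
#'
#' Estimates the fraction `x` of a null-allele class attributable to
#' genotyping error from the ratio `r` of SNPs found in family 1 versus
#' family 2 for that class, and the corresponding ratio `re` for the
#' different-homozygotes error category, via `x = (r - 1) / (re - 1)`.
#' Estimation requires the error category to be family-1 enriched
#' (`re > 1`); `x` is unset when `r < 1` (the class shows no enrichment to
#' explain).
#'
#' @param r Family-1 to family-2 count ratio for the null-allele class.
#' @param re The same ratio for the different-homozygotes error category.
#' @return An object of class `mixture_estimate` with elements `r`, `re`,
#'   `x` (fraction in `[0, 1]`, `NA` when unset), `pct` (integer percent)
#'   and `available`. [tidy()] and [glance()] methods are provided.
#' @export
#' @examples
#' mixture_error_fraction(9.6, 15.4)  # ~60% of the class is error
mixture_error_fraction <- function(r, re) {
  stopifnot(is.numeric(r), is.numeric(re), length(r) == 1L, length(re) == 1L)
  available <- is.finite(re) && re > 1
  x <- NA_real_
  reason <- NULL
  if (!available) {
    reason <- "error category not family-1 enriched (re <= 1)"
  } else if (!is.finite(r) || r < 1) {
    reason <- "class not family-1 enriched (r < 1); x unset"
  } else {
    x <- (r - 1) / (re - 1)
  }
  structure(list(r = r, re = re, x = x,
                 pct = if (is.na(x)) NA_integer_ else as.integer(round(100 * x)),
                 available = available, reason = reason),
            class = "mixture_estimate")
}

#' @export
print.mixture_estimate <- function(x, ...) {
  cat("Family-ratio mixture estimate\n")
  cat(sprintf("  r  (class ratio, family 1 : family 2): %.3g\n", x$r))
  cat(sprintf("  re (different-homozygote error ratio): %.3g\n", x$re))
  if (is.na(x$x)) {
    cat("  x: unavailable -", x$reason %||% "", "\n")
  } else {
    cat(sprintf("  x  (estimated error fraction): %.3f (%d%%)\n", x$x, x$pct))
  }
  invisible(x)
}

#' @rdname mixture_error_fraction
#' @param x A `mixture_estimate`.
#' @param ... Unused.
#' @export
tidy.mixture_estimate <- function(x, ...) {
  tibble::tibble(term = c("r", "re", "x"),
                 estimate = c(x$r, x$re, x$x))
}

#' @rdname mixture_error_fraction
#' @export
glance.mixture_estimate <- function(x, ...) {
  est <- x
  tibble::tibble(x = est$x, pct = est$pct, r = est$r, re = est$re,
                 available = est$available)
}

#' Family-1 to family-2 count ratio
#'
#' @param n1,n2 Per-family SNP counts (vectorised).
#' @return `n1 / n2`, `NA` where `n2` is 0 (the ratio is undefined, not 0).
#' @export
family_ratio <- function(n1, n2) {
  ifelse(n2 == 0, NA_real_, n1 / n2)
}

#' Summarise null-allele and error categories across families
#'
#' Builds the per-category summary table: per-family counts, overall counts
#' after integration, the percentage of SNPs detected in both families, the
#' family-1 to family-2 ratio, and the mixture-model error-fraction estimate
#' for family-1-enriched null classes. Family 1 and family 2 are the first
#' two family labels in sort order.
#'
#' @param fam_cls Per-(marker, family) classifications from
#'   [classify_families()].
#' @return A tibble of class `nullscan_summary`, one row per category:
#'   `category`, `n_family1`, `n_family2`, `n_overall`, `pct_both` (0-100,
#'   unrounded; `NA` for the consistent row), `ratio` (unrounded; `NA` when
#'   the family-2 count is 0), `est_error_pct` (integer percent, `NA` when
#'   no estimate is possible). The family labels are kept in the
#'   `"families"` attribute.
#' @export
summarize_classes <- function(fam_cls) {
  fams <- sort(unique(fam_cls$family))
  if (length(fams) < 2L) {
    abort("summarize_classes() needs classifications for two families")
  }
  if (length(fams) > 2L) {
    warn("more than two families; ratios use the first two in sort order")
  }
  integ <- integrate_classifications(fam_cls)
  per_fam <- fam_cls |>
    dplyr::count(.data$family, .data$category) |>
    tidyr::pivot_wider(names_from = "family", values_from = "n",
                       values_fill = 0L)
  tbl <- tibble::tibble(category = CATEGORIES) |>
    dplyr::left_join(per_fam, by = "category") |>
    dplyr::mutate(dplyr::across(-"category", ~ tidyr::replace_na(.x, 0L)))
  n1 <- tbl[[fams[[1L]]]]
  n2 <- tbl[[fams[[2L]]]]
  n_overall <- vapply(CATEGORIES, function(cc) sum(integ$category == cc),
                      integer(1), USE.NAMES = FALSE)
  # both-family percentage: of the SNPs in a null class overall, how many had
  # null-allele evidence in two families; for error rows, error evidence
  both_n <- vapply(CATEGORIES, function(cc) {
    rows <- integ$category == cc
    if (cc %in% NULL_CLASSES) sum(rows & integ$n_fam_null >= 2L)
    else if (cc %in% ERR_CLASSES) sum(rows & integ$n_fam_err >= 2L)
    else NA_integer_
  }, integer(1), USE.NAMES = FALSE)
  ratio <- family_ratio(n1, n2)
  re <- ratio[[match("err_diffhom", CATEGORIES)]]
  est <- vapply(seq_along(CATEGORIES), function(i) {
    cc <- CATEGORIES[[i]]
    if (!cc %in% NULL_CLASSES) return(NA_integer_)
    r <- ratio[[i]]
    if (is.na(r) || r <= 1 || is.na(re) || re <= 1) return(NA_integer_)
    mixture_error_fraction(r, re)$pct
  }, integer(1))
  out <- tibble::tibble(
    category = CATEGORIES,
    n_family1 = n1, n_family2 = n2, n_overall = n_overall,
    pct_both = ifelse(n_overall > 0L, 100 * both_n / n_overall,
                      ifelse(is.na(both_n), NA_real_, NA_real_)),
    ratio = ratio, est_error_pct = est)
  attr(out, "families") <- fams[1:2]
  class(out) <- c("nullscan_summary", class(out))
  out
}

#' Overall null-allele and error percentages
#'
#' Computes the headline rates: the percentage of markers with null alleles
#' (classes 1, 2, 3 and 5 — class 4 is excluded as mostly error) and with
#' genotyping errors (class 4 plus both error categories), each rounded to
#' one decimal.
#'
#' @param summary A summary tibble with `category` and `n_overall` columns
#'   ([summarize_classes()] output, or a hand-built table of counts).
#' @param n_markers Total number of markers scanned.
#' @return A one-row tibble: `null_pct`, `error_pct`.
#' @export
overall_percentages <- function(summary, n_markers) {
  stopifnot(n_markers > 0)
  cnt <- setNames(summary$n_overall, summary$category)
  null_n <- sum(cnt[c("class1", "class2", "class3", "class5")], na.rm = TRUE)
  err_n <- sum(cnt[c("class4", "err_diffhom", "err_other")], na.rm = TRUE)
  tibble::tibble(null_pct = round(100 * null_n / n_markers, 1),
                 error_pct = round(100 * err_n / n_markers, 1))
}

#' Write a summary table as TSV and/or JSON
#'
#' The TSV mirrors the layout of the per-category summary with reporting
#' precision (percentages to the nearest integer, ratios to one decimal).
#'
#' @param summary A [summarize_classes()] result.
#' @param tsv_path,json_path Output paths (`NULL` to skip either).
#' @return Invisibly, `summary`.
#' @export
write_summary <- function(summary, tsv_path = NULL, json_path = NULL) {
  rounded <- dplyr::mutate(summary,
                           pct_both = round(.data$pct_both),
                           ratio = round(.data$ratio, 1))
  if (!is.null(tsv_path)) {
    readr::write_tsv(rounded, tsv_path, progress = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(rounded, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(summary)
}
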