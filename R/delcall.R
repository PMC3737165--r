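# Candidate deletions from linked null alleles at adjacent markers.
#
# A single SNP with a possible null allele may reflect a deletion or merely a
# polymorphism under a genotyping probe; independent null evidence at two
# adjacent SNPs carried by the same individuals is the signature used to call
# a candidate deletion.

#' Call candidate deletions from linked null alleles
#'
#' Walks each chromosome's markers in map order and, for every pair of
#' consecutive markers that both carry a null-allele classification in the
#' same family, tests whether some null hypothesis at each marker shares the
#' same carrier F1 parent and at least `min_f2_carriers` common putative F2
#' carriers. Pairs supported independently by several families are reported
#' as one call listing all supporting families. Runs of more than two linked
#' markers are reported as overlapping pairwise calls flagged by `run`.
#'
#' @param fam_cls Per-(marker, family) classifications with hypothesis
#'   evidence, from [classify_families()].
#' @param map Marker map (`marker`, `chrom`, `pos`), sorted by chromosome
#'   and position; an unsorted map is an error.
#' @param min_f2_carriers Minimum shared putative F2 carriers (default 3).
#' @return A tibble of class `deletion_calls`, one row per called region:
#'   `region`, `chrom`, `marker1`, `marker2`, `pos1`, `pos2`, `size_kb`
#'   (from exact bp positions), `families`, `carrier_parents`, `shared_f2`,
#'   `classes` (list-columns), and `run`.
#' @export
call_deletions <- function(fam_cls, map, min_f2_carriers = 3L) {
  if (!all(c("marker", "chrom", "pos") %in% names(map))) {
    abort("`map` must have columns marker, chrom, pos")
  }
  # each chromosome must form one contiguous block with non-decreasing
  # positions; the order of the chromosome blocks themselves is free
  blocks <- rle(map$chrom)$values
  pos_ok <- all(vapply(split(map$pos, map$chrom),
                       function(p) !is.unsorted(p), logical(1)))
  if (anyDuplicated(blocks) || !pos_ok) {
    abort("marker map is not sorted by (chrom, pos)")
  }

  nulls <- dplyr::filter(fam_cls, .data$category %in% NULL_CLASSES,
                         lengths(.data$hypotheses) > 0L)
  key <- paste(nulls$marker, nulls$family)
  calls <- list()
  for (chr in unique(map$chrom)) {
    cm <- map[map$chrom == chr, ]
    if (nrow(cm) < 2L) next
    for (i in seq_len(nrow(cm) - 1L)) {
      m1 <- cm$marker[[i]]; m2 <- cm$marker[[i + 1L]]
      fams1 <- nulls$family[nulls$marker == m1]
      shared_fams <- intersect(fams1, nulls$family[nulls$marker == m2])
      if (length(shared_fams) == 0L) next
      support <- list()
      for (f in shared_fams) {
        h1 <- nulls$hypotheses[[match(paste(m1, f), key)]]
        h2 <- nulls$hypotheses[[match(paste(m2, f), key)]]
        best <- linked_support(h1, h2, min_f2_carriers)
        if (!is.null(best)) {
          support[[f]] <- c(best, list(
            classes = c(nulls$category[nulls$marker == m1 & nulls$family == f],
                        nulls$category[nulls$marker == m2 & nulls$family == f])))
        }
      }
      if (length(support) == 0L) next
      calls[[length(calls) + 1L]] <- tibble::tibble(
        chrom = chr, marker1 = m1, marker2 = m2,
        pos1 = cm$pos[[i]], pos2 = cm$pos[[i + 1L]],
        size_kb = (cm$pos[[i + 1L]] - cm$pos[[i]]) / 1000,
        families = list(names(support)),
        carrier_parents = list(sort(unique(unlist(
          lapply(support, `[[`, "parents"))))),
        shared_f2 = list(sort(unique(unlist(
          lapply(support, `[[`, "carriers"))))),
        classes = list(sort(unique(unlist(
          lapply(support, `[[`, "classes"))))))
    }
  }
  if (length(calls) == 0L) {
    out <- tibble::tibble(region = integer(), chrom = character(),
                          marker1 = character(), marker2 = character(),
                          pos1 = integer(), pos2 = integer(),
                          size_kb = double(), families = list(),
                          carrier_parents = list(), shared_f2 = list(),
                          classes = list(), run = logical())
    class(out) <- c("deletion_calls", class(out))
    return(out)
  }
  out <- dplyr::bind_rows(calls) |>
    dplyr::arrange(.data$chrom, .data$pos1) |>
    dplyr::mutate(region = dplyr::row_number(), .before = 1L)
  # overlapping pairwise calls (three or more linked markers) are flagged,
  # not merged
  out$run <- vapply(seq_len(nrow(out)), function(i) {
    any(out$chrom == out$chrom[[i]] &
          (out$marker1 == out$marker2[[i]] | out$marker2 == out$marker1[[i]]))
  }, logical(1))
  class(out) <- c("deletion_calls", class(out))
  out
}

# strongest family-level link between two markers' hypothesis sets: a shared
# carrier parent plus enough shared putative F2 carriers
linked_support <- function(h1, h2, min_f2_carriers) {
  best <- NULL
  for (a in h1) {
    pa <- a$states$parent[a$states$type != "none"]
    for (b in h2) {
      pb <- b$states$parent[b$states$type != "none"]
      shared_p <- intersect(pa, pb)
      if (length(shared_p) == 0L) next
      shared_f2 <- intersect(a$f2_carriers, b$f2_carriers)
      if (length(shared_f2) < min_f2_carriers) next
      if (is.null(best) || length(shared_f2) > length(best$carriers)) {
        best <- list(parents = shared_p, carriers = shared_f2)
      }
    }
  }
  best
}

#' Write deletion calls as BED and TSV
#'
#' The BED file uses 0-based half-open coordinates spanning the two markers;
#' the TSV reports the full call table with sizes in kb to one decimal.
#'
#' @param calls A [call_deletions()] result.
#' @param bed_path,tsv_path Output paths (`NULL` to skip either).
#' @return Invisibly, `calls`.
#' @export
write_regions <- function(calls, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    lines <- sprintf("%s\t%d\t%d\tregion%d", calls$chrom,
                     calls$pos1 - 1L, calls$pos2, calls$region)
    writeLines(lines, bed_path)
  }
  if (!is.null(tsv_path)) {
    flat <- dplyr::mutate(
      calls,
      snps = paste(.data$marker1, .data$marker2, sep = ","),
      size_kb = round(.data$size_kb, 1),
      dplyr::across(c("families", "carrier_parents", "shared_f2", "classes"),
                    ~ vapply(.x, paste, character(1), collapse = ","))) |>
      dplyr::select("region", "chrom", "snps", "classes", "pos1", "pos2",
                    "size_kb", "families", "carrier_parents", "shared_f2")
    readr::write_tsv(flat, tsv_path, progress = FALSE)
  }
  invisible(calls)
}
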