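#' Read SNP genotypes from PED/MAP files
#'
#' Reads a whitespace-delimited PED file (one row per individual: the
#' individual id followed by two allele columns per marker, in map order)
#' together with its MAP file (one row per marker: chromosome, marker id,
#' base-pair position). Allele codes are `1` and `2`; `0` marks a missing
#' allele and a call with either allele missing is treated as fully missing
#' (the assays report either a complete genotype or none).
#'
#' @param ped_path Path to the PED file.
#' @param map_path Path to the MAP file.
#' @return A tibble with one row per (marker, individual) call and columns
#'   `marker`, `chrom`, `pos`, `individual`, `a1`, `a2`. Missing calls carry
#'   `NA` alleles; called genotypes are normalised so `a1 <= a2`.
#' @seealso [read_genotypes_long()], [write_genotypes()]
#' @export
#' @examples
#' ped <- tempfile(); map <- tempfile()
#' writeLines(c("1 snp1 1000", "1 snp2 2000"), map)
#' writeLines(c("F2_01 1 1 1 2", "F2_02 0 0 2 2"), ped)
#' read_genotypes(ped, map)
read_genotypes <- function(ped_path, map_path) {
  map <- read_map(map_path)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n_mark <- nrow(map)
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (length(tok) != 1L + 2L * n_mark) {
      abort(sprintf(
        "PED line %d: expected %d allele columns for %d mapped markers, found %d",
        i, 2L * n_mark, n_mark, length(tok) - 1L))
    }
    al <- suppressWarnings(as.integer(tok[-1L]))
    if (anyNA(al) || any(!al %in% 0:2)) {
      abort(sprintf("PED line %d: allele codes must be 0, 1 or 2", i))
    }
    rows[[i]] <- tibble::tibble(
      marker = map$marker,
      individual = tok[[1L]],
      a1 = al[seq(1L, by = 2L, length.out = n_mark)],
      a2 = al[seq(2L, by = 2L, length.out = n_mark)]
    )
  }
  geno <- dplyr::bind_rows(rows)
  if (nrow(geno) == 0L) {
    geno <- tibble::tibble(marker = character(), individual = character(),
                           a1 = integer(), a2 = integer())
  }
  geno <- normalize_calls(geno)
  dplyr::left_join(map, geno, by = "marker") |>
    dplyr::filter(!is.na(.data$individual)) |>
    dplyr::select("marker", "chrom", "pos", "individual", "a1", "a2")
}

#' Read a marker map
#'
#' Whitespace-delimited, one row per marker: chromosome, marker id, 1-based
#' bp position.
#'
#' @param map_path Path to the MAP file.
#' @return A tibble with columns `marker`, `chrom`, `pos`.
#' @export
read_map <- function(map_path) {
  lines <- readLines(map_path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(seq_along(lines), function(i) {
    tok <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (length(tok) != 3L) {
      abort(sprintf("MAP line %d: expected 3 columns (chrom, marker, pos)", i))
    }
    pos <- suppressWarnings(as.integer(tok[[3L]]))
    if (is.na(pos) || pos < 1L) {
      abort(sprintf("MAP line %d: position must be an integer >= 1", i))
    }
    tibble::tibble(chrom = tok[[1L]], marker = tok[[2L]], pos = pos)
  })
  map <- dplyr::bind_rows(rows)
  if (nrow(map) == 0L) {
    return(tibble::tibble(chrom = character(), marker = character(),
                          pos = integer()))
  }
  if (anyDuplicated(map$marker)) {
    abort(paste0("MAP: duplicated marker ids: ",
                 paste(unique(map$marker[duplicated(map$marker)]),
                       collapse = ", ")))
  }
  dplyr::select(map, "marker", "chrom", "pos")
}

normalize_calls <- function(geno) {
  miss <- is.na(geno$a1) | is.na(geno$a2) | geno$a1 == 0L | geno$a2 == 0L
  lo <- pmin(geno$a1, geno$a2)
  hi <- pmax(geno$a1, geno$a2)
  geno$a1 <- ifelse(miss, NA_integer_, as.integer(lo))
  geno$a2 <- ifelse(miss, NA_integer_, as.integer(hi))
  geno
}

#' Read genotypes from a long-format TSV
#'
#' Reads a tab-separated table with columns `marker`, `individual`, `a1`,
#' `a2` (one row per call). Produces the same tibble as [read_genotypes()] on
#' equivalent content when the marker map is supplied.
#'
#' @param path Path to the TSV file.
#' @param map Optional marker map (tibble with `marker`, `chrom`, `pos`) to
#'   join onto the calls.
#' @return A tibble of calls as in [read_genotypes()] (without `chrom`/`pos`
#'   unless `map` is given).
#' @export
read_genotypes_long <- function(path, map = NULL) {
  geno <- readr::read_tsv(path, col_types = readr::cols(
    marker = readr::col_character(), individual = readr::col_character(),
    a1 = readr::col_integer(), a2 = readr::col_integer()
  ), progress = FALSE)
  geno <- normalize_calls(geno)
  dup <- dplyr::distinct(geno) |>
    dplyr::count(.data$marker, .data$individual) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    abort(paste0("conflicting duplicate calls for: ",
                 paste(dup$marker, dup$individual, sep = "/", collapse = ", ")))
  }
  geno <- dplyr::distinct(geno)
  if (!is.null(map)) {
    geno <- dplyr::left_join(map, geno, by = "marker") |>
      dplyr::filter(!is.na(.data$individual)) |>
      dplyr::select("marker", "chrom", "pos", "individual", "a1", "a2")
  }
  geno
}

#' Write genotypes to PED/MAP files
#'
#' Inverse of [read_genotypes()]: writing a call tibble and re-reading it
#' reproduces the calls exactly. Missing calls are written as `0 0`.
#'
#' @param geno Call tibble with columns `marker`, `individual`, `a1`, `a2`;
#'   `chrom` and `pos` columns are used for the MAP unless `map` is supplied.
#' @param ped_path,map_path Output paths.
#' @param map Optional marker map overriding map columns in `geno`.
#' @return Invisibly, `geno`.
#' @export
write_genotypes <- function(geno, ped_path, map_path, map = NULL) {
  check_geno_tbl(geno)
  if (is.null(map)) {
    if (!all(c("chrom", "pos") %in% names(geno))) {
      abort("`geno` lacks chrom/pos columns; supply `map`")
    }
    map <- dplyr::distinct(geno, .data$marker, .data$chrom, .data$pos)
  }
  map <- dplyr::arrange(map, .data$chrom, .data$pos)
  writeLines(sprintf("%s %s %d", map$chrom, map$marker, map$pos), map_path)
  inds <- unique(geno$individual)
  codes <- geno_code_matrix(geno, markers = map$marker, individuals = inds)
  al <- geno_alleles(as.vector(codes))
  al[is.na(al)] <- 0L
  # interleave a1/a2 per marker, one PED row per individual
  n_mark <- nrow(map)
  ped_lines <- vapply(seq_along(inds), function(j) {
    idx <- (j - 1L) * n_mark + seq_len(n_mark)
    paste(inds[[j]],
          paste(as.vector(rbind(al[idx, 1L], al[idx, 2L])), collapse = " "))
  }, character(1))
  writeLines(ped_lines, ped_path)
  invisible(geno)
}

#' Read a three-generation pedigree
#'
#' Reads a tab-separated pedigree with columns `individual`, `sire`, `dam`,
#' `generation` (one of F0, F1, F2) and `family` (one or more family labels,
#' comma-separated; individuals such as a shared grandfather may belong to
#' several families). Missing parents are encoded as `0`, an empty field or
#' `NA`. The link structure is validated against the generation labels: F2
#' individuals must have F1 parents, F1 individuals F0 parents, and F0
#' individuals no recorded parents.
#'
#' @param path Path to the pedigree TSV.
#' @return A validated pedigree tibble.
#' @seealso [build_families()]
#' @export
read_pedigree <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) {
    return(tibble::tibble(individual = character(), sire = character(),
                          dam = character(), generation = character(),
                          family = character()))
  }
  ped <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("individual", "sire", "dam", "generation", "family")
  if (!all(need %in% names(ped))) {
    abort(paste0("pedigree file must have columns: ",
                 paste(need, collapse = ", ")))
  }
  ped <- dplyr::mutate(ped, dplyr::across(
    c("sire", "dam"), ~ ifelse(.x %in% c("0", "") | is.na(.x), NA_character_, .x)
  ))
  validate_pedigree(ped)
  ped
}

validate_pedigree <- function(pedigree) {
  gen <- setNames(pedigree$generation, pedigree$individual)
  bad_gen <- pedigree$individual[!pedigree$generation %in% c("F0", "F1", "F2")]
  if (length(bad_gen) > 0L) {
    abort(paste0("unknown generation label for: ",
                 paste(bad_gen, collapse = ", ")))
  }
  for (i in seq_len(nrow(pedigree))) {
    id <- pedigree$individual[[i]]
    g <- pedigree$generation[[i]]
    sire <- pedigree$sire[[i]]
    dam <- pedigree$dam[[i]]
    if (g == "F0") {
      if (!is.na(sire) || !is.na(dam)) {
        abort(paste0("F0 individual ", id, " has recorded parents"))
      }
    } else {
      want <- if (g == "F2") "F1" else "F0"
      for (p in c(sire, dam)) {
        if (is.na(p)) {
          abort(paste0(g, " individual ", id, " is missing a ",
                       want, " parent record"))
        }
        if (!p %in% names(gen)) {
          abort(paste0(g, " individual ", id, ": parent ", p,
                       " has no pedigree record"))
        }
        if (gen[[p]] != want) {
          abort(paste0(g, " individual ", id, ": parent ", p,
                       " is not ", want))
        }
      }
    }
  }
  invisible(pedigree)
}

#' Assemble families from a pedigree
#'
#' Groups F2 individuals by family label and resolves each family's two F1
#' parents and their F0 grandparents. Families may share F0 (and in principle
#' F1) individuals; sharing is preserved by reference to the same ids.
#'
#' @param pedigree A pedigree tibble as returned by [read_pedigree()].
#' @return A tibble with one row per family: `family`, `parent1`, `parent2`,
#'   and list-columns `offspring` (F2 ids), `gp1`, `gp2` (each `c(sire, dam)`
#'   of the corresponding parent).
#' @export
build_families <- function(pedigree) {
  validate_pedigree(pedigree)
  f2 <- dplyr::filter(pedigree, .data$generation == "F2")
  if (nrow(f2) == 0L) {
    return(tibble::tibble(family = character(), parent1 = character(),
                          parent2 = character(), offspring = list(),
                          gp1 = list(), gp2 = list()))
  }
  f2 <- tidyr::separate_longer_delim(f2, "family", delim = stringr_comma())
  fams <- split(f2, f2$family)
  rows <- lapply(names(fams), function(lab) {
    ff <- fams[[lab]]
    pp <- unique(paste(ff$sire, ff$dam))
    if (length(pp) != 1L) {
      abort(paste0("family ", lab,
                   ": offspring do not share a single parent pair"))
    }
    p1 <- ff$sire[[1L]]
    p2 <- ff$dam[[1L]]
    gp <- lapply(c(p1, p2), function(p) {
      row <- pedigree[pedigree$individual == p, ]
      c(row$sire[[1L]], row$dam[[1L]])
    })
    tibble::tibble(family = lab, parent1 = p1, parent2 = p2,
                   offspring = list(ff$individual),
                   gp1 = gp[1L], gp2 = gp[2L])
  })
  dplyr::bind_rows(rows) |> dplyr::arrange(.data$family)
}

stringr_comma <- function() stringr::regex(",\\s*")

#' Write a pedigree TSV
#'
#' @param pedigree Pedigree tibble (`individual`, `sire`, `dam`,
#'   `generation`, `family`).
#' @param path Output path.
#' @return Invisibly, `pedigree`.
#' @export
write_pedigree <- function(pedigree, path) {
  out <- dplyr::mutate(pedigree, dplyr::across(
    c("sire", "dam"), ~ ifelse(is.na(.x), "0", .x)
  ))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(pedigree)
}
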