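# Gene-drop simulator for three-generation intercross families.
#
# Emulates the structure of the studied population: a single F0 grandfather
# shared by all families, F0 grandmothers of which one is shared between
# consecutive families, two F1 parents per family, and ~23-25 F2 offspring.
# Null alleles (single markers or multi-marker deletion runs), genotyping
# errors, random missingness and whole-assay failures are injected with a
# recorded truth table.

#' Simulation configuration
#'
#' @param n_families Number of F2 families (default 2).
#' @param n_offspring F2 offspring per family (recycled; default 23 and 25).
#' @param n_markers Number of biallelic markers (default 10150).
#' @param n_chromosomes Autosomes the markers are spread over (default 28).
#' @param null_rate Fraction of markers receiving an injected single-marker
#'   null allele in a random founder haplotype (default 0.03).
#' @param deletion_runs Optional tibble of multi-marker deletion runs:
#'   columns `start` (row index into the sorted map), `length` (number of
#'   consecutive markers), and optionally `carrier` (founder id; random
#'   founder when absent). A run crossing a chromosome boundary is an error.
#' @param error_rate Per-call probability of substituting a different
#'   genotype (default 0.002).
#' @param missing_rate Per-call probability of dropping the call to missing
#'   (default 0.01).
#' @param assay_fail_rate Per-marker probability that the whole assay fails
#'   and every individual is missing (default 0.001).
#' @param seed Integer seed fixing the entire output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_families = 2L, n_offspring = c(23L, 25L),
                       n_markers = 10150L, n_chromosomes = 28L,
                       null_rate = 0.03, deletion_runs = NULL,
                       error_rate = 0.002, missing_rate = 0.01,
                       assay_fail_rate = 0.001, seed = 1L) {
  rates <- c(null_rate, error_rate, missing_rate, assay_fail_rate)
  if (any(rates < 0 | rates > 1)) abort("rates must lie in [0, 1]")
  if (n_families < 1L || n_markers < 0L) abort("invalid population size")
  structure(list(
    n_families = as.integer(n_families),
    n_offspring = rep_len(as.integer(n_offspring), n_families),
    n_markers = as.integer(n_markers),
    n_chromosomes = as.integer(n_chromosomes),
    null_rate = null_rate, deletion_runs = deletion_runs,
    error_rate = error_rate, missing_rate = missing_rate,
    assay_fail_rate = assay_fail_rate, seed = as.integer(seed)
  ), class = "sim_config")
}

sim_pedigree <- function(config) {
  nf <- config$n_families
  gf <- "F0_GF"
  gms <- sprintf("F0_GM%d", seq_len(nf + 1L))
  rows <- list(tibble::tibble(individual = gf, sire = NA_character_,
                              dam = NA_character_, generation = "F0",
                              family = paste(seq_len(nf), collapse = ",")))
  gm_fams <- lapply(seq_len(nf + 1L), function(i) {
    sort(intersect(seq_len(nf), c(i - 1L, i)))
  })
  for (i in seq_len(nf + 1L)) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      individual = gms[[i]], sire = NA_character_, dam = NA_character_,
      generation = "F0", family = paste(gm_fams[[i]], collapse = ","))
  }
  for (f in seq_len(nf)) {
    p <- sprintf("F1_%d%s", f, c("a", "b"))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      individual = p, sire = gf, dam = gms[c(f, f + 1L)],
      generation = "F1", family = as.character(f))
    off <- sprintf("F2_%d_%02d", f, seq_len(config$n_offspring[[f]]))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      individual = off, sire = p[[1L]], dam = p[[2L]],
      generation = "F2", family = as.character(f))
  }
  dplyr::bind_rows(rows)
}

sim_map <- function(config) {
  n <- config$n_markers
  if (n == 0L) {
    return(tibble::tibble(marker = character(), chrom = character(),
                          pos = integer()))
  }
  chrom <- sort(rep_len(seq_len(config$n_chromosomes), n))
  pos <- unlist(lapply(split(seq_len(n), chrom), function(idx) {
    sort(sample.int(2e8L, length(idx)))
  }), use.names = FALSE)
  tibble::tibble(marker = sprintf("snp%05d", seq_len(n)),
                 chrom = as.character(chrom), pos = as.integer(pos))
}

#' Simulate a genotyped three-generation intercross
#'
#' Draws founder genotypes from per-marker allele frequencies, transmits
#' alleles (including injected nulls and deletion runs) by Mendelian
#' segregation through the shared-grandfather pedigree, applies the
#' observation model ([observe_genotypes()]) and then genotyping noise, and
#' records the full truth.
#'
#' Deletion runs are transmitted as one linked haplotype block: a single
#' segregation draw per meiosis covers all markers of the run (the regions
#' of interest are far smaller than typical recombination distances at this
#' family size). All other markers segregate independently.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return A list of class `intercross_sim`: `geno` (observed call tibble
#'   with map columns), `pedigree`, `map`, and `truth` — itself a list of
#'   `genotypes` (true alleles, 0 = null), `markers` (per-marker mechanism:
#'   none/null/error/assay_failure, and `run_id`), and `runs` (per deletion
#'   run: `run_id`, `marker`, `carrier`).
#' @export
simulate_intercross <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed %||% config$seed)
  pedigree <- sim_pedigree(config)
  map <- sim_map(config)
  n <- config$n_markers
  founders <- pedigree$individual[pedigree$generation == "F0"]
  inds <- pedigree$individual
  A1 <- matrix(0L, n, length(inds), dimnames = list(map$marker, inds))
  A2 <- A1
  freq <- runif(n, 0.1, 0.9)
  for (f0 in founders) {
    A1[, f0] <- ifelse(runif(n) < freq, 1L, 2L)
    A2[, f0] <- ifelse(runif(n) < freq, 1L, 2L)
  }

  # deletion runs: one founder haplotype zeroed across consecutive markers
  runs <- config$deletion_runs
  run_rows <- list()
  run_of_marker <- rep(NA_integer_, n)
  if (!is.null(runs) && nrow(runs) > 0L) {
    for (ri in seq_len(nrow(runs))) {
      idx <- runs$start[[ri]] + seq_len(runs$length[[ri]]) - 1L
      if (any(idx > n) || length(unique(map$chrom[idx])) != 1L) {
        abort(sprintf("deletion run %d falls off the map or crosses a chromosome boundary", ri))
      }
      carrier <- if ("carrier" %in% names(runs) && !is.na(runs$carrier[[ri]])) {
        runs$carrier[[ri]]
      } else {
        sample(founders, 1L)
      }
      if (!carrier %in% founders) {
        abort(sprintf("deletion run %d: carrier %s is not a founder", ri, carrier))
      }
      slot <- sample(1:2, 1L)
      if (slot == 1L) A1[idx, carrier] <- 0L else A2[idx, carrier] <- 0L
      run_of_marker[idx] <- ri
      run_rows[[ri]] <- tibble::tibble(run_id = ri, marker = map$marker[idx],
                                       carrier = carrier)
    }
  }

  # single-marker null injection in random founder haplotypes
  free <- which(is.na(run_of_marker))
  n_null <- min(length(free), round(config$null_rate * n))
  null_idx <- if (n_null > 0L) sort(sample(free, n_null)) else integer()
  for (mi in null_idx) {
    f0 <- sample(founders, 1L)
    if (sample(1:2, 1L) == 1L) A1[mi, f0] <- 0L else A2[mi, f0] <- 0L
  }

  # gene drop: slot 1 is the paternally derived haplotype
  meiosis <- function(parent) {
    pick <- runif(n) < 0.5
    if (!is.null(runs) && nrow(runs) > 0L) {
      for (ri in seq_len(nrow(runs))) {
        idx <- which(run_of_marker == ri)
        pick[idx] <- runif(1) < 0.5
      }
    }
    ifelse(pick, A1[, parent], A2[, parent])
  }
  f1s <- pedigree[pedigree$generation == "F1", ]
  for (i in seq_len(nrow(f1s))) {
    A1[, f1s$individual[[i]]] <- meiosis(f1s$sire[[i]])
    A2[, f1s$individual[[i]]] <- meiosis(f1s$dam[[i]])
  }
  f2s <- pedigree[pedigree$generation == "F2", ]
  for (i in seq_len(nrow(f2s))) {
    A1[, f2s$individual[[i]]] <- meiosis(f2s$sire[[i]])
    A2[, f2s$individual[[i]]] <- meiosis(f2s$dam[[i]])
  }

  truth_geno <- tibble::tibble(
    marker = rep(map$marker, times = length(inds)),
    individual = rep(inds, each = n),
    a1 = as.vector(A1), a2 = as.vector(A2))

  obs <- observe_genotypes(truth_geno)

  # genotyping noise, recorded for the per-marker mechanism labels
  code <- geno_code(obs$a1, obs$a2)
  err <- runif(length(code)) < config$error_rate & code != 0L
  code[err] <- vapply(code[err], function(g) sample(setdiff(1:3, g), 1L),
                      integer(1))
  code[runif(length(code)) < config$missing_rate] <- 0L
  fail <- runif(n) < config$assay_fail_rate
  code[rep(fail, times = length(inds))] <- 0L
  al <- geno_alleles(code)
  geno <- dplyr::mutate(obs, a1 = al[, "a1"], a2 = al[, "a2"])
  geno <- dplyr::left_join(geno, map, by = "marker") |>
    dplyr::select("marker", "chrom", "pos", "individual", "a1", "a2")

  err_marker <- unique(truth_geno$marker[err])
  mechanism <- rep("none", n)
  mechanism[map$marker %in% err_marker] <- "error"
  mechanism[fail] <- "assay_failure"
  mechanism[null_idx] <- "null"
  mechanism[!is.na(run_of_marker)] <- "null"
  truth <- list(
    genotypes = truth_geno,
    markers = tibble::tibble(marker = map$marker, mechanism = mechanism,
                             run_id = run_of_marker),
    runs = if (length(run_rows) > 0L) dplyr::bind_rows(run_rows)
           else tibble::tibble(run_id = integer(), marker = character(),
                               carrier = character()))
  structure(list(geno = geno, pedigree = pedigree, map = map, truth = truth),
            class = "intercross_sim")
}

#' Apply the null-allele observation model
#'
#' Maps true genotypes (0 encoding a null allele) to genotype calls: a
#' carrier of one null is called homozygous for its visible allele, a null
#' homozygote is called missing, and ordinary genotypes are called
#' faithfully.
#'
#' @param truth Tibble of true genotypes: `marker`, `individual`, `a1`,
#'   `a2` with 0 for a null allele.
#' @return A call tibble (`NA` alleles for missing).
#' @export
#' @examples
#' observe_genotypes(tibble::tibble(marker = "m", individual = c("x", "y"),
#'                                  a1 = c(1L, 0L), a2 = c(0L, 0L)))
observe_genotypes <- function(truth) {
  check_geno_tbl(truth, "truth")
  a1 <- truth$a1; a2 <- truth$a2
  vis <- pmax(a1, a2)           # the amplifying allele, if any
  both_null <- a1 == 0L & a2 == 0L
  one_null <- xor(a1 == 0L, a2 == 0L)
  out <- truth
  out$a1 <- ifelse(both_null, NA_integer_,
                   ifelse(one_null, vis, pmin(a1, a2)))
  out$a2 <- ifelse(both_null, NA_integer_, vis)
  out
}

#' Add genotyping noise to a call tibble
#'
#' Each called genotype is independently replaced by one of the two other
#' valid genotypes with probability `error_rate`, then every call is set to
#' missing with probability `missing_rate`.
#'
#' @param geno Call tibble.
#' @param error_rate,missing_rate Per-call rates in `[0, 1]`.
#' @param seed Optional seed.
#' @return The noised call tibble.
#' @export
add_noise <- function(geno, error_rate = 0, missing_rate = 0, seed = NULL) {
  check_geno_tbl(geno)
  stopifnot(error_rate >= 0, error_rate <= 1,
            missing_rate >= 0, missing_rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  code <- geno_code(geno$a1, geno$a2)
  err <- runif(length(code)) < error_rate & code != 0L
  code[err] <- vapply(code[err], function(g) sample(setdiff(1:3, g), 1L),
                      integer(1))
  code[runif(length(code)) < missing_rate] <- 0L
  al <- geno_alleles(code)
  geno$a1 <- al[, "a1"]
  geno$a2 <- al[, "a2"]
  geno
}

#' Write / read a simulation truth table
#'
#' One TSV row per (marker, individual) with the true alleles (0 = null),
#' the per-marker mechanism label and deletion run id; markers of a deletion
#' run share a `run_id` and carry the run's founder carrier.
#'
#' @param truth The `truth` element of an [simulate_intercross()] result.
#' @param path Output path.
#' @return `write_truth()` returns `truth` invisibly; `read_truth()` returns
#'   a truth list with the same structure.
#' @export
write_truth <- function(truth, path) {
  flat <- truth$genotypes |>
    dplyr::left_join(truth$markers, by = "marker") |>
    dplyr::left_join(dplyr::distinct(truth$runs, .data$run_id,
                                     .data$carrier),
                     by = "run_id")
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(truth)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  flat <- readr::read_tsv(path, col_types = readr::cols(
    marker = "c", individual = "c", a1 = "i", a2 = "i",
    mechanism = "c", run_id = "i", carrier = "c"), progress = FALSE)
  markers <- dplyr::distinct(flat, .data$marker, .data$mechanism, .data$run_id)
  runs <- flat |>
    dplyr::filter(!is.na(.data$run_id)) |>
    dplyr::distinct(.data$run_id, .data$marker, .data$carrier)
  list(genotypes = dplyr::select(flat, "marker", "individual", "a1", "a2"),
       markers = markers, runs = runs)
}
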