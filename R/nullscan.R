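# Mendelian incompatibility detection and null-allele hypothesis enumeration.
#
# A null allele is a marker allele that fails to amplify: an individual
# carrying one null is called homozygous for its other allele, and a null
# homozygote is called missing. The engine asks, per SNP per family, whether
# the calls in all three generations can be explained by assigning null
# alleles to the F1 parents (at most one null per parental chromosome, so a
# parent is [a,0] or [0,0]), subject to the grandparent filter: a parent may
# carry a null only if one of its F0 parents is called homozygous or missing.

# internal family context from a build_families() row
fam_ctx <- function(fam_row) {
  list(id = fam_row$family,
       p = c(fam_row$parent1, fam_row$parent2),
       off = fam_row$offspring[[1L]],
       gp1 = fam_row$gp1[[1L]],
       gp2 = fam_row$gp2[[1L]])
}

# per-marker genotype codes for one family, from the code matrix
fam_codes <- function(M, fam, marker) {
  list(p = M[marker, fam$p],
       o = M[marker, fam$off],
       gp1 = M[marker, fam$gp1],
       gp2 = M[marker, fam$gp2])
}

incompat_pairs_one <- function(cd, fam) {
  rows <- list()
  g1 <- cd$p[[1L]]; g2 <- cd$p[[2L]]
  add <- function(parent, offspring, level, kind) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      parent = parent, offspring = offspring, level = level, kind = kind)
  }
  for (j in seq_along(cd$o)) {
    o <- cd$o[[j]]
    d1 <- diff_hom(g1, o)
    d2 <- diff_hom(g2, o)
    if (d1) add(fam$p[[1L]], fam$off[[j]], "F1-F2", "different_homozygotes")
    if (d2) add(fam$p[[2L]], fam$off[[j]], "F1-F2", "different_homozygotes")
    if (!d1 && !d2 && !trio_ok(g1, g2, o)) {
      # both parents share the blame (e.g. two identical homozygotes with a
      # heterozygous offspring); attributed to the first parent by convention
      add(fam$p[[1L]], fam$off[[j]], "F1-F2", "other")
    }
  }
  gps <- list(cd$gp1, cd$gp2)
  gp_ids <- list(fam$gp1, fam$gp2)
  for (k in 1:2) {
    gs <- gps[[k]][[1L]]; gd <- gps[[k]][[2L]]
    gk <- cd$p[[k]]
    ds <- diff_hom(gs, gk)
    dd <- diff_hom(gd, gk)
    if (ds) add(gp_ids[[k]][[1L]], fam$p[[k]], "F0-F1", "different_homozygotes")
    if (dd) add(gp_ids[[k]][[2L]], fam$p[[k]], "F0-F1", "different_homozygotes")
    if (!ds && !dd && !trio_ok(gs, gd, gk)) {
      add(gp_ids[[k]][[1L]], fam$p[[k]], "F0-F1", "other")
    }
  }
  if (length(rows) == 0L) {
    tibble::tibble(parent = character(), offspring = character(),
                   level = character(), kind = character())
  } else {
    dplyr::bind_rows(rows)
  }
}

# candidate true states for an F1 parent with observed code g
parent_states <- function(g) {
  states <- list(list(type = "none", vis = NA_integer_))
  if (g == 1L) states <- c(states, list(list(type = "carrier", vis = 1L)))
  if (g == 3L) states <- c(states, list(list(type = "carrier", vis = 2L)))
  if (g == 0L) {
    states <- c(states,
                list(list(type = "carrier", vis = 1L)),
                list(list(type = "carrier", vis = 2L)),
                list(list(type = "twonull", vis = NA_integer_)))
  }
  states
}

state_gametes <- function(state, g) {
  switch(state$type,
         none = if (g == 0L) c(1L, 2L) else ALLELE_SETS[[g + 1L]],
         carrier = c(state$vis, 0L),
         twonull = 0L)
}

# observed code produced by a gamete pair under the observation model:
# a null with a visible allele is called homozygous, two nulls are missing
pair_obs <- function(x, y) {
  if (x == 0L && y == 0L) return(0L)
  if (x == 0L) return(geno_code(y, y))
  if (y == 0L) return(geno_code(x, x))
  geno_code(min(x, y), max(x, y))
}

# can the parent's state be transmitted from its F0 pair, and from which
# grandparent does the null descend (NA when unresolved or no null)?
f0_transmission <- function(state, g, gp_codes, gp_ids) {
  gs <- gp_codes[[1L]]; gd <- gp_codes[[2L]]
  if (state$type == "none") {
    ok <- if (g == 0L) TRUE else trio_ok(gs, gd, g)
    return(list(ok = ok, source = NA_character_))
  }
  if (state$type == "twonull") {
    return(list(ok = hom_or_missing(gs) && hom_or_missing(gd),
                source = NA_character_))
  }
  a <- state$vis
  via_s <- hom_or_missing(gs) && has_allele(gd, a)
  via_d <- hom_or_missing(gd) && has_allele(gs, a)
  src <- if (via_s && !via_d) gp_ids[[1L]]
         else if (via_d && !via_s) gp_ids[[2L]]
         else NA_character_
  list(ok = via_s || via_d, source = src)
}

# check all offspring against the parental gamete sets; returns feasibility
# and which offspring can only be explained through a null gamete
offspring_fit <- function(o_codes, G1, G2) {
  ok <- logical(length(o_codes))
  carrier <- logical(length(o_codes))
  null00 <- (0L %in% G1) && (0L %in% G2)
  for (j in seq_along(o_codes)) {
    o <- o_codes[[j]]
    if (o == 0L) {
      ok[[j]] <- TRUE
      carrier[[j]] <- null00  # missing call readable as a null homozygote
      next
    }
    nullfree <- FALSE; withnull <- FALSE
    for (x in G1) {
      for (y in G2) {
        if (pair_obs(x, y) == o) {
          if (x == 0L || y == 0L) withnull <- TRUE else nullfree <- TRUE
        }
      }
    }
    ok[[j]] <- nullfree || withnull
    carrier[[j]] <- withnull && !nullfree
  }
  list(ok = all(ok), carrier = carrier)
}

enumerate_hypotheses_one <- function(cd, fam) {
  out <- list()
  s1_list <- parent_states(cd$p[[1L]])
  s2_list <- parent_states(cd$p[[2L]])
  for (s1 in s1_list) {
    f0_1 <- f0_transmission(s1, cd$p[[1L]], cd$gp1, fam$gp1)
    if (!f0_1$ok) next
    G1 <- state_gametes(s1, cd$p[[1L]])
    for (s2 in s2_list) {
      if (s1$type == "none" && s2$type == "none") next
      f0_2 <- f0_transmission(s2, cd$p[[2L]], cd$gp2, fam$gp2)
      if (!f0_2$ok) next
      G2 <- state_gametes(s2, cd$p[[2L]])
      fit <- offspring_fit(cd$o, G1, G2)
      if (!fit$ok) next
      states <- tibble::tibble(
        parent = fam$p,
        type = c(s1$type, s2$type),
        visible_allele = c(s1$vis, s2$vis),
        n_nulls = vapply(c(s1$type, s2$type),
                         function(t) switch(t, none = 0L, carrier = 1L,
                                            twonull = 2L),
                         integer(1), USE.NAMES = FALSE),
        gp_source = c(f0_1$source, f0_2$source)
      )
      out[[length(out) + 1L]] <- list(
        states = states,
        f2_carriers = fam$off[fit$carrier]
      )
    }
  }
  out
}

min_edits_one <- function(cd, fam, cap = 3L) {
  ids <- unique(c(fam$gp1, fam$gp2, fam$p, fam$off))
  v <- integer(length(ids))
  names(v) <- ids
  v[fam$gp1] <- cd$gp1; v[fam$gp2] <- cd$gp2
  v[fam$p] <- cd$p; v[fam$off] <- cd$o
  t1 <- c(rep(match(fam$p[[1L]], ids), length(fam$off)),
          match(fam$gp1[[1L]], ids), match(fam$gp2[[1L]], ids))
  t2 <- c(rep(match(fam$p[[2L]], ids), length(fam$off)),
          match(fam$gp1[[2L]], ids), match(fam$gp2[[2L]], ids))
  t3 <- c(match(fam$off, ids), match(fam$p[[1L]], ids), match(fam$p[[2L]], ids))
  consistent <- function(w) all(TRIO_OK[cbind(w[t1] + 1L, w[t2] + 1L, w[t3] + 1L)])
  if (consistent(v)) return(0L)
  # editing a missing call can never remove a conflict (missing acts as a
  # wildcard), so only called genotypes are candidates for substitution
  editable <- which(v > 0L)
  for (k in seq_len(cap)) {
    if (length(editable) < k) break
    combos <- combn(editable, k)
    for (ci in seq_len(ncol(combos))) {
      idx <- combos[, ci]
      opts <- lapply(v[idx], function(g) setdiff(1:3, g))
      grid <- as.matrix(expand.grid(opts, KEEP.OUT.ATTRS = FALSE))
      for (ri in seq_len(nrow(grid))) {
        w <- v
        w[idx] <- as.integer(grid[ri, ])
        if (consistent(w)) return(k)
      }
    }
  }
  cap + 1L
}

# vectorised per-marker incompatibility counts for one family
incompat_counts_matrix <- function(M, fam) {
  P1 <- M[, fam$p[[1L]]]; P2 <- M[, fam$p[[2L]]]
  O <- M[, fam$off, drop = FALSE]
  dh1 <- (P1 %in% c(1L, 3L)) & (O == (4L - P1))
  dh2 <- (P2 %in% c(1L, 3L)) & (O == (4L - P2))
  tri <- matrix(trio_ok(rep(P1, ncol(O)), rep(P2, ncol(O)), as.vector(O)),
                nrow = nrow(O))
  oth <- !dh1 & !dh2 & !tri
  n_dh <- rowSums(dh1) + rowSums(dh2)
  n_oth <- rowSums(oth)
  gps <- list(fam$gp1, fam$gp2)
  for (k in 1:2) {
    gs <- M[, gps[[k]][[1L]]]; gd <- M[, gps[[k]][[2L]]]
    gk <- M[, fam$p[[k]]]
    ds <- (gs %in% c(1L, 3L)) & (gk == (4L - gs))
    dd <- (gd %in% c(1L, 3L)) & (gk == (4L - gd))
    oo <- !ds & !dd & !trio_ok(gs, gd, gk)
    n_dh <- n_dh + ds + dd
    n_oth <- n_oth + oo
  }
  list(n_incompat = n_dh + n_oth, n_diffhom = n_dh)
}

#' Find Mendelian incompatibilities
#'
#' Scans every marker and family for parent-offspring genotype pairs that
#' violate Mendelian transmission, at both the F1-F2 and the F0-F1 level.
#' One incompatibility is one (parent, offspring) pair at one marker; an
#' offspring conflicting with both parents therefore counts twice. Missing
#' calls never generate incompatibilities. Pairs called homozygous for
#' different alleles are flagged `different_homozygotes`; violations that
#' only emerge at the trio level are flagged `other`.
#'
#' @param geno Call tibble (`marker`, `individual`, `a1`, `a2`).
#' @param pedigree Pedigree tibble (see [read_pedigree()]).
#' @param markers Optional character vector restricting the scan.
#' @return A tibble with columns `marker`, `family`, `parent`, `offspring`,
#'   `level` (`"F1-F2"` or `"F0-F1"`) and `kind`.
#' @export
find_incompatibilities <- function(geno, pedigree, markers = NULL) {
  fams <- build_families(pedigree)
  markers <- markers %||% unique(geno$marker)
  M <- geno_code_matrix(geno, markers = markers,
                        individuals = union(unique(geno$individual),
                                            pedigree$individual))
  out <- list()
  for (i in seq_len(nrow(fams))) {
    fam <- fam_ctx(fams[i, ])
    counts <- incompat_counts_matrix(M, fam)
    hot <- markers[counts$n_incompat > 0L]
    for (m in hot) {
      rows <- incompat_pairs_one(fam_codes(M, fam, m), fam)
      rows$marker <- m
      rows$family <- fam$id
      out[[length(out) + 1L]] <- rows
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(marker = character(), family = character(),
                          parent = character(), offspring = character(),
                          level = character(), kind = character()))
  }
  dplyr::bind_rows(out) |>
    dplyr::select("marker", "family", "parent", "offspring", "level", "kind")
}

#' Enumerate null-allele hypotheses for one SNP in one family
#'
#' Lists every assignment of null alleles to the family's F1 parents (a
#' parent may carry one null alongside its visible allele, or two nulls)
#' that reproduces all observed calls in the three generations under the
#' observation model and passes the grandparent filter. An empty result
#' means the marker is not explainable by null alleles alone.
#'
#' @inheritParams find_incompatibilities
#' @param marker Marker id.
#' @param family Family label (defaults to the only family in the pedigree).
#' @return A tibble with one row per carrier parent per hypothesis:
#'   `hypothesis` (integer id), `parent`, `n_nulls` (1 or 2),
#'   `visible_allele` (`NA` for a null homozygote), `gp_source` (the F0
#'   individual the null descends from, `NA` when unresolved) and
#'   `f2_carriers` (list-column of putative F2 carrier ids, shared by all
#'   rows of a hypothesis).
#' @export
null_hypotheses <- function(geno, pedigree, marker, family = NULL) {
  fam <- get_family(pedigree, family)
  M <- geno_code_matrix(geno, markers = marker,
                        individuals = union(unique(geno$individual),
                                            pedigree$individual))
  hyps <- enumerate_hypotheses_one(fam_codes(M, fam, marker), fam)
  hypotheses_tbl(hyps)
}

hypotheses_tbl <- function(hyps) {
  if (length(hyps) == 0L) {
    return(tibble::tibble(hypothesis = integer(), parent = character(),
                          n_nulls = integer(), visible_allele = integer(),
                          gp_source = character(), f2_carriers = list()))
  }
  dplyr::bind_rows(lapply(seq_along(hyps), function(i) {
    st <- dplyr::filter(hyps[[i]]$states, .data$type != "none")
    tibble::tibble(hypothesis = i, parent = st$parent, n_nulls = st$n_nulls,
                   visible_allele = st$visible_allele,
                   gp_source = st$gp_source,
                   f2_carriers = rep(list(hyps[[i]]$f2_carriers), nrow(st)))
  }))
}

get_family <- function(pedigree, family = NULL) {
  fams <- build_families(pedigree)
  if (is.null(family)) {
    if (nrow(fams) != 1L) {
      abort("pedigree holds several families; pass `family`")
    }
    return(fam_ctx(fams[1L, ]))
  }
  i <- match(family, fams$family)
  if (is.na(i)) abort(paste0("no family labelled ", family))
  fam_ctx(fams[i, ])
}

#' Minimum genotyping errors explaining a marker's conflicts
#'
#' Breadth-first search for the smallest number of single-genotype
#' substitutions (changing one individual's call to another non-missing
#' genotype; F0 individuals included) that makes the whole three-generation
#' family Mendelian-consistent without invoking null alleles.
#'
#' @inheritParams null_hypotheses
#' @param cap Search depth cap; a return value of `cap + 1` means more than
#'   `cap` edits would be needed.
#' @return An integer: 0 for an already consistent marker.
#' @export
min_error_explanation <- function(geno, pedigree, marker, family = NULL,
                                  cap = 3L) {
  fam <- get_family(pedigree, family)
  M <- geno_code_matrix(geno, markers = marker,
                        individuals = union(unique(geno$individual),
                                            pedigree$individual))
  min_edits_one(fam_codes(M, fam, marker), fam, cap = cap)
}
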