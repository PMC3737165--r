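# Independent brute-force oracles, written against genotype strings and
# explicit allele enumeration (no shared code with the package internals).

# alleles an individual can transmit; missing is uninformative
o_gametes <- function(gt) {
  if (gt == "--") return(c(1L, 2L))
  sort(unique(as.integer(strsplit(gt, "")[[1]])))
}

o_sort_gt <- function(a, b) paste0(min(a, b), max(a, b))

# can offspring `o` arise from parents `s` and `d` (no nulls)?
o_trio_ok <- function(s, d, o) {
  if (o == "--") return(TRUE)
  for (x in o_gametes(s)) {
    for (y in o_gametes(d)) {
      if (o_sort_gt(x, y) == o) return(TRUE)
    }
  }
  FALSE
}

o_diffhom <- function(parent, child) {
  parent %in% c("11", "22") && child %in% c("11", "22") && parent != child
}

# count (parent, offspring) incompatibilities for a single-marker family
# given as a list of genotype strings: p1, p2, off (vector), gp1, gp2
o_incompat_count <- function(fl) {
  n <- 0L
  for (o in fl$off) {
    d1 <- o_diffhom(fl$p1, o)
    d2 <- o_diffhom(fl$p2, o)
    n <- n + d1 + d2
    if (!d1 && !d2 && !o_trio_ok(fl$p1, fl$p2, o)) n <- n + 1L
  }
  for (k in 1:2) {
    gp <- if (k == 1) fl$gp1 else fl$gp2
    pk <- if (k == 1) fl$p1 else fl$p2
    ds <- o_diffhom(gp[1], pk)
    dd <- o_diffhom(gp[2], pk)
    n <- n + ds + dd
    if (!ds && !dd && !o_trio_ok(gp[1], gp[2], pk)) n <- n + 1L
  }
  n
}

# the family is Mendelian-consistent iff every trio passes; individuals are
# named so shared grandparents are edited coherently
o_family_genos <- function(fl) {
  g <- c(G1s = fl$gp1[1], G1d = fl$gp1[2], G2s = fl$gp2[1], G2d = fl$gp2[2],
         P1 = fl$p1, P2 = fl$p2)
  for (i in seq_along(fl$off)) g[[paste0("O", i)]] <- fl$off[i]
  g
}

o_consistent <- function(g, n_off) {
  if (!o_trio_ok(g[["G1s"]], g[["G1d"]], g[["P1"]])) return(FALSE)
  if (!o_trio_ok(g[["G2s"]], g[["G2d"]], g[["P2"]])) return(FALSE)
  for (i in seq_len(n_off)) {
    if (!o_trio_ok(g[["P1"]], g[["P2"]], g[[paste0("O", i)]])) return(FALSE)
  }
  TRUE
}

# minimum number of single-genotype substitutions (to a non-missing call)
# restoring Mendelian consistency, by exhaustive enumeration in edit count
o_min_edits <- function(fl, cap = 3L) {
  g0 <- o_family_genos(fl)
  n_off <- length(fl$off)
  if (o_consistent(g0, n_off)) return(0L)
  editable <- names(g0)[g0 != "--"]
  gts <- c("11", "12", "22")
  for (k in seq_len(cap)) {
    if (length(editable) < k) break
    who <- utils::combn(editable, k, simplify = FALSE)
    for (ids in who) {
      opts <- lapply(ids, function(id) setdiff(gts, g0[[id]]))
      grid <- expand.grid(opts, stringsAsFactors = FALSE)
      for (ri in seq_len(nrow(grid))) {
        g <- g0
        for (j in seq_len(k)) g[[ids[[j]]]] <- grid[ri, j]
        if (o_consistent(g, n_off)) return(k)
      }
    }
  }
  cap + 1L
}

# string-genotype view of a fixture's single marker, for feeding the oracles
fixture_to_list <- function(fx) {
  gt <- function(id) {
    row <- fx$geno[fx$geno$individual == id, ]
    if (is.na(row$a1[1])) "--" else paste0(row$a1[1], row$a2[1])
  }
  off_ids <- fx$pedigree$individual[fx$pedigree$generation == "F2"]
  list(p1 = gt("P1"), p2 = gt("P2"),
       off = vapply(off_ids, gt, character(1)),
       gp1 = c(gt("G1s"), gt("G1d")), gp2 = c(gt("G2s"), gt("G2d")))
}
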