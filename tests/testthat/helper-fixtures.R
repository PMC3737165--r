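# Builders for single-marker family fixtures.
#
# Genotypes are given as strings: "11", "12", "22", or "--" for missing.

g2a <- function(x) {
  lut <- list("--" = c(NA_integer_, NA_integer_),
              "11" = c(1L, 1L), "12" = c(1L, 2L),
              "21" = c(1L, 2L), "22" = c(2L, 2L))
  out <- lut[[x]]
  if (is.null(out)) stop("bad genotype string: ", x)
  out
}

# one family: F0 grandparents G1s/G1d (of P1) and G2s/G2d (of P2), F1 parents
# P1/P2, F2 offspring O1..On; single marker unless `marker` is a vector and
# the genotype arguments are lists (one element per marker)
fam_fixture <- function(p1, p2, off,
                        gp1 = c("11", "11"), gp2 = c("11", "11"),
                        marker = "m1", family = "1",
                        chrom = "1", pos = seq_along(marker) * 1000L) {
  n_off <- if (is.list(off)) length(off[[1]]) else length(off)
  ped <- tibble::tibble(
    individual = c("G1s", "G1d", "G2s", "G2d", "P1", "P2",
                   sprintf("O%02d", seq_len(n_off))),
    sire = c(rep(NA, 4), "G1s", "G2s", rep("P1", n_off)),
    dam = c(rep(NA, 4), "G1d", "G2d", rep("P2", n_off)),
    generation = c(rep("F0", 4), rep("F1", 2), rep("F2", n_off)),
    family = family)
  as_list <- function(x) if (is.list(x)) x else list(x)
  p1 <- as_list(p1); p2 <- as_list(p2); off <- as_list(off)
  gp1 <- as_list(gp1); gp2 <- as_list(gp2)
  rows <- lapply(seq_along(marker), function(m) {
    gts <- c(gp1[[m]], gp2[[m]], p1[[m]], p2[[m]], off[[m]])
    al <- t(vapply(gts, g2a, integer(2)))
    tibble::tibble(marker = marker[[m]],
                   individual = ped$individual[c(1, 2, 3, 4, 5, 6,
                                                 6 + seq_len(n_off))],
                   a1 = al[, 1], a2 = al[, 2])
  })
  geno <- dplyr::bind_rows(rows)
  map <- tibble::tibble(marker = marker, chrom = chrom, pos = pos)
  list(geno = geno, pedigree = ped, map = map)
}

# random single-marker family with 4 F0, 2 F1 and n_off F2, genotypes drawn
# uniformly from all calls (missing included); used for fuzzing
random_fixture <- function(n_off = 6L, p_miss = 0.15) {
  draw <- function(n) {
    sample(c("11", "12", "22", "--"), n, replace = TRUE,
           prob = c((1 - p_miss) / 3, (1 - p_miss) / 3, (1 - p_miss) / 3,
                    p_miss))
  }
  fam_fixture(p1 = draw(1), p2 = draw(1), off = draw(n_off),
              gp1 = draw(2), gp2 = draw(2))
}

# two-family pedigree mirroring the studied population: one shared F0
# grandfather, three grandmothers (one shared), four F1, 23 + 25 F2
paper_pedigree <- function() {
  sim_pedigree_pub(sim_config(n_markers = 0L))
}

sim_pedigree_pub <- function(config) {
  sim <- simulate_intercross(config)
  sim$pedigree
}
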