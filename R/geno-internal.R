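# Internal genotype encoding and Mendelian transmission tables.
#
# A biallelic genotype call is held as an integer code:
#   0 = missing, 1 = hom 1/1, 2 = het 1/2, 3 = hom 2/2.
# The pair is unordered, so (2,1) and (1,2) both map to code 2.

geno_code <- function(a1, a2) {
  code <- rep(NA_integer_, length(a1))
  miss <- is.na(a1) | is.na(a2) | a1 == 0L | a2 == 0L
  code[miss] <- 0L
  code[!miss] <- a1[!miss] + a2[!miss] - 1L  # 1+1-1=1, 1+2-1=2, 2+2-1=3
  code
}

# code -> two allele columns (NA for missing)
geno_alleles <- function(code) {
  a1 <- c(NA_integer_, 1L, 1L, 2L)[code + 1L]
  a2 <- c(NA_integer_, 1L, 2L, 2L)[code + 1L]
  cbind(a1 = a1, a2 = a2)
}

geno_label <- function(code) c("--", "11", "12", "22")[code + 1L]

# gametes transmissible by an ordinary (null-free) genotype code;
# a missing call is uninformative and treated as able to transmit either allele
ALLELE_SETS <- list(c(1L, 2L), 1L, c(1L, 2L), 2L)

has_allele <- function(code, a) {
  code == 0L | vapply(code, function(g) a %in% ALLELE_SETS[[g + 1L]], logical(1))
}

hom_or_missing <- function(code) code %in% c(0L, 1L, 3L)

# trio_ok[p1+1, p2+1, o+1]: can offspring code o arise from parent codes p1, p2
# under ordinary Mendelian transmission, missing calls acting as wildcards?
TRIO_OK <- local({
  arr <- array(FALSE, dim = c(4L, 4L, 4L))
  for (p1 in 0:3) {
    for (p2 in 0:3) {
      for (o in 0:3) {
        if (o == 0L) {
          arr[p1 + 1L, p2 + 1L, o + 1L] <- TRUE
          next
        }
        for (x in ALLELE_SETS[[p1 + 1L]]) {
          for (y in ALLELE_SETS[[p2 + 1L]]) {
            if (geno_code(min(x, y), max(x, y)) == o) {
              arr[p1 + 1L, p2 + 1L, o + 1L] <- TRUE
            }
          }
        }
      }
    }
  }
  arr
})

trio_ok <- function(p1, p2, o) TRIO_OK[cbind(p1 + 1L, p2 + 1L, o + 1L)]

# parent/offspring pairwise conflict: at a biallelic marker this is exactly the
# "different homozygotes" configuration
diff_hom <- function(parent, offspring) {
  parent %in% c(1L, 3L) & offspring %in% c(1L, 3L) & parent != offspring
}

check_geno_tbl <- function(geno, arg = "geno") {
  if (!is.data.frame(geno) ||
      !all(c("marker", "individual", "a1", "a2") %in% names(geno))) {
    abort(paste0("`", arg, "` must be a data frame with columns marker, ",
                 "individual, a1, a2"))
  }
  invisible(geno)
}

# markers x individuals integer code matrix from a long genotype tibble
geno_code_matrix <- function(geno, markers = NULL, individuals = NULL) {
  check_geno_tbl(geno)
  markers <- markers %||% unique(geno$marker)
  individuals <- individuals %||% unique(geno$individual)
  m <- matrix(0L, nrow = length(markers), ncol = length(individuals),
              dimnames = list(markers, individuals))
  keep <- geno$marker %in% markers & geno$individual %in% individuals
  g <- geno[keep, ]
  m[cbind(match(g$marker, markers), match(g$individual, individuals))] <-
    geno_code(g$a1, g$a2)
  m
}
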