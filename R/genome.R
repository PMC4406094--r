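# Genotypes: 22 diallelic loci (2 selected + 20 neutral), Mendelian
# transmission with free recombination, directional mutation at the selected
# loci, symmetric flip mutation at the neutral loci, and the
# Dobzhansky-Muller viability model.
#
# Allele coding: each locus has two unordered allele slots holding 0 or 1.
# Locus 1 carries A (0) / a (1); locus 2 carries b (0) / B (1); neutral loci
# carry arbitrary binary labels. Alleles a and B are the derived,
# jointly-incompatible pair. A population's genotypes are stored as an
# integer array of dimension (individuals, loci, 2).

#' Locus layout and mutation rate
#'
#' @param n_neutral number of neutral diallelic loci (default 20).
#' @param mu mutation rate per allele per transmission (default 0.0005).
#' @return A `dm_loci` list: `n_loci`, `n_neutral`, `selected` (always loci
#'   1 and 2) and `mu`.
#' @export
loci_config <- function(n_neutral = 20, mu = 0.0005) {
  stopifnot(n_neutral >= 0, n_neutral == round(n_neutral),
            mu >= 0, mu <= 1)
  structure(list(n_loci = 2L + as.integer(n_neutral),
                 n_neutral = as.integer(n_neutral),
                 selected = 1:2, mu = mu),
            class = "dm_loci")
}

#' Initial genotypes: monomorphic AAbb, maximally diverse neutral loci
#'
#' Every founder is `AAbb` at the two selected loci; each neutral allele slot
#' is an independent uniform draw from \{0, 1\}, i.e. expected allele
#' frequency 1/2 at every neutral locus. Uses the current R RNG stream.
#'
#' @param n number of individuals.
#' @param loci a `dm_loci`.
#' @return Integer array of dimension `(n, n_loci, 2)`.
#' @export
initial_genotypes <- function(n, loci = loci_config()) {
  stopifnot(n >= 1)
  g <- array(0L, dim = c(n, loci$n_loci, 2L))
  if (loci$n_neutral > 0) {
    g[, -(1:2), ] <- sample(0:1, n * loci$n_neutral * 2L, replace = TRUE)
  }
  g
}

#' Gamete formation under free recombination
#'
#' Each locus transmits one of the parent's two alleles with probability 1/2,
#' independently across loci. Mutation is a separate step
#' ([mutate_gametes()]). Uses the current R RNG stream.
#'
#' @param parent an `n_loci x 2` integer matrix (one individual's genotype).
#' @param n number of gametes to draw.
#' @return Integer matrix `n_loci x n`, one gamete per column.
#' @export
make_gametes <- function(parent, n = 1) {
  L <- nrow(parent)
  pick <- sample(c(1L, 2L), L * n, replace = TRUE)
  matrix(parent[cbind(rep.int(seq_len(L), n), pick)], nrow = L)
}

#' @rdname make_gametes
#' @export
make_gamete <- function(parent) drop(make_gametes(parent, 1))

#' Mutation at transmission
#'
#' Applied per allele with probability `mu`: locus 1 mutates forward only
#' (A to a, never back), locus 2 mutates backward only (b to B, never back),
#' and every neutral allele flips to the other allele (the 2-allele case of
#' the k-allele model). Uses the current R RNG stream.
#'
#' @param gametes integer matrix `n_loci x n` (or a single gamete vector).
#' @param loci a `dm_loci`.
#' @return Object of the same shape with mutations applied.
#' @export
mutate_gametes <- function(gametes, loci = loci_config()) {
  vec <- is.null(dim(gametes))
  g <- if (vec) matrix(gametes, ncol = 1) else gametes
  if (loci$mu > 0) {
    hit <- matrix(runif(length(g)) < loci$mu, nrow(g))
    sel <- row(g) <= 2L
    g[sel & hit & g == 0L] <- 1L          # a and B arise, never revert
    flip <- !sel & hit
    g[flip] <- 1L - g[flip]
  }
  if (vec) drop(g) else g
}

# class index 0..8 = 3 * (#a) + (#B); labels in that internal order
.class_labels_internal <- c("AAbb", "AABb", "AABB",
                            "Aabb", "AaBb", "AaBB",
                            "aabb", "aaBb", "aaBB")

#' Two-locus genotype classes and the Dobzhansky-Muller fitness model
#'
#' `dm_fitness_model()` returns the relative viability of each of the nine
#' two-locus classes. By default the four classes carrying at least one `a`
#' and at least one `B` (`AaBB`, `AaBb`, `aaBB`, `aaBb`) are inviable (0) and
#' the five compatible classes (`AABB`, `AABb`, `AAbb`, `Aabb`, `aabb`) have
#' viability 1; the surfaces are spatially constant.
#'
#' @param incompatible viability of the a/B-carrying classes (default 0).
#' @param compatible viability of the remaining classes (default 1).
#' @return Named numeric vector of length 9 (values in `[0, 1]`).
#' @export
dm_fitness_model <- function(incompatible = 0, compatible = 1) {
  stopifnot(incompatible >= 0, incompatible <= 1,
            compatible >= 0, compatible <= 1)
  a_cnt <- rep(0:2, each = 3)
  B_cnt <- rep(0:2, times = 3)
  w <- ifelse(a_cnt >= 1 & B_cnt >= 1, incompatible, compatible)
  setNames(w, .class_labels_internal)
}

#' @rdname dm_fitness_model
#' @param genotype an `n_loci x 2` genotype matrix.
#' @param model a fitness model from `dm_fitness_model()`.
#' @return `dm_fitness()`: the genotype's relative viability.
#' @examples
#' g <- matrix(0L, 22, 2); g[1, 1] <- 1L; g[2, 1] <- 1L   # AaBb
#' dm_fitness(g)                                           # 0
#' @export
dm_fitness <- function(genotype, model = dm_fitness_model()) {
  a <- sum(genotype[1, ])
  B <- sum(genotype[2, ])
  unname(model[3 * a + B + 1])
}

#' @rdname dm_fitness_model
#' @param geno integer genotype array `(n, n_loci, 2)`.
#' @return `genotype_class()`: character vector of two-locus class labels.
#' @export
genotype_class <- function(geno) {
  a <- geno[, 1, 1] + geno[, 1, 2]
  B <- geno[, 2, 1] + geno[, 2, 2]
  .class_labels_internal[3 * a + B + 1]
}

# counts in the reporting order used throughout the package outputs
.class_labels_report <- c("AABB", "AABb", "AAbb", "AaBB", "AaBb", "Aabb",
                          "aaBB", "aaBb", "aabb")

#' @rdname dm_fitness_model
#' @return `genotype_class_counts()`: named integer vector of the nine class
#'   counts, ordered `AABB, AABb, AAbb, AaBB, AaBb, Aabb, aaBB, aaBb, aabb`.
#' @export
genotype_class_counts <- function(geno) {
  cls <- factor(genotype_class(geno), levels = .class_labels_report)
  table(cls)[.class_labels_report]
}

#' Dump a population's genotypes to CSV
#'
#' One row per individual: `generation,site_id,sex,locus1,locus2,...` with
#' the selected loci written as two-letter genotypes (`"Aa"`, `"bB"`; slot
#' order preserved) and the neutral loci as binary allele pairs (`"01"`).
#'
#' @param pop a `dm_population`.
#' @param path file path.
#' @export
write_genotypes_csv <- function(pop, path) {
  stopifnot(inherits(pop, "dm_population"))
  L <- dim(pop$geno)[2]
  code <- function(l, letters2) {
    paste0(letters2[pop$geno[, l, 1] + 1], letters2[pop$geno[, l, 2] + 1])
  }
  cols <- c(list(code(1, c("A", "a")), code(2, c("b", "B"))),
            lapply(seq_len(L - 2) + 2, function(l) code(l, c("0", "1"))))
  df <- data.frame(generation = pop$generation, site_id = pop$site,
                   sex = pop$sex, cols)
  names(df)[-(1:3)] <- paste0("locus", seq_len(L))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
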