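# Pooled heterozygosity and Wright's F over the neutral loci. All individuals
# are pooled (no subpopulations are defined), so a positive F is a Wahlund-
# style heterozygote deficit caused by spatial substructure.

#' Observed heterozygosity pooled over individuals and loci
#'
#' The fraction of (individual, locus) pairs that are heterozygous, over the
#' requested loci (the 20 neutral loci by default).
#'
#' @param geno integer genotype array `(n, n_loci, 2)`.
#' @param loci integer vector of locus indices; default all but the two
#'   selected loci.
#' @return A proportion in `[0, 1]`.
#' @export
observed_heterozygosity <- function(geno, loci = NULL) {
  if (is.null(loci)) loci <- setdiff(seq_len(dim(geno)[2]), 1:2)
  if (dim(geno)[1] == 0) stop("observed heterozygosity undefined for an empty population")
  mean(geno[, loci, 1, drop = FALSE] != geno[, loci, 2, drop = FALSE])
}

#' Expected heterozygosity pooled over individuals, averaged over loci
#'
#' Per locus, `1 - sum(p_i^2)` from the pooled allele frequencies (for
#' diallelic loci, `2 p (1 - p)`, at most 0.5); the returned value is the
#' mean across the requested loci.
#'
#' @inheritParams observed_heterozygosity
#' @return A proportion in `[0, 0.5]` for diallelic loci.
#' @export
expected_heterozygosity <- function(geno, loci = NULL) {
  if (is.null(loci)) loci <- setdiff(seq_len(dim(geno)[2]), 1:2)
  if (dim(geno)[1] == 0) stop("expected heterozygosity undefined for an empty population")
  p <- (colSums(geno[, loci, 1, drop = FALSE]) +
        colSums(geno[, loci, 2, drop = FALSE])) / (2 * dim(geno)[1])
  mean(2 * p * (1 - p))
}

#' Wright's inbreeding coefficient from pooled heterozygosities
#'
#' `F = 1 - Ho / He`, where `Ho` and `He` are the cross-locus *means* --
#' the ratio of means, not the mean of per-locus ratios. Undefined when
#' `He` is zero (monomorphic loci), which is signalled, never silently 0.
#'
#' @param Ho pooled observed heterozygosity.
#' @param He pooled expected heterozygosity (> 0).
#' @return `F`, at most 1; near 0 for a well-mixed randomly mating
#'   population, increasingly positive under isolation by distance.
#' @export
wright_F <- function(Ho, He) {
  stopifnot(Ho >= 0, He >= 0)
  if (He == 0) stop("F undefined: expected heterozygosity is zero")
  1 - Ho / He
}

#' One-row summary of a population's neutral-locus structure
#'
#' @param geno integer genotype array `(n, n_loci, 2)`.
#' @param loci optional locus indices (default: neutral loci).
#' @return data.frame with `n`, `Ho`, `He`, `F`.
#' @export
neutral_summary <- function(geno, loci = NULL) {
  Ho <- observed_heterozygosity(geno, loci)
  He <- expected_heterozygosity(geno, loci)
  data.frame(n = dim(geno)[1], Ho = Ho, He = He,
             F = if (He > 0) wright_F(Ho, He) else NA_real_)
}
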