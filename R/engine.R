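# Reference implementation of the generation cycle in plain R.
#
# These functions define the per-operation semantics -- truncated
# inverse-square kernel, one mate draw per female with replacement,
# Poisson(lambda) broods, 100% adult mortality, sequential dispersal of
# offspring over vacant sites with viability selection at settlement -- and
# are exercised directly by the unit tests and usable for small landscapes.
# Production runs use the compiled engine (`run_replicate(engine =
# "compiled")`), which implements the same cycle; the test suite cross-checks
# the two on shared invariants and statistics.

#' Truncated inverse-square kernel weights
#'
#' Movement probabilities proportional to `1 / max(d, d_floor)^2` over the
#' candidate set, normalized to sum to one. Candidates beyond the movement
#' limit are excluded upstream by the neighbor index, so the truncation never
#' appears here. The floor regularizes the singularity at distance zero
#' (the natal site) and gives it the largest finite weight.
#'
#' @param distances distances to the candidates (same units as the landscape).
#' @param d_floor positive distance floor; by default half the minimum
#'   site spacing, see [min_site_spacing()].
#' @return Probability vector summing to 1.
#' @export
kernel_weights <- function(distances, d_floor) {
  stopifnot(length(distances) >= 1, d_floor > 0, all(distances >= 0))
  w <- 1 / pmax(distances, d_floor)^2
  w / sum(w)
}

# Population container: parallel vectors over individuals plus the genotype
# array; `site` holds the occupied site ids (at most one individual per site).
new_population <- function(site, sex, geno, generation = 0L) {
  stopifnot(length(site) == length(sex), dim(geno)[1] == length(site),
            !anyDuplicated(site))
  structure(list(site = as.integer(site), sex = as.integer(sex),
                 geno = geno, generation = as.integer(generation)),
            class = "dm_population")
}

#' Founding population on a site map
#'
#' Fills every site with one individual: sex Bernoulli(1/2) (0 = female,
#' 1 = male), genotype from [initial_genotypes()] (`AAbb` plus uniform
#' neutral alleles). Uses the current R RNG stream.
#'
#' @param sites a `dm_sitemap`.
#' @param loci a `dm_loci`.
#' @return A `dm_population`.
#' @export
init_population <- function(sites, loci = loci_config()) {
  n <- nrow(sites)
  new_population(site = sites$site_id,
                 sex = rbinom(n, 1, 0.5),
                 geno = initial_genotypes(n, loci),
                 generation = 0L)
}

#' @export
print.dm_population <- function(x, ...) {
  cat(sprintf("<dm_population> %d individuals (%d female), generation %d\n",
              length(x$site), sum(x$sex == 0), x$generation))
  invisible(x)
}

#' Mate draw for one female
#'
#' Draws one male from the candidates by the inverse-square kernel. Candidates
#' are the living males within the movement limit of the female's site
#' (truncation enforced by the caller via the neighbor index). Males mate
#' with replacement: the same male may be chosen by several females. With no
#' candidate in range the female produces no offspring this generation --
#' a valid outcome, returned as `NA`.
#'
#' @param candidates integer ids of the candidate males' sites.
#' @param distances matching distances from the female's site.
#' @param d_floor kernel distance floor.
#' @return The chosen candidate id, or `NA_integer_` when none is in range.
#' @export
select_mate <- function(candidates, distances, d_floor) {
  if (length(candidates) == 0) return(NA_integer_)
  if (length(candidates) == 1) return(candidates)
  candidates[sample.int(length(candidates), 1,
                        prob = kernel_weights(distances, d_floor))]
}

#' Reproduction: Poisson broods with Mendelian inheritance and mutation
#'
#' Each mated pair draws a brood size from Poisson(`lambda`); every offspring
#' gets one mutated gamete from each parent ([make_gametes()],
#' [mutate_gametes()]), a Bernoulli(1/2) sex, and its mother's site as natal
#' site. Uses the current R RNG stream.
#'
#' @param mothers,fathers positions (row indices) of the paired individuals
#'   in `pop`; equal lengths.
#' @param pop a `dm_population`.
#' @param lambda mean offspring per mated female.
#' @param loci a `dm_loci`.
#' @return Offspring pool: list with `natal` (site ids), `sex`, and `geno`
#'   array `(n_offspring, n_loci, 2)`.
#' @export
reproduce <- function(mothers, fathers, pop, lambda = 4, loci = loci_config()) {
  stopifnot(length(mothers) == length(fathers), lambda >= 0)
  broods <- rpois(length(mothers), lambda)
  total <- sum(broods)
  L <- loci$n_loci
  geno <- array(0L, dim = c(total, L, 2L))
  natal <- integer(total)
  at <- 0L
  for (p in seq_along(mothers)) {
    b <- broods[p]
    if (b == 0) next
    gm <- mutate_gametes(make_gametes(pop$geno[mothers[p], , ], b), loci)
    gf <- mutate_gametes(make_gametes(pop$geno[fathers[p], , ], b), loci)
    rows <- at + seq_len(b)
    geno[rows, , 1] <- t(gm)
    geno[rows, , 2] <- t(gf)
    natal[rows] <- pop$site[mothers[p]]
    at <- at + b
  }
  list(natal = natal, sex = rbinom(total, 1, 0.5), geno = geno)
}

#' Dispersal with viability selection at settlement
#'
#' All adults are already dead (non-overlapping generations), so every site
#' starts vacant. Offspring are processed in uniformly random order; each
#' draws one settlement site by the inverse-square kernel over the *vacant*
#' sites within the movement limit of its natal site (the natal site itself
#' is a candidate, at the distance floor). The settler then survives with
#' probability equal to its genotype's viability; death re-vacates the site
#' for later offspring. Offspring with no vacant site in range are discarded,
#' and processing stops once every site is occupied.
#'
#' @param offspring pool from [reproduce()].
#' @param sites a `dm_sitemap`.
#' @param index a `dm_neighbor_index` built on `sites` at the movement limit.
#' @param fitness a fitness model from [dm_fitness_model()].
#' @param d_floor kernel distance floor.
#' @param generation generation counter for the returned population.
#' @return A `dm_population` (possibly smaller than the site count if the
#'   pool is exhausted; possibly empty).
#' @export
disperse_and_select <- function(offspring, sites, index, fitness = dm_fitness_model(),
                                d_floor = min_site_spacing(sites) / 2,
                                generation = 0L) {
  n_sites <- nrow(sites)
  n_off <- length(offspring$natal)
  vacant <- rep(TRUE, n_sites)
  settled_site <- integer(0)
  settled_row <- integer(0)
  n_occ <- 0L
  for (o in if (n_off > 0) sample.int(n_off) else integer(0)) {
    if (n_occ >= n_sites) break
    natal <- offspring$natal[o]
    nb <- neighbors(index, natal)
    cand <- c(natal, nb$idx)
    dist <- c(0, nb$dist)
    keep <- vacant[cand]
    if (!any(keep)) next
    cand <- cand[keep]; dist <- dist[keep]
    s <- if (length(cand) == 1) cand else
      cand[sample.int(length(cand), 1, prob = kernel_weights(dist, d_floor))]
    w <- dm_fitness(offspring$geno[o, , ], fitness)
    if (w < 1 && !(w > 0 && runif(1) < w)) next   # inviable: site stays vacant
    vacant[s] <- FALSE
    n_occ <- n_occ + 1L
    settled_site <- c(settled_site, s)
    settled_row <- c(settled_row, o)
  }
  new_population(site = settled_site,
                 sex = offspring$sex[settled_row],
                 geno = offspring$geno[settled_row, , , drop = FALSE],
                 generation = generation)
}

#' One full generation of the reference engine
#'
#' Event order: mate selection for every female, reproduction, adult
#' mortality, offspring dispersal with viability selection. Uses the current
#' R RNG stream; with a fixed seed the successor population is bit-identical
#' across runs.
#'
#' @param pop a `dm_population`.
#' @param sites a `dm_sitemap`.
#' @param index a `dm_neighbor_index` at the scenario's movement limit.
#' @param loci a `dm_loci`.
#' @param fitness a fitness model.
#' @param lambda mean brood size.
#' @param d_floor kernel distance floor.
#' @return The next `dm_population` (possibly empty: extinction).
#' @export
step_generation <- function(pop, sites, index, loci = loci_config(),
                            fitness = dm_fitness_model(), lambda = 4,
                            d_floor = min_site_spacing(sites) / 2) {
  occupant <- integer(nrow(sites))        # 0 = vacant, else row in pop
  occupant[pop$site] <- seq_along(pop$site)
  male_at <- logical(nrow(sites))
  male_at[pop$site[pop$sex == 1]] <- TRUE

  mothers <- integer(0); fathers <- integer(0)
  for (f in which(pop$sex == 0)) {
    nb <- neighbors(index, pop$site[f])
    in_range <- male_at[nb$idx]
    m_site <- select_mate(nb$idx[in_range], nb$dist[in_range], d_floor)
    if (is.na(m_site)) next
    mothers <- c(mothers, f)
    fathers <- c(fathers, occupant[m_site])
  }
  off <- reproduce(mothers, fathers, pop, lambda, loci)
  disperse_and_select(off, sites, index, fitness, d_floor,
                      generation = pop$generation + 1L)
}
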