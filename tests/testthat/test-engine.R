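test_that("kernel weights follow the floored inverse-square law", {
  expect_equal(kernel_weights(3.2, d_floor = 0.1), 1)
  expect_equal(kernel_weights(c(2, 2), d_floor = 0.1), c(0.5, 0.5))
  expect_equal(kernel_weights(c(1, 2), d_floor = 0.1), c(0.8, 0.2))
  # distances at or below the floor share the floor weight
  expect_equal(kernel_weights(c(0, 0.05, 0.1), d_floor = 0.1), rep(1 / 3, 3))
  set.seed(1)
  for (i in 1:20) {
    w <- kernel_weights(runif(50, 0, 10), d_floor = 0.01)
    expect_equal(sum(w), 1, tolerance = 1e-12)
  }
})

test_that("mate draw handles empty, singleton and weighted candidate sets", {
  expect_identical(select_mate(integer(0), numeric(0), 0.1), NA_integer_)
  expect_identical(select_mate(7L, 2.5, 0.1), 7L)
  # replacement: the same male can serve repeatedly
  set.seed(2)
  draws <- replicate(200, select_mate(c(3L, 9L), c(1, 2), 0.1))
  expect_setequal(unique(draws), c(3L, 9L))
  expect_equal(mean(draws == 3L), 0.8, tolerance = 0.08)
})

test_that("reproduction is Poisson with Mendelian offspring", {
  sites <- small_landscape(40, seed = 4)
  loci <- loci_config(mu = 0)
  set.seed(3)
  pop <- init_population(sites, loci)

  # AABB mother x aabb father: every offspring is AaBb
  pop$geno[1, 1, ] <- 0L; pop$geno[1, 2, ] <- 1L   # AABB
  pop$sex[1] <- 0L
  pop$geno[2, 1, ] <- 1L; pop$geno[2, 2, ] <- 0L   # aabb
  pop$sex[2] <- 1L
  off <- reproduce(rep(1L, 50), rep(2L, 50), pop, lambda = 4, loci = loci)
  expect_gt(length(off$natal), 0)
  expect_true(all(off$geno[, 1, 1] + off$geno[, 1, 2] == 1L))  # Aa
  expect_true(all(off$geno[, 2, 1] + off$geno[, 2, 2] == 1L))  # Bb
  expect_true(all(off$natal == pop$site[1]))

  # lambda = 0: no offspring
  none <- reproduce(1L, 2L, pop, lambda = 0, loci = loci)
  expect_length(none$natal, 0)

  # 2500 mated females at lambda = 4: pool mean 10000 within 3 sd (= 300)
  set.seed(4)
  total <- sum(rpois(2500, 4))                 # the brood-size model itself
  off2 <- reproduce(rep(1L, 2500), rep(2L, 2500), pop, lambda = 4, loci = loci)
  expect_lt(abs(length(off2$natal) - 10000), 300)
  expect_lt(abs(total - 10000), 300)
})

test_that("dispersal settles offspring on vacant sites and applies viability", {
  sites <- small_landscape(30, seed = 6)
  index <- build_neighbor_index(sites, 10)
  loci <- loci_config(mu = 0)

  # one viable offspring with a vacant site in range settles
  one <- list(natal = 5L, sex = 0L, geno = initial_genotypes(1, loci))
  set.seed(5)
  pop <- disperse_and_select(one, sites, index, generation = 1L)
  expect_length(pop$site, 1)
  expect_true(pop$site %in% c(5L, index$idx[[5]]))

  # a pool made entirely of AaBb offspring leaves the landscape empty
  bad <- initial_genotypes(40, loci)
  bad[, 1, 1] <- 1L; bad[, 2, 1] <- 1L
  pool <- list(natal = rep(5L, 40), sex = rep(0L, 40), geno = bad)
  empty <- disperse_and_select(pool, sites, index, generation = 1L)
  expect_length(empty$site, 0)

  # capacity: more offspring than sites in range fills without duplicates
  many <- list(natal = sample(30, 200, TRUE), sex = rep(0L, 200),
               geno = initial_genotypes(200, loci))
  full <- disperse_and_select(many, sites, index, generation = 1L)
  expect_lte(length(full$site), 30)
  expect_false(anyDuplicated(full$site) > 0)
})

test_that("the reference generation step is deterministic and respects dioecy", {
  sites <- small_landscape(80, seed = 8)
  index <- build_neighbor_index(sites, 8)
  loci <- loci_config()
  set.seed(9); pop <- init_population(sites, loci)
  set.seed(10); a <- step_generation(pop, sites, index, loci)
  set.seed(10); b <- step_generation(pop, sites, index, loci)
  expect_identical(a, b)

  # single-sex population goes extinct in one step
  fem <- pop; fem$sex[] <- 0L
  set.seed(11)
  expect_length(step_generation(fem, sites, index, loci)$site, 0)
})

test_that("no survivor ever carries both a and B (reference engine)", {
  sites <- small_landscape(100, seed = 12)
  index <- build_neighbor_index(sites, 6)
  loci <- loci_config(mu = 0.01)              # fast mutation to stress it
  set.seed(13)
  pop <- init_population(sites, loci)
  for (g in 1:12) {
    pop <- step_generation(pop, sites, index, loci)
    if (length(pop$site) == 0) break
    a <- pop$geno[, 1, 1] + pop$geno[, 1, 2]
    B <- pop$geno[, 2, 1] + pop$geno[, 2, 2]
    expect_false(any(a >= 1 & B >= 1))
    expect_false(anyDuplicated(pop$site) > 0)
    expect_lte(length(pop$site), nrow(sites))
  }
})

test_that("compiled and reference engines agree in law on a small landscape", {
  cfg <- scenario_config(0.3, n_sites = 100, generations = 12, area = 400,
                         max_distance = 30, seed = 14, eps = 1.5)
  sites <- generate_sites(100, cfg$extent, seed = 14)
  comp <- run_replicate(cfg, sites = sites, engine = "compiled")
  ref <- run_replicate(cfg, sites = sites, engine = "reference")
  expect_identical(names(comp$stats), names(ref$stats))
  expect_equal(nrow(comp$stats), 13)
  # both maintain near-capacity populations and the selection invariant
  for (st in list(comp$stats, ref$stats)) {
    expect_true(all(st$n_alive <= 100))
    expect_true(all(st[-1, c("n_AaBB", "n_AaBb", "n_aaBB", "n_aaBb")] == 0))
    expect_true(all(st$n_alive[-1] > 60))     # lambda = 4 keeps sites filled
  }
})

test_that("the compiled engine is reproducible and self-consistent", {
  cfg <- scenario_config(0.3, n_sites = 150, generations = 10, area = 400,
                         max_distance = 30, seed = 15, eps = 1.5)
  sites <- generate_sites(150, cfg$extent, seed = 15)
  r1 <- run_replicate(cfg, sites = sites)
  r2 <- run_replicate(cfg, sites = sites)
  expect_identical(r1$stats, r2$stats)
  expect_identical(r1$population$geno, r2$population$geno)
  # identical CSV bytes for identical (config, seed)
  p1 <- tempfile(); p2 <- tempfile()
  on.exit(unlink(c(p1, p2)))
  write_stats_csv(r1, p1); write_stats_csv(r2, p2)
  expect_identical(readLines(p1), readLines(p2))

  # the engine's final stats row matches the R statistics recomputed from the
  # returned population (dual-route check of Ho, He, F and class counts)
  last <- r1$stats[nrow(r1$stats), ]
  ns <- neutral_summary(r1$population$geno)
  expect_equal(last$n_alive, ns$n)
  expect_equal(last$Ho, ns$Ho)
  expect_equal(last$He, ns$He)
  expect_equal(last$F, ns$F)
  cls <- genotype_class_counts(r1$population$geno)
  expect_equal(unname(unlist(last[paste0("n_", names(cls))])),
               as.vector(unname(cls)))
  # and the RI flag matches the R-side detector on the same snapshot
  ri <- detect_ri_event(r1$population, sites, eps = cfg$eps,
                        minpts = cfg$minpts)
  expect_equal(last$ri_flag, as.integer(ri$ri_event))
  expect_equal(last$n_clusters_AABB, ri$n_clusters_AABB)
  expect_equal(last$n_clusters_aabb, ri$n_clusters_aabb)
})
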