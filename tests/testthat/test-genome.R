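test_that("founders are monomorphic AAbb with balanced neutral alleles", {
  loci <- loci_config()
  set.seed(1)
  g <- initial_genotypes(5000, loci)
  expect_true(all(g[, 1, ] == 0L))            # AA
  expect_true(all(g[, 2, ] == 0L))            # bb
  # each neutral locus: allele frequency within 0.02 of 0.5 (10,000 draws)
  freq <- (colSums(g[, -(1:2), 1]) + colSums(g[, -(1:2), 2])) / 10000
  expect_true(all(abs(freq - 0.5) < 0.02))

  # mutation rate plays no role at initialization
  set.seed(7); a <- initial_genotypes(20, loci_config(mu = 0))
  set.seed(7); b <- initial_genotypes(20, loci_config(mu = 0.5))
  expect_identical(a, b)
})

test_that("gametes obey Mendelian transmission with free recombination", {
  loci <- loci_config(mu = 0)
  hom <- matrix(1L, loci$n_loci, 2)
  expect_true(all(make_gametes(hom, 50) == 1L))

  # heterozygous parent: each allele transmitted half the time
  par <- matrix(0L, loci$n_loci, 2)
  par[, 2] <- 1L
  set.seed(11)
  g <- make_gametes(par, 10000)
  p <- rowMeans(g)
  expect_true(all(abs(p - 0.5) < 0.015))
  # transmission at two heterozygous loci is uncorrelated
  expect_lt(abs(cor(g[1, ], g[2, ])), 0.03)
  # gamete alleles are always drawn from the parent
  mixed <- matrix(c(0L, 1L), loci$n_loci, 2)
  expect_true(all(make_gametes(mixed, 200) %in% c(0L, 1L)))
})

test_that("mutation is directional at selected loci and a flip at neutral loci", {
  loci0 <- loci_config(mu = 0)
  g <- matrix(0L, 22, 10)
  expect_identical(mutate_gametes(g, loci0), g)

  # a and B never revert
  loci_hi <- loci_config(mu = 1)
  gam <- rep(1L, 22)
  out <- mutate_gametes(gam, loci_hi)
  expect_identical(out[1], 1L)
  expect_identical(out[2], 1L)
  expect_true(all(out[3:22] == 0L))           # neutral flip 1 -> 0 at mu = 1
  # and with mu = 1 every wild-type selected allele mutates
  expect_identical(mutate_gametes(rep(0L, 22), loci_hi)[1:2], c(1L, 1L))

  # mu = 0.0005: over 1e6 transmissions of allele A, the a count is within
  # 3 binomial sd of 500
  loci <- loci_config(mu = 0.0005)
  set.seed(21)
  big <- mutate_gametes(matrix(0L, 22, 50000), loci)   # 1.1e6 allele slots
  n_a <- sum(big[1, ])
  expect_lt(abs(n_a - 50000 * 0.0005), 3 * sqrt(50000 * 0.0005))
  transmissions <- 1e6
  hits <- sum(big[3:22, ] == 1L)               # 1e6 neutral transmissions
  expect_lt(abs(hits - transmissions * 0.0005),
            3 * sqrt(transmissions * 0.0005))
})

test_that("Dobzhansky-Muller viability is zero exactly when a and B co-occur", {
  model <- dm_fitness_model()
  for (a in 0:2) for (B in 0:2) {
    g <- matrix(0L, 22, 2)
    if (a > 0) g[1, seq_len(a)] <- 1L
    if (B > 0) g[2, seq_len(B)] <- 1L
    expect_identical(dm_fitness(g, model),
                     if (a >= 1 && B >= 1) 0 else 1)
  }
  # the published assignments, by class label
  expect_identical(unname(model[c("AaBB", "AaBb", "aaBB", "aaBb")]),
                   rep(0, 4))
  expect_identical(unname(model[c("AABB", "AABb", "AAbb", "Aabb", "aabb")]),
                   rep(1, 5))
  # unordered genotypes: Aa is aA
  g1 <- matrix(0L, 22, 2); g1[1, 1] <- 1L; g1[2, 2] <- 1L
  g2 <- matrix(0L, 22, 2); g2[1, 2] <- 1L; g2[2, 1] <- 1L
  expect_identical(dm_fitness(g1), dm_fitness(g2))
})

test_that("genotype dumps use field labels for the selected loci", {
  sites <- small_landscape(10, seed = 91)
  set.seed(92)
  pop <- init_population(sites, loci_config(n_neutral = 2))
  pop$geno[1, 1, 2] <- 1L                     # Aa
  pop$geno[2, 2, ] <- 1L                      # BB
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_genotypes_csv(pop, path)
  df <- read.csv(path, colClasses = "character")
  expect_identical(names(df),
                   c("generation", "site_id", "sex",
                     paste0("locus", 1:4)))
  expect_identical(df$locus1[1], "Aa")
  expect_identical(df$locus2[2], "BB")
  expect_true(all(df$locus1[-1] == "AA"))
  expect_true(all(grepl("^[01]{2}$", df$locus3)))
  expect_equal(nrow(df), 10)
})

test_that("allele frequencies are a martingale under transmission without selection", {
  # fixed parent pool, 200 replicate one-generation transmissions
  loci <- loci_config(mu = 0)
  set.seed(31)
  pool <- initial_genotypes(60, loci)
  locus <- 5
  p0 <- mean(pool[, locus, ])
  freqs <- replicate(200, {
    parents <- sample(60, 60, replace = TRUE)
    gam <- vapply(parents, function(i) make_gamete(pool[i, , ])[locus], 0L)
    mean(gam)
  })
  se <- sqrt(p0 * (1 - p0) / 60)
  expect_lt(abs(mean(freqs) - p0), 3 * se / sqrt(200))
})
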