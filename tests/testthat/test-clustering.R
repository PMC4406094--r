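test_that("DBSCAN base cases follow the core-point definition", {
  # fewer than minpts points: all noise
  out <- dbscan_cluster(c(0, 1, 2), c(0, 0, 0), eps = 5, minpts = 4)
  expect_equal(out$n_clusters, 0)
  expect_true(all(out$labels == 0))
  # empty input
  empty <- dbscan_cluster(numeric(0), numeric(0), eps = 1, minpts = 4)
  expect_equal(empty$n_clusters, 0)
  expect_length(empty$labels, 0)
  # one dense blob of 6 plus a far outlier: one cluster, one noise point
  theta <- seq(0, 2 * pi, length.out = 7)[-7]
  x <- c(cos(theta) * 0.3, 50)
  y <- c(sin(theta) * 0.3, 50)
  out <- dbscan_cluster(x, y, eps = 1, minpts = 4)
  expect_equal(out$n_clusters, 1)
  expect_identical(out$labels, c(rep(1L, 6), 0L))
})

test_that("DBSCAN matches the brute-force reachability oracle", {
  set.seed(61)
  for (case in 1:100) {
    n <- sample(20:300, 1)
    # mixture of uniform background and a few Gaussian clumps
    k <- sample(0:4, 1)
    cx <- runif(k, 0, 50); cy <- runif(k, 0, 50)
    nb <- if (k > 0) rmultinom(1, round(n * 0.6), rep(1, k))[, 1] else integer(0)
    x <- c(runif(n - sum(nb), 0, 50), rnorm(sum(nb), rep(cx, nb), 1))
    y <- c(runif(n - sum(nb), 0, 50), rnorm(sum(nb), rep(cy, nb), 1))
    eps <- runif(1, 0.5, 4)
    minpts <- sample(2:6, 1)
    expect_dbscan_matches_oracle(x, y, eps, minpts)
  }
})

test_that("sorted k-dist curve and knee heuristic behave on known geometry", {
  # equilateral triangle, k = 1: all three 1-dists equal the side
  s <- 2.5
  tri <- rbind(c(0, 0), c(s, 0), c(s / 2, s * sqrt(3) / 2))
  expect_equal(sorted_kdist(tri, k = 1), rep(s, 3))
  expect_error(sorted_kdist(tri, k = 3), "at least")

  # two well-separated dense blobs: suggested eps separates the intra-blob
  # 4-dist scale from the blob separation, so DBSCAN finds exactly 2 clusters
  set.seed(62)
  x <- c(rnorm(50, 0, 0.5), rnorm(50, 30, 0.5))
  y <- c(rnorm(50, 0, 0.5), rnorm(50, 0, 0.5))
  eps_hat <- suggest_epsilon(x, y, k = 4)
  expect_lt(eps_hat, 29)                    # below the blob separation
  out <- dbscan_cluster(x, y, eps = eps_hat, minpts = 4)
  expect_equal(out$n_clusters, 2)
  expect_true(all(out$labels[1:50] == out$labels[1]))
  expect_true(all(out$labels[51:100] == out$labels[51]))
})

test_that("RI events require simultaneous clusters of both pure classes", {
  blob <- function(cx, cy, n = 6) cbind(cx + cos(1:n), cy + sin(1:n))
  a <- blob(0, 0); b <- blob(40, 40)
  # both classes clustered: event, counts (1, 1)
  ev <- ri_event_flag(a, b, eps = 2.5, minpts = 4)
  expect_true(ev$ri_event)
  expect_equal(ev$n_clusters_AABB, 1)
  expect_equal(ev$n_clusters_aabb, 1)
  # no AABB individuals at all: no event
  ev0 <- ri_event_flag(a[0, , drop = FALSE], b, eps = 2.5, minpts = 4)
  expect_false(ev0$ri_event)
  # one class scattered (no cluster): no event
  scat <- cbind(seq(0, 100, length.out = 6), seq(0, 100, length.out = 6))
  expect_false(ri_event_flag(a, scat, eps = 2.5, minpts = 4)$ri_event)
  # symmetry: swapping the two point sets swaps the counts, keeps the flag
  set.seed(63)
  p1 <- cbind(runif(40, 0, 10), runif(40, 0, 10))
  p2 <- cbind(runif(25, 0, 10), runif(25, 0, 10))
  e12 <- ri_event_flag(p1, p2, eps = 1.5, minpts = 4)
  e21 <- ri_event_flag(p2, p1, eps = 1.5, minpts = 4)
  expect_identical(e12$ri_event, e21$ri_event)
  expect_identical(e12$n_clusters_AABB, e21$n_clusters_aabb)
  expect_identical(e12$n_clusters_aabb, e21$n_clusters_AABB)
})

test_that("detect_ri_event reads genotype classes off a population", {
  sites <- small_landscape(60, seed = 64)
  loci <- loci_config(mu = 0)
  set.seed(65)
  pop <- init_population(sites, loci)     # all AAbb: neither class present
  ev <- detect_ri_event(pop, sites, eps = 3, minpts = 4)
  expect_false(ev$ri_event)
  expect_equal(ev$n_clusters_AABB, 0)
  # promote the 10 mutually closest individuals around site 1 to AABB and
  # another local group to aabb
  d <- sqrt((sites$x - sites$x[1])^2 + (sites$y - sites$y[1])^2)
  near1 <- order(d)[1:10]
  d2 <- sqrt((sites$x - max(sites$x))^2 + (sites$y - max(sites$y))^2)
  near2 <- setdiff(order(d2), near1)[1:10]
  pop$geno[near1, 2, ] <- 1L                               # AABB
  pop$geno[near2, 1, ] <- 1L; pop$geno[near2, 2, ] <- 0L   # aabb
  eps <- max(sorted_kdist(cbind(sites$x[near1], sites$y[near1]), k = 4)) + 0.01
  ev2 <- detect_ri_event(pop, sites, eps = eps, minpts = 4)
  expect_gte(ev2$n_clusters_AABB, 1)
})

test_that("event durations are the run lengths of consecutive flags", {
  ev <- event_durations(c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(ev$durations, c(2, 1))
  expect_equal(ev$mean_duration, 1.5)
  expect_equal(ev$max_duration, 2)
  expect_equal(ev$n_flagged, 3)

  none <- event_durations(rep(FALSE, 10))
  expect_equal(none$n_events, 0)
  expect_true(is.na(none$mean_duration))

  all_on <- event_durations(rep(1, 7))
  expect_equal(all_on$durations, 7)

  # conservation: sum of durations equals the flagged-generation count
  set.seed(66)
  for (i in 1:25) {
    flags <- runif(200) < runif(1, 0.05, 0.95)
    ev <- event_durations(flags)
    expect_equal(sum(ev$durations), sum(flags))
    expect_true(all(ev$durations >= 1))
  }
})
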