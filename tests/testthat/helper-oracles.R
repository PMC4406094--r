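# Independent brute-force oracles used to validate the fast implementations.

# O(n^2) all-pairs neighbor lists (ascending neighbor ids), the oracle for
# build_neighbor_index().
oracle_neighbors <- function(sites, radius) {
  D <- as.matrix(dist(cbind(sites$x, sites$y)))
  lapply(seq_len(nrow(sites)), function(i) {
    j <- unname(which(D[i, ] <= radius & seq_len(nrow(sites)) != i))
    list(idx = j, dist = unname(D[i, j]))
  })
}

# Brute-force DBSCAN by explicit density reachability: core points are those
# with >= minpts points (self included) within eps; clusters are connected
# components of core points in the eps-graph; border points attach to a
# reachable core's cluster (any; ties are checked loosely by the comparator).
oracle_dbscan <- function(x, y, eps, minpts) {
  n <- length(x)
  if (n == 0) return(list(labels = integer(0), core = logical(0), n_clusters = 0L))
  D <- as.matrix(dist(cbind(x, y)))
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))   # includes self
  core <- vapply(nb, length, 1L) >= minpts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- i
    while (length(queue) > 0) {
      q <- queue[[1]]
      queue <- queue[-1]
      nxt <- nb[[q]][core[nb[[q]]] & labels[nb[[q]]] == 0L]
      labels[nxt] <- cl
      queue <- c(queue, nxt)
    }
  }
  for (i in which(!core & labels == 0L)) {   # border points
    cs <- nb[[i]][core[nb[[i]]]]
    if (length(cs) > 0) labels[i] <- labels[cs[1]]
  }
  list(labels = labels, core = core, n_clusters = cl)
}

# Equivalence modulo cluster-id permutation and border-point ties:
#  - identical core/noise status per point,
#  - core points partitioned identically (bijective label mapping),
#  - each border point assigned to a cluster containing a core point within eps.
expect_dbscan_matches_oracle <- function(x, y, eps, minpts) {
  impl <- dbscan_cluster(x, y, eps = eps, minpts = minpts)
  ora <- oracle_dbscan(x, y, eps, minpts)
  expect_equal(impl$n_clusters, ora$n_clusters)
  expect_identical(impl$labels == 0L, ora$labels == 0L)
  co <- ora$core
  if (any(co)) {
    # bijection between impl and oracle labels on core points
    key <- paste(impl$labels[co], ora$labels[co])
    expect_equal(length(unique(key)), length(unique(impl$labels[co])))
    expect_equal(length(unique(key)), length(unique(ora$labels[co])))
  }
  border <- !co & impl$labels != 0L
  if (any(border)) {
    D <- as.matrix(dist(cbind(x, y)))
    for (i in which(border)) {
      reachable <- unique(impl$labels[co & D[i, ] <= eps])
      expect_true(impl$labels[i] %in% reachable)
    }
  }
  invisible(impl)
}

# Small test landscape: ~n sites on a 25.6 x 15.6 rectangle (area 400,
# diagonal 30), built fresh from a seed.
small_landscape <- function(n = 120, seed = 42) {
  generate_sites(n, make_extent(400, 30), seed = seed)
}
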