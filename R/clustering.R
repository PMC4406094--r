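# DBSCAN spatial clustering, the sorted k-dist heuristic for choosing eps,
# and the per-generation reproductive-isolation (RI) event statistic.

#' DBSCAN density-based spatial clustering
#'
#' Classical DBSCAN (Ester et al.): a core point has at least `minpts` points
#' -- the point itself included -- within distance `eps`; clusters are the
#' density-reachability closures of core points; border points join the first
#' cluster that reaches them under ascending point-index order (deterministic
#' given input order); remaining points are noise.
#'
#' @param x numeric vector of x coordinates, or a two-column matrix of
#'   points.
#' @param y numeric vector of y coordinates (ignored when `x` is a matrix).
#' @param eps neighborhood radius (> 0), in landscape length-units.
#' @param minpts minimum neighborhood size for a core point (default 4).
#' @return A `dm_dbscan` list: `labels` (0 = noise, clusters numbered from
#'   1 in order of discovery) and `n_clusters`.
#' @export
dbscan_cluster <- function(x, y = NULL, eps, minpts = 4) {
  if (is.matrix(x) || is.data.frame(x)) {
    y <- x[, 2]
    x <- x[, 1]
  }
  stopifnot(length(x) == length(y), eps > 0, minpts >= 1)
  out <- .dbscan_cpp(as.numeric(x), as.numeric(y), eps, as.integer(minpts))
  structure(out, class = "dm_dbscan")
}

#' @export
print.dm_dbscan <- function(x, ...) {
  cat(sprintf("<dm_dbscan> %d points, %d cluster(s), %d noise\n",
              length(x$labels), x$n_clusters, sum(x$labels == 0)))
  invisible(x)
}

#' Sorted k-dist curve and the knee heuristic for eps
#'
#' `sorted_kdist()` returns every point's distance to its k-th nearest other
#' point, sorted in descending order -- the curve inspected to choose the
#' DBSCAN radius. `suggest_epsilon()` places eps at the knee: the maximum
#' discrete second difference of the curve after light moving-average
#' smoothing. The heuristic is advisory; scenario sweeps use a fixed eps for
#' comparability across generations.
#'
#' @param x,y coordinates as in [dbscan_cluster()].
#' @param k neighbor rank (default 4, matching `minpts`).
#' @return `sorted_kdist()`: descending numeric vector of length n.
#' @export
sorted_kdist <- function(x, y = NULL, k = 4) {
  if (is.matrix(x) || is.data.frame(x)) {
    y <- x[, 2]
    x <- x[, 1]
  }
  stopifnot(length(x) == length(y), k >= 1)
  if (length(x) < k + 1) stop("sorted k-dist needs at least k + 1 points")
  sort(.kth_nn_dist_cpp(as.numeric(x), as.numeric(y), as.integer(k)),
       decreasing = TRUE)
}

#' @rdname sorted_kdist
#' @param smooth moving-average window applied before knee detection.
#' @return `suggest_epsilon()`: a single eps value.
#' @export
suggest_epsilon <- function(x, y = NULL, k = 4, smooth = 5) {
  kd <- sorted_kdist(x, y, k)
  if (length(kd) < smooth + 2) return(stats::median(kd))
  sm <- stats::filter(kd, rep(1 / smooth, smooth), sides = 2)
  sm[is.na(sm)] <- kd[is.na(sm)]
  knee <- which.max(diff(diff(sm)))
  kd[knee + 1]
}

#' Per-generation reproductive-isolation event
#'
#' Runs DBSCAN separately on the locations of the `AABB` individuals and on
#' those of the `aabb` individuals; an RI event is flagged when each set
#' contains at least one cluster -- two spatial clusters of mutually
#' incompatible pure genotypes present simultaneously.
#'
#' @param pop a `dm_population`.
#' @param sites the `dm_sitemap` the population lives on.
#' @param eps DBSCAN radius (default 2 landscape units, about 1.6% of the
#'   study landscape's 123.2-unit maximum distance).
#' @param minpts DBSCAN core threshold (default 4).
#' @return List: `ri_event` (logical), `n_clusters_AABB`, `n_clusters_aabb`.
#' @export
detect_ri_event <- function(pop, sites, eps = 2, minpts = 4) {
  cls <- genotype_class(pop$geno)
  xy <- function(keep) cbind(sites$x[pop$site[keep]], sites$y[pop$site[keep]])
  ri_event_flag(xy(cls == "AABB"), xy(cls == "aabb"), eps, minpts)
}

#' @rdname detect_ri_event
#' @param points_AABB,points_aabb two-column coordinate matrices of the two
#'   pure double-homozygote classes.
#' @export
ri_event_flag <- function(points_AABB, points_aabb, eps = 2, minpts = 4) {
  n1 <- if (is.null(points_AABB)) 0 else nrow(points_AABB)
  n2 <- if (is.null(points_aabb)) 0 else nrow(points_aabb)
  c1 <- if (n1 > 0) dbscan_cluster(points_AABB, eps = eps, minpts = minpts)$n_clusters else 0L
  c2 <- if (n2 > 0) dbscan_cluster(points_aabb, eps = eps, minpts = minpts)$n_clusters else 0L
  list(ri_event = c1 >= 1 && c2 >= 1,
       n_clusters_AABB = c1, n_clusters_aabb = c2)
}

#' Run lengths of consecutive RI-event generations
#'
#' Maximal runs of consecutive flagged generations and their lengths. The
#' number of flagged generations equals the sum of the durations; persistence
#' is reported through the durations and does not filter the event count.
#'
#' @param flags logical (or 0/1) vector of per-generation RI flags.
#' @return List: `durations` (lengths of the maximal runs, in generations),
#'   `n_events` (number of runs), `n_flagged` (total flagged generations),
#'   `mean_duration` and `max_duration` (`NA` when there is no event).
#' @export
event_durations <- function(flags) {
  stopifnot(is.logical(flags) || all(flags %in% c(0, 1)))
  flags <- as.logical(flags)
  r <- rle(flags)
  durations <- r$lengths[r$values]
  list(durations = durations,
       n_events = length(durations),
       n_flagged = sum(durations),
       mean_duration = if (length(durations)) mean(durations) else NA_real_,
       max_duration = if (length(durations)) max(durations) else NA_real_)
}
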