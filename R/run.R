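# Scenario configuration, single-replicate runs (compiled or reference
# engine), and the movement-distance sweep with its summary table.

.stats_cols <- c("generation", "n_alive", "Ho", "He", "F",
                 "n_AABB", "n_AABb", "n_AAbb", "n_AaBB", "n_AaBb", "n_Aabb",
                 "n_aaBB", "n_aaBb", "n_aabb",
                 "n_clusters_AABB", "n_clusters_aabb", "ri_flag")

#' Scenario configuration
#'
#' Bundles every parameter of one simulation scenario. The movement fraction
#' scales the landscape's maximum distance (123.2 units for the study
#' landscape) into the truncation radius shared by mate choice and dispersal.
#'
#' @param movement_fraction maximum movement distance as a fraction of the
#'   landscape maximum distance, in (0, 1]. The study sweep uses
#'   2.5, 5, 7.5, 10, 15, 20, 25 and 100%.
#' @param n_sites number of home-range sites (default 5000).
#' @param generations number of non-overlapping generations (default 1000).
#' @param lambda mean offspring per mated female (default 4).
#' @param loci a `dm_loci` (default: 2 selected + 20 neutral, mu = 0.0005).
#' @param fitness a nine-class viability vector from [dm_fitness_model()].
#' @param area landscape area in squared units (default 7237.60).
#' @param max_distance landscape maximum (diagonal) distance (default 123.2).
#' @param eps DBSCAN radius for RI detection (default 2 units).
#' @param minpts DBSCAN core threshold (default 4).
#' @param detect_ri run the RI-event detector every generation (default TRUE).
#' @param seed integer seed; the replicate is fully reproducible from the
#'   configuration and this seed.
#' @return A `dm_scenario` list; `extent` and `dmax` are precomputed.
#' @export
scenario_config <- function(movement_fraction, n_sites = 5000,
                            generations = 1000, lambda = 4,
                            loci = loci_config(), fitness = dm_fitness_model(),
                            area = 7237.60, max_distance = 123.2,
                            eps = 2, minpts = 4, detect_ri = TRUE, seed = 1) {
  stopifnot(movement_fraction > 0, movement_fraction <= 1,
            n_sites >= 1, generations >= 1, lambda >= 0, eps > 0, minpts >= 1)
  structure(list(movement_fraction = movement_fraction,
                 n_sites = as.integer(n_sites),
                 generations = as.integer(generations),
                 lambda = lambda, loci = loci, fitness = fitness,
                 area = area, max_distance = max_distance,
                 extent = make_extent(area, max_distance),
                 dmax = movement_fraction * max_distance,
                 eps = eps, minpts = as.integer(minpts),
                 detect_ri = isTRUE(detect_ri),
                 seed = as.integer(seed)),
            class = "dm_scenario")
}

#' @export
print.dm_scenario <- function(x, ...) {
  cat(sprintf(paste0("<dm_scenario> %d sites, %d generations, movement %.1f%%",
                     " (dmax %.2f), lambda %.1f, mu %.2g, seed %d\n"),
              x$n_sites, x$generations, 100 * x$movement_fraction, x$dmax,
              x$lambda, x$loci$mu, x$seed))
  invisible(x)
}

#' Run one simulation replicate
#'
#' Executes the full generation cycle for a scenario: founding population
#' (`AAbb` at the selected loci, uniform neutral alleles, all sites
#' occupied), then per generation mate selection, Poisson reproduction with
#' Mendelian inheritance and mutation, adult mortality, kernel-weighted
#' dispersal over vacant sites with viability selection, neutral-locus
#' statistics, and (optionally) DBSCAN-based RI detection.
#'
#' The compiled engine carries its own seeded RNG stream, so a replicate is
#' bit-reproducible from `(config, sites)` alone and leaves R's RNG state
#' untouched. The reference engine runs the plain-R operations
#' ([step_generation()] etc.) and is meant for small landscapes.
#'
#' @param config a `dm_scenario`.
#' @param sites optional `dm_sitemap`; by default generated from the
#'   scenario seed. Passing the same `sites` to several replicates keeps the
#'   landscape fixed while demographic stochasticity varies.
#' @param engine `"compiled"` (default) or `"reference"`.
#' @return A `dm_replicate` list: `stats` (one row per generation, columns
#'   `generation, n_alive, Ho, He, F`, the nine genotype-class counts,
#'   `n_clusters_AABB, n_clusters_aabb, ri_flag`), `population` (final
#'   `dm_population`), `status` (`"ok"` or `"extinct"`), `sites`, `config`,
#'   `d_floor`.
#' @export
run_replicate <- function(config, sites = NULL,
                          engine = c("compiled", "reference")) {
  stopifnot(inherits(config, "dm_scenario"))
  engine <- match.arg(engine)
  if (is.null(sites)) {
    sites <- generate_sites(config$n_sites, config$extent, seed = config$seed)
  }
  stopifnot(nrow(sites) == config$n_sites)
  d_floor <- min_site_spacing(sites) / 2
  if (engine == "compiled") {
    res <- .sim_replicate_cpp(sites$x, sites$y, config$dmax, d_floor,
                              config$generations, config$lambda,
                              config$loci$mu, config$loci$n_neutral,
                              unname(config$fitness),
                              config$detect_ri, config$eps, config$minpts,
                              as.double(config$seed))
    stats <- as.data.frame(res$stats)
    names(stats) <- .stats_cols
    L <- config$loci$n_loci
    g <- res$geno
    geno <- array(0L, dim = c(nrow(g), L, 2L))
    geno[, , 1] <- g[, seq(1, 2 * L, by = 2)]
    geno[, , 2] <- g[, seq(2, 2 * L, by = 2)]
    pop <- new_population(res$site, res$sex, geno,
                          generation = stats$generation[nrow(stats)])
    status <- res$status
  } else {
    run <- with_seed(config$seed,
                     run_reference(config, sites, d_floor))
    stats <- run$stats
    pop <- run$pop
    status <- run$status
  }
  structure(list(stats = stats, population = pop, status = status,
                 sites = sites, config = config, d_floor = d_floor),
            class = "dm_replicate")
}

# plain-R generation loop (small landscapes; shares all operation semantics
# with the exported reference functions)
run_reference <- function(config, sites, d_floor) {
  index <- build_neighbor_index(sites, config$dmax)
  pop <- init_population(sites, config$loci)
  rows <- vector("list", config$generations + 1)
  snap <- function(p) {
    n <- length(p$site)
    if (n > 0) {
      ns <- neutral_summary(p$geno)
      cls <- genotype_class_counts(p$geno)
    } else {
      ns <- data.frame(n = 0L, Ho = NA_real_, He = NA_real_, F = NA_real_)
      cls <- setNames(rep(0L, 9), .class_labels_report)
    }
    ri <- if (config$detect_ri && n > 0) {
      detect_ri_event(p, sites, config$eps, config$minpts)
    } else list(ri_event = FALSE, n_clusters_AABB = 0L, n_clusters_aabb = 0L)
    as.data.frame(c(list(generation = p$generation, n_alive = ns$n,
                         Ho = ns$Ho, He = ns$He, F = ns$F),
                    setNames(as.list(as.integer(cls)),
                             paste0("n_", names(cls))),
                    list(n_clusters_AABB = ri$n_clusters_AABB,
                         n_clusters_aabb = ri$n_clusters_aabb,
                         ri_flag = as.integer(ri$ri_event))))
  }
  rows[[1]] <- snap(pop)
  status <- "ok"
  for (g in seq_len(config$generations)) {
    pop <- step_generation(pop, sites, index, config$loci, config$fitness,
                           config$lambda, d_floor)
    rows[[g + 1]] <- snap(pop)
    if (length(pop$site) == 0) {
      status <- "extinct"
      rows <- rows[seq_len(g + 1)]
      break
    }
  }
  list(stats = do.call(rbind, rows), pop = pop, status = status)
}

#' RI events and durations of a finished replicate
#'
#' Applies [event_durations()] to the per-generation RI flags of a
#' replicate's stats table (generation 0, the founding snapshot, excluded).
#'
#' @param stats a `dm_replicate` or its `stats` data.frame.
#' @return See [event_durations()].
#' @export
ri_events_from_stats <- function(stats) {
  if (inherits(stats, "dm_replicate")) stats <- stats$stats
  event_durations(stats$ri_flag[stats$generation > 0] == 1)
}

#' Movement-distance sweep with replicate summaries
#'
#' Runs `replicates` seeded replicates for every movement fraction on one
#' shared landscape (generated once from `base_seed`; replicate r uses seed
#' `base_seed + r`) and summarizes, per scenario: mean count of RI-flagged
#' generations with a normal-theory 95% CI across replicates (mean +/- 1.96
#' SE), mean and maximum RI-event duration (all run lengths pooled across
#' replicates), and final-generation F with CI.
#'
#' @param fractions movement fractions to sweep. The study's full set is
#'   `c(0.025, 0.05, 0.075, 0.10, 0.15, 0.20, 0.25, 1.00)`.
#' @param replicates Monte Carlo replicates per fraction (default 3).
#' @param base_seed integer; seeds the landscape and, offset by the replicate
#'   index, each replicate.
#' @param ... further arguments passed to [scenario_config()]
#'   (e.g. `generations`, `n_sites`, `eps`).
#' @param keep_stats keep each replicate's full per-generation stats table
#'   (default TRUE).
#' @param verbose print one line per finished replicate.
#' @return A `dm_sweep` list: `summary` (one row per fraction) and
#'   `replicates` (per-run details: fraction, seed, status, event
#'   durations, final F, and optionally `stats`).
#' @export
run_sweep <- function(fractions, replicates = 3, base_seed = 1, ...,
                      keep_stats = TRUE, verbose = FALSE) {
  stopifnot(replicates >= 1, all(fractions > 0), all(fractions <= 1))
  if (length(fractions) == 0) {
    return(structure(list(summary = data.frame(), replicates = list()),
                     class = "dm_sweep"))
  }
  cfg0 <- scenario_config(movement_fraction = fractions[1], seed = base_seed, ...)
  sites <- generate_sites(cfg0$n_sites, cfg0$extent, seed = base_seed)
  runs <- list()
  summary_rows <- vector("list", length(fractions))
  for (fi in seq_along(fractions)) {
    f <- fractions[fi]
    n_events <- numeric(replicates)
    f_final <- numeric(replicates)
    durations <- numeric(0)
    for (r in seq_len(replicates)) {
      cfg <- scenario_config(movement_fraction = f, seed = base_seed + r, ...)
      rep_run <- run_replicate(cfg, sites = sites)
      ev <- ri_events_from_stats(rep_run)
      n_events[r] <- ev$n_flagged
      f_final[r] <- rep_run$stats$F[nrow(rep_run$stats)]
      durations <- c(durations, ev$durations)
      runs[[length(runs) + 1]] <- list(
        movement_fraction = f, replicate = r, seed = cfg$seed,
        status = rep_run$status, n_ri_generations = ev$n_flagged,
        durations = ev$durations, F_final = f_final[r],
        stats = if (keep_stats) rep_run$stats)
      if (verbose) {
        message(sprintf("fraction %.3f replicate %d: %d RI generations, F = %.3f",
                        f, r, ev$n_flagged, f_final[r]))
      }
    }
    se_ev <- stats::sd(n_events) / sqrt(replicates)
    se_F <- stats::sd(f_final) / sqrt(replicates)
    summary_rows[[fi]] <- data.frame(
      movement_fraction = f,
      dmax = f * cfg0$max_distance,
      replicates = replicates,
      mean_ri_events = mean(n_events),
      ri_ci_lo = mean(n_events) - 1.96 * se_ev,
      ri_ci_hi = mean(n_events) + 1.96 * se_ev,
      mean_duration = if (length(durations)) mean(durations) else NA_real_,
      max_duration = if (length(durations)) max(durations) else NA_real_,
      F_final_mean = mean(f_final),
      F_ci_lo = mean(f_final) - 1.96 * se_F,
      F_ci_hi = mean(f_final) + 1.96 * se_F)
  }
  structure(list(summary = do.call(rbind, summary_rows), replicates = runs),
            class = "dm_sweep")
}

#' @export
print.dm_sweep <- function(x, ...) {
  cat("<dm_sweep>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Analytic neighborhood-size table
#'
#' For each movement fraction: the truncation radius and the expected number
#' (and proportion) of other individuals within it, `density * pi * r^2`,
#' ignoring edge effects -- the analytic counterpart of the published
#' neighborhood-size table (21 expected mates at 2.5% movement up to the
#' whole population at 100%).
#'
#' @param fractions movement fractions (default: the study's eight).
#' @param n population size (default 5000).
#' @param area landscape area (default 7237.60).
#' @param max_distance landscape maximum distance (default 123.2).
#' @return data.frame: `movement_pct`, `radius`, `expected_neighbors`
#'   (rounded; capped at `n` since at 100% every individual is in range),
#'   `proportion`.
#' @export
neighborhood_table <- function(fractions = c(1, 0.25, 0.20, 0.15, 0.10,
                                             0.075, 0.05, 0.025),
                               n = 5000, area = 7237.60, max_distance = 123.2) {
  density <- n / area
  radius <- fractions * max_distance
  expected <- pmin(round(expected_neighbors(density, radius)), n)
  data.frame(movement_pct = 100 * fractions,
             radius = radius,
             expected_neighbors = expected,
             proportion = round(expected / n, 3))
}

#' Write per-generation statistics to CSV
#'
#' @param x a `dm_replicate` or its `stats` data.frame.
#' @param path file path.
#' @export
write_stats_csv <- function(x, path) {
  if (inherits(x, "dm_replicate")) x <- x$stats
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}
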