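#' Run one simulation and record its time series
#'
#' Seeds the random stream, draws a fresh landscape and founder population,
#' then iterates [step_generation()] for up to `generations` generations
#' (or until extinction), recording per generation the population size, the
#' number of species clusters, the within-cluster diversity, the count of
#' lineage-labeled organisms, the largest per-organism brood size, and -- in
#' competition mode -- the number of distinct mu values still alive, the
#' modal mu and its carrier fraction.
#'
#' @param landscape_cfg A [landscape_config()].
#' @param repro_cfg A [reproduction_config()].
#' @param generations Number of generations to simulate.
#' @param n_init Founder population size (default 300).
#' @param seed Integer seed; when non-`NULL` the whole trajectory is
#'   reproducible bitwise.
#' @param label_founder If `TRUE`, one random founder is labeled and the
#'   label propagates to any offspring with at least one labeled parent.
#' @param measure_clusters,measure_diversity Toggle the cluster count and
#'   diversity measurements (diversity requires clusters). Turning them off
#'   speeds up runs whose analysis needs neither.
#' @param record_mu_every In competition mode, store the full vector of mu
#'   values every this many generations (for histograms). `0` disables.
#' @param mu_breaks In competition mode, histogram break points used for
#'   the per-generation modal-bin statistics (the figure-level observable
#'   of mu dominance). Default 0.05-wide bins on `[0, 1]`.
#' @return An object of class `run_record`: list with `series` (data.frame,
#'   one row per recorded generation), `extinct_at` (generation at which
#'   fewer than two organisms remained, or `NA`), `seed`, `config`,
#'   `mu_snapshots` (competition mode) and `final_organisms`.
#' @export
run_simulation <- function(landscape_cfg = landscape_config(),
                           repro_cfg = reproduction_config(),
                           generations = 300L,
                           n_init = 300L,
                           seed = NULL,
                           label_founder = FALSE,
                           measure_clusters = TRUE,
                           measure_diversity = TRUE,
                           record_mu_every = 10L,
                           mu_breaks = seq(0, 1, by = 0.05)) {
  if (!is.null(seed)) set.seed(seed)
  generations <- as.integer(generations)
  competition <- repro_cfg$competition

  landscape <- new_landscape(init_grid(landscape_cfg), landscape_cfg)
  state <- init_population(n_init, repro_cfg)
  if (label_founder) {
    state$organisms$labeled[sample.int(n_init, 1L)] <- TRUE
  }
  founder_mu <- unique(state$organisms$mu)

  n_rows <- generations + 1L
  series <- data.frame(generation = integer(n_rows), population = integer(n_rows),
                       n_clusters = NA_integer_, diversity = NA_real_,
                       n_labeled = integer(n_rows), max_offspring = NA_integer_)
  if (competition) {
    series$n_distinct_mu <- NA_integer_
    series$modal_mu <- NA_real_
    series$modal_fraction <- NA_real_
    series$modal_bin_left <- NA_real_
    series$modal_bin_fraction <- NA_real_
  }
  mu_snapshots <- list()
  extinct_at <- NA_integer_
  row <- 0L

  for (g in 0:generations) {
    org <- state$organisms
    n <- nrow(org)
    row <- row + 1L
    series$generation[row] <- g
    series$population[row] <- n
    series$n_labeled[row] <- sum(org$labeled)

    if (n < 2L) {
      extinct_at <- g
      break
    }

    neighbors <- nearest_two(org, repro_cfg$extent)
    if (measure_clusters) {
      part <- find_clusters(org, neighbors = neighbors, generation = g,
                            extent = repro_cfg$extent)
      series$n_clusters[row] <- part$n_clusters
      if (measure_diversity) {
        series$diversity[row] <- within_cluster_diversity(part, org)
      }
    }
    if (competition) {
      counts <- tabulate(match(org$mu, founder_mu), nbins = length(founder_mu))
      series$n_distinct_mu[row] <- sum(counts > 0L)
      imax <- which.max(counts)
      series$modal_mu[row] <- founder_mu[imax]
      series$modal_fraction[row] <- counts[imax] / n
      bins <- findInterval(org$mu, mu_breaks, rightmost.closed = TRUE,
                           all.inside = TRUE)
      bcounts <- tabulate(bins, nbins = length(mu_breaks) - 1L)
      bmax <- which.max(bcounts)
      series$modal_bin_left[row] <- mu_breaks[bmax]
      series$modal_bin_fraction[row] <- bcounts[bmax] / n
      if (record_mu_every > 0L && g %% record_mu_every == 0L) {
        mu_snapshots[[as.character(g)]] <- org$mu
      }
    }

    if (g == generations) break

    mates <- org$id[neighbors[, 1]]
    names(mates) <- org$id
    brood <- reproduce(state, landscape, repro_cfg, mates = mates)
    series$max_offspring[row] <- attr(brood, "max_brood", exact = TRUE)
    brood <- random_death(brood, repro_cfg)
    brood <- thin_overcrowded(brood, repro_cfg$overpop_radius)

    gen <- g + 1L
    if (landscape_cfg$mode == "shifting" &&
        gen %% landscape_cfg$lambda_shift == 0L) {
      landscape$grid <- shift_grid(landscape$grid, landscape_cfg)
    } else if (landscape_cfg$mode == "feedback") {
      landscape$grid <- apply_feedback(landscape$grid, brood$x, brood$y,
                                       landscape_cfg)
    }
    state$generation <- gen
    state$organisms <- brood
  }

  structure(list(series = series[seq_len(row), , drop = FALSE],
                 extinct_at = extinct_at,
                 seed = seed,
                 config = list(landscape = landscape_cfg,
                               reproduction = repro_cfg,
                               generations = generations, n_init = n_init),
                 mu_snapshots = mu_snapshots,
                 final_organisms = state$organisms),
            class = "run_record")
}

#' @export
print.run_record <- function(x, ...) {
  s <- x$series
  cat(sprintf("<run_record: %d generations recorded, final population %d%s>\n",
              nrow(s), s$population[nrow(s)],
              if (is.na(x$extinct_at)) "" else
                sprintf(", extinct at generation %d", x$extinct_at)))
  invisible(x)
}

#' Per-run summary statistics
#'
#' Means of population size, cluster count and within-cluster diversity,
#' taken over generations where the population size exceeded zero (so runs
#' ending in extinction still contribute their surviving generations).
#' Undefined diversity entries are skipped.
#'
#' @param x A `run_record` or its `series` data.frame.
#' @return Named list with `mean_population`, `mean_clusters`,
#'   `mean_diversity` (`NA` when nothing is defined).
#' @export
summarize_run <- function(x) {
  series <- if (inherits(x, "run_record")) x$series else x
  alive <- series$population > 0
  if (!any(alive)) {
    return(list(mean_population = NA_real_, mean_clusters = NA_real_,
                mean_diversity = NA_real_))
  }
  mean_or_na <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  list(mean_population = mean(series$population[alive]),
       mean_clusters = mean_or_na(series$n_clusters[alive]),
       mean_diversity = mean_or_na(series$diversity[alive]))
}

#' Correlation between population size and cluster count
#'
#' Pearson correlation between the time series of the population size and
#' the time series of the number of clusters, over generations with
#' positive population. `NA` when fewer than three such generations exist
#' or either series is constant.
#'
#' @param x A `run_record` or its `series` data.frame.
#' @return Correlation coefficient in `[-1, 1]`, or `NA`.
#' @export
population_cluster_correlation <- function(x) {
  series <- if (inherits(x, "run_record")) x$series else x
  ok <- series$population > 0 & !is.na(series$n_clusters)
  p <- series$population[ok]
  k <- series$n_clusters[ok]
  if (length(p) < 3L || sd(p) == 0 || sd(k) == 0) return(NA_real_)
  cor(p, k)
}

#' Lineage trace of a labeled founder
#'
#' For a run started with `label_founder = TRUE`, the per-generation ratio
#' of labeled organisms (descendants of the founder through either parent)
#' to the total population, and its maximum over the run. A ratio of 1
#' means every organism counts the labeled founder among its ancestors.
#'
#' @param record A `run_record` from a labeled run.
#' @return Object of class `lineage_trace`: list with `ratio_series`
#'   (data.frame `generation, ratio`) and `max_ratio`.
#' @export
trace_lineage <- function(record) {
  s <- record$series
  if (sum(s$n_labeled[1]) != 1L)
    stop("run was not started with exactly one labeled founder")
  alive <- s$population > 0
  ratio <- ifelse(alive, s$n_labeled / s$population, 0)
  structure(list(ratio_series = data.frame(generation = s$generation,
                                           ratio = ratio),
                 max_ratio = max(ratio)),
            class = "lineage_trace")
}

#' Histograms of lineage fixation by mutation-size band
#'
#' Bins the maximum labeled-to-total ratios of a set of lineage traces into
#' `breaks`, separately for a low and a high mu band (the reference bands
#' are 0.2--0.35 and 0.36--0.5).
#'
#' @param traces data.frame with columns `mu` and `max_ratio`.
#' @param low_range,high_range Numeric pairs giving the inclusive mu bands.
#' @param breaks Histogram break points on `[0, 1]`.
#' @return List with `low` and `high` histogram count vectors and `breaks`.
#' @export
lineage_histograms <- function(traces,
                               low_range = c(0.2, 0.35),
                               high_range = c(0.36, 0.5),
                               breaks = seq(0, 1, by = 0.1)) {
  bin <- function(v) {
    if (!length(v)) return(integer(length(breaks) - 1L))
    tabulate(findInterval(v, breaks, rightmost.closed = TRUE,
                          all.inside = TRUE),
             nbins = length(breaks) - 1L)
  }
  in_band <- function(range) {
    traces$max_ratio[traces$mu >= range[1] & traces$mu <= range[2]]
  }
  list(low = bin(in_band(low_range)), high = bin(in_band(high_range)),
       breaks = breaks)
}

#' Sweep the maximum mutation size
#'
#' Runs `reps` independently seeded simulations at every mu in `mu_grid`
#' and aggregates the per-run summaries (surviving-generation means of
#' population, clusters, diversity, and the population-cluster correlation)
#' into across-replicate means and standard deviations.
#'
#' @param mu_grid Numeric vector of mu values.
#' @param reps Replicates per mu.
#' @param landscape_cfg,repro_cfg Configurations; `repro_cfg$mu` is
#'   overridden by the grid value.
#' @param generations,n_init Passed to [run_simulation()].
#' @param base_seed Seed for the replicate seed stream.
#' @param measure_diversity Toggle the (relatively costly) diversity
#'   measurement.
#' @return A data.frame of class `sweep_summary`, one row per mu, with
#'   columns `mu, mean_population, sd_population, mean_clusters,
#'   sd_clusters, mean_diversity, sd_diversity, mean_corr, sd_corr,
#'   n_extinct, n_reps`. Replicate seeds are stored in the `run_seeds`
#'   attribute.
#' @export
sweep_mu <- function(mu_grid,
                     reps = 3L,
                     landscape_cfg = landscape_config(),
                     repro_cfg = reproduction_config(),
                     generations = 300L,
                     n_init = 300L,
                     base_seed = 1L,
                     measure_diversity = TRUE) {
  stopifnot(reps >= 1L, length(mu_grid) >= 1L)
  set.seed(base_seed)
  run_seeds <- matrix(sample.int(.Machine$integer.max, length(mu_grid) * reps),
                      nrow = length(mu_grid))

  rows <- lapply(seq_along(mu_grid), function(i) {
    cfg <- repro_cfg
    cfg$mu <- mu_grid[i]
    pop <- clu <- div <- corr <- numeric(reps)
    ext <- logical(reps)
    for (r in seq_len(reps)) {
      rec <- run_simulation(landscape_cfg, cfg, generations, n_init,
                            seed = run_seeds[i, r],
                            measure_diversity = measure_diversity)
      sm <- summarize_run(rec)
      pop[r] <- sm$mean_population
      clu[r] <- sm$mean_clusters
      div[r] <- sm$mean_diversity
      corr[r] <- population_cluster_correlation(rec)
      ext[r] <- !is.na(rec$extinct_at)
    }
    sd0 <- function(v) if (sum(!is.na(v)) < 2L) 0 else sd(v, na.rm = TRUE)
    mn <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    data.frame(mu = mu_grid[i],
               mean_population = mn(pop), sd_population = sd0(pop),
               mean_clusters = mn(clu), sd_clusters = sd0(clu),
               mean_diversity = mn(div), sd_diversity = sd0(div),
               mean_corr = mn(corr), sd_corr = sd0(corr),
               n_extinct = sum(ext), n_reps = reps)
  })
  out <- do.call(rbind, rows)
  attr(out, "run_seeds") <- run_seeds
  class(out) <- c("sweep_summary", "data.frame")
  out
}

#' Mutation size maximizing the mean number of species
#'
#' Returns the mu at which the across-replicate mean cluster count is
#' maximal; ties are broken in favour of the smaller mu. The result carries
#' an `interior` attribute that is `FALSE` when the argmax sits at either
#' end of the grid (no interior maximum resolved).
#'
#' @param summary A [sweep_mu()] result (or any data.frame with `mu` and
#'   `mean_clusters`).
#' @return The optimal mu (numeric scalar) with attribute `interior`.
#' @export
find_optimal_mu <- function(summary) {
  stopifnot(nrow(summary) >= 3L)
  o <- summary[order(summary$mu), ]
  i <- which.max(o$mean_clusters)   # first maximum = smaller mu on ties
  structure(o$mu[i], interior = i > 1L && i < nrow(o))
}

#' Competition among heritable mutation sizes
#'
#' Runs the model with a per-organism heritable mu (founders draw mu ~
#' U(0, 1); each offspring copies one parent's mu, and extinct mu values
#' can never re-emerge) on the shifting landscape with the uniform kernel,
#' and summarizes the fate of the mu distribution: histograms of mu at
#' recorded generations, the modal mu of the final generation, and the
#' generation at which one mu value comes to dominate.
#'
#' Dominance is assessed on the mu histogram (`hist_breaks`, 0.05-wide
#' bins by default): `dominance_generation` is the first generation at
#' which the modal bin's carriers exceed `dominance_threshold` of the
#' population. This is the observable a histogram of the mu distribution
#' shows; the stricter single-exact-value version is reported alongside as
#' `exact_dominance_generation` (with several hundred distinct continuous
#' founder values it is reached only on much longer horizons, long after
#' the histogram has collapsed to one peak).
#'
#' @param generations Number of generations.
#' @param n_init Founder count (default 300).
#' @param seed Integer seed.
#' @param landscape_cfg,repro_cfg Configurations; `repro_cfg$competition`
#'   is forced on.
#' @param record_every Generations between stored mu histograms.
#' @param dominance_threshold Carrier fraction defining dominance
#'   (default 0.5).
#' @param hist_breaks Break points for the mu histograms and the binned
#'   dominance statistic.
#' @return Object of class `competition_summary`: list with
#'   `mu_histograms` (data.frame `generation, mu_bin_left, count`),
#'   `dominant_mu` (modal exact value at the final generation),
#'   `dominance_generation`, `exact_dominance_generation` (`NA` if never
#'   reached), `series` and the underlying `record`.
#' @export
run_competition <- function(generations = 300L,
                            n_init = 300L,
                            seed = NULL,
                            landscape_cfg = landscape_config("shifting"),
                            repro_cfg = reproduction_config(kernel = "uniform",
                                                            competition = TRUE),
                            record_every = 10L,
                            dominance_threshold = 0.5,
                            hist_breaks = seq(0, 1, by = 0.05)) {
  repro_cfg$competition <- TRUE
  rec <- run_simulation(landscape_cfg, repro_cfg, generations, n_init,
                        seed = seed, measure_clusters = FALSE,
                        measure_diversity = FALSE,
                        record_mu_every = record_every,
                        mu_breaks = hist_breaks)
  s <- rec$series

  hists <- lapply(names(rec$mu_snapshots), function(g) {
    v <- rec$mu_snapshots[[g]]
    counts <- tabulate(findInterval(v, hist_breaks, rightmost.closed = TRUE,
                                    all.inside = TRUE),
                       nbins = length(hist_breaks) - 1L)
    data.frame(generation = as.integer(g),
               mu_bin_left = hist_breaks[-length(hist_breaks)],
               count = counts)
  })
  mu_histograms <- if (length(hists)) do.call(rbind, hists) else
    data.frame(generation = integer(), mu_bin_left = numeric(),
               count = integer())

  first_over <- function(frac) {
    hit <- which(!is.na(frac) & frac > dominance_threshold)
    if (length(hit)) s$generation[hit[1]] else NA_integer_
  }
  structure(list(mu_histograms = mu_histograms,
                 dominant_mu = s$modal_mu[nrow(s)],
                 dominance_generation = first_over(s$modal_bin_fraction),
                 exact_dominance_generation = first_over(s$modal_fraction),
                 dominance_threshold = dominance_threshold,
                 series = s,
                 record = rec),
            class = "competition_summary")
}

#' @export
print.competition_summary <- function(x, ...) {
  cat(sprintf("<competition_summary: dominant mu %.4f, dominance (>%d%%) at generation %s>\n",
              x$dominant_mu, round(100 * x$dominance_threshold),
              ifelse(is.na(x$dominance_generation), "never",
                     x$dominance_generation)))
  invisible(x)
}
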