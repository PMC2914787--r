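#' The five reference experiments
#'
#' Maps each named experiment to its (landscape mode, mutation kernel,
#' competition) triple:
#' `exp1_shift_uniform`, `exp2_feedback_uniform`, `exp3_shift_normal`,
#' `exp4_feedback_normal` are mu sweeps; `exp5_competition` evolves a
#' heritable mu on the shifting landscape with uniform mutations.
#'
#' @return data.frame listing the experiment names and their settings.
#' @export
experiment_table <- function() {
  data.frame(
    name = c("exp1_shift_uniform", "exp2_feedback_uniform",
             "exp3_shift_normal", "exp4_feedback_normal",
             "exp5_competition"),
    landscape_mode = c("shifting", "feedback", "shifting", "feedback",
                       "shifting"),
    kernel = c("uniform", "uniform", "normal", "normal", "uniform"),
    competition = c(FALSE, FALSE, FALSE, FALSE, TRUE)
  )
}

#' Build an experiment specification
#'
#' @param name One of the five names in [experiment_table()].
#' @param scale `"paper"` (1000 generations, 5 replicates per mu, full mu
#'   grid: 0.05--1.0 step 0.05 for the uniform kernel, 0.05--1.5 for the
#'   normal kernel, whose transitions sit at larger mu) or `"desk"` (300
#'   generations, 3 replicates, grid thinned twofold) -- a reduced setting
#'   on which the qualitative curves (population rise and plateau, interior
#'   cluster maximum) remain resolvable.
#' @param overrides Named list overriding fields of the spec (`generations`,
#'   `reps`, `mu_grid`, `n_init`, `record_every`).
#' @return Object of class `experiment_spec`.
#' @export
experiment_spec <- function(name, scale = c("desk", "paper"),
                            overrides = list()) {
  scale <- match.arg(scale)
  tab <- experiment_table()
  row <- tab[tab$name == name, ]
  if (nrow(row) != 1L)
    stop("unknown experiment '", name, "'; available: ",
         paste(tab$name, collapse = ", "))
  mu_max <- if (row$kernel == "normal") 1.5 else 1.0
  spec <- list(name = name,
               landscape_mode = row$landscape_mode,
               kernel = row$kernel,
               competition = row$competition,
               scale = scale,
               generations = if (scale == "paper") 1000L else 300L,
               reps = if (scale == "paper") 5L else 3L,
               mu_grid = seq(0.05, mu_max,
                             by = if (scale == "paper") 0.05 else 0.10),
               n_init = 300L,
               record_every = 10L)
  for (nm in names(overrides)) spec[[nm]] <- overrides[[nm]]
  structure(spec, class = "experiment_spec")
}

#' Run a reference experiment end to end
#'
#' Sweeps mu (experiments 1--4) or runs competition replicates (experiment
#' 5) and writes all artifacts -- sweep summary CSV or competition
#' histogram CSV plus per-replicate series, and a JSON sidecar echoing the
#' configuration and seed -- into `out_dir`.
#'
#' @param spec An [experiment_spec()].
#' @param out_dir Output directory (created if needed).
#' @param seed Base seed for the experiment.
#' @param quiet Suppress progress messages.
#' @return (Invisibly) a list of the file paths written plus the in-memory
#'   summary object.
#' @export
run_experiment <- function(spec, out_dir, seed = 1L, quiet = FALSE) {
  stopifnot(inherits(spec, "experiment_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  say <- function(...) if (!quiet) message(...)

  lcfg <- landscape_config(spec$landscape_mode)
  paths <- list()

  if (!spec$competition) {
    rcfg <- reproduction_config(kernel = spec$kernel)
    say(sprintf("%s: sweeping %d mu values x %d reps x %d generations",
                spec$name, length(spec$mu_grid), spec$reps, spec$generations))
    sw <- sweep_mu(spec$mu_grid, spec$reps, lcfg, rcfg,
                   generations = spec$generations, n_init = spec$n_init,
                   base_seed = seed)
    paths$sweep <- file.path(out_dir, paste0(spec$name, "_sweep.csv"))
    write_sweep_summary(sw, paths$sweep)
    result <- sw
  } else {
    say(sprintf("%s: %d competition replicates x %d generations",
                spec$name, spec$reps, spec$generations))
    set.seed(seed)
    run_seeds <- sample.int(.Machine$integer.max, spec$reps)
    result <- lapply(seq_len(spec$reps), function(r) {
      run_competition(generations = spec$generations, n_init = spec$n_init,
                      seed = run_seeds[r], landscape_cfg = lcfg,
                      record_every = spec$record_every)
    })
    hist_df <- do.call(rbind, lapply(seq_along(result), function(r) {
      cbind(replicate = r, result[[r]]$mu_histograms)
    }))
    paths$histograms <- file.path(out_dir, paste0(spec$name, "_mu_histograms.csv"))
    write.csv(hist_df, paths$histograms, row.names = FALSE)
    summary_df <- data.frame(
      replicate = seq_along(result),
      dominant_mu = vapply(result, function(z) z$dominant_mu, numeric(1)),
      dominance_generation = vapply(result, function(z)
        as.integer(z$dominance_generation), integer(1)))
    paths$summary <- file.path(out_dir, paste0(spec$name, "_summary.csv"))
    write.csv(summary_df, paths$summary, row.names = FALSE)
  }

  paths$sidecar <- file.path(out_dir, paste0(spec$name, "_config.json"))
  write_sidecar(c(unclass(spec), list(seed = seed)), paths$sidecar)
  say(sprintf("%s: wrote %s", spec$name,
              paste(basename(unlist(paths)), collapse = ", ")))
  invisible(c(paths, list(result = result)))
}

#' Deterministic micro-fixtures for tests and examples
#'
#' Hand-placed organism configurations with known mating and clustering
#' structure:
#' * `"two-pairs"`: two tight pairs far apart -- one cluster, because the
#'   rank-based second-nearest-neighbour edges bridge any two isolated
#'   pairs.
#' * `"three-triplets"`: three tight triplets, mutually distant -- three
#'   clusters.
#' * `"line-of-five"`: five organisms on a line spaced 0.2 apart --
#'   overcrowded at the 0.25 limit.
#'
#' @param name Fixture name.
#' @return List with `name`, `organisms` and an `expected` list.
#' @export
make_fixture <- function(name) {
  fixtures <- list(
    "two-pairs" = list(
      organisms = new_organisms(1:4,
                                x = c(1.0, 1.2, 20.0, 20.2),
                                y = c(1.0, 1.0, 20.0, 20.0),
                                mu = 0.3),
      expected = list(n_clusters = 1L,
                      mates = c(`1` = 2L, `2` = 1L, `3` = 4L, `4` = 3L))),
    "three-triplets" = list(
      organisms = new_organisms(1:9,
                                x = c(0, 1, 0.5, 30, 31, 30.5, 0, 1, 0.5),
                                y = c(0, 0, 0.8, 0, 0, 0.8, 30, 30, 30.8),
                                mu = 0.3),
      expected = list(n_clusters = 3L)),
    "line-of-five" = list(
      organisms = new_organisms(1:5,
                                x = seq(0, by = 0.2, length.out = 5),
                                y = rep(1, 5),
                                mu = 0.3),
      expected = list(min_spacing = 0.25)))
  fx <- fixtures[[name]]
  if (is.null(fx))
    stop("unknown fixture '", name, "'; available: ",
         paste(names(fixtures), collapse = ", "))
  c(list(name = name), fx)
}
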