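#' Reproduction configuration
#'
#' Parameters governing mating, mutation, random death and overcrowding.
#'
#' @param mu Global maximum mutation size, in trait units: the hard bound on
#'   how far an offspring coordinate may fall outside its parents' range on
#'   each axis. Ignored when `competition = TRUE`, where mu is a heritable
#'   per-organism trait.
#' @param kernel Mutation kernel: `"uniform"` draws each offspring axis
#'   coordinate uniformly over the mu-extended parental interval;
#'   `"normal"` draws the parental midpoint plus a zero-mean normal offset,
#'   truncated (by redraw) to the same interval.
#' @param b Width parameter of the normal kernel. Default 0.1581.
#' @param extent Morphospace side length, trait units. Default 45.
#' @param overpop_radius Overpopulation limit: minimum spacing below which
#'   only one organism may survive. Default 0.25.
#' @param death_fraction_max Upper bound of the per-generation random death
#'   fraction rho ~ U(0, death_fraction_max). Default 0.70.
#' @param competition If `TRUE`, each organism carries its own heritable mu
#'   (founders draw mu ~ U(0, 1); offspring copy one parent's mu at random).
#'
#' @return An object of class `reproduction_config`.
#' @export
reproduction_config <- function(mu = 0.35,
                                kernel = c("uniform", "normal"),
                                b = 0.1581,
                                extent = 45,
                                overpop_radius = 0.25,
                                death_fraction_max = 0.70,
                                competition = FALSE) {
  kernel <- match.arg(kernel)
  stopifnot(mu >= 0, b > 0, extent > 0, overpop_radius > 0,
            death_fraction_max >= 0, death_fraction_max <= 1)
  structure(list(mu = mu, kernel = kernel, b = b, extent = extent,
                 overpop_radius = overpop_radius,
                 death_fraction_max = death_fraction_max,
                 competition = isTRUE(competition)),
            class = "reproduction_config")
}

new_organisms <- function(id, x, y, mu, parent1 = NA_integer_,
                          parent2 = NA_integer_, labeled = FALSE) {
  data.frame(id = as.integer(id), x = x, y = y, mu = mu,
             parent1 = as.integer(parent1), parent2 = as.integer(parent2),
             labeled = labeled)
}

#' Initial population
#'
#' Places `n` founder organisms i.i.d. uniformly over the morphospace. In
#' competition mode each founder additionally draws its own mu ~ U(0, 1);
#' otherwise every organism carries the configured global mu.
#'
#' @param n Number of founders (the reference experiments use 300).
#' @param config A [reproduction_config()].
#' @return An object of class `population_state`: a list with `generation`
#'   (0) and `organisms` (a data.frame with columns `id, x, y, mu, parent1,
#'   parent2, labeled`).
#' @export
init_population <- function(n = 300L, config = reproduction_config()) {
  n <- as.integer(n)
  if (n < 1L) stop("need at least one founder organism")
  x <- runif(n, 0, config$extent)
  y <- runif(n, 0, config$extent)
  mu <- if (config$competition) runif(n, 0, 1) else rep(config$mu, n)
  structure(list(generation = 0L,
                 organisms = new_organisms(seq_len(n), x, y, mu),
                 extinct = FALSE),
            class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("<population_state generation %d: %d organisms%s>\n",
              x$generation, nrow(x$organisms),
              if (isTRUE(x$extinct)) " (extinct)" else ""))
  invisible(x)
}

# Nearest and second-nearest other organism (positions, not ids), ties
# broken by lowest id. Organisms are assumed sorted by id, as produced by
# the package's own constructors; callers with unsorted tables should sort
# first.
nearest_two <- function(organisms, extent = 45) {
  n <- nrow(organisms)
  cell <- max(min(extent / 8, extent / max(1, floor(sqrt(n / 4)))), 0.25)
  nearest_two_cpp(organisms$x, organisms$y, cell)
}

#' Assortative mate assignment
#'
#' Every organism picks the nearest *other* organism in the morphospace and
#' mates with it. The relation need not be symmetric; exact distance ties
#' are broken in favour of the lowest id.
#'
#' @param organisms Organism data.frame (columns `id, x, y`).
#' @param extent Morphospace side length (used to size the spatial hash).
#' @return Integer vector of mate ids, named by organism id.
#' @export
assign_mates <- function(organisms, extent = 45) {
  if (nrow(organisms) < 2L)
    stop("extinction: fewer than two organisms, no mate exists")
  ord <- order(organisms$id)
  o <- organisms[ord, ]
  nn <- nearest_two(o, extent)
  mates <- o$id[nn[, 1]]
  names(mates) <- o$id
  mates[as.character(organisms$id)]
}

# One axis of the uniform kernel: c_b = (min - mu) + r * (span + 2 mu),
# r ~ U(0,1); out-of-bounds coordinates are redrawn up to 100 times, then
# clamped to the morphospace.
draw_axis_uniform <- function(c1, c2, mu, extent) {
  lo <- pmin(c1, c2) - mu
  span <- abs(c1 - c2) + 2 * mu
  out <- lo + runif(length(c1)) * span
  bad <- which(out < 0 | out > extent)
  tries <- 0L
  while (length(bad) && tries < 100L) {
    out[bad] <- lo[bad] + runif(length(bad)) * span[bad]
    bad <- bad[out[bad] < 0 | out[bad] > extent]
    tries <- tries + 1L
  }
  if (length(bad)) out[bad] <- pmin(pmax(out[bad], 0), extent)
  out
}

# One axis of the normal kernel: c_b = midpoint + eps * (span + 2 mu),
# eps ~ N(0, b^2), redrawn until it lies in the mu-extended parental
# interval intersected with the morphospace (mu stays a hard bound; b sets
# the spread), clamped after 100 attempts.
draw_axis_normal <- function(c1, c2, mu, b, extent) {
  mid <- (c1 + c2) / 2
  w <- abs(c1 - c2) + 2 * mu
  lo <- pmax(pmin(c1, c2) - mu, 0)
  hi <- pmin(pmax(c1, c2) + mu, extent)
  out <- mid + rnorm(length(c1), 0, b) * w
  bad <- which(out < lo | out > hi)
  tries <- 0L
  while (length(bad) && tries < 100L) {
    out[bad] <- mid[bad] + rnorm(length(bad), 0, b) * w[bad]
    bad <- bad[out[bad] < lo[bad] | out[bad] > hi[bad]]
    tries <- tries + 1L
  }
  if (length(bad)) out[bad] <- pmin(pmax(out[bad], lo[bad]), hi[bad])
  out
}

#' Offspring coordinates under the uniform kernel
#'
#' Each axis is drawn independently and uniformly over the parental
#' coordinate range extended by mu on both sides; draws falling outside the
#' morphospace are redrawn (organisms cannot exist beyond the boundaries).
#'
#' @param p1,p2 Parent coordinates: length-2 vectors or n x 2 matrices.
#' @param mu Maximum mutation size (scalar or per-row vector).
#' @param extent Morphospace side length.
#' @return An n x 2 matrix of offspring coordinates.
#' @export
draw_offspring_uniform <- function(p1, p2, mu, extent = 45) {
  p1 <- rbind(p1); p2 <- rbind(p2)
  cbind(x = draw_axis_uniform(p1[, 1], p2[, 1], mu, extent),
        y = draw_axis_uniform(p1[, 2], p2[, 2], mu, extent))
}

#' Offspring coordinates under the normal kernel
#'
#' Each axis is the parental midpoint plus a zero-mean normal offset of
#' standard deviation `b` scaled by the mu-extended parental span, redrawn
#' until it falls inside both the mu-extended parental interval and the
#' morphospace. mu therefore remains a hard bound on the mutation
#' extension; increasing `b` widens the effective mutation distribution.
#'
#' @inheritParams draw_offspring_uniform
#' @param b Normal kernel width (default 0.1581).
#' @return An n x 2 matrix of offspring coordinates.
#' @export
draw_offspring_normal <- function(p1, p2, mu, b = 0.1581, extent = 45) {
  p1 <- rbind(p1); p2 <- rbind(p2)
  cbind(x = draw_axis_normal(p1[, 1], p2[, 1], mu, b, extent),
        y = draw_axis_normal(p1[, 2], p2[, 2], mu, b, extent))
}

#' Produce the next generation's brood
#'
#' Each organism produces `offspring_count(fitness_at(its location))`
#' offspring with its assigned mate (mate choice may be asymmetric; each
#' organism still reproduces exactly once). Offspring record both parents'
#' ids, inherit the lineage label if either parent carries it, and in
#' competition mode copy the mu value of one parent chosen by a fair coin.
#' Parents vanish afterwards: the returned brood is the entire next
#' generation before culling.
#'
#' @param state A `population_state`.
#' @param landscape A landscape (see [new_landscape()]).
#' @param config A [reproduction_config()].
#' @param mates Optional precomputed mate assignment ([assign_mates()]
#'   output, positionally aligned with `state$organisms`); computed when
#'   missing.
#' @return Organism data.frame of offspring (fresh ids `1..N`).
#' @export
reproduce <- function(state, landscape, config, mates = NULL) {
  org <- state$organisms
  n <- nrow(org)
  if (n < 2L) stop("extinction: fewer than two parents")
  if (is.null(mates)) mates <- assign_mates(org, config$extent)
  mate_pos <- match(unname(mates), org$id)

  f <- fitness_at(landscape, org$x, org$y)
  k <- offspring_count(f, landscape$config$fitness_range)

  oi <- rep.int(seq_len(n), k)   # brood's "own" parent index
  mi <- mate_pos[oi]             # brood's mate parent index
  p1 <- cbind(org$x[oi], org$y[oi])
  p2 <- cbind(org$x[mi], org$y[mi])
  mu <- if (config$competition) {
    ifelse(runif(length(oi)) < 0.5, org$mu[oi], org$mu[mi])
  } else {
    org$mu[oi]
  }
  coords <- if (config$kernel == "uniform") {
    draw_offspring_uniform(p1, p2, mu, config$extent)
  } else {
    draw_offspring_normal(p1, p2, mu, config$b, config$extent)
  }
  brood <- new_organisms(seq_along(oi), coords[, 1], coords[, 2], mu,
                         parent1 = org$id[oi], parent2 = org$id[mi],
                         labeled = org$labeled[oi] | org$labeled[mi])
  attr(brood, "max_brood") <- max(k)   # audit: per-organism brood size cap
  brood
}

#' Random death
#'
#' Draws a single death fraction rho ~ U(0, `death_fraction_max`) for the
#' generation and removes `round(rho * N)` organisms chosen uniformly
#' without replacement.
#'
#' @param offspring Organism data.frame.
#' @param config A [reproduction_config()].
#' @param rho Optional fixed death fraction (mainly for tests); drawn when
#'   `NULL`.
#' @return The surviving organisms.
#' @export
random_death <- function(offspring, config, rho = NULL) {
  n <- nrow(offspring)
  if (is.null(rho)) rho <- runif(1, 0, config$death_fraction_max)
  n_remove <- round(rho * n)
  if (n_remove <= 0L || n == 0L) return(offspring)
  offspring[-sample.int(n, n_remove), , drop = FALSE]
}

#' Overcrowding thinning
#'
#' Enforces the overpopulation limit: within a distance `radius` only one
#' organism can exist. Organisms are visited in uniformly random order and
#' kept iff no already-kept organism lies strictly within `radius`, so all
#' surviving pairwise distances are at least `radius`.
#'
#' @param offspring Organism data.frame.
#' @param radius Minimum spacing, trait units (default 0.25).
#' @param order Optional visiting order (row indices; mainly for tests);
#'   a random permutation when `NULL`.
#' @return The surviving organisms.
#' @export
thin_overcrowded <- function(offspring, radius = 0.25, order = NULL) {
  n <- nrow(offspring)
  if (n <= 1L) return(offspring)
  if (is.null(order)) order <- sample.int(n)
  keep <- thin_cpp(offspring$x, offspring$y, as.integer(order), radius)
  offspring[keep, , drop = FALSE]
}

#' Advance the model one generation
#'
#' Runs the per-generation pipeline: mate assignment, reproduction, random
#' death, overcrowding thinning, then the landscape update (column shift
#' every `lambda_shift` generations in shifting mode; density feedback from
#' the survivors' positions in feedback mode). The previous offspring now
#' play the role of parents; if fewer than two survive the state is flagged
#' extinct.
#'
#' @param state A `population_state`.
#' @param landscape A landscape.
#' @param config A [reproduction_config()].
#' @param mates Optional precomputed mate assignment for the current
#'   organisms.
#' @return A list with the advanced `state` and (possibly updated)
#'   `landscape`.
#' @export
step_generation <- function(state, landscape, config, mates = NULL) {
  if (nrow(state$organisms) < 2L || isTRUE(state$extinct)) {
    state$extinct <- TRUE
    return(list(state = state, landscape = landscape))
  }
  brood <- reproduce(state, landscape, config, mates = mates)
  brood <- random_death(brood, config)
  brood <- thin_overcrowded(brood, config$overpop_radius)
  gen <- state$generation + 1L

  lcfg <- landscape$config
  if (lcfg$mode == "shifting" && gen %% lcfg$lambda_shift == 0L) {
    landscape$grid <- shift_grid(landscape$grid, lcfg)
  } else if (lcfg$mode == "feedback") {
    landscape$grid <- apply_feedback(landscape$grid, brood$x, brood$y, lcfg)
  }

  state$generation <- gen
  state$organisms <- brood
  state$extinct <- nrow(brood) < 2L
  list(state = state, landscape = landscape)
}
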