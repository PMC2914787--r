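#' Landscape configuration
#'
#' Parameters governing the fitness landscape: its coarse resolution, the
#' fitness range, the morphospace extent, and which of the three dynamic
#' regimes it follows across generations.
#'
#' @param mode Landscape dynamics: `"shifting"` translates the coarse matrix
#'   one column rightwards every `lambda_shift` generations, inserting a
#'   fresh random column; `"feedback"` depletes fitness in proportion to
#'   local organism density while conserving the landscape-wide total;
#'   `"static"` leaves the landscape untouched.
#' @param lambda_shift Generations between shifts (shifting mode). Default 2.
#' @param feedback_coefficient Fitness decrement per organism resident in a
#'   coarse cell (feedback mode). Default 0.0071.
#' @param fitness_range Numeric pair `(min, max)` for freshly drawn fitness
#'   levels. Default `c(1, 4)`; realized as 1--4 offspring per organism.
#' @param extent Side length of the square morphospace, in trait units.
#'   Default 45.
#' @param coarse_size Number of coarse fitness nodes per axis. Default 12.
#'
#' @return An object of class `landscape_config`.
#' @export
landscape_config <- function(mode = c("shifting", "feedback", "static"),
                             lambda_shift = 2L,
                             feedback_coefficient = 0.0071,
                             fitness_range = c(1, 4),
                             extent = 45,
                             coarse_size = 12L) {
  mode <- match.arg(mode)
  lambda_shift <- as.integer(lambda_shift)
  coarse_size <- as.integer(coarse_size)
  stopifnot(lambda_shift >= 1L,
            feedback_coefficient >= 0,
            length(fitness_range) == 2L,
            fitness_range[1] < fitness_range[2],
            extent > 0,
            coarse_size >= 2L)
  structure(list(mode = mode,
                 lambda_shift = lambda_shift,
                 feedback_coefficient = feedback_coefficient,
                 fitness_range = as.numeric(fitness_range),
                 extent = as.numeric(extent),
                 coarse_size = coarse_size),
            class = "landscape_config")
}

#' Draw a fresh coarse fitness grid
#'
#' The landscape originates from a randomly generated `coarse_size` x
#' `coarse_size` matrix of fitness levels, each entry drawn i.i.d. uniform
#' over `fitness_range`. Rows index the y axis, columns the x axis, so a
#' rightward landscape shift is a column shift of the matrix.
#'
#' @param config A [landscape_config()].
#' @return An object of class `fitness_grid`: a list with `values` (the
#'   coarse matrix) and `generation_stamp`.
#' @export
init_grid <- function(config = landscape_config()) {
  m <- config$coarse_size
  v <- matrix(runif(m * m, config$fitness_range[1], config$fitness_range[2]),
              nrow = m, ncol = m)
  new_fitness_grid(v, 0L)
}

new_fitness_grid <- function(values, generation_stamp = 0L) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  structure(list(values = values,
                 generation_stamp = as.integer(generation_stamp)),
            class = "fitness_grid")
}

#' @export
print.fitness_grid <- function(x, ...) {
  cat(sprintf("<fitness_grid %dx%d, generation %d, range [%.3f, %.3f], sum %.4f>\n",
              nrow(x$values), ncol(x$values), x$generation_stamp,
              min(x$values), max(x$values), sum(x$values)))
  invisible(x)
}

#' Continuous landscape over the morphospace
#'
#' Pairs a coarse fitness grid with the morphospace geometry. The
#' `coarse_size` nodes per axis sit at `i * extent / (coarse_size - 1)`,
#' `i = 0 .. coarse_size - 1`, so the bilinear interpolant spans the full
#' `[0, extent]^2` square. The classic 45x45 expanded matrix is a sampled
#' view of this interpolant (see [sample_landscape()]); lookups evaluate the
#' continuous interpolant directly.
#'
#' @param grid A `fitness_grid`.
#' @param config A [landscape_config()].
#' @return An object of class `landscape`.
#' @export
new_landscape <- function(grid, config = landscape_config()) {
  stopifnot(inherits(grid, "fitness_grid"),
            nrow(grid$values) == config$coarse_size)
  structure(list(grid = grid,
                 config = config,
                 extent = config$extent,
                 node_positions = seq(0, config$extent,
                                      length.out = config$coarse_size)),
            class = "landscape")
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("<landscape extent %g, %dx%d coarse grid, mode '%s'>\n",
              x$extent, x$config$coarse_size, x$config$coarse_size,
              x$config$mode))
  invisible(x)
}

#' Fitness at morphospace coordinates
#'
#' Bilinear interpolation of the coarse grid at arbitrary coordinates.
#' At a node position the interpolant equals the node value exactly, and
#' every value is bounded by the four surrounding node values.
#'
#' @param landscape A [new_landscape()] object.
#' @param x,y Numeric vectors of coordinates, each in `[0, extent]`.
#' @return Numeric vector of fitness values.
#' @export
fitness_at <- function(landscape, x, y) {
  ext <- landscape$extent
  if (any(x < 0 | x > ext | y < 0 | y > ext, na.rm = FALSE))
    stop("coordinates outside the morphospace [0, ", ext, "]^2")
  v <- landscape$grid$values
  m <- nrow(v)
  h <- ext / (m - 1)
  jx <- pmin(floor(x / h), m - 2)   # 0-based column cell index (x axis)
  iy <- pmin(floor(y / h), m - 2)   # 0-based row cell index (y axis)
  tx <- x / h - jx
  ty <- y / h - iy
  i1 <- iy + 1L
  j1 <- jx + 1L
  (1 - tx) * (1 - ty) * v[cbind(i1, j1)] +
    tx * (1 - ty) * v[cbind(i1, j1 + 1L)] +
    (1 - tx) * ty * v[cbind(i1 + 1L, j1)] +
    tx * ty * v[cbind(i1 + 1L, j1 + 1L)]
}

#' Sample the landscape on a regular lattice
#'
#' Returns the interpolated fitness field evaluated on an `n x n` lattice
#' spanning the morphospace (the classic expanded 45x45 view when `n = 45`).
#'
#' @param landscape A landscape.
#' @param n Lattice points per axis. Default 45.
#' @return A data.frame with columns `x`, `y`, `fitness`.
#' @export
sample_landscape <- function(landscape, n = 45L) {
  s <- seq(0, landscape$extent, length.out = n)
  g <- expand.grid(x = s, y = s)
  g$fitness <- fitness_at(landscape, g$x, g$y)
  g
}

#' Brood size implied by a fitness value
#'
#' Fitness levels, nominally ranging 1--4, are realized as the number of
#' offspring an organism produces: the value is rounded to the nearest
#' integer (halves away from zero) and clamped to the fitness range, so the
#' least fit organisms leave one offspring and the most fit four even when
#' landscape dynamics push interpolated values outside the nominal range.
#'
#' @param fitness Numeric vector of fitness values.
#' @param fitness_range Numeric pair; default `c(1, 4)`.
#' @return Integer vector of offspring counts.
#' @export
offspring_count <- function(fitness, fitness_range = c(1, 4)) {
  r <- sign(fitness) * floor(abs(fitness) + 0.5)  # round half away from zero
  lo <- round(fitness_range[1])
  hi <- round(fitness_range[2])
  as.integer(pmin(pmax(r, lo), hi))
}

#' Shift the coarse grid one column rightwards
#'
#' The last column of the coarse matrix is deleted, every other column moves
#' one position rightwards, and the vacated first column is refilled with
#' fresh uniform draws -- gradually translating the landscape to the right.
#' Callers apply this every `lambda_shift` generations.
#'
#' @param grid A `fitness_grid`.
#' @param config A [landscape_config()].
#' @return A new `fitness_grid` with incremented `generation_stamp`.
#' @export
shift_grid <- function(grid, config = landscape_config()) {
  v <- grid$values
  m <- ncol(v)
  v[, 2:m] <- v[, 1:(m - 1)]
  v[, 1] <- runif(m, config$fitness_range[1], config$fitness_range[2])
  new_fitness_grid(v, grid$generation_stamp + 1L)
}

#' Density feedback on the coarse grid
#'
#' Each coarse cell's fitness is decreased by `feedback_coefficient` times
#' the number of organisms resident in that cell (resource depletion by
#' over-use); the entire subtracted quantity is then added back, divided
#' equally amongst all cells, so the landscape-wide fitness total is
#' conserved and undepleted regions become relatively more advantageous.
#' Values are deliberately not clamped to the fitness range -- clamping
#' would break conservation; brood sizes are clamped instead (see
#' [offspring_count()]).
#'
#' @param grid A `fitness_grid`.
#' @param x,y Coordinates of the resident organisms.
#' @param config A [landscape_config()].
#' @return A new `fitness_grid` with the same total fitness.
#' @export
apply_feedback <- function(grid, x, y, config = landscape_config()) {
  m <- nrow(grid$values)
  n <- length(x)
  if (n == 0L) return(grid)
  w <- config$extent / m                     # coarse cell width for binning
  jx <- pmin(pmax(floor(x / w), 0), m - 1)   # 0-based x bin (column)
  iy <- pmin(pmax(floor(y / w), 0), m - 1)   # 0-based y bin (row)
  counts <- matrix(tabulate(iy * m + jx + 1L, nbins = m * m),
                   nrow = m, ncol = m, byrow = TRUE)
  dec <- config$feedback_coefficient * counts
  v <- grid$values - dec + sum(dec) / (m * m)
  new_fitness_grid(v, grid$generation_stamp)
}
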