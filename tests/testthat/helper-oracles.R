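# Independent brute-force oracles, kept deliberately naive (O(n^2) loops,
# literal algorithm transcriptions) so they share no code path with the
# implementation they check.

# Nearest and second-nearest other organism by exhaustive pairwise
# distances; ties broken by lowest position.
oracle_nearest_two <- function(x, y) {
  n <- length(x)
  out <- matrix(0L, n, 2)
  if (n < 2) return(out)
  for (i in seq_len(n)) {
    d <- sqrt((x - x[i])^2 + (y - y[i])^2)
    d[i] <- Inf
    ord <- order(d, seq_len(n))
    out[i, 1] <- ord[1]
    if (n >= 3) out[i, 2] <- ord[2]
  }
  out
}

# Literal iterative mating closure: starting from a seed organism, gather
# everything it, its mate (nearest neighbour) and its second-nearest
# neighbour have mated with; repeat for every organism found until the set
# closes. "z mated with w" iff w is z's mate or z is w's mate. Closure sets
# from different seeds are merged when they overlap (each organism belongs
# to exactly one cluster), yielding the unique partition.
oracle_closure_partition <- function(x, y) {
  n <- length(x)
  nn <- oracle_nearest_two(x, y)
  mated_with <- lapply(seq_len(n), function(z)
    sort(unique(c(nn[z, 1], which(nn[, 1] == z)))))
  closure_from <- function(seed) {
    set <- seed
    repeat {
      add <- integer()
      for (z in set) {
        add <- c(add, mated_with[[z]], mated_with[[nn[z, 1]]])
        if (nn[z, 2] > 0) add <- c(add, mated_with[[nn[z, 2]]])
      }
      new_set <- sort(unique(c(set, add)))
      if (identical(new_set, set)) return(set)
      set <- new_set
    }
  }
  label <- integer(n)
  next_lab <- 0L
  for (seed in seq_len(n)) {
    if (label[seed] > 0L) next
    members <- closure_from(seed)
    touched <- unique(label[members])
    touched <- touched[touched > 0L]
    if (length(touched)) {
      # overlapping closures merge into one cluster
      lab <- min(touched)
      label[label %in% touched] <- lab
      label[members] <- lab
    } else {
      next_lab <- next_lab + 1L
      label[members] <- next_lab
    }
  }
  as.integer(match(label, unique(label)))
}

# Greedy thinning replay: same rule, plain loops.
oracle_thin <- function(x, y, order, radius) {
  keep <- logical(length(x))
  for (i in order) {
    kept <- which(keep)
    ok <- TRUE
    for (j in kept) {
      if ((x[i] - x[j])^2 + (y[i] - y[j])^2 < radius^2) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  keep
}

# Mean within-cluster pairwise distance, brute force over all pairs.
oracle_diversity <- function(x, y, memb) {
  per <- c()
  for (lab in unique(memb)) {
    ix <- which(memb == lab)
    if (length(ix) < 2) next
    s <- 0; m <- 0
    for (a in seq_along(ix)) for (b in seq_along(ix)) if (a < b) {
      s <- s + sqrt((x[ix[a]] - x[ix[b]])^2 + (y[ix[a]] - y[ix[b]])^2)
      m <- m + 1
    }
    per <- c(per, s / m)
  }
  if (!length(per)) NA_real_ else mean(per)
}

# Direct rejection sampler for the truncated-normal mutation kernel on one
# axis (the documented generative rule, sampled naively).
oracle_normal_axis <- function(n, c1, c2, mu, b, extent) {
  mid <- (c1 + c2) / 2
  w <- abs(c1 - c2) + 2 * mu
  lo <- max(min(c1, c2) - mu, 0)
  hi <- min(max(c1, c2) + mu, extent)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      v <- mid + rnorm(1, 0, b) * w
      if (v >= lo && v <= hi) break
    }
    out[i] <- v
  }
  out
}

# Tiny helper: a static landscape whose fitness is constant everywhere.
constant_landscape <- function(value = 3, extent = 45, coarse_size = 12) {
  cfg <- landscape_config("static", extent = extent,
                          coarse_size = coarse_size)
  grid <- init_grid(cfg)
  grid$values[] <- value
  new_landscape(grid, cfg)
}

random_organisms <- function(n, extent = 45) {
  new_organisms_df <- data.frame(id = seq_len(n),
                                 x = runif(n, 0, extent),
                                 y = runif(n, 0, extent),
                                 mu = 0.3,
                                 parent1 = NA_integer_,
                                 parent2 = NA_integer_,
                                 labeled = FALSE)
  new_organisms_df
}
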