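test_that("founders are uniform over the morphospace; competition founders draw mu ~ U(0,1)", {
  cfg <- reproduction_config(mu = 0.3)
  set.seed(1)
  st <- init_population(300, cfg)
  expect_equal(nrow(st$organisms), 300)
  expect_identical(st$generation, 0L)
  expect_true(all(st$organisms$x >= 0 & st$organisms$x <= 45))
  expect_true(all(st$organisms$mu == 0.3))
  expect_false(any(duplicated(st$organisms$id)))

  set.seed(11); a <- init_population(50, cfg)
  set.seed(11); b <- init_population(50, cfg)
  expect_identical(a$organisms, b$organisms)

  ccfg <- reproduction_config(competition = TRUE)
  set.seed(12)
  big <- init_population(10000, ccfg)
  se <- sd(big$organisms$mu) / sqrt(10000)
  expect_lt(abs(mean(big$organisms$mu) - 0.5), 3 * se)
  expect_true(all(big$organisms$mu >= 0 & big$organisms$mu <= 1))

  expect_error(init_population(0, cfg), "founder")
})

test_that("every organism mates with its nearest other organism", {
  # two organisms: each maps to the other
  two <- random_organisms(2)
  m <- assign_mates(two)
  expect_identical(unname(m), c(2L, 1L))

  # collinear at x = 0, 1, 3: 1->2, 2->1, 3->2
  tri <- data.frame(id = 1:3, x = c(0, 1, 3), y = 0)
  m <- assign_mates(tri)
  expect_identical(unname(m), c(2L, 1L, 2L))

  # no organism maps to itself; matches the brute-force oracle
  set.seed(13)
  for (rep in 1:10) {
    org <- random_organisms(sample(3:60, 1))
    m <- assign_mates(org)
    expect_false(any(unname(m) == org$id))
    nn <- oracle_nearest_two(org$x, org$y)
    expect_identical(unname(m), org$id[nn[, 1]])
  }

  expect_error(assign_mates(random_organisms(1)), "extinction")
})

test_that("the uniform kernel covers exactly the mu-extended parental box", {
  # degenerate interval: mu = 0, coincident parents
  set.seed(14)
  o <- draw_offspring_uniform(c(10, 10), c(10, 10), mu = 0)
  expect_equal(unname(o), matrix(c(10, 10), 1))

  # mu = 0: confined to the parental box
  p1 <- matrix(rep(c(10, 10), 50), ncol = 2, byrow = TRUE)
  p2 <- matrix(rep(c(12, 14), 50), ncol = 2, byrow = TRUE)
  o <- draw_offspring_uniform(p1, p2, mu = 0)
  expect_true(all(o[, 1] >= 10 & o[, 1] <= 12))
  expect_true(all(o[, 2] >= 10 & o[, 2] <= 14))

  # mu = 1, parents x = 10 and 12: x uniform on [9, 13]
  set.seed(15)
  n <- 2e4
  p1 <- cbind(rep(10, n), rep(20, n))
  p2 <- cbind(rep(12, n), rep(20, n))
  o <- draw_offspring_uniform(p1, p2, mu = 1)
  expect_true(all(o[, 1] >= 9 & o[, 1] <= 13))
  ks <- suppressWarnings(stats::ks.test(o[, 1], "punif", 9, 13))
  expect_gt(ks$p.value, 0.001)
})

test_that("the normal kernel is truncated to the mu-extended interval and matches a rejection-sampling oracle", {
  set.seed(16)
  o <- draw_offspring_normal(c(10, 10), c(10, 10), mu = 0)
  expect_equal(unname(o), matrix(c(10, 10), 1))

  # hard truncation bound
  set.seed(17)
  n <- 5e3
  p1 <- cbind(rep(18, n), rep(20, n))
  p2 <- cbind(rep(22, n), rep(21, n))
  o <- draw_offspring_normal(p1, p2, mu = 0.5)
  expect_true(all(o[, 1] >= 17.5 & o[, 1] <= 22.5))
  expect_true(all(o[, 2] >= 19.5 & o[, 2] <= 21.5))

  # coincident parents, mu = 1: distribution matches a direct rejection
  # sampler with identical parameters
  set.seed(18)
  n <- 5e4
  pc <- cbind(rep(20, n), rep(20, n))
  o <- draw_offspring_normal(pc, pc, mu = 1)
  ref <- oracle_normal_axis(n, 20, 20, mu = 1, b = 0.1581, extent = 45)
  expect_lt(abs(sd(o[, 1]) / sd(ref) - 1), 0.05)
  expect_lt(abs(mean(o[, 1]) - mean(ref)), 4 * sd(ref) / sqrt(n) * 2)
  ks <- suppressWarnings(stats::ks.test(o[, 1], ref))
  expect_gt(ks$p.value, 0.001)
})

test_that("each organism produces its fitness-determined brood with its own mate", {
  cfg <- reproduction_config(mu = 0.2)
  ls <- constant_landscape(3)
  st <- structure(list(generation = 0L,
                       organisms = new_organisms(1:2, x = c(10, 10.5),
                                                 y = c(10, 10), mu = 0.2),
                       extinct = FALSE), class = "population_state")
  set.seed(19)
  brood <- reproduce(st, ls, cfg)
  expect_equal(nrow(brood), 6)   # 3 offspring each on a fitness-3 landscape
  expect_identical(attr(brood, "max_brood"), 3L)
  expect_true(all(brood$parent1 %in% 1:2 & brood$parent2 %in% 1:2))
  expect_false(any(brood$labeled))

  # labeled parent marks every one of its broods
  st$organisms$labeled[1] <- TRUE
  set.seed(20)
  brood <- reproduce(st, ls, cfg)
  expect_true(all(brood$labeled))  # with 2 organisms both broods involve parent 1

  # competition: offspring mu copied from one parent by a fair coin
  ccfg <- reproduction_config(competition = TRUE)
  st2 <- structure(list(generation = 0L,
                        organisms = new_organisms(1:2, x = c(10, 10.5),
                                                  y = c(10, 10),
                                                  mu = c(0.2, 0.8)),
                        extinct = FALSE), class = "population_state")
  lbig <- constant_landscape(4)
  set.seed(21)
  mus <- replicate(1500, reproduce(st2, lbig, ccfg)$mu)
  frac <- mean(unlist(mus) == 0.2)
  n_tot <- length(unlist(mus))
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n_tot))
  expect_true(all(unlist(mus) %in% c(0.2, 0.8)))
})

test_that("random death removes round(rho * N) organisms chosen at random", {
  cfg <- reproduction_config()
  org <- random_organisms(100)
  cfg0 <- reproduction_config(death_fraction_max = 0)
  set.seed(22)
  expect_identical(random_death(org, cfg0), org)
  expect_equal(nrow(random_death(org, cfg, rho = 0.5)), 50)
  expect_equal(nrow(random_death(org, cfg, rho = 0.704)), 30)

  # mean removed fraction ~ mean of U(0, 0.70) = 0.35
  set.seed(23)
  fr <- replicate(4000, 1 - nrow(random_death(org, cfg)) / 100)
  se <- sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - 0.35), 3 * se)
})

test_that("thinning enforces the overpopulation limit and replays the greedy oracle", {
  # two organisms 0.1 apart: exactly one survives
  pair <- data.frame(id = 1:2, x = c(1, 1.1), y = 1)
  expect_equal(nrow(thin_overcrowded(pair, 0.25, order = 1:2)), 1)

  # all pairwise distances >= 0.25: unchanged
  far <- random_organisms(30)
  far$x <- far$x * 10  # scale spacing up; extent irrelevant to thinning
  set.seed(24)
  if (min(dist(cbind(far$x, far$y))) >= 0.25) {
    expect_identical(thin_overcrowded(far, 0.25), far)
  }

  # line of five spaced 0.2: greedy oracle replay, min spacing respected
  five <- data.frame(id = 1:5, x = seq(0, 0.8, by = 0.2), y = 1)
  for (ord in list(1:5, 5:1, c(3, 1, 5, 2, 4))) {
    got <- thin_overcrowded(five, 0.25, order = ord)
    keep <- oracle_thin(five$x, five$y, ord, 0.25)
    expect_identical(got$id, five$id[keep])
    if (nrow(got) > 1) expect_gte(min(dist(cbind(got$x, got$y))), 0.25)
  }

  # random dense clouds match the oracle under the same order
  set.seed(25)
  for (rep in 1:8) {
    n <- sample(20:120, 1)
    org <- data.frame(id = seq_len(n), x = runif(n, 0, 3), y = runif(n, 0, 3))
    ord <- sample.int(n)
    got <- thin_overcrowded(org, 0.25, order = ord)
    keep <- oracle_thin(org$x, org$y, ord, 0.25)
    expect_identical(got$id, org$id[keep])
    expect_gte(min(dist(cbind(got$x, got$y))), 0.25)
  }
})

test_that("a generation step keeps organisms in bounds, spaced, and is seed-reproducible", {
  lcfg <- landscape_config("shifting")
  rcfg <- reproduction_config(mu = 0.4)
  run_steps <- function(seed, gens) {
    set.seed(seed)
    ls <- new_landscape(init_grid(lcfg), lcfg)
    st <- init_population(100, rcfg)
    for (i in seq_len(gens)) {
      out <- step_generation(st, ls, rcfg)
      st <- out$state; ls <- out$landscape
      if (isTRUE(st$extinct)) break
    }
    st
  }
  a <- run_steps(26, 10)
  b <- run_steps(26, 10)
  expect_identical(a$organisms, b$organisms)   # bitwise reproducible
  expect_true(all(a$organisms$x >= 0 & a$organisms$x <= 45 &
                    a$organisms$y >= 0 & a$organisms$y <= 45))
  if (nrow(a$organisms) > 1) {
    expect_gte(min(dist(cbind(a$organisms$x, a$organisms$y))), 0.25)
  }

  # single parent: extinction flagged, not an error
  lone <- structure(list(generation = 0L,
                         organisms = random_organisms(1),
                         extinct = FALSE), class = "population_state")
  ls <- constant_landscape(3)
  out <- step_generation(lone, ls, rcfg)
  expect_true(out$state$extinct)
})

test_that("offspring coordinates respect the mu bound up to boundary clipping", {
  lcfg <- landscape_config("static")
  set.seed(27)
  ls <- constant_landscape(4)
  for (kernel in c("uniform", "normal")) {
    for (mu in c(0.1, 0.5)) {
      rcfg <- reproduction_config(mu = mu, kernel = kernel)
      st <- init_population(60, rcfg)
      mates <- assign_mates(st$organisms)
      brood <- reproduce(st, ls, rcfg, mates = mates)
      org <- st$organisms
      oi <- match(brood$parent1, org$id)
      mi <- match(brood$parent2, org$id)
      lo_x <- pmax(pmin(org$x[oi], org$x[mi]) - mu, 0)
      hi_x <- pmin(pmax(org$x[oi], org$x[mi]) + mu, 45)
      lo_y <- pmax(pmin(org$y[oi], org$y[mi]) - mu, 0)
      hi_y <- pmin(pmax(org$y[oi], org$y[mi]) + mu, 45)
      expect_true(all(brood$x >= lo_x - 1e-12 & brood$x <= hi_x + 1e-12))
      expect_true(all(brood$y >= lo_y - 1e-12 & brood$y <= hi_y + 1e-12))
    }
  }
})
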