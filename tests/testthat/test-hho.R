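test_that("escape energy decays linearly and flags iteration overflow", {
  expect_equal(escape_energy(1, 10, 10), 0)
  expect_equal(escape_energy(0.5, 0, 10), 1)
  expect_equal(escape_energy(-1, 5, 10), -1)
  expect_error(escape_energy(0.3, 11, 10), "overflow")
  # |E| <= 2|E0| always
  for (E0 in seq(-0.9, 0.9, by = 0.3))
    expect_lte(abs(escape_energy(E0, 3, 10)), 2 * abs(E0))
})

test_that("mean position matches an elementwise summation oracle", {
  p <- c(1.5, -2, 3)
  sw <- hho_swarm(rbind(p, p, p), c(1, 2, 3))
  expect_equal(mean_position(sw), p)
  sw2 <- hho_swarm(rbind(rep(0, 3), rep(2, 3)), c(1, 2))
  expect_equal(mean_position(sw2), rep(1, 3))
  set.seed(42)
  X <- matrix(rnorm(100), 20, 5)
  sw3 <- hho_swarm(X, rnorm(20))
  oracle <- sapply(1:5, function(j) sum(X[, j]) / 20)
  expect_equal(mean_position(sw3), oracle, tolerance = 1e-12)
})

test_that("exploration move follows both perch equations and stays in bounds", {
  b <- hho_bounds(rep(-10, 3), rep(10, 3))
  set.seed(1)
  X <- matrix(runif(15, -5, 5), 5, 3)
  sw <- hho_swarm(X, apply(X, 1, sphere))
  # q >= 0.5 with r1 = 0 reduces to X_rand: must be one of the current rows
  set.seed(7)
  mv <- exploration_move(2, sw, b, draws = list(q = 0.8, r1 = 0, r2 = 0.3,
                                                r3 = 0, r4 = 0))
  expect_true(any(apply(X, 1, function(r) isTRUE(all.equal(r, mv)))))
  # q < 0.5 with r3 = 0 reduces to rabbit minus mean
  mv2 <- exploration_move(2, sw, b, draws = list(q = 0.2, r1 = 0, r2 = 0,
                                                 r3 = 0, r4 = 0.9))
  expect_equal(mv2, sw$rabbit_position - mean_position(sw))
  # containment over many random moves
  set.seed(99)
  for (i in 1:300) {
    mv <- exploration_move(sample(5, 1), sw, b)
    expect_true(all(mv >= b$lower & mv <= b$upper))
  }
})

test_that("besiege updates match term-by-term recomputation", {
  set.seed(3)
  for (i in 1:50) {
    x <- rnorm(4); rb <- rnorm(4); E <- runif(1, -2, 2); J <- runif(1, 0, 2)
    expect_equal(soft_besiege(x, rb, E, J),
                 (rb - x) - E * abs(J * rb - x), tolerance = 1e-14)
    expect_equal(hard_besiege(x, rb, E),
                 rb - E * abs(rb - x), tolerance = 1e-14)
  }
  rb <- c(1, 2)
  expect_equal(soft_besiege(c(0, 0), rb, 0, 1.3), rb)   # E=0: pure delta-X
  expect_equal(hard_besiege(c(5, 5), rb, 0), rb)
  expect_equal(hard_besiege(rb, rb, 0.7), rb)           # coincident case
})

test_that("Levy flights have the Mantegna normalizer and heavy tails", {
  expect_equal(levy_sigma(1.5), 0.6965745, tolerance = 1e-6)
  set.seed(5); a <- levy_flight(10)
  set.seed(5); b <- levy_flight(10)
  expect_identical(a, b)
  set.seed(11)
  draws <- replicate(20, levy_flight(1000))
  expect_gt(sample_excess_kurtosis(as.vector(draws)), 10)
})

test_that("rapid dives are greedy: first strict improvement among Y, Z, X", {
  b <- hho_bounds(rep(-10, 3), rep(10, 3))
  # constant objective: no strict improvement, position retained
  res <- rapid_dive_soft(c(1, 2, 3), c(0, 0, 0), 0.6, 1.1,
                         function(x) 7, b)
  expect_equal(as.numeric(res), c(1, 2, 3))
  res <- rapid_dive_hard(c(1, 2, 3), c(0, 0, 0), c(1, 1, 1), 0.3, 1,
                         function(x) 7, b)
  expect_equal(as.numeric(res), c(1, 2, 3))
  # E = 0 puts Y at the rabbit; on a sphere with rabbit at optimum Y wins
  res <- rapid_dive_soft(c(4, 4, 4), c(0, 0, 0), 0, 1, sphere, b)
  expect_equal(as.numeric(res), c(0, 0, 0))
  expect_equal(attr(res, "fitness"), 0)
  # swarm mean at rabbit and J = 1 puts the hard dive Y at the rabbit
  res <- rapid_dive_hard(c(4, 4, 4), c(1, 1, 1), c(1, 1, 1), 0.8, 1, sphere, b)
  expect_equal(as.numeric(res), c(1, 1, 1))
  # random instances against a seed-replayed three-way recomputation
  for (k in 1:60) {
    x <- rnorm(3); rb <- rnorm(3); E <- runif(1, -1, 1); J <- runif(1, 0, 2)
    fx <- sphere(x)
    set.seed(1000 + k)
    got <- rapid_dive_soft(x, rb, E, J, sphere, b, position_fitness = fx)
    set.seed(1000 + k)
    Y <- pmin(pmax(rb - E * abs(J * rb - x), b$lower), b$upper)
    fY <- sphere(Y)
    expected <- if (fY < fx) Y else {
      S <- runif(3); u <- rnorm(3); v <- rnorm(3)
      lf <- 0.01 * u * levy_sigma(1.5) / abs(v)^(1 / 1.5)
      Z <- pmin(pmax(Y + S * lf, b$lower), b$upper)
      if (sphere(Z) < fx) Z else x
    }
    expect_equal(as.numeric(got), expected, tolerance = 1e-12)
  }
})

test_that("iterations preserve elitism, bounds and the optimum", {
  b <- hho_bounds(rep(-10, 2), rep(10, 2))
  cfg <- hho_config(10, 50, seed = 1)
  set.seed(2)
  X <- matrix(runif(20, -10, 10), 10, 2)
  sw <- hho_swarm(X, apply(X, 1, sphere), max_iterations = 50)
  for (it in 1:10) {
    prev <- sw$rabbit_fitness
    sw <- hho_iteration(sw, sphere, b, cfg)
    expect_lte(sw$rabbit_fitness, prev)
    expect_true(all(sw$positions >= -10 & sw$positions <= 10))
    expect_lte(sw$rabbit_fitness, min(sw$fitness))
  }
  # swarm already at the optimum: rabbit cannot move away
  X0 <- matrix(0, 6, 2)
  sw0 <- hho_swarm(X0, rep(0, 6), max_iterations = 10)
  sw0 <- hho_iteration(sw0, sphere, b, cfg)
  expect_equal(sw0$rabbit_fitness, 0)
  expect_equal(sw0$rabbit_position, c(0, 0))
})

test_that("chaotic iterations keep the elitism contract and accept greedily", {
  b <- hho_bounds(rep(-5, 3), rep(5, 3))
  cfg <- hho_config(8, 30, variant = "lc_hhoa", seed = 4)
  st <- chaotic_state(0.7)
  set.seed(4)
  X <- matrix(runif(24, -5, 5), 8, 3)
  sw <- hho_swarm(X, apply(X, 1, sphere), max_iterations = 30)
  for (it in 1:8) {
    prev_fit <- sw$fitness
    prev_rabbit <- sw$rabbit_fitness
    sw <- lc_hhoa_iteration(sw, sphere, b, cfg, st)
    st <- attr(sw, "chaos")
    expect_lte(sw$rabbit_fitness, prev_rabbit)
    expect_true(all(sw$positions >= -5 & sw$positions <= 5))
  }
  expect_s3_class(st, "chaotic_state")
})

test_that("non-finite objectives are rejected", {
  b <- hho_bounds(-1, 1)
  sw <- hho_swarm(matrix(c(0.1, 0.2), 2, 1), c(1, 2), max_iterations = 5)
  set.seed(1)
  expect_error(hho_iteration(sw, function(x) NaN, b, hho_config(2, 5)),
               "non-finite")
})

test_that("optimize honours constant objectives, determinism and patience", {
  b <- hho_bounds(rep(-3, 2), rep(3, 2))
  res <- hho_optimize(function(x) 5, b, hho_config(4, 6, seed = 2))
  expect_equal(res$best_fitness, 5)
  expect_true(all(res$trace == 5))
  r1 <- hho_optimize(sphere, b, hho_config(8, 40, seed = 9))
  r2 <- hho_optimize(sphere, b, hho_config(8, 40, seed = 9))
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$best_position, r2$best_position)
  expect_true(all(diff(r1$trace) <= 0))
  expect_equal(r1$trace[length(r1$trace)], r1$best_fitness)
  # patience = 0 with T = 1: exactly one iteration
  res <- hho_optimize(sphere, b, hho_config(4, 1, seed = 1, patience = 0))
  expect_equal(res$iterations, 1L)
  # constant objective never improves: stops after patience + 1 iterations
  res <- hho_optimize(function(x) 1, b, hho_config(4, 50, seed = 1,
                                                   patience = 2))
  expect_equal(res$iterations, 3L)
})

test_that("the optimizer solves a small sphere to high precision", {
  b <- hho_bounds(rep(-10, 2), rep(10, 2))
  res <- hho_optimize(sphere, b, hho_config(20, 200, seed = 3))
  expect_lt(res$best_fitness, 1e-6)
})
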