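#' Search box for the hawk swarm
#'
#' @param lower,upper numeric vectors of equal length with `lower < upper`
#'   componentwise.
#' @return an object of class `hho_bounds` with fields `lower`, `upper`, `dim`.
#' @export
hho_bounds <- function(lower, upper) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (length(lower) != length(upper) || length(lower) < 1L)
    stop_config("bounds must be non-empty vectors of equal length")
  if (!all(is.finite(lower)) || !all(is.finite(upper)) || !all(lower < upper))
    stop_config("bounds require finite lower < upper componentwise")
  structure(list(lower = lower, upper = upper, dim = length(lower)),
            class = "hho_bounds")
}

clip_to_bounds <- function(x, bounds) {
  pmin(pmax(x, bounds$lower), bounds$upper)
}

#' Optimizer configuration
#'
#' @param population number of hawks (N >= 2).
#' @param max_iterations iteration budget T >= 1.
#' @param variant `"hho"` (vanilla) or `"lc_hhoa"` (logistic-chaotic: besiege
#'   positions and the initial population come from a logistic map stream).
#' @param seed integer seed; every random draw of the run flows from it.
#' @param levy_beta stability index of the Levy flight (1 < beta <= 2).
#' @param levy_scale step scale of the Levy flight.
#' @param chaos_control,chaos_init logistic map parameters for `lc_hhoa`.
#' @param patience early-stopping patience: stop when the best fitness has not
#'   strictly improved for more than `patience` consecutive iterations
#'   (`Inf` disables).
#' @return an object of class `hho_config`.
#' @export
hho_config <- function(population = 20, max_iterations = 200,
                       variant = c("hho", "lc_hhoa"), seed = 1L,
                       levy_beta = 1.5, levy_scale = 0.01,
                       chaos_control = 4, chaos_init = 0.7,
                       patience = Inf) {
  variant <- match.arg(variant)
  if (population < 2) stop_config("population must be at least 2")
  if (max_iterations < 1) stop_config("max_iterations must be at least 1")
  if (levy_beta <= 1 || levy_beta > 2) stop_config("levy_beta must be in (1, 2]")
  if (levy_scale <= 0) stop_config("levy_scale must be positive")
  structure(list(population = as.integer(population),
                 max_iterations = as.integer(max_iterations),
                 variant = variant, seed = as.integer(seed),
                 levy_beta = levy_beta, levy_scale = levy_scale,
                 chaos_control = chaos_control, chaos_init = chaos_init,
                 patience = patience),
            class = "hho_config")
}

#' Escape energy of the prey
#'
#' `E = 2 * E0 * (1 - t/T)`: linear decay of the initial energy `E0` over the
#' iteration budget. `|E| >= 1` dispatches exploration, smaller values the
#' four exploitation strategies.
#'
#' @param E0 initial energy in (-1, 1), redrawn per hawk per iteration.
#' @param t current iteration (0-based), `t <= T`.
#' @param T_max iteration budget.
#' @export
escape_energy <- function(E0, t, T_max) {
  if (T_max < 1) stop_config("T_max must be at least 1")
  if (t > T_max) stop_numeric("iteration overflow: t exceeds T_max")
  E0 * 2 * (1 - t / T_max)
}

#' Mean position of the swarm
#' @param swarm a swarm as built by [hho_swarm()].
#' @export
mean_position <- function(swarm) {
  if (is.null(swarm$positions) || nrow(swarm$positions) < 1L)
    stop_numeric("empty swarm has no mean position")
  colMeans(swarm$positions)
}

# Swarm container: positions (N x D), per-hawk fitness, best-so-far rabbit.
#' Build a hawk swarm from evaluated positions
#'
#' @param positions N x D matrix of hawk positions.
#' @param fitness numeric vector of length N (objective at each position).
#' @param iteration current iteration t (0-based).
#' @param max_iterations budget T.
#' @return object of class `hho_swarm`; the rabbit holds the best evaluated
#'   position and fitness.
#' @export
hho_swarm <- function(positions, fitness, iteration = 0L, max_iterations = 1L) {
  positions <- as.matrix(positions)
  stopifnot(nrow(positions) == length(fitness))
  if (any(!is.finite(fitness))) stop_numeric("non-finite fitness in swarm")
  best <- which.min(fitness)
  structure(list(positions = positions, fitness = as.numeric(fitness),
                 rabbit_position = positions[best, ],
                 rabbit_fitness = fitness[best],
                 iteration = as.integer(iteration),
                 max_iterations = as.integer(max_iterations)),
            class = "hho_swarm")
}

#' Exploration move (perch selection)
#'
#' With probability draw `q >= 0.5` a hawk perches relative to a random flock
#' member: `X_rand - r1 * |X_rand - 2 * r2 * X|`; otherwise relative to rabbit
#' and flock mean: `(X_rabbit - X_m) - r3 * (LB + r4 * (UB - LB))`. The result
#' is clipped to the search box.
#'
#' @param index hawk row index.
#' @param swarm an `hho_swarm`.
#' @param bounds an [hho_bounds()].
#' @param draws optional list with elements `q`, `r1`..`r4` to pin the uniform
#'   draws (used in testing); by default they come from the RNG.
#' @export
exploration_move <- function(index, swarm, bounds, draws = NULL) {
  if (is.null(draws)) {
    u <- stats::runif(5)
    draws <- list(q = u[1], r1 = u[2], r2 = u[3], r3 = u[4], r4 = u[5])
  }
  x <- swarm$positions[index, ]
  if (draws$q >= 0.5) {
    other <- sample.int(nrow(swarm$positions), 1L)
    x_rand <- swarm$positions[other, ]
    cand <- x_rand - draws$r1 * abs(x_rand - 2 * draws$r2 * x)
  } else {
    cand <- (swarm$rabbit_position - mean_position(swarm)) -
      draws$r3 * (bounds$lower + draws$r4 * (bounds$upper - bounds$lower))
  }
  clip_to_bounds(cand, bounds)
}

#' Levy flight step (Mantegna construction)
#'
#' Heavy-tailed step `scale * u * sigma / |v|^(1/beta)` with `u`, `v` standard
#' normal and `sigma` the Mantegna normalizer; at `beta = 1.5` the normalizer
#' is approximately 0.69657.
#'
#' @param dim number of coordinates.
#' @param beta stability index in (1, 2].
#' @param scale step scale.
#' @export
levy_flight <- function(dim, beta = 1.5, scale = 0.01) {
  stopifnot(dim >= 1)
  u <- stats::rnorm(dim)
  v <- stats::rnorm(dim)
  scale * u * levy_sigma(beta) / abs(v)^(1 / beta)
}

#' @describeIn levy_flight the Mantegna scale normalizer sigma(beta).
#' @export
levy_sigma <- function(beta = 1.5) {
  (gamma(1 + beta) * sin(pi * beta / 2) /
     (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
}

#' Besiege updates
#'
#' Soft besiege (prey still energetic, `|E| >= 0.5`):
#' `(rabbit - position) - E * |J * rabbit - position|` with jump strength
#' `J = 2 * (1 - r5)`. Hard besiege (`|E| < 0.5`):
#' `rabbit - E * |rabbit - position|`.
#'
#' @param position current hawk position.
#' @param rabbit best-so-far position.
#' @param E escape energy.
#' @param J jump strength.
#' @export
soft_besiege <- function(position, rabbit, E, J) {
  (rabbit - position) - E * abs(J * rabbit - position)
}

#' @rdname soft_besiege
#' @export
hard_besiege <- function(position, rabbit, E) {
  rabbit - E * abs(rabbit - position)
}

# Shared greedy three-way comparison for the dive branches: try Y, then
# Z = Y + S * LF, accept the first strict improvement over the current
# position, else keep the position. Returns the chosen point with its
# fitness and the number of objective evaluations as attributes.
dive_greedy <- function(Y, position, position_fitness, objective, bounds,
                        beta, scale) {
  Y <- clip_to_bounds(Y, bounds)
  evals <- 0L
  if (is.null(position_fitness)) {
    position_fitness <- objective(position)
    evals <- evals + 1L
  }
  fY <- objective(Y); evals <- evals + 1L
  if (is.finite(fY) && fY < position_fitness)
    return(structure(Y, fitness = fY, evaluations = evals))
  S <- stats::runif(length(Y))
  Z <- clip_to_bounds(Y + S * levy_flight(length(Y), beta, scale), bounds)
  fZ <- objective(Z); evals <- evals + 1L
  if (is.finite(fZ) && fZ < position_fitness)
    return(structure(Z, fitness = fZ, evaluations = evals))
  structure(position, fitness = position_fitness, evaluations = evals)
}

#' Rapid dive updates
#'
#' Progressive rapid dives with Levy flights. Soft variant
#' (`|E| >= 0.5`, escape draw `r < 0.5`): `Y = rabbit - E * |J * rabbit -
#' position|`; hard variant (`|E| < 0.5`): the hawk position term is the swarm
#' mean. In both, `Z = Y + S (*) LF(D)` and the hawk keeps the first strict
#' improvement among Y, Z, else its current position (greedy acceptance).
#'
#' @inheritParams soft_besiege
#' @param objective the fitness callable (minimized).
#' @param bounds an [hho_bounds()].
#' @param swarm_mean mean position of the swarm (hard variant).
#' @param position_fitness objective value at `position`, if already known.
#' @param beta,scale Levy flight parameters.
#' @return the accepted position, with attributes `fitness` and
#'   `evaluations`.
#' @export
rapid_dive_soft <- function(position, rabbit, E, J, objective, bounds,
                            position_fitness = NULL, beta = 1.5, scale = 0.01) {
  Y <- rabbit - E * abs(J * rabbit - position)
  dive_greedy(Y, position, position_fitness, objective, bounds, beta, scale)
}

#' @rdname rapid_dive_soft
#' @export
rapid_dive_hard <- function(position, rabbit, swarm_mean, E, J, objective,
                            bounds, position_fitness = NULL, beta = 1.5,
                            scale = 0.01) {
  Y <- rabbit - E * abs(J * rabbit - swarm_mean)
  dive_greedy(Y, position, position_fitness, objective, bounds, beta, scale)
}

#' One optimizer iteration
#'
#' Per hawk: draw initial energy `E0 ~ U(-1, 1)` and compute the escape
#' energy; `|E| >= 1` explores, otherwise the escape draw `r` and `|E|`
#' dispatch soft/hard besiege or the corresponding rapid-dive branch. In the
#' chaotic variant (`chaos` supplied) the hawk-position term inside the
#' soft besiege is replaced by a fresh logistic-map position and that
#' candidate is greedily accepted; the hard besiege (prey exhausted, the
#' swarm collapsing onto the rabbit) keeps its canonical form, which
#' preserves late-stage convergence depth. Positions are clipped to the box, the
#' rabbit always holds the best evaluated point, and its fitness never
#' increases.
#'
#' @param swarm an `hho_swarm`.
#' @param objective fitness callable (minimized); must return finite values.
#' @param bounds an [hho_bounds()].
#' @param config an [hho_config()].
#' @param chaos optional [chaotic_state()]; supplying it selects the
#'   logistic-chaotic update.
#' @return the updated swarm; attributes `chaos` (advanced state) and
#'   `evaluations` (objective calls consumed).
#' @export
hho_iteration <- function(swarm, objective, bounds, config, chaos = NULL) {
  N <- nrow(swarm$positions)
  t <- swarm$iteration
  T_max <- swarm$max_iterations
  evals <- 0L
  eval_obj <- function(x) {
    f <- objective(x)
    if (!is.finite(f)) stop_numeric("objective returned a non-finite fitness")
    evals <<- evals + 1L
    f
  }
  for (i in seq_len(N)) {
    x <- swarm$positions[i, ]
    E0 <- stats::runif(1, -1, 1)
    E <- escape_energy(E0, t, T_max)
    if (abs(E) >= 1) {
      cand <- exploration_move(i, swarm, bounds)
      f <- eval_obj(cand)
      swarm$positions[i, ] <- cand
      swarm$fitness[i] <- f
    } else {
      r <- stats::runif(1)
      J <- 2 * (1 - stats::runif(1))
      if (r >= 0.5) {
        if (!is.null(chaos) && abs(E) >= 0.5) {
          # chaotic soft besiege: the hawk-position term is a fresh
          # logistic-map point (the jump-strength form of the substituted
          # equation matches the soft besiege only). The chaotic candidate
          # is accepted greedily; when it does not improve the hawk, the
          # canonical soft-besiege move is taken instead, so the chaotic
          # jumps add global exploration without forfeiting refinement.
          cp <- chaotic_position(chaos, bounds)
          chaos <- cp$state
          xc <- cp$position
          cand <- xc - E * abs(J * swarm$rabbit_position - xc)
          cand <- clip_to_bounds(cand, bounds)
          f <- eval_obj(cand)
          if (f < swarm$fitness[i]) {
            swarm$positions[i, ] <- cand
            swarm$fitness[i] <- f
          } else {
            cand <- clip_to_bounds(soft_besiege(x, swarm$rabbit_position, E, J),
                                   bounds)
            f <- eval_obj(cand)
            swarm$positions[i, ] <- cand
            swarm$fitness[i] <- f
          }
        } else {
          cand <- if (abs(E) >= 0.5) soft_besiege(x, swarm$rabbit_position, E, J)
                  else hard_besiege(x, swarm$rabbit_position, E)
          cand <- clip_to_bounds(cand, bounds)
          f <- eval_obj(cand)
          swarm$positions[i, ] <- cand
          swarm$fitness[i] <- f
        }
      } else {
        res <- if (abs(E) >= 0.5)
          rapid_dive_soft(x, swarm$rabbit_position, E, J, eval_obj, bounds,
                          position_fitness = swarm$fitness[i],
                          beta = config$levy_beta, scale = config$levy_scale)
        else
          rapid_dive_hard(x, swarm$rabbit_position, mean_position(swarm), E, J,
                          eval_obj, bounds,
                          position_fitness = swarm$fitness[i],
                          beta = config$levy_beta, scale = config$levy_scale)
        swarm$positions[i, ] <- as.numeric(res)
        swarm$fitness[i] <- attr(res, "fitness")
      }
    }
    if (swarm$fitness[i] < swarm$rabbit_fitness) {
      swarm$rabbit_fitness <- swarm$fitness[i]
      swarm$rabbit_position <- swarm$positions[i, ]
    }
  }
  swarm$iteration <- t + 1L
  attr(swarm, "chaos") <- chaos
  attr(swarm, "evaluations") <- evals
  swarm
}

#' @describeIn hho_iteration the logistic-chaotic iteration; identical to
#'   `hho_iteration` with a mandatory chaotic state.
#' @export
lc_hhoa_iteration <- function(swarm, objective, bounds, config, chaos) {
  stopifnot(inherits(chaos, "chaotic_state"))
  hho_iteration(swarm, objective, bounds, config, chaos = chaos)
}

#' Run the Harris Hawks Optimizer
#'
#' Minimizes `objective` over the box with the selected variant. The vanilla
#' variant initializes hawks uniformly at random; the logistic-chaotic
#' variant seeds the initial population from the logistic-map stream and
#' substitutes chaotic positions inside the besiege updates.
#'
#' @param objective fitness callable mapping a D-vector to a finite scalar.
#' @param bounds an [hho_bounds()].
#' @param config an [hho_config()].
#' @return object of class `hho_result`: `best_position`, `best_fitness`,
#'   `trace` (best-so-far fitness per iteration, non-increasing),
#'   `evaluations`, `iterations`, `variant`.
#' @examples
#' sphere <- function(x) sum(x^2)
#' b <- hho_bounds(rep(-10, 2), rep(10, 2))
#' res <- hho_optimize(sphere, b, hho_config(20, 50, seed = 1))
#' res$best_fitness
#' @export
hho_optimize <- function(objective, bounds, config = hho_config()) {
  stopifnot(inherits(bounds, "hho_bounds"), inherits(config, "hho_config"))
  with_seed(config$seed, {
    N <- config$population
    D <- bounds$dim
    chaos <- NULL
    if (config$variant == "lc_hhoa") {
      chaos <- chaotic_state(config$chaos_init, config$chaos_control)
      pos <- matrix(0, N, D)
      for (i in seq_len(N)) {
        cp <- chaotic_position(chaos, bounds)
        pos[i, ] <- cp$position
        chaos <- cp$state
      }
    } else {
      pos <- matrix(stats::runif(N * D), N, D)
      pos <- sweep(sweep(pos, 2, bounds$upper - bounds$lower, `*`),
                   2, bounds$lower, `+`)
    }
    fit <- apply(pos, 1, objective)
    if (any(!is.finite(fit))) stop_numeric("objective returned non-finite fitness")
    swarm <- hho_swarm(pos, fit, iteration = 0L,
                       max_iterations = config$max_iterations)
    evals <- N
    trace <- numeric(config$max_iterations)
    stall <- 0L
    iters <- 0L
    for (it in seq_len(config$max_iterations)) {
      prev_best <- swarm$rabbit_fitness
      swarm <- hho_iteration(swarm, objective, bounds, config, chaos = chaos)
      chaos <- attr(swarm, "chaos")
      evals <- evals + attr(swarm, "evaluations")
      trace[it] <- swarm$rabbit_fitness
      iters <- it
      if (swarm$rabbit_fitness < prev_best) stall <- 0L else stall <- stall + 1L
      if (stall > config$patience) break
    }
    structure(list(best_position = swarm$rabbit_position,
                   best_fitness = swarm$rabbit_fitness,
                   trace = trace[seq_len(iters)],
                   evaluations = evals,
                   iterations = iters,
                   variant = config$variant),
              class = "hho_result")
  })
}

#' @export
print.hho_result <- function(x, ...) {
  cat("Harris Hawks Optimization result (", x$variant, ")\n", sep = "")
  cat("  best fitness:", format(x$best_fitness, digits = 6),
      "after", x$iterations, "iterations,", x$evaluations, "evaluations\n")
  invisible(x)
}
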