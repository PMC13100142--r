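#' Define an objective for the optimizer
#'
#' An objective bundles a fitness function (minimization convention) with the
#' dimension and box bounds of its search space. Accuracy-style objectives
#' should be converted to an error upstream so that smaller is always better.
#'
#' @param name identifier for the objective.
#' @param dimension positive integer, number of search-space coordinates.
#' @param lower,upper numeric bounds; scalars are recycled to `dimension`.
#' @param fn function mapping a numeric position vector to a single finite
#'   fitness value.
#' @return an object of class `objective_spec`.
#' @examples
#' sphere <- objective_spec("sphere", 3, -5, 5, function(x) sum(x^2))
#' sphere$evaluate(c(1, 2, 0))
#' @export
objective_spec <- function(name, dimension, lower, upper, fn) {
  dimension <- as.integer(dimension)
  if (length(dimension) != 1L || is.na(dimension) || dimension < 1L)
    stop("'dimension' must be a positive integer")
  lower <- rep_len(as.numeric(lower), dimension)
  upper <- rep_len(as.numeric(upper), dimension)
  if (any(!is.finite(lower)) || any(!is.finite(upper)))
    stop("bounds must be finite")
  if (any(lower > upper))
    stop("lower bounds must not exceed upper bounds")
  if (!is.function(fn)) stop("'fn' must be a function")
  structure(list(name = name, dimension = dimension,
                 lower = lower, upper = upper, evaluate = fn),
            class = "objective_spec")
}

#' Settings for the Al-Biruni Earth Radius optimizer
#'
#' The population is split into an exploration group and an exploitation
#' group. The exploitation share starts at `exploit_fraction_start` and grows
#' linearly to `exploit_fraction_end` over the run, so early iterations probe
#' the space widely while late iterations refine around the leader. An agent
#' whose fitness fails to improve by more than `stagnation_tolerance` for
#' `stagnation_window` consecutive iterations is replaced by a mutated
#' position.
#'
#' @param population_size number of agents (n).
#' @param iterations number of iterations (N).
#' @param exploit_fraction_start,exploit_fraction_end exploitation-group
#'   fraction at the first and last iteration.
#' @param stagnation_window consecutive non-improving iterations before an
#'   agent is mutated.
#' @param stagnation_tolerance minimum fitness decrease that counts as an
#'   improvement.
#' @param r_cap cap on the absolute value of the trigonometric step factor
#'   `h * cos(x) / (1 - cos(x))`, which is unbounded as x approaches 0.
#' @param x_min_degrees lower bound (degrees) for the sampled angle x,
#'   guarding the cos(x) -> 1 singularity.
#' @param seed integer seed; every stochastic draw of a run flows from it.
#' @return an object of class `ber_settings`.
#' @export
ber_settings <- function(population_size = 15L, iterations = 100L,
                         exploit_fraction_start = 0.3,
                         exploit_fraction_end = 0.7,
                         stagnation_window = 3L,
                         stagnation_tolerance = 1e-12,
                         r_cap = 10, x_min_degrees = 1, seed = 1L) {
  population_size <- as.integer(population_size)
  iterations <- as.integer(iterations)
  if (population_size < 1L) stop("'population_size' must be >= 1")
  if (iterations < 0L) stop("'iterations' must be >= 0")
  if (exploit_fraction_start < 0 || exploit_fraction_start > 1 ||
      exploit_fraction_end < 0 || exploit_fraction_end > 1)
    stop("exploitation fractions must lie in [0, 1]")
  if (x_min_degrees <= 0 || x_min_degrees > 180)
    stop("'x_min_degrees' must lie in (0, 180]")
  if (r_cap <= 0) stop("'r_cap' must be positive")
  structure(list(population_size = population_size, iterations = iterations,
                 exploit_fraction_start = exploit_fraction_start,
                 exploit_fraction_end = exploit_fraction_end,
                 stagnation_window = as.integer(stagnation_window),
                 stagnation_tolerance = stagnation_tolerance,
                 r_cap = r_cap, x_min_degrees = x_min_degrees,
                 seed = as.integer(seed)),
            class = "ber_settings")
}

#' Trigonometric step factor
#'
#' Computes `r = h * cos(x) / (1 - cos(x))` with x in degrees, the radius-like
#' coefficient that scales exploitation moves. The ratio diverges as x -> 0,
#' so the result is clamped to `[-r_cap, r_cap]`.
#'
#' @param h scalar in `[0, 2]`.
#' @param x_degrees angle in degrees, in (0, 180].
#' @param r_cap clamp on the absolute value.
#' @return a scalar.
#' @examples
#' sample_r(1, 90)   # 0
#' sample_r(1, 60)   # 1
#' sample_r(1, 180)  # -0.5
#' @export
sample_r <- function(h, x_degrees, r_cap = 10) {
  if (any(x_degrees <= 0) || any(x_degrees > 180))
    stop("'x_degrees' must lie in (0, 180]")
  cx <- cospi(x_degrees / 180)
  r <- h * cx / (1 - cx)
  pmin(pmax(r, -r_cap), r_cap)
}

#' Exploration move
#'
#' An exploration agent probes the neighbourhood of its current position:
#' the displacement `D = r1 * (S - 1)` (elementwise, scalar 1 broadcast) is
#' applied with a random sign-and-magnitude factor `2 * r2 - 1`, so each
#' coordinate moves by at most `|D|` in either direction. The caller is
#' responsible for clipping to bounds.
#'
#' @param position current position vector S.
#' @param r1,r2 coefficient vectors, elementwise in `[0, 1]`, same length
#'   as `position`.
#' @return the proposed position.
#' @export
exploration_step <- function(position, r1, r2) {
  d <- length(position)
  if (length(r1) != d || length(r2) != d)
    stop("'r1' and 'r2' must have the same length as 'position'")
  D <- r1 * (position - 1)
  position + D * (2 * r2 - 1)
}

#' Exploitation move toward the leader
#'
#' Moves an agent a random fraction `r3` of the way toward the leader and
#' rescales by `r^2`, where `r` comes from [sample_r()].
#'
#' @param position current position S.
#' @param leader leader position L.
#' @param r scalar step factor.
#' @param r3 coefficient vector in `[0, 1]`, same length as `position`.
#' @return the proposed position `r^2 * (S + r3 * (L - S))`.
#' @export
exploit_toward_leader <- function(position, leader, r, r3) {
  d <- length(position)
  if (length(leader) != d || length(r3) != d)
    stop("'leader' and 'r3' must have the same length as 'position'")
  D <- r3 * (leader - position)
  r^2 * (position + D)
}

#' Exploitation move around the leader
#'
#' Probes the region surrounding the current best solution. The offset
#' `k = z + 2 t^2 / N^2` grows quadratically over the run, widening the
#' probed shell in late iterations.
#'
#' @param leader leader position.
#' @param r scalar step factor.
#' @param z scalar in `[0, 1]`.
#' @param t current iteration.
#' @param n_iter total number of iterations N.
#' @return the proposed position `r * (leader + k)`.
#' @export
exploit_around_leader <- function(leader, r, z, t, n_iter) {
  if (n_iter == 0) stop("'n_iter' must be positive")
  if (t < 0 || t > n_iter) stop("'t' must lie in [0, n_iter]")
  k <- z + 2 * t^2 / n_iter^2
  r * (leader + k)
}

#' Mutation value for a stagnated coordinate
#'
#' Replacement value `k * z^2 - h * cos(x) / (1 - cos(x))` used when an agent
#' has stagnated; the trigonometric term uses the same degree convention and
#' cap as [sample_r()].
#'
#' @param k scalar offset (in the optimizer, `z + 2 t^2 / N^2`).
#' @param z scalar in `[0, 1]`.
#' @param h scalar in `[0, 2]`.
#' @param x_degrees angle in degrees, in (0, 180].
#' @param r_cap clamp on the trigonometric term.
#' @return a scalar replacement value.
#' @export
mutate_position <- function(k, z, h, x_degrees, r_cap = 10) {
  k * z^2 - sample_r(h, x_degrees, r_cap)
}

#' Exploration/exploitation group sizes at an iteration
#'
#' The exploitation fraction interpolates linearly from
#' `exploit_fraction_start` at t = 0 to `exploit_fraction_end` at t = N.
#' Both groups keep at least one member whenever the population has two.
#'
#' @param t iteration in `[0, N]`.
#' @param settings a [ber_settings()] object.
#' @return integer vector `c(n_exploit, n_explore)`.
#' @examples
#' update_group_sizes(0, ber_settings(population_size = 10, iterations = 10))
#' @export
update_group_sizes <- function(t, settings) {
  n <- settings$population_size
  N <- settings$iterations
  frac <- if (N == 0) settings$exploit_fraction_start else
    settings$exploit_fraction_start +
      (settings$exploit_fraction_end - settings$exploit_fraction_start) * t / N
  n_exploit <- as.integer(round(frac * n))
  if (n >= 2L) {
    n_exploit <- max(1L, min(n - 1L, n_exploit))
  } else {
    n_exploit <- min(n, max(0L, n_exploit))
  }
  c(n_exploit = n_exploit, n_explore = n - n_exploit)
}

## fitness evaluation with the non-finite guard: a position whose fitness is
## NaN/Inf is kept in the population but scored +Inf so it can never lead
eval_fitness <- function(spec, position) {
  f <- spec$evaluate(position)
  if (!is.finite(f)) {
    warning("non-finite fitness treated as +Inf", call. = FALSE)
    f <- Inf
  }
  f
}

clip_bounds <- function(x, spec) pmin(pmax(x, spec$lower), spec$upper)

#' Initialize the optimizer population
#'
#' Draws `population_size` positions uniformly within the bounds, evaluates
#' them, assigns exploration/exploitation roles per the t = 0 group split and
#' records the initial leader. Consumes the current RNG stream; [ber_run()]
#' seeds it from `settings$seed`.
#'
#' @param spec an [objective_spec()].
#' @param settings a [ber_settings()].
#' @return an object of class `ber_state` with elements `agents`, `leader`,
#'   `iteration`, `best_history`, `evaluations`, `rng_state`.
#' @export
ber_initialize <- function(spec, settings) {
  n <- settings$population_size
  d <- spec$dimension
  sizes <- update_group_sizes(0L, settings)
  roles <- rep(c("exploitation", "exploration"), c(sizes[1L], sizes[2L]))
  agents <- vector("list", n)
  for (i in seq_len(n)) {
    pos <- spec$lower + stats::runif(d) * (spec$upper - spec$lower)
    agents[[i]] <- list(position = pos,
                        fitness = eval_fitness(spec, pos),
                        role = roles[i],
                        stagnation_count = 0L)
  }
  fits <- vapply(agents, `[[`, numeric(1), "fitness")
  best <- which.min(fits)  # ties: lowest index
  structure(list(agents = agents,
                 leader = agents[[best]][c("position", "fitness")],
                 iteration = 0L,
                 best_history = fits[best],
                 evaluations = n,
                 rng_state = .Random.seed),
            class = "ber_state")
}

#' Advance the optimizer by one iteration
#'
#' Exploration agents move via [exploration_step()]; exploitation agents pick
#' one of the two exploitation strategies by a fair coin each iteration. All
#' positions are clipped to bounds and re-evaluated. Elitism: the leader is
#' replaced only by a strictly better solution, and if every current agent is
#' worse than the leader, the leader overwrites the worst agent. Agents that
#' stagnated for `stagnation_window` iterations are replaced by mutation.
#' Finally the agent order is shuffled and roles are reassigned from the
#' iteration's group sizes.
#'
#' @param state a `ber_state` from [ber_initialize()] or a previous step.
#' @param spec the [objective_spec()].
#' @param settings the [ber_settings()].
#' @return the updated `ber_state`.
#' @export
ber_step <- function(state, spec, settings) {
  assign(".Random.seed", state$rng_state, envir = globalenv())
  t <- state$iteration + 1L
  N <- max(settings$iterations, 1L)
  d <- spec$dimension
  n <- length(state$agents)
  L <- state$leader$position
  evals <- 0L

  for (i in seq_len(n)) {
    a <- state$agents[[i]]
    if (a$role == "exploration") {
      r1 <- stats::runif(d)
      r2 <- stats::runif(d)
      newpos <- exploration_step(a$position, r1, r2)
    } else if (stats::runif(1) < 0.5) {
      r <- sample_r(stats::runif(1, 0, 2),
                    stats::runif(1, settings$x_min_degrees, 180),
                    settings$r_cap)
      r3 <- stats::runif(d)
      newpos <- exploit_toward_leader(a$position, L, r, r3)
    } else {
      r <- sample_r(stats::runif(1, 0, 2),
                    stats::runif(1, settings$x_min_degrees, 180),
                    settings$r_cap)
      z <- stats::runif(1)
      newpos <- exploit_around_leader(L, r, z, t, N)
    }
    newpos <- clip_bounds(newpos, spec)
    newfit <- eval_fitness(spec, newpos)
    evals <- evals + 1L

    # Inf - Inf is NaN; treat any non-finite comparison as no improvement
    improved <- isTRUE((a$fitness - newfit) >= settings$stagnation_tolerance)
    a$stagnation_count <- if (improved) 0L else a$stagnation_count + 1L
    a$position <- newpos
    a$fitness <- newfit

    if (a$stagnation_count >= settings$stagnation_window) {
      # wholesale replacement: each coordinate gets an independent draw
      z <- stats::runif(d)
      h <- stats::runif(d, 0, 2)
      x <- stats::runif(d, settings$x_min_degrees, 180)
      k <- z + 2 * t^2 / N^2
      mut <- clip_bounds(mutate_position(k, z, h, x, settings$r_cap), spec)
      a$position <- mut
      a$fitness <- eval_fitness(spec, mut)
      evals <- evals + 1L
      a$stagnation_count <- 0L
    }
    state$agents[[i]] <- a
  }

  fits <- vapply(state$agents, `[[`, numeric(1), "fitness")
  best <- which.min(fits)
  if (fits[best] < state$leader$fitness) {
    state$leader <- state$agents[[best]][c("position", "fitness")]
  } else if (all(fits > state$leader$fitness)) {
    # elitist reinsertion over the current worst agent
    worst <- which.max(fits)
    state$agents[[worst]]$position <- state$leader$position
    state$agents[[worst]]$fitness <- state$leader$fitness
    state$agents[[worst]]$stagnation_count <- 0L
  }

  perm <- sample.int(n)
  state$agents <- state$agents[perm]
  sizes <- update_group_sizes(t, settings)
  roles <- rep(c("exploitation", "exploration"), c(sizes[1L], sizes[2L]))
  for (i in seq_len(n)) state$agents[[i]]$role <- roles[i]

  state$iteration <- t
  state$best_history <- c(state$best_history, state$leader$fitness)
  state$evaluations <- state$evaluations + evals
  state$rng_state <- .Random.seed
  state
}

#' Run the Al-Biruni Earth Radius optimizer
#'
#' Seeds the RNG from `settings$seed`, initializes the population and runs
#' `settings$iterations` steps. The best-fitness trajectory is non-increasing
#' by elitism and its final entry equals the returned best fitness.
#'
#' @param spec an [objective_spec()].
#' @param settings a [ber_settings()].
#' @return an object of class `ber_result` with `best_position`,
#'   `best_fitness`, `trajectory`, `evaluations` and a `settings` echo.
#' @examples
#' sphere <- objective_spec("sphere", 5, -5, 5, function(x) sum(x^2))
#' res <- ber_run(sphere, ber_settings(population_size = 10, iterations = 20,
#'                                     seed = 42))
#' res$best_fitness
#' @export
ber_run <- function(spec, settings) {
  set.seed(settings$seed)
  state <- ber_initialize(spec, settings)
  for (t in seq_len(settings$iterations)) {
    state <- ber_step(state, spec, settings)
  }
  structure(list(best_position = state$leader$position,
                 best_fitness = state$leader$fitness,
                 trajectory = state$best_history,
                 evaluations = state$evaluations,
                 settings = settings),
            class = "ber_result")
}

#' @export
print.ber_result <- function(x, ...) {
  cat("BER optimization result\n")
  cat("  best fitness:", format(x$best_fitness), "\n")
  cat("  iterations:  ", length(x$trajectory) - 1L, "\n")
  cat("  evaluations: ", x$evaluations, "\n")
  invisible(x)
}

#' Uniform random search control
#'
#' Evaluates `n_evals` positions drawn uniformly within the bounds and keeps
#' the best; the null optimizer against which BER is benchmarked at equal
#' evaluation budget.
#'
#' @param spec an [objective_spec()].
#' @param n_evals evaluation budget.
#' @param seed integer seed.
#' @return a list with `best_position`, `best_fitness`, `trajectory`,
#'   `evaluations`.
#' @export
random_search <- function(spec, n_evals, seed = 1L) {
  set.seed(seed)
  d <- spec$dimension
  best_fit <- Inf
  best_pos <- NULL
  traj <- numeric(n_evals)
  for (i in seq_len(n_evals)) {
    pos <- spec$lower + stats::runif(d) * (spec$upper - spec$lower)
    f <- eval_fitness(spec, pos)
    if (f < best_fit) {
      best_fit <- f
      best_pos <- pos
    }
    traj[i] <- best_fit
  }
  list(best_position = best_pos, best_fitness = best_fit,
       trajectory = traj, evaluations = n_evals)
}
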