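sphere10 <- make_benchmark("sphere", 10)

test_that("trigonometric step factor matches its closed forms and domain", {
  expect_equal(sample_r(1.7, 90), 0)
  expect_equal(sample_r(1, 180), -0.5)
  expect_equal(sample_r(1, 60), 1)
  # divergence near x = 0 is clamped
  expect_equal(sample_r(2, 1e-4), 10)
  expect_equal(sample_r(2, 1e-4, r_cap = 3), 3)
  expect_error(sample_r(1, 0), "x_degrees")
  expect_error(sample_r(1, 181), "x_degrees")
})

test_that("exploration move: null move, fixed point, direct arithmetic", {
  S <- c(2, -1, 0.5)
  expect_equal(exploration_step(S, runif(3), rep(0.5, 3)), S)
  expect_equal(exploration_step(rep(1, 4), runif(4), runif(4)), rep(1, 4))
  expect_equal(exploration_step(3, 0.5, 1), 4)
  expect_error(exploration_step(S, runif(2), runif(3)), "length")
})

test_that("exploitation moves follow their update equations", {
  S <- c(1, 2); L <- c(-1, 0)
  expect_equal(exploit_toward_leader(S, L, 1, c(1, 1)), L)
  expect_equal(exploit_toward_leader(S, L, 0, runif(2)), c(0, 0))
  expect_equal(exploit_toward_leader(0, 2, 1, 0.5), 1)
  expect_error(exploit_toward_leader(S, L, 1, runif(3)), "length")

  expect_equal(exploit_around_leader(L, 0.3, z = 0, t = 0, n_iter = 10),
               0.3 * L)
  # schedule end: k = 2
  expect_equal(exploit_around_leader(0, 1, z = 0, t = 10, n_iter = 10), 2)
  expect_equal(exploit_around_leader(1, 1, z = 0.5, t = 5, n_iter = 10), 2)
  expect_error(exploit_around_leader(L, 1, 0.5, 0, 0), "positive")
})

test_that("mutation value follows the replacement formula", {
  expect_equal(mutate_position(5, 0, 1, 90), 0)
  expect_equal(mutate_position(1, 1, 1, 90), 1)
  expect_equal(mutate_position(2, 0.5, 1, 60), -0.5)
})

test_that("group sizes interpolate 30% -> 70% and always conserve n", {
  st <- ber_settings(population_size = 10L, iterations = 10L)
  expect_equal(unname(update_group_sizes(0, st)), c(3L, 7L))
  expect_equal(unname(update_group_sizes(10, st)), c(7L, 3L))
  expect_equal(unname(update_group_sizes(5, st)), c(5L, 5L))
  for (n in c(2L, 5L, 23L)) {
    stn <- ber_settings(population_size = n, iterations = 7L)
    for (t in 0:7) {
      gs <- update_group_sizes(t, stn)
      expect_equal(sum(gs), n)
      expect_true(all(gs >= 1L))
    }
  }
})

test_that("initialization: bounds, roles, and an independent re-draw", {
  st <- ber_settings(population_size = 10L, iterations = 5L, seed = 7L)
  degenerate <- objective_spec("point", 2, 2, 2, function(x) sum(x))
  set.seed(7)
  state <- ber_initialize(degenerate, st)
  for (a in state$agents) expect_equal(a$position, c(2, 2))
  roles <- vapply(state$agents, `[[`, character(1), "role")
  expect_equal(sum(roles == "exploitation"), 3L)
  expect_equal(sum(roles == "exploration"), 7L)

  # independent seeded re-draw of the same generator protocol
  spec <- objective_spec("unit", 5, 0, 1, function(x) sum(x^2))
  set.seed(42)
  state <- ber_initialize(spec, st)
  set.seed(42)
  expected <- lapply(1:10, function(i) runif(5))
  for (i in 1:10) expect_equal(state$agents[[i]]$position, expected[[i]])

  expect_error(objective_spec("bad", 3, 1, 0, identity), "lower bounds")
  expect_error(objective_spec("bad", 0, 0, 1, identity), "dimension")
})

test_that("elitism, feasibility and budget hold across seeded runs", {
  st <- ber_settings(population_size = 8L, iterations = 30L, seed = 1L)
  for (seed in c(1L, 2L, 3L)) {
    for (spec in list(sphere10, make_benchmark("schwefel_2_22", 5),
                      make_benchmark("sum_squares", 4))) {
      st$seed <- seed
      res <- ber_run(spec, st)
      expect_true(all(diff(res$trajectory) <= 0))
      expect_true(all(res$best_position >= spec$lower - 1e-12))
      expect_true(all(res$best_position <= spec$upper + 1e-12))
      expect_equal(res$trajectory[length(res$trajectory)], res$best_fitness)
      n <- st$population_size; N <- st$iterations
      expect_lte(res$evaluations,
                 n * (N + 1) + floor(n * N / st$stagnation_window))
    }
  }
})

test_that("a flat landscape leaves the leader fitness unchanged", {
  flat <- objective_spec("flat", 3, -1, 1, function(x) 4.2)
  res <- ber_run(flat, ber_settings(population_size = 6L, iterations = 10L,
                                    seed = 3L))
  expect_true(all(res$trajectory == 4.2))
})

test_that("zero iterations return the best of the initial population", {
  st <- ber_settings(population_size = 12L, iterations = 0L, seed = 11L)
  res <- ber_run(sphere10, st)
  set.seed(11)
  d <- sphere10$dimension
  fits <- replicate(12, sphere10$evaluate(
    sphere10$lower + runif(d) * (sphere10$upper - sphere10$lower)))
  expect_equal(res$best_fitness, min(fits))
  expect_equal(length(res$trajectory), 1L)
})

test_that("identical seeds give bit-identical runs", {
  st <- ber_settings(population_size = 10L, iterations = 25L, seed = 99L)
  r1 <- ber_run(sphere10, st)
  r2 <- ber_run(sphere10, st)
  expect_identical(r1$best_position, r2$best_position)
  expect_identical(r1$trajectory, r2$trajectory)
})

test_that("non-finite fitness is flagged and never leads", {
  spiky <- objective_spec("spiky", 2, -1, 1,
                          function(x) if (x[1] > 0) NaN else sum(x^2))
  st <- ber_settings(population_size = 6L, iterations = 5L, seed = 2L)
  w <- capture_warnings(res <- ber_run(spiky, st))
  expect_gte(length(w), 1L)
  expect_true(all(grepl("non-finite", w)))
  expect_true(is.finite(res$best_fitness))
})
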