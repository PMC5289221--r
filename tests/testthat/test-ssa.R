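test_that("trajectories are deterministic given (seed, cell_index)", {
  p <- rate_params("initial")
  prof <- step_pair(1)
  a <- simulate_cell(p, prof, t_end = 8, seed = 42, cell_index = 3L)
  b <- simulate_cell(p, prof, t_end = 8, seed = 42, cell_index = 3L)
  expect_identical(a$events, b$events)
  d <- simulate_cell(p, prof, t_end = 8, seed = 43, cell_index = 3L)
  expect_false(identical(a$events, d$events))
})

test_that("simulate_cell reproduces any cell of an ensemble", {
  p <- rate_params("revised")
  prof <- pulse_b(1, 2)
  ens <- simulate_population(p, prof, t_end = 10, n_cells = 20, seed = 7)
  for (i in c(1L, 11L, 20L)) {
    tr <- simulate_cell(p, prof, t_end = 10, seed = 7, cell_index = i)
    expect_equal(tr$final$dna,
                 c("S_o", "S_a", "S_b", "S_ab")[ens$final_dna[i] + 1L])
  }
})

test_that("the null process produces no events", {
  p <- rate_params(kleakA = 0, kleakB = 0)
  prof <- induction_profile(NULL, NULL)    # never induced
  tr <- simulate_cell(p, prof, t_end = 20, seed = 1)
  expect_equal(nrow(tr$events), 0L)
  expect_equal(tr$final$dna, "S_o")
  expect_equal(tr$final$intA, 0L)
  expect_equal(tr$final$intB, 0L)
})

test_that("inter-event times of a pure birth process are exponential", {
  # only IntA births active: rate kprodA, no deaths, no flips possible
  p <- rate_params(kprodA = 50, kprodB = 0, kdeg = 0, kflipA = 0,
                   kflipB = 0, kflipB_exc = 0)
  tr <- simulate_cell(p, step_pair(0), t_end = 20, seed = 11)
  waits <- diff(c(0, tr$events$time))
  expect_gt(length(waits), 500)
  ks <- stats::ks.test(waits, "pexp", rate = 50)
  expect_gt(ks$p.value, 0.001)
})

test_that("IntA count reaches the birth-death stationary mean", {
  # kprod/kdeg = 50/0.3 = 166.67; flips do not alter counts
  p <- rate_params("initial")
  ens <- simulate_population(p, step_pair(0), t_end = 30, n_cells = 300,
                             seed = 5, grid = 30, record_counts = TRUE)
  m <- mean(ens$intA_grid[, 1])
  mu <- 50 / 0.3
  se <- sqrt(mu) / sqrt(300)                # Poisson stationary variance
  expect_lt(abs(m - mu), 4 * se)
})

test_that("splitting a segment at an artificial breakpoint is invariant", {
  p <- rate_params("initial")
  whole <- step_pair(0)                               # a & b on [0, Inf)
  split <- induction_profile(matrix(c(0, 5, 5, Inf), 2, byrow = TRUE),
                             matrix(c(0, 5, 5, Inf), 2, byrow = TRUE))
  n <- 2000
  e1 <- simulate_population(p, whole, 12, n, seed = 21)
  e2 <- simulate_population(p, split, 12, n, seed = 22)
  f1 <- tabulate(e1$final_dna + 1L, 4) / n
  f2 <- tabulate(e2$final_dna + 1L, 4) / n
  se <- sqrt(2 * 0.25 / n)
  expect_true(all(abs(f1 - f2) < 4 * se))
})

test_that("fractions sum to one and S_o is non-increasing (absorption)", {
  p <- rate_params("revised")
  ens <- simulate_population(p, step_pair(1), t_end = 15, n_cells = 500,
                             seed = 3)
  tab <- state_fractions(ens, grid = seq(0, 15, by = 0.5))
  sums <- rowSums(tab[, c("frac_S_o", "frac_S_a", "frac_S_b", "frac_S_ab")])
  expect_equal(sums, rep(1, nrow(tab)))
  expect_true(all(diff(tab$frac_S_o) <= 0))
})

test_that("cells flip at most twice and flips follow the gate topology", {
  p <- rate_params("initial")
  ens <- simulate_population(p, step_pair(0), 12, 500, seed = 9)
  nf <- rowSums(!is.na(ens$flip_time))
  expect_true(all(nf <= 2))
  first <- ens$flip_to[, 1]
  expect_true(all(is.na(first) | first %in% c(1L, 2L)))  # S_o -> S_a or S_b
  second <- ens$flip_to[, 2]
  has2 <- !is.na(second)
  expect_true(all(second[has2] == 3L))                   # S_a -> S_ab only
  expect_true(all(first[has2] == 1L))
})

test_that("the event guard stops runaway simulations", {
  p <- rate_params("initial")
  expect_error(simulate_cell(p, step_pair(0), 24, seed = 1, max_events = 10),
               "max_events")
})
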