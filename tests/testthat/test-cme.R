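test_that("closed-form chain solution matches hand values", {
  # a1 = 0, a2 = a3 = 1, t = 1: degenerate case a1 + a2 = a3
  m <- conditional_dna_solution(0, 1, 1, 1)
  expect_equal(m[1, "P_S_o"], exp(-1), ignore_attr = TRUE)
  expect_equal(m[1, "P_S_a"], exp(-1), ignore_attr = TRUE)
  expect_equal(m[1, "P_S_b"], 0, ignore_attr = TRUE)
  expect_equal(m[1, "P_S_ab"], 1 - 2 * exp(-1), ignore_attr = TRUE)
})

test_that("closed-form solution conserves probability and is consistent", {
  t <- seq(0, 10, by = 0.25)
  m <- conditional_dna_solution(0.3, 0.5, 0.7, t)
  expect_equal(rowSums(m), rep(1, length(t)))
  expect_equal(m[1, ], c(P_S_o = 1, P_S_a = 0, P_S_b = 0, P_S_ab = 0))
  # branch ratio at t -> Inf: P(S_b) -> a1 / (a1 + a2)
  late <- conditional_dna_solution(0.3, 0.5, 0.7, 100)
  expect_equal(late[1, "P_S_b"], 0.3 / 0.8, tolerance = 1e-6,
               ignore_attr = TRUE)
  # degenerate-case continuity: a3 = a1 + a2 vs a slightly different a3
  md <- conditional_dna_solution(0.3, 0.5, 0.8, 2)
  mn <- conditional_dna_solution(0.3, 0.5, 0.8 + 1e-6, 2)
  expect_equal(md, mn, tolerance = 1e-4)
  expect_error(conditional_dna_solution(-1, 1, 1, 1), "non-negative")
  expect_error(conditional_dna_solution(0, 1, 1, -1), ">= 0")
})

test_that("closed form solves the frozen-propensity master equation", {
  a1 <- 0.2; a2 <- 0.4; a3 <- 0.5
  rhs <- function(t, y, parms)
    list(c(-(a1 + a2) * y[1], a2 * y[1] - a3 * y[2], a1 * y[1], a3 * y[2]))
  num <- deSolve::ode(c(1, 0, 0, 0), times = c(0, 1, 3, 7), rhs, NULL,
                      rtol = 1e-10, atol = 1e-12)
  ana <- conditional_dna_solution(a1, a2, a3, c(0, 1, 3, 7))
  expect_equal(unname(num[, 2:5]), unname(ana), tolerance = 1e-7)
})

test_that("truncated CME conserves probability up to the tracked defect", {
  p <- rate_params(kprodA = 3, kprodB = 3, kdeg = 0.3, kflipA = 0.4,
                   kflipB = 0.4)
  sol <- solve_truncated_cme(p, step_pair(0), t_end = 6, capA = 25,
                             capB = 25, grid = c(0, 2, 4, 6))
  tot <- sol$P_S_o + sol$P_S_a + sol$P_S_b + sol$P_S_ab + sol$mass_defect
  expect_equal(tot, rep(1, nrow(sol)), tolerance = 1e-6)
  expect_equal(sol$P_S_o[1], 1)
  expect_true(all(diff(sol$P_S_o) <= 1e-10))
  expect_false(attr(sol, "defect_warning"))
})

test_that("tight caps trigger the mass-defect warning", {
  p <- rate_params(kprodA = 10, kprodB = 10, kdeg = 0.3)
  expect_warning(
    solve_truncated_cme(p, step_pair(0), t_end = 8, capA = 8, capB = 8,
                        grid = c(0, 8)),
    "mass defect")
})

test_that("SSA marginals agree with the CME oracle at reduced rates", {
  p <- rate_params(kprodA = 5, kprodB = 5, kdeg = 0.3, kflipA = 0.4,
                   kflipB = 0.4)
  prof <- step_pair(0)
  n <- 4000
  cme <- solve_truncated_cme(p, prof, t_end = 8, capA = 35, capB = 35,
                             grid = 8)
  ens <- simulate_population(p, prof, t_end = 8, n_cells = n, seed = 17)
  emp <- tabulate(ens$final_dna + 1L, 4) / n
  prob <- as.numeric(cme[nrow(cme), c("P_S_o", "P_S_a", "P_S_b", "P_S_ab")])
  se <- sqrt(pmax(prob * (1 - prob), 1e-12) / n)
  expect_true(all(abs(emp - prob) <= 3 * se))
})

test_that("marginal-ODE self-consistency rejects a falsified ensemble", {
  p <- rate_params(kprodA = 5, kprodB = 5, kdeg = 0.3, kflipA = 0.4,
                   kflipB = 0.4)
  grid <- seq(0, 8, by = 0.25)
  ens <- simulate_population(p, step_pair(0), 8, 1500, seed = 23,
                             grid = grid, record_counts = TRUE)
  ok <- verify_marginal_ode(ens)
  expect_true(ok$pass)
  # negative control: pretend the ensemble was generated with a much
  # faster kflipA than it actually was
  bad <- ens
  bad$params <- update_params(p, kflipA = 2.0)
  res <- verify_marginal_ode(bad)
  expect_false(res$pass)
  expect_gt(res$max_residual, 3 * res$tol)
})

test_that("verify_marginal_ode demands gridded count records", {
  ens <- simulate_population(rate_params("initial"), step_pair(0), 5, 50,
                             seed = 1)
  expect_error(verify_marginal_ode(ens), "record_counts")
})
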