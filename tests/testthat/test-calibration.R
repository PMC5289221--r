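test_that("curve_mse matches hand arithmetic and is symmetric", {
  a <- c("0" = 0.5, "1" = 0.7)
  b <- c("0" = 0.5, "1" = 0.9)
  expect_equal(curve_mse(a, b), 0.02)
  expect_equal(curve_mse(b, a), 0.02)
  expect_equal(curve_mse(a, a), 0)
  # lists of curves: mean over all points of all curves
  expect_equal(curve_mse(list(a, a), list(b, a)), 0.01)
})

test_that("curve_mse rejects mismatched keys and list shapes", {
  expect_error(curve_mse(c("0" = 0.5), c("1" = 0.5)), "not shared")
  expect_error(curve_mse(list(c("0" = 1)), c("0" = 1)), "both")
  expect_error(curve_mse(list(c("0" = 1)), list(c("0" = 1), c("1" = 1))),
               "lengths differ")
})

test_that("normalize_fractions rescales by the switching ceiling", {
  tab <- tibble::tibble(frac_S_o = 0.4, frac_S_a = 0.42, frac_S_b = 0.1,
                        frac_S_ab = 0.08)
  out <- normalize_fractions(tab, max_switch = 0.70)
  expect_equal(out$frac_S_a, 0.6)
  expect_equal(out$frac_S_o, 0.4)            # untouched
  expect_equal(attr(out, "normalization"), 0.7)
  expect_warning(normalize_fractions(tibble::tibble(
    frac_S_o = 0, frac_S_a = 0.9, frac_S_b = 0, frac_S_ab = 0.1),
    max_switch = 0.7), "clipped")
  expect_error(normalize_fractions(tab, max_switch = 0), "\\(0, 1]")
  expect_error(normalize_fractions(tab, max_switch = 1.2), "\\(0, 1]")
})

test_that("a single candidate pair is selected trivially", {
  p <- rate_params("revised")
  obs <- rbind(scan_dt(p, "ab", c(0, 2, 4), n_cells = 150, seed = 8),
               scan_dt(p, "ba", c(0, 2, 4), n_cells = 150, seed = 9))
  fit <- grid_fit(obs, kflip_candidates = 0.3, n_cells = 100, seed = 1)
  expect_equal(unname(fit$best_pair), c(0.3, 0.3))
  expect_equal(dim(fit$mse_matrix), c(1L, 1L))
})

test_that("self-fit: a pair's own curves give it the minimal MSE", {
  # construct obs exactly as grid_fit will simulate candidate (0.2, 0.4),
  # i.e. same derived seed chain, so its MSE is 0 there
  cand <- c(0.2, 0.4)
  fixed <- rate_params("revised")
  seed <- 33
  i <- 1L; j <- 2L                      # position of (0.2, 0.4) in the grid
  pars <- update_params(fixed, kflipA = 0.2, kflipB = 0.4,
                        kflipB_exc = 0.4,
                        kleakA = 0.01 * fixed$kprodA,
                        kleakB = 0.02 * fixed$kprodB)
  sub <- tempogate:::derive_seed(seed, i, salt = j)
  dts <- c(0, 2, 4)
  obs <- rbind(
    scan_dt(pars, "ab", dts, 200, seed = tempogate:::derive_seed(sub, 1L)),
    scan_dt(pars, "ba", dts, 200, seed = tempogate:::derive_seed(sub, 2L)))
  fit <- grid_fit(obs, kflip_candidates = cand, n_cells = 200, seed = seed)
  expect_equal(unname(fit$best_pair), c(0.2, 0.4))
  expect_equal(min(fit$mse_matrix), 0)
})

test_that("grid_fit demands both event orders", {
  p <- rate_params("revised")
  obs <- scan_dt(p, "ab", c(0, 2), n_cells = 100, seed = 1)
  expect_error(grid_fit(obs, 0.3, n_cells = 50), "E_ba")
})

test_that("sweep_parameter handles empty values and unknown names", {
  p <- rate_params("initial")
  expect_error(sweep_parameter(p, "nope", 0.3), "unknown parameter")
  out <- sweep_parameter(p, "kflipA", numeric(0), dts = 0:1, n_cells = 50)
  expect_equal(nrow(out), 0L)
  out2 <- sweep_parameter(p, "kflipA", c(0.2, 0.4), dts = c(0, 1),
                          n_cells = 100, seed = 2)
  expect_equal(nrow(out2), 4L)
  expect_setequal(unique(out2$param_value), c(0.2, 0.4))
  expect_equal(attr(out2, "swept"), "kflipA")
})
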