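test_that("noise_model validates growth bias names", {
  expect_error(noise_model(growth_bias = c(0.1)), "named")
  expect_error(noise_model(growth_bias = c(S_x = 0.1)), "DNA state")
  nm <- noise_model(growth_bias = c(S_o = 0.05))
  expect_equal(nm$growth_bias,
               c(S_o = 0.05, S_a = 0, S_b = 0, S_ab = 0))
  expect_error(noise_model(replicates = 0))
})

test_that("the noiseless limit reproduces the exact simulated fractions", {
  p <- rate_params("revised")
  design <- data.frame(dt = 1, pw_b = 2)
  nm <- noise_model(n_sampled_cells = Inf, replicates = 1L,
                    replicate_cv = 0)
  out <- generate_fraction_dataset(p, design, nm, n_cells = 300, seed = 5)
  # same ensemble simulated directly with the derived per-replicate seed
  sub <- tempogate:::derive_seed(5, 1L, salt = 1L)
  ens <- simulate_population(p, pulse_b(1, 2), 1 + 2 + 24, 300, seed = sub)
  frac <- tabulate(ens$final_dna + 1L, 4) / 300
  expect_equal(as.numeric(out[1, c("frac_S_o", "frac_S_a", "frac_S_b",
                                   "frac_S_ab")]), frac)
})

test_that("generated datasets are reproducible and well-formed", {
  p <- rate_params("revised")
  design <- data.frame(dt = c(0, 2), pw_b = c(1, Inf))
  nm <- noise_model(n_sampled_cells = 1e5, replicates = 2L)
  a <- generate_fraction_dataset(p, design, nm, n_cells = 150, seed = 12)
  b <- generate_fraction_dataset(p, design, nm, n_cells = 150, seed = 12)
  expect_identical(a, b)
  expect_equal(nrow(a), 4L)
  expect_equal(a$replicate, c(1L, 2L, 1L, 2L))
  sums <- rowSums(a[, c("frac_S_o", "frac_S_a", "frac_S_b", "frac_S_ab")])
  expect_equal(sums, rep(1, 4))
  c2 <- generate_fraction_dataset(p, design, nm, n_cells = 150, seed = 13)
  expect_false(identical(a$frac_S_ab, c2$frac_S_ab))
})

test_that("step designs use the (order, dt) columns", {
  p <- rate_params("initial")
  design <- data.frame(order = c("ab", "ba"), dt = c(1, 1))
  nm <- noise_model(n_sampled_cells = Inf, replicates = 1L,
                    replicate_cv = 0)
  out <- generate_fraction_dataset(p, design, nm, n_cells = 100, seed = 2)
  expect_equal(out$event, c("E_ab", "E_ba"))
  expect_equal(out$time, c(25, 25))
  expect_error(generate_fraction_dataset(p, data.frame(x = 1), nm),
               "design needs")
})

test_that("a growth bias against switched cells lowers their fractions", {
  p <- rate_params("initial")
  design <- data.frame(dt = 2, pw_b = Inf)
  plain <- noise_model(n_sampled_cells = Inf, replicates = 1L,
                       replicate_cv = 0)
  biased <- noise_model(n_sampled_cells = Inf, replicates = 1L,
                        replicate_cv = 0,
                        growth_bias = c(S_ab = -0.05)) # switched grow slower
  a <- generate_fraction_dataset(p, design, plain, n_cells = 400, seed = 3)
  b <- generate_fraction_dataset(p, design, biased, n_cells = 400, seed = 3)
  expect_lt(b$frac_S_ab, a$frac_S_ab)
  # reweighting keeps the fractions normalized
  expect_equal(sum(b[1, c("frac_S_o", "frac_S_a", "frac_S_b",
                          "frac_S_ab")]), 1)
})

test_that("cytometry events gate back to the source fractions", {
  row <- tibble::tibble(condition = "c1", replicate = 1L,
                        frac_S_o = 0.2, frac_S_a = 0.3,
                        frac_S_b = 0.1, frac_S_ab = 0.4)
  fm <- fluorescence_model(residual_rfp = 0)
  ev <- generate_cytometry_events(row, n_events = 40000, fm, seed = 8)
  expect_equal(nrow(ev), 40000L)
  g <- gate_quadrants(ev)
  expect_equal(sum(g$quadrants), 1)
  # G reads S_ab, R reads S_a; mis-gating error is small at 10x separation
  expect_lt(abs(g$G - 0.4), 0.02)
  expect_lt(abs(g$R - 0.3), 0.02)
  expect_equal(unname(g$quadrants["Q1"] + g$quadrants["Q2"]), g$G)
})

test_that("residual RFP populates the double-positive quadrant", {
  row <- tibble::tibble(condition = "c1", replicate = 1L,
                        frac_S_o = 0, frac_S_a = 0,
                        frac_S_b = 0, frac_S_ab = 1)
  fm <- fluorescence_model(residual_rfp = 0.5)
  ev <- generate_cytometry_events(row, n_events = 20000, fm, seed = 4)
  g <- gate_quadrants(ev)
  expect_gt(g$quadrants["Q2"], 0.4)
  expect_lt(abs(g$G - 1), 0.02)          # still GFP-positive throughout
})

test_that("gate_quadrants needs thresholds", {
  ev <- tibble::tibble(rfp = c(1, 2), gfp = c(1, 2))
  expect_error(gate_quadrants(ev), "thresholds")
  g <- gate_quadrants(ev, threshold_rfp = 1.5, threshold_gfp = 1.5)
  expect_equal(unname(g$quadrants["Q2"]), 0.5)
})

test_that("fluorescence_model validates its shape", {
  expect_error(fluorescence_model(on_mean = 50), "on_mean")
  expect_error(fluorescence_model(residual_rfp = 2))
  expect_error(generate_cytometry_events(
    tibble::tibble(condition = "x", frac_S_o = 1, frac_S_a = 0,
                   frac_S_b = 0, frac_S_ab = 0),
    10, fluor_model = list(a = 1)), "missing")
})
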