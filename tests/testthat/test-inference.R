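# Analytic calibration table: R depends only on pw_b (decreasing), G is
# monotone increasing in dt with a mild pw dependence — a noiseless
# stand-in for a simulated (dt, pw_b) design.
fake_calib <- function(dts = 0:6, pwbs = 0:6) {
  g <- expand.grid(dt = dts, pw_b = pwbs)
  tibble::tibble(
    dt = g$dt, pw_b = g$pw_b,
    frac_S_a = 0.95 - 0.13 * g$pw_b,
    frac_S_ab = 0.2 + 0.08 * g$dt + 0.02 * g$pw_b
  )
}

test_that("fit_surface validates its design", {
  expect_error(fit_surface(fake_calib(pwbs = c(0, 1))), ">= 3 distinct")
  expect_error(fit_surface(fake_calib(dts = c(0, 1))), ">= 3 distinct")
  expect_error(fit_surface(tibble::tibble(dt = 1)), "columns")
})

test_that("non-monotone pooled R advises a larger calibration", {
  bad <- fake_calib()
  bad$frac_S_a <- 0.5 + 0.1 * (bad$pw_b %% 2)    # zig-zag in pw_b
  expect_error(fit_surface(bad), "n_cells")
})

test_that("noiseless round trip recovers the training design", {
  calib <- fake_calib()
  surf <- fit_surface(calib)
  train <- calib[calib$pw_b > 0, ]
  est <- estimate_event(train$frac_S_a, train$frac_S_ab, surf)
  expect_equal(est$pw_b_hat, train$pw_b, tolerance = 1e-6)
  expect_equal(est$dt_hat, train$dt, tolerance = 1e-6)
  expect_false(any(est$out_of_domain))
  # training residuals stored per pw_b > 0 point
  expect_equal(nrow(surf$residuals), nrow(train))
  expect_lt(max(abs(surf$residuals$dt_residual)), 1e-6)
})

test_that("pwb_of_R is monotone non-increasing over its domain", {
  surf <- fit_surface(fake_calib())
  Rs <- seq(surf$R_domain[1], surf$R_domain[2], length.out = 101)
  est <- estimate_event(Rs, rep(0.5, 101), surf)
  expect_true(all(diff(est$pw_b_hat) <= 1e-9))
})

test_that("estimates clamp to the design range and are flagged", {
  surf <- fit_surface(fake_calib())
  est <- estimate_event(c(0.01, 0.999), c(0.5, 0.5), surf)
  expect_equal(est$pw_b_hat, c(6, 0))
  expect_true(all(est$out_of_domain))
  expect_true(all(est$dt_hat >= 0 & est$dt_hat <= 6))
  expect_error(estimate_event(1.2, 0.5, surf), "\\[0, 1\\]")
  expect_error(estimate_event(0.5, -0.1, surf), "\\[0, 1\\]")
  expect_error(estimate_event(c(0.5, 0.5), 0.5, surf), "length")
})

test_that("the quadratic surface option fits and predicts in range", {
  surf <- fit_surface(fake_calib(), dt_method = "quadratic")
  expect_s3_class(surf$dt_model, "lm")
  est <- estimate_event(c(0.8, 0.4), c(0.3, 0.6), surf)
  expect_true(all(est$dt_hat >= 0 & est$dt_hat <= 6))
  expect_true(all(est$pw_b_hat >= 0 & est$pw_b_hat <= 6))
})

test_that("lookup table shape, consistency and monotone columns", {
  surf <- fit_surface(fake_calib())
  step <- 0.05
  lk <- build_lookup(surf, mesh_step = step)
  nR <- length(seq(surf$R_domain[1], surf$R_domain[2], by = step))
  nG <- length(seq(surf$G_domain[1], surf$G_domain[2], by = step))
  expect_equal(nrow(lk), nR * nG)
  # a node equals estimate_event at that node
  k <- 17L
  node <- estimate_event(lk$R[k], lk$G[k], surf)
  expect_equal(lk$pw_b_hat[k], node$pw_b_hat)
  expect_equal(lk$dt_hat[k], node$dt_hat)
  # within a fixed G row, PW_b predictions non-increasing in R
  for (g in unique(lk$G)[c(1, nG)]) {
    rows <- lk[lk$G == g, ]
    rows <- rows[order(rows$R), ]
    expect_true(all(diff(rows$pw_b_hat) <= 1e-9))
  }
  expect_error(build_lookup(surf, mesh_step = 0), "mesh_step")
})

test_that("resolution_analysis matches hand arithmetic", {
  truths <- data.frame(pw_b = c(1, 1, 1), dt = c(2, 2, 2))
  est <- data.frame(pw_b_hat = c(0.9, 1.0, 1.1), dt_hat = c(2, 2, 2))
  res <- resolution_analysis(truths, est)
  expect_equal(res$pw_b$mean, 1)
  expect_equal(res$pw_b$sd, 0.1)
  expect_equal(res$pw_b$n, 3L)
  expect_equal(res$dt$sd, 0)              # perfect estimates
  expect_error(resolution_analysis(data.frame(), data.frame()), "empty")
  expect_error(resolution_analysis(truths, est[1:2, ]), "same number")
})
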