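#' Fit the inversion surface from a calibration matrix
#'
#' Builds the two fitted inversion functions of the practical-use layer
#' from a (dt, pw_b) calibration design of final population fractions:
#'
#' * `pwb_of_R`: pulse width as a function of the RFP fraction
#'   `R = frac_S_a`. Because the a-first fraction `S_a + S_ab` depends
#'   only on `pw_b`, `R` is pooled across dt (mean R per pw_b level) and
#'   fitted with a monotone-decreasing piecewise-cubic interpolant
#'   (isotonic regression first irons out Monte-Carlo wiggles; pooled
#'   means deviating from monotonicity by more than `mono_tol` raise an
#'   error advising a larger calibration `n_cells`).
#' * `dt_of_G_pwb`: separation time as a function of the GFP fraction
#'   `G = frac_S_ab` and the pulse width. The default
#'   `dt_method = "levels"` fits one monotone inversion curve
#'   `dt(G)` per training pulse-width level (isotonic means, linear
#'   interpolation) and interpolates the estimate linearly between the
#'   two bracketing levels; `"quadratic"` fits a single quadratic
#'   least-squares response surface in `(G, pw_b)`.
#'
#' Conditions with `pw_b = 0` never see inducer b, so no separation time
#' exists for them; they enter the `pwb_of_R` fit but are excluded from
#' the dt fit.
#'
#' @param calib fraction table over a design with >= 3 distinct finite
#'   `pw_b` and >= 3 distinct `dt` values (replicate rows welcome).
#' @param mono_tol tolerance on non-monotonicity of pooled R vs pw_b.
#' @param dt_method `"levels"` (default) or `"quadratic"`.
#' @return an object of class `tlg_surface` with elements `pwb_knots`
#'   (pooled calibration points), `dt_levels`/`dt_curves` (per-level
#'   inversion data) or `dt_model` (the fitted `lm`), domain boxes
#'   `R_domain`, `G_domain`, `pwb_domain`, `dt_domain`, and
#'   per-training-point `residuals`.
#' @export
fit_surface <- function(calib, mono_tol = 0.05,
                        dt_method = c("levels", "quadratic")) {
  dt_method <- match.arg(dt_method)
  need <- c("dt", "pw_b", "frac_S_a", "frac_S_ab")
  if (!all(need %in% names(calib)))
    stop("calib must have columns ", paste(need, collapse = ", "))
  calib <- calib[is.finite(calib$pw_b), , drop = FALSE]
  if (length(unique(calib$pw_b)) < 3L || length(unique(calib$dt)) < 3L)
    stop("calibration design needs >= 3 distinct pw_b and dt values")

  # ---- pwb_of_R: pooled mean R per pw_b, monotone decreasing in pw_b ----
  pool <- stats::aggregate(frac_S_a ~ pw_b, data = calib, FUN = mean)
  pool <- pool[order(pool$pw_b), ]
  viol <- max(c(0, diff(pool$frac_S_a)))
  if (viol > mono_tol)
    stop("pooled R vs pw_b is non-monotone (max violation ",
         signif(viol, 3), " > ", mono_tol,
         "); increase n_cells in the calibration run")
  # isotonic (decreasing) projection, then a strictly decreasing nudge so
  # the interpolant is invertible
  iso <- stats::isoreg(pool$pw_b, -pool$frac_S_a)
  r_fit <- -iso$yf - 1e-9 * seq_along(iso$yf)
  knots <- data.frame(pw_b = pool$pw_b, R = r_fit, R_raw = pool$frac_S_a)

  # ---- dt_of_G_pwb on the pw_b > 0 conditions ----
  df <- data.frame(dt = calib$dt, G = calib$frac_S_ab, pw = calib$pw_b)
  dfp <- df[df$pw > 0, , drop = FALSE]
  if (length(unique(dfp$pw)) < 2L)
    stop("need >= 2 distinct pw_b > 0 levels to fit the dt surface")
  dt_levels <- NULL; dt_curves <- NULL; dt_model <- NULL
  if (dt_method == "levels") {
    agg <- stats::aggregate(G ~ dt + pw, data = dfp, FUN = mean)
    dt_levels <- sort(unique(agg$pw))
    dt_curves <- lapply(dt_levels, function(w) {
      a <- agg[agg$pw == w, ]
      a <- a[order(a$dt), ]
      # monotone increasing G in dt, strictified for inversion
      g <- stats::isoreg(a$dt, a$G)$yf + 1e-9 * seq_len(nrow(a))
      data.frame(G = g, dt = a$dt)
    })
  } else {
    dt_model <- stats::lm(dt ~ G + pw + I(G^2) + I(pw^2) + G:pw, data = dfp)
  }

  surface <- structure(list(
    dt_method = dt_method,
    pwb_knots = knots,
    dt_levels = dt_levels,
    dt_curves = dt_curves,
    dt_model = dt_model,
    R_domain = range(knots$R),
    G_domain = range(dfp$G),
    pwb_domain = range(calib$pw_b),
    dt_domain = range(calib$dt)
  ), class = "tlg_surface")

  est <- estimate_event(calib$frac_S_a[df$pw > 0], dfp$G, surface)
  surface$residuals <- data.frame(
    dt = dfp$dt, pw_b = dfp$pw,
    pwb_residual = est$pw_b_hat - dfp$pw,
    dt_residual = est$dt_hat - dfp$dt
  )
  surface
}

#' @export
print.tlg_surface <- function(x, ...) {
  cat("Calibration surface for event inference\n")
  cat(sprintf("  pwb_of_R: %d knots, R in [%.3f, %.3f] -> pw_b in [%g, %g] h\n",
              nrow(x$pwb_knots), x$R_domain[1], x$R_domain[2],
              x$pwb_domain[1], x$pwb_domain[2]))
  cat(sprintf("  dt_of_G_pwb: %s, G in [%.3f, %.3f]\n",
              if (x$dt_method == "levels")
                sprintf("monotone curves at %d pw_b levels",
                        length(x$dt_levels))
              else "quadratic surface",
              x$G_domain[1], x$G_domain[2]))
  if (!is.null(x$residuals))
    cat(sprintf("  training RMSE: pw_b %.3f h, dt %.3f h\n",
                sqrt(mean(x$residuals$pwb_residual^2)),
                sqrt(mean(x$residuals$dt_residual^2))))
  invisible(x)
}

# Evaluate the monotone pwb_of_R interpolant (R sorted increasing maps to
# decreasing pw_b); out-of-domain inputs clamp to the design range.
eval_pwb_of_R <- function(surface, R) {
  kn <- surface$pwb_knots[order(surface$pwb_knots$R), ]
  f <- stats::splinefun(kn$R, kn$pw_b, method = "hyman")
  # tolerance covers the strictifying nudge applied to the knots
  low <- R < min(kn$R) - 1e-8
  high <- R > max(kn$R) + 1e-8
  out <- f(pmin(pmax(R, min(kn$R)), max(kn$R)))
  out[low] <- max(surface$pwb_domain)   # less RFP than ever trained: longest pulse
  out[high] <- min(surface$pwb_domain)
  list(value = out, clamped = low | high)
}

# Evaluate dt(G, pw) for the "levels" method: invert the bracketing
# per-level monotone curves and interpolate linearly in pw.
eval_dt_levels <- function(surface, G, pw) {
  lv <- surface$dt_levels
  n <- length(G)
  val <- numeric(n)
  clamped <- logical(n)
  inv <- function(k, g) {
    cu <- surface$dt_curves[[k]]
    stats::approx(cu$G, cu$dt, xout = g, rule = 2)$y
  }
  rng <- function(k) range(surface$dt_curves[[k]]$G)
  for (i in seq_len(n)) {
    k <- findInterval(pw[i], lv, all.inside = TRUE)
    w1 <- lv[k]; w2 <- lv[k + 1]
    d1 <- inv(k, G[i]); d2 <- inv(k + 1, G[i])
    val[i] <- if (pw[i] <= w1) d1
              else if (pw[i] >= w2) d2
              else d1 + (pw[i] - w1) / (w2 - w1) * (d2 - d1)
    r1 <- rng(k); r2 <- rng(k + 1)
    clamped[i] <- G[i] < min(r1[1], r2[1]) - 1e-8 ||
      G[i] > max(r1[2], r2[2]) + 1e-8
  }
  list(value = val, clamped = clamped)
}

#' Invert measured fractions into pulse width and separation time
#'
#' Applies the fitted surface: `pw_b_hat = pwb_of_R(R)`, then
#' `dt_hat = dt_of_G_pwb(G, pw_b_hat)`. Estimates are clamped to the
#' calibration design range with a flag recording whether clamping
#' occurred.
#'
#' @param R measured RFP-positive (S_a proxy) fraction(s), in `[0, 1]`.
#' @param G measured GFP-positive (S_ab proxy) fraction(s), in `[0, 1]`.
#' @param surface a `tlg_surface`.
#' @return a tibble with columns `R`, `G`, `pw_b_hat`, `dt_hat`,
#'   `out_of_domain` (TRUE where any clamping occurred).
#' @export
estimate_event <- function(R, G, surface) {
  stopifnot(inherits(surface, "tlg_surface"),
            length(R) == length(G))
  if (any(R < 0 | R > 1 | G < 0 | G > 1, na.rm = TRUE))
    stop("R and G must be fractions in [0, 1]")
  pw <- eval_pwb_of_R(surface, R)
  pw_hat <- pmin(pmax(pw$value, surface$pwb_domain[1]), surface$pwb_domain[2])
  if (surface$dt_method == "levels") {
    dt <- eval_dt_levels(surface, G, pw_hat)
    dt_raw <- dt$value
    dt_flag <- dt$clamped
  } else {
    dt_raw <- as.numeric(stats::predict(surface$dt_model,
                                        newdata = data.frame(G = G,
                                                             pw = pw_hat)))
    dt_flag <- FALSE
  }
  dt_flag <- dt_flag | dt_raw < surface$dt_domain[1] |
    dt_raw > surface$dt_domain[2]
  dt_hat <- pmin(pmax(dt_raw, surface$dt_domain[1]), surface$dt_domain[2])
  tibble::tibble(R = R, G = G, pw_b_hat = pw_hat, dt_hat = dt_hat,
                 out_of_domain = pw$clamped | dt_flag)
}

#' Reference lookup table over the (R, G) mesh
#'
#' Pre-computes [estimate_event()] on a rectangular mesh over the training
#' domain of the surface, giving a reference table that converts measured
#' RFP/GFP fractions directly into predicted pulse width and separation
#' time.
#'
#' @param surface a `tlg_surface`.
#' @param mesh_step mesh spacing in fraction units (e.g. 0.05), > 0.
#' @return a tibble with one row per mesh node: `R`, `G`, `pw_b_hat`,
#'   `dt_hat`, `out_of_domain`.
#' @export
build_lookup <- function(surface, mesh_step = 0.05) {
  stopifnot(inherits(surface, "tlg_surface"),
            is.numeric(mesh_step), length(mesh_step) == 1L, mesh_step > 0)
  Rs <- seq(surface$R_domain[1], surface$R_domain[2], by = mesh_step)
  Gs <- seq(surface$G_domain[1], surface$G_domain[2], by = mesh_step)
  mesh <- expand.grid(R = Rs, G = Gs, KEEP.OUT.ATTRS = FALSE)
  estimate_event(mesh$R, mesh$G, surface)
}

#' Resolution of the inversion: estimate spread per true value
#'
#' Groups paired (truth, estimate) records by the true value and reports
#' the mean, standard deviation and count of the estimates — separately
#' for pulse width and separation time. The SD per true value is the
#' detection resolution (the +/- window of actual-versus-estimated
#' plots).
#'
#' @param truths data frame with columns `pw_b` and `dt` (true values).
#' @param estimates data frame with columns `pw_b_hat` and `dt_hat`,
#'   row-aligned with `truths`.
#' @return an object of class `tlg_resolution`: a list of two tibbles,
#'   `pw_b` (columns `true`, `mean`, `sd`, `n`) and `dt` (same).
#' @export
resolution_analysis <- function(truths, estimates) {
  if (NROW(truths) == 0L) stop("empty input")
  if (NROW(truths) != NROW(estimates))
    stop("truths and estimates must have the same number of rows")
  grp <- function(true, est) {
    out <- stats::aggregate(est, by = list(true = true),
                            FUN = function(x) c(mean = mean(x),
                                                sd = stats::sd(x),
                                                n = length(x)))
    tibble::tibble(true = out$true,
                   mean = unname(out$x[, "mean"]),
                   sd = unname(ifelse(is.na(out$x[, "sd"]), 0,
                                      out$x[, "sd"])),
                   n = as.integer(out$x[, "n"]))
  }
  structure(list(pw_b = grp(truths$pw_b, estimates$pw_b_hat),
                 dt = grp(truths$dt, estimates$dt_hat)),
            class = "tlg_resolution")
}

#' @export
print.tlg_resolution <- function(x, ...) {
  cat("Inversion resolution (per true value: mean estimate +/- SD)\n")
  cat("  pulse width PW_b:\n")
  for (i in seq_len(nrow(x$pw_b)))
    cat(sprintf("    true %4.1f h -> %5.2f +/- %.2f h (n = %d)\n",
                x$pw_b$true[i], x$pw_b$mean[i], x$pw_b$sd[i], x$pw_b$n[i]))
  cat("  separation time dt:\n")
  for (i in seq_len(nrow(x$dt)))
    cat(sprintf("    true %4.1f h -> %5.2f +/- %.2f h (n = %d)\n",
                x$dt$true[i], x$dt$mean[i], x$dt$sd[i], x$dt$n[i]))
  invisible(x)
}
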