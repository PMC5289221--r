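# Truncated chemical-master-equation oracle.
#
# The full CTMC lives on {S_o,S_a,S_b,S_ab} x Z+ x Z+. Truncating the
# integrase counts at (capA, capB) and redirecting births at the cap into a
# tracked mass defect gives a finite linear ODE system dP/dt = Q(t) P whose
# DNA marginals serve as a non-stochastic reference for the SSA. Rates are
# piecewise constant in time, so the system is integrated segment by
# segment with a constant sparse generator per segment.

cme_index <- function(dna, iA, iB, capA, capB) {
  # dna 0..3, iA 0..capA, iB 0..capB -> 1-based linear index
  1L + dna + 4L * (iA + (capA + 1L) * iB)
}

# Sparse generator blocks that do not depend on the inducer indicators:
# unit-rate birth structure per species (scaled by gamma(t) at solve time),
# degradation, and the DNA flips.
cme_generators <- function(params, capA, capB) {
  nA <- capA + 1L; nB <- capB + 1L
  n <- 4L * nA * nB
  iA <- rep(rep(0:capA, each = 4L), times = nB)
  iB <- rep(0:capB, each = 4L * nA)
  dna <- rep(0:3, times = nA * nB)
  idx <- seq_len(n)

  # off-diagonal inflow plus diagonal outflow; `to` NULL means the
  # probability leaves the truncated system (cap overflow)
  trip <- function(from, to, rate) {
    keep <- rate > 0
    from <- from[keep]; rate <- rate[keep]
    if (is.null(to))
      return(Matrix::sparseMatrix(i = from, j = from, x = -rate,
                                  dims = c(n, n)))
    to <- to[keep]
    Matrix::sparseMatrix(i = c(to, from), j = c(from, from),
                         x = c(rate, -rate), dims = c(n, n))
  }

  # births: iA -> iA + 1 (unit rate; overflow at the cap leaves the system)
  inA <- iA < capA
  birthA <- trip(idx[inA], cme_index(dna[inA], iA[inA] + 1L, iB[inA], capA, capB),
                 rep(1, sum(inA))) +
            trip(idx[!inA], NULL, rep(1, sum(!inA)))
  inB <- iB < capB
  birthB <- trip(idx[inB], cme_index(dna[inB], iA[inB], iB[inB] + 1L, capA, capB),
                 rep(1, sum(inB))) +
            trip(idx[!inB], NULL, rep(1, sum(!inB)))

  deathA <- trip(idx, cme_index(dna, pmax(iA - 1L, 0L), iB, capA, capB),
                 params$kdeg * iA)
  deathB <- trip(idx, cme_index(dna, iA, pmax(iB - 1L, 0L), capA, capB),
                 params$kdeg * iB)

  a2 <- tetramer_propensity(iA, params$kflipA, params$KdA) * (dna == 0L)
  a1 <- tetramer_propensity(iB, params$kflipB_exc, params$KdB) * (dna == 0L)
  a3 <- tetramer_propensity(iB, params$kflipB, params$KdB) * (dna == 1L)
  flips <- trip(idx, cme_index(1L, iA, iB, capA, capB), a2) +
           trip(idx, cme_index(2L, iA, iB, capA, capB), a1) +
           trip(idx, cme_index(3L, iA, iB, capA, capB), a3)

  list(birthA = birthA, birthB = birthB,
       fixed = deathA + deathB + flips,
       dna = dna, n = n)
}

#' Solve the truncated master equation for the DNA marginals
#'
#' Integrates the probability vector of the gate CTMC on the truncated
#' state space `{S_o,S_a,S_b,S_ab} x {0..capA} x {0..capB}` forward in
#' time, with integrase births at the cap redirected into a tracked mass
#' defect. Intended as a validation oracle at reduced production rates,
#' where modest caps hold the defect far below the Monte-Carlo error of
#' the SSA ensembles it is compared against.
#'
#' @param params a `tlg_params`.
#' @param profile a `tlg_profile`.
#' @param t_end horizon in hours.
#' @param capA,capB integrase count caps (>= 4 recommended).
#' @param grid output times within `[0, t_end]`; default 121 points.
#' @param rtol,atol integrator tolerances (lsoda).
#' @param defect_threshold mass defect above which a warning is recorded.
#' @return an object of class `tlg_marginals`: a tibble with columns
#'   `time`, `P_S_o`, `P_S_a`, `P_S_b`, `P_S_ab`, `mass_defect`, plus a
#'   `defect_warning` attribute.
#' @export
solve_truncated_cme <- function(params, profile, t_end, capA = 40L, capB = 40L,
                                grid = NULL, rtol = 1e-8, atol = 1e-10,
                                defect_threshold = 1e-3) {
  stopifnot(inherits(params, "tlg_params"), inherits(profile, "tlg_profile"),
            t_end > 0, capA >= 1, capB >= 1)
  if (is.null(grid)) grid <- seq(0, t_end, length.out = 121L)
  if (any(grid < 0) || any(grid > t_end))
    stop("grid must lie within [0, t_end]")
  grid <- sort(unique(grid))

  gen <- cme_generators(params, capA, capB)
  seg <- profile_segments(profile, t_end)

  p0 <- numeric(gen$n)
  p0[cme_index(0L, 0L, 0L, capA, capB)] <- 1

  out_t <- numeric(0)
  out_p <- NULL
  seg_t0 <- 0
  state <- p0
  for (k in seq_along(seg$seg_end)) {
    seg_t1 <- seg$seg_end[k]
    gA <- params$kprodA * seg$ua[k] + params$kleakA
    gB <- params$kprodB * seg$ub[k] + params$kleakB
    Q <- gA * gen$birthA + gB * gen$birthB + gen$fixed
    times <- sort(unique(c(seg_t0, grid[grid >= seg_t0 & grid <= seg_t1], seg_t1)))
    sol <- deSolve::ode(y = state, times = times,
                        func = function(t, y, parms) list(as.vector(parms %*% y)),
                        parms = Q, method = "lsoda", rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0) stop("CME integration failed in segment ", k)
    keep <- times %in% grid & (times < seg_t1 | k == length(seg$seg_end))
    if (any(keep)) {
      out_t <- c(out_t, times[keep])
      out_p <- rbind(out_p, sol[keep, -1, drop = FALSE])
    }
    state <- as.numeric(sol[nrow(sol), -1])
    seg_t0 <- seg_t1
  }

  marg <- t(apply(out_p, 1, function(p) {
    c(vapply(0:3, function(d) sum(p[gen$dna == d]), numeric(1)), 1 - sum(p))
  }))
  res <- tibble::tibble(
    time = out_t,
    P_S_o = marg[, 1], P_S_a = marg[, 2],
    P_S_b = marg[, 3], P_S_ab = marg[, 4],
    mass_defect = pmax(marg[, 5], 0)
  )
  warn <- max(res$mass_defect) > defect_threshold
  if (warn)
    warning("CME mass defect ", signif(max(res$mass_defect), 3),
            " exceeds threshold ", defect_threshold,
            "; increase capA/capB")
  structure(res, class = c("tlg_marginals", class(res)), defect_warning = warn)
}

#' Closed-form DNA-chain solution for frozen flip propensities
#'
#' With the three flip propensities held constant (integrase counts
#' frozen), the DNA state follows a linear 4-state chain
#' `S_o -> S_a -> S_ab` with the side branch `S_o -> S_b`, solved exactly:
#' \deqn{P(S_o) = e^{-(a_1+a_2)t},\quad
#'       P(S_b) = \frac{a_1}{a_1+a_2}(1 - e^{-(a_1+a_2)t}),\quad
#'       P(S_a) = a_2\frac{e^{-(a_1+a_2)t} - e^{-a_3 t}}{a_3 - (a_1+a_2)},}
#' with the degenerate cases `a1 + a2 = 0` and `a1 + a2 = a3` handled
#' analytically, and `P(S_ab)` by conservation.
#'
#' @param a1 propensity S_o -> S_b (h^-1, >= 0).
#' @param a2 propensity S_o -> S_a (h^-1, >= 0).
#' @param a3 propensity S_a -> S_ab (h^-1, >= 0).
#' @param t time(s) in hours, >= 0 (vectorized).
#' @return matrix with columns `P_S_o`, `P_S_a`, `P_S_b`, `P_S_ab`
#'   (rows sum to 1).
#' @examples
#' conditional_dna_solution(0, 1, 1, 1) # (e^-1, e^-1, 0, 1 - 2 e^-1)
#' @export
conditional_dna_solution <- function(a1, a2, a3, t) {
  for (v in list(a1, a2, a3))
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("propensities must be single non-negative rates")
  if (any(t < 0)) stop("t must be >= 0")
  s <- a1 + a2
  Po <- exp(-s * t)
  Pb <- if (s == 0) rep(0, length(t)) else (a1 / s) * (1 - exp(-s * t))
  if (a2 == 0) {
    Pa <- rep(0, length(t))
  } else if (isTRUE(all.equal(s, a3))) {
    Pa <- a2 * t * exp(-a3 * t)
  } else {
    Pa <- a2 * (exp(-s * t) - exp(-a3 * t)) / (a3 - s)
  }
  Pab <- pmax(1 - Po - Pa - Pb, 0)
  cbind(P_S_o = Po, P_S_a = Pa, P_S_b = Pb, P_S_ab = Pab)
}

#' Self-consistency of ensemble fractions with the marginal ODE
#'
#' The DNA marginals of the full chain obey a linear ODE whose
#' coefficients are the conditional expectations of the flip propensities
#' given the current DNA state. This check estimates those expectations
#' from a simulated ensemble (which must carry integrase counts on a
#' grid), integrates the marginal ODE from the same initial condition,
#' and reports the maximum discrepancy against the empirical state
#' fractions per state.
#'
#' @param ensemble a `tlg_ensemble` simulated with a `grid` and
#'   `record_counts = TRUE`.
#' @param tol pass threshold on the maximum discrepancy; default is
#'   3 Monte-Carlo standard errors, `3 * sqrt(0.25 / n_cells)`.
#' @return a list with `residuals` (per-state maximum discrepancy),
#'   `max_residual`, `tol`, `pass`, and `notes` (times at which a
#'   conditioning set was empty and the corresponding term taken as 0).
#' @export
verify_marginal_ode <- function(ensemble, tol = NULL) {
  stopifnot(inherits(ensemble, "tlg_ensemble"))
  if (is.null(ensemble$grid) || is.null(ensemble$intA_grid))
    stop("ensemble must be simulated with grid= and record_counts=TRUE")
  grid <- ensemble$grid
  p <- ensemble$params
  n <- ensemble$n_cells
  if (is.null(tol)) tol <- 3 * sqrt(0.25 / n)

  G <- length(grid)
  emp <- matrix(0, G, 4L)
  Ea2 <- Ea1 <- Ea3 <- numeric(G)
  notes <- character(0)
  for (j in seq_len(G)) {
    code <- ensemble$dna_grid[, j]
    emp[j, ] <- tabulate(code + 1L, nbins = 4L) / n
    so <- code == 0L
    sa <- code == 1L
    if (any(so)) {
      Ea2[j] <- mean(tetramer_propensity(ensemble$intA_grid[so, j],
                                         p$kflipA, p$KdA))
      Ea1[j] <- mean(tetramer_propensity(ensemble$intB_grid[so, j],
                                         p$kflipB_exc, p$KdB))
    } else notes <- c(notes, sprintf("t=%g: no cells in S_o; terms set to 0",
                                     grid[j]))
    if (any(sa)) {
      Ea3[j] <- mean(tetramer_propensity(ensemble$intB_grid[sa, j],
                                         p$kflipB, p$KdB))
    } else notes <- c(notes, sprintf("t=%g: no cells in S_a; term set to 0",
                                     grid[j]))
  }

  fa1 <- stats::approxfun(grid, Ea1, rule = 2)
  fa2 <- stats::approxfun(grid, Ea2, rule = 2)
  fa3 <- stats::approxfun(grid, Ea3, rule = 2)
  rhs <- function(t, y, parms) {
    a1 <- fa1(t); a2 <- fa2(t); a3 <- fa3(t)
    list(c(-(a1 + a2) * y[1],
           a2 * y[1] - a3 * y[2],
           a1 * y[1],
           a3 * y[2]))
  }
  sol <- deSolve::ode(y = c(1, 0, 0, 0), times = grid, func = rhs,
                      parms = NULL, rtol = 1e-8, atol = 1e-10)
  model <- sol[, 2:5, drop = FALSE]
  resid <- apply(abs(model - emp), 2, max)
  names(resid) <- dna_levels()
  list(residuals = resid, max_residual = max(resid), tol = tol,
       pass = max(resid) <= tol, notes = notes)
}
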