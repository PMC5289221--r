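#' Normalize measured switched-state fractions
#'
#' Wet-lab populations saturate below 100% switching (non-fluorescent
#' cells hold a slight growth advantage), so measured switched-state
#' fractions are rescaled by the observed population maximum before model
#' fitting: each of `frac_S_a`, `frac_S_b`, `frac_S_ab` is divided by
#' `max_switch` (default 0.70) and clipped at 1. The original `frac_S_o`
#' is left untouched; normalized rows are measurement-side rescalings for
#' fitting and no longer sum to 1.
#'
#' @param data a fraction table.
#' @param max_switch the population switching ceiling, in `(0, 1]`.
#' @return the table with switched fractions rescaled and a
#'   `normalization` attribute recording `max_switch`.
#' @export
normalize_fractions <- function(data, max_switch = 0.70) {
  if (!is.numeric(max_switch) || length(max_switch) != 1L ||
      is.na(max_switch) || max_switch <= 0 || max_switch > 1)
    stop("max_switch must be in (0, 1]")
  out <- data
  for (col in c("frac_S_a", "frac_S_b", "frac_S_ab")) {
    v <- out[[col]] / max_switch
    if (any(v > 1)) {
      warning(sum(v > 1), " normalized value(s) in ", col, " clipped at 1")
      v <- pmin(v, 1)
    }
    out[[col]] <- v
  }
  attr(out, "normalization") <- max_switch
  out
}

#' Mean squared error between separation-time response curves
#'
#' @param sim,obs named numeric vectors mapping dt (names) to final S_ab
#'   fraction, or lists of such vectors (e.g. the E_ab and E_ba curves);
#'   list entries are matched by position and the MSE is the mean over
#'   all points of all curves.
#' @return the mean squared difference (symmetric in its arguments).
#' @examples
#' curve_mse(c("0" = 0.5, "1" = 0.7), c("0" = 0.5, "1" = 0.9)) # 0.02
#' @export
curve_mse <- function(sim, obs) {
  if (is.list(sim) != is.list(obs))
    stop("sim and obs must both be curves or both be lists of curves")
  if (!is.list(sim)) { sim <- list(sim); obs <- list(obs) }
  if (length(sim) != length(obs)) stop("sim and obs list lengths differ")
  sq <- numeric(0)
  for (k in seq_along(sim)) {
    s <- sim[[k]]; o <- obs[[k]]
    miss <- c(setdiff(names(o), names(s)), setdiff(names(s), names(o)))
    if (length(miss))
      stop("curve ", k, ": dt keys not shared: ",
           paste(unique(miss), collapse = ", "))
    sq <- c(sq, (s[names(o)] - o)^2)
  }
  mean(sq)
}

# Extract the E_ab / E_ba final S_ab curves from a fraction table as named
# vectors keyed by dt.
sab_curves <- function(obs) {
  out <- list()
  for (ev in c("E_ab", "E_ba")) {
    rows <- obs[obs$event == ev, , drop = FALSE]
    if (nrow(rows)) {
      rows <- rows[order(rows$dt), ]
      out[[ev]] <- stats::setNames(rows$frac_S_ab, format(rows$dt))
    }
  }
  out
}

#' Grid search for the integrase flipping rates
#'
#' Reproduces the model-refinement fit: with leak rates pinned to their
#' measured values (kleakA = 1% of kprodA, kleakB = 2% of kprodB), every
#' candidate pair (kflipA, kflipB) is simulated over the observed
#' separation-time design for both inducer orders, and the pair minimizing
#' the mean squared error of the final S_ab curves against the
#' observations is selected. Ties are broken toward the smallest kflipA,
#' then the smallest kflipB, and reported.
#'
#' @param obs fraction table containing final-fraction rows for events
#'   `E_ab` and `E_ba` over a common dt grid.
#' @param kflip_candidates candidate rate values in h^-1 (used for both
#'   kflipA and kflipB), default `seq(0.1, 0.6, by = 0.1)`.
#' @param fixed a `tlg_params` supplying every other constant; its leak
#'   rates are reset to the pinned 1%/2% values.
#' @param n_cells trajectories per candidate condition (default 500).
#' @param seed integer seed.
#' @return an object of class `tlg_fit`: `grid_axes`, `mse_matrix`
#'   (kflipA by kflipB), `best_pair`, `n_cells_per_condition`,
#'   `normalization`, `tied` (logical).
#' @export
grid_fit <- function(obs, kflip_candidates = seq(0.1, 0.6, by = 0.1),
                     fixed = rate_params("revised"), n_cells = 500L,
                     seed = 1L) {
  stopifnot(length(kflip_candidates) >= 1L, all(kflip_candidates >= 0))
  curves_obs <- sab_curves(obs)
  if (!all(c("E_ab", "E_ba") %in% names(curves_obs)))
    stop("obs must contain E_ab and E_ba final-fraction rows")
  dts <- sort(unique(obs$dt[obs$event %in% c("E_ab", "E_ba")]))

  ka <- sort(kflip_candidates)
  kb <- sort(kflip_candidates)
  mse <- matrix(NA_real_, length(ka), length(kb),
                dimnames = list(kflipA = format(ka), kflipB = format(kb)))
  for (i in seq_along(ka)) {
    for (j in seq_along(kb)) {
      pars <- update_params(fixed,
                            kflipA = ka[i], kflipB = kb[j],
                            kflipB_exc = kb[j],
                            kleakA = 0.01 * fixed$kprodA,
                            kleakB = 0.02 * fixed$kprodB)
      sim <- tryCatch({
        sub <- derive_seed(seed, i, salt = j)
        rbind(scan_dt(pars, "ab", dts, n_cells, seed = derive_seed(sub, 1L)),
              scan_dt(pars, "ba", dts, n_cells, seed = derive_seed(sub, 2L)))
      }, error = function(e) e)
      if (inherits(sim, "error")) {
        warning("candidate (", ka[i], ", ", kb[j], ") failed: ",
                conditionMessage(sim), "; marked invalid")
        next
      }
      curves_sim <- sab_curves(sim)
      mse[i, j] <- curve_mse(curves_sim[c("E_ab", "E_ba")],
                             curves_obs[c("E_ab", "E_ba")])
    }
  }
  best <- which(mse == min(mse, na.rm = TRUE), arr.ind = TRUE)
  tied <- nrow(best) > 1L
  if (tied) {
    message("grid_fit: ", nrow(best), " tied minima; choosing smallest ",
            "kflipA, then smallest kflipB")
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
  }
  structure(list(
    grid_axes = list(kflipA = ka, kflipB = kb),
    mse_matrix = mse,
    best_pair = c(kflipA = ka[best[1, 1]], kflipB = kb[best[1, 2]]),
    n_cells_per_condition = as.integer(n_cells),
    normalization = attr(obs, "normalization") %||% 1,
    tied = tied
  ), class = "tlg_fit")
}

#' @export
print.tlg_fit <- function(x, ...) {
  cat("Flipping-rate grid fit (", nrow(x$mse_matrix), "x",
      ncol(x$mse_matrix), " grid, N = ", x$n_cells_per_condition,
      " cells/condition)\n", sep = "")
  cat(sprintf("  best pair: kflipA = %g, kflipB = %g (MSE = %.3g%s)\n",
              x$best_pair[1], x$best_pair[2], min(x$mse_matrix, na.rm = TRUE),
              if (x$tied) ", tie broken" else ""))
  invisible(x)
}

#' One-parameter family of separation-time scans
#'
#' Re-runs [scan_dt()] for each value of one rate constant, holding the
#' rest fixed — the tool behind the qualitative parameter sweeps (e.g.
#' kflipA over 0.2-0.5 h^-1, or kleakB over 1-20% of kprodB).
#'
#' @param params baseline `tlg_params`.
#' @param name parameter field to sweep.
#' @param values values to assign to it.
#' @param order inducer order for the scans.
#' @param dts separation times in hours.
#' @param n_cells trajectories per condition.
#' @param seed integer seed.
#' @return a fraction table with an extra column `param_value` (and
#'   attribute `swept` naming the parameter). Empty `values` give an
#'   empty table.
#' @export
sweep_parameter <- function(params, name, values, order = "ab",
                            dts = 0:6, n_cells = 3000L, seed = 1L) {
  stopifnot(inherits(params, "tlg_params"))
  if (!name %in% names(unclass(params)))
    stop("unknown parameter name: ", name)
  rows <- vector("list", length(values))
  for (i in seq_along(values)) {
    args <- stats::setNames(list(values[i]), name)
    pars <- do.call(update_params, c(list(params), args))
    tab <- scan_dt(pars, order, dts, n_cells, seed = derive_seed(seed, i))
    tab$param_value <- values[i]
    rows[[i]] <- tab
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "swept") <- name
  out
}
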