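#' Simulate a single-cell trajectory (exact SSA)
#'
#' Generates one statistically exact sample path of the gate CTMC using the
#' direct stochastic simulation algorithm, starting from (S_o, 0, 0).
#' Induction profiles are piecewise constant, so within each inter-breakpoint
#' segment the rates are constant; a sampled waiting time that overshoots the
#' next breakpoint is discarded and resampled from the breakpoint, which is
#' exact by memorylessness.
#'
#' Identical `(params, profile, t_end, seed, cell_index)` yield a
#' bitwise-identical trajectory. `cell_index` selects the per-cell
#' substream, so `simulate_cell(..., seed = s, cell_index = i)` reproduces
#' cell `i` of `simulate_population(..., seed = s)`.
#'
#' @param params a `tlg_params`.
#' @param profile a `tlg_profile`.
#' @param t_end simulation horizon in hours, > 0.
#' @param seed integer RNG seed.
#' @param cell_index substream index (default 1).
#' @param max_events event-count guard; exceeding it raises an error.
#' @return an object of class `tlg_trajectory`: a list with `events`
#'   (tibble of time and the state after each event), `t_end`, `seed`,
#'   `cell_index` and `final` (the `tlg_cell` at `t_end`).
#' @export
simulate_cell <- function(params, profile, t_end, seed, cell_index = 1L,
                          max_events = 1e7) {
  stopifnot(inherits(params, "tlg_params"), inherits(profile, "tlg_profile"),
            is.numeric(t_end), length(t_end) == 1L, t_end > 0, is.finite(t_end))
  seg <- profile_segments(profile, t_end)
  raw <- cpp_simulate_cell(unclass(params), seg$seg_end, seg$ua, seg$ub,
                           t_end, as.double(seed), as.integer(cell_index),
                           max_events)
  ev <- tibble::tibble(
    time = raw$time,
    dna = dna_code_to_label(raw$dna),
    intA = raw$intA,
    intB = raw$intB
  )
  n <- nrow(ev)
  final <- if (n == 0L) cell_state("S_o", 0L, 0L)
           else cell_state(ev$dna[n], ev$intA[n], ev$intB[n])
  structure(list(events = ev, t_end = t_end, seed = seed,
                 cell_index = as.integer(cell_index),
                 params = params, profile = profile, final = final),
            class = "tlg_trajectory")
}

#' @export
print.tlg_trajectory <- function(x, ...) {
  cat(sprintf("SSA trajectory: %d events over [0, %g] h, final state %s\n",
              nrow(x$events), x$t_end, x$final$dna))
  invisible(x)
}

#' Simulate an ensemble of independent cells
#'
#' Runs `n_cells` independent SSA trajectories sharing the same parameters
#' and induction profile. Per-cell seeds are derived deterministically from
#' `(seed, cell index)`, so results are reproducible and each cell can be
#' re-simulated in isolation with [simulate_cell()].
#'
#' Only the DNA-flip events (at most two per cell) are retained per cell,
#' which is sufficient to reconstruct the DNA state at any time. Pass
#' `grid` to additionally record the DNA state — and, with
#' `record_counts = TRUE`, the integrase copy numbers — of every cell at
#' each grid time.
#'
#' @inheritParams simulate_cell
#' @param n_cells number of trajectories, >= 1.
#' @param grid optional time grid (hours, within `[0, t_end]`) at which to
#'   record per-cell states.
#' @param record_counts also record IntA/IntB counts on `grid`.
#' @return an object of class `tlg_ensemble`.
#' @export
simulate_population <- function(params, profile, t_end, n_cells, seed,
                                grid = NULL, record_counts = FALSE,
                                max_events = 1e7) {
  stopifnot(inherits(params, "tlg_params"), inherits(profile, "tlg_profile"),
            is.numeric(t_end), length(t_end) == 1L, t_end > 0, is.finite(t_end),
            is.numeric(n_cells), length(n_cells) == 1L, n_cells >= 1)
  if (is.null(grid)) grid <- numeric(0)
  if (length(grid) && (any(grid < 0) || any(grid > t_end)))
    stop("grid times must lie within [0, t_end]")
  seg <- profile_segments(profile, t_end)
  raw <- cpp_simulate_ensemble(unclass(params), seg$seg_end, seg$ua, seg$ub,
                               t_end, as.integer(n_cells), as.double(seed),
                               as.double(grid), isTRUE(record_counts),
                               max_events)
  structure(list(
    params = params, profile = profile, t_end = t_end,
    n_cells = as.integer(n_cells), seed = seed,
    final_dna = raw$final_dna,          # codes 0..3
    flip_time = raw$flip_time,          # n_cells x 2, NA-padded
    flip_to = raw$flip_to,              # n_cells x 2 codes, NA-padded
    grid = if (length(grid)) as.double(grid) else NULL,
    dna_grid = raw$dna_grid,            # n_cells x n_grid codes, or NULL
    intA_grid = raw$intA_grid,
    intB_grid = raw$intB_grid
  ), class = "tlg_ensemble")
}

#' @export
print.tlg_ensemble <- function(x, ...) {
  fr <- tabulate(x$final_dna + 1L, nbins = 4L) / x$n_cells
  cat(sprintf("SSA ensemble: %d cells to t = %g h (seed %s)\n",
              x$n_cells, x$t_end, format(x$seed)))
  cat(sprintf("  final fractions: S_o %.3f | S_a %.3f | S_b %.3f | S_ab %.3f\n",
              fr[1], fr[2], fr[3], fr[4]))
  invisible(x)
}

#' DNA state codes of every cell at time t
#'
#' Reconstructs each cell's DNA state at `t` from its recorded flip events
#' (the state after the last flip at or before `t`).
#'
#' @param ensemble a `tlg_ensemble`.
#' @param t a single time in hours within `[0, t_end]`.
#' @return integer vector of codes 0..3 (`S_o`, `S_a`, `S_b`, `S_ab`).
#' @keywords internal
dna_codes_at <- function(ensemble, t) {
  stopifnot(inherits(ensemble, "tlg_ensemble"),
            length(t) == 1L, t >= 0, t <= ensemble$t_end)
  code <- integer(ensemble$n_cells)            # all S_o
  f1 <- !is.na(ensemble$flip_time[, 1]) & ensemble$flip_time[, 1] <= t
  code[f1] <- ensemble$flip_to[f1, 1]
  f2 <- !is.na(ensemble$flip_time[, 2]) & ensemble$flip_time[, 2] <= t
  code[f2] <- ensemble$flip_to[f2, 2]
  code
}

#' Final DNA states of an ensemble
#'
#' @param ensemble a `tlg_ensemble`.
#' @return factor of DNA states at `t_end`, levels `S_o, S_a, S_b, S_ab`.
#' @export
final_states <- function(ensemble) {
  stopifnot(inherits(ensemble, "tlg_ensemble"))
  factor(dna_code_to_label(ensemble$final_dna), levels = dna_levels())
}
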