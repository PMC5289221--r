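#' @importFrom dplyr %>%
NULL

# Canonical FractionTable constructor: one row per (condition, time).
fraction_table <- function(condition, event, dt, pw_b, time, counts, n_cells) {
  frac <- counts / n_cells
  tibble::tibble(
    condition = condition, event = event, dt = dt, pw_b = pw_b, time = time,
    frac_S_o = frac[, 1], frac_S_a = frac[, 2],
    frac_S_b = frac[, 3], frac_S_ab = frac[, 4],
    n_cells = as.integer(n_cells)
  )
}

fraction_cols <- function() c("frac_S_o", "frac_S_a", "frac_S_b", "frac_S_ab")

#' Population state fractions over time
#'
#' Counts the cells of an ensemble in each DNA state at every grid time
#' (a cell's state at `t` is its state after its last event at or before
#' `t`) and divides by the ensemble size.
#'
#' @param ensemble a `tlg_ensemble`.
#' @param grid time grid in hours within `[0, t_end]`; defaults to the
#'   grid recorded in the ensemble, or 121 equally spaced points.
#' @param condition condition identifier for the output rows.
#' @return a fraction table: a tibble with one row per time, columns
#'   `condition`, `event`, `dt`, `pw_b`, `time`, `frac_S_o`, `frac_S_a`,
#'   `frac_S_b`, `frac_S_ab`, `n_cells`. Fractions sum to 1 per row.
#' @export
state_fractions <- function(ensemble, grid = NULL, condition = "cond1") {
  stopifnot(inherits(ensemble, "tlg_ensemble"))
  if (is.null(grid)) {
    grid <- if (!is.null(ensemble$grid)) ensemble$grid
            else seq(0, ensemble$t_end, length.out = 121L)
  }
  if (any(grid < 0) || any(grid > ensemble$t_end))
    stop("grid times must lie within [0, t_end]")
  counts <- matrix(0, nrow = length(grid), ncol = 4L)
  for (j in seq_along(grid)) {
    code <- dna_codes_at(ensemble, grid[j])
    counts[j, ] <- tabulate(code + 1L, nbins = 4L)
  }
  prof <- ensemble$profile
  fraction_table(condition,
                 event = attr(prof, "event") %||% NA_character_,
                 dt = attr(prof, "dt") %||% NA_real_,
                 pw_b = attr(prof, "pw_b") %||% NA_real_,
                 time = grid, counts = counts, n_cells = ensemble$n_cells)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# End-point fractions of one ensemble as a single fraction-table row.
final_fraction_row <- function(ensemble, condition) {
  counts <- matrix(tabulate(ensemble$final_dna + 1L, nbins = 4L), nrow = 1)
  prof <- ensemble$profile
  fraction_table(condition,
                 event = attr(prof, "event") %||% NA_character_,
                 dt = attr(prof, "dt") %||% NA_real_,
                 pw_b = attr(prof, "pw_b") %||% NA_real_,
                 time = ensemble$t_end, counts = counts,
                 n_cells = ensemble$n_cells)
}

#' Final-fraction scan over inducer separation times
#'
#' For each separation time, simulates a step-pair induction (a-then-b for
#' `order = "ab"`, b-then-a for `"ba"`) and reports the end-point state
#' fractions. This is the population signature used to read off event
#' order and timing: E_ab S_ab fractions increase with dt, E_ba fractions
#' decrease.
#'
#' @param params a `tlg_params`.
#' @param order `"ab"` or `"ba"`.
#' @param dts separation times in hours, >= 0.
#' @param n_cells trajectories per condition.
#' @param t_end horizon; default `NULL` runs each condition to
#'   `dt + 24` hours (24 h of growth after the second inducer arrives).
#' @param seed integer seed; per-condition seeds are derived from it.
#' @return a fraction table with one row per dt (at `time = t_end`).
#' @export
scan_dt <- function(params, order = c("ab", "ba"), dts, n_cells = 5000L,
                    t_end = NULL, seed = 1L) {
  order <- match.arg(order)
  stopifnot(is.numeric(dts), length(dts) >= 1L, all(dts >= 0))
  rows <- vector("list", length(dts))
  for (i in seq_along(dts)) {
    te <- if (is.null(t_end)) dts[i] + 24 else t_end
    ens <- simulate_population(params, step_pair(dts[i], order), te,
                               n_cells, seed = derive_seed(seed, i))
    rows[[i]] <- final_fraction_row(ens, sprintf("%s_dt%g", order, dts[i]))
  }
  dplyr::bind_rows(rows)
}

#' Final-fraction matrix over (dt, pulse width) designs
#'
#' Simulates one population per combination of b-pulse start (`dt`) and
#' width (`pw_b`) under a constant inducer-a reference signal, and reports
#' end-point fractions. The defaults give the 11 x 11 design over 0-6 h in
#' 0.5-h increments; use `seq(0, 6, 1)` on both axes for the 7 x 7
#' experiment-style design.
#'
#' @param params a `tlg_params`.
#' @param dts pulse start times in hours.
#' @param pwbs pulse widths in hours.
#' @param n_cells trajectories per condition.
#' @param seed integer seed.
#' @param t_end horizon; default `NULL` runs each condition to
#'   `dt + pw_b + 24` hours.
#' @return a fraction table with one row per (dt, pw_b) condition.
#' @export
scan_matrix <- function(params, dts = seq(0, 6, by = 0.5),
                        pwbs = seq(0, 6, by = 0.5), n_cells = 3000L,
                        seed = 1L, t_end = NULL) {
  stopifnot(length(dts) >= 1L, length(pwbs) >= 1L,
            all(dts >= 0), all(pwbs >= 0))
  design <- expand.grid(dt = dts, pw_b = pwbs, KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    d <- design$dt[i]; w <- design$pw_b[i]
    te <- if (is.null(t_end)) d + w + 24 else t_end
    ens <- simulate_population(params, pulse_b(d, w), te, n_cells,
                               seed = derive_seed(seed, i))
    rows[[i]] <- final_fraction_row(ens, sprintf("dt%g_pw%g", d, w))
  }
  dplyr::bind_rows(rows)
}

#' Detection limit dt90 of a separation-time response curve
#'
#' The smallest separation time at which the final S_ab fraction reaches
#' 90% — of the whole population (`mode = "absolute"`) or of the curve's
#' own maximum (`mode = "relative"`). Crossings between grid points are
#' linearly interpolated.
#'
#' @param curve named numeric vector mapping dt (names, hours) to final
#'   S_ab fraction, or a data frame with columns `dt` and `frac_S_ab`.
#' @param mode `"absolute"` or `"relative"`.
#' @return the dt90 in hours; `NA` (with a message) if the threshold is
#'   never reached in absolute mode.
#' @examples
#' dt90(c("0" = 0.5, "1" = 0.7, "2" = 0.88, "3" = 0.92, "4" = 0.96))
#' @export
dt90 <- function(curve, mode = c("absolute", "relative")) {
  mode <- match.arg(mode)
  if (is.data.frame(curve)) {
    dt <- curve$dt
    y <- curve$frac_S_ab
  } else {
    if (length(curve) == 0L) stop("empty curve")
    dt <- as.numeric(names(curve))
    y <- as.numeric(curve)
  }
  if (length(dt) < 2L) stop("curve needs at least 2 points")
  if (anyNA(dt) || is.unsorted(dt, strictly = TRUE))
    stop("dt keys must be sorted and numeric")
  thr <- if (mode == "absolute") 0.9 else 0.9 * max(y)
  if (y[1] >= thr) return(dt[1])
  idx <- which(y >= thr)
  if (length(idx) == 0L) {
    message("dt90: threshold ", signif(thr, 3), " not reached on the curve")
    return(NA_real_)
  }
  i <- idx[1]
  # linear interpolation of the crossing between grid points i-1 and i
  dt[i - 1] + (thr - y[i - 1]) / (y[i] - y[i - 1]) * (dt[i] - dt[i - 1])
}

# Deterministic sub-seed derivation, kept within the positive 32-bit range.
derive_seed <- function(seed, index, salt = 0L) {
  s <- (as.double(seed) %% 2147483647) + 1
  x <- (s * 48271 + index * 65537 + salt * 2654435761) %% 2147483647
  as.integer(x)
}
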