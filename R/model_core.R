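#' Tetramerization-limited flipping propensity
#'
#' A serine integrase acts on its target site as a tetramer (a dimer of
#' dimers). With no binding cooperativity, the probability that four of
#' `n` free monomers are assembled on the site follows the saturating
#' combinatorial form
#' \deqn{\alpha(n) = k_{flip}\,
#'   \frac{n(n-1)(n-2)(n-3)}{K_d^4 + K_d^3 n + K_d^2 n(n-1) +
#'   K_d\, n(n-1)(n-2) + n(n-1)(n-2)(n-3)},}
#' which is exactly zero for fewer than four monomers, strictly increasing
#' in `n`, and saturates at `kflip` for large `n`.
#'
#' @param n integer monomer count(s), >= 0 (vectorized).
#' @param kflip flipping rate constant at saturation (h^-1), >= 0.
#' @param Kd monomer dissociation constant (molecules), > 0.
#' @return propensity in h^-1, in `[0, kflip)`.
#' @examples
#' tetramer_propensity(0:6, kflip = 0.4, Kd = 10)
#' @export
tetramer_propensity <- function(n, kflip, Kd) {
  if (!is.numeric(n) || anyNA(n) || any(n < 0) || any(n != round(n)))
    stop("n must be non-negative integer count(s)")
  if (!is.numeric(kflip) || length(kflip) != 1L || is.na(kflip) || kflip < 0)
    stop("kflip must be a single non-negative rate")
  if (!is.numeric(Kd) || length(Kd) != 1L || is.na(Kd) || Kd <= 0)
    stop("Kd must be a single positive dissociation constant")
  f1 <- n
  f2 <- n * (n - 1)
  f3 <- f2 * (n - 2)
  f4 <- f3 * (n - 3)
  out <- ifelse(n < 4, 0,
                kflip * f4 / (Kd^4 + Kd^3 * f1 + Kd^2 * f2 + Kd * f3 + f4))
  as.numeric(out)
}

#' Single-cell state of the gate
#'
#' A cell is described by the tuple (DNA state, IntA count, IntB count).
#' DNA states: `S_o` (original), `S_a` (after the intA flip), `S_b`
#' (after intB excision, a dead end), `S_ab` (intA flip then intB flip).
#'
#' @param dna one of `"S_o"`, `"S_a"`, `"S_b"`, `"S_ab"`.
#' @param intA,intB non-negative integer monomer counts.
#' @return an object of class `tlg_cell`.
#' @export
cell_state <- function(dna = "S_o", intA = 0L, intB = 0L) {
  dna <- match.arg(dna, dna_levels())
  for (v in list(intA, intB))
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v != round(v))
      stop("integrase counts must be single non-negative integers")
  structure(list(dna = dna, intA = as.integer(intA), intB = as.integer(intB)),
            class = "tlg_cell")
}

#' @export
print.tlg_cell <- function(x, ...) {
  cat(sprintf("(%s; IntA = %d; IntB = %d)\n", x$dna, x$intA, x$intB))
  invisible(x)
}

#' Enabled reactions and their rates for one cell
#'
#' Enumerates the CTMC transitions out of a cell state at time `t`:
#' integrase births at `kprod * u(t) + kleak`, deaths at `kdeg * count`,
#' and the DNA flips available from the current DNA state — from `S_o`,
#' `alpha2` (intA-mediated, to `S_a`) and `alpha1` (intB-mediated
#' excision, to `S_b`); from `S_a`, `alpha3` (intB-mediated, to `S_ab`).
#' `S_b` and `S_ab` are absorbing: no DNA transitions leave them. Flips
#' do not change integrase counts.
#'
#' @param cell a `tlg_cell`.
#' @param params a `tlg_params`.
#' @param profile a `tlg_profile`.
#' @param t time in hours, >= 0.
#' @return a tibble with columns `reaction`, `dna`, `intA`, `intB`
#'   (the target state) and `rate` (h^-1). Rows for structurally
#'   unavailable DNA flips are omitted; zero-rate birth/death rows
#'   are retained.
#' @export
transition_rates <- function(cell, params, profile, t) {
  stopifnot(inherits(cell, "tlg_cell"), inherits(params, "tlg_params"),
            inherits(profile, "tlg_profile"),
            is.numeric(t), length(t) == 1L, t >= 0)
  on <- inducer_on(profile, t)
  rows <- list(
    list("IntA_birth", cell$dna, cell$intA + 1L, cell$intB,
         params$kprodA * on$a + params$kleakA),
    list("IntB_birth", cell$dna, cell$intA, cell$intB + 1L,
         params$kprodB * on$b + params$kleakB),
    list("IntA_death", cell$dna, cell$intA - 1L, cell$intB,
         params$kdeg * cell$intA),
    list("IntB_death", cell$dna, cell$intA, cell$intB - 1L,
         params$kdeg * cell$intB)
  )
  if (cell$dna == "S_o") {
    rows <- c(rows, list(
      list("flip_So_Sa", "S_a", cell$intA, cell$intB,
           tetramer_propensity(cell$intA, params$kflipA, params$KdA)),
      list("flip_So_Sb", "S_b", cell$intA, cell$intB,
           tetramer_propensity(cell$intB, params$kflipB_exc, params$KdB))))
  } else if (cell$dna == "S_a") {
    rows <- c(rows, list(
      list("flip_Sa_Sab", "S_ab", cell$intA, cell$intB,
           tetramer_propensity(cell$intB, params$kflipB, params$KdB))))
  }
  # death reactions from zero counts have rate 0 and would target -1;
  # drop them rather than emit an invalid state
  keep <- vapply(rows, function(r) r[[3]] >= 0 && r[[4]] >= 0, logical(1))
  rows <- rows[keep]
  tibble::tibble(
    reaction = vapply(rows, `[[`, character(1), 1),
    dna = vapply(rows, `[[`, character(1), 2),
    intA = vapply(rows, function(r) as.integer(r[[3]]), integer(1)),
    intB = vapply(rows, function(r) as.integer(r[[4]]), integer(1)),
    rate = vapply(rows, function(r) as.numeric(r[[5]]), numeric(1))
  )
}
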