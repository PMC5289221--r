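#' Kinetic parameters of the temporal logic gate
#'
#' Bundles every rate constant of the two-integrase gate model: induced and
#' leaky (basal) integrase production, first-order degradation/dilution,
#' DNA flipping rate constants, and the tetramerization dissociation
#' constants. Copy-number rates are molecules per hour in a fixed unit cell
#' volume, so integrase counts are dimensionless integers.
#'
#' Two named presets are provided. `"initial"` is the symmetric exploratory
#' set (kprodA = kprodB = 50 h^-1, kdeg = 0.3 h^-1, kflipA = kflipB =
#' 0.4 h^-1, zero leak, KdA = KdB = 10 molecules). `"revised"` is the
#' data-constrained set (kflipA = 0.2 h^-1, kflipB = 0.3 h^-1, kleakA = 1%
#' of kprodA, kleakB = 2% of kprodB, all other values as in `"initial"`).
#'
#' The excision transition S_o -> S_b normally shares `kflipB`; the
#' separate `kflipB_exc` constant supports the variant in which excision is
#' slower than recombination (alpha1 < alpha2 = alpha3).
#'
#' @param preset optional preset name, `"initial"` or `"revised"`; named
#'   arguments in `...` override preset fields.
#' @param ... fields to set: `kprodA`, `kprodB`, `kleakA`, `kleakB`,
#'   `kdeg`, `kflipA`, `kflipB`, `kflipB_exc`, `KdA`, `KdB`. Rates in
#'   h^-1 (production in molecules h^-1), Kd in molecules.
#' @return an object of class `tlg_params` (named list of rate constants).
#' @examples
#' rate_params("initial")
#' rate_params("revised", kflipB_exc = 0.15) # slower excision variant
#' @export
rate_params <- function(preset = NULL, ...) {
  base <- list(
    kprodA = 50, kprodB = 50, kleakA = 0, kleakB = 0,
    kdeg = 0.3, kflipA = 0.4, kflipB = 0.4, kflipB_exc = NULL,
    KdA = 10, KdB = 10
  )
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("initial", "revised"))
    if (preset == "revised") {
      base$kflipA <- 0.2
      base$kflipB <- 0.3
      base$kleakA <- 0.01 * base$kprodA
      base$kleakB <- 0.02 * base$kprodB
    }
  }
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(base))
    if (length(bad) || is.null(names(dots)) || any(names(dots) == ""))
      stop("unknown parameter field(s): ", paste(bad, collapse = ", "))
    base[names(dots)] <- dots
  }
  if (is.null(base$kflipB_exc)) base$kflipB_exc <- base$kflipB
  validate_params(base)
  structure(base, class = "tlg_params", preset = preset)
}

validate_params <- function(p) {
  rate_fields <- c("kprodA", "kprodB", "kleakA", "kleakB", "kdeg",
                   "kflipA", "kflipB", "kflipB_exc")
  for (f in rate_fields) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("parameter '", f, "' must be a single non-negative number")
  }
  for (f in c("KdA", "KdB")) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      stop("parameter '", f, "' must be a single positive number")
  }
  invisible(p)
}

#' @export
print.tlg_params <- function(x, ...) {
  preset <- attr(x, "preset")
  cat("Temporal logic gate rate parameters",
      if (!is.null(preset)) paste0(" (preset: ", preset, ")"), "\n", sep = "")
  cat(sprintf("  production : kprodA = %g, kprodB = %g  [molecules/h]\n",
              x$kprodA, x$kprodB))
  cat(sprintf("  leak       : kleakA = %g, kleakB = %g  [molecules/h]\n",
              x$kleakA, x$kleakB))
  cat(sprintf("  degradation: kdeg = %g  [1/h]\n", x$kdeg))
  cat(sprintf("  flipping   : kflipA = %g, kflipB = %g, kflipB_exc = %g  [1/h]\n",
              x$kflipA, x$kflipB, x$kflipB_exc))
  cat(sprintf("  Kd         : KdA = %g, KdB = %g  [molecules]\n", x$KdA, x$KdB))
  invisible(x)
}

#' Modify a parameter set
#'
#' Returns a copy of `params` with the named fields replaced, revalidated.
#' `kflipB_exc` is not silently re-tied to `kflipB`: updating `kflipB`
#' also updates `kflipB_exc` only when the two were equal beforehand.
#'
#' @param params a `tlg_params` object.
#' @param ... fields to replace.
#' @return a `tlg_params` object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "tlg_params"))
  dots <- list(...)
  bad <- setdiff(names(dots), names(unclass(params)))
  if (length(bad)) stop("unknown parameter field(s): ", paste(bad, collapse = ", "))
  tied <- isTRUE(all.equal(params$kflipB, params$kflipB_exc))
  out <- unclass(params)
  out[names(dots)] <- dots
  if (tied && "kflipB" %in% names(dots) && !("kflipB_exc" %in% names(dots)))
    out$kflipB_exc <- out$kflipB
  validate_params(out)
  structure(out, class = "tlg_params", preset = NULL)
}

# DNA state coding shared across the package: C++ core uses 0..3, R uses
# this fixed level order everywhere.
dna_levels <- function() c("S_o", "S_a", "S_b", "S_ab")

dna_code_to_label <- function(code) dna_levels()[code + 1L]

dna_label_to_code <- function(label) {
  m <- match(label, dna_levels())
  if (anyNA(m)) stop("unknown DNA state label: ",
                     paste(label[is.na(m)], collapse = ", "))
  m - 1L
}
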