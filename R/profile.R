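#' Piecewise-constant induction schedules
#'
#' An induction profile records when each of the two inducers is present as
#' a set of half-open intervals `[start, end)` per channel. Inducer
#' concentrations are on/off only: `u_a(t)` and `u_b(t)` are indicator
#' functions.
#'
#' @param intervals_a,intervals_b two-column matrices (start, end) of
#'   on-intervals in hours, or `NULL` for a channel that is never induced.
#'   Intervals must be sorted, non-overlapping, with start < end; `Inf`
#'   is allowed as an end point (a step input).
#' @param event optional event-class label (`"E_a"`, `"E_b"`, `"E_ab"`,
#'   `"E_ba"`, `"none"`), carried as metadata.
#' @param dt,pw_b optional inducer separation time and b-pulse width
#'   metadata (hours; `pw_b = Inf` for step inputs).
#' @return an object of class `tlg_profile`.
#' @seealso [step_pair()], [pulse_b()]
#' @export
induction_profile <- function(intervals_a = NULL, intervals_b = NULL,
                              event = NA_character_, dt = NA_real_,
                              pw_b = NA_real_) {
  norm <- function(x, ch) {
    if (is.null(x) || length(x) == 0L) return(matrix(numeric(0), ncol = 2))
    if (is.vector(x) && length(x) == 2L) x <- matrix(x, ncol = 2, byrow = TRUE)
    x <- as.matrix(x)
    if (ncol(x) != 2L) stop("intervals_", ch, " must have two columns (start, end)")
    if (any(!is.finite(x[, 1])) || any(is.na(x[, 2])))
      stop("intervals_", ch, ": starts must be finite, ends non-missing")
    if (any(x[, 1] < 0)) stop("intervals_", ch, ": negative start time")
    if (any(x[, 1] >= x[, 2])) stop("intervals_", ch, ": need start < end")
    if (nrow(x) > 1L) {
      if (is.unsorted(x[, 1], strictly = TRUE))
        stop("intervals_", ch, " must be sorted by start time")
      if (any(x[-1L, 1] < x[-nrow(x), 2]))
        stop("intervals_", ch, " must not overlap")
    }
    unname(x)
  }
  structure(
    list(intervals_a = norm(intervals_a, "a"),
         intervals_b = norm(intervals_b, "b")),
    class = "tlg_profile", event = event, dt = dt, pw_b = pw_b)
}

#' Step-input pair separated by dt
#'
#' The canonical two-step schedule: the first inducer switches on at t = 0
#' and stays on; the second switches on `dt` hours later and stays on.
#' `order = "ab"` gives inducer a first (an E_ab event), `order = "ba"`
#' inducer b first (E_ba). At `dt = 0` the two orders coincide (both
#' inducers from t = 0, labelled by the requested order).
#'
#' @param dt inducer separation time in hours, >= 0.
#' @param order which inducer comes first, `"ab"` (default) or `"ba"`.
#' @return a `tlg_profile`.
#' @export
step_pair <- function(dt, order = c("ab", "ba")) {
  order <- match.arg(order)
  stopifnot(is.numeric(dt), length(dt) == 1L, is.finite(dt), dt >= 0)
  first <- c(0, Inf)
  second <- c(dt, Inf)
  if (order == "ab")
    induction_profile(first, second, event = "E_ab", dt = dt, pw_b = Inf)
  else
    induction_profile(second, first, event = "E_ba", dt = dt, pw_b = Inf)
}

#' Constant reference input a with a finite pulse of b
#'
#' Inducer a is on from t = 0 for the whole run (the reference signal);
#' inducer b is applied as a single pulse on `[dt, dt + pw_b)`.
#' `pw_b = 0` yields an empty b channel (an a-only event);
#' `pw_b = Inf` recovers the step pair.
#'
#' @param dt start of the b pulse (hours, >= 0).
#' @param pw_b pulse width of inducer b (hours, >= 0; may be `Inf`).
#' @return a `tlg_profile`.
#' @export
pulse_b <- function(dt, pw_b) {
  stopifnot(is.numeric(dt), length(dt) == 1L, is.finite(dt), dt >= 0,
            is.numeric(pw_b), length(pw_b) == 1L, !is.na(pw_b), pw_b >= 0)
  b <- if (pw_b > 0) c(dt, dt + pw_b) else NULL
  ev <- if (pw_b > 0) "E_ab" else "E_a"
  induction_profile(c(0, Inf), b, event = ev, dt = dt, pw_b = pw_b)
}

#' @export
print.tlg_profile <- function(x, ...) {
  fmt <- function(m, ch) {
    if (nrow(m) == 0L) return(sprintf("  %s: never on\n", ch))
    iv <- apply(m, 1, function(r) sprintf("[%g, %g)", r[1], r[2]))
    sprintf("  %s: on %s\n", ch, paste(iv, collapse = ", "))
  }
  cat("Induction profile (hours)\n")
  cat(fmt(x$intervals_a, "a"))
  cat(fmt(x$intervals_b, "b"))
  invisible(x)
}

#' Indicator value of each inducer at time t
#'
#' @param profile a `tlg_profile`.
#' @param t time in hours (vectorized).
#' @return a list with logical vectors `a` and `b`.
#' @export
inducer_on <- function(profile, t) {
  stopifnot(inherits(profile, "tlg_profile"))
  on <- function(m, t) {
    if (nrow(m) == 0L) return(rep(FALSE, length(t)))
    vapply(t, function(ti) any(ti >= m[, 1] & ti < m[, 2]), logical(1))
  }
  list(a = on(profile$intervals_a, t), b = on(profile$intervals_b, t))
}

#' Finite sorted breakpoint set of a profile
#'
#' All interval endpoints below the horizon, i.e. the times at which the
#' reaction rates can change.
#'
#' @param profile a `tlg_profile`.
#' @param t_end horizon in hours (breakpoints at or beyond it are dropped).
#' @return sorted numeric vector of breakpoints in `(0, t_end)`.
#' @export
profile_breakpoints <- function(profile, t_end = Inf) {
  bp <- c(profile$intervals_a, profile$intervals_b)
  bp <- sort(unique(bp[is.finite(bp) & bp > 0 & bp < t_end]))
  bp
}

# Segment decomposition used by the SSA core and the CME integrator:
# right endpoints of the constant-rate segments partitioning [0, t_end],
# with the inducer indicators on each segment (evaluated at midpoints).
profile_segments <- function(profile, t_end) {
  stopifnot(is.finite(t_end), t_end > 0)
  bp <- profile_breakpoints(profile, t_end)
  seg_end <- c(bp, t_end)
  seg_start <- c(0, bp)
  mid <- (seg_start + seg_end) / 2
  on <- inducer_on(profile, mid)
  list(seg_end = seg_end, ua = as.integer(on$a), ub = as.integer(on$b))
}
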