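#' Measurement noise model for synthetic datasets
#'
#' Describes how a true simulated population is turned into an observed
#' one: finite sampling of cells on the cytometer, replicate-to-replicate
#' biological variability (a log-normal multiplicative perturbation of the
#' flipping rates), and an optional growth-rate bias between DNA states
#' applied as deterministic exponential reweighting of the final
#' fractions.
#'
#' @param n_sampled_cells events measured per population (default 1e6,
#'   the order counted per population on a cytometer); `Inf` returns the
#'   exact simulated fractions.
#' @param replicates replicate populations per condition.
#' @param replicate_cv coefficient of variation of the per-replicate
#'   multiplicative effect on kflipA/kflipB/kflipB_exc (default 0.1).
#' @param growth_bias optional named numeric of per-state relative growth
#'   rates in h^-1 (names among `S_o`, `S_a`, `S_b`, `S_ab`; missing
#'   states get 0). Final fractions are reweighted by
#'   `exp(growth_bias * elapsed_time)` and renormalized.
#' @return an object of class `tlg_noise`.
#' @export
noise_model <- function(n_sampled_cells = 1e6, replicates = 3L,
                        replicate_cv = 0.1, growth_bias = NULL) {
  stopifnot(n_sampled_cells >= 1, replicates >= 1, replicate_cv >= 0)
  if (!is.null(growth_bias)) {
    if (is.null(names(growth_bias)) ||
        !all(names(growth_bias) %in% dna_levels()))
      stop("growth_bias must be named with DNA state labels")
    gb <- stats::setNames(numeric(4), dna_levels())
    gb[names(growth_bias)] <- growth_bias
    growth_bias <- gb
  }
  structure(list(n_sampled_cells = n_sampled_cells,
                 replicates = as.integer(replicates),
                 replicate_cv = replicate_cv,
                 growth_bias = growth_bias),
            class = "tlg_noise")
}

# log-normal multiplier with unit mean and the requested CV
lognormal_multiplier <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a noisy per-condition fraction dataset
#'
#' Stands in for the wet-lab measurements: for every design condition and
#' replicate, the gate model is simulated with replicate-specific
#' flipping-rate perturbations, the final fractions are optionally
#' reweighted by the growth bias over the run duration, and the observed
#' state counts are drawn multinomially at the sampled-cell depth.
#' Fully reproducible from `seed`.
#'
#' @param params a `tlg_params` (true kinetics).
#' @param design data frame of conditions: either columns `dt` and
#'   `pw_b` (pulse design; `pw_b = Inf` for steps) or columns `order`
#'   (`"ab"`/`"ba"`) and `dt` (step design).
#' @param noise a `tlg_noise`.
#' @param n_cells SSA trajectories per population.
#' @param seed integer seed.
#' @param t_end horizon; default `NULL` uses `dt + pw_b + 24` h for pulse
#'   conditions (with `pw_b` capped at 0 h for a-only runs) and
#'   `dt + 24` h for step conditions.
#' @return a fraction table with one row per (condition, replicate) and
#'   an extra `replicate` column; `n_cells` records the sampled depth
#'   when finite.
#' @export
generate_fraction_dataset <- function(params, design, noise = noise_model(),
                                      n_cells = 500L, seed = 1L,
                                      t_end = NULL) {
  stopifnot(inherits(params, "tlg_params"), inherits(noise, "tlg_noise"),
            NROW(design) >= 1L)
  by_order <- "order" %in% names(design)
  if (!by_order && !all(c("dt", "pw_b") %in% names(design)))
    stop("design needs columns (dt, pw_b) or (order, dt)")
  rows <- vector("list", nrow(design) * noise$replicates)
  k <- 0L
  for (i in seq_len(nrow(design))) {
    d <- design$dt[i]
    if (by_order) {
      prof <- step_pair(d, design$order[i])
      te <- if (is.null(t_end)) d + 24 else t_end
    } else {
      w <- design$pw_b[i]
      prof <- if (is.finite(w)) pulse_b(d, w) else step_pair(d, "ab")
      te <- if (is.null(t_end)) d + (if (is.finite(w)) w else 0) + 24 else t_end
    }
    for (r in seq_len(noise$replicates)) {
      k <- k + 1L
      sub <- derive_seed(seed, i, salt = r)
      # replicate-specific biology: perturb the flipping rates
      set.seed(derive_seed(sub, 7L))
      mult <- lognormal_multiplier(3L, noise$replicate_cv)
      pars_r <- update_params(params,
                              kflipA = params$kflipA * mult[1],
                              kflipB = params$kflipB * mult[2],
                              kflipB_exc = params$kflipB_exc * mult[3])
      ens <- simulate_population(pars_r, prof, te, n_cells, seed = sub)
      frac <- tabulate(ens$final_dna + 1L, nbins = 4L) / n_cells
      if (!is.null(noise$growth_bias)) {
        w_gb <- frac * exp(noise$growth_bias * te)
        frac <- w_gb / sum(w_gb)
      }
      if (is.finite(noise$n_sampled_cells)) {
        set.seed(derive_seed(sub, 11L))
        cnt <- stats::rmultinom(1, size = noise$n_sampled_cells, prob = frac)
        frac <- as.numeric(cnt) / noise$n_sampled_cells
        n_obs <- noise$n_sampled_cells
      } else {
        n_obs <- n_cells
      }
      row <- final_fraction_row(ens, sprintf("cond%d_rep%d", i, r))
      row[, fraction_cols()] <- as.list(frac)
      row$n_cells <- as.integer(min(n_obs, .Machine$integer.max))
      row$replicate <- r
      rows[[k]] <- row
    }
  }
  dplyr::bind_rows(rows)
}

#' Default two-channel fluorescence model
#'
#' Log-normal intensity distributions per DNA state and channel, with a
#' 10-fold separation between the "on" and "off" channel means and a
#' CV of 0.3 (declared defaults, not measured values). `S_ab` may carry
#' residual RFP with probability `residual_rfp` to emulate cells that
#' switched recently and have not yet diluted their RFP.
#'
#' @param off_mean,on_mean channel means in arbitrary units.
#' @param cv per-channel log-normal coefficient of variation.
#' @param residual_rfp probability that an `S_ab` event still shows RFP
#'   (default 0.03, the observed ceiling of the double-positive quadrant).
#' @return a list describing the per-state emission model, with gate
#'   thresholds at the geometric midpoint of the two means.
#' @export
fluorescence_model <- function(off_mean = 100, on_mean = 1000, cv = 0.3,
                               residual_rfp = 0.03) {
  stopifnot(off_mean > 0, on_mean > off_mean, cv > 0,
            residual_rfp >= 0, residual_rfp <= 1)
  list(
    rfp_on = c(S_o = FALSE, S_a = TRUE, S_b = FALSE, S_ab = FALSE),
    gfp_on = c(S_o = FALSE, S_a = FALSE, S_b = FALSE, S_ab = TRUE),
    off_mean = off_mean, on_mean = on_mean, cv = cv,
    residual_rfp = residual_rfp,
    threshold_rfp = sqrt(off_mean * on_mean),
    threshold_gfp = sqrt(off_mean * on_mean)
  )
}

#' Synthesize flow-cytometry-like two-channel events
#'
#' For each event a hidden DNA state is drawn from one fraction-table
#' row's state fractions, then RFP and GFP intensities are drawn from the
#' state's log-normal emission model.
#'
#' @param fractions a single fraction-table row.
#' @param n_events events to draw, >= 1.
#' @param fluor_model emission model from [fluorescence_model()].
#' @param seed integer seed.
#' @return an object of class `tlg_cytometry`: tibble of
#'   (condition, replicate, state, rfp, gfp) with gate thresholds as
#'   attributes.
#' @export
generate_cytometry_events <- function(fractions, n_events,
                                      fluor_model = fluorescence_model(),
                                      seed = 1L) {
  stopifnot(NROW(fractions) == 1L, n_events >= 1)
  need <- c("rfp_on", "gfp_on", "off_mean", "on_mean", "cv",
            "residual_rfp", "threshold_rfp", "threshold_gfp")
  if (!all(need %in% names(fluor_model)))
    stop("fluor_model is missing: ",
         paste(setdiff(need, names(fluor_model)), collapse = ", "))
  if (!all(dna_levels() %in% names(fluor_model$rfp_on)))
    stop("fluor_model must cover every DNA state")
  probs <- as.numeric(fractions[1, fraction_cols()])
  set.seed(derive_seed(seed, 13L))
  state <- sample(dna_levels(), n_events, replace = TRUE, prob = probs)

  sdlog <- sqrt(log(1 + fluor_model$cv^2))
  draw <- function(on) {
    mu <- ifelse(on, fluor_model$on_mean, fluor_model$off_mean)
    stats::rlnorm(n_events, meanlog = log(mu) - sdlog^2 / 2, sdlog = sdlog)
  }
  rfp_on <- fluor_model$rfp_on[state]
  # recently switched S_ab cells may still carry RFP
  res <- state == "S_ab" &
    stats::runif(n_events) < fluor_model$residual_rfp
  rfp_on[res] <- TRUE
  gfp_on <- fluor_model$gfp_on[state]

  structure(tibble::tibble(
    condition = fractions$condition[1],
    replicate = fractions$replicate[1] %||% 1L,
    state = state,
    rfp = draw(rfp_on),
    gfp = draw(gfp_on)
  ), class = c("tlg_cytometry", "tbl_df", "tbl", "data.frame"),
  threshold_rfp = fluor_model$threshold_rfp,
  threshold_gfp = fluor_model$threshold_gfp)
}

#' Gate cytometry events into quadrants and fraction readouts
#'
#' Classifies every event by the two channel thresholds into quadrants
#' Q1 (GFP only), Q2 (both), Q3 (RFP only), Q4 (neither), and derives the
#' population readouts used for inference: `G = Q1 + Q2` (GFP-positive,
#' the S_ab proxy) and `R = Q3` (RFP only, the S_a proxy).
#'
#' @param events a `tlg_cytometry` table (thresholds carried as
#'   attributes, overridable).
#' @param threshold_rfp,threshold_gfp gate thresholds in intensity units.
#' @return a list with `quadrants` (named fractions Q1..Q4, summing
#'   to 1), `R`, and `G`.
#' @export
gate_quadrants <- function(events,
                           threshold_rfp = attr(events, "threshold_rfp"),
                           threshold_gfp = attr(events, "threshold_gfp")) {
  if (is.null(threshold_rfp) || is.null(threshold_gfp))
    stop("gate thresholds are not set")
  rfp <- events$rfp > threshold_rfp
  gfp <- events$gfp > threshold_gfp
  q <- c(Q1 = mean(gfp & !rfp), Q2 = mean(gfp & rfp),
         Q3 = mean(rfp & !gfp), Q4 = mean(!rfp & !gfp))
  list(quadrants = q, R = unname(q["Q3"]), G = unname(q["Q1"] + q["Q2"]))
}
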