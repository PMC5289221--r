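#' Run configuration for reproducible pipelines
#'
#' A run configuration bundles everything a simulation stage needs —
#' parameters (or a preset name), the induction profile spec, simulation
#' settings and the output directory — so a run re-executed from its
#' saved config and seed reproduces its outputs.
#'
#' Recognized keys: `preset` or `params` (list of rate fields),
#' `profile` (list with `type` = `"step"`/`"pulse"`, `order`, `dt`,
#' `pw_b`), `n_cells`, `t_end`, `seed`, `grid_points`, `out_dir`.
#'
#' @param x a named list, or a path to a JSON/YAML file containing one.
#' @return an object of class `tlg_config` (validated named list).
#' @export
run_config <- function(x) {
  if (is.character(x) && length(x) == 1L) x <- read_doc(x)
  if (!is.list(x)) stop("config must be a named list or a file path")
  known <- c("preset", "params", "profile", "n_cells", "t_end", "seed",
             "grid_points", "out_dir")
  bad <- setdiff(names(x), known)
  if (length(bad))
    stop("invalid config key(s): ", paste(bad, collapse = ", "),
         " (known: ", paste(known, collapse = ", "), ")")
  if (!is.null(x$preset) && !x$preset %in% c("initial", "revised"))
    stop("unknown preset '", x$preset, "'; valid presets: initial, revised")
  defaults <- list(n_cells = 1000L, t_end = NULL, seed = 1L,
                   grid_points = 121L, out_dir = ".")
  for (k in names(defaults)) if (is.null(x[[k]])) x[[k]] <- defaults[[k]]
  structure(x, class = "tlg_config")
}

config_params <- function(config) {
  if (!is.null(config$params)) do.call(rate_params, config$params)
  else rate_params(config$preset %||% "initial")
}

config_profile <- function(config) {
  p <- config$profile %||% list(type = "step", order = "ab", dt = 0)
  type <- p$type %||% "step"
  if (type == "step") step_pair(p$dt %||% 0, p$order %||% "ab")
  else if (type == "pulse") pulse_b(p$dt %||% 0, p$pw_b %||% 0)
  else stop("unknown profile type '", type, "' (use 'step' or 'pulse')")
}

#' Simulate from a run configuration and write the outputs
#'
#' Runs an SSA ensemble per the config and writes `fractions.csv` (the
#' state-fraction time course), `summary.json` (final fractions, seed,
#' parameters, package version) and `run.log` to the output directory.
#'
#' @param config a `tlg_config`, a named list, or a config file path.
#' @return invisibly, a list with the fraction table and the file paths.
#' @export
run_simulate <- function(config) {
  config <- if (inherits(config, "tlg_config")) config else run_config(config)
  params <- config_params(config)
  profile <- config_profile(config)
  dt <- attr(profile, "dt"); pw <- attr(profile, "pw_b")
  t_end <- config$t_end %||%
    (if (is.finite(pw)) dt + pw + 24 else max(30, dt + 24))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  grid <- seq(0, t_end, length.out = config$grid_points)
  ens <- simulate_population(params, profile, t_end, config$n_cells,
                             seed = config$seed)
  tab <- state_fractions(ens, grid)

  paths <- file.path(config$out_dir,
                     c("fractions.csv", "summary.json", "run.log"))
  write_fraction_table(tab, paths[1])
  final <- tab[nrow(tab), fraction_cols()]
  jsonlite::write_json(list(
    seed = config$seed, n_cells = config$n_cells, t_end = t_end,
    params = unclass(params),
    profile = list(event = attr(profile, "event"), dt = dt, pw_b = pw),
    final_fractions = as.list(final),
    package_version = as.character(utils::packageVersion("tempogate"))
  ), paths[2], auto_unbox = TRUE, digits = NA, na = "string")
  writeLines(c(
    sprintf("tempogate run at %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("seed=%s n_cells=%d t_end=%g", format(config$seed),
            as.integer(config$n_cells), t_end),
    sprintf("params: %s", paste(sprintf("%s=%g", names(unclass(params)),
                                        unlist(unclass(params))),
                                collapse = " ")),
    sprintf("R %s, tempogate %s", getRversion(),
            utils::packageVersion("tempogate"))
  ), paths[3])
  invisible(list(fractions = tab, paths = paths))
}

#' Fit a surface from a calibration CSV and invert sample measurements
#'
#' Reads a calibration fraction table and a samples table (columns `R`,
#' `G`), fits the inversion surface, and writes per-sample estimates
#' (`estimates.csv`) plus the mesh lookup table (`lookup.csv`). Samples
#' with `R` or `G` outside `[0, 1]` are flagged and skipped, not fatal;
#' an empty samples file yields an empty estimates file.
#'
#' @param calib_csv path to the calibration fraction table CSV.
#' @param samples_csv path to the samples CSV with columns `R` and `G`.
#' @param out_dir output directory.
#' @param mesh_step lookup mesh spacing (fraction units).
#' @return invisibly, a list with the estimates, the lookup table and the
#'   fitted surface.
#' @export
run_infer <- function(calib_csv, samples_csv, out_dir = ".",
                      mesh_step = 0.05) {
  calib <- read_fraction_table(calib_csv)
  samples <- read_fraction_table(samples_csv)
  if (!all(c("R", "G") %in% names(samples)) && nrow(samples) > 0L)
    stop("samples CSV must have columns R and G")
  surface <- fit_surface(calib)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (nrow(samples) == 0L) {
    est <- tibble::tibble(R = numeric(0), G = numeric(0),
                          pw_b_hat = numeric(0), dt_hat = numeric(0),
                          out_of_domain = logical(0), invalid = logical(0))
  } else {
    ok <- !is.na(samples$R) & !is.na(samples$G) &
      samples$R >= 0 & samples$R <= 1 & samples$G >= 0 & samples$G <= 1
    est <- tibble::tibble(R = samples$R, G = samples$G,
                          pw_b_hat = NA_real_, dt_hat = NA_real_,
                          out_of_domain = NA, invalid = !ok)
    if (any(ok)) {
      e <- estimate_event(samples$R[ok], samples$G[ok], surface)
      est$pw_b_hat[ok] <- e$pw_b_hat
      est$dt_hat[ok] <- e$dt_hat
      est$out_of_domain[ok] <- e$out_of_domain
    }
    if (any(!ok))
      warning(sum(!ok), " sample row(s) with R/G outside [0,1] flagged ",
              "invalid and skipped")
  }
  paths <- file.path(out_dir, c("estimates.csv", "lookup.csv"))
  utils::write.csv(est, paths[1], row.names = FALSE)
  utils::write.csv(build_lookup(surface, mesh_step), paths[2],
                   row.names = FALSE)
  invisible(list(estimates = est, lookup_path = paths[2], surface = surface))
}

#' Run the SSA-versus-CME validation suite
#'
#' Cross-validates the stochastic engine against the truncated
#' master-equation oracle on a reduced-rate instance (kprod = 5 so modest
#' truncation caps suffice), comparing DNA marginals at the horizon
#' within binomial Monte-Carlo error.
#'
#' @param seed integer seed for the SSA side.
#' @param n_cells SSA trajectories.
#' @param t_end horizon in hours.
#' @return a list with the per-state comparison table (`z` scores in
#'   units of binomial SE) and `pass`.
#' @export
run_validate <- function(seed = 1L, n_cells = 10000L, t_end = 10) {
  params <- rate_params(kprodA = 5, kprodB = 5, kdeg = 0.3,
                        kflipA = 0.4, kflipB = 0.4, KdA = 10, KdB = 10)
  profile <- step_pair(0)
  cme <- solve_truncated_cme(params, profile, t_end, capA = 40, capB = 40,
                             grid = t_end)
  ens <- simulate_population(params, profile, t_end, n_cells, seed = seed)
  emp <- tabulate(ens$final_dna + 1L, nbins = 4L) / n_cells
  p <- as.numeric(cme[nrow(cme), c("P_S_o", "P_S_a", "P_S_b", "P_S_ab")])
  se <- sqrt(pmax(p * (1 - p), 1e-12) / n_cells)
  z <- (emp - p) / se
  tab <- tibble::tibble(state = dna_levels(), cme = p, ssa = emp,
                        se = se, z = z)
  list(comparison = tab, pass = all(abs(z) <= 3),
       mass_defect = max(cme$mass_defect))
}
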