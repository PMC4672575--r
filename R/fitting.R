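# Forward harnesses reproducing the three calibration protocols (DSB decay
# after acute irradiation, DSB-positive bystander fraction, clonogenic
# survival by phase) and a grid-search least-squares fitter over them.

#' DSB-decay harness: repair-only kinetics
#'
#' Simulates a population of independent cells that start with `Z0` DSBs
#' and experience repair only (signals and background forced to zero, as
#' in the calibration protocol). Each cell draws its repair probability
#' from the catalogue; every DSB then survives a step with probability
#' `1 - lambda`, so the count after any number of steps is an exact
#' binomial thinning — the harness draws it blockwise per output time,
#' which reproduces the per-step process distribution exactly.
#'
#' @param catalogue Parameter catalogue.
#' @param phase Phase whose repair distribution to use.
#' @param Z0 Initial DSB count per cell.
#' @param duration_h Followed time span (h).
#' @param n_cells Number of cells.
#' @param dt Time step (s) defining the per-step repair trial.
#' @param record_every_min Output cadence (min).
#' @param repair_mode `"per_step"` or `"per_second"` (see [sim_config()]).
#' @return Data frame `time_h`, `mean_Z`.
#' @export
harness_dsb_decay <- function(catalogue = default_catalogue(),
                              phase = "G1", Z0 = 35, duration_h = 24,
                              n_cells = 10000L, dt = 0.1,
                              record_every_min = 30,
                              repair_mode = c("per_step", "per_second")) {
  repair_mode <- match.arg(repair_mode)
  code <- if (is.character(phase)) PHASES[[phase]] else as.integer(phase)
  lam <- sample_truncated_normal(n_cells,
                                 .field_spec(catalogue, "repair_lambda", code))
  p_step <- if (repair_mode == "per_step") lam else pmin(lam * dt, 1)
  times_h <- seq(0, duration_h, by = record_every_min / 60)
  steps <- round(times_h * 3600 / dt)
  Z <- rep.int(as.integer(Z0), n_cells)
  mean_Z <- numeric(length(times_h))
  mean_Z[1L] <- mean(Z)
  for (k in seq_along(times_h)[-1L]) {
    nsub <- steps[k] - steps[k - 1L]
    Z <- stats::rbinom(n_cells, Z, (1 - p_step)^nsub)
    mean_Z[k] <- mean(Z)
  }
  data.frame(time_h = times_h, mean_Z = mean_Z)
}

#' DSB-positive-fraction harness
#'
#' Reproduces the bystander-focus-count protocol: a confluent dish of
#' quiescent cells (no irradiation) carries an initial quantity of both
#' virtual signals, and the fraction of cells with at least one DSB
#' (one or more foci) is scored after `duration_min` minutes. Disabling
#' the gap-junctional pathway emulates lindane treatment. The full engine
#' runs underneath.
#'
#' @param catalogue Parameter catalogue.
#' @param gjp_enabled Gap-junctional pathway switch.
#' @param mdp_enabled Medium-mediated pathway switch.
#' @param n_side Lattice side (cells are `(n_side - 2)^2`).
#' @param duration_min Scoring time (min).
#' @param dt Time step (s).
#' @param init_M,init_G Initial signal per cell site (units).
#' @return List with `fraction` (DSB-positive fraction at the end),
#'   `n_cells`, and `records` (the engine time series).
#' @export
harness_dsb_positive <- function(catalogue = default_catalogue(),
                                 gjp_enabled = TRUE, mdp_enabled = TRUE,
                                 n_side = 102L, duration_min = 30,
                                 dt = 0.1, init_M = 2.5e-3,
                                 init_G = 2.5e-3) {
  cfg <- sim_config("confluent", n_rows = n_side, n_cols = n_side,
                    duration_h = duration_min / 60, dt = dt,
                    record_every_min = duration_min,
                    catalogue = catalogue, init_phase = "G0",
                    init_M = if (mdp_enabled) init_M else 0,
                    init_G = if (gjp_enabled) init_G else 0,
                    mdp_enabled = mdp_enabled, gjp_enabled = gjp_enabled)
  world <- build_confluent_world(cfg)
  n_steps <- ceiling(cfg$duration_h * 3600 / dt)
  for (k in seq_len(n_steps)) world <- step_world(world)
  rec <- count_states(world)
  list(fraction = rec$frac_Z_pos[1L], n_cells = rec$n_cells[1L],
       records = rec)
}

#' Clonogenic-survival harness
#'
#' Reproduces the survival-fraction protocol: independent cells of one
#' phase are irradiated at a fixed dose rate, repair is off during the
#' exposure, and a cell survives if its final DSB count stays below its
#' own reproductive-death threshold. Dose is delivered as Poisson track
#' traversals; the per-step Poisson cascade is collapsed exactly (a
#' Poisson number of tracks, then Poisson DSBs given the realised dose).
#'
#' @param catalogue Parameter catalogue.
#' @param dose_gy Dose (Gy).
#' @param phase Cell-cycle phase of the synchronised population.
#' @param n_cells Number of cells.
#' @param d1track_gy Dose per track (Gy).
#' @param dose_rate_gy_min Dose rate (Gy/min); with the track dose it
#'   fixes the exposure duration, which does not affect the final count
#'   because repair is off.
#' @return List with `fraction` (surviving fraction), `n_cells`,
#'   `dose_gy`, `phase`.
#' @export
harness_survival <- function(catalogue = default_catalogue(), dose_gy,
                             phase = "G1", n_cells = 10000L,
                             d1track_gy = 1e-3, dose_rate_gy_min = 0.5) {
  code <- if (is.character(phase)) PHASES[[phase]] else as.integer(phase)
  lam <- sample_truncated_normal(n_cells,
                                 .field_spec(catalogue, "zr_lambda", code))
  H <- sample_truncated_normal(n_cells,
                               .field_spec(catalogue, "prd_threshold", code))
  if (dose_gy == 0) {
    Z <- numeric(n_cells)
  } else {
    K <- stats::rpois(n_cells, dose_gy / d1track_gy)
    Z <- stats::rpois(n_cells, lam * d1track_gy * K)
  }
  list(fraction = mean(Z < H), n_cells = n_cells, dose_gy = dose_gy,
       phase = phase)
}

#' Grid-search least-squares fit
#'
#' Evaluates a forward model over a full factorial grid of parameter
#' values and scores each point by the (optionally weighted) sum of
#' squared residuals against a calibration dataset. The whole loss
#' surface is returned so the fit can be audited, not just the argmin.
#'
#' @param simulate Function taking a named numeric vector of parameters
#'   and returning either a data frame whose first two columns are
#'   (abscissa, value) or a single numeric value.
#' @param dataset Data frame whose first two columns are (abscissa,
#'   observed value); for scalar `simulate` output a one-row dataset.
#' @param ranges Named list of `c(lo, hi)` parameter bounds.
#' @param resolution Number of grid points per parameter (scalar or named
#'   vector).
#' @param weights Optional residual weights (recycled over observations).
#' @return Object of class `grid_search`: list with `best` (named
#'   parameter vector), `best_loss`, and `surface` (grid plus loss).
#' @export
grid_search <- function(simulate, dataset, ranges, resolution = 10,
                        weights = 1) {
  stopifnot(length(ranges) >= 1, nrow(dataset) >= 1)
  for (r in ranges) if (r[1L] > r[2L]) stop("range with lo > hi")
  res <- rep_len(if (is.null(names(resolution))) resolution
                 else resolution[names(ranges)], length(ranges))
  axes <- Map(function(r, n) if (n == 1L) mean(r)
              else seq(r[1L], r[2L], length.out = n), ranges, res)
  grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  names(grid) <- names(ranges)
  obs_x <- dataset[[1L]]; obs_y <- dataset[[2L]]
  w <- rep_len(weights, length(obs_y))
  loss <- vapply(seq_len(nrow(grid)), function(i) {
    out <- simulate(unlist(grid[i, , drop = FALSE]))
    pred <- if (is.data.frame(out) && nrow(out) >= 2L)
      stats::approx(out[[1L]], out[[2L]], xout = obs_x, rule = 2)$y
    else if (is.data.frame(out)) rep_len(out[[2L]], length(obs_y))
    else rep_len(out, length(obs_y))
    sum(w * (pred - obs_y)^2)
  }, numeric(1L))
  i <- which.min(loss)
  structure(list(best = unlist(grid[i, , drop = FALSE]),
                 best_loss = loss[i],
                 surface = cbind(grid, loss = loss)),
            class = "grid_search")
}

#' @export
print.grid_search <- function(x, ...) {
  cat("<grid_search>", nrow(x$surface), "grid points\n  best:",
      paste(sprintf("%s = %.4g", names(x$best), x$best), collapse = ", "),
      sprintf("(loss %.4g)\n", x$best_loss))
  invisible(x)
}

#' Read a calibration dataset from CSV
#'
#' @param path CSV with columns (abscissa, value); extra columns kept.
#' @return Data frame, validated to have strictly increasing abscissae
#'   and non-negative values.
#' @export
read_calibration <- function(path) {
  df <- utils::read.csv(path)
  if (ncol(df) < 2) stop("calibration data needs two columns")
  if (any(diff(df[[1L]]) <= 0)) stop("abscissae must be strictly increasing")
  if (any(df[[2L]] < 0)) stop("values must be non-negative")
  df
}
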