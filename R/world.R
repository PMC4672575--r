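#' Simulation configuration
#'
#' Assembles and validates everything a run needs: scenario and geometry,
#' time stepping, irradiation, the parameter catalogue, pathway switches
#' and the resolution of the model's unit ambiguities (decay, repair and
#' background modes). The explicit diffusion scheme's stability condition
#' is enforced here for every enabled pathway.
#'
#' @param scenario `"three_area"` (three colonies A/B/C, the central disc
#'   of B irradiated), `"confluent"` (a fully cell-filled rectangle) or
#'   `"colony"` (sparse random seeding, for growth studies).
#' @param dose_gy Target dose (Gy) delivered to the masked sites.
#' @param duration_h Simulated culture time (h).
#' @param dt Time step (s).
#' @param n_rows,n_cols Lattice dimensions including the wall ring;
#'   `NULL` picks the scenario default (`three_area`: 103 x 303).
#' @param d Grid spacing (m); default from the catalogue.
#' @param record_every_min Output cadence (simulated minutes).
#' @param catalogue Parameter catalogue, see [default_catalogue()].
#' @param n_trials Number of independent replicate runs.
#' @param master_seed Master seed; per-trial streams are derived from it.
#' @param scale Geometry scale factor for `three_area` (radii and lattice
#'   shrink proportionally; 1 = full geometry).
#' @param colony_radius Colony disc radius in sites (before scaling).
#' @param irr_radius Irradiated-disc radius in sites (before scaling).
#' @param density_A Cell density of the sparse colony (area A).
#' @param n_colony_cells Number of seeded cells for `"colony"`.
#' @param init_phase Initial clock state: `"uniform"` (random position in
#'   the cycle) or `"G0"`; `NULL` picks the scenario default.
#' @param init_M,init_G Initial signal concentration placed on every cell
#'   site (units); used by calibration scenarios.
#' @param mdp_enabled,gjp_enabled Pathway switches (disabling the GJP
#'   emulates gap-junction inhibition, e.g. lindane).
#' @param mask_mode Irradiation geometry: `"disc"` (central disc of area B
#'   or of the lattice), `"all"` (every cell) or `"none"`.
#' @param decay_mode Signal decay per step: `"per_second"` (fraction
#'   `beta * dt`; default) or `"literal"` (fraction `beta`).
#' @param repair_mode DSB repair probability per step: `"per_step"`
#'   (the catalogue value used directly each step; default) or
#'   `"per_second"` (value times `dt`).
#' @param background_mode Background DSB mean per step: `"per_step"`
#'   (default) or `"per_second"`.
#' @param inherit_mode DSB inheritance at division: `"binomial"`
#'   (half-split; default), `"copy"` or `"zero"`.
#' @param g0_reentry Whether a quiescent cell re-enters G1 when an
#'   adjacent medium site becomes available.
#' @param signal_scale Multiplier on both signal production constants.
#' @param check_stability Refuse configurations violating the diffusion
#'   stability bound.
#' @param record_snapshots Keep the final world state in the result.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(scenario = c("three_area", "confluent", "colony"),
                       dose_gy = 0, duration_h = 2, dt = NULL,
                       n_rows = NULL, n_cols = NULL, d = NULL,
                       record_every_min = 10,
                       catalogue = default_catalogue(),
                       n_trials = 1L, master_seed = 1L, scale = 1,
                       colony_radius = 40, irr_radius = 20,
                       density_A = 0.15, n_colony_cells = 30L,
                       init_phase = NULL, init_M = 0, init_G = 0,
                       mdp_enabled = TRUE, gjp_enabled = TRUE,
                       mask_mode = c("disc", "all", "none"),
                       decay_mode = c("per_second", "literal"),
                       repair_mode = c("per_step", "per_second"),
                       background_mode = c("per_step", "per_second"),
                       inherit_mode = c("binomial", "copy", "zero"),
                       g0_reentry = TRUE, signal_scale = 1,
                       check_stability = TRUE, record_snapshots = FALSE) {
  scenario <- match.arg(scenario)
  mask_mode <- match.arg(mask_mode)
  if (is.null(dt)) dt <- catalogue$time$dt_s
  if (is.null(d)) d <- catalogue$lattice$grid_spacing_m
  if (is.null(n_rows))
    n_rows <- switch(scenario,
                     three_area = 2L + round(101 * scale),
                     confluent = 102L, colony = 103L)
  if (is.null(n_cols))
    n_cols <- switch(scenario,
                     three_area = 2L + round(301 * scale),
                     confluent = 102L, colony = 103L)
  if (is.null(init_phase))
    init_phase <- switch(scenario, three_area = "mixed",
                         confluent = "G0", colony = "uniform")
  stopifnot(dt > 0, duration_h >= 0, dose_gy >= 0, n_trials >= 1)
  mdp <- pathway_params(catalogue$signal$mdp$w_m2_s,
                        catalogue$signal$mdp$alpha_unit_gy * signal_scale,
                        catalogue$signal$mdp$beta_s, TRUE)
  gjp <- pathway_params(catalogue$signal$gjp$w_m2_s,
                        catalogue$signal$gjp$alpha_unit_gy * signal_scale,
                        catalogue$signal$gjp$beta_s, FALSE)
  if (check_stability) {
    for (p in list(if (mdp_enabled) mdp, if (gjp_enabled) gjp)) {
      if (is.null(p)) next
      sc <- stability_check(p$w, dt, d)
      if (!sc$stable)
        stop(sprintf("%s diffusion unstable: 3*dt*w/d^2 = %.3g > 1",
                     p$name, sc$margin))
    }
  }
  structure(list(
    scenario = scenario, dose_gy = dose_gy, duration_h = duration_h,
    dt = dt, n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    d = d, record_every_min = record_every_min, catalogue = catalogue,
    n_trials = as.integer(n_trials), master_seed = master_seed,
    scale = scale, colony_radius = colony_radius, irr_radius = irr_radius,
    density_A = density_A, n_colony_cells = as.integer(n_colony_cells),
    init_phase = init_phase, init_M = init_M, init_G = init_G,
    mdp = mdp, gjp = gjp,
    mdp_enabled = mdp_enabled, gjp_enabled = gjp_enabled,
    mask_mode = mask_mode,
    decay_mode = match.arg(decay_mode),
    repair_mode = match.arg(repair_mode),
    background_mode = match.arg(background_mode),
    inherit_mode = match.arg(inherit_mode),
    g0_reentry = g0_reentry, signal_scale = signal_scale,
    record_snapshots = record_snapshots
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %s, %d x %d, dose %g Gy, %g h, dt %g s, %d trial(s)\n",
              x$scenario, x$n_rows, x$n_cols, x$dose_gy, x$duration_h,
              x$dt, x$n_trials))
  invisible(x)
}

# Precompile the catalogue's phase-group structure: for each per-cell
# field, the group name per phase code (index = code + 1) and the specs.
.compile_groups <- function(catalogue) {
  out <- lapply(.CELL_FIELDS, function(f) {
    gs <- vapply(names(PHASES), function(ph)
      catalogue$cell[[f]]$groups[[ph]], character(1L))
    list(group = unname(gs), values = catalogue$cell[[f]]$values)
  })
  names(out) <- .CELL_FIELDS
  out
}

# Allocate an empty world around a lattice.
.make_world <- function(lat, config) {
  N <- lat$n_rows * lat$n_cols
  na_n <- rep.int(NA_real_, N)
  w <- list(
    lat = lat, config = config,
    M = matrix(0, lat$n_rows, lat$n_cols),
    G = matrix(0, lat$n_rows, lat$n_cols),
    Z = numeric(N), cum_dose = numeric(N),
    phase = rep.int(NA_integer_, N), elapsed = na_n, dur = na_n,
    arrested = logical(N), state = rep.int(NA_integer_, N),
    div_left = na_n, birth_s = na_n, pid_deadline_s = na_n,
    zr_lambda = na_n, zm_lambda = na_n, zg_lambda = na_n,
    zb_lambda = na_n, repair_lambda = na_n,
    prd_threshold = na_n, pid_threshold = na_n,
    thr_g1s = na_n, thr_sg2 = na_n, thr_g2m1 = na_n, thr_m1m2 = na_n,
    time_s = 0, step = 0L, plan = NULL,
    pcache = .compile_groups(config$catalogue),
    baseline_g0 = integer(4L), n_removed = 0L,
    division_times = numeric(0), division_ages = numeric(0),
    division_births = numeric(0)
  )
  .refresh_cache(w)
}

# Recompute everything derived from site kinds (after divisions/deaths).
.refresh_cache <- function(world) {
  lat <- world$lat
  world$cell_idx <- which(lat$kind == KIND_CELL)
  world$kM <- .diffusion_kernel(lat, world$config$mdp)
  world$kG <- .diffusion_kernel(lat, world$config$gjp)
  world$nmed <- medium_neighbor_count(lat)
  world$mask_cell_idx <- which(lat$mask & lat$kind == KIND_CELL)
  world
}

# Initialise freshly created cells at `idx` in the given phase
# (vector or scalar), drawing every per-cell parameter anew.
.add_cells <- function(world, idx, phase, state = LIFE_STATES[["PR"]],
                       div_left = Inf, elapsed = 0) {
  if (!length(idx)) return(world)
  cat <- world$config$catalogue
  world$lat$kind[idx] <- KIND_CELL
  phase <- rep_len(as.integer(phase), length(idx))
  for (ph in unique(phase)) {
    sel <- idx[phase == ph]
    ps <- sample_cell_params(ph, cat, length(sel))
    for (f in names(ps)) world[[f]][sel] <- ps[[f]]
    world$dur[sel] <- sample_phase_period(ph, cat, length(sel))
  }
  world$phase[idx] <- phase
  world$elapsed[idx] <- rep_len(elapsed, length(idx))
  world$arrested[idx] <- FALSE
  world$state[idx] <- state
  world$div_left[idx] <- div_left
  world$birth_s[idx] <- world$time_s
  world$pid_deadline_s[idx] <- NA_real_
  world$Z[idx] <- 0
  world
}

# Move existing cells at `idx` into `new_phase`, re-drawing the
# phase-grouped parameters whose group changed and a fresh duration.
.enter_phase <- function(world, idx, new_phase, old_phase) {
  if (!length(idx)) return(world)
  cat <- world$config$catalogue
  new_phase <- rep_len(as.integer(new_phase), length(idx))
  old_phase <- rep_len(as.integer(old_phase), length(idx))
  for (np in unique(new_phase)) {
    sel <- new_phase == np
    ii <- idx[sel]
    for (f in .CELL_FIELDS) {
      g <- world$pcache[[f]]$group
      redraw <- ii[g[old_phase[sel] + 1L] != g[np + 1L]]
      if (length(redraw))
        world[[f]][redraw] <-
          sample_truncated_normal(length(redraw),
                                  world$pcache[[f]]$values[[g[np + 1L]]])
    }
    world$dur[ii] <- sample_phase_period(np, cat, length(ii))
  }
  world$phase[idx] <- new_phase
  world$elapsed[idx] <- 0
  world$arrested[idx] <- FALSE
  world
}

# Uniformly random position within the cycle: phase chosen with
# probability proportional to its mean period, elapsed uniform within the
# sampled duration.
.seed_uniform_phase <- function(world, idx) {
  cat <- world$config$catalogue
  means <- vapply(names(PHASES)[-1L],
                  function(ph) cat$period$values[[ph]]$av, numeric(1L))
  ph <- sample(PHASES[-1L], length(idx), replace = TRUE,
               prob = means / sum(means))
  world <- .add_cells(world, idx, ph)
  world$elapsed[idx] <- stats::runif(length(idx)) * world$dur[idx]
  world
}

.disc_sites <- function(lat, r0, c0, radius) {
  rows <- matrix(seq_len(lat$n_rows), lat$n_rows, lat$n_cols)
  cols <- matrix(seq_len(lat$n_cols), lat$n_rows, lat$n_cols, byrow = TRUE)
  which((rows - r0)^2 + (cols - c0)^2 <= radius^2 &
          lat$kind != KIND_WALL)
}

#' Build the three-area bystander world
#'
#' The canonical experiment layout: three disc colonies side by side in a
#' 103 x 303 lattice (area footprints of 101 x 101 sites). Area A is
#' seeded sparsely (15 % of its disc, random clock positions) so
#' cycle effects are visible; areas B and C are confluent discs of
#' quiescent (G0) cells. Only the central disc of area B is irradiated,
#' so area B bystanders receive both signals while areas A and C receive
#' the medium-mediated signal only.
#'
#' @param config A [sim_config()] with `scenario = "three_area"`.
#' @return A world list ready for [step_world()].
#' @export
build_three_area_world <- function(config) {
  lat <- build_lattice(config$n_rows, config$n_cols, config$d)
  R <- config$colony_radius * config$scale
  rad_irr <- config$irr_radius * config$scale
  r0 <- round((lat$n_rows + 1) / 2)
  cB <- round((lat$n_cols + 1) / 2)
  off <- round((lat$n_cols - 2) / 3)
  cA <- cB - off; cC <- cB + off
  if (cA - R < 2 || cC + R > lat$n_cols - 1 ||
      r0 - R < 2 || r0 + R > lat$n_rows - 1)
    stop("geometry too small for three colonies of this radius")
  b1 <- cB - off / 2; b2 <- cB + off / 2
  cols <- matrix(seq_len(lat$n_cols), lat$n_rows, lat$n_cols, byrow = TRUE)
  lat$region <- matrix(1L + (cols > b1) + (cols > b2),
                       lat$n_rows, lat$n_cols)
  world <- .make_world(lat, config)

  discA <- .disc_sites(lat, r0, cA, R)
  discB <- .disc_sites(lat, r0, cB, R)
  discC <- .disc_sites(lat, r0, cC, R)
  seedA <- sample(discA, round(config$density_A * length(discA)))
  world <- .seed_uniform_phase(world, seedA)
  world <- .add_cells(world, discB, PHASES[["G0"]])
  world <- .add_cells(world, discC, PHASES[["G0"]])

  if (config$mask_mode == "disc" && config$dose_gy > 0) {
    m <- .disc_sites(world$lat, r0, cB, rad_irr)
    world$lat$mask[m[world$lat$kind[m] == KIND_CELL]] <- TRUE
  }
  .finish_world(world)
}

#' Build a confluent rectangular world
#'
#' Every interior site is a cell (a dish at 100 % confluence); used by
#' the calibration harnesses, with all clocks in G0 by default.
#'
#' @param config A [sim_config()] with `scenario = "confluent"`.
#' @return A world list.
#' @export
build_confluent_world <- function(config) {
  lat <- build_lattice(config$n_rows, config$n_cols, config$d)
  world <- .make_world(lat, config)
  interior <- which(lat$kind == KIND_MEDIUM)
  world <- if (identical(config$init_phase, "uniform"))
    .seed_uniform_phase(world, interior)
  else .add_cells(world, interior, PHASES[["G0"]])
  if (config$dose_gy > 0) {
    if (config$mask_mode == "all") {
      world$lat$mask[world$lat$kind == KIND_CELL] <- TRUE
    } else if (config$mask_mode == "disc") {
      r0 <- round((lat$n_rows + 1) / 2); c0 <- round((lat$n_cols + 1) / 2)
      m <- .disc_sites(world$lat, r0, c0, config$irr_radius)
      world$lat$mask[m[world$lat$kind[m] == KIND_CELL]] <- TRUE
    }
  }
  .finish_world(world)
}

#' Build a sparse colony world
#'
#' Seeds `n_colony_cells` cells at random interior sites with uniformly
#' random clock positions; the unperturbed-growth scenario.
#'
#' @param config A [sim_config()] with `scenario = "colony"`.
#' @return A world list.
#' @export
build_colony_world <- function(config) {
  lat <- build_lattice(config$n_rows, config$n_cols, config$d)
  world <- .make_world(lat, config)
  interior <- which(lat$kind == KIND_MEDIUM)
  idx <- sample(interior, min(config$n_colony_cells, length(interior)))
  world <- if (identical(config$init_phase, "G0"))
    .add_cells(world, idx, PHASES[["G0"]])
  else .seed_uniform_phase(world, idx)
  if (config$dose_gy > 0 && config$mask_mode != "none")
    world$lat$mask[world$lat$kind == KIND_CELL] <- TRUE
  .finish_world(world)
}

# Common world finalisation: initial signals, irradiation plan, caches,
# initial-count baselines.
.finish_world <- function(world) {
  cfg <- world$config
  cells <- world$lat$kind == KIND_CELL
  if (cfg$init_M > 0) world$M[cells] <- cfg$init_M
  if (cfg$init_G > 0) world$G[cells] <- cfg$init_G
  if (cfg$dose_gy > 0 && any(world$lat$mask))
    world$plan <- irradiation_plan(cfg$dose_gy,
                                   cfg$catalogue$irradiation$d1track_gy,
                                   cfg$catalogue$irradiation$tracks_per_min,
                                   world$lat$mask)
  world <- .refresh_cache(world)
  g0 <- !is.na(world$phase) & world$phase == PHASES[["G0"]]
  for (r in 0:3)
    world$baseline_g0[r + 1L] <- sum(g0 & world$lat$region == r)
  world
}

#' Build the world for a configuration
#'
#' Dispatches to the scenario-specific builder.
#'
#' @param config A [sim_config()].
#' @return A world list.
#' @export
build_world <- function(config) {
  switch(config$scenario,
         three_area = build_three_area_world(config),
         confluent = build_confluent_world(config),
         colony = build_colony_world(config))
}
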