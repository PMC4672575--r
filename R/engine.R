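# The synchronous time loop. Fixed order within a step: sample dose ->
# update both signal fields (from the fields at t) -> DSB induction and
# repair (repair thins the previous step's DSBs) -> death transitions ->
# checkpoint/arrest and clock advance -> divisions and removals (lattice
# edits take effect next step, since all caches are rebuilt at the end).

#' Advance the world by one time step
#'
#' @param world A world list from [build_world()].
#' @return The updated world.
#' @export
step_world <- function(world) {
  cfg <- world$config
  dt <- cfg$dt
  lat <- world$lat
  ci <- world$cell_idx
  dirty <- FALSE

  ## 1. irradiation -------------------------------------------------------
  dose <- NULL
  if (!is.null(world$plan)) {
    dose <- sample_step_dose(world$plan, world$time_s, dt)
    if (!is.null(dose)) {
      dose[lat$kind != KIND_CELL] <- 0   # masked sites whose cell has died
      world$cum_dose <- world$cum_dose + as.numeric(dose)
    }
  }

  ## 2. signal fields (synchronous, both from the fields at t) -----------
  if (cfg$mdp_enabled)
    world$M <- diffusion_step(world$M, lat, cfg$mdp, dt, dose,
                              cfg$decay_mode, world$kM)
  if (cfg$gjp_enabled)
    world$G <- diffusion_step(world$G, lat, cfg$gjp, dt, dose,
                              cfg$decay_mode, world$kG)

  if (length(ci)) {
    ## 3. DSB induction and repair ----------------------------------------
    # The four Poisson sources are independent, so one draw from the summed
    # mean is distributionally identical to four separate draws.
    mean_tot <- if (cfg$background_mode == "per_step")
      world$zb_lambda[ci] else world$zb_lambda[ci] * dt
    if (cfg$mdp_enabled)
      mean_tot <- mean_tot + world$zm_lambda[ci] * world$M[ci] * dt
    if (cfg$gjp_enabled)
      mean_tot <- mean_tot + world$zg_lambda[ci] * world$G[ci] * dt
    if (!is.null(dose))
      mean_tot <- mean_tot + world$zr_lambda[ci] * dose[ci]
    Zc <- world$Z[ci]
    p_rep <- if (cfg$repair_mode == "per_step")
      world$repair_lambda[ci] else world$repair_lambda[ci] * dt
    repaired <- stats::rbinom(length(ci), Zc, pmin(p_rep, 1))
    Zc <- Zc + stats::rpois(length(ci), mean_tot) - repaired
    world$Z[ci] <- Zc

    ## 4. death transitions (out of PR only, irreversible) ----------------
    st <- world$state[ci]
    pr <- st == LIFE_STATES[["PR"]]
    if (any(pr)) {
      cls <- integer(length(ci))
      cls[pr] <- classify_death(Zc[pr], world$prd_threshold[ci[pr]],
                                world$pid_threshold[ci[pr]])
      to_prd <- ci[cls == 1L]
      if (length(to_prd)) {
        world$state[to_prd] <- LIFE_STATES[["pRD"]]
        world$div_left[to_prd] <- sample_divisions_remaining(length(to_prd))
        st[cls == 1L] <- LIFE_STATES[["pRD"]]
      }
      to_pid <- ci[cls == 2L]
      if (length(to_pid)) {
        world$state[to_pid] <- LIFE_STATES[["pID"]]
        # removal deadline: one nominal cycle of this cell from now
        tot <- numeric(length(to_pid))
        for (ph in names(PHASES)[-1L])
          tot <- tot + sample_phase_period(ph, cfg$catalogue, length(to_pid))
        world$pid_deadline_s[to_pid] <- world$time_s + 3600 * tot
        st[cls == 2L] <- LIFE_STATES[["pID"]]
      }
    }

    ## 5. checkpoints, arrest, clock advance ------------------------------
    ph <- world$phase[ci]
    cycling <- st != LIFE_STATES[["RD"]] & ph != PHASES[["G0"]]
    el <- world$elapsed[ci]; du <- world$dur[ci]
    parked <- cycling & el >= du
    at_cp <- which(parked & ph <= PHASES[["M1"]])
    if (length(at_cp)) {
      thr <- .arrest_threshold_at(world, ci[at_cp], ph[at_cp])
      arr <- checkpoint_decision(Zc[at_cp], thr)
      world$arrested[ci[at_cp]] <- arr
      rel <- at_cp[!arr]
      if (length(rel))
        world <- .enter_phase(world, ci[rel], ph[rel] + 1L, ph[rel])
    }
    active <- which(cycling & el < du)
    if (length(active))
      world$elapsed[ci[active]] <-
        pmin(el[active] + dt / 3600, du[active])

    ## 6. divisions and interphase removals -------------------------------
    at_div <- parked & ph == PHASES[["M2"]]
    dividers <- ci[at_div & (st == LIFE_STATES[["PR"]] |
                               st == LIFE_STATES[["pRD"]])]
    removals <- ci[(at_div & st == LIFE_STATES[["pID"]]) |
                     (st == LIFE_STATES[["pID"]] &
                        !is.na(world$pid_deadline_s[ci]) &
                        world$time_s >= world$pid_deadline_s[ci])]
    if (length(dividers)) {
      world <- .do_divisions(world, dividers)
      dirty <- TRUE
    }
    if (length(removals)) {
      world <- .do_removals(world, setdiff(removals, dividers))
      dirty <- TRUE
    }

    ## 7. quiescence release (uses pre-edit adjacency) ---------------------
    if (cfg$g0_reentry) {
      g0 <- ci[!is.na(world$phase[ci]) &
                 world$phase[ci] == PHASES[["G0"]] &
                 (world$state[ci] == LIFE_STATES[["PR"]] |
                    world$state[ci] == LIFE_STATES[["pRD"]]) &
                 world$nmed[ci] > 0L]
      if (length(g0))
        world <- .enter_phase(world, g0, PHASES[["G1"]], PHASES[["G0"]])
    }
  }

  if (dirty) world <- .refresh_cache(world)
  world$time_s <- world$time_s + dt
  world$step <- world$step + 1L
  world
}

# Division of every cell in `idx` (all parked at the division point).
# One adjacent medium site, chosen uniformly, becomes a daughter; with no
# such site the parent enters G0 instead. Both daughters restart in G1
# with fresh parameters; DSBs are inherited per the configured mode and
# the gap-junctional signal is split in half.
.do_divisions <- function(world, idx) {
  cfg <- world$config
  for (s in idx) {
    nbrs <- s + .neighbor_offsets(world$lat$n_rows)
    med <- nbrs[world$lat$kind[nbrs] == KIND_MEDIUM]
    if (!length(med)) {
      world <- .enter_phase(world, s, PHASES[["G0"]], PHASES[["M2"]])
      world$dur[s] <- Inf
      next
    }
    dsite <- med[sample.int(length(med), 1L)]
    age_h <- (world$time_s - world$birth_s[s]) / 3600
    world$division_times <- c(world$division_times, world$time_s)
    world$division_ages <- c(world$division_ages, age_h)
    world$division_births <- c(world$division_births, world$birth_s[s])
    Zp <- world$Z[s]
    Zd <- switch(cfg$inherit_mode,
                 binomial = stats::rbinom(1L, Zp, 0.5),
                 copy = Zp, zero = 0)
    st <- world$state[s]
    dl <- Inf; newstate <- LIFE_STATES[["PR"]]
    if (st == LIFE_STATES[["pRD"]]) {
      dl <- world$div_left[s] - 1
      newstate <- if (dl <= 0) LIFE_STATES[["RD"]] else LIFE_STATES[["pRD"]]
    }
    pair <- c(s, dsite)
    world <- .add_cells(world, pair, PHASES[["G1"]], newstate, dl)
    world$Z[s] <- if (cfg$inherit_mode == "copy") Zp else Zp - Zd
    world$Z[dsite] <- Zd
    world$G[dsite] <- world$G[s] / 2
    world$G[s] <- world$G[s] / 2
    if (newstate == LIFE_STATES[["RD"]]) world$dur[pair] <- Inf
  }
  world
}

# Interphase death: the site reverts to medium; its gap-junctional signal
# is discarded, the medium-mediated signal at the site stays.
.do_removals <- function(world, idx) {
  if (!length(idx)) return(world)
  world$lat$kind[idx] <- KIND_MEDIUM
  world$lat$mask[idx] <- FALSE
  world$G[idx] <- 0
  world$Z[idx] <- 0
  for (f in c("phase", "state")) world[[f]][idx] <- NA_integer_
  for (f in c("elapsed", "dur", "div_left", "birth_s", "pid_deadline_s"))
    world[[f]][idx] <- NA_real_
  world$arrested[idx] <- FALSE
  world$n_removed <- world$n_removed + length(idx)
  world
}

#' Count cell states per region
#'
#' One row per region with phase counts, arrest-mode counts (G1 arrest =
#' halted at the G1/S checkpoint, S at S/G2, G2 at G2/M1, M at M1/M2),
#' life-state counts, mean DSB burdens, and region signal totals. Also
#' reports the adjusted counts used to compare regions: the number of
#' irradiated (masked) cells, and the G0 count minus the region's initial
#' G0 population.
#'
#' @param world A world list.
#' @return A data frame, one row per region present on the lattice.
#' @export
count_states <- function(world) {
  lat <- world$lat
  regs <- sort(unique(as.integer(lat$region)))
  reg_names <- c("all", "A", "B", "C")
  rows <- lapply(regs, function(r) {
    in_reg <- lat$region == r
    ci <- which(in_reg & lat$kind == KIND_CELL)
    ph <- world$phase[ci]
    st <- world$state[ci]
    masked <- lat$mask[ci]
    arr <- world$arrested[ci]
    g1 <- ph == PHASES[["G1"]]
    byst <- g1 & !masked
    Z <- world$Z[ci]
    phc <- tabulate(ph + 1L, 6L)
    stc <- tabulate(st, 4L)
    arrc <- tabulate(ph[arr], 4L)   # arrested cells sit parked in phase 1..4
    data.frame(
      region = reg_names[r + 1L], n_cells = length(ci),
      n_G0 = phc[1L], n_G1 = phc[2L], n_S = phc[3L], n_G2 = phc[4L],
      n_M1 = phc[5L], n_M2 = phc[6L],
      n_arr_G1 = arrc[1L], n_arr_S = arrc[2L], n_arr_G2 = arrc[3L],
      n_arr_M = arrc[4L],
      n_PR = stc[1L], n_pRD = stc[2L], n_RD = stc[3L], n_pID = stc[4L],
      n_masked = sum(masked),
      mean_Z = if (length(ci)) mean(Z) else NA_real_,
      mean_Z_G1 = if (any(g1)) mean(Z[g1]) else NA_real_,
      mean_Z_G1_byst = if (any(byst)) mean(Z[byst]) else NA_real_,
      frac_Z_pos = if (length(ci)) mean(Z > 0) else NA_real_,
      total_M = sum(world$M[in_reg]), total_G = sum(world$G[in_reg]),
      n_G0_adj = phc[1L] - world$baseline_g0[r + 1L],
      mean_dose = if (any(masked)) mean(world$cum_dose[ci[masked]]) else 0,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$time_h <- world$time_s / 3600
  out[, c("time_h", setdiff(names(out), "time_h"))]
}

#' Run the bystander-effect simulation
#'
#' Executes `n_trials` independent replicates of the configured scenario,
#' each with its own derived random stream and its own random initial
#' placement, recording region-level state counts at the configured
#' cadence.
#'
#' @param config A [sim_config()].
#' @param progress Print a line per trial.
#' @return Object of class `bystander_sim`: a list with `records` (long
#'   data frame over trials, times and regions), `divisions` (per-trial
#'   intermitotic intervals), `config`, and the final world of the last
#'   trial when `record_snapshots` is set.
#' @examples
#' cfg <- sim_config("colony", n_rows = 20, n_cols = 20,
#'                   n_colony_cells = 4, duration_h = 0.01,
#'                   gjp_enabled = FALSE, mdp_enabled = FALSE)
#' sim <- run_simulation(cfg)
#' summary(sim)
#' @export
run_simulation <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  n_steps <- ceiling(config$duration_h * 3600 / config$dt)
  stride <- max(1L, round(config$record_every_min * 60 / config$dt))
  recs <- vector("list", config$n_trials)
  divs <- vector("list", config$n_trials)
  final_world <- NULL
  for (trial in seq_len(config$n_trials)) {
    set.seed(derive_seed(config$master_seed, trial, "trial"))
    world <- build_world(config)
    rows <- list(count_states(world))
    if (n_steps > 0) for (k in seq_len(n_steps)) {
      world <- step_world(world)
      if (k %% stride == 0L || k == n_steps)
        rows[[length(rows) + 1L]] <- count_states(world)
    }
    rec <- do.call(rbind, rows)
    rec$trial <- trial
    recs[[trial]] <- rec
    divs[[trial]] <- if (length(world$division_ages))
      data.frame(trial = trial, time_h = world$division_times / 3600,
                 intermitotic_h = world$division_ages)
    else NULL
    if (progress)
      message(sprintf("trial %d/%d done (%d cells)",
                      trial, config$n_trials, length(world$cell_idx)))
    final_world <- world
  }
  structure(list(
    records = do.call(rbind, recs),
    divisions = do.call(rbind, divs),
    config = config,
    world = if (config$record_snapshots) final_world else NULL
  ), class = "bystander_sim")
}

#' @export
print.bystander_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<bystander_sim> %s scenario, %g Gy, %g h, %d trial(s)\n",
              cfg$scenario, cfg$dose_gy, cfg$duration_h, cfg$n_trials))
  fin <- x$records[x$records$time_h == max(x$records$time_h), ]
  agg <- stats::aggregate(n_cells ~ region, fin, mean)
  cat("  final mean cell counts:",
      paste(sprintf("%s=%g", agg$region, round(agg$n_cells, 1)),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.bystander_sim <- function(object, ...) {
  r <- object$records
  peaks <- do.call(rbind, lapply(split(r, r$region), function(d) {
    m <- stats::aggregate(cbind(mean_Z_G1_byst, n_cells) ~ time_h, d,
                          mean, na.action = stats::na.pass)
    i <- which.max(m$mean_Z_G1_byst)
    data.frame(region = d$region[1L],
               peak_Z_G1_byst = if (length(i)) m$mean_Z_G1_byst[i]
                                else NA_real_,
               peak_time_h = if (length(i)) m$time_h[i] else NA_real_,
               final_cells = m$n_cells[nrow(m)])
  }))
  rownames(peaks) <- NULL
  structure(list(peaks = peaks, config = object$config),
            class = "summary.bystander_sim")
}

#' @export
print.summary.bystander_sim <- function(x, ...) {
  cat("Bystander DSB summary (mean over trials)\n")
  print(x$peaks, row.names = FALSE)
  invisible(x)
}

#' Plot a recorded metric over time
#'
#' @param x A `bystander_sim`.
#' @param metric Column of the records to plot.
#' @param regions Regions to include (default all).
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, the wide matrix plotted.
#' @export
plot.bystander_sim <- function(x, metric = "n_cells", regions = NULL, ...) {
  r <- x$records
  if (!metric %in% names(r)) stop("unknown metric: ", metric)
  if (is.null(regions)) regions <- unique(r$region)
  r <- r[r$region %in% regions, ]
  agg <- stats::aggregate(r[[metric]],
                          list(time_h = r$time_h, region = r$region),
                          mean, na.rm = TRUE)
  wide <- stats::reshape(agg, idvar = "time_h", timevar = "region",
                         direction = "wide")
  wide <- wide[order(wide$time_h), ]
  graphics::matplot(wide$time_h, wide[, -1L, drop = FALSE], type = "l",
                    lty = 1, xlab = "time (h)", ylab = metric, ...)
  graphics::legend("topleft", legend = sub("^x\\.", "", names(wide)[-1L]),
                   col = seq_len(ncol(wide) - 1L), lty = 1, bty = "n")
  invisible(wide)
}

#' Write simulation records as long-format CSV
#'
#' @param sim A `bystander_sim`.
#' @param file Output path.
#' @return Invisibly, the long data frame written
#'   (`trial, time_h, region, metric, value`).
#' @export
write_records <- function(sim, file) {
  r <- sim$records
  idv <- c("trial", "time_h", "region")
  metrics <- setdiff(names(r), idv)
  long <- do.call(rbind, lapply(metrics, function(m)
    data.frame(r[idv], metric = m, value = r[[m]])))
  utils::write.csv(long, file, row.names = FALSE)
  invisible(long)
}
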