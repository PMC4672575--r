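# Controlled single-cell and few-cell worlds; signalling is disabled so a
# coarse time step can be used (the clock operates on hours).
quiet_cfg <- function(duration_h = 0, ...) {
  sim_config("colony", n_rows = 9, n_cols = 9, n_colony_cells = 0,
             dt = 360, duration_h = duration_h,
             catalogue = degenerate_catalogue(),
             mdp_enabled = FALSE, gjp_enabled = FALSE, ...)
}

test_that("pure decision helpers follow the thresholds", {
  expect_equal(classify_death(c(10, 100, 200), rep(93, 3), rep(186, 3)),
               c(0L, 1L, 2L))
  expect_false(checkpoint_decision(0, 20))
  expect_true(checkpoint_decision(25, 20))    # at G2/M1 with threshold 20
  expect_true(checkpoint_decision(20, 20))    # a tie counts as arrest
  expect_false(checkpoint_decision(12, 20))   # repair releases the clock
  set.seed(31)
  d <- sample_divisions_remaining(6e4)
  expect_true(all(d %in% 1:3))
  for (k in 1:3)
    expect_lt(abs(mean(d == k) - 1 / 3), 3 * sqrt(2 / 9 / 6e4))
  el <- advance_clock(c(1, 2, 10.9), c(11, 11, 11), c(TRUE, FALSE, TRUE), 0.2)
  expect_equal(el, c(1.2, 2, 11))   # frozen when inactive; clips at duration
})

test_that("an undamaged cell traverses the cycle on schedule and divides", {
  cfg <- quiet_cfg(duration_h = 26)
  w <- build_world(cfg)
  w <- bystandr:::.add_cells(w, 41L, 1L)  # G1 cell, centre of 9x9
  w <- bystandr:::.refresh_cache(w)
  phase_at <- function(w) w$phase[41L]
  hits <- c(G1 = NA, S = NA, G2 = NA, M1 = NA, M2 = NA)
  for (k in 1:260) {   # 26 h at 0.1 h steps
    w <- step_world(w)
    ph <- names(PHASES)[match(phase_at(w), PHASES)]
    if (!is.na(ph) && ph %in% names(hits) && is.na(hits[ph]))
      hits[ph] <- w$time_s / 3600
  }
  # degenerate periods: G1 11 h, S 8 h, G2 4 h, M 0.5 + 0.5 h
  expect_equal(unname(hits["S"]), 11.1, tolerance = 0.05)
  expect_equal(unname(hits["G2"]), 19.2, tolerance = 0.05)
  expect_equal(unname(hits["M1"]), 23.3, tolerance = 0.05)
  expect_equal(length(w$cell_idx), 2L)          # divided
  expect_true(all(w$phase[w$cell_idx] == PHASES[["G1"]]))
  expect_gt(w$division_ages[1], 23.9)
  expect_lt(w$division_ages[1], 25)
})

test_that("checkpoint arrest halts the clock and repair releases it", {
  cfg <- quiet_cfg(duration_h = 0)
  w <- build_world(cfg)
  w <- bystandr:::.add_cells(w, 41L, PHASES[["G2"]])
  w <- bystandr:::.refresh_cache(w)
  w$elapsed[41L] <- w$dur[41L]     # parked at G2/M1
  w$Z[41L] <- 25                   # above the G2/M1 threshold of 20
  w$repair_lambda[41L] <- 0        # hold the damage fixed
  w$zb_lambda[41L] <- 0
  for (k in 1:5) w <- step_world(w)
  expect_true(w$arrested[41L])
  expect_equal(w$phase[41L], PHASES[["G2"]])
  w$Z[41L] <- 12                   # below threshold: release
  w <- step_world(w)
  expect_false(w$arrested[41L])
  expect_equal(w$phase[41L], PHASES[["M1"]])
  expect_equal(w$elapsed[41L], 0)
})

test_that("death transitions are threshold-ordered and irreversible", {
  cfg <- quiet_cfg()
  w <- build_world(cfg)
  w <- bystandr:::.add_cells(w, c(31L, 41L, 51L), 1L)
  w <- bystandr:::.refresh_cache(w)
  w$zb_lambda[c(31L, 41L, 51L)] <- 0
  w$Z[31L] <- 10; w$Z[41L] <- 100; w$Z[51L] <- 200
  w <- step_world(w)
  expect_equal(w$state[31L], LIFE_STATES[["PR"]])
  expect_equal(w$state[41L], LIFE_STATES[["pRD"]])   # 93 < 100 < 186
  expect_true(w$div_left[41L] %in% 1:3)
  expect_equal(w$state[51L], LIFE_STATES[["pID"]])
  # repair back to zero must not revert the states
  w$Z[c(41L, 51L)] <- 0
  w <- step_world(w)
  expect_equal(w$state[41L], LIFE_STATES[["pRD"]])
  expect_equal(w$state[51L], LIFE_STATES[["pID"]])
})

test_that("division splits DSBs, halves the junctional signal and counts down", {
  set.seed(33)
  cfg <- quiet_cfg()
  w <- build_world(cfg)
  w <- bystandr:::.add_cells(w, 41L, PHASES[["M2"]])
  w <- bystandr:::.refresh_cache(w)
  w$elapsed[41L] <- w$dur[41L]
  w$Z[41L] <- 10; w$zb_lambda[41L] <- 0
  w$G[41L] <- 0.8
  w$state[41L] <- LIFE_STATES[["pRD"]]; w$div_left[41L] <- 1
  w <- step_world(w)
  ci <- w$cell_idx
  expect_equal(length(ci), 2L)
  expect_equal(sum(w$Z[ci]), 10)              # binomial half-split conserves
  expect_equal(sum(w$G[ci]), 0.8)             # cytoplasm partition
  expect_true(all(w$state[ci] == LIFE_STATES[["RD"]]))  # last division
  # reproductively dead clocks never move again
  el <- w$elapsed[ci]
  for (k in 1:10) w <- step_world(w)
  expect_equal(w$elapsed[w$cell_idx], el)
})

test_that("a fully surrounded cell enters G0 and re-enters when space opens", {
  cfg <- sim_config("confluent", n_rows = 5, n_cols = 5, dt = 360,
                    duration_h = 0, catalogue = degenerate_catalogue(),
                    mdp_enabled = FALSE, gjp_enabled = FALSE)
  w <- build_confluent_world(cfg)     # 3x3 block of cells, all G0
  centre <- 13L                       # (3,3) in a 5x5 lattice
  w <- bystandr:::.enter_phase(w, centre, PHASES[["M2"]], PHASES[["G0"]])
  w$elapsed[centre] <- w$dur[centre]
  w <- step_world(w)
  expect_equal(w$phase[centre], PHASES[["G0"]])   # nowhere to put a daughter
  # open a site next to it: the quiescent cell re-enters G1
  w <- bystandr:::.do_removals(w, 12L)
  w <- bystandr:::.refresh_cache(w)
  w <- step_world(w)
  expect_equal(w$phase[centre], PHASES[["G1"]])
  expect_equal(w$lat$kind[12L], 1L)
  # with re-entry disabled the cell stays quiescent
  cfg2 <- quiet_cfg(g0_reentry = FALSE)
  w2 <- build_world(cfg2)
  w2 <- bystandr:::.add_cells(w2, 41L, PHASES[["G0"]])
  w2 <- bystandr:::.refresh_cache(w2)
  for (k in 1:5) w2 <- step_world(w2)
  expect_equal(w2$phase[41L], PHASES[["G0"]])
})

test_that("pre-interphase-death cells vanish within one division", {
  cfg <- quiet_cfg()
  w <- build_world(cfg)
  w <- bystandr:::.add_cells(w, 41L, PHASES[["M2"]])
  w <- bystandr:::.refresh_cache(w)
  w$elapsed[41L] <- w$dur[41L]
  w$state[41L] <- LIFE_STATES[["pID"]]
  w$pid_deadline_s[41L] <- Inf
  w <- step_world(w)                 # reaches the division point: removed
  expect_equal(length(w$cell_idx), 0L)
  expect_equal(w$lat$kind[41L], 1L)  # the site is medium again
  expect_equal(w$n_removed, 1L)
  # an arrested pID cell is removed when its nominal cycle runs out
  w2 <- build_world(cfg)
  w2 <- bystandr:::.add_cells(w2, 41L, PHASES[["G0"]])
  w2 <- bystandr:::.refresh_cache(w2)
  w2$state[41L] <- LIFE_STATES[["pID"]]
  w2$pid_deadline_s[41L] <- 2 * 360
  w2 <- step_world(w2); expect_equal(length(w2$cell_idx), 1L)
  w2 <- step_world(w2); w2 <- step_world(w2)
  expect_equal(length(w2$cell_idx), 0L)
})

test_that("life states never move backwards over a full irradiated run", {
  cfg <- sim_config("colony", n_rows = 21, n_cols = 21,
                    n_colony_cells = 60, dose_gy = 5, mask_mode = "all",
                    dt = 60, duration_h = 30,
                    mdp_enabled = FALSE, gjp_enabled = FALSE,
                    master_seed = 9)
  set.seed(derive_seed(9, 1, "trial"))
  w <- build_world(cfg)
  prev <- w$state
  bad <- 0L
  for (k in 1:1800) {
    w <- step_world(w)
    s <- w$state
    both <- !is.na(prev) & !is.na(s)
    # allowed: PR->PR/pRD/pID, pRD->pRD/RD, RD->RD, pID->pID (or removal)
    bad <- bad + sum(both & prev == 2L & !(s %in% c(2L, 3L)) |
                       both & prev == 3L & s != 3L |
                       both & prev == 4L & s != 4L |
                       both & prev == 1L & s == 3L)
    # removal is the only exit for pID; RD and pRD sites never vanish by death
    bad <- bad + sum(!is.na(prev) & is.na(s) & prev %in% c(2L, 3L) &
                       w$lat$kind[seq_along(s)] == 1L)
    prev <- s
  }
  expect_equal(bad, 0L)
  # divisions consumed exactly the vanished medium sites
  interior <- 19L * 19L
  expect_equal(length(w$cell_idx) + sum(w$lat$kind == 1L), interior)
  expect_equal(length(w$cell_idx),
               60L + length(w$division_times) - w$n_removed)
})
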