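test_that("an empty world is a fixed point of the step", {
  cfg <- sim_config("colony", n_rows = 9, n_cols = 9, n_colony_cells = 0,
                    duration_h = 0)
  w <- build_world(cfg)
  w2 <- step_world(w)
  expect_equal(w2$lat$kind, w$lat$kind)
  expect_equal(w2$M, w$M)
  expect_equal(sum(w2$Z), 0)
})

test_that("the three-area world matches its blueprint", {
  cfg <- sim_config("three_area", dose_gy = 5, duration_h = 0)
  set.seed(1)
  w <- build_three_area_world(cfg)
  lat <- w$lat
  # disc site count by enumeration, 15 % seeded in area A
  disc <- sum(outer(1:103, 1:303, function(i, j)
    (i - 52)^2 + (j - 52)^2 <= 40^2))
  nA <- sum(lat$kind == 2L & lat$region == 1L)
  expect_equal(nA, round(0.15 * disc))
  # areas B and C are identical confluent discs of quiescent cells
  nB <- sum(lat$kind == 2L & lat$region == 2L)
  nC <- sum(lat$kind == 2L & lat$region == 3L)
  expect_equal(nB, disc)
  expect_equal(nB, nC)
  expect_true(all(w$phase[which(lat$region == 3L & lat$kind == 2L)] ==
                    PHASES[["G0"]]))
  # the irradiation mask is a cell-only disc inside area B
  expect_true(all(lat$region[lat$mask] == 2L))
  expect_true(all(lat$kind[lat$mask] == 2L))
  expect_gt(sum(lat$mask), 0)
  expect_error(build_three_area_world(
    sim_config("three_area", scale = 0.2, colony_radius = 80,
               duration_h = 0)), "too small")
})

test_that("state counts are consistent and respect the exclusions", {
  cfg <- sim_config("three_area", dose_gy = 1, duration_h = 0)
  set.seed(2)
  w <- build_three_area_world(cfg)
  cs <- count_states(w)
  expect_equal(cs$region, c("A", "B", "C"))
  phases <- cs$n_G0 + cs$n_G1 + cs$n_S + cs$n_G2 + cs$n_M1 + cs$n_M2
  expect_equal(phases, cs$n_cells)
  states <- cs$n_PR + cs$n_pRD + cs$n_RD + cs$n_pID
  expect_equal(states, cs$n_cells)
  b <- cs[cs$region == "B", ]
  expect_equal(b$n_masked, sum(w$lat$mask))
  expect_equal(b$n_G0_adj, 0)               # at t = 0 nothing has moved yet
  expect_equal(cs[cs$region == "C", "n_G0"], cs[cs$region == "C", "n_cells"])
})

test_that("runs are reproducible under a fixed seed and scale with trials", {
  cfg <- sim_config("three_area", scale = 0.25, dose_gy = 0.5,
                    duration_h = 0.3, dt = 0.25, record_every_min = 6,
                    n_trials = 2, master_seed = 11)
  a <- run_simulation(cfg)
  b <- run_simulation(cfg)
  expect_identical(a$records, b$records)
  expect_equal(sort(unique(a$records$trial)), 1:2)
  # trials differ from each other (independent placement and streams)
  r1 <- a$records[a$records$trial == 1 & a$records$region == "A", "n_cells"]
  r2 <- a$records[a$records$trial == 2 & a$records$region == "A", "n_cells"]
  expect_false(identical(r1, r2))
})

test_that("duration zero yields the initial record only", {
  cfg <- sim_config("three_area", scale = 0.25, duration_h = 0)
  sim <- run_simulation(cfg)
  expect_equal(unique(sim$records$time_h), 0)
  expect_s3_class(summary(sim), "summary.bystander_sim")
})

test_that("the junctional signal never appears on medium sites", {
  cfg <- sim_config("three_area", scale = 0.25, dose_gy = 2,
                    duration_h = 0.25, dt = 0.25,
                    record_snapshots = TRUE, master_seed = 3)
  sim <- run_simulation(cfg)
  w <- sim$world
  expect_true(all(w$G[w$lat$kind != 2L] == 0))
  expect_true(all(w$G >= 0))
  expect_true(all(w$M >= 0))
  expect_true(all(w$M[w$lat$kind == 0L] == 0))
  expect_true(all(w$Z >= 0))
  expect_equal(w$Z, round(w$Z))   # integer-valued ledger
})

test_that("records can be exported as long CSV and plotted", {
  cfg <- sim_config("colony", n_rows = 15, n_cols = 15,
                    n_colony_cells = 10, duration_h = 2, dt = 120,
                    mdp_enabled = FALSE, gjp_enabled = FALSE)
  sim <- run_simulation(cfg)
  f <- tempfile(fileext = ".csv")
  long <- write_records(sim, f)
  expect_true(file.exists(f))
  expect_true(all(c("trial", "time_h", "region", "metric", "value")
                  %in% names(long)))
  pdf(NULL)
  expect_silent(plot(sim, metric = "n_cells"))
  dev.off()
})
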