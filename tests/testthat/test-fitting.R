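test_that("repair-only harness follows the geometric decay law", {
  cat0 <- degenerate_catalogue()
  # no repair: flat at the initial burden
  flat <- harness_dsb_decay(zero_fields(cat0, "repair_lambda"),
                            n_cells = 200, duration_h = 6)
  expect_true(all(flat$mean_Z == 35))
  # degenerate repair probability: closed form 35 (1 - lambda)^(t/dt)
  set.seed(41)
  out <- harness_dsb_decay(cat0, phase = "G1", n_cells = 1e4,
                           duration_h = 24, record_every_min = 360)
  lam <- 9.33e-7
  for (k in seq_len(nrow(out))) {
    n <- out$time_h[k] * 36000
    exp_mean <- 35 * (1 - lam)^n
    se <- sqrt(35 * (1 - lam)^n * (1 - (1 - lam)^n) / 1e4)
    expect_lt(abs(out$mean_Z[k] - exp_mean), 3 * se + 1e-12)
  }
  # the G2-group probability is smaller: slower decay at equal start
  set.seed(42)
  g2 <- harness_dsb_decay(cat0, phase = "G2", n_cells = 1e4,
                          duration_h = 24, record_every_min = 720)
  g1 <- harness_dsb_decay(cat0, phase = "G1", n_cells = 1e4,
                          duration_h = 24, record_every_min = 720)
  expect_gt(g2$mean_Z[nrow(g2)], g1$mean_Z[nrow(g1)])
})

test_that("DSB-positive fraction reduces to the background law and orders by pathway", {
  cat0 <- degenerate_catalogue()
  # all induction off: nothing is ever positive
  none <- harness_dsb_positive(
    zero_fields(cat0, c("zb_lambda", "zm_lambda", "zg_lambda")),
    n_side = 12, duration_min = 2)
  expect_equal(none$fraction, 0)
  # background only: fraction = 1 - exp(-lambda * n_steps)
  set.seed(43)
  bg <- harness_dsb_positive(zero_fields(cat0, c("zm_lambda", "zg_lambda")),
                             n_side = 32, duration_min = 10,
                             init_M = 0, init_G = 0)
  p_exp <- 1 - exp(-1.4e-5 * 6000)
  se <- sqrt(p_exp * (1 - p_exp) / bg$n_cells)
  expect_lt(abs(bg$fraction - p_exp), 3 * se)
  # enabling the junctional pathway can only add hazard
  set.seed(44)
  on <- harness_dsb_positive(cat0, gjp_enabled = TRUE, n_side = 32,
                             duration_min = 30)
  set.seed(44)
  off <- harness_dsb_positive(cat0, gjp_enabled = FALSE, n_side = 32,
                              duration_min = 30)
  expect_gte(on$fraction, off$fraction)
})

test_that("survival harness is monotone in dose and matches its oracle", {
  expect_equal(harness_survival(dose_gy = 0, n_cells = 100)$fraction, 1)
  set.seed(45)
  fr <- vapply(c(0.5, 1, 2, 4), function(d)
    harness_survival(dose_gy = d, phase = "G1", n_cells = 1e4)$fraction,
    numeric(1))
  expect_true(all(diff(fr) <= 0))
  # independent oracle: average over inverse-CDF draws of the induction
  # coefficient and threshold of P(Poisson(lambda * D) < H)
  set.seed(46)
  n <- 2e5
  lam <- qnorm(runif(n, pnorm(0, 40, 22, lower.tail = TRUE), 1), 40, 22)
  H <- qnorm(runif(n, pnorm(0, 93, 38, lower.tail = TRUE), 1), 93, 38)
  p_oracle <- mean(ppois(ceiling(H) - 1, lam * 1))
  set.seed(47)
  mc <- harness_survival(dose_gy = 1, phase = "G1", n_cells = 1e4)$fraction
  se <- sqrt(p_oracle * (1 - p_oracle) / 1e4)
  expect_lt(abs(mc - p_oracle), 4 * se)
})

test_that("grid search recovers known parameters and reports its surface", {
  # self-consistency: data generated at the catalogue repair value
  cat0 <- degenerate_catalogue()
  set.seed(48)
  dataset <- harness_dsb_decay(cat0, n_cells = 2e4, duration_h = 24,
                               record_every_min = 240)
  sim_fun <- function(p) {
    cc <- cat0
    cc$cell$repair_lambda$values$g0g1$av <- p[["av"]]
    harness_dsb_decay(cc, n_cells = 4e3, duration_h = 24,
                      record_every_min = 240)
  }
  fit <- grid_search(sim_fun, dataset,
                     ranges = list(av = c(1e-8, 1.5e-6)), resolution = 13)
  cell_w <- (1.5e-6 - 1e-8) / 12
  expect_lt(abs(fit$best[["av"]] - 9.33e-7), cell_w + 1e-12)
  expect_equal(nrow(fit$surface), 13L)
  expect_true(all(fit$surface$loss >= fit$best_loss))
  # single-point grid returns that point
  one <- grid_search(function(p) 1, data.frame(x = 1, y = 2),
                     ranges = list(a = c(3, 3)), resolution = 1)
  expect_equal(unname(one$best), 3)
  # widening a range never increases the minimum loss
  f <- function(p) data.frame(x = 0, value = p[["a"]]^2)
  d <- data.frame(x = 0, y = 0.2)
  narrow <- grid_search(f, d, list(a = c(1, 2)), resolution = 5)
  wide <- grid_search(f, d, list(a = c(0, 2)), resolution = 9)
  expect_lte(wide$best_loss, narrow$best_loss)
})

test_that("calibration files are validated on read", {
  path <- system.file("extdata", "synthetic_dsb_decay_g1.csv",
                      package = "bystandr")
  df <- read_calibration(path)
  expect_true(nrow(df) > 3)
  expect_true(all(diff(df[[1]]) > 0))
  bad <- tempfile(fileext = ".csv")
  write.csv(data.frame(t = c(1, 1, 2), v = c(3, 2, 1)), bad,
            row.names = FALSE)
  expect_error(read_calibration(bad), "increasing")
})
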