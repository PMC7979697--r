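one_pixel_history <- function(age, nr = 3, nc = 3) {
  cls <- matrix("anthropic", nr, nc)
  ag <- matrix(NA_integer_, nr, nc)
  cls[2, 2] <- "secondary"; ag[2, 2] <- as.integer(age)
  make_history(cls, ag)
}

test_that("total stock follows the unit arithmetic", {
  fits <- list(region1.single_not_burnt = make_fit(100, 0.1, 1))
  reg <- matrix(1L, 3, 3)
  h <- one_pixel_history(5)
  # Y(5) = 100 (1 - e^-0.5) = 39.347 Mg C/ha over 0.09 ha
  expect_equal(total_stock(h, reg, fits), 39.34693 * 0.09 / 1e6,
               tolerance = 1e-6)
  empty <- make_history(matrix("anthropic", 3, 3))
  expect_equal(total_stock(empty, reg, fits), 0)
  # additivity: two identical pixels double the stock
  cls <- matrix("anthropic", 3, 3); cls[2, 2:3] <- "secondary"
  ag <- matrix(NA_integer_, 3, 3); ag[2, 2:3] <- 5L
  h2 <- make_history(cls, ag)
  expect_equal(total_stock(h2, reg, fits), 2 * total_stock(h, reg, fits))
  # unassigned pixels are an error
  expect_error(total_stock(h, matrix(2L, 3, 3), fits), "unassigned")
})

test_that("the annual ledger matches closed-form gains and losses", {
  fits <- list(region1.single_not_burnt = make_fit(100, 0.1, 1))
  reg <- matrix(1L, 3, 3)

  # one persisting pixel ageing 5 -> 6
  led <- annual_net_change(one_pixel_history(5), one_pixel_history(6),
                           reg, fits)
  expect_equal(led$gains_TgC, 100 * (exp(-0.5) - exp(-0.6)) * 0.09 / 1e6,
               tolerance = 1e-9)
  expect_equal(led$losses_TgC, 0)

  # one pixel of age 4 deforested
  led2 <- annual_net_change(one_pixel_history(4),
                            make_history(matrix("anthropic", 3, 3)), reg, fits)
  expect_equal(led2$losses_TgC, 100 * (1 - exp(-0.4)) * 0.09 / 1e6,
               tolerance = 1e-9)
  expect_equal(led2$gains_TgC, 0)
  expect_equal(led2$net_TgC, -led2$losses_TgC)

  # recruitment enters at Y(1)
  led3 <- annual_net_change(make_history(matrix("anthropic", 3, 3)),
                            one_pixel_history(1), reg, fits)
  expect_equal(led3$gains_TgC, 100 * (1 - exp(-0.1)) * 0.09 / 1e6,
               tolerance = 1e-9)

  # empty landscape: all-zero ledger
  e <- make_history(matrix("anthropic", 2, 2))
  led4 <- annual_net_change(e, e, matrix(1L, 2, 2), fits)
  expect_equal(unlist(led4[c("gains_TgC", "losses_TgC", "net_TgC")]),
               c(gains_TgC = 0, losses_TgC = 0, net_TgC = 0))

  # age must advance by exactly one year
  expect_error(annual_net_change(one_pixel_history(5), one_pixel_history(8),
                                 reg, fits), "inconsistent")
})

test_that("the ledger constructor enforces the conservation identity", {
  led <- stock_ledger(28.0, 16.1, 281.8)
  expect_equal(led$net_TgC, 11.9)
  expect_equal(led$stock_end_TgC, 293.7)
  expect_error(stock_ledger(-1, 0), "non-negative")
})

test_that("conservation holds on simulated landscapes", {
  fits <- true_fit_set()
  for (seed in 1:10) {
    cfg <- tiny_config(seed = seed, years = 2000:2017)
    sim <- simulate_landcover(cfg)
    ny <- length(cfg$years)
    h_b <- classify_history(sim$stack, sim$burned_masks)
    h_a <- classify_history(sim$stack[, , -ny, drop = FALSE],
                            sim$burned_masks[as.integer(names(sim$burned_masks)) <
                                               cfg$years[ny]])
    reg <- sim$truth$region
    led <- annual_net_change(h_a, h_b, reg, fits)
    expect_lt(abs(led$stock_end_TgC - led$stock_start_TgC -
                    led$gains_TgC + led$losses_TgC), 1e-12)
    expect_gte(led$gains_TgC, 0)
    expect_gte(led$losses_TgC, 0)
  }
})

test_that("the no-disturbance counterfactual dominates when its curves do", {
  cfg <- tiny_config(seed = 4)
  fits <- true_fit_set(cfg)
  # the generator's no-disturbance curve dominates every disturbed curve
  tm <- cfg$true_models
  for (r in 1:4) {
    base <- fits[[model_key(r, "single_not_burnt")]]
    for (cls in setdiff(DISTURBANCE_CLASSES, "single_not_burnt")) {
      f <- fits[[model_key(r, cls)]]
      expect_true(all(predict_agc(base, 1:32) >= predict_agc(f, 1:32)))
    }
  }
  sim <- simulate_landcover(cfg)
  h <- classify_history(sim$stack, sim$burned_masks)
  reg <- sim$truth$region
  actual <- total_stock(h, reg, fits)
  potential <- potential_stock_no_disturbance(h, reg, fits)
  expect_gte(potential, actual)
  expect_gte(disturbance_reduction(actual, potential), 0)

  # a single burnt pixel: potential - actual = (35 - 20) * area
  fits2 <- list(region1.single_not_burnt = make_fit(35 / (1 - exp(-1))^1, 0.1, 1),
                region1.single_burnt = make_fit(20 / (1 - exp(-1)), 0.1, 1))
  hb <- one_pixel_history(10)
  hb$burned[2, 2] <- TRUE
  reg1 <- matrix(1L, 3, 3)
  gap <- potential_stock_no_disturbance(hb, reg1, fits2) -
    total_stock(hb, reg1, fits2)
  expect_equal(gap, 15 * 0.09 / 1e6, tolerance = 1e-9)
})

test_that("coarse gridding is a partition that conserves totals", {
  set.seed(61)
  x <- matrix(runif(30 * 45), 30, 45)
  g <- grid_aggregate(x, 10)
  expect_equal(dim(g), c(3, 5))
  expect_equal(sum(g), sum(x), tolerance = 1e-12)
  # flat-loop binning oracle
  oracle <- matrix(0, 3, 5)
  for (i in 1:30) for (j in 1:45) {
    ci <- (i - 1) %/% 10 + 1; cj <- (j - 1) %/% 10 + 1
    oracle[ci, cj] <- oracle[ci, cj] + x[i, j]
  }
  expect_equal(g, oracle, tolerance = 1e-12)
  # one cell covering everything
  expect_equal(as.vector(grid_aggregate(x, 100)), sum(x))
  expect_error(grid_aggregate(x, 0), ">= 1")
})
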