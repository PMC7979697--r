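test_that("config validation rejects impossible settings", {
  expect_error(synth_config(grid_rows = 0), "positive")
  expect_error(synth_config(clearing_rate = 1.2), "rates")
  expect_error(synth_config(noise_sd = -1), "noise_sd")
  expect_error(synth_config(years = c(1985, 1987, 1988)), "consecutive")
  bad <- default_true_models(); bad$k[1] <- -0.1
  expect_error(synth_config(true_models = bad), "true models")
})

test_that("same seed and config give byte-identical simulations", {
  a <- simulate_landcover(tiny_config(seed = 7))
  b <- simulate_landcover(tiny_config(seed = 7))
  expect_identical(a$stack, b$stack)
  expect_identical(a$ledger, b$ledger)
  expect_identical(simulate_agc(a), simulate_agc(b))
  d <- simulate_landcover(tiny_config(seed = 8))
  expect_false(identical(a$stack, d$stack))
})

test_that("degenerate rates produce the forced landscapes", {
  all_forest <- simulate_landcover(tiny_config(
    clearing_rate = 0, initial_anthropic_frac = 0))
  expect_true(all(all_forest$stack == 1L))
  expect_true(all(all_forest$truth$class == "old_growth"))

  no_regrow <- simulate_landcover(tiny_config(
    clearing_rate = 0.1, abandonment_rate = 0, initial_anthropic_frac = 0))
  expect_equal(sum(no_regrow$truth$class == "secondary"), 0)

  no_fire <- simulate_landcover(tiny_config(fire_rate = 0))
  expect_true(all(!vapply(no_fire$burned_masks, any, logical(1))))
})

test_that("truth ledger replay reproduces the stack-derived final state", {
  sim <- simulate_landcover(synth_config(
    seed = 42, clearing_rate = 0.02, abandonment_rate = 0.1,
    reclearing_rate = 0.05))
  replay <- oracle_replay_ledger(sim)
  expect_identical(as.vector(sim$truth$class), replay$class)
  expect_identical(as.vector(sim$truth$age), replay$age)
  expect_identical(as.vector(sim$truth$defor_count), replay$defor)
  # and the stack itself agrees with the truth on the secondary fraction
  hist <- classify_history(sim$stack)
  expect_identical(hist$class, sim$truth$class)
})

test_that("raising the clearing rate never removes primary clearing events", {
  n_clearings <- function(rate) {
    sim <- simulate_landcover(tiny_config(seed = 3, clearing_rate = rate))
    sum(sim$ledger$event == "deforest_primary")
  }
  counts <- vapply(c(0, 0.01, 0.02, 0.05, 0.1), n_clearings, numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_equal(counts[1], 0)
})

test_that("burned masks exist only from the fire start year", {
  sim <- simulate_landcover(tiny_config())
  yrs <- as.integer(names(sim$burned_masks))
  expect_true(all(yrs >= 2001))
  expect_error(get_burned_mask(sim, 1999), "2001")
})

test_that("AGC map encodes the true growth curves exactly when noise-free", {
  tm <- default_true_models()
  tm$A <- rep(100, 16); tm$k <- rep(0.1, 16); tm$c <- rep(1, 16)
  clim <- default_region_climate(); clim$A_old_growth <- rep(135.5, 4)
  cfg <- tiny_config(seed = 5, noise_sd = 0, true_models = tm,
                     region_climate = clim)
  sim <- simulate_landcover(cfg)
  agb <- simulate_agc(sim)
  sec <- sim$truth$class == "secondary"
  # closed form: age 1 under (A=100, k=0.1, c=1) has AGC 9.516, AGB 19.03
  a1 <- sec & !is.na(sim$truth$age) & sim$truth$age == 1L
  if (any(a1)) expect_equal(unique(agb[a1]), 19.03252, tolerance = 1e-6)
  expect_equal(agb[sec], 2 * cr_curve(sim$truth$age[sec], 100, 0.1, 1),
               tolerance = 1e-12)
  og <- sim$truth$class == "old_growth"
  expect_true(all(abs(agb[og] - 271) < 1e-9))  # 2 x 135.5
  ant <- sim$truth$class == "anthropic"
  expect_true(all(agb[ant] >= 0 & agb[ant] <= 10))
})

test_that("a missing true model for an occurring class is reported", {
  cfg <- tiny_config(seed = 5)
  cfg$true_models <- cfg$true_models[cfg$true_models$class != "single_not_burnt", ]
  sim <- simulate_landcover(cfg)
  expect_error(simulate_agc(sim), "no true model")
})

test_that("importance records plant the age signal and nothing else", {
  rec <- simulate_importance_records(n = 500, seed = 2)
  expect_equal(nrow(rec), 500)
  expect_true(all(rec$agc >= 0))
  # the age signal is strong, the drivers are noise
  expect_gt(cor(rec$agc, cr_curve(rec$forest_age, 120, 0.043, 1.3)), 0.9)
  expect_lt(abs(cor(rec$agc, rec$scc)), 0.2)
})
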