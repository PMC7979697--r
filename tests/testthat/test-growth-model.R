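test_that("the growth curve evaluates its closed forms", {
  expect_equal(cr_curve(0, 100, 0.1, 1), 0)
  expect_equal(cr_curve(1, 100, 0.1, 1), 9.516258, tolerance = 1e-6)
  expect_equal(cr_curve(20, 100, 0.1, 1), 86.46647, tolerance = 1e-6)
  expect_equal(cr_curve(1000, 100, 0.1, 1), 100, tolerance = 1e-6)
})

test_that("the old-growth asymptote is a bias-shifted median", {
  agc <- matrix(c(120, 130, 140, 999), 2, 2)
  og <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  expect_equal(old_growth_asymptote(agc, og), 130)
  expect_equal(old_growth_asymptote(agc, og, bias_offset = 10), 120)
  grp <- matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2)
  expect_equal(old_growth_asymptote(agc, og, grp), 130)
  expect_error(old_growth_asymptote(agc, matrix(FALSE, 2, 2)), "no old-growth")
})

test_that("noiseless tables return the generating parameters", {
  tab <- tibble::tibble(age = 1:30, median_agc = cr_curve(1:30, 100, 0.1, 1.5))
  f <- fit_chapman_richards(tab, A = 100)
  expect_equal(f$k, 0.1, tolerance = 1e-4)
  expect_equal(f$c, 1.5, tolerance = 1e-4)
  expect_lt(f$residual_sd, 1e-4)

  # exponential special case: c free returns c ~ 1
  tab1 <- tibble::tibble(age = 1:25, median_agc = cr_curve(1:25, 80, 0.07, 1))
  f1 <- fit_chapman_richards(tab1, A = 80)
  expect_equal(f1$c, 1, tolerance = 1e-4)

  expect_error(fit_chapman_richards(
    tibble::tibble(age = 1:2, median_agc = c(1, 2)), A = 10), "3 age rows")
  expect_error(fit_chapman_richards(tab, A = -5), "positive")
})

test_that("the optimiser beats a dense grid scan of the objective", {
  set.seed(41)
  age <- 1:15
  y <- cr_curve(age, 90, 0.08, 1.4) + rnorm(15, 0, 4)
  tab <- tibble::tibble(age = age, median_agc = y - min(y))
  f <- fit_chapman_richards(tab, A = 90)
  obj <- function(k, c) sum((tab$median_agc - cr_curve(age, 90, k, c))^2)
  grid_best <- Inf
  for (k in seq(0.005, 0.4, length.out = 200))
    for (c in seq(0.2, 5, length.out = 200))
      grid_best <- min(grid_best, obj(k, c))
  expect_lte(f$rss, grid_best + 1e-8)
})

test_that("derived regrowth statistics follow their closed forms", {
  f <- make_fit(100, 0.1, 1)
  expect_equal(predict_agc(f, 0), 0)
  expect_equal(predict_agc(f, 20), 86.46647, tolerance = 1e-6)
  expect_error(predict_agc(f, -1), "non-negative")

  expect_equal(mean_rate_first_n_years(f, 20), 4.323324, tolerance = 1e-6)
  expect_equal(mean_rate_first_n_years(f, 1), predict_agc(f, 1))
  expect_error(mean_rate_first_n_years(f, 0), ">= 1")

  tt <- time_to_fraction(f, 0.9)
  expect_equal(tt$exact, -log(0.1) / 0.1, tolerance = 1e-9)
  expect_equal(tt$years, 24L)

  half <- time_to_fraction(make_fit(100, log(2) / 10, 1), 0.5)
  expect_equal(half$years, 10L)
  expect_equal(half$exact, 10, tolerance = 1e-9)

  slow <- time_to_fraction(make_fit(100, 0.001, 1), 0.9, max_years = 40)
  expect_false(slow$reached)
  expect_true(is.na(slow$years))
  expect_error(time_to_fraction(f, 1), "between 0 and 1")
})

test_that("the curve is monotone in age and rate, and shape delays early growth", {
  t <- seq(0.5, 60, by = 0.5)
  y <- cr_curve(t, 120, 0.05, 1.3)
  expect_true(all(diff(y) > 0))
  expect_true(all(y < 120))
  expect_true(all(cr_curve(10, 120, seq(0.02, 0.3, 0.02), 1.3) ==
                    cummax(cr_curve(10, 120, seq(0.02, 0.3, 0.02), 1.3))))
  expect_gt(cr_curve(3, 120, 0.05, 1), cr_curve(3, 120, 0.05, 2))
})

test_that("parameters are recovered from noisy tables with honest intervals", {
  set.seed(43)
  truths <- default_true_models()
  truths <- truths[truths$class == "single_not_burnt", ]
  rows <- list()
  for (i in 1:120) {
    tm <- truths[sample(nrow(truths), 1), ]
    noise <- runif(1, 0.02, 0.10) * tm$A
    y <- cr_curve(1:32, tm$A, tm$k, tm$c) + rnorm(32, 0, noise)
    tab <- tibble::tibble(age = 1:32, median_agc = y)
    f <- fit_chapman_richards(tab, A = tm$A)
    rows[[i]] <- c(
      k_err = abs(f$k - tm$k) / tm$k, c_err = abs(f$c - tm$c) / tm$c,
      k_cov = f$ci95["k", "lower"] <= tm$k && tm$k <= f$ci95["k", "upper"],
      c_cov = f$ci95["c", "lower"] <= tm$c && tm$c <= f$ci95["c", "upper"])
  }
  res <- do.call(rbind, rows)
  expect_lte(median(res[, "k_err"]), 0.10)
  expect_lte(median(res[, "c_err"]), 0.10)
  expect_gte(mean(res[, "k_cov"]), 0.90)
  expect_gte(mean(res[, "c_cov"]), 0.90)
})

test_that("bootstrap intervals bracket the point estimate", {
  set.seed(44)
  y <- cr_curve(1:25, 110, 0.06, 1.4) + rnorm(25, 0, 5)
  tab <- tibble::tibble(age = 1:25, median_agc = y - min(y))
  f <- fit_chapman_richards(tab, A = 110, ci = "bootstrap", boot_reps = 200,
                            seed = 7)
  expect_true(nrow(f$boot) > 150)
  expect_lte(f$ci95["k", "lower"], f$k)
  expect_gte(f$ci95["k", "upper"], f$k)
  # deterministic under the seed
  f2 <- fit_chapman_richards(tab, A = 110, ci = "bootstrap", boot_reps = 200,
                             seed = 7)
  expect_identical(f$ci95, f2$ci95)
})
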