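as_stack <- function(...) {
  series <- list(...)
  ny <- length(series[[1]])
  arr <- array(NA_integer_, c(length(series), 1, ny))
  for (i in seq_along(series)) arr[i, 1, ] <- series[[i]]
  arr
}
F <- 1L; A <- 0L

test_that("single-pixel histories classify as worked out by hand", {
  h <- classify_history(as_stack(
    c(F, F, F, F, F, F, F),    # old-growth
    c(F, F, A, A, F, F, F),    # secondary, age 3, one clearing
    c(F, A, F, A, F, F, A),    # anthropic at the end: history discarded
    c(A, F, F, F, F, F, F),    # regrowth from pre-window clearing
    c(F, F, NA, F, F, F, F)    # gap => nodata
  ))
  expect_equal(as.vector(h$class), c("old_growth", "secondary", "anthropic",
                                     "secondary", "nodata"))
  expect_equal(as.vector(h$age), c(NA, 3L, NA, 6L, NA))
  expect_equal(as.vector(h$defor_count), c(NA, 1L, NA, 1L, NA))
})

test_that("classification rejects malformed stacks", {
  expect_error(classify_history(array(1L, c(2, 2, 1))), "2 annual layers")
  expect_error(classify_history(array(2L, c(2, 2, 3))), "0, 1 or NA")
})

test_that("repeated-deforestation counting matches hand counts", {
  expect_equal(count_repeated_deforestations(c(F, F, A, F, F)), 1)
  expect_equal(count_repeated_deforestations(c(F, A, F, A, F, F)), 2)
  expect_equal(count_repeated_deforestations(rep(F, 6)), 0)
  expect_equal(count_repeated_deforestations(c(A, F, F)), 1)  # original conversion
  expect_error(count_repeated_deforestations(c(1L)), "length")
  expect_error(count_repeated_deforestations(c(1L, 2L)), "0 or 1")
})

test_that("per-pixel classification equals the replay oracle on random series", {
  set.seed(11)
  nr <- 100; nc <- 100; ny <- 10
  stack <- array(rbinom(nr * nc * ny, 1, 0.6), c(nr, nc, ny))
  h <- classify_history(stack)
  m <- matrix(stack, nr * nc, ny)
  for (i in sample(nr * nc, 2000)) {  # spot-check a large random subset
    o <- oracle_classify_series(m[i, ])
    expect_identical(h$class[i], o$class)
    if (o$class == "secondary") {
      expect_identical(h$age[i], as.integer(o$age))
      expect_identical(h$defor_count[i], as.integer(o$defor))
    }
  }
})

test_that("appending a forest year increments age and preserves the count", {
  set.seed(12)
  for (rep in 1:50) {
    s <- rbinom(12, 1, 0.6)
    s[12] <- 1L  # ends in forest
    if (all(s == 1L)) s[3] <- 0L
    h1 <- classify_history(as_stack(s))
    h2 <- classify_history(as_stack(c(s, 1L)))
    expect_identical(h2$age[1], h1$age[1] + 1L)
    expect_identical(h2$defor_count[1], h1$defor_count[1])
  }
})

test_that("exclusion masks and buffers remove exactly the flagged pixels", {
  sim <- simulate_landcover(tiny_config(seed = 2))
  h <- classify_history(sim$stack)
  expect_identical(apply_exclusion_masks(h), h)

  full <- matrix(TRUE, 40, 40)
  h_full <- apply_exclusion_masks(h, masks = list(full))
  expect_equal(sum(h_full$class == "secondary"), 0)
  expect_true(all(h_full$class == "excluded"))

  # 3 km buffer on the 30 m grid versus a brute-force distance scan
  pt <- data.frame(x = 600, y = 450)
  h_buf <- apply_exclusion_masks(h, points = pt, radius_m = 300,
                                 pixel_size_m = 30)
  brute <- matrix(FALSE, 40, 40)
  for (i in 1:40) for (j in 1:40) {
    cx <- (j - 0.5) * 30; cy <- (i - 0.5) * 30
    brute[i, j] <- sqrt((cx - 600)^2 + (cy - 450)^2) <= 300
  }
  expect_identical(h_buf$class == "excluded", brute)
  expect_error(apply_exclusion_masks(h, masks = list(matrix(TRUE, 3, 3))),
               "mismatch")
})

test_that("the minimum mapping unit keeps 10-pixel patches and drops 9", {
  age <- matrix(NA_real_, 20, 20)
  age[2, 2:10] <- 1       # 9 pixels = 8100 m2, below the unit
  age[10, 2:11] <- 1      # 10 pixels = 9000 m2, kept under ">="
  h <- classify_history(stack_from_age(age, n_years = 5))
  p <- label_patches(h, min_area_m2 = 9000, pixel_size_m = 30)
  expect_equal(nrow(p), 1)
  expect_equal(p$n_pixels, 10L)
  expect_equal(p$area_m2, 9000)

  empty <- label_patches(classify_history(stack_from_age(
    matrix(NA_real_, 5, 5), n_years = 5)))
  expect_equal(nrow(empty), 0)
  expect_error(label_patches(h, min_area_m2 = 0), "positive")
})

test_that("connectivity and age grouping control patch delineation", {
  # two 10-pixel runs touching only diagonally at (5,11)-(6,12)
  age <- matrix(NA_real_, 20, 25)
  age[5, 2:11] <- 2
  age[6, 12:21] <- 2
  h <- classify_history(stack_from_age(age, n_years = 5))
  p8 <- label_patches(h, connectivity = 8)
  p4 <- label_patches(h, connectivity = 4)
  expect_equal(nrow(p8), 1)  # merged across the diagonal
  expect_equal(nrow(p4), 2)
  expect_equal(sum(p8$n_pixels), sum(!is.na(age)))

  # adjacent blocks of different age: split by default, merged when asked
  age2 <- matrix(NA_real_, 20, 20)
  age2[2:5, 2:5] <- 3   # 16 px, age 3
  age2[2:5, 6:9] <- 7   # 16 px, age 7
  h2 <- classify_history(stack_from_age(age2, n_years = 12))
  by_age <- label_patches(h2)
  merged <- label_patches(h2, group_by_age = FALSE)
  expect_equal(nrow(by_age), 2)
  expect_setequal(by_age$age, c(3L, 7L))
  expect_equal(nrow(merged), 1)
  expect_equal(merged$age, 3L)  # modal tie broken toward the smaller age
})

test_that("patches inherit burn and repeated-deforestation tags", {
  age <- matrix(NA_real_, 12, 12)
  age[2:5, 2:5] <- 4
  burn <- matrix(FALSE, 12, 12); burn[2:5, 2:5] <- TRUE
  h <- classify_history(stack_from_age(age, n_years = 8),
                        burned_masks = list("2001" = burn))
  p <- label_patches(h)
  expect_true(p$burned)
  expect_false(p$repeated)
  expect_equal(disturbance_class(p$repeated, p$burned), "single_burnt")
  # a partially burnt polygon splits into a burnt and an unburnt patch
  # under class-coherent delineation, and merges when grouping is off
  half <- matrix(FALSE, 12, 12); half[2:5, 2:3] <- TRUE
  h2 <- classify_history(stack_from_age(age, n_years = 8),
                         burned_masks = list("2001" = half))
  expect_equal(nrow(label_patches(h2, min_area_m2 = 900)), 2)
  merged <- label_patches(h2, min_area_m2 = 900, group_by_age = FALSE)
  expect_equal(nrow(merged), 1)
  expect_true(merged$burned)
})
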