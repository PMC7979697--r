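# Independent oracles used across the suite.  They replay histories with
# plain per-pixel loops and never share code with the implementation.

# classify one 0/1 series the slow, obvious way
oracle_classify_series <- function(s) {
  n <- length(s)
  if (anyNA(s)) return(list(class = "nodata", age = NA, defor = NA))
  if (all(s == 1)) return(list(class = "old_growth", age = NA, defor = NA))
  if (s[n] == 0) return(list(class = "anthropic", age = NA, defor = NA))
  defor <- 0
  for (t in 2:n) if (s[t - 1] == 1 && s[t] == 0) defor <- defor + 1
  t <- n
  while (t >= 1 && s[t] == 1) t <- t - 1
  list(class = "secondary", age = n - t, defor = max(defor, 1))
}

# replay a simulation's truth ledger event by event, per pixel
oracle_replay_ledger <- function(sim) {
  cfg <- sim$config
  npix <- cfg$grid_rows * cfg$grid_cols
  years <- cfg$years
  state <- rep("old_growth", npix)
  age <- rep(0L, npix)
  defor <- rep(0L, npix)
  led <- sim$ledger
  init <- led$pixel_id[led$event == "initial_anthropic"]
  state[init] <- "anthropic"
  for (yr in years[-1]) {
    ev <- led[led$year == yr, ]
    cl <- ev$pixel_id[ev$event %in% c("deforest_primary", "deforest_secondary")]
    rg <- ev$pixel_id[ev$event == "regrow"]
    state[cl] <- "anthropic"
    age[cl] <- 0L
    defor[cl] <- defor[cl] + 1L
    state[rg] <- "secondary"
    sec <- state == "secondary"
    age[sec] <- age[sec] + 1L
  }
  sec <- state == "secondary"
  defor_out <- rep(NA_integer_, npix)
  defor_out[sec] <- pmax(defor[sec], 1L)
  age_out <- rep(NA_integer_, npix)
  age_out[sec] <- age[sec]
  list(class = state, age = age_out, defor = defor_out)
}

# a quickly-simulated landscape small enough for per-test use; block size 4
# keeps single-block patches (16 px = 14400 m2) above the 9000 m2 filter
tiny_config <- function(seed = 1L, ...) {
  synth_config(grid_rows = 40, grid_cols = 40, block_size = 4, seed = seed, ...)
}

# build a forest_history by hand for accounting tests
make_history <- function(class, age = NULL, defor = NULL, burned = NULL,
                         n_years = 33) {
  nr <- nrow(class); nc <- ncol(class)
  blank_int <- matrix(NA_integer_, nr, nc)
  blank_lgl <- matrix(NA, nr, nc)
  sec <- class == "secondary"
  if (is.null(age)) age <- blank_int
  if (is.null(defor)) { defor <- blank_int; defor[sec] <- 1L }
  if (is.null(burned)) { burned <- blank_lgl; burned[sec] <- FALSE }
  structure(list(class = class, age = age, defor_count = defor,
                 burned = burned, n_years = n_years),
            class = "forest_history")
}

# a synthetic growth fit with known parameters
make_fit <- function(A, k, c, boot = NULL) {
  structure(list(A = A, k = k, c = c,
                 se = c(k = NA, c = NA),
                 ci95 = matrix(c(0, 0, Inf, Inf), 2,
                               dimnames = list(c("k", "c"),
                                               c("lower", "upper"))),
                 residual_sd = 0, n_ages = NA, group = NULL,
                 converged = TRUE, bias_offset = 0, boot = boot),
            class = "cr_fit")
}

# full 4-region model set from the generator's truth table
true_fit_set <- function(config = synth_config()) {
  tm <- config$true_models
  fits <- list()
  for (i in seq_len(nrow(tm)))
    fits[[model_key(tm$region[i], tm$class[i])]] <-
      make_fit(tm$A[i], tm$k[i], tm$c[i])
  fits
}

# stack helper: constant-habit series per pixel from a final-age template.
# age NA => old-growth (forest throughout); age 0 => anthropic at the end.
stack_from_age <- function(age_mat, n_years = 33) {
  nr <- nrow(age_mat); nc <- ncol(age_mat)
  st <- array(1L, c(nr, nc, n_years))
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    a <- age_mat[i, j]
    if (is.na(a)) next
    if (a == 0) {
      st[i, j, n_years] <- 0L
    } else {
      st[i, j, n_years - a] <- 0L  # cleared once, regrew for the last a years
    }
  }
  st
}
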