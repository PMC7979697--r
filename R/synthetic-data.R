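#' @importFrom tibble tibble as_tibble
#' @importFrom stats runif rnorm median quantile kmeans coef vcov qt sd setNames
NULL

#' Disturbance class labels
#'
#' The four disturbance histories a secondary-forest patch can carry:
#' whether it was deforested once or repeatedly before the most recent
#' regrowth, crossed with whether it burned.
#' @export
DISTURBANCE_CLASSES <- c(
  "single_not_burnt", "single_burnt",
  "repeated_not_burnt", "repeated_burnt"
)

#' Default climate anchors for the four synthetic regions
#'
#' One row per region, ordered by ascending mean shortwave radiation so that
#' region 1 is the wet, low-radiation north-west-like corner and region 4 the
#' dry, high-radiation north-east-like corner.  Values are the regional means
#' the driver generator plants: shortwave radiation (W m-2), annual
#' precipitation (mm yr-1), maximum cumulative water deficit (mm yr-1) and the
#' old-growth aboveground-carbon asymptote (Mg C ha-1).
#' @return a tibble with columns `region`, `sw`, `precip`, `mcwd`,
#'   `A_old_growth`.
#' @export
default_region_climate <- function() {
  tibble(
    region = 1:4,
    sw = c(163.6, 173.0, 181.7, 188.0),
    precip = c(2049, 2100, 1913, 1920),
    mcwd = c(-64.4, -150.0, -328.5, -322.5),
    A_old_growth = c(112.0, 120.0, 126.0, 135.5)
  )
}

#' Solve the Chapman-Richards rate constant from a target value
#'
#' Given a fixed asymptote `A` and shape `c`, returns the rate `k` such that
#' the curve passes through `Y(t_ref) = y_ref`.
#'
#' @param A asymptote (Mg C ha-1).
#' @param c shape parameter (> 0).
#' @param y_ref target carbon at the reference age (must be in (0, A)).
#' @param t_ref reference age in years (default 20).
#' @return rate constant k (yr-1).
#' @export
cr_solve_k <- function(A, c, y_ref, t_ref = 20) {
  stop_if_not(A > 0 && c > 0, "A and c must be positive")
  stop_if_not(y_ref > 0 && y_ref < A, "y_ref must lie strictly between 0 and A")
  -log(1 - (y_ref / A)^(1 / c)) / t_ref
}

#' Default ground-truth regrowth models for the synthetic landscape
#'
#' 16 Chapman-Richards parameter sets: 4 climate regions x 4 disturbance
#' classes.  Asymptotes come from [default_region_climate()]; the
#' no-disturbance curves are anchored so their mean accumulation rate over the
#' first 20 years matches the regional rates reported for Amazonian secondary
#' forests (3.0, 2.8, 1.8 and 1.3 Mg C ha-1 yr-1 from the wettest to the
#' driest region), and disturbance classes scale those rates down by fixed
#' multipliers (fire and repeated clearing barely matter in the wet region,
#' roughly halve growth in the dry regions, and compound when combined).
#'
#' @return a tibble with columns `region`, `class`, `A`, `k`, `c`.
#' @export
default_true_models <- function() {
  clim <- default_region_climate()
  rate20 <- c(3.0, 2.8, 1.8, 1.3)              # Mg C ha-1 yr-1, no disturbance
  shape <- c(1.3, 1.4, 1.5, 1.5)
  mult <- rbind(                               # rows = regions, cols = classes
    c(1, 0.80, 0.87, 0.70),
    c(1, 0.40, 0.75, 0.35),
    c(1, 0.50, 0.70, 0.30),
    c(1, 0.62, 0.75, 0.45)
  )
  out <- expand.grid(
    class = DISTURBANCE_CLASSES, region = 1:4,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  out <- out[, c("region", "class")]
  out$A <- clim$A_old_growth[out$region]
  out$c <- shape[out$region]
  y20 <- 20 * rate20[out$region] *
    mult[cbind(out$region, match(out$class, DISTURBANCE_CLASSES))]
  out$k <- mapply(cr_solve_k, A = out$A, c = out$c, y_ref = y20)
  as_tibble(out)
}

#' Configuration of the synthetic landscape generator
#'
#' Bundles and validates every knob of the generator: grid geometry, the
#' annual land-use Markov chain rates, fire occurrence, the ground-truth
#' regrowth models, driver-surface anchors and gradient amplitudes, and the
#' observation noise on aboveground carbon.
#'
#' Transitions are drawn per square block of `block_size` pixels (a "field"),
#' which gives clearing events the spatial coherence of real land use; within
#' a block the process is a per-pixel Markov chain: old-growth forest is
#' cleared at `clearing_rate` per year, anthropic land returns to (secondary)
#' forest at `abandonment_rate`, and secondary forest is re-cleared at
#' `reclearing_rate`.  Fires strike standing secondary forest from
#' `fire_start_year` onward at `fire_rate` per year.
#'
#' @param grid_rows,grid_cols grid dimensions (positive integers).
#' @param pixel_size_m pixel edge length in metres (default 30).
#' @param years inclusive, consecutive run of calendar years (default
#'   1985:2017, i.e. ages 1..32 in the final year).
#' @param clearing_rate,abandonment_rate,reclearing_rate,fire_rate annual
#'   transition probabilities, all in \[0, 1\].
#' @param fire_start_year first year with burned-area observations (2001).
#' @param initial_anthropic_frac fraction of blocks already cleared before the
#'   first layer (regrowth on them has no observed conversion in-window).
#' @param block_size block edge length in pixels for event drawing.
#' @param true_models tibble of ground-truth `(region, class, A, k, c)` rows;
#'   see [default_true_models()].
#' @param region_climate tibble of per-region driver anchors; see
#'   [default_region_climate()].
#' @param sw_gradient_amp,precip_gradient_amp,mcwd_gradient_amp amplitudes of
#'   the smooth within-region driver gradients (surface units).
#' @param noise_sd standard deviation of per-pixel AGC noise (Mg C ha-1).
#' @param seed integer seed; identical config + seed gives identical output.
#' @return an object of class `synth_config` (a validated list).
#' @export
synth_config <- function(grid_rows = 100, grid_cols = 100, pixel_size_m = 30,
                         years = 1985:2017,
                         clearing_rate = 0.02, abandonment_rate = 0.10,
                         reclearing_rate = 0.05, fire_rate = 0.02,
                         fire_start_year = 2001,
                         initial_anthropic_frac = 0.10,
                         block_size = 5,
                         true_models = default_true_models(),
                         region_climate = default_region_climate(),
                         sw_gradient_amp = 1.5, precip_gradient_amp = 30,
                         mcwd_gradient_amp = 6,
                         noise_sd = 8, seed = 1L) {
  stop_if_not(grid_rows >= 1 && grid_cols >= 1, "grid dimensions must be positive")
  stop_if_not(length(years) >= 2 && all(diff(years) == 1),
              "years must be a consecutive range of length >= 2")
  rates <- c(clearing_rate, abandonment_rate, reclearing_rate, fire_rate,
             initial_anthropic_frac)
  stop_if_not(all(rates >= 0 & rates <= 1), "all rates must lie in [0, 1]")
  stop_if_not(noise_sd >= 0, "noise_sd must be non-negative")
  stop_if_not(all(c(true_models$A, true_models$k, true_models$c) > 0),
              "true models require A, k, c > 0")
  cfg <- list(
    grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
    pixel_size_m = pixel_size_m, years = as.integer(years),
    clearing_rate = clearing_rate, abandonment_rate = abandonment_rate,
    reclearing_rate = reclearing_rate, fire_rate = fire_rate,
    fire_start_year = as.integer(fire_start_year),
    initial_anthropic_frac = initial_anthropic_frac,
    block_size = as.integer(block_size),
    true_models = true_models, region_climate = region_climate,
    sw_gradient_amp = sw_gradient_amp, precip_gradient_amp = precip_gradient_amp,
    mcwd_gradient_amp = mcwd_gradient_amp,
    noise_sd = noise_sd, seed = as.integer(seed)
  )
  class(cfg) <- "synth_config"
  cfg
}

#' Region membership map of the synthetic landscape
#'
#' Splits the grid into four quadrants; region ids follow the row order of
#' `config$region_climate` (ascending shortwave radiation).
#'
#' @param config a [synth_config()].
#' @return integer matrix of region ids (1..4).
#' @export
region_map <- function(config) {
  nr <- config$grid_rows; nc <- config$grid_cols
  top <- seq_len(nr) <= ceiling(nr / 2)
  left <- seq_len(nc) <= ceiling(nc / 2)
  reg <- matrix(0L, nr, nc)
  reg[top, left] <- 1L
  reg[top, !left] <- 2L
  reg[!top, left] <- 3L
  reg[!top, !left] <- 4L
  reg
}

block_index <- function(config) {
  bs <- config$block_size
  brow <- ((seq_len(config$grid_rows) - 1L) %/% bs) + 1L
  bcol <- ((seq_len(config$grid_cols) - 1L) %/% bs) + 1L
  nbr <- max(brow)
  list(id = outer(brow, (bcol - 1L) * nbr, `+`), n = nbr * max(bcol))
}

#' Simulate an annual land-cover stack with a known event history
#'
#' Runs the blockwise clearing/abandonment/re-clearing Markov chain over the
#' configured years and returns the binary forest (1) / anthropic (0) stack, a
#' per-pixel truth ledger of every event, annual burned-area masks, and the
#' exact final-year class/age/deforestation-count ground truth.
#'
#' @param config a [synth_config()].
#' @return an object of class `regrow_sim`: a list with elements `stack`
#'   (integer array rows x cols x years), `ledger` (tibble `pixel_id`, `year`,
#'   `event` with events `initial_anthropic`, `deforest_primary`,
#'   `deforest_secondary`, `regrow`, `fire`), `burned_masks` (named list of
#'   logical matrices, years >= `fire_start_year`), `truth` (final-year class,
#'   age, deforestation count, burned flag and region matrices) and `config`.
#' @export
simulate_landcover <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  nr <- config$grid_rows; nc <- config$grid_cols
  years <- config$years; ny <- length(years)
  blk <- block_index(config)
  bid <- blk$id; nblocks <- blk$n

  set.seed(config$seed)
  st <- matrix(2L, nr, nc)  # 2 old-growth, 1 secondary, 0 anthropic
  init_anthropic <- matrix(runif(nblocks)[bid] < config$initial_anthropic_frac,
                           nr, nc)
  st[init_anthropic] <- 0L

  age <- matrix(0L, nr, nc)
  defor <- matrix(0L, nr, nc)
  burned <- matrix(FALSE, nr, nc)
  stack <- array(NA_integer_, dim = c(nr, nc, ny),
                 dimnames = list(NULL, NULL, years))
  stack[, , 1] <- as.integer(st > 0L)
  burned_masks <- list()
  ev_pix <- list(); ev_year <- list(); ev_type <- list()
  push_event <- function(idx, yr, type) {
    n <- length(ev_pix) + 1L
    ev_pix[[n]] <<- idx
    ev_year[[n]] <<- rep.int(yr, length(idx))
    ev_type[[n]] <<- rep.int(type, length(idx))
  }
  if (any(init_anthropic))
    push_event(which(init_anthropic), years[1], "initial_anthropic")

  for (t in 2:ny) {
    yr <- years[t]
    # one uniform per block per decision channel, drawn every year in a fixed
    # order so the random stream is identical across rate settings
    u_clear <- matrix(runif(nblocks)[bid], nr, nc)
    u_aband <- matrix(runif(nblocks)[bid], nr, nc)
    u_reclear <- matrix(runif(nblocks)[bid], nr, nc)
    u_fire <- matrix(runif(nblocks)[bid], nr, nc)

    clear_p <- st == 2L & u_clear < config$clearing_rate
    clear_s <- st == 1L & u_reclear < config$reclearing_rate
    regrow <- st == 0L & u_aband < config$abandonment_rate

    if (any(clear_p)) push_event(which(clear_p), yr, "deforest_primary")
    if (any(clear_s)) push_event(which(clear_s), yr, "deforest_secondary")
    if (any(regrow)) push_event(which(regrow), yr, "regrow")

    cleared <- clear_p | clear_s
    st[cleared] <- 0L
    st[regrow] <- 1L
    age[cleared] <- 0L
    age[st == 1L] <- age[st == 1L] + 1L
    defor[cleared] <- defor[cleared] + 1L

    if (yr >= config$fire_start_year) {
      fire <- st == 1L & u_fire < config$fire_rate
      if (any(fire)) push_event(which(fire), yr, "fire")
      burned <- burned | fire
      burned_masks[[as.character(yr)]] <- fire
    }
    stack[, , t] <- as.integer(st > 0L)
  }

  cls <- matrix("anthropic", nr, nc)
  cls[st == 2L] <- "old_growth"
  cls[st == 1L] <- "secondary"
  sec <- st == 1L
  age_out <- matrix(NA_integer_, nr, nc); age_out[sec] <- age[sec]
  # the original conversion counts as 1 even when it predates the window
  def_out <- matrix(NA_integer_, nr, nc); def_out[sec] <- pmax(defor[sec], 1L)
  burned_out <- matrix(NA, nr, nc); burned_out[sec] <- burned[sec]

  ledger <- tibble(
    pixel_id = as.integer(unlist(ev_pix)),
    year = as.integer(unlist(ev_year)),
    event = unlist(ev_type)
  )
  structure(list(
    stack = stack, ledger = ledger, burned_masks = burned_masks,
    truth = list(class = cls, age = age_out, defor_count = def_out,
                 burned = burned_out, region = region_map(config)),
    config = config
  ), class = "regrow_sim")
}

#' Burned-area mask for one year
#'
#' @param sim a `regrow_sim` from [simulate_landcover()].
#' @param year calendar year; must be on or after the configured fire start.
#' @return logical matrix of pixels that burned in that year.
#' @export
get_burned_mask <- function(sim, year) {
  if (year < sim$config$fire_start_year)
    stop("burned-area observations start in ", sim$config$fire_start_year,
         "; year ", year, " requested", call. = FALSE)
  m <- sim$burned_masks[[as.character(year)]]
  if (is.null(m)) stop("no burned mask simulated for year ", year, call. = FALSE)
  m
}

#' Simulate the driver surfaces
#'
#' Builds the continuous driver rasters on the same grid as the land-cover
#' stack: mean annual shortwave radiation, a 12-month precipitation
#' climatology (months 4-9 form a dry season whose depth sets the maximum
#' cumulative water deficit), mean annual precipitation, and soil cation
#' concentration (a smooth ramp unrelated to regrowth).  Each region receives
#' its anchor value from `config$region_climate` plus a smooth gradient, so
#' clustering on the climate drivers can recover the planted regions.
#'
#' @param config a [synth_config()].
#' @return list with matrices `sw` (W m-2), `precip_annual` (mm yr-1), `scc`
#'   (cmol(+) kg-1), array `precip_monthly` (rows x cols x 12, mm month-1),
#'   and the `region` map.
#' @export
simulate_drivers <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  nr <- config$grid_rows; nc <- config$grid_cols
  set.seed(config$seed + 1L)
  reg <- region_map(config)
  anchors <- config$region_climate
  gx <- matrix(rep(seq(-1, 1, length.out = nc), each = nr), nr, nc)
  gy <- matrix(rep(seq(-1, 1, length.out = nr), times = nc), nr, nc)
  # centre the gradients within each region so the anchors are exactly the
  # regional means
  for (r in unique(as.vector(reg))) {
    gx[reg == r] <- gx[reg == r] - mean(gx[reg == r])
    gy[reg == r] <- gy[reg == r] - mean(gy[reg == r])
  }

  sw <- matrix(anchors$sw[reg], nr, nc) + config$sw_gradient_amp * gx
  scc <- 0.1 + 0.45 * (gx + 1) + matrix(rnorm(nr * nc, 0, 0.03), nr, nc)
  scc <- pmax(scc, 0.01)

  # dry-season depth carries the MCWD target: six dry months at p_dry give
  # MCWD = 6 * (p_dry - 100); wet months absorb the rest of annual precip
  mcwd_t <- matrix(anchors$mcwd[reg], nr, nc) + config$mcwd_gradient_amp * gy
  mcwd_t <- pmin(mcwd_t, 0)
  p_dry <- 100 + mcwd_t / 6
  annual_t <- matrix(anchors$precip[reg], nr, nc) + config$precip_gradient_amp * gx
  p_wet <- (annual_t - 6 * p_dry) / 6
  stop_if_not(all(p_wet > 100),
              "precipitation anchors too low for a deficit-free wet season")
  precip_monthly <- array(NA_real_, c(nr, nc, 12))
  for (m in 1:12) precip_monthly[, , m] <- if (m %in% 4:9) p_dry else p_wet

  list(sw = sw, precip_monthly = precip_monthly,
       precip_annual = 6 * p_dry + 6 * p_wet, scc = scc, region = reg)
}

true_model_table <- function(config) {
  tm <- config$true_models
  setNames(split(tm, seq_len(nrow(tm))), paste0(tm$region, ".", tm$class))
}

#' Simulate the aboveground-biomass raster from the ground truth
#'
#' Inverts the analysis: every secondary pixel carries twice (biomass:carbon =
#' 2:1) the Chapman-Richards carbon of its true `(region, disturbance class)`
#' model at its true age, plus Gaussian noise; old-growth pixels carry twice
#' the regional asymptote plus noise; anthropic pixels carry low uniform
#' background biomass.
#'
#' @param sim a `regrow_sim`.
#' @param config configuration (defaults to `sim$config`).
#' @return matrix of AGB in Mg ha-1 (non-negative).
#' @export
simulate_agc <- function(sim, config = sim$config) {
  nr <- config$grid_rows; nc <- config$grid_cols
  set.seed(config$seed + 2L)
  tr <- sim$truth
  agb <- matrix(NA_real_, nr, nc)

  ant <- which(tr$class == "anthropic")
  agb[ant] <- runif(length(ant), 0, 10)

  og <- which(tr$class == "old_growth")
  A_og <- config$region_climate$A_old_growth
  agb[og] <- 2 * (A_og[tr$region[og]] + rnorm(length(og), 0, config$noise_sd))

  sec <- which(tr$class == "secondary")
  if (length(sec)) {
    cls <- ifelse(tr$defor_count[sec] >= 2L,
                  ifelse(tr$burned[sec], "repeated_burnt", "repeated_not_burnt"),
                  ifelse(tr$burned[sec], "single_burnt", "single_not_burnt"))
    key <- paste0(tr$region[sec], ".", cls)
    tab <- true_model_table(config)
    missing <- setdiff(unique(key), names(tab))
    if (length(missing))
      stop("no true model for (region.class): ", paste(missing, collapse = ", "),
           call. = FALSE)
    A <- vapply(tab, `[[`, numeric(1), "A")[key]
    k <- vapply(tab, `[[`, numeric(1), "k")[key]
    cc <- vapply(tab, `[[`, numeric(1), "c")[key]
    y <- cr_curve(tr$age[sec], A, k, cc)
    agb[sec] <- 2 * (y + rnorm(length(sec), 0, config$noise_sd))
  }
  pmax(agb, 0)
}

#' Simulate a flat patch-record table with a planted age signal
#'
#' Produces patch records in which aboveground carbon depends only on forest
#' age (through a Chapman-Richards curve plus noise) while the six driver
#' columns are pure noise; used to check that the importance ranking recovers
#' the planted signal.
#'
#' @param n number of records.
#' @param A,k,c curve parameters of the age signal.
#' @param noise_sd AGC noise (Mg C ha-1).
#' @param seed integer seed.
#' @return tibble with columns `agc`, `forest_age`, `sw_radiation`,
#'   `precipitation`, `mcwd`, `scc`, `burn_count`, `deforestation_count`.
#' @export
simulate_importance_records <- function(n = 30000, A = 120, k = 0.043, c = 1.3,
                                        noise_sd = 8, seed = 1L) {
  set.seed(seed)
  age <- sample(1:32, n, replace = TRUE)
  tibble(
    agc = pmax(cr_curve(age, A, k, c) + rnorm(n, 0, noise_sd), 0),
    forest_age = age,
    sw_radiation = runif(n, 160, 195),
    precipitation = runif(n, 1800, 2300),
    mcwd = runif(n, -400, 0),
    scc = runif(n, 0.05, 1),
    burn_count = sample(0:3, n, replace = TRUE),
    deforestation_count = sample(1:4, n, replace = TRUE)
  )
}
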