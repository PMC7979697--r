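#' Fit the 16 regional disturbance-class growth models
#'
#' For every (region, disturbance class) combination with at least
#' `min_ages` distinct patch ages: build the bias-corrected chronosequence
#' table, take the region's bias-corrected old-growth median AGC as the fixed
#' asymptote, and fit the Chapman-Richards curve.  Combinations with too few
#' ages are skipped and listed in the `skipped` attribute.
#'
#' @param records patch records with columns `region`, `class`, `age`, `agc`.
#' @param agc_raster AGC matrix (Mg C ha-1).
#' @param history `forest_history` (provides the old-growth mask).
#' @param region_raster integer region matrix.
#' @param k_regions number of regions (default 4).
#' @param min_ages minimum distinct ages per group (default 3).
#' @param classes disturbance classes to fit (default all four).
#' @param ci,boot_reps,seed forwarded to [fit_chapman_richards()].
#' @return named list of `cr_fit` objects keyed by [model_key()], with a
#'   `skipped` attribute naming combinations without a fit.
#' @export
fit_regional_models <- function(records, agc_raster, history, region_raster,
                                k_regions = 4, min_ages = 3,
                                classes = DISTURBANCE_CLASSES,
                                ci = "asymptotic", boot_reps = 1000,
                                seed = 1L) {
  og_mask <- history$class == "old_growth"
  fits <- list()
  skipped <- character()
  for (r in seq_len(k_regions)) {
    for (cls in classes) {
      key <- model_key(r, cls)
      grp <- records[records$region == r & records$class == cls, ]
      if (nrow(grp) == 0 || length(unique(grp$age)) < min_ages) {
        skipped <- c(skipped, key)
        next
      }
      tab <- build_age_table(grp, group = key)
      A <- old_growth_asymptote(agc_raster, og_mask, region_raster == r,
                                bias_offset = attr(tab, "bias_offset"))
      fits[[key]] <- tryCatch(
        fit_chapman_richards(tab, A, ci = ci, boot_reps = boot_reps,
                             seed = seed, group = key),
        error = function(e) NULL
      )
      if (is.null(fits[[key]])) {
        fits[[key]] <- NULL
        skipped <- c(skipped, key)
      }
    }
  }
  attr(fits, "skipped") <- skipped
  fits
}

# fill gaps in a 16-model set with the region's no-disturbance fit so the
# per-pixel accounting stays total; the gap list is preserved
complete_model_set <- function(fits, k_regions = 4) {
  filled <- character()
  for (r in seq_len(k_regions)) {
    base <- fits[[model_key(r, "single_not_burnt")]]
    if (is.null(base)) next
    for (cls in DISTURBANCE_CLASSES) {
      key <- model_key(r, cls)
      if (is.null(fits[[key]])) {
        fits[[key]] <- base
        filled <- c(filled, key)
      }
    }
  }
  attr(fits, "filled") <- filled
  fits
}

#' Run the full synthetic-landscape analysis pipeline
#'
#' Chains every stage on one generated landscape: simulate the land-cover
#' stack and drivers, reconstruct the forest history, delineate patches,
#' derive the AGC raster, compute MCWD, cluster the climate regions, build
#' patch records, fit the 16 regional growth models, and (optionally) run the
#' 2016-to-2017 carbon accounting, the no-disturbance counterfactual, the
#' preservation scenarios and the driver-importance ranking.
#'
#' @param config a [synth_config()].
#' @param min_area_m2 minimum patch area (default 9000).
#' @param k_regions number of climate regions (default 4).
#' @param connectivity patch connectivity, 8 or 4.
#' @param ci,boot_reps confidence-interval method for the growth fits.
#' @param do_accounting run the stock/net-change/counterfactual stage.
#' @param do_scenarios run the five preservation scenarios to 2030.
#' @param do_importance run the driver-importance ranking (slowest stage).
#' @param importance_n subsample size per importance iteration; capped at the
#'   number of patch records.
#' @return a list with elements `sim`, `drivers`, `history`, `patches`,
#'   `agc`, `mcwd`, `regions`, `records`, `fits` and, when enabled,
#'   `accounting` (list: `stock_2017`, `ledger`, `potential_2017`,
#'   `reduction_pct`), `scenarios` (list of `scenario_projection`s) and
#'   `importance`.
#' @export
run_pipeline <- function(config = synth_config(), min_area_m2 = 9000,
                         k_regions = 4, connectivity = 8,
                         ci = "asymptotic", boot_reps = 1000,
                         fit_classes = DISTURBANCE_CLASSES,
                         do_accounting = TRUE, do_scenarios = TRUE,
                         do_importance = FALSE, importance_n = 2500) {
  sim <- simulate_landcover(config)
  drv <- simulate_drivers(config)
  hist_b <- classify_history(sim$stack, sim$burned_masks)
  agc <- agb_to_agc(simulate_agc(sim))
  mcwd <- compute_mcwd(drv$precip_monthly)
  regions <- kmeans_regions(
    list(mcwd = mcwd, sw = drv$sw, precip = drv$precip_annual),
    mask = hist_b$class == "secondary", k = k_regions,
    seed = config$seed + 3L)
  patches <- label_patches(hist_b, min_area_m2 = min_area_m2,
                           pixel_size_m = config$pixel_size_m,
                           connectivity = connectivity,
                           region_raster = regions$region)
  records <- attach_patch_records(
    patches, agc,
    drivers = list(sw_radiation = drv$sw, precipitation = drv$precip_annual,
                   mcwd = mcwd, scc = drv$scc),
    region_raster = regions$region)
  fits <- fit_regional_models(records, agc, hist_b, regions$region,
                              k_regions = k_regions, classes = fit_classes,
                              ci = ci, boot_reps = boot_reps,
                              seed = config$seed + 4L)
  out <- list(sim = sim, drivers = drv, history = hist_b, patches = patches,
              agc = agc, mcwd = mcwd, regions = regions, records = records,
              fits = fits, config = config)

  if (do_accounting || do_scenarios) {
    full <- complete_model_set(fits, k_regions)
    out$model_set <- full
    px_ha <- (config$pixel_size_m / 100)^2
    if (do_accounting) {
      ny <- length(config$years)
      prev_masks <- sim$burned_masks[
        as.integer(names(sim$burned_masks)) < config$years[ny]]
      hist_a <- classify_history(sim$stack[, , -ny, drop = FALSE], prev_masks)
      actual <- total_stock(hist_b, regions$region, full, px_ha)
      potential <- potential_stock_no_disturbance(hist_b, regions$region,
                                                  full, px_ha)
      out$accounting <- list(
        stock_2017 = actual,
        ledger = annual_net_change(hist_a, hist_b, regions$region, full,
                                   px_ha, rasters = TRUE),
        potential_2017 = potential,
        reduction_pct = disturbance_reduction(actual, potential)
      )
    }
    if (do_scenarios) {
      out$scenarios <- lapply(names(SCENARIO_THRESHOLDS), function(s)
        project_scenario(hist_b, regions$region, full, scenario = s,
                         pixel_area_ha = px_ha, n_boot = 0))
      names(out$scenarios) <- names(SCENARIO_THRESHOLDS)
    }
  }
  if (do_importance) {
    records$burned_num <- as.numeric(records$burned)
    out$importance <- rank_importance(
      records, response = "agc",
      predictors = c("age", "sw_radiation", "precipitation", "mcwd", "scc",
                     "burned_num", "defor_count"),
      strata = "region",
      sample_n = min(importance_n, nrow(records)),
      seed = config$seed + 5L)
  }
  out
}

#' Recover the no-disturbance growth parameters across replicates
#'
#' The parameter-recovery experiment: generate `n_replicates` independent
#' synthetic landscapes from the configured ground-truth model set, run the
#' full pipeline (history, patches, AGC, clustering, chronosequence tables,
#' constrained fits) on each, and compare the fitted no-disturbance `(k, c)`
#' of every region with the generator's truth.
#'
#' @param n_replicates number of landscapes (default 100).
#' @param seed base seed; replicate i uses `seed + i`.
#' @param grid_rows,grid_cols landscape size (default 100 x 100).
#' @param ci,boot_reps confidence-interval method for the no-disturbance
#'   fits (default: asymptotic, which is better calibrated than the residual
#'   bootstrap at the short tables this experiment produces).
#' @param ... further arguments to [synth_config()].
#' @return tibble with one row per replicate x region: the true and fitted
#'   `k` and `c`, their absolute relative errors, and whether each truth lies
#'   inside the fit's 95% confidence interval.
#' @export
recover_growth_parameters <- function(n_replicates = 100, seed = 1L,
                                      grid_rows = 100, grid_cols = 100,
                                      ci = "asymptotic", boot_reps = 300, ...) {
  rows <- list()
  for (rep in seq_len(n_replicates)) {
    cfg <- synth_config(grid_rows = grid_rows, grid_cols = grid_cols,
                        seed = seed + rep, ...)
    pl <- run_pipeline(cfg, do_accounting = FALSE, do_scenarios = FALSE,
                       fit_classes = "single_not_burnt",
                       ci = ci, boot_reps = boot_reps)
    truth <- cfg$true_models[cfg$true_models$class == "single_not_burnt", ]
    for (r in truth$region) {
      f <- pl$fits[[model_key(r, "single_not_burnt")]]
      if (is.null(f)) next
      kt <- truth$k[truth$region == r]
      ct <- truth$c[truth$region == r]
      rows[[length(rows) + 1L]] <- tibble(
        replicate = rep, region = r,
        k_true = kt, k_hat = f$k, c_true = ct, c_hat = f$c,
        k_rel_err = abs(f$k - kt) / kt,
        c_rel_err = abs(f$c - ct) / ct,
        k_in_ci = f$ci95["k", "lower"] <= kt & kt <= f$ci95["k", "upper"],
        c_in_ci = f$ci95["c", "lower"] <= ct & ct <= f$ci95["c", "upper"]
      )
    }
  }
  dplyr::bind_rows(rows)
}
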