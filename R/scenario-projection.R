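SCENARIO_THRESHOLDS <- c(all = 0, age5plus = 5, age10plus = 10,
                         age15plus = 15, age20plus = 20)

#' Project the standing secondary-forest sink under a preservation scenario
#'
#' Ages the secondary forest standing in the base year forward to the horizon
#' under one of five preservation scenarios: preserve all forests, or only
#' those at least 5, 10, 15 or 20 years old in the base year.  Preserved
#' pixels accrue carbon along their (region, disturbance class) curve at
#' `Y(age + delta)`; non-preserved pixels are removed at the base year and
#' contribute nothing (their standing stock is excluded, not booked as an
#' emission).  A 95% band is propagated by re-evaluating the projection at
#' bootstrap `(k, c)` draws when the fits carry them.
#'
#' @param history `forest_history` of the base year.
#' @param region_raster integer region matrix.
#' @param fits named list of `cr_fit` objects keyed by [model_key()].
#' @param scenario one of `"all"`, `"age5plus"`, `"age10plus"`,
#'   `"age15plus"`, `"age20plus"`.
#' @param base_year first calendar year (default 2017).
#' @param horizon_end last calendar year (default 2030).
#' @param pixel_area_ha pixel area in hectares (default 0.09).
#' @param n_boot number of bootstrap draws used for the band (default 200,
#'   capped at what the fits carry); 0 disables the band.
#' @param seed seed for sampling bootstrap draws.
#' @return an object of class `scenario_projection`: list with `scenario`,
#'   `preserved_area_ha`, `table` (tibble: `year`, `stock_TgC`,
#'   `accumulation_TgC_yr` and, when available, `stock_lower`/`stock_upper`),
#'   and `mean_accumulation_TgC_yr`.
#' @export
project_scenario <- function(history, region_raster, fits,
                             scenario = c("all", "age5plus", "age10plus",
                                          "age15plus", "age20plus"),
                             base_year = 2017, horizon_end = 2030,
                             pixel_area_ha = 0.09, n_boot = 200, seed = 1L) {
  scenario <- match.arg(scenario)
  stop_if_not(horizon_end > base_year, "horizon must extend past the base year")
  thr <- SCENARIO_THRESHOLDS[[scenario]]

  pk <- pixel_keys(history, region_raster)
  keep <- pk$age >= thr
  key <- pk$key[keep]; age <- pk$age[keep]
  years <- base_year:horizon_end
  nyr <- length(years)

  stock_path <- function(get_par) {
    vapply(seq_len(nyr) - 1L, function(delta) {
      s <- 0
      for (kk in unique(key)) {
        i <- key == kk
        par <- get_par(kk)
        s <- s + sum(cr_curve(age[i] + delta, par[1], par[2], par[3]))
      }
      s * pixel_area_ha / MG_PER_TG
    }, numeric(1))
  }

  stock <- stock_path(function(kk) {
    f <- fits[[kk]]
    if (is.null(f)) stop("unassigned pixels: no fit for ", kk, call. = FALSE)
    c(f$A, f$k, f$c)
  })

  tab <- tibble(year = years, stock_TgC = stock,
                accumulation_TgC_yr = c(NA, diff(stock)))

  have_boot <- n_boot > 0 &&
    all(vapply(unique(key), function(kk) !is.null(fits[[kk]]$boot), logical(1)))
  if (length(key) && have_boot) {
    set.seed(seed)
    nb <- min(n_boot, min(vapply(unique(key),
                                 function(kk) nrow(fits[[kk]]$boot), numeric(1))))
    draws <- matrix(NA_real_, nb, nyr)
    rows <- lapply(unique(key), function(kk)
      sample(nrow(fits[[kk]]$boot), nb, replace = TRUE))
    names(rows) <- unique(key)
    for (b in seq_len(nb)) {
      draws[b, ] <- stock_path(function(kk) {
        f <- fits[[kk]]
        c(f$A, f$boot[rows[[kk]][b], "k"], f$boot[rows[[kk]][b], "c"])
      })
    }
    tab$stock_lower <- apply(draws, 2, quantile, 0.025)
    tab$stock_upper <- apply(draws, 2, quantile, 0.975)
  }

  structure(list(
    scenario = scenario,
    preserved_area_ha = sum(keep) * pixel_area_ha,
    table = tab,
    mean_accumulation_TgC_yr = (stock[nyr] - stock[1]) / (nyr - 1)
  ), class = "scenario_projection")
}

#' @export
print.scenario_projection <- function(x, ...) {
  cat(sprintf(
    "Scenario '%s': %.1f ha preserved, mean accumulation %.4g Tg C yr-1\n",
    x$scenario, x$preserved_area_ha, x$mean_accumulation_TgC_yr))
  invisible(x)
}

#' NDC emissions target in carbon units
#'
#' Converts a percentage reduction of the 2005 baseline (2.1 GtCO2e yr-1)
#' into the implied net-emissions target in Tg C yr-1:
#' `baseline x (1 - reduction) x 1000 Tg/Gt x 12/44`.
#'
#' @param reduction_fraction pledged reduction, in `[0, 1)` (0 converts the
#'   baseline itself).
#' @param baseline_GtCO2e baseline emissions (default 2.1 GtCO2e yr-1).
#' @return target in Tg C yr-1 (unrounded).
#' @export
ndc_target <- function(reduction_fraction, baseline_GtCO2e = 2.1) {
  stop_if_not(reduction_fraction >= 0 && reduction_fraction < 1,
              "reduction_fraction must lie in [0, 1)")
  baseline_GtCO2e * (1 - reduction_fraction) * 1000 * 12 / 44
}

#' Sink contribution relative to an emissions target
#'
#' @param mean_accumulation_TgC_yr projected annual carbon accumulation.
#' @param target_TgC_yr emissions target (> 0).
#' @return contribution in percent.
#' @export
contribution_percent <- function(mean_accumulation_TgC_yr, target_TgC_yr) {
  stop_if_not(target_TgC_yr > 0, "target must be positive")
  100 * mean_accumulation_TgC_yr / target_TgC_yr
}

#' Relative spread between two preservation scenarios
#'
#' Percentage difference between the annual accumulation of a reference
#' scenario and a less ambitious one, relative to the reference.
#'
#' @param accumulation_ref,accumulation_alt annual accumulations
#'   (Tg C yr-1); the reference must be positive.
#' @return spread in percent, `100 * (ref - alt) / ref`.
#' @export
preservation_spread_percent <- function(accumulation_ref, accumulation_alt) {
  stop_if_not(accumulation_ref > 0, "reference accumulation must be positive")
  100 * (accumulation_ref - accumulation_alt) / accumulation_ref
}
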