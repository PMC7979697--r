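#' Convert aboveground biomass to aboveground carbon
#'
#' Applies the 2:1 biomass-to-carbon ratio used throughout the analysis.
#'
#' @param agb aboveground biomass (Mg ha-1), non-negative.
#' @return aboveground carbon (Mg C ha-1).
#' @export
agb_to_agc <- function(agb) {
  stop_if_not(all(agb >= 0, na.rm = TRUE), "AGB must be non-negative")
  agb / 2
}

#' Modal aboveground carbon of a patch
#'
#' Most frequent AGC value among the raster cells a patch overlaps.  Because
#' biomass rasters are near-continuous, values are first binned (1 Mg C ha-1
#' by default) so the mode is well defined; ties break toward the smaller
#' value.
#'
#' @param pixels linear indices of the patch's pixels.
#' @param agc_raster AGC matrix (Mg C ha-1).
#' @param bin_width bin width in Mg C ha-1 (default 1).
#' @param tie tie-break direction (default `"smallest"`).
#' @return modal AGC, or `NA` (with a warning) when no valid cell overlaps.
#' @export
zonal_modal_agc <- function(pixels, agc_raster, bin_width = 1,
                            tie = "smallest") {
  vals <- agc_raster[pixels]
  vals <- vals[!is.na(vals)]
  if (!length(vals)) {
    warning("patch has no valid AGC overlap; dropping", call. = FALSE)
    return(NA_real_)
  }
  modal_value(round(vals / bin_width) * bin_width, tie = tie)
}

#' Mean driver value over a patch
#'
#' @param pixels linear indices of the patch's pixels.
#' @param surface driver matrix.
#' @return arithmetic mean over valid overlapped cells (`NA` if none).
#' @export
zonal_mean_driver <- function(pixels, surface) {
  vals <- surface[pixels]
  if (all(is.na(vals))) return(NA_real_)
  mean(vals, na.rm = TRUE)
}

#' Build the per-patch record table
#'
#' Attaches the modal AGC, mean driver values, the region id (modal over
#' member pixels) and the disturbance class to every patch.  Patches without
#' valid AGC overlap are dropped with a warning.
#'
#' @param patches a `patch_set` from [label_patches()].
#' @param agc_raster AGC matrix (Mg C ha-1).
#' @param drivers named list of driver matrices to summarise by patch mean.
#' @param region_raster optional integer region matrix.
#' @param bin_width AGC mode bin width (default 1 Mg C ha-1).
#' @return tibble of patch records with columns `patch_id`, `age`, `agc`,
#'   one column per driver, `burned`, `repeated`, `class` and (if supplied)
#'   `region`.
#' @export
attach_patch_records <- function(patches, agc_raster, drivers = list(),
                                 region_raster = NULL, bin_width = 1) {
  stopifnot(inherits(patches, "patch_set"))
  rec <- tibble(
    patch_id = patches$patch_id,
    age = patches$age,
    agc = vapply(patches$pixels, zonal_modal_agc, numeric(1),
                 agc_raster = agc_raster, bin_width = bin_width),
    burned = patches$burned,
    repeated = patches$repeated,
    defor_count = patches$defor_count,
    n_pixels = patches$n_pixels
  )
  for (nm in names(drivers))
    rec[[nm]] <- vapply(patches$pixels, zonal_mean_driver, numeric(1),
                        surface = drivers[[nm]])
  if (!is.null(region_raster))
    rec$region <- vapply(patches$pixels,
                         function(p) as.integer(modal_value(region_raster[p])),
                         integer(1))
  rec$class <- disturbance_class(rec$repeated, rec$burned)
  rec[!is.na(rec$agc), ]
}

#' Bias-corrected median AGC by age for one group
#'
#' The space-for-time chronosequence table: median patch AGC per age, shifted
#' so the smallest median is exactly 0 (the bias correction makes a
#' one-year-old stand start at or near zero carbon).  The subtracted offset is
#' reported so curves can be mapped back to raw AGC.
#'
#' @param records patch records of a single group (needs columns `age`,
#'   `agc`).
#' @param group label stored with the table.
#' @param bias_correct subtract the smallest median (default `TRUE`); with
#'   `FALSE` the offset is 0 and `median_agc` equals the raw medians.
#' @return an object of class `age_agc_table`: tibble with columns `age`,
#'   `median_agc` (bias-corrected), `median_agc_raw`, `n_patches`, plus
#'   attributes `bias_offset` and `group`.
#' @export
build_age_table <- function(records, group = "all", bias_correct = TRUE) {
  stop_if_not(nrow(records) > 0, "empty group")
  stop_if_not(length(unique(records$age)) >= 3,
              "need >= 3 distinct ages to build a chronosequence table")
  agg <- dplyr::summarise(
    dplyr::group_by(records, .data$age),
    median_agc_raw = median(.data$agc),
    n_patches = dplyr::n(),
    .groups = "drop"
  )
  agg <- dplyr::arrange(agg, .data$age)
  offset <- if (bias_correct) min(agg$median_agc_raw) else 0
  agg$median_agc <- agg$median_agc_raw - offset
  out <- agg[, c("age", "median_agc", "median_agc_raw", "n_patches")]
  attr(out, "bias_offset") <- offset
  attr(out, "group") <- group
  class(out) <- c("age_agc_table", class(out))
  out
}
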