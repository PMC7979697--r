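#' Maximum cumulative water deficit of one monthly series
#'
#' Runs the water-deficit recursion over one or more years of monthly
#' precipitation: within each 12-month window the cumulative deficit starts
#' afresh, accumulates `P - E` with a fixed evapotranspiration `E` (100 mm
#' month-1), is capped at 0, and the year's MCWD is its most negative value.
#' Multiple years are averaged.
#'
#' @param precip numeric vector of monthly precipitation (mm), length a
#'   multiple of 12; the window starts at `start_month` within each year
#'   (1 = calendar year, other values give a hydrological-year anchor by
#'   rotating the series).
#' @param evapotranspiration fixed monthly evapotranspiration (default 100).
#' @param start_month first month of the deficit window (default 1).
#' @return mean annual MCWD in mm yr-1 (always <= 0).
#' @export
mcwd_series <- function(precip, evapotranspiration = 100, start_month = 1) {
  stop_if_not(length(precip) >= 12 && length(precip) %% 12 == 0,
              "precip must contain whole years (multiples of 12 months)")
  stop_if_not(all(precip >= 0), "precipitation must be non-negative")
  if (start_month != 1) {
    shift <- start_month - 1
    precip <- c(precip[-seq_len(shift)], precip[seq_len(shift)])
  }
  yrs <- matrix(precip, nrow = 12)
  mcwd_year <- apply(yrs, 2, function(p) {
    cwd <- 0
    worst <- 0
    for (m in 1:12) {
      cwd <- min(0, cwd + p[m] - evapotranspiration)
      worst <- min(worst, cwd)
    }
    worst
  })
  mean(mcwd_year)
}

#' Mean annual MCWD surface from gridded monthly precipitation
#'
#' Applies the deficit recursion to every pixel of a monthly precipitation
#' array, vectorised over pixels.
#'
#' @param precip_monthly array rows x cols x (12 * n_years) of monthly
#'   precipitation (mm); a single 12-month climatology stands for all years.
#' @param evapotranspiration fixed monthly evapotranspiration (default 100).
#' @param start_month first month of the deficit window (default 1, calendar).
#' @return matrix of mean annual MCWD (mm yr-1), all values <= 0.
#' @export
compute_mcwd <- function(precip_monthly, evapotranspiration = 100,
                         start_month = 1) {
  d <- dim(precip_monthly)
  stop_if_not(length(d) == 3 && d[3] %% 12 == 0,
              "precip_monthly must be rows x cols x (12 * n_years)")
  stop_if_not(!anyNA(precip_monthly) && all(precip_monthly >= 0),
              "precipitation must be complete and non-negative")
  npix <- d[1] * d[2]
  nm <- d[3]
  m <- matrix(precip_monthly, npix, nm)
  if (start_month != 1) {
    shift <- start_month - 1
    m <- m[, c((shift + 1):nm, seq_len(shift)), drop = FALSE]
  }
  acc <- matrix(0, npix, nm / 12)
  for (y in seq_len(nm / 12)) {
    cwd <- rep(0, npix)
    worst <- rep(0, npix)
    for (k in 1:12) {
      cwd <- pmin(0, cwd + m[, (y - 1) * 12 + k] - evapotranspiration)
      worst <- pmin(worst, cwd)
    }
    acc[, y] <- worst
  }
  matrix(rowMeans(acc), d[1], d[2])
}

#' Nearest-neighbour resampling between aligned grids
#'
#' Resamples a raster to a different pixel size by nearest neighbour (values
#' are replicated or subsetted, never averaged), assuming both grids share the
#' top-left origin.
#'
#' @param src source matrix.
#' @param src_pixel_size source pixel edge length.
#' @param dst_pixel_size target pixel edge length.
#' @param dst_dim optional target dimensions `c(rows, cols)`; defaults to the
#'   source extent divided by the target pixel size.
#' @return matrix on the target grid.
#' @export
resample_to_grid <- function(src, src_pixel_size, dst_pixel_size,
                             dst_dim = NULL) {
  stop_if_not(src_pixel_size > 0 && dst_pixel_size > 0,
              "pixel sizes must be positive")
  if (is.null(dst_dim))
    dst_dim <- round(dim(src) * src_pixel_size / dst_pixel_size)
  ri <- pmin(pmax(ceiling(((seq_len(dst_dim[1]) - 0.5) * dst_pixel_size) /
                            src_pixel_size), 1L), nrow(src))
  ci <- pmin(pmax(ceiling(((seq_len(dst_dim[2]) - 0.5) * dst_pixel_size) /
                            src_pixel_size), 1L), ncol(src))
  src[ri, ci, drop = FALSE]
}

#' Bin a continuous driver into ordered categories
#'
#' Cuts patch-level driver values into categories at explicit thresholds or at
#' percentiles (default quartiles), using half-open intervals `[b_i, b_{i+1})`
#' so every finite value receives exactly one label.  The thresholds used are
#' attached as the `breaks` attribute.
#'
#' @param values numeric vector (one value per patch).
#' @param breaks explicit increasing thresholds, or `NULL` to use percentiles.
#' @param probs percentile probabilities when `breaks` is `NULL`
#'   (default `c(0.25, 0.5, 0.75)`).
#' @param labels category labels, lowest first; defaults to
#'   `very_low/low/moderate/high` for three thresholds, or
#'   `low/moderate/high` for two.
#' @return factor of length `length(values)` with a `breaks` attribute.
#' @export
bin_driver <- function(values, breaks = NULL, probs = c(0.25, 0.5, 0.75),
                       labels = NULL) {
  if (is.null(breaks)) {
    stop_if_not(length(unique(values[is.finite(values)])) >= 4,
                "percentile binning needs >= 4 distinct values")
    breaks <- unname(quantile(values, probs = probs, na.rm = TRUE, type = 7))
  }
  stop_if_not(!is.unsorted(breaks, strictly = FALSE),
              "explicit breaks must be sorted increasingly")
  breaks <- unique(breaks)
  if (is.null(labels)) {
    labels <- switch(as.character(length(breaks)),
                     "3" = c("very_low", "low", "moderate", "high"),
                     "2" = c("low", "moderate", "high"),
                     paste0("class_", seq_len(length(breaks) + 1)))
  }
  stop_if_not(length(labels) == length(breaks) + 1,
              "need one more label than breaks")
  lev <- findInterval(values, breaks) + 1L  # [b_i, b_{i+1})
  out <- factor(labels[lev], levels = labels)
  attr(out, "breaks") <- breaks
  out
}
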