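MG_PER_TG <- 1e6

pixel_keys <- function(history, region_raster) {
  sec <- which(history$class == "secondary")
  cls <- disturbance_class(history$defor_count[sec] >= 2L,
                           history$burned[sec] %in% TRUE)
  list(idx = sec, key = model_key(region_raster[sec], cls),
       age = history$age[sec])
}

predict_by_key <- function(key, age, fits) {
  missing <- setdiff(unique(key), names(fits))
  if (length(missing))
    stop("unassigned pixels: no fit for ", paste(missing, collapse = ", "),
         call. = FALSE)
  out <- numeric(length(key))
  for (k in unique(key)) {
    i <- key == k
    out[i] <- predict_agc(fits[[k]], age[i])
  }
  out
}

#' Per-pixel secondary-forest carbon (Mg per pixel)
#'
#' Scores every secondary pixel with its (region, disturbance class) growth
#' model at the pixel's own age and multiplies by the pixel area.
#'
#' @param history a `forest_history`.
#' @param region_raster integer region matrix.
#' @param fits named list of `cr_fit` objects keyed by [model_key()].
#' @param pixel_area_ha pixel area in hectares (default 0.09 for 30 m).
#' @return matrix of Mg C per pixel (0 outside secondary forest).
#' @export
stock_raster <- function(history, region_raster, fits, pixel_area_ha = 0.09) {
  pk <- pixel_keys(history, region_raster)
  out <- matrix(0, nrow(history$class), ncol(history$class))
  if (length(pk$idx))
    out[pk$idx] <- predict_by_key(pk$key, pk$age, fits) * pixel_area_ha
  out
}

#' Total secondary-forest carbon stock
#'
#' @inheritParams stock_raster
#' @return total stock in Tg C.
#' @export
total_stock <- function(history, region_raster, fits, pixel_area_ha = 0.09) {
  sum(stock_raster(history, region_raster, fits, pixel_area_ha)) / MG_PER_TG
}

#' Build a stock ledger from its components
#'
#' Closes the accounting identity `stock_end = stock_start + gains - losses`.
#'
#' @param gains_TgC,losses_TgC gross gains and losses (Tg C, non-negative).
#' @param stock_start_TgC opening stock (Tg C).
#' @return an object of class `stock_ledger`.
#' @export
stock_ledger <- function(gains_TgC, losses_TgC, stock_start_TgC = 0) {
  stop_if_not(gains_TgC >= 0 && losses_TgC >= 0,
              "gains and losses must be non-negative")
  structure(list(
    gains_TgC = gains_TgC, losses_TgC = losses_TgC,
    net_TgC = gains_TgC - losses_TgC,
    stock_start_TgC = stock_start_TgC,
    stock_end_TgC = stock_start_TgC + gains_TgC - losses_TgC
  ), class = "stock_ledger")
}

#' @export
print.stock_ledger <- function(x, ...) {
  cat(sprintf(
    "Stock ledger: gains %.4g, losses %.4g, net %.4g Tg C (stock %.4g -> %.4g)\n",
    x$gains_TgC, x$losses_TgC, x$net_TgC, x$stock_start_TgC, x$stock_end_TgC))
  invisible(x)
}

#' Annual net change in secondary-forest carbon
#'
#' Compares two consecutive forest histories.  Gains are the growth increment
#' of persisting secondary pixels (`Y(age+1) - Y(age)`) plus the first-year
#' carbon `Y(1)` of newly recruited secondary forest; losses are the
#' model-predicted stock of secondary pixels deforested between the two
#' years.  Persisting pixels are scored with their end-year disturbance class
#' in both years, so the conservation identity `stock_end = stock_start +
#' gains - losses` holds exactly even when a pixel burns between the two
#' years; deforested pixels are scored with their start-year class.
#'
#' @param history_a,history_b `forest_history` objects for years Y and Y+1.
#' @param region_raster integer region matrix.
#' @param fits named list of `cr_fit` objects keyed by [model_key()].
#' @param pixel_area_ha pixel area in hectares (default 0.09).
#' @param rasters also attach per-pixel gain/loss/net matrices (Mg C).
#' @return a `stock_ledger`; with `rasters = TRUE` it carries a `rasters`
#'   element of per-pixel components.
#' @export
annual_net_change <- function(history_a, history_b, region_raster, fits,
                              pixel_area_ha = 0.09, rasters = FALSE) {
  sec_a <- history_a$class == "secondary"
  sec_b <- history_b$class == "secondary"

  persisting <- which(sec_a & sec_b)
  recruited <- which(sec_b & !sec_a)
  deforested <- which(sec_a & history_b$class == "anthropic")

  if (length(persisting)) {
    bad <- history_b$age[persisting] != history_a$age[persisting] + 1L
    if (any(bad))
      stop("inconsistent histories: persisting secondary pixels whose age ",
           "does not advance by one year", call. = FALSE)
  }
  if (length(recruited) && any(history_b$age[recruited] != 1L))
    stop("inconsistent histories: recruited pixels must have age 1",
         call. = FALSE)

  key_b <- function(idx) {
    cls <- disturbance_class(history_b$defor_count[idx] >= 2L,
                             history_b$burned[idx] %in% TRUE)
    model_key(region_raster[idx], cls)
  }
  key_a <- function(idx) {
    cls <- disturbance_class(history_a$defor_count[idx] >= 2L,
                             history_a$burned[idx] %in% TRUE)
    model_key(region_raster[idx], cls)
  }

  nr <- nrow(history_a$class); nc <- ncol(history_a$class)
  gain_px <- matrix(0, nr, nc); loss_px <- matrix(0, nr, nc)
  start_px <- matrix(0, nr, nc)

  if (length(persisting)) {
    kp <- key_b(persisting)
    a0 <- history_a$age[persisting]
    y0 <- predict_by_key(kp, a0, fits)
    y1 <- predict_by_key(kp, a0 + 1L, fits)
    gain_px[persisting] <- (y1 - y0) * pixel_area_ha
    start_px[persisting] <- y0 * pixel_area_ha
  }
  if (length(recruited)) {
    kr <- key_b(recruited)
    gain_px[recruited] <- predict_by_key(kr, rep(1L, length(recruited)), fits) *
      pixel_area_ha
  }
  if (length(deforested)) {
    kd <- key_a(deforested)
    yl <- predict_by_key(kd, history_a$age[deforested], fits)
    loss_px[deforested] <- yl * pixel_area_ha
    start_px[deforested] <- yl * pixel_area_ha
  }

  led <- stock_ledger(sum(gain_px) / MG_PER_TG, sum(loss_px) / MG_PER_TG,
                      sum(start_px) / MG_PER_TG)
  if (rasters)
    led$rasters <- list(gains = gain_px, losses = loss_px,
                        net = gain_px - loss_px)
  led
}

#' Potential stock under the no-disturbance counterfactual
#'
#' Scores every secondary pixel with its region's no-disturbance
#' (`single_not_burnt`) model at the pixel's observed age, i.e. what the 2017
#' stock would have been had no regrowing forest burned or been re-cleared.
#' Observed ages are kept; the counterfactual does not rewind the clearing
#' history itself.
#'
#' @inheritParams stock_raster
#' @return potential stock in Tg C.
#' @export
potential_stock_no_disturbance <- function(history, region_raster, fits,
                                           pixel_area_ha = 0.09) {
  sec <- which(history$class == "secondary")
  if (!length(sec)) return(0)
  key <- model_key(region_raster[sec], "single_not_burnt")
  missing <- setdiff(unique(key), names(fits))
  if (length(missing))
    stop("missing no-disturbance fit for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  sum(predict_by_key(key, history$age[sec], fits)) * pixel_area_ha / MG_PER_TG
}

#' Percentage stock reduction attributable to disturbance
#'
#' @param actual_TgC observed stock.
#' @param potential_TgC no-disturbance counterfactual stock (> 0).
#' @return reduction in percent, `100 * (potential - actual) / potential`.
#' @export
disturbance_reduction <- function(actual_TgC, potential_TgC) {
  stop_if_not(potential_TgC > 0, "potential stock must be positive")
  100 * (potential_TgC - actual_TgC) / potential_TgC
}

#' Aggregate a per-pixel component to a coarse grid
#'
#' Sums pixel values into square coarse cells (`cell_pixels` fine pixels per
#' cell edge, e.g. a 0.1 degree cell spans ~370 Landsat pixels); partial edge
#' cells are kept, so the cell sums re-add exactly to the fine-grid total.
#'
#' @param x matrix of per-pixel values (e.g. Mg C per pixel).
#' @param cell_pixels number of fine pixels per coarse cell edge.
#' @return matrix of coarse cell sums.
#' @export
grid_aggregate <- function(x, cell_pixels) {
  stop_if_not(cell_pixels >= 1, "cell_pixels must be >= 1")
  nr <- nrow(x); nc <- ncol(x)
  ri <- ((seq_len(nr) - 1L) %/% cell_pixels) + 1L
  ci <- ((seq_len(nc) - 1L) %/% cell_pixels) + 1L
  cell_row <- matrix(ri, nr, nc)
  cell_col <- matrix(ci, nr, nc, byrow = TRUE)
  id <- (cell_col - 1L) * max(ri) + cell_row
  sums <- rowsum(as.vector(x), as.vector(id))
  out <- matrix(0, max(ri), max(ci))
  out[as.integer(rownames(sums))] <- sums
  out
}
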