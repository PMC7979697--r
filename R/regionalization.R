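#' Partition the landscape into climate regions by K-means
#'
#' Clusters pixels on z-scored (MCWD, shortwave radiation, precipitation)
#' vectors with K-means (10 seeded restarts, best objective kept).  By
#' default only pixels carrying secondary forest drive the clustering; every
#' pixel of the grid is then assigned to its nearest centroid so old-growth
#' pixels also receive a region.  Region labels are canonicalised by
#' ascending mean shortwave radiation, so region 1 is reproducibly the
#' lowest-radiation cluster regardless of pixel order or K-means label
#' permutation.
#'
#' @param drivers named list with matrices `mcwd`, `sw`, `precip`.
#' @param mask optional logical matrix of pixels to cluster on (e.g.
#'   secondary forest); `NULL` clusters on the whole grid.
#' @param k number of regions (default 4).
#' @param nstart K-means restarts (default 10).
#' @param seed integer seed.
#' @return an object of class `region_set`: list with `region` (integer
#'   matrix over the whole grid), `summary` (tibble of per-region driver
#'   means over the clustered pixels), `centers` (z-space centroids), `k`.
#' @export
kmeans_regions <- function(drivers, mask = NULL, k = 4, nstart = 10,
                           seed = 1L) {
  stop_if_not(all(c("mcwd", "sw", "precip") %in% names(drivers)),
              "drivers must contain mcwd, sw and precip")
  stop_if_not(k >= 1, "k must be >= 1")
  X <- cbind(mcwd = as.vector(drivers$mcwd),
             sw = as.vector(drivers$sw),
             precip = as.vector(drivers$precip))
  sel <- if (is.null(mask)) rep(TRUE, nrow(X)) else as.vector(mask)
  Xt <- X[sel, , drop = FALSE]
  stop_if_not(nrow(unique(Xt)) >= k,
              "k exceeds the number of distinct driver vectors")
  mu <- colMeans(Xt)
  sg <- apply(Xt, 2, sd)
  sg[sg == 0] <- 1  # constant driver: no information, avoid 0/0
  Z <- sweep(sweep(Xt, 2, mu), 2, sg, "/")

  set.seed(seed)
  km <- kmeans(Z, centers = k, nstart = nstart, iter.max = 50)

  # canonical ids: ascending mean SW radiation among clustered pixels
  mean_sw <- vapply(seq_len(k), function(i) mean(Xt[km$cluster == i, "sw"]),
                    numeric(1))
  relabel <- match(seq_len(k), order(mean_sw))

  # assign every pixel of the grid to the nearest centroid in z-space
  Zall <- sweep(sweep(X, 2, mu), 2, sg, "/")
  d2 <- vapply(seq_len(k), function(i)
    rowSums(sweep(Zall, 2, km$centers[i, ])^2), numeric(nrow(Zall)))
  assign_all <- relabel[max.col(-d2, ties.method = "first")]
  region <- matrix(as.integer(assign_all),
                   nrow(drivers$sw), ncol(drivers$sw))

  cl_canon <- relabel[km$cluster]
  summary <- tibble(
    region = seq_len(k),
    n_pixels = as.integer(table(factor(cl_canon, levels = seq_len(k)))),
    mean_sw = vapply(seq_len(k), function(i)
      mean(Xt[cl_canon == i, "sw"]), numeric(1)),
    mean_precip = vapply(seq_len(k), function(i)
      mean(Xt[cl_canon == i, "precip"]), numeric(1)),
    mean_mcwd = vapply(seq_len(k), function(i)
      mean(Xt[cl_canon == i, "mcwd"]), numeric(1))
  )
  centers <- km$centers[order(mean_sw), , drop = FALSE]
  rownames(centers) <- seq_len(k)
  structure(list(region = region, summary = summary, centers = centers,
                 k = k, tot.withinss = km$tot.withinss),
            class = "region_set")
}

#' Model-set key for a (region, disturbance class) pair
#'
#' @param region integer region id.
#' @param class one of [DISTURBANCE_CLASSES].
#' @return character key `"region<i>.<class>"`.
#' @export
model_key <- function(region, class) paste0("region", region, ".", class)

#' Map every patch to its regional disturbance-class growth model
#'
#' Attaches the region id (modal over member pixels) and the model key to a
#' patch set and verifies the model set is complete for every occurring
#' (region, class) combination.
#'
#' @param patches a `patch_set`.
#' @param region_raster integer region matrix.
#' @param fits named list of `cr_fit` objects keyed by [model_key()].
#' @return the patch tibble with columns `region` and `model_key` added.
#' @export
assign_models <- function(patches, region_raster, fits) {
  stopifnot(inherits(patches, "patch_set"))
  region <- vapply(patches$pixels,
                   function(p) as.integer(modal_value(region_raster[p])),
                   integer(1))
  key <- model_key(region, disturbance_class(patches$repeated, patches$burned))
  missing <- setdiff(unique(key), names(fits))
  if (length(missing))
    stop("model set is missing fits for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  out <- patches
  out$region <- region
  out$model_key <- key
  out
}

#' Disturbance-class prevalence by region
#'
#' @param patches patch tibble with `region` and disturbance flags.
#' @param weight `"patches"` (count) or `"area"` (sum of `area_m2`).
#' @return tibble of region, class and prevalence in percent (summing to 100
#'   within each region).
#' @export
class_prevalence <- function(patches, weight = c("patches", "area")) {
  weight <- match.arg(weight)
  w <- if (weight == "area") patches$area_m2 else rep(1, nrow(patches))
  df <- tibble(region = patches$region,
               class = disturbance_class(patches$repeated, patches$burned),
               w = w)
  tot <- dplyr::summarise(dplyr::group_by(df, .data$region),
                          tot = sum(.data$w), .groups = "drop")
  out <- dplyr::summarise(dplyr::group_by(df, .data$region, .data$class),
                          w = sum(.data$w), .groups = "drop")
  out <- dplyr::left_join(out, tot, by = "region")
  out$percent <- 100 * out$w / out$tot
  out[, c("region", "class", "percent")]
}
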