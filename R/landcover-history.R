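#' Reconstruct per-pixel forest history from an annual binary stack
#'
#' Scans each pixel's annual forest (1) / anthropic (0) series and classifies
#' it in the final year: pixels forested throughout are `old_growth`; pixels
#' anthropic in the final year are `anthropic` (any earlier regrowth is
#' discarded); pixels whose series contains a `NA` are `nodata`; the rest are
#' `secondary`, with age equal to the length of the uninterrupted forest run
#' ending at the final layer and a deforestation count equal to the number of
#' forest-to-anthropic transitions before that run (floored at 1, since land
#' that entered the window already cleared still experienced the original
#' conversion).
#'
#' @param stack integer array (rows x cols x years) with values 0, 1 or `NA`.
#' @param burned_masks optional named list of logical burned-area matrices;
#'   a secondary pixel is flagged burned if any mask is `TRUE` there.
#' @return an object of class `forest_history`: list of matrices `class`
#'   (character), `age`, `defor_count` (integer, secondary pixels only),
#'   `burned` (logical, secondary pixels only), plus `n_years`.
#' @export
classify_history <- function(stack, burned_masks = NULL) {
  d <- dim(stack)
  stop_if_not(length(d) == 3 && d[3] >= 2, "stack must have >= 2 annual layers")
  vals <- unique(as.vector(stack))
  stop_if_not(all(vals %in% c(0L, 1L, NA)), "stack values must be 0, 1 or NA")
  nr <- d[1]; nc <- d[2]; ny <- d[3]
  m <- matrix(stack, nr * nc, ny)  # pixels x years

  has_na <- rowSums(is.na(m)) > 0
  final_forest <- m[, ny] == 1L
  all_forest <- rowSums(m == 1L) == ny

  # last year with value 0 (0 if none): onset of the final forest run is the
  # following year
  z <- m == 0L
  last_zero <- apply(z, 1, function(x) {
    w <- which(x)
    if (length(w)) w[length(w)] else 0L
  })
  age_v <- ny - last_zero
  # forest -> anthropic transitions anywhere in the series; for a pixel
  # forested in the final year all of them precede the final run
  trans <- rowSums(m[, -ny, drop = FALSE] == 1L & m[, -1, drop = FALSE] == 0L)

  cls <- rep("anthropic", nr * nc)
  cls[final_forest] <- "secondary"
  cls[all_forest] <- "old_growth"
  cls[has_na] <- "nodata"
  sec <- cls == "secondary"

  age <- matrix(NA_integer_, nr, nc)
  age[sec] <- as.integer(age_v[sec])
  defc <- matrix(NA_integer_, nr, nc)
  defc[sec] <- as.integer(pmax(trans[sec], 1L))
  burned <- matrix(NA, nr, nc)
  burned[sec] <- FALSE
  if (!is.null(burned_masks) && length(burned_masks)) {
    any_burn <- Reduce(`|`, burned_masks)
    burned[sec] <- any_burn[sec]
  }

  structure(list(class = matrix(cls, nr, nc), age = age, defor_count = defc,
                 burned = burned, n_years = ny),
            class = "forest_history")
}

#' Count repeated deforestations in one pixel series
#'
#' Number of forest-to-anthropic (1 to 0) transitions occurring at or before
#' the onset of the final uninterrupted forest run.  Returns 0 for an
#' all-forest (old-growth) series.  When the series ends in forest that
#' regrew from land already anthropic at the start of the window, the count is
#' floored at 1: the original conversion happened before observation began.
#'
#' @param series integer vector of 0/1 values, length >= 2.
#' @return non-negative integer.
#' @export
count_repeated_deforestations <- function(series) {
  stop_if_not(length(series) >= 2, "series must have length >= 2")
  stop_if_not(all(series %in% c(0L, 1L)), "series values must be 0 or 1")
  n <- length(series)
  z <- which(series == 0L)
  onset <- if (length(z)) max(z) + 1L else 1L
  upto <- min(onset, n)
  tr <- sum(series[seq_len(upto - 1L)] == 1L & series[2:upto] == 0L)
  if (series[n] == 1L && any(series == 0L)) max(tr, 1L) else tr
}

#' Exclude pixels by masks and point buffers
#'
#' Sets pixels to class `excluded` where any boolean mask is `TRUE`, or where
#' the pixel centre lies within `radius_m` of any given point (e.g. field
#' inventory sites).  Pixel centres sit at `(col - 0.5, row - 0.5) *
#' pixel_size_m` with the origin at the top-left corner.
#'
#' @param history a `forest_history`.
#' @param masks list of logical matrices co-registered with the history.
#' @param points optional data frame with columns `x`, `y` (metres).
#' @param radius_m buffer radius in metres (default 3000).
#' @param pixel_size_m pixel edge length (default 30).
#' @return the modified `forest_history`.
#' @export
apply_exclusion_masks <- function(history, masks = list(), points = NULL,
                                  radius_m = 3000, pixel_size_m = 30) {
  stopifnot(inherits(history, "forest_history"))
  nr <- nrow(history$class); nc <- ncol(history$class)
  excl <- matrix(FALSE, nr, nc)
  for (m in masks) {
    stop_if_not(all(dim(m) == c(nr, nc)), "exclusion mask grid mismatch")
    excl <- excl | m
  }
  if (!is.null(points) && nrow(points)) {
    cx <- (matrix(rep(seq_len(nc), each = nr), nr, nc) - 0.5) * pixel_size_m
    cy <- (matrix(rep(seq_len(nr), times = nc), nr, nc) - 0.5) * pixel_size_m
    for (i in seq_len(nrow(points))) {
      d2 <- (cx - points$x[i])^2 + (cy - points$y[i])^2
      excl <- excl | d2 <= radius_m^2
    }
  }
  history$class[excl] <- "excluded"
  history$age[excl] <- NA_integer_
  history$defor_count[excl] <- NA_integer_
  history$burned[excl] <- NA
  history
}

neighbour_shifts <- function(connectivity) {
  if (connectivity == 4) list(c(0L, 1L), c(1L, 0L))
  else list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(-1L, 1L))
}

# connected components of a logical matrix, optionally split by a grouping
# matrix (edges only join equal group values); returns integer labels (NA off
# the mask)
label_components <- function(mask, group = NULL, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  if (!length(idx)) return(matrix(NA_integer_, nr, nc))
  edges <- list()
  for (s in neighbour_shifts(connectivity)) {
    di <- s[1]; dj <- s[2]
    i1 <- max(1L, 1L - di):min(nr, nr - di)
    j1 <- max(1L, 1L - dj):min(nc, nc - dj)
    a <- mask[i1, j1, drop = FALSE]
    b <- mask[i1 + di, j1 + dj, drop = FALSE]
    both <- a & b
    if (!is.null(group)) {
      g1 <- group[i1, j1, drop = FALSE]
      g2 <- group[i1 + di, j1 + dj, drop = FALSE]
      both <- both & !is.na(g1) & !is.na(g2) & g1 == g2
    }
    w <- which(both)
    if (length(w)) {
      r <- ((w - 1L) %% length(i1)) + i1[1]
      cl <- ((w - 1L) %/% length(i1)) + j1[1]
      edges[[length(edges) + 1L]] <-
        cbind(pixel_index(r, cl, nr), pixel_index(r + di, cl + dj, nr))
    }
  }
  vert <- as.character(idx)
  g <- if (length(edges)) {
    e <- do.call(rbind, edges)
    igraph::graph_from_data_frame(
      data.frame(from = as.character(e[, 1]), to = as.character(e[, 2])),
      directed = FALSE, vertices = data.frame(name = vert))
  } else {
    igraph::make_empty_graph(n = length(vert), directed = FALSE) |>
      igraph::set_vertex_attr("name", value = vert)
  }
  memb <- igraph::components(g)$membership[vert]
  lab <- matrix(NA_integer_, nr, nc)
  lab[idx] <- as.integer(memb)
  lab
}

#' Delineate secondary-forest patches
#'
#' Labels connected components of secondary pixels (8-neighbour by default)
#' and drops components smaller than the minimum mapping unit (9000 m2, i.e.
#' ten 30-m pixels under the inclusive ">=" convention).  By default
#' components are additionally split by final-year age and disturbance flags
#' (`group_by_age = TRUE`), so each patch is an age- and class-coherent
#' polygon as the chronosequence-by-disturbance analysis requires; set it to
#' `FALSE` to label contiguous secondary areas regardless of age and
#' represent the patch by its modal attributes.
#'
#' Each patch is tagged `burnt` if any member pixel burned and `repeated` if
#' its representative (modal, ties toward the smaller value) deforestation
#' count is at least 2.
#'
#' @param history a `forest_history`.
#' @param min_area_m2 minimum patch area (default 9000).
#' @param pixel_size_m pixel edge length in metres (default 30).
#' @param connectivity 8 (default) or 4.
#' @param group_by_age split components by age and disturbance flags
#'   (default `TRUE`).
#' @param region_raster optional integer region matrix; when given (and
#'   `group_by_age` is on) components are also split at region boundaries so
#'   no polygon straddles two regional models.
#' @return an object of class `patch_set`: a tibble with columns `patch_id`,
#'   `n_pixels`, `area_m2`, `age`, `defor_count`, `repeated`, `burned` and a
#'   list-column `pixels` of linear pixel indices.
#' @export
label_patches <- function(history, min_area_m2 = 9000, pixel_size_m = 30,
                          connectivity = 8, group_by_age = TRUE,
                          region_raster = NULL) {
  stopifnot(inherits(history, "forest_history"))
  stop_if_not(min_area_m2 > 0, "min_area_m2 must be positive")
  stop_if_not(connectivity %in% c(4, 8), "connectivity must be 4 or 8")
  mask <- history$class == "secondary"
  group <- NULL
  if (group_by_age) {
    group <- matrix(NA_integer_, nrow(mask), ncol(mask))
    group[mask] <- history$age[mask] * 4L +
      2L * (history$defor_count[mask] >= 2L) +
      1L * (history$burned[mask] %in% TRUE)
    if (!is.null(region_raster))
      group[mask] <- group[mask] * 1000L + region_raster[mask]
  }
  lab <- label_components(mask, group = group, connectivity = connectivity)
  idx <- which(!is.na(lab))
  empty <- tibble(patch_id = integer(), n_pixels = integer(),
                  area_m2 = numeric(), age = integer(),
                  defor_count = integer(), repeated = logical(),
                  burned = logical(), pixels = list())
  if (!length(idx)) return(structure(empty, class = c("patch_set", class(empty))))

  by_patch <- split(idx, lab[idx])
  area <- lengths(by_patch) * pixel_size_m^2
  keep <- area >= min_area_m2
  by_patch <- by_patch[keep]
  if (!length(by_patch)) return(structure(empty, class = c("patch_set", class(empty))))

  age <- unname(vapply(by_patch, function(p) modal_value(history$age[p]),
                       numeric(1)))
  defc <- unname(vapply(by_patch,
                        function(p) modal_value(history$defor_count[p]),
                        numeric(1)))
  burned <- unname(vapply(by_patch,
                          function(p) any(history$burned[p], na.rm = TRUE),
                          logical(1)))
  out <- tibble(
    patch_id = seq_along(by_patch),
    n_pixels = unname(lengths(by_patch)),
    area_m2 = unname(area[keep]),
    age = as.integer(age),
    defor_count = as.integer(defc),
    repeated = defc >= 2,
    burned = burned,
    pixels = unname(by_patch)
  )
  structure(out, class = c("patch_set", class(out)))
}

#' Disturbance-class label of a patch or pixel
#'
#' @param repeated logical: deforested 2+ times before regrowth.
#' @param burned logical: intersected a burned-area mask.
#' @return one of the four [DISTURBANCE_CLASSES].
#' @export
disturbance_class <- function(repeated, burned) {
  ifelse(repeated,
         ifelse(burned, "repeated_burnt", "repeated_not_burnt"),
         ifelse(burned, "single_burnt", "single_not_burnt"))
}
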