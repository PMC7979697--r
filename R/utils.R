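#' Modal value of a discrete vector
#'
#' Most frequent value; ties are broken deterministically toward the smaller
#' (default) or larger candidate. `NA`s are dropped.
#'
#' @param x numeric vector.
#' @param tie tie-break direction, `"smallest"` or `"largest"`.
#' @return a single numeric, or `NA` if `x` has no non-missing values.
#' @export
modal_value <- function(x, tie = c("smallest", "largest")) {
  tie <- match.arg(tie)
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  tab <- table(x)
  cand <- as.numeric(names(tab)[tab == max(tab)])
  if (tie == "smallest") min(cand) else max(cand)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

# linear (column-major) pixel index helpers used throughout
pixel_index <- function(row, col, n_rows) (col - 1L) * n_rows + row
pixel_row <- function(idx, n_rows) ((idx - 1L) %% n_rows) + 1L
pixel_col <- function(idx, n_rows) ((idx - 1L) %/% n_rows) + 1L
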