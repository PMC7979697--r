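#' Rank driver importance by repeated subsample tree ensembles
#'
#' Repeats (default 30 times): draw a (optionally stratified) random subsample
#' of the patch records, split it 80/20, grow a regression-tree ensemble (500
#' trees) on the training part, and measure each predictor's marginal
#' permutation importance on the held-out 20% (increase in mean squared error
#' when the predictor's held-out column is permuted).  Within each iteration
#' importances are converted to ranks (1 = least important, `p` = most
#' important; ties break alphabetically by variable name) and the ranks are
#' averaged over iterations with a t-based 95% confidence interval.
#'
#' Rank aggregation is deliberate: only the ordering of importances is
#' comparable across subsamples, not their absolute values.  Raw importances
#' are kept for audit.
#'
#' @param records data frame of patch records.
#' @param response name of the response column (default `"agc"`).
#' @param predictors character vector of predictor columns (default: all
#'   numeric columns except the response).
#' @param strata optional name of a stratification column for the subsample.
#' @param n_iterations number of repeats (default 30).
#' @param sample_n subsample size per iteration (default 2500).
#' @param n_trees trees per ensemble (default 500).
#' @param train_fraction training share of the subsample (default 0.8).
#' @param mtry variables tried per split (default: ranger's default).
#' @param seed integer seed; iteration i uses `seed + i`.
#' @return an object of class `importance_result`: list with `summary`
#'   (tibble: `variable`, `mean_rank`, `ci_lower`, `ci_upper`, `times_top`),
#'   `ranks` and `importances` (iterations x variables matrices) and `config`.
#' @export
rank_importance <- function(records, response = "agc", predictors = NULL,
                            strata = NULL, n_iterations = 30, sample_n = 2500,
                            n_trees = 500, train_fraction = 0.8, mtry = NULL,
                            seed = 1L) {
  if (is.null(predictors)) {
    num <- names(records)[vapply(records, is.numeric, logical(1))]
    predictors <- setdiff(num, response)
  }
  stop_if_not(length(predictors) >= 2, "need at least 2 predictors")
  stop_if_not(sample_n <= nrow(records),
              "sample_n exceeds the number of records")
  p <- length(predictors)
  ranks <- matrix(NA_real_, n_iterations, p,
                  dimnames = list(NULL, predictors))
  imps <- ranks

  for (it in seq_len(n_iterations)) {
    set.seed(seed + it)
    idx <- if (is.null(strata)) {
      sample(nrow(records), sample_n)
    } else {
      # proportional allocation across strata
      sp <- split(seq_len(nrow(records)), records[[strata]])
      alloc <- pmax(1L, round(lengths(sp) / nrow(records) * sample_n))
      unlist(mapply(function(ii, n) sample(ii, min(n, length(ii))),
                    sp, alloc, SIMPLIFY = FALSE), use.names = FALSE)
    }
    dat <- as.data.frame(records[idx, c(response, predictors)])
    n_train <- floor(train_fraction * nrow(dat))
    tr_idx <- sample(nrow(dat), n_train)
    train <- dat[tr_idx, ]
    test <- dat[-tr_idx, ]

    rf <- ranger::ranger(
      dependent.variable.name = response, data = train,
      num.trees = n_trees, mtry = mtry, seed = seed + it,
      num.threads = 1
    )
    base_pred <- stats::predict(rf, data = test)$predictions
    base_mse <- mean((test[[response]] - base_pred)^2)
    for (j in seq_len(p)) {
      perm <- test
      perm[[predictors[j]]] <- sample(perm[[predictors[j]]])
      mse_j <- mean((test[[response]] -
                       stats::predict(rf, data = perm)$predictions)^2)
      imps[it, j] <- mse_j - base_mse
    }
    # rank 1 = least important; ties broken by alphabetical variable name
    ord <- order(imps[it, ], predictors)
    ranks[it, ord] <- seq_len(p)
  }

  mean_rank <- colMeans(ranks)
  se <- apply(ranks, 2, sd) / sqrt(n_iterations)
  tq <- qt(0.975, n_iterations - 1)
  summary <- tibble(
    variable = predictors,
    mean_rank = unname(mean_rank),
    ci_lower = unname(mean_rank - tq * se),
    ci_upper = unname(mean_rank + tq * se),
    times_top = unname(colSums(ranks == p))
  )
  summary <- dplyr::arrange(summary, dplyr::desc(.data$mean_rank))
  structure(list(
    summary = summary, ranks = ranks, importances = imps,
    config = list(n_iterations = n_iterations, sample_n = sample_n,
                  n_trees = n_trees, train_fraction = train_fraction,
                  strata = strata, mtry = mtry, seed = seed)
  ), class = "importance_result")
}

#' @export
print.importance_result <- function(x, ...) {
  cat(sprintf("Driver importance over %d iterations (n = %d, %d trees):\n",
              x$config$n_iterations, x$config$sample_n, x$config$n_trees))
  print(x$summary)
  invisible(x)
}
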