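#' Random hold-out split of observations
#'
#' Partitions the observation rows (not region-year cells: a cell with two
#' surveys may keep one) uniformly at random without replacement. The
#' held-out count is `round(fraction * N)` under R's round-half-even rule.
#'
#' @param data A `factor_dataset`.
#' @param fraction Held-out fraction, default 0.10.
#' @param seed Integer seed making the split reproducible.
#' @return A list with `train` and `test`, both `factor_dataset`s over the
#'   same graph and years.
#' @export
holdout_split <- function(data, fraction = 0.10, seed = 1L) {
  stopifnot(inherits(data, "factor_dataset"))
  if (fraction <= 0 || fraction >= 1) {
    abort("`fraction` must lie strictly between 0 and 1.")
  }
  N <- data$n_obs
  if (N < 2) abort("Need at least 2 observations to split.")
  n_test <- round(fraction * N)
  set.seed(seed)
  test_idx <- sort(sample.int(N, n_test))
  obs <- data$observations
  list(
    train = assemble_dataset(obs[setdiff(seq_len(N), test_idx), ],
                             data$graph, data$years),
    test = assemble_dataset(obs[test_idx, ], data$graph, data$years)
  )
}

#' Predictive-performance metrics on held-out observations
#'
#' Compares each held-out design-weighted proportion `q` with the posterior
#' mean prevalence at the same (region, year) cell, on the proportion scale:
#' Pearson correlation, mean absolute error and root mean square error.
#'
#' @param test A `factor_dataset` of held-out observations.
#' @param surface A `stgpr_surface` covering every test cell.
#' @return A one-row tibble: `correlation`, `mae`, `rmse`, `n_held_out`.
#'   When fewer than 2 observations are held out, or the predictions (or
#'   observations) are constant, the correlation is undefined: it is
#'   returned as `NA` with a warning while MAE and RMSE are still reported.
#' @export
cv_metrics <- function(test, surface) {
  stopifnot(inherits(test, "factor_dataset"),
            inherits(surface, "stgpr_surface"))
  obs <- test$observations
  if (nrow(obs) == 0) abort("No held-out observations.")
  key <- paste(obs$region_id, obs$year)
  skey <- paste(surface$region_id, surface$year)
  idx <- match(key, skey)
  if (anyNA(idx)) {
    abort("Some held-out (region, year) cells are missing from the surface.")
  }
  pred <- surface$mean[idx]
  err <- obs$q - pred
  n <- length(err)
  correlation <- NA_real_
  if (n < 2) {
    warn("Correlation undefined: fewer than 2 held-out observations.")
  } else if (sd(pred) == 0 || sd(obs$q) == 0) {
    warn("Correlation undefined: constant predictions or observations.")
  } else {
    correlation <- cor(obs$q, pred)
  }
  tibble::tibble(
    correlation = correlation,
    mae = mean(abs(err)),
    rmse = sqrt(mean(err^2)),
    n_held_out = n
  )
}

#' Write a cross-validation report row
#'
#' @param report A one-row tibble from [cv_metrics()].
#' @param path Output path.
#' @param factor_id Label for the factor being validated.
#' @param seed The hold-out seed, recorded for reproducibility.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(report, path, factor_id = "factor", seed = NA) {
  readr::write_csv(dplyr::mutate(report, factor_id = factor_id, seed = seed,
                                 .before = 1), path)
  invisible(path)
}
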