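#' Posterior prevalence surface
#'
#' Transforms every retained draw to the probability scale,
#' `Q_kt = plogis(alpha + S_kt)`, for every (region, year) cell — including
#' cells with no observations, which is how the model interpolates
#' non-sampled years and regions — and summarises by the posterior mean and
#' central 95% interval.
#'
#' @param fit A `stgpr_fit` from [stgpr()].
#' @return A tibble of class `stgpr_surface` with columns `region_id`,
#'   `year`, `mean`, `lo95`, `hi95`, ordered region-major. The full matrix
#'   of probability-scale draws (draws x cells, cells in the same order) is
#'   attached as attribute `"draws"`.
#' @export
posterior_surface <- function(fit) {
  stopifnot(inherits(fit, "stgpr_fit"))
  if (fit$n_draws < 1) abort("Empty draw store.")
  Q <- plogis(fit$draws$alpha + fit$draws$field)  # n_draws x KT
  K <- fit$data$n_regions
  T <- fit$data$n_years
  out <- tibble::tibble(
    region_id = rep(fit$graph$region_ids, each = T),
    year = rep(fit$years, times = K),
    mean = colMeans(Q),
    lo95 = apply(Q, 2, quantile, probs = 0.025),
    hi95 = apply(Q, 2, quantile, probs = 0.975)
  )
  attr(out, "draws") <- Q
  class(out) <- c("stgpr_surface", class(out))
  out
}

#' Extract probability-scale draws for one surface cell
#'
#' @param surface A `stgpr_surface` from [posterior_surface()].
#' @param region_id Region label.
#' @param year Calendar year.
#' @return Numeric vector of posterior draws of prevalence for that cell.
#' @export
surface_cell_draws <- function(surface, region_id, year) {
  stopifnot(inherits(surface, "stgpr_surface"))
  idx <- which(surface$region_id == region_id & surface$year == year)
  if (length(idx) != 1) {
    abort(paste0("No unique surface cell for (", region_id, ", ", year, ")."))
  }
  attr(surface, "draws")[, idx]
}

#' Plot a posterior prevalence surface
#'
#' Annual posterior mean with 95% credible ribbon, one panel per region.
#'
#' @param object A `stgpr_surface`.
#' @param regions Optional character vector restricting the panels.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.stgpr_surface <- function(object, regions = NULL, ...) {
  df <- tibble::as_tibble(object)
  if (!is.null(regions)) df <- dplyr::filter(df, .data$region_id %in% regions)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$year, y = .data$mean)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lo95, ymax = .data$hi95),
      fill = "steelblue", alpha = 0.3
    ) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~region_id) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Year", y = "Prevalence / coverage") +
    ggplot2::theme_minimal()
}

#' Trace plots of hyperparameter draws
#'
#' @param object A `stgpr_fit`.
#' @param ... Unused.
#' @return A ggplot object, one panel per hyperparameter.
#' @exportS3Method ggplot2::autoplot
autoplot.stgpr_fit <- function(object, ...) {
  pars <- c("alpha", "sigma2", "rho_s", "phi", "tau2")
  df <- purrr::map_dfr(pars, function(p) {
    tibble::tibble(term = p, draw = seq_along(object$draws[[p]]),
                   value = object$draws[[p]])
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$draw, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(x = "Retained draw", y = NULL) +
    ggplot2::theme_minimal()
}

#' Write a posterior surface to a delimited file
#'
#' Columns `region_id, year, mean, lo95, hi95`; draws are not written.
#'
#' @param surface A `stgpr_surface`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_surface <- function(surface, path) {
  readr::write_csv(tibble::as_tibble(surface), path)
  invisible(path)
}
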