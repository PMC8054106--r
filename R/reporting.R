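#' Absolute and percentage change between two anchor years
#'
#' Both inputs are on the percent (0-100) scale. Absolute change is
#' `end - start` in percentage points; percentage change is
#' `100 * (end - start) / start`. Values are returned unrounded; round to
#' one decimal for display. A zero start makes the percentage change
#' undefined (`NA`, flagged).
#'
#' @param start,end Estimates in percent; vectors recycle together.
#' @return A tibble with columns `start`, `end`, `absolute`,
#'   `percent_change`, `pct_undefined`.
#' @examples
#' change_metrics(6.2, 61.9) # absolute 55.7, percent 898.4
#' @export
change_metrics <- function(start, end) {
  stopifnot(is.numeric(start), is.numeric(end),
            all(is.finite(start)), all(is.finite(end)))
  n <- max(length(start), length(end))
  start <- rep_len(start, n)
  end <- rep_len(end, n)
  undef <- start == 0
  pct <- ifelse(undef, NA_real_, 100 * (end - start) / start)
  tibble::tibble(start = start, end = end, absolute = end - start,
                 percent_change = pct, pct_undefined = undef)
}

#' Posterior change report between two anchor years
#'
#' Computes the absolute and percentage change draw by draw (draws paired by
#' index) and summarises by the 2.5/97.5 percentiles. Point estimates are
#' the changes of the draw means: exact for the absolute change (linearity
#' of expectation) but for the percentage change this differs in general
#' from the mean of per-draw percentage changes, which is reported alongside.
#'
#' @param draws_start,draws_end Equal-length numeric vectors of posterior
#'   draws on the percent (0-100) scale, paired by draw index.
#' @param factor_id Optional label carried into the report.
#' @param start_year,end_year Optional anchor years carried into the report.
#' @return A one-row tibble of class `change_report`: `start`, `end` (draw
#'   means), `absolute`, `absolute_lo95`, `absolute_hi95`,
#'   `percent_change`, `percent_change_draws_mean`, `pct_lo95`, `pct_hi95`.
#' @export
change_metrics_posterior <- function(draws_start, draws_end,
                                     factor_id = NA_character_,
                                     start_year = NA_integer_,
                                     end_year = NA_integer_) {
  if (length(draws_start) != length(draws_end)) {
    abort("Draw vectors must have equal length (paired by draw index).")
  }
  if (length(draws_start) < 1) abort("Empty draw vectors.")
  abs_d <- draws_end - draws_start
  pct_d <- 100 * (draws_end - draws_start) / draws_start
  start <- mean(draws_start)
  end <- mean(draws_end)
  point <- change_metrics(start, end)
  tibble::new_tibble(tibble::tibble(
    factor_id = factor_id,
    start_year = start_year, end_year = end_year,
    start = start, end = end,
    absolute = point$absolute,
    absolute_lo95 = unname(quantile(abs_d, 0.025)),
    absolute_hi95 = unname(quantile(abs_d, 0.975)),
    percent_change = point$percent_change,
    percent_change_draws_mean = mean(pct_d),
    pct_lo95 = unname(quantile(pct_d, 0.025)),
    pct_hi95 = unname(quantile(pct_d, 0.975))
  ), class = "change_report")
}

#' Octile ranking of regional values
#'
#' Classifies each region's percent value into eight fixed-width classes of
#' 12.5 points: class `c = 1 + floor(value / 12.5)`, capped at 8, so class 1
#' is `< 12.5%` and class 8 is `>= 87.5%` (boundaries belong to the upper
#' class). Factors whose values are not naturally a 0-100 percentage are
#' first min-max rescaled to 0-100 across regions. With
#' `orientation = "low_good"` the class is flipped to `9 - c` so that class
#' 1 always reads as unfavourable.
#'
#' @param data A data frame with a region identifier column and a value
#'   column.
#' @param value Name of the value column (string). Default `"value"`.
#' @param orientation `"high_good"` (coverage-type factors) or `"low_good"`
#'   (prevalence-type factors, flipped).
#' @param natural_scale If `TRUE` (default) values must already be percents
#'   in [0, 100]; otherwise they are min-max rescaled first.
#' @return The input tibble with columns `scaled` (the classified 0-100
#'   value) and `octile` (integer 1-8).
#' @examples
#' octile_rank(data.frame(region_id = c("A", "B"), value = c(0, 87.5)))
#' @export
octile_rank <- function(data, value = "value",
                        orientation = c("high_good", "low_good"),
                        natural_scale = TRUE) {
  orientation <- match.arg(orientation)
  data <- tibble::as_tibble(data)
  v <- data[[value]]
  if (is.null(v)) abort(paste0("No column `", value, "` in `data`."))
  if (!all(is.finite(v))) abort("Values must be finite.")
  if (natural_scale) {
    if (any(v < 0 | v > 100)) {
      abort("Natural-scale values must lie in [0, 100].")
    }
    scaled <- v
  } else {
    rng <- range(v)
    if (rng[1] == rng[2]) {
      scaled <- rep(0, length(v)) # constant factor: a single (lowest) class
    } else {
      scaled <- 100 * (v - rng[1]) / (rng[2] - rng[1])
    }
  }
  cls <- pmin(8L, 1L + as.integer(floor(scaled / 12.5)))
  if (orientation == "low_good") cls <- 9L - cls
  data$scaled <- scaled
  data$octile <- cls
  data
}

#' Coverage bands
#'
#' Classifies a percent value as `low` (< 35), `moderate` (35-65, closed
#' interval) or `high` (> 65).
#'
#' @param value Numeric vector of percents in [0, 100].
#' @return A factor with levels `low`, `moderate`, `high`.
#' @examples
#' coverage_band(c(8.4, 50, 91))
#' @export
coverage_band <- function(value) {
  if (any(!is.finite(value)) || any(value < 0 | value > 100)) {
    abort("`value` must lie in [0, 100].")
  }
  factor(
    dplyr::case_when(
      value < 35 ~ "low",
      value <= 65 ~ "moderate",
      TRUE ~ "high"
    ),
    levels = c("low", "moderate", "high")
  )
}

#' National-style change report from a posterior surface
#'
#' Averages the probability-scale draws across regions (unweighted) at the
#' two anchor years and summarises the change on the percent scale.
#'
#' @param surface A `stgpr_surface`.
#' @param start_year,end_year Anchor years present in the surface.
#' @param factor_id Label carried into the report.
#' @return A one-row `change_report` tibble (see
#'   [change_metrics_posterior()]).
#' @export
surface_change_report <- function(surface, start_year, end_year,
                                  factor_id = "factor") {
  stopifnot(inherits(surface, "stgpr_surface"))
  draws <- attr(surface, "draws")
  for (yr in c(start_year, end_year)) {
    if (!yr %in% surface$year) {
      abort(paste0("Year ", yr, " is not in the surface."))
    }
  }
  d_start <- 100 * rowMeans(draws[, surface$year == start_year, drop = FALSE])
  d_end <- 100 * rowMeans(draws[, surface$year == end_year, drop = FALSE])
  change_metrics_posterior(d_start, d_end, factor_id = factor_id,
                           start_year = start_year, end_year = end_year)
}

#' Plot a change report
#'
#' Dot-and-interval display of the absolute change per factor.
#'
#' @param report A tibble of one or more `change_report` rows.
#' @return A ggplot object.
#' @export
plot_change_report <- function(report) {
  ggplot2::ggplot(report, ggplot2::aes(x = .data$absolute,
                                       y = .data$factor_id)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$absolute_lo95, xmax = .data$absolute_hi95),
      height = 0.15
    ) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Absolute change (percentage points)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Write a change report to a delimited file
#'
#' @param report A `change_report` tibble (one or more rows).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_change_report <- function(report, path) {
  readr::write_csv(tibble::as_tibble(report), path)
  invisible(path)
}

#' Write an octile table to a delimited file
#'
#' @param octiles A tibble from [octile_rank()] (optionally several factors
#'   row-bound with a `factor_id` column).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_octile_table <- function(octiles, path) {
  readr::write_csv(tibble::as_tibble(octiles), path)
  invisible(path)
}
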