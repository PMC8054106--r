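#' Apply the survey recall-window filter
#'
#' Harmonises heterogeneous survey instruments by restricting each survey's
#' retrospective records to a short window before the interview year:
#' DHS-like surveys keep events strictly less than 3 years old, MICS-like
#' strictly less than 2 years, and census-like records are kept unfiltered
#' (a census reports the enumeration year itself). This trades recall bias
#' against sample size when pooling survey families.
#'
#' @param records A microdata tibble with at least `survey_id`,
#'   `survey_family` (one of `"DHS-like"`, `"MICS-like"`, `"census-like"`)
#'   and `event_year`.
#' @param survey_years Either a single interview year applied to all records,
#'   or a data frame with columns `survey_id`, `survey_year` mapping each
#'   survey to its interview year.
#' @return The filtered tibble (same columns). Idempotent.
#' @examples
#' rec <- tibble::tibble(
#'   survey_id = "s1", survey_family = "DHS-like",
#'   region_id = "A", event_year = 2010:2013, outcome = 1, weight = 1,
#'   cluster_id = "c1"
#' )
#' filter_recall_window(rec, 2014) # keeps 2012 and 2013 only
#' @export
filter_recall_window <- function(records, survey_years) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) return(records)
  known <- c("DHS-like", "MICS-like", "census-like")
  bad <- setdiff(unique(records$survey_family), known)
  if (length(bad) > 0) {
    abort(paste0("Unknown survey_family: ", paste(bad, collapse = ", "),
                 ". Expected one of: ", paste(known, collapse = ", ")))
  }
  if (is.data.frame(survey_years)) {
    if (!all(c("survey_id", "survey_year") %in% names(survey_years))) {
      abort("`survey_years` data frame needs columns survey_id, survey_year.")
    }
    sy <- survey_years$survey_year[match(records$survey_id,
                                         survey_years$survey_id)]
    if (anyNA(sy)) {
      abort("Some survey_id values have no survey_year mapping.")
    }
  } else {
    stopifnot(is.numeric(survey_years), length(survey_years) == 1)
    sy <- rep(survey_years, nrow(records))
  }
  if (any(records$event_year > sy)) {
    abort("Found event_year after the survey interview year.")
  }
  lag <- sy - records$event_year
  max_lag <- c("DHS-like" = 3, "MICS-like" = 2, "census-like" = Inf)
  keep <- lag < max_lag[records$survey_family]
  records[keep, , drop = FALSE]
}

# empirical logit with a 0.5 pseudo-count continuity correction on the
# effective-sample-size scale; only applied at the boundary q in {0, 1}
empirical_logit <- function(q, n_eff) {
  floor_needed <- q %in% c(0, 1)
  q_star <- ifelse(floor_needed, (q * n_eff + 0.5) / (n_eff + 1), q)
  list(y_logit = qlogis(q_star), v_floor = floor_needed)
}

#' Design-weighted prevalence estimates by survey, region and year
#'
#' Collapses binary microdata to one observation per (survey, region,
#' event year): the weighted proportion `q = sum(w*y)/sum(w)`, the Kish
#' effective sample size `n_eff = sum(w)^2 / sum(w^2)`, and the empirical
#' logit of `q`. When `q` is exactly 0 or 1 a continuity correction
#' `q* = (q * n_eff + 0.5) / (n_eff + 1)` keeps the logit finite; such rows
#' are flagged with `v_floor = TRUE` for audit.
#'
#' @param records A microdata tibble with columns `survey_id`, `region_id`,
#'   `event_year`, `outcome` (0/1) and `weight` (> 0). Usually the output of
#'   [filter_recall_window()].
#' @return A tibble with one row per (survey_id, region_id, year) and
#'   columns `q`, `n`, `n_eff`, `y_logit`, `v_floor`.
#' @examples
#' rec <- tibble::tibble(
#'   survey_id = "s1", survey_family = "DHS-like", region_id = "A",
#'   event_year = 2013, outcome = c(1, 0, 0), weight = c(2, 1, 1),
#'   cluster_id = "c1"
#' )
#' estimate_prevalence(rec) # q = 0.5, n_eff = 16/6
#' @export
estimate_prevalence <- function(records) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) abort("No microdata records to estimate from.")
  if (any(records$weight <= 0)) abort("Design weights must be positive.")
  if (!all(records$outcome %in% c(0, 1))) {
    abort("`outcome` must be binary 0/1.")
  }
  out <- records |>
    dplyr::group_by(.data$survey_id, .data$region_id,
                    year = .data$event_year) |>
    dplyr::summarise(
      q = sum(.data$weight * .data$outcome) / sum(.data$weight),
      n = dplyr::n(),
      n_eff = sum(.data$weight)^2 / sum(.data$weight^2),
      .groups = "drop"
    )
  el <- empirical_logit(out$q, out$n_eff)
  out$y_logit <- el$y_logit
  out$v_floor <- el$v_floor
  out
}

#' Assemble observations into a model-ready dataset
#'
#' Indexes design-weighted observations against the region graph and the
#' analysis year window. Multiple observations in the same (region, year)
#' cell are retained — that multiplicity is the survey index of the model and
#' is how estimates from surveys conducted in the same year are combined.
#' Years inside the window with no observations remain part of the
#' prediction support.
#'
#' @param observations A tibble with columns `survey_id`, `region_id`,
#'   `year`, `q`, `n_eff` and optionally `y_logit`/`v_floor` (recomputed if
#'   absent).
#' @param graph A [region_graph()]; every `region_id` must appear in it.
#' @param years Integer vector of consecutive calendar years (the analysis
#'   window); every observation year must fall inside it.
#' @return An object of class `factor_dataset`: list with `observations`
#'   (tibble augmented with region index `k` and year index `t`), `graph`,
#'   `years`, and coverage counts.
#' @export
assemble_dataset <- function(observations, graph, years) {
  stopifnot(inherits(graph, "region_graph"))
  years <- as.integer(years)
  if (length(years) < 1 || !all(diff(years) == 1)) {
    abort("`years` must be a set of consecutive calendar years.")
  }
  obs <- tibble::as_tibble(observations)
  needed <- c("survey_id", "region_id", "year", "q", "n_eff")
  miss <- setdiff(needed, names(obs))
  if (length(miss) > 0) {
    abort(paste0("Observations lack columns: ", paste(miss, collapse = ", ")))
  }
  if (nrow(obs) > 0) {
    unknown <- setdiff(unique(obs$region_id), graph$region_ids)
    if (length(unknown) > 0) {
      abort(paste0("Observation regions not in graph: ",
                   paste(unknown, collapse = ", ")))
    }
    if (any(!obs$year %in% years)) {
      off <- sort(unique(obs$year[!obs$year %in% years]))
      abort(paste0("Observation years outside the analysis window: ",
                   paste(off, collapse = ", ")))
    }
    if (any(obs$q < 0 | obs$q > 1)) abort("`q` must lie in [0, 1].")
    if (any(obs$n_eff <= 0)) abort("`n_eff` must be positive.")
    if (!"y_logit" %in% names(obs)) {
      el <- empirical_logit(obs$q, obs$n_eff)
      obs$y_logit <- el$y_logit
      obs$v_floor <- el$v_floor
    }
    obs$k <- match(obs$region_id, graph$region_ids)
    obs$t <- match(obs$year, years)
  } else {
    obs$y_logit <- numeric(0)
    obs$v_floor <- logical(0)
    obs$k <- integer(0)
    obs$t <- integer(0)
  }
  K <- graph$n_regions
  T <- length(years)
  covered <- nrow(dplyr::distinct(obs[c("k", "t")]))
  structure(
    list(
      observations = obs, graph = graph, years = years,
      n_regions = K, n_years = T,
      n_obs = nrow(obs), n_cells = K * T, n_cells_observed = covered
    ),
    class = "factor_dataset"
  )
}

#' @export
print.factor_dataset <- function(x, ...) {
  cat("<factor_dataset> ", x$n_obs, " observations over ",
      x$n_regions, " regions x ", x$n_years, " years (",
      x$n_cells_observed, "/", x$n_cells, " cells observed)\n", sep = "")
  invisible(x)
}

#' Read pre-aggregated survey observations
#'
#' Alternative entry point when design-weighted estimates already exist:
#' a delimited file with columns `survey_id, region_id, year, q, n_eff`.
#'
#' @param path Path to a delimited text file.
#' @return A tibble of observations suitable for [assemble_dataset()].
#' @export
read_observations <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Read survey microdata from a delimited file
#'
#' Columns: `survey_id, survey_family, region_id, event_year, outcome,
#' weight, cluster_id`.
#'
#' @param path Path to a delimited text file.
#' @return A microdata tibble.
#' @export
read_microdata <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
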