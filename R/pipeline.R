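#' Pipeline configuration
#'
#' Collects everything one factor's end-to-end run needs. Either construct
#' directly or load from a YAML file with the same field names; explicit
#' arguments override file values.
#'
#' @param adjacency Path to the region adjacency file (see
#'   [read_adjacency()]).
#' @param microdata Path to a microdata file, or `NULL` when pre-aggregated
#'   `observations` are supplied instead.
#' @param observations Path to a pre-aggregated observation file.
#' @param survey_years Path to a two-column file (`survey_id, survey_year`)
#'   mapping each survey to its interview year; required with `microdata`.
#' @param out_dir Output directory (created if missing).
#' @param factor_id Label of the factor being modelled.
#' @param years Analysis window, integer vector of consecutive years.
#' @param seed Integer seed for hold-out and MCMC.
#' @param holdout_fraction Held-out fraction for validation (0 disables).
#' @param n_iter,burn_in,thin MCMC settings, see [stgpr_control()].
#' @param change_years Length-2 vector of anchor years for the change
#'   report; defaults to the window endpoints.
#' @param orientation `"high_good"` or `"low_good"` for the octile table.
#' @param file Optional YAML file to read defaults from.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(adjacency = NULL, microdata = NULL,
                            observations = NULL, survey_years = NULL,
                            out_dir = "stgpr-run", factor_id = "factor",
                            years = NULL, seed = 1L,
                            holdout_fraction = 0.10,
                            n_iter = 110000, burn_in = 10000, thin = 10,
                            change_years = NULL,
                            orientation = "high_good", file = NULL) {
  defaults <- list(
    adjacency = NULL, microdata = NULL, observations = NULL,
    survey_years = NULL, out_dir = "stgpr-run", factor_id = "factor",
    years = NULL, seed = 1L, holdout_fraction = 0.10, n_iter = 110000,
    burn_in = 10000, thin = 10, change_years = NULL,
    orientation = "high_good"
  )
  cfg <- defaults
  if (!is.null(file)) {
    from_file <- yaml::read_yaml(file)
    unknown <- setdiff(names(from_file), names(defaults))
    if (length(unknown) > 0) {
      abort(paste0("Unknown config fields: ", paste(unknown, collapse = ", ")))
    }
    cfg <- modifyList(cfg, from_file)
  }
  # explicit arguments override file values
  explicit <- names(Filter(isFALSE, list(
    adjacency = missing(adjacency), microdata = missing(microdata),
    observations = missing(observations),
    survey_years = missing(survey_years), out_dir = missing(out_dir),
    factor_id = missing(factor_id), years = missing(years),
    seed = missing(seed), holdout_fraction = missing(holdout_fraction),
    n_iter = missing(n_iter), burn_in = missing(burn_in),
    thin = missing(thin), change_years = missing(change_years),
    orientation = missing(orientation)
  )))
  supplied <- mget(explicit)
  cfg[explicit] <- supplied
  if (is.null(cfg$adjacency)) abort("`adjacency` path is required.")
  if (is.null(cfg$microdata) && is.null(cfg$observations)) {
    abort("Provide either `microdata` or `observations`.")
  }
  if (!is.null(cfg$microdata) && is.null(cfg$survey_years)) {
    abort("`survey_years` is required with `microdata` (recall filter).")
  }
  if (is.null(cfg$years)) abort("`years` (analysis window) is required.")
  cfg$years <- as.integer(cfg$years)
  if (is.null(cfg$change_years)) cfg$change_years <- range(cfg$years)
  structure(cfg, class = "pipeline_config")
}

file_digest <- function(path) unname(tools::md5sum(path))

#' Run the full analysis pipeline for one factor
#'
#' Stages in order: estimate (design-weighted prevalence from microdata,
#' after the recall-window filter) or load pre-aggregated observations;
#' fit (hold-out split, MCMC on the training set); predict (posterior
#' surface); validate (hold-out metrics); report (change between the anchor
#' years and the end-year octile table). Every stage writes a delimited
#' file into `out_dir`, and a JSON manifest records the config, input
#' digests, stage timings and record counts. When `resume = TRUE` and the
#' manifest shows unchanged input digests, config and completed outputs, the
#' run is skipped.
#'
#' @param config A [pipeline_config()].
#' @param resume Skip recomputation when inputs and config are unchanged.
#' @return Invisibly, a list with the fitted model, surface, CV report,
#'   change report, octile table and manifest path.
#' @export
run_pipeline <- function(config, resume = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))

  ## pre-flight: inputs must exist before anything is written
  inputs <- Filter(Negate(is.null),
                   config[c("adjacency", "microdata", "observations",
                            "survey_years")])
  for (p in inputs) {
    if (!file.exists(p)) abort(paste0("Pre-flight: input file missing: ", p))
  }
  digests <- purrr::map_chr(inputs, file_digest)
  cfg_snapshot <- unclass(config)
  cfg_digest <- digest_of(cfg_snapshot)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    observations = file.path(config$out_dir, "observations.csv"),
    hyper_draws = file.path(config$out_dir, "hyperparameter_draws.csv"),
    surface = file.path(config$out_dir, "surface.csv"),
    cv = file.path(config$out_dir, "cv_report.csv"),
    change = file.path(config$out_dir, "change_report.csv"),
    octiles = file.path(config$out_dir, "octile_table.csv"),
    manifest = file.path(config$out_dir, "manifest.json")
  )

  if (resume && file.exists(paths$manifest)) {
    old <- jsonlite::read_json(paths$manifest)
    if (identical(unlist(old$input_digests), unlist(digests)) &&
        identical(old$config_digest, cfg_digest) &&
        all(purrr::map_lgl(paths, file.exists))) {
      message("run_pipeline: inputs and config unchanged; skipping.")
      return(invisible(list(manifest = paths$manifest, skipped = TRUE)))
    }
  }

  timings <- list()
  counts <- list()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      abort(paste0("Pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
    timings[[name]] <<- round(
      as.numeric(difftime(Sys.time(), t0, units = "secs")), 3)
    res
  }

  graph <- stage("graph", read_adjacency(config$adjacency))

  obs <- stage("estimate", {
    if (!is.null(config$microdata)) {
      rec <- read_microdata(config$microdata)
      sy <- readr::read_csv(config$survey_years, show_col_types = FALSE)
      rec <- filter_recall_window(rec, sy)
      estimate_prevalence(rec)
    } else {
      read_observations(config$observations)
    }
  })
  readr::write_csv(obs, paths$observations)
  counts$observations <- nrow(obs)

  dataset <- assemble_dataset(obs, graph, config$years)
  fit <- stage("fit", {
    if (config$holdout_fraction > 0) {
      split <- holdout_split(dataset, config$holdout_fraction,
                             seed = config$seed)
      train <- split$train
    } else {
      split <- NULL
      train <- dataset
    }
    ctrl <- stgpr_control(n_iter = config$n_iter, burn_in = config$burn_in,
                          thin = config$thin, seed = config$seed)
    list(fit = stgpr(train, ctrl), split = split)
  })
  readr::write_csv(
    tibble::as_tibble(fit$fit$draws[c("alpha", "sigma2", "rho_s", "phi",
                                      "tau2")]),
    paths$hyper_draws
  )
  counts$retained_draws <- fit$fit$n_draws

  surface <- stage("predict", posterior_surface(fit$fit))
  write_surface(surface, paths$surface)

  cv <- stage("validate", {
    if (!is.null(fit$split)) {
      cv_metrics(fit$split$test, surface)
    } else {
      tibble::tibble(correlation = NA_real_, mae = NA_real_, rmse = NA_real_,
                     n_held_out = 0L)
    }
  })
  write_cv_report(cv, paths$cv, factor_id = config$factor_id,
                  seed = config$seed)

  report <- stage("report", {
    cr <- surface_change_report(surface, config$change_years[1],
                                config$change_years[2],
                                factor_id = config$factor_id)
    end_vals <- surface |>
      tibble::as_tibble() |>
      dplyr::filter(.data$year == config$change_years[2]) |>
      dplyr::transmute(.data$region_id, value = 100 * .data$mean)
    oct <- octile_rank(end_vals, orientation = config$orientation)
    oct$factor_id <- config$factor_id
    list(change = cr, octiles = oct)
  })
  write_change_report(report$change, paths$change)
  write_octile_table(report$octiles, paths$octiles)

  manifest <- list(
    package_version = as.character(utils::packageVersion("stgpr")),
    config = cfg_snapshot,
    config_digest = cfg_digest,
    input_digests = as.list(digests),
    seed = config$seed,
    timings_sec = timings,
    counts = counts,
    finished = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  # atomic write: temp file then rename
  tmp <- tempfile(tmpdir = config$out_dir, fileext = ".json")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE)
  file.rename(tmp, paths$manifest)

  invisible(list(fit = fit$fit, surface = surface, cv = cv,
                 change = report$change, octiles = report$octiles,
                 manifest = paths$manifest, skipped = FALSE))
}

# stable digest of an R object via its serialized text representation
digest_of <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(deparse(x), collapse = "\n"), tmp)
  unname(tools::md5sum(tmp))
}
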