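#' Simulate a connected planar-like region graph
#'
#' Random geometric graph on the unit square (edges join points closer than
#' `sqrt(2 / K)`), augmented with the Euclidean minimum spanning tree so the
#' result is always connected — a reasonable stand-in for a county
#' contiguity graph.
#'
#' @param n_regions Number of regions, K >= 2.
#' @param seed Integer seed; the graph is reproducible.
#' @return A [region_graph()] with region ids `R01, R02, ...`.
#' @export
simulate_graph <- function(n_regions, seed = 1L) {
  stopifnot(n_regions >= 2)
  set.seed(seed)
  ids <- sprintf("R%02d", seq_len(n_regions))
  xy <- cbind(runif(n_regions), runif(n_regions))
  dd <- as.matrix(stats::dist(xy))
  radius <- sqrt(2 / n_regions)
  A <- (dd < radius) * 1
  diag(A) <- 0
  mst <- igraph::mst(
    igraph::graph_from_adjacency_matrix(dd, mode = "undirected",
                                        weighted = TRUE)
  )
  A_mst <- as.matrix(igraph::as_adjacency_matrix(mst))
  A <- pmax(A, A_mst)
  idx <- which(A == 1 & upper.tri(A), arr.ind = TRUE)
  region_graph(
    data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]]),
    region_ids = ids
  )
}

#' Simulate the latent field and true prevalence surface
#'
#' Draws `S ~ MVN(0, sigma2 * (R_S %x% R_T))` using the Cholesky roots of
#' the two factors (`S = sqrt(sigma2) * L_S Z L_T'`), then maps to the
#' probability scale: `surface = plogis(alpha + S)`.
#'
#' @param graph A [region_graph()].
#' @param years Integer vector of consecutive years.
#' @param params A [model_params()] used as the generative truth.
#' @param seed Integer seed.
#' @return A list of class `stgpr_truth`: `field` (K x T matrix of
#'   logit-scale deviations), `surface` (K x T probabilities), `years`,
#'   `params`.
#' @export
simulate_truth <- function(graph, years, params, seed = 1L) {
  stopifnot(inherits(graph, "region_graph"), inherits(params, "model_params"))
  years <- as.integer(years)
  T <- length(years)
  set.seed(seed)
  R_s <- car_correlation(graph, params$rho_s)
  R_t <- ar1_correlation(T, params$phi)
  L_s <- t(chol(R_s))
  U_t <- chol(R_t)
  Z <- matrix(rnorm(graph$n_regions * T), graph$n_regions, T)
  field <- sqrt(params$sigma2) * (L_s %*% Z %*% U_t)
  dimnames(field) <- list(graph$region_ids, years)
  structure(
    list(field = field, surface = plogis(params$alpha + field),
         years = years, params = params),
    class = "stgpr_truth"
  )
}

#' Define a synthetic survey simulation plan
#'
#' Pins down everything the microdata generator needs: the survey schedule
#' (which survey, of which family, interviews which regions in which year,
#' with what per-region sample-size range) and the design-weight dispersion.
#'
#' @param schedule A tibble with columns `survey_id`, `survey_family`,
#'   `survey_year`, `regions` (list-column of region-id vectors) and
#'   `n_per_region` (list-column or numeric: target respondents per region,
#'   each >= 5).
#' @param weight_dispersion Coefficient of variation of the log-normal
#'   cluster-level design weights (0 gives equal weights and so Kish
#'   `n_eff = n`).
#' @param cluster_size Mean respondents per sampling cluster.
#' @param seed Integer seed used by the generator.
#' @return A `simulation_plan` list.
#' @export
simulation_plan <- function(schedule, weight_dispersion = 0.5,
                            cluster_size = 25, seed = 1L) {
  schedule <- tibble::as_tibble(schedule)
  needed <- c("survey_id", "survey_family", "survey_year", "regions",
              "n_per_region")
  miss <- setdiff(needed, names(schedule))
  if (length(miss) > 0) {
    abort(paste0("Schedule lacks columns: ", paste(miss, collapse = ", ")))
  }
  if (any(unlist(schedule$n_per_region) < 5)) {
    abort("Per-region sample targets must be at least 5.")
  }
  stopifnot(weight_dispersion >= 0, cluster_size >= 1)
  structure(
    list(schedule = schedule, weight_dispersion = weight_dispersion,
         cluster_size = cluster_size, seed = as.integer(seed)),
    class = "simulation_plan"
  )
}

# family-specific maximum recall lag used by the generator; one extra year
# beyond what the recall filter keeps, so filtering is exercised
generator_lags <- c("DHS-like" = 3, "MICS-like" = 2, "census-like" = 0)

#' Simulate survey microdata from a true prevalence surface
#'
#' For every scheduled (survey, region) pair the generator draws respondents
#' whose event years are spread over the survey's recall window (including
#' the one lag the recall filter will drop, so harmonisation is exercised;
#' lags are capped so no event precedes the analysis window), assigns them
#' to sampling clusters whose log-normal weights create the configured
#' design-weight dispersion, and draws binary outcomes
#' `Bernoulli(surface[region, event_year])`.
#'
#' @param plan A [simulation_plan()].
#' @param truth An `stgpr_truth` from [simulate_truth()].
#' @param graph The [region_graph()] the truth was simulated on.
#' @return A microdata tibble with columns `survey_id`, `survey_family`,
#'   `region_id`, `event_year`, `outcome`, `weight`, `cluster_id`.
#' @export
simulate_microdata <- function(plan, truth, graph) {
  stopifnot(inherits(plan, "simulation_plan"), inherits(truth, "stgpr_truth"),
            inherits(graph, "region_graph"))
  sched <- plan$schedule
  if (nrow(sched) == 0) {
    return(tibble::tibble(
      survey_id = character(), survey_family = character(),
      region_id = character(), event_year = integer(), outcome = integer(),
      weight = numeric(), cluster_id = character()
    ))
  }
  bad <- setdiff(unique(unlist(sched$regions)), graph$region_ids)
  if (length(bad) > 0) {
    abort(paste0("Schedule references unknown regions: ",
                 paste(bad, collapse = ", ")))
  }
  set.seed(plan$seed)
  year0 <- min(truth$years)
  sdlog <- sqrt(log(1 + plan$weight_dispersion^2))

  rows <- purrr::pmap(sched, function(survey_id, survey_family, survey_year,
                                      regions, n_per_region, ...) {
    max_lag <- min(generator_lags[[survey_family]], survey_year - year0)
    n_per <- rep_len(unlist(n_per_region), length(regions))
    purrr::map2(regions, n_per, function(r, n) {
      k <- match(r, graph$region_ids)
      lag <- sample.int(max_lag + 1L, n, replace = TRUE) - 1L
      event_year <- as.integer(survey_year - lag)
      t_idx <- match(event_year, truth$years)
      n_clusters <- max(1L, round(n / plan$cluster_size))
      cl <- sample.int(n_clusters, n, replace = TRUE)
      w_cl <- if (plan$weight_dispersion > 0) {
        rlnorm(n_clusters, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      } else {
        rep(1, n_clusters)
      }
      tibble::tibble(
        survey_id = survey_id, survey_family = survey_family,
        region_id = r, event_year = event_year,
        outcome = rbinom(n, 1L, truth$surface[k, t_idx]),
        weight = w_cl[cl],
        cluster_id = sprintf("%s_%s_c%02d", survey_id, r, cl)
      )
    })
  })
  dplyr::bind_rows(rows)
}

#' Simulate observations directly from the observation model
#'
#' The well-specified generator: one observation per scheduled cell with
#' `y_logit ~ Normal(alpha + S_kt, tau2 / log(n_eff))` and
#' `q = plogis(y_logit)`. Used for calibration experiments where the noise
#' model must hold exactly (survey microdata instead carries binomial
#' noise).
#'
#' @param truth An `stgpr_truth`.
#' @param graph The matching [region_graph()].
#' @param n_eff_range Range the per-cell effective sample sizes are drawn
#'   from (uniformly).
#' @param prop_observed Fraction of (region, year) cells that receive an
#'   observation.
#' @param seed Integer seed.
#' @return An observation tibble for [assemble_dataset()].
#' @export
simulate_observations <- function(truth, graph, n_eff_range = c(50, 500),
                                  prop_observed = 1, seed = 1L) {
  stopifnot(inherits(truth, "stgpr_truth"), inherits(graph, "region_graph"),
            prop_observed > 0, prop_observed <= 1)
  set.seed(seed)
  K <- graph$n_regions
  T <- length(truth$years)
  cells <- tidyr::expand_grid(k = seq_len(K), t = seq_len(T))
  n_keep <- max(2, round(prop_observed * nrow(cells)))
  cells <- cells[sort(sample.int(nrow(cells), n_keep)), ]
  p <- truth$params
  n_eff <- runif(nrow(cells), n_eff_range[1], n_eff_range[2])
  mu <- p$alpha + truth$field[cbind(cells$k, cells$t)]
  y <- rnorm(nrow(cells), mu, sqrt(noise_variance(n_eff, p$tau2)))
  tibble::tibble(
    survey_id = "sim",
    region_id = graph$region_ids[cells$k],
    year = truth$years[cells$t],
    q = plogis(y),
    n_eff = n_eff,
    y_logit = y,
    v_floor = FALSE
  )
}

#' The canonical synthetic test scenario
#'
#' A fixed mid-scale bundle used throughout the test-suite and validation
#' experiments: 12 regions, 10 years (2005-2014), truth
#' `alpha = -0.5, sigma2 = 1, rho_s = 0.9, phi = 0.8, tau2 = 1.5`, and seven
#' surveys of mixed families (three DHS-like, three MICS-like, one
#' census-like) with per-region samples between 30 and 800 and partial
#' region coverage, leaving some (region, year) cells unobserved so
#' prediction into non-sampled cells is exercised.
#'
#' @param seed Integer seed controlling the graph, the latent truth and the
#'   microdata.
#' @return A list: `graph`, `truth`, `plan`, `microdata`, `params`, `years`.
#' @export
reference_scenario <- function(seed = 1L) {
  years <- 2005:2014
  params <- model_params(alpha = -0.5, sigma2 = 1.0, rho_s = 0.9, phi = 0.8,
                         tau2 = 1.5)
  graph <- simulate_graph(12, seed = seed)
  truth <- simulate_truth(graph, years, params, seed = seed + 1000L)

  set.seed(seed + 2000L)
  ids <- graph$region_ids
  pick <- function(n) sort(sample(ids, n))
  schedule <- tibble::tibble(
    survey_id = sprintf("svy%02d", 1:7),
    survey_family = c("DHS-like", "MICS-like", "census-like", "DHS-like",
                      "MICS-like", "DHS-like", "MICS-like"),
    survey_year = c(2006L, 2008L, 2009L, 2011L, 2012L, 2014L, 2010L),
    regions = list(pick(9), pick(8), ids, pick(10), pick(8), ids, pick(9)),
    n_per_region = list(
      sample(100:400, 9, TRUE), sample(30:200, 8, TRUE),
      sample(500:800, 12, TRUE), sample(100:400, 10, TRUE),
      sample(30:200, 8, TRUE), sample(100:400, 12, TRUE),
      sample(30:200, 9, TRUE)
    )
  )
  plan <- simulation_plan(schedule, weight_dispersion = 0.5,
                          seed = seed + 3000L)
  microdata <- simulate_microdata(plan, truth, graph)
  list(graph = graph, truth = truth, plan = plan, microdata = microdata,
       params = params, years = years)
}

#' A study-scale synthetic survey plan
#'
#' Emulates the structure of a two-decade national survey archive: 47
#' regions, 22 years, twenty surveys of two families (seven DHS-like with a
#' 3-year recall window, eleven MICS-like with 2-year recall) plus two
#' census-like enumerations, irregular survey years, partial region
#' coverage for the sample surveys, and per-region samples between 20 and
#' 2000.
#'
#' @param graph A [region_graph()] (typically `simulate_graph(47, ...)`).
#' @param years Analysis window, default `1993:2014`.
#' @param seed Integer seed.
#' @return A [simulation_plan()].
#' @export
study_scale_plan <- function(graph, years = 1993:2014, seed = 1L) {
  stopifnot(inherits(graph, "region_graph"))
  set.seed(seed)
  ids <- graph$region_ids
  dhs_years <- c(1993L, 1998L, 2003L, 2007L, 2008L, 2010L, 2014L)
  mics_years <- sort(sample(setdiff(min(years):max(years), dhs_years), 11))
  census_years <- c(1999L, 2009L)
  fam <- c(rep("DHS-like", length(dhs_years)),
           rep("MICS-like", length(mics_years)),
           rep("census-like", length(census_years)))
  yrs <- c(dhs_years, mics_years, census_years)
  n_surveys <- length(yrs)
  schedule <- tibble::tibble(
    survey_id = sprintf("svy%02d", seq_len(n_surveys)),
    survey_family = fam,
    survey_year = as.integer(yrs),
    regions = purrr::map(fam, function(f) {
      if (f == "census-like") ids
      else sort(sample(ids, round(length(ids) * runif(1, 0.6, 1))))
    })
  )
  schedule$n_per_region <- purrr::map(schedule$regions, function(r) {
    sample(20:2000, length(r), replace = TRUE)
  })
  simulation_plan(schedule, weight_dispersion = 0.5, seed = seed)
}
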