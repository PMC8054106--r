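# Independent oracles and small fixtures shared across tests.
# The dense multivariate-normal oracle deliberately forms the full KT x KT
# covariance and uses a plain Cholesky, independent of the package's
# factor-spectral evaluation path.

dense_mvn_logpdf <- function(x, Sigma) {
  L <- chol(Sigma)
  z <- backsolve(L, x, transpose = TRUE)
  -0.5 * (length(x) * log(2 * pi) + 2 * sum(log(diag(L))) + sum(z^2))
}

path_graph <- function(n = 3) {
  ids <- LETTERS[seq_len(n)]
  region_graph(data.frame(from = ids[-n], to = ids[-1]), region_ids = ids)
}

# random connected graph on K vertices: random spanning tree plus extras
random_graph <- function(K, p_extra = 0.3) {
  stopifnot(K >= 2)
  ids <- sprintf("G%02d", seq_len(K))
  from <- integer(0); to <- integer(0)
  for (k in 2:K) {
    j <- sample.int(k - 1, 1)
    from <- c(from, j); to <- c(to, k)
  }
  extra <- which(upper.tri(matrix(0, K, K)), arr.ind = TRUE)
  keep <- runif(nrow(extra)) < p_extra
  from <- c(from, extra[keep, 1]); to <- c(to, extra[keep, 2])
  region_graph(data.frame(from = ids[from], to = ids[to]), region_ids = ids)
}

# minimal observation tibble for assembling tiny datasets
make_obs <- function(region_id, year, q, n_eff, survey_id = "s1") {
  tibble::tibble(survey_id = survey_id, region_id = region_id, year = year,
                 q = q, n_eff = n_eff)
}

two_region_graph <- function() {
  region_graph(data.frame(from = "A", to = "B"))
}

# batch-means Monte-Carlo standard error of a chain mean (robust to
# autocorrelation)
mcse_batch <- function(x, n_batches = 40) {
  n <- length(x)
  bs <- floor(n / n_batches)
  means <- vapply(seq_len(n_batches), function(b) {
    mean(x[((b - 1) * bs + 1):(b * bs)])
  }, numeric(1))
  sd(means) / sqrt(n_batches)
}

# hyperprior terms at the default priors, written out independently of the
# package internals: alpha ~ N(0,10^2), half-normal(5) on both SDs expressed
# as densities over the variances, phi ~ U(-1,1)
hyper_const <- function(p, alpha_sd = 10, sigma_scale = 5, tau_scale = 5) {
  hn <- function(v, scale) {
    s <- sqrt(v)
    log(2) + dnorm(s, 0, scale, log = TRUE) - log(2 * s)
  }
  dnorm(p$alpha, 0, alpha_sd, log = TRUE) +
    hn(p$sigma2, sigma_scale) + hn(p$tau2, tau_scale) - log(2)
}
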