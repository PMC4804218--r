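test_that("log_joint equals an independent term-by-term density computation", {
  set.seed(2)
  x <- rnorm(40, 0.8, 0.05)
  pr <- gmm_priors()
  ## k = 1: every term has a closed form via stats d* functions
  st <- list(k = 1L, pi = 1, mu = 0.79, sigma2 = 0.003, beta = 2.5,
             z = rep(1L, 40))
  r <- max(x) - min(x)
  want <- dpois(1, 1, log = TRUE) +
    0 +  # Dirichlet(1) over a single weight: log Gamma(1) = 0
    dnorm(0.79, median(x), r, log = TRUE) +
    dgamma(1 / 0.003, 2, rate = 2.5, log = TRUE) +
    dgamma(2.5, 0.2, rate = 10 / r^2, log = TRUE) +
    sum(dnorm(x, 0.79, sqrt(0.003), log = TRUE))
  expect_equal(log_joint(x, st, pr), want, tolerance = 1e-12)

  ## doubling gamma changes only the Dirichlet term
  st2 <- list(k = 2L, pi = c(0.3, 0.7), mu = c(0.7, 0.9),
              sigma2 = c(0.002, 0.004), beta = 1.5,
              z = rep(1:2, each = 20))
  ddir <- function(p, g) lgamma(2 * g) - 2 * lgamma(g) + sum((g - 1) * log(p))
  delta <- log_joint(x, st2, gmm_priors(gamma = 2)) - log_joint(x, st2, pr)
  ## isolate: the z term log pi[z] is unchanged, so delta is the Dirichlet diff
  expect_equal(delta, ddir(c(0.3, 0.7), 2) - ddir(c(0.3, 0.7), 1),
               tolerance = 1e-12)

  ## permuting component labels leaves log_joint unchanged
  st2p <- list(k = 2L, pi = c(0.7, 0.3), mu = c(0.9, 0.7),
               sigma2 = c(0.004, 0.002), beta = 1.5,
               z = rep(2:1, each = 20))
  expect_equal(log_joint(x, st2, pr), log_joint(x, st2p, pr), tolerance = 1e-12)

  expect_error(log_joint(x, modifyList(st, list(sigma2 = 0)), pr), "positive")
})

test_that("with k_max = 1 the sampler matches the conjugate closed form", {
  x <- generate_gmm_data(1, 0.8, 0.05, n = 200, seed = 31)
  fit <- fit_rjmcmc(x, priors = gmm_priors(k_max = 1),
                    settings = mcmc_settings(6000, 1000, 2, seed = 17))
  mus <- purrr::map_dbl(fit$samples, "mu")
  s2s <- purrr::map_dbl(fit$samples, "sigma2")
  pr <- fit$priors
  ## closed-form Normal-Normal posterior mean of mu given sigma2; average
  ## over the sampled sigma2 to integrate the scale out
  closed <- mean((sum(x) / s2s + pr$kappa * pr$xi) /
                   (length(x) / s2s + pr$kappa))
  mc_se <- sd(mus) / sqrt(length(mus) / 10)  # generous ESS discount
  expect_lt(abs(mean(mus) - closed), 3 * mc_se + 1e-4)
  expect_equal(modal_k(fit), 1L)
  ## no dimension-changing moves are ever attempted at k_max = 1
  expect_equal(sum(fit$accept$attempts[fit$accept$move %in%
                                         c("split", "combine")]), 0L)
})

test_that("short-chain recovery: one- and two-component mixtures", {
  x1 <- generate_gmm_data(1, 0.8, 0.05, n = 150, seed = 41)
  f1 <- fit_rjmcmc(x1, settings = short_mcmc(3, iterations = 4000, burn_in = 1000))
  expect_equal(modal_k(f1), 1L)
  mu1 <- purrr::map_dbl(Filter(function(s) s$k == 1, f1$samples), "mu")
  expect_lt(abs(mean(mu1) - 0.8), 0.03)

  x2 <- generate_gmm_data(c(0.5, 0.5), c(0.65, 0.90), c(0.03, 0.02),
                          n = 300, seed = 42)
  f2 <- fit_rjmcmc(x2, settings = short_mcmc(4, iterations = 6000, burn_in = 1500))
  expect_equal(modal_k(f2), 2L)
  mm <- purrr::map(Filter(function(s) s$k == 2, f2$samples),
                   function(s) sort(s$mu))
  mm <- do.call(rbind, mm)
  expect_lt(max(abs(colMeans(mm) - c(0.65, 0.90))), 0.04)
  ## the sampler genuinely moves between models
  sc <- fit_rjmcmc(x2, settings = short_mcmc(4, iterations = 2000))$accept
  rate <- sum(sc$accepted[sc$move %in% c("split", "combine")]) /
    sum(sc$attempts[sc$move %in% c("split", "combine")])
  expect_gt(rate, 0)
  expect_lt(rate, 1)
})

test_that("chains are byte-identical under the same seed", {
  x <- generate_gmm_data(1, 0.75, 0.04, n = 60, seed = 9)
  f1 <- fit_rjmcmc(x, settings = short_mcmc(99))
  f2 <- fit_rjmcmc(x, settings = short_mcmc(99))
  expect_identical(f1$samples, f2$samples)
  expect_identical(f1$k_trace, f2$k_trace)
  f3 <- fit_rjmcmc(x, settings = short_mcmc(100))
  expect_false(identical(f1$k_trace, f3$k_trace))
})

test_that("sampler rejects unusable data", {
  expect_error(fit_rjmcmc(c(0.7, 0.8, 0.9), settings = short_mcmc(1)), "CEP")
  expect_error(fit_rjmcmc(c(0.7, 0.8, NA, 0.9, 0.8, 0.7),
                          settings = short_mcmc(1)), "finite")
})

test_that("posterior predictive draws follow the mixture moments", {
  ## degenerate limit: single component, near-zero variance
  f <- structure(list(samples = list(list(k = 1L, pi = 1, mu = 0.8,
                                          sigma2 = 1e-12, beta = 1)),
                      settings = mcmc_settings(seed = 1), x = rep(0.8, 10)),
                 class = "rjmcmc_gmm")
  pp <- posterior_predictive(f, draws_per_sample = 50, seed = 2)
  expect_equal(length(pp$draws), 50)
  expect_equal(pp$draws, rep(0.8, 50), tolerance = 1e-5)

  ## law of large numbers: mean of draws ~ E[sum pi mu] over samples
  set.seed(5)
  samples <- random_samples(200)
  f2 <- structure(list(samples = samples, settings = mcmc_settings(seed = 3),
                       x = runif(30, 0.5, 1)),
                  class = "rjmcmc_gmm")
  pp2 <- posterior_predictive(f2, draws_per_sample = 50, seed = 4)
  want <- mean(purrr::map_dbl(samples, function(s) sum(s$pi * s$mu)))
  sigma_bar <- sqrt(mean(purrr::map_dbl(samples, function(s)
    sum(s$pi * (s$sigma2 + s$mu^2)) - sum(s$pi * s$mu)^2)))
  expect_lt(abs(mean(pp2$draws) - want),
            3 * sigma_bar / sqrt(length(pp2$draws)) + 0.01)

  pp3 <- posterior_predictive(f2, draws_per_sample = 50, seed = 4)
  expect_identical(pp2$draws, pp3$draws)
})

test_that("c3p bounds, monotonicity and the all-below limit", {
  set.seed(6)
  f <- structure(list(samples = random_samples(100),
                      settings = mcmc_settings(seed = 7), x = runif(20, 0.5, 1)),
                 class = "rjmcmc_gmm")
  pp <- posterior_predictive(f, draws_per_sample = 20, seed = 8)
  s <- seq(0, 1.5, by = 0.05)
  v <- c3p(s, pp)
  expect_true(all(diff(v) >= 0))
  expect_equal(c3p(max(pp$draws), pp), 1)
  expect_equal(c3p(min(pp$draws) - 1, pp), 0)
})

test_that("Monte-Carlo c3p agrees with the analytic mixture-CDF average", {
  ## posterior fixed at a single Normal(0.8, 0.05^2): c3p(0.8) ~ 0.5
  f <- structure(list(samples = list(list(k = 1L, pi = 1, mu = 0.8,
                                          sigma2 = 0.05^2, beta = 1)),
                      settings = mcmc_settings(seed = 1), x = rep(0.8, 10)),
                 class = "rjmcmc_gmm")
  m_draws <- 4000
  pp <- posterior_predictive(f, draws_per_sample = m_draws, seed = 11)
  expect_lt(abs(c3p(0.8, pp) - 0.5), 3 * sqrt(0.25 / m_draws))
  expect_equal(c3p_analytic(0.8, f), 0.5, tolerance = 1e-12)

  ## randomized posteriors: binomial-SE agreement
  set.seed(12)
  for (i in 1:10) {
    samples <- random_samples(40)
    fr <- structure(list(samples = samples, settings = mcmc_settings(seed = i),
                         x = runif(20, 0.5, 1)),
                    class = "rjmcmc_gmm")
    s <- runif(1, 0.5, 1)
    ppr <- posterior_predictive(fr, draws_per_sample = 250, seed = i)
    p_hat <- c3p(s, ppr)
    p_true <- c3p_analytic(s, fr)
    se <- sqrt(max(p_true * (1 - p_true), 1e-4) / length(ppr$draws))
    expect_lt(abs(p_hat - p_true), 4 * se + 1e-3)
  }
})

test_that("analytic c3p matches numerical integration of the mixture CDF", {
  samples <- list(
    list(k = 2L, pi = c(0.4, 0.6), mu = c(0.65, 0.9),
         sigma2 = c(0.03, 0.02)^2, beta = 1),
    list(k = 1L, pi = 1, mu = 0.8, sigma2 = 0.04^2, beta = 1)
  )
  dens <- function(t) {
    purrr::map_dbl(t, function(ti) {
      mean(purrr::map_dbl(samples, function(s)
        sum(s$pi * dnorm(ti, s$mu, sqrt(s$sigma2)))))
    })
  }
  for (s in c(0.6, 0.75, 0.85, 0.95)) {
    quad <- stats::integrate(dens, -Inf, s, rel.tol = 1e-10)$value
    expect_equal(c3p_analytic(s, samples), quad, tolerance = 1e-8)
  }
})

test_that("C3P classification is label-invariant, order-independent and seeded", {
  u <- generate_universe(discrete_universe_config(3, 25), seed = 44)
  q <- purrr::map_chr(u$truth$members, 1)  # one query per fold
  rest <- u$classification[!u$classification$domain_id %in% q, ]
  profs <- build_profiles(u$local, rest, min_fold_size = 2)
  fits <- fit_fold_models(profs, settings = short_mcmc(55))
  r1 <- classify_c3p(q[1], u$local, profs, fits, draws_per_sample = 5)
  r2 <- classify_c3p(q[1], u$local, profs, fits, draws_per_sample = 5)
  expect_identical(r1$per_fold, r2$per_fold)   # order/evaluation independent
  ## permuting component labels inside every sample leaves C3P unchanged
  fits_perm <- purrr::map(fits, function(f) {
    f$samples <- purrr::map(f$samples, function(s) {
      if (s$k == 1) return(s)
      p <- rev(seq_len(s$k))
      list(k = s$k, pi = s$pi[p], mu = s$mu[p], sigma2 = s$sigma2[p],
           beta = s$beta)
    })
    f
  })
  s_grid <- c(0.6, 0.8, 0.95)
  expect_equal(c3p_analytic(s_grid, fits[[1]]),
               c3p_analytic(s_grid, fits_perm[[1]]), tolerance = 1e-12)

  ## discrete universe: c3p agrees with tm_max for every query
  res <- classify_queries(q, u$local, profs, methods = c("tm_max", "c3p"),
                          original = u$classification, fits = fits)
  wide <- res |>
    dplyr::distinct(query_id, method, assigned_fold) |>
    tidyr::pivot_wider(names_from = "method", values_from = "assigned_fold")
  expect_equal(wide$c3p, wide$tm_max)
  expect_equal(wide$c3p, unname(u$classification$fold_id[
    match(wide$query_id, u$classification$domain_id)]))
})
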