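#' Priors for the within-fold Gaussian mixture
#'
#' The Bayesian mixture of an unknown number `k` of Gaussian components
#' fitted to a fold's within-fold TM_max scores `x`. Hyperparameters follow
#' the weakly-informative settings of Richardson & Green's univariate
#' mixture analysis: Dirichlet concentration `gamma = 1` per component;
#' component means `mu_j ~ N(xi, 1/kappa)` with `xi` the data median and
#' `kappa = 1/R^2` (`R` = data range); component precisions
#' `1/sigma_j^2 ~ Gamma(alpha = 2, beta)` with the rate hyperprior
#' `beta ~ Gamma(g = 0.2, h = 10/R^2)` expressing the belief that component
#' variances are similar; `k ~ Poisson(lambda = 1)` truncated to
#' `1..k_max`.
#'
#' Data-dependent defaults (`xi`, `kappa`, `h`) are resolved against `x`
#' when the sampler runs; set them explicitly to override.
#'
#' @param gamma Dirichlet concentration per component (default 1).
#' @param xi Prior mean of component means (default: `median(x)`).
#' @param kappa Prior precision of component means (default: `1/R^2`).
#' @param alpha Shape of the precision prior (default 2).
#' @param g Shape of the hyperprior on `beta` (default 0.2).
#' @param h Rate of the hyperprior on `beta` (default `10/R^2`).
#' @param lambda Poisson rate for `k` (default 1).
#' @param k_max Truncation of the number of components (default 30).
#' @returns A `gmm_priors` list.
#' @export
gmm_priors <- function(gamma = 1, xi = NULL, kappa = NULL, alpha = 2,
                       g = 0.2, h = NULL, lambda = 1, k_max = 30) {
  stopifnot(gamma > 0, alpha > 0, g > 0, lambda > 0, k_max >= 1)
  structure(list(gamma = gamma, xi = xi, kappa = kappa, alpha = alpha,
                 g = g, h = h, lambda = lambda, k_max = as.integer(k_max)),
            class = "gmm_priors")
}

resolve_priors <- function(priors, x) {
  priors <- priors %||% gmm_priors()
  r <- max(x) - min(x)
  if (r <= 0) r <- max(abs(x), 1e-3)  # degenerate constant data
  priors$xi <- priors$xi %||% median(x)
  priors$kappa <- priors$kappa %||% (1 / r^2)
  priors$h <- priors$h %||% (10 / r^2)
  stopifnot(priors$kappa > 0, priors$h > 0)
  priors
}

#' MCMC settings for the reversible-jump sampler
#'
#' @param iterations Total sweeps (default 30000).
#' @param burn_in Discarded initial sweeps (default 5000).
#' @param thin Keep every `thin`-th post-burn-in sweep (default 5).
#' @param seed Integer seed (required for reproducible chains).
#' @returns An `mcmc_settings` list.
#' @export
mcmc_settings <- function(iterations = 30000, burn_in = 5000, thin = 5,
                          seed = NULL) {
  stopifnot(burn_in < iterations, thin >= 1)
  structure(list(iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = seed),
            class = "mcmc_settings")
}

#' Log joint density of the mixture model
#'
#' Log of prior times likelihood (up to the truncation constant of the
#' Poisson prior on `k`): Poisson(k) x Dirichlet(pi) x Normal(mu | xi,
#' 1/kappa) x Gamma(1/sigma^2 | alpha, beta) x Gamma(beta | g, h) x
#' Categorical(z | pi) x Normal(x | mu_z, sigma_z^2).
#'
#' @param x Data vector.
#' @param state List with `k`, `pi`, `mu`, `sigma2`, `beta`, `z`.
#' @param priors A [gmm_priors()] (data-dependent defaults resolved
#'   against `x`).
#' @returns Log density (finite for valid states).
#' @export
log_joint <- function(x, state, priors = NULL) {
  pr <- resolve_priors(priors, x)
  k <- state$k
  if (length(state$pi) != k || length(state$mu) != k ||
      length(state$sigma2) != k || length(state$z) != length(x)) {
    abort("state dimensions inconsistent with `x` and `k`.")
  }
  if (any(state$sigma2 <= 0)) abort("component variances must be positive.")
  if (any(state$z < 1 | state$z > k)) abort("allocations out of range.")
  if (abs(sum(state$pi) - 1) > 1e-9) abort("mixture proportions must sum to 1.")
  lp <- dpois(k, pr$lambda, log = TRUE)
  lp <- lp + lgamma(k * pr$gamma) - k * lgamma(pr$gamma) +
    sum((pr$gamma - 1) * log(state$pi))
  lp <- lp + sum(dnorm(state$mu, pr$xi, 1 / sqrt(pr$kappa), log = TRUE))
  lp <- lp + sum(dgamma(1 / state$sigma2, pr$alpha, rate = state$beta, log = TRUE))
  lp <- lp + dgamma(state$beta, pr$g, rate = pr$h, log = TRUE)
  lp <- lp + sum(log(state$pi[state$z]))
  lp <- lp + sum(dnorm(x, state$mu[state$z], sqrt(state$sigma2[state$z]),
                       log = TRUE))
  lp
}

## move probabilities: P(split | k) for split/combine, P(birth | k) for
## birth/death; boundaries b_1 = 1, b_kmax = 0, otherwise 1/2
p_up <- function(k, k_max) {
  if (k >= k_max) 0 else if (k == 1) 1 else 0.5
}

## full sweep sampler ------------------------------------------------------

#' Fit the within-fold Gaussian mixture by reversible-jump MCMC
#'
#' Samples `(k, pi, mu, sigma2, beta)` from the posterior of the mixture
#' with unknown component count using the Richardson-Green move set: Gibbs
#' updates of the mixture proportions, component parameters, allocations and
#' the precision-prior rate `beta`, a split/combine move with
#' moment-matching proposals (`u1, u2 ~ Beta(2,2)`, `u3 ~ Beta(1,1)`; only
#' components adjacent in mean order may combine), and a birth/death move
#' for empty components. The chain is fully reproducible from
#' `settings$seed`.
#'
#' @param x Numeric vector of within-fold TM_max scores (N >= 5).
#' @param priors A [gmm_priors()] (defaults resolved against `x`).
#' @param settings An [mcmc_settings()].
#' @returns An `rjmcmc_gmm` object: `samples` (list of retained draws, each
#'   with `k`, `pi`, `mu`, `sigma2`, `beta`), `k_trace` (every sweep),
#'   `accept` (attempt/accept counts per move type), resolved `priors`,
#'   `settings`, and the data `x`.
#' @examples
#' \donttest{
#' x <- generate_gmm_data(1, 0.8, 0.05, n = 100, seed = 1)
#' fit <- fit_rjmcmc(x, settings = mcmc_settings(2000, 500, 5, seed = 1))
#' glance(fit)
#' }
#' @export
fit_rjmcmc <- function(x, priors = NULL, settings = mcmc_settings()) {
  if (length(x) < 5) {
    abort("fewer than 5 observations: fit the empirical CEP instead of C3P.")
  }
  if (any(!is.finite(x))) abort("`x` must be finite.")
  pr <- resolve_priors(priors, x)
  if (!is.null(settings$seed)) set.seed(settings$seed)
  n <- length(x)
  k_max <- pr$k_max

  ## initial state: single component at the data moments
  k <- 1L
  z <- rep(1L, n)
  pi_w <- 1
  mu <- mean(x)
  sigma2 <- max(stats::var(x), 1e-6)
  beta <- pr$g / pr$h

  n_keep <- (settings$iterations - settings$burn_in) %/% settings$thin
  samples <- vector("list", n_keep)
  k_trace <- integer(settings$iterations)
  acc <- c(split_att = 0L, split_acc = 0L, comb_att = 0L, comb_acc = 0L,
           birth_att = 0L, birth_acc = 0L, death_att = 0L, death_acc = 0L)
  kept <- 0L

  dnorm_log <- function(v, m, s2) -0.5 * log(2 * pi * s2) - (v - m)^2 / (2 * s2)

  ## log of the split acceptance ratio; combine uses its negative
  split_log_ratio <- function(k_old, w, m, s2, w1, m1, s21, w2, m2, s22,
                              u1, u2, u3, l1, l2, log_palloc, dloglik) {
    b_k <- p_up(k_old, k_max)
    d_k1 <- if (k_old + 1 == k_max) 1 else 0.5
    log(pr$lambda) +
      dloglik +
      (pr$gamma - 1 + l1) * log(w1) + (pr$gamma - 1 + l2) * log(w2) -
      (pr$gamma - 1 + l1 + l2) * log(w) - lbeta(pr$gamma, k_old * pr$gamma) +
      0.5 * log(pr$kappa / (2 * pi)) -
      0.5 * pr$kappa * ((m1 - pr$xi)^2 + (m2 - pr$xi)^2 - (m - pr$xi)^2) +
      pr$alpha * log(beta) - lgamma(pr$alpha) -
      (pr$alpha + 1) * (log(s21) + log(s22) - log(s2)) -
      beta * (1 / s21 + 1 / s22 - 1 / s2) +
      log(d_k1) - log(b_k) - log_palloc -
      dbeta(u1, 2, 2, log = TRUE) - dbeta(u2, 2, 2, log = TRUE) +
      log(w) + log(abs(m2 - m1)) + log(s21) + log(s22) -
      log(u2) - log(1 - u2^2) - log(u3) - log(1 - u3) - log(s2)
  }

  ## log acceptance ratio of a birth of an empty component with weight w_new
  ## into a state with k_old components, n0 of them empty
  birth_log_ratio <- function(k_old, w_new, n0) {
    b_k <- p_up(k_old, k_max)
    d_k1 <- if (k_old + 1 == k_max) 1 else 0.5
    log(pr$lambda) -
      lbeta(k_old * pr$gamma, pr$gamma) +
      (pr$gamma - 1) * log(w_new) +
      (n + k_old * pr$gamma - k_old) * log(1 - w_new) +
      log(d_k1) - log(n0 + 1) - log(b_k) -
      dbeta(w_new, 1, k_old, log = TRUE) +
      (k_old - 1) * log(1 - w_new)
  }

  ## group sums aligned to 1..k even when some components are empty
  group_sum <- function(v, z, k) {
    out <- numeric(k)
    tmp <- rowsum(v, z)
    out[as.integer(rownames(tmp))] <- tmp
    out
  }

  for (it in seq_len(settings$iterations)) {
    counts <- tabulate(z, k)

    ## (i) mixture proportions | z
    gam <- rgamma(k, pr$gamma + counts, 1)
    pi_w <- gam / sum(gam)

    ## (ii) component means and variances | z
    sx <- group_sum(x, z, k)
    prec <- counts / sigma2 + pr$kappa
    mpost <- (sx / sigma2 + pr$kappa * pr$xi) / prec
    mu <- rnorm(k, mpost, 1 / sqrt(prec))
    ss <- group_sum((x - mu[z])^2, z, k)
    sigma2 <- 1 / rgamma(k, pr$alpha + counts / 2, rate = beta + ss / 2)
    ## numeric guard for near-degenerate data (e.g. tied scores): scores
    ## carry ~6 decimals, so variances outside this window are noise
    sigma2 <- pmin(pmax(sigma2, 1e-10), 1e10)

    ## (iii) allocations | parameters
    if (k == 1) {
      z <- rep(1L, n)
    } else {
      ll <- matrix(0, n, k)
      for (j in seq_len(k)) {
        ll[, j] <- log(pi_w[j]) + dnorm_log(x, mu[j], sigma2[j])
      }
      mx <- ll[cbind(seq_len(n), max.col(ll, ties.method = "first"))]
      p <- exp(ll - mx)
      cum <- p
      for (j in 2:k) cum[, j] <- cum[, j - 1] + p[, j]
      u <- runif(n) * cum[, k]
      znew <- rep(1L, n)
      for (j in 1:(k - 1)) znew <- znew + (u > cum[, j])
      z <- znew
    }

    ## (iv) beta | variances
    beta <- rgamma(1, pr$g + k * pr$alpha, rate = pr$h + sum(1 / sigma2))

    ## (v) split / combine
    if (runif(1) < p_up(k, k_max)) {
      acc["split_att"] <- acc["split_att"] + 1L
      j <- sample.int(k, 1)
      w <- pi_w[j]; m <- mu[j]; s2 <- sigma2[j]
      u1 <- rbeta(1, 2, 2); u2 <- rbeta(1, 2, 2); u3 <- runif(1)
      w1 <- w * u1; w2 <- w * (1 - u1)
      m1 <- m - u2 * sqrt(s2 * w2 / w1)
      m2 <- m + u2 * sqrt(s2 * w1 / w2)
      s21 <- u3 * (1 - u2^2) * s2 * w / w1
      s22 <- (1 - u3) * (1 - u2^2) * s2 * w / w2
      others <- mu[-j]
      if (!any(others > m1 & others < m2)) {  # adjacency after split
        idx <- which(z == j)
        if (length(idx)) {
          l1d <- dnorm_log(x[idx], m1, s21) + log(w1)
          l2d <- dnorm_log(x[idx], m2, s22) + log(w2)
          mxp <- pmax(l1d, l2d)
          p1 <- exp(l1d - mxp) / (exp(l1d - mxp) + exp(l2d - mxp))
          to1 <- runif(length(idx)) < p1
          log_palloc <- sum(log(ifelse(to1, p1, 1 - p1)))
          dloglik <- sum(dnorm_log(x[idx][to1], m1, s21)) +
            sum(dnorm_log(x[idx][!to1], m2, s22)) -
            sum(dnorm_log(x[idx], m, s2))
          l1 <- sum(to1); l2 <- sum(!to1)
        } else {
          to1 <- logical(0); log_palloc <- 0; dloglik <- 0; l1 <- 0; l2 <- 0
        }
        la <- split_log_ratio(k, w, m, s2, w1, m1, s21, w2, m2, s22,
                              u1, u2, u3, l1, l2, log_palloc, dloglik)
        if (is.finite(la) && log(runif(1)) < la) {
          acc["split_acc"] <- acc["split_acc"] + 1L
          pi_w <- c(pi_w[-j], w1, w2)
          mu <- c(mu[-j], m1, m2)
          sigma2 <- c(sigma2[-j], s21, s22)
          zmap <- integer(k)
          zmap[-j] <- seq_len(k - 1)
          znew <- zmap[z]
          znew[idx[to1]] <- k
          znew[idx[!to1]] <- k + 1L
          z <- znew
          k <- k + 1L
        }
      }
    } else if (k > 1) {
      acc["comb_att"] <- acc["comb_att"] + 1L
      ordm <- order(mu)
      pick <- sample.int(k - 1, 1)
      j1 <- ordm[pick]; j2 <- ordm[pick + 1]
      w1 <- pi_w[j1]; m1 <- mu[j1]; s21 <- sigma2[j1]
      w2 <- pi_w[j2]; m2 <- mu[j2]; s22 <- sigma2[j2]
      w <- w1 + w2
      m <- (w1 * m1 + w2 * m2) / w
      s2 <- (w1 * (m1^2 + s21) + w2 * (m2^2 + s22)) / w - m^2
      u1 <- w1 / w
      u2 <- (m - m1) / sqrt(s2 * w2 / w1)
      u3 <- s21 * w1 / ((1 - u2^2) * s2 * w)
      ok <- s2 > 0 && u2 > 0 && u2 < 1 && u3 > 0 && u3 < 1
      if (ok) {
        idx <- which(z == j1 | z == j2)
        if (length(idx)) {
          in1 <- z[idx] == j1
          l1d <- dnorm_log(x[idx], m1, s21) + log(w1)
          l2d <- dnorm_log(x[idx], m2, s22) + log(w2)
          mxp <- pmax(l1d, l2d)
          p1 <- exp(l1d - mxp) / (exp(l1d - mxp) + exp(l2d - mxp))
          log_palloc <- sum(log(ifelse(in1, p1, 1 - p1)))
          dloglik <- sum(dnorm_log(x[idx][in1], m1, s21)) +
            sum(dnorm_log(x[idx][!in1], m2, s22)) -
            sum(dnorm_log(x[idx], m, s2))
          l1 <- sum(in1); l2 <- sum(!in1)
        } else {
          log_palloc <- 0; dloglik <- 0; l1 <- 0; l2 <- 0
        }
        la <- -split_log_ratio(k - 1L, w, m, s2, w1, m1, s21, w2, m2, s22,
                               u1, u2, u3, l1, l2, log_palloc, dloglik)
        if (is.finite(la) && log(runif(1)) < la) {
          acc["comb_acc"] <- acc["comb_acc"] + 1L
          keep <- setdiff(seq_len(k), c(j1, j2))
          pi_new <- c(pi_w[keep], w)
          mu_new <- c(mu[keep], m)
          s2_new <- c(sigma2[keep], s2)
          zmap <- integer(k)
          zmap[keep] <- seq_along(keep)
          zmap[c(j1, j2)] <- k - 1L
          z <- zmap[z]
          pi_w <- pi_new; mu <- mu_new; sigma2 <- s2_new
          k <- k - 1L
        }
      }
    }

    ## (vi) birth / death of empty components
    counts <- tabulate(z, k)
    empty <- which(counts == 0L)
    if (runif(1) < p_up(k, k_max)) {
      acc["birth_att"] <- acc["birth_att"] + 1L
      w_new <- rbeta(1, 1, k)
      la <- birth_log_ratio(k, w_new, length(empty))
      if (is.finite(la) && log(runif(1)) < la) {
        acc["birth_acc"] <- acc["birth_acc"] + 1L
        pi_w <- c(pi_w * (1 - w_new), w_new)
        mu <- c(mu, rnorm(1, pr$xi, 1 / sqrt(pr$kappa)))
        sigma2 <- c(sigma2, pmin(pmax(1 / rgamma(1, pr$alpha, rate = beta),
                                      1e-10), 1e10))
        k <- k + 1L
      }
    } else if (k > 1 && length(empty)) {
      acc["death_att"] <- acc["death_att"] + 1L
      j <- if (length(empty) == 1) empty else sample(empty, 1)
      w_del <- pi_w[j]
      la <- -birth_log_ratio(k - 1L, w_del, length(empty) - 1L)
      if (is.finite(la) && log(runif(1)) < la) {
        acc["death_acc"] <- acc["death_acc"] + 1L
        pi_w <- pi_w[-j] / (1 - w_del)
        mu <- mu[-j]
        sigma2 <- sigma2[-j]
        zmap <- integer(k)
        zmap[-j] <- seq_len(k - 1)
        z <- zmap[z]
        k <- k - 1L
      }
    }

    k_trace[it] <- k
    if (it > settings$burn_in &&
        (it - settings$burn_in) %% settings$thin == 0) {
      kept <- kept + 1L
      samples[[kept]] <- list(k = k, pi = pi_w, mu = mu, sigma2 = sigma2,
                              beta = beta)
    }
  }

  accept <- tibble::tibble(
    move = c("split", "combine", "birth", "death"),
    attempts = as.integer(acc[c("split_att", "comb_att", "birth_att", "death_att")]),
    accepted = as.integer(acc[c("split_acc", "comb_acc", "birth_acc", "death_acc")])
  ) |>
    dplyr::mutate(rate = ifelse(.data$attempts > 0,
                                .data$accepted / .data$attempts, NA_real_))

  structure(list(samples = samples[seq_len(kept)], k_trace = k_trace,
                 accept = accept, priors = pr, settings = settings, x = x),
            class = "rjmcmc_gmm")
}

#' @export
print.rjmcmc_gmm <- function(x, ...) {
  ks <- purrr::map_int(x$samples, "k")
  cat(sprintf("<rjmcmc_gmm> %d retained samples (of %d sweeps), N = %d observations\n",
              length(x$samples), x$settings$iterations, length(x$x)))
  tab <- table(ks)
  cat("  posterior on k:",
      paste(sprintf("k=%s: %.2f", names(tab), as.numeric(tab) / length(ks)),
            collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.rjmcmc_gmm <- function(x, ...) {
  purrr::imap_dfr(x$samples, function(s, i) {
    tibble::tibble(sample = i, k = s$k, component = seq_len(s$k),
                   pi = s$pi, mu = s$mu, sigma2 = s$sigma2, beta = s$beta)
  })
}

#' @exportS3Method generics::glance
glance.rjmcmc_gmm <- function(x, ...) {
  ks <- purrr::map_int(x$samples, "k")
  tab <- table(ks)
  sc <- x$accept[x$accept$move %in% c("split", "combine"), ]
  tibble::tibble(
    n_samples = length(ks),
    modal_k = as.integer(names(tab)[which.max(tab)]),
    mean_k = mean(ks),
    accept_split_combine = sum(sc$accepted) / sum(sc$attempts),
    n_obs = length(x$x)
  )
}

#' Posterior modal number of components
#' @param fit An `rjmcmc_gmm` fit.
#' @returns Integer modal `k` over retained samples.
#' @export
modal_k <- function(fit) {
  stopifnot(inherits(fit, "rjmcmc_gmm"))
  ks <- purrr::map_int(fit$samples, "k")
  tab <- table(ks)
  as.integer(names(tab)[which.max(tab)])
}
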