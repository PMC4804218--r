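#' Monte-Carlo posterior predictive distribution
#'
#' For each retained posterior sample, draws unobserved TM_max scores from
#' the fitted Gaussian mixture: pick component `j` with probability `pi_j`,
#' then draw `Normal(mu_j, sigma2_j)`. Draws are not truncated to (0, 1] —
#' the model is an untruncated mixture; draws outside the unit interval
#' simply count as below or above a query score.
#'
#' @param fit An `rjmcmc_gmm` fit ([fit_rjmcmc()]).
#' @param draws_per_sample Predictive draws per retained sample (default 1).
#' @param seed Optional integer seed.
#' @returns A `posterior_predictive`: list with `draws` (numeric vector of
#'   length `n_samples * draws_per_sample`) and bookkeeping fields.
#' @export
posterior_predictive <- function(fit, draws_per_sample = 1, seed = NULL) {
  stopifnot(inherits(fit, "rjmcmc_gmm"))
  if (!length(fit$samples)) abort("no retained posterior samples.")
  if (!is.null(seed)) set.seed(seed)
  m <- as.integer(draws_per_sample)
  stopifnot(m >= 1)
  draws <- unlist(purrr::map(fit$samples, function(s) {
    j <- if (s$k == 1) rep(1L, m) else sample.int(s$k, m, replace = TRUE, prob = s$pi)
    rnorm(m, s$mu[j], sqrt(s$sigma2[j]))
  }), use.names = FALSE)
  structure(list(draws = draws, n_samples = length(fit$samples),
                 draws_per_sample = m),
            class = "posterior_predictive")
}

#' @export
print.posterior_predictive <- function(x, ...) {
  cat(sprintf("<posterior_predictive> %d draws (%d samples x %d per sample)\n",
              length(x$draws), x$n_samples, x$draws_per_sample))
  invisible(x)
}

#' Cumulative posterior predictive probability (C3P)
#'
#' CEP evaluated against Monte-Carlo draws from the posterior predictive
#' distribution of the within-fold mixture, as if the potentially observed
#' TM_max scores were actually observed: the fraction of predictive draws
#' equal to or smaller than the query-fold TM_max score. Smooths the
#' empirical CEP where fold membership is small (e.g. it is positive, not 0,
#' for a query scoring just below all observed within-fold TM_max values).
#'
#' @param s Query-fold TM_max score(s).
#' @param predictive A [posterior_predictive()].
#' @returns C3P value(s) in \[0, 1\], same length as `s`.
#' @export
c3p <- function(s, predictive) {
  stopifnot(inherits(predictive, "posterior_predictive"))
  if (!length(predictive$draws)) abort("empty posterior predictive.")
  vapply(s, function(si) mean(predictive$draws <= si), numeric(1))
}

#' Analytic (Rao-Blackwellized) C3P
#'
#' Variance-reduced equivalent of the Monte-Carlo C3P estimator: the mixture
#' CDF averaged over retained posterior samples,
#' `mean over samples of sum_j pi_j * Phi((s - mu_j) / sigma_j)`.
#'
#' @param s Query-fold TM_max score(s).
#' @param fit An `rjmcmc_gmm` fit, or a bare list of posterior samples.
#' @returns C3P value(s), same length as `s`.
#' @export
c3p_analytic <- function(s, fit) {
  samples <- if (inherits(fit, "rjmcmc_gmm")) fit$samples else fit
  if (!length(samples)) abort("no posterior samples.")
  vapply(s, function(si) {
    mean(purrr::map_dbl(samples, function(sm) {
      sum(sm$pi * pnorm(si, sm$mu, sqrt(sm$sigma2)))
    }))
  }, numeric(1))
}

#' Fit the within-fold mixture for every profiled fold
#'
#' The posterior depends on the fold profile only, never on the query, so
#' fits are computed once per profile set and reused across queries.
#' Per-fold seeds derive deterministically from `settings$seed`.
#'
#' @param profiles Named list of `fold_profile`s ([build_profiles()]).
#' @param priors Optional [gmm_priors()] overrides.
#' @param settings An [mcmc_settings()]; `settings$seed` must be set.
#' @returns Named list of `rjmcmc_gmm` fits (one per fold).
#' @export
fit_fold_models <- function(profiles, priors = NULL,
                            settings = mcmc_settings()) {
  if (is.null(settings$seed)) abort("`settings$seed` is required for reproducible fits.")
  purrr::imap(profiles, function(p, fid) {
    st <- settings
    st$seed <- (settings$seed + match(fid, names(profiles)) * 1009L) %% 2147483647L
    fit_rjmcmc(p$x, priors = priors, settings = st)
  })
}

#' Classify one query by C3P
#'
#' Same argmax protocol as CEP with C3P as the per-fold score: compute the
#' query-fold TM_max per fold, evaluate C3P against each fold's posterior
#' predictive, assign the fold with the highest C3P. Ties break by higher
#' query-fold TM_max, then lexicographic fold id. Predictive draws per fold
#' are seeded from that fold's fit, so results are independent of query
#' evaluation order.
#'
#' @param query_id Query domain id (held out of every profile).
#' @param matrix A [tm_matrix()].
#' @param profiles Named list of `fold_profile`s.
#' @param fits Named list of `rjmcmc_gmm` fits covering every profiled fold
#'   ([fit_fold_models()]).
#' @param draws_per_sample Predictive draws per retained sample (default 1).
#' @param original_fold Optional reference fold id.
#' @param predictives Optional precomputed named list of
#'   [posterior_predictive()] objects (a cache for repeated queries).
#' @returns A `query_result` (see [classify_query()]) with `method = "c3p"`.
#' @export
classify_c3p <- function(query_id, matrix, profiles, fits,
                         draws_per_sample = 1, original_fold = NA_character_,
                         predictives = NULL) {
  missing_fit <- setdiff(names(profiles), names(fits))
  if (length(missing_fit)) {
    abort(paste0("missing mixture fit for fold(s): ",
                 paste(missing_fit, collapse = ", ")))
  }
  member_hit <- purrr::map_lgl(profiles, ~ query_id %in% .x$member_ids)
  if (any(member_hit)) {
    abort(sprintf("query %s is still a member of fold %s; hold it out first.",
                  query_id, profiles[[which(member_hit)[1]]]$fold_id))
  }
  predictives <- predictives %||% fold_predictives(fits, draws_per_sample)
  per_fold <- purrr::map_dfr(profiles, function(p) {
    tmx <- query_fold_statistic(matrix, query_id, p$member_ids, "max")
    score <- c3p(as.numeric(tmx), predictives[[p$fold_id]])
    tibble::tibble(fold_id = p$fold_id, tm_max = as.numeric(tmx),
                   partner = attr(tmx, "partner"),
                   stat = as.numeric(tmx), score = score)
  }) |>
    dplyr::arrange(.data$fold_id)
  ord <- order(-per_fold$score, -per_fold$tm_max, per_fold$fold_id)
  structure(list(query_id = query_id, original_fold = original_fold,
                 mode = matrix$mode, method = "c3p",
                 assigned_fold = per_fold$fold_id[ord[1]], per_fold = per_fold),
            class = "query_result")
}

## deterministic per-fold predictive cache: seeded from each fold's fit seed
fold_predictives <- function(fits, draws_per_sample = 1) {
  purrr::map(fits, function(f) {
    posterior_predictive(f, draws_per_sample = draws_per_sample,
                         seed = f$settings$seed %||% 0L)
  })
}
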