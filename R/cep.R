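#' Cumulative empirical probability (CEP)
#'
#' The fraction of a fold's within-fold TM_max scores that are equal to or
#' smaller than the query-fold TM_max score `s`. CEP measures how well a
#' query's similarity to a fold fits among the similarities of domains
#' already classified there: heterogeneous folds (wide TM_max distributions)
#' are more accommodating to a query than tight ones. CEP is not a posterior
#' probability and CEP values across folds need not sum to 1.
#'
#' @param s Query-fold TM_max score in (0, 1].
#' @param profile A `fold_profile` ([build_profile()]).
#' @returns CEP in \[0, 1\].
#' @examples
#' prof <- structure(list(fold_id = "f", x = c(.5, .6, .7, .8, .9), n = 5),
#'                   class = "fold_profile")
#' cep(0.75, prof) # 3 of 5 members at or below 0.75
#' @export
cep <- function(s, profile) {
  stopifnot(inherits(profile, "fold_profile"))
  if (!length(profile$x)) abort("empty fold profile.")
  if (s <= 0 || s > 1) abort("`s` must lie in (0, 1].")
  sum(profile$x <= s) / length(profile$x)
}

#' Classify one query domain into an existing fold
#'
#' For `method = "tm_max"`, `"tm_mean"` or `"tm_median"` the query is
#' assigned to the fold maximizing that query-fold statistic. For
#' `method = "cep"` the query-fold TM_max is computed per fold, converted to
#' CEP against each fold's within-fold TM_max distribution, and the query is
#' assigned to the fold with the highest CEP — which may differ from the
#' TM_max assignment when a heterogeneous fold accommodates the query better
#' despite a lower raw similarity. Ties are broken by higher query-fold
#' TM_max, then lexicographic fold id.
#'
#' @param query_id Query domain id. Must not be a member of any profile
#'   (hold it out first).
#' @param matrix A [tm_matrix()].
#' @param profiles Named list of `fold_profile`s ([build_profiles()]).
#' @param method One of `"tm_max"`, `"tm_mean"`, `"tm_median"`, `"cep"`.
#' @param original_fold Optional fold id from the reference classification.
#' @returns A `query_result`: list with `query_id`, `original_fold`, `mode`,
#'   `method`, `assigned_fold`, and `per_fold` (tibble of fold_id, tm_max,
#'   partner, stat, score).
#' @export
classify_query <- function(query_id, matrix, profiles,
                           method = c("tm_max", "tm_mean", "tm_median", "cep"),
                           original_fold = NA_character_) {
  method <- match.arg(method)
  if (!length(profiles)) abort("no fold profiles supplied.")
  member_hit <- purrr::map_lgl(profiles, ~ query_id %in% .x$member_ids)
  if (any(member_hit)) {
    abort(sprintf("query %s is still a member of fold %s; hold it out first.",
                  query_id, profiles[[which(member_hit)[1]]]$fold_id))
  }
  per_fold <- purrr::map_dfr(profiles, function(p) {
    tmx <- query_fold_statistic(matrix, query_id, p$member_ids, "max")
    stat <- switch(method,
      tm_max = as.numeric(tmx),
      tm_mean = query_fold_statistic(matrix, query_id, p$member_ids, "mean"),
      tm_median = query_fold_statistic(matrix, query_id, p$member_ids, "median"),
      cep = as.numeric(tmx)
    )
    score <- if (method == "cep") cep(as.numeric(tmx), p) else stat
    tibble::tibble(fold_id = p$fold_id, tm_max = as.numeric(tmx),
                   partner = attr(tmx, "partner"), stat = stat, score = score)
  }) |>
    dplyr::arrange(.data$fold_id)
  ord <- order(-per_fold$score, -per_fold$tm_max, per_fold$fold_id)
  assigned <- per_fold$fold_id[ord[1]]
  structure(list(query_id = query_id, original_fold = original_fold,
                 mode = matrix$mode, method = method,
                 assigned_fold = assigned, per_fold = per_fold),
            class = "query_result")
}

#' @export
print.query_result <- function(x, ...) {
  cat(sprintf("<query_result> %s -> %s by %s (%s scores)\n",
              x$query_id, x$assigned_fold, x$method, x$mode))
  if (!is.na(x$original_fold)) {
    cat(sprintf("  original fold: %s (%s)\n", x$original_fold,
                if (identical(x$original_fold, x$assigned_fold)) "consistent"
                else "reclassified"))
  }
  invisible(x)
}

tidy_query_result <- function(qr) {
  qr$per_fold |>
    dplyr::mutate(query_id = qr$query_id,
                  original_fold = qr$original_fold,
                  method = qr$method,
                  assigned_fold = qr$assigned_fold,
                  mode = qr$mode,
                  .before = 1)
}

#' @exportS3Method generics::tidy
tidy.query_result <- function(x, ...) tidy_query_result(x)

#' Classify a set of queries by one or more methods
#'
#' @param queries Character vector of query domain ids.
#' @param matrix A [tm_matrix()].
#' @param profiles Named list of `fold_profile`s with the queries held out.
#' @param methods Character vector of methods (see [classify_query()];
#'   `"c3p"` is available via [classify_c3p()] when `fits` is supplied).
#' @param original Optional classification tibble giving each query's
#'   original fold.
#' @param fits Optional named list (fold id -> `rjmcmc_gmm` fit) enabling
#'   `method = "c3p"`.
#' @param c3p_draws Predictive draws per retained posterior sample for C3P
#'   (default 1).
#' @returns A tidy tibble, one row per (query, method, fold): `query_id`,
#'   `original_fold`, `method`, `fold_id`, `tm_max`, `partner`, `stat`,
#'   `score`, `assigned_fold`, `mode`.
#' @export
classify_queries <- function(queries, matrix, profiles,
                             methods = "cep", original = NULL,
                             fits = NULL, c3p_draws = 1) {
  orig <- function(q) {
    if (is.null(original)) return(NA_character_)
    hit <- original$fold_id[original$domain_id == q]
    if (length(hit)) hit[1] else NA_character_
  }
  predictives <- NULL
  if ("c3p" %in% methods) {
    if (is.null(fits)) abort("method 'c3p' requires `fits`.")
    predictives <- fold_predictives(fits, c3p_draws)
  }
  purrr::map_dfr(queries, function(q) {
    purrr::map_dfr(methods, function(m) {
      qr <- if (m == "c3p") {
        classify_c3p(q, matrix, profiles, fits, draws_per_sample = c3p_draws,
                     original_fold = orig(q), predictives = predictives)
      } else {
        classify_query(q, matrix, profiles, m, original_fold = orig(q))
      }
      tidy_query_result(qr)
    })
  })
}

#' Leave-one-out classification of dataset members
#'
#' Classifies each listed domain after removing it from its own fold's
#' profile (all other domains stay in their originally classified folds),
#' the hold-out semantics used throughout: a member must never contribute to
#' the profile it is being scored against.
#'
#' @param members Character vector of domain ids present in
#'   `classification`.
#' @param classification Classification tibble.
#' @param matrix A [tm_matrix()].
#' @param methods Methods to run (see [classify_queries()]).
#' @param min_fold_size Minimum fold size for profiled folds (default 25).
#' @param fits,c3p_draws Passed to [classify_queries()] for `"c3p"`. Note
#'   the fits must come from profiles excluding each query; for C3P prefer
#'   [holdout_experiment()], which refits per held-out set.
#' @returns Tidy assignment tibble as from [classify_queries()].
#' @export
classify_members <- function(members, classification, matrix,
                             methods = "cep", min_fold_size = 25,
                             fits = NULL, c3p_draws = 1) {
  purrr::map_dfr(members, function(q) {
    rest <- classification[classification$domain_id != q, ]
    profiles <- build_profiles(matrix, rest, min_fold_size = min_fold_size)
    classify_queries(q, matrix, profiles, methods = methods,
                     original = classification, fits = fits,
                     c3p_draws = c3p_draws)
  })
}

#' Repeated hold-out classification experiment
#'
#' The protocol used to compare automated classifications against a reference
#' hierarchy: in each repeat, `floor(fraction * N_f)` domains (minimum 1) are
#' sampled from each profiled fold as queries, fold profiles are rebuilt
#' without them, every query is classified by every requested method, and the
#' disagreement fraction against the original classification is recorded.
#'
#' @param classification Classification tibble ([classification_table()]).
#' @param matrix A [tm_matrix()].
#' @param fraction Fraction of each fold to hold out per repeat (default 0.1).
#' @param n_repeats Number of repeats (default 30).
#' @param methods Methods to run (any of `"tm_max"`, `"tm_mean"`,
#'   `"tm_median"`, `"cep"`, `"c3p"`).
#' @param seed Integer seed controlling query sampling and, when `"c3p"` is
#'   requested, the per-fold MCMC fits and predictive draws.
#' @param min_fold_size Minimum original fold size to enter the experiment
#'   (default 25).
#' @param mcmc Optional [mcmc_settings()] for C3P fits (seed field is
#'   ignored; per-fold seeds derive from `seed`).
#' @param priors Optional [gmm_priors()] overrides for C3P fits.
#' @param c3p_draws Predictive draws per retained sample (default 1).
#' @returns A `holdout_result`: list with `results` (per-repeat tidy
#'   assignment tibble: repeat, query_id, original_fold, method,
#'   assigned_fold), and `summary` (per-method mean and SD across repeats of
#'   the disagreement fraction).
#' @export
holdout_experiment <- function(classification, matrix, fraction = 0.1,
                               n_repeats = 30, methods = c("tm_max", "cep"),
                               seed = NULL, min_fold_size = 25,
                               mcmc = NULL, priors = NULL, c3p_draws = 1) {
  if (fraction <= 0 || fraction >= 1) abort("`fraction` must lie in (0, 1).")
  if (!is.null(seed)) set.seed(seed)
  folds <- split(classification$domain_id, classification$fold_id)
  folds <- folds[purrr::map_int(folds, length) >= min_fold_size]
  if (!length(folds)) abort("no fold meets `min_fold_size`.")
  small <- names(folds)[purrr::map_int(folds, length) -
                          pmax(1L, floor(fraction * purrr::map_int(folds, length))) < 2]
  if (length(small)) {
    warn(paste0("folds excluded from sampling (would drop below 2 members): ",
                paste(small, collapse = ", ")))
    folds <- folds[setdiff(names(folds), small)]
  }
  want_c3p <- "c3p" %in% methods
  mcmc <- mcmc %||% mcmc_settings()

  all_rows <- purrr::map_dfr(seq_len(n_repeats), function(rep_i) {
    queries <- sort(unlist(purrr::imap(folds, function(mem, fid) {
      k <- max(1L, floor(fraction * length(mem)))
      sort(sample(mem, k))
    }), use.names = FALSE))
    remaining <- classification[!classification$domain_id %in% queries &
                                  classification$fold_id %in% names(folds), ]
    profiles <- build_profiles(matrix, remaining, min_fold_size = 2)
    fits <- NULL
    if (want_c3p) {
      fits <- purrr::map(profiles, function(p) {
        st <- mcmc
        st$seed <- sample.int(.Machine$integer.max - 1L, 1)
        fit_rjmcmc(p$x, priors = priors, settings = st)
      })
    }
    res <- classify_queries(queries, matrix, profiles, methods = methods,
                            original = classification, fits = fits,
                            c3p_draws = c3p_draws)
    res |>
      dplyr::distinct(.data$query_id, .data$original_fold, .data$method,
                      .data$assigned_fold) |>
      dplyr::mutate(`repeat` = rep_i, .before = 1)
  })
  summary <- all_rows |>
    dplyr::group_by(.data$`repeat`, .data$method) |>
    dplyr::summarise(disagreement = mean(.data$assigned_fold != .data$original_fold),
                     .groups = "drop") |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(mean_disagreement = mean(.data$disagreement),
                     sd_disagreement = ifelse(dplyr::n() > 1, sd(.data$disagreement), 0),
                     n_repeats = dplyr::n(), .groups = "drop")
  structure(list(results = all_rows, summary = summary,
                 fraction = fraction, n_repeats = n_repeats,
                 methods = methods, mode = matrix$mode),
            class = "holdout_result")
}

#' @export
print.holdout_result <- function(x, ...) {
  cat(sprintf("<holdout_result> %d repeats, %.0f%% of each fold held out (%s scores)\n",
              x$n_repeats, 100 * x$fraction, x$mode))
  print(x$summary)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.holdout_result <- function(x, ...) x$results

#' @exportS3Method generics::glance
glance.holdout_result <- function(x, ...) {
  wide <- x$summary |>
    dplyr::select("method", "mean_disagreement") |>
    tidyr::pivot_wider(names_from = "method", values_from = "mean_disagreement")
  dplyr::bind_cols(
    tibble::tibble(n_repeats = x$n_repeats, fraction = x$fraction, mode = x$mode),
    wide
  )
}
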