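#' Within-fold TM_max scores
#'
#' For every member of a fold, the highest TM-score between it and any other
#' member of the same fold. Self-scores are excluded.
#'
#' @param matrix A [tm_matrix()].
#' @param members Character vector of member domain ids (>= 2).
#' @returns Named numeric vector, one TM_max per member.
#' @examples
#' m <- matrix(c(1, .9, .6, .9, 1, .7, .6, .7, 1), 3, 3,
#'             dimnames = list(c("A","B","C"), c("A","B","C")))
#' within_fold_tmmax(tm_matrix(m, "local"), c("A", "B", "C"))
#' @export
within_fold_tmmax <- function(matrix, members) {
  if (length(members) < 2) abort("a fold needs at least 2 members.")
  block <- tm_block(matrix, members, members)
  diag(block) <- NA_real_
  if (anyNA(block[upper.tri(block)])) {
    abort("missing pairwise scores among fold members.")
  }
  apply(block, 1, max, na.rm = TRUE)
}

#' Build a within-fold heterogeneity profile
#'
#' A fold profile holds the vector `x` of within-fold TM_max scores plus its
#' summaries: `mean_x` (structure homogeneity — near 1 for tight folds, as
#' low as 0.6-0.7 for heterogeneous ones), `sd_x` (sample SD, N-1
#' denominator) and the range `r = max(x) - min(x)`. Folds with fewer than
#' `min_fold_size` members provide too little information for the empirical
#' distribution and are skipped with a warning.
#'
#' @param matrix A [tm_matrix()].
#' @param fold_id Fold identifier.
#' @param members Member domain ids.
#' @param min_fold_size Minimum members required (default 25).
#' @returns A `fold_profile` object, or `NULL` (with a warning) when the fold
#'   is below `min_fold_size`.
#' @export
build_profile <- function(matrix, fold_id, members, min_fold_size = 25) {
  members <- sort(unique(as.character(members)))
  if (length(members) < min_fold_size) {
    warn(sprintf("fold %s has %d members (< %d); excluded from classification targets.",
                 fold_id, length(members), min_fold_size))
    return(NULL)
  }
  x <- within_fold_tmmax(matrix, members)
  structure(list(fold_id = fold_id, member_ids = members, x = x,
                 n = length(x), mean_x = mean(x), sd_x = sd(x),
                 r = max(x) - min(x), mode = matrix$mode),
            class = "fold_profile")
}

#' @export
print.fold_profile <- function(x, ...) {
  cat(sprintf("<fold_profile> %s (%s): N = %d, mean TM_max = %.3f, SD = %.3f, range = %.3f\n",
              x$fold_id, x$mode, x$n, x$mean_x, x$sd_x, x$r))
  invisible(x)
}

#' Build profiles for every sufficiently large fold
#'
#' @param matrix A [tm_matrix()].
#' @param classification Classification tibble ([classification_table()]).
#' @param min_fold_size Minimum fold size (default 25).
#' @param quiet Suppress per-fold exclusion warnings (default TRUE; small
#'   folds are expected in real classifications).
#' @returns Named list of `fold_profile` objects, sorted by fold id.
#' @export
build_profiles <- function(matrix, classification, min_fold_size = 25,
                           quiet = TRUE) {
  folds <- split(classification$domain_id, classification$fold_id)
  maker <- function(fid) build_profile(matrix, fid, folds[[fid]], min_fold_size)
  if (quiet) {
    maker_q <- function(fid) suppressWarnings(maker(fid))
  } else {
    maker_q <- maker
  }
  profs <- purrr::map(sort(names(folds)), maker_q)
  names(profs) <- sort(names(folds))
  purrr::compact(profs)
}

#' Query-fold similarity statistic
#'
#' The chosen statistic (max, mean or median) of the TM-scores between a
#' query and every member of a fold. The maximum is the query-fold TM_max
#' score; for `stat = "max"` the id of the member achieving it (the "partner
#' domain") is attached as attribute `partner` (ties broken by lexicographic
#' member id).
#'
#' @param matrix A [tm_matrix()].
#' @param query_id Query domain id (must not be a fold member).
#' @param members Fold member ids.
#' @param stat `"max"`, `"mean"` or `"median"`.
#' @returns The statistic; for `"max"` with attribute `partner`.
#' @export
query_fold_statistic <- function(matrix, query_id, members,
                                 stat = c("max", "mean", "median")) {
  stat <- match.arg(stat)
  if (query_id %in% members) {
    abort("query is among the fold members; hold it out before scoring.")
  }
  members <- sort(as.character(members))
  s <- tm_lookup(matrix, rep(query_id, length(members)), members)
  if (anyNA(s)) abort(sprintf("missing query-member scores for query %s.", query_id))
  switch(stat,
    max = {
      out <- max(s)
      attr(out, "partner") <- members[which(s == out)[1]]
      out
    },
    mean = mean(s),
    median = median(s)
  )
}

#' Closeness of two folds
#'
#' The highest TM-score over all domain pairs across two disjoint folds.
#'
#' @param matrix A [tm_matrix()].
#' @param members_a,members_b Disjoint member id sets.
#' @returns Maximum cross-fold score.
#' @export
fold_closeness <- function(matrix, members_a, members_b) {
  if (length(intersect(members_a, members_b))) {
    abort("fold member sets overlap.")
  }
  max(tm_block(matrix, members_a, members_b))
}

#' Heterogeneity summary table
#'
#' One row per fold with its size and the mean and SD of within-fold TM_max
#' scores, sorted by fold id.
#'
#' @param profiles List of `fold_profile` objects ([build_profiles()]).
#' @returns Tibble with columns `fold_id`, `n`, `mean_x`, `sd_x`, `r`, `mode`.
#' @export
heterogeneity_table <- function(profiles) {
  if (inherits(profiles, "fold_profile")) profiles <- list(profiles)
  if (!length(profiles)) abort("no profiles supplied.")
  purrr::map_dfr(profiles, function(p) {
    tibble::tibble(fold_id = p$fold_id, n = p$n, mean_x = p$mean_x,
                   sd_x = p$sd_x, r = p$r, mode = p$mode)
  }) |>
    dplyr::arrange(.data$fold_id)
}
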