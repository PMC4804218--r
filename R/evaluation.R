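#' Reclassification rate against the original classification
#'
#' Queries whose assigned fold differs from their original fold are
#' "reclassified"; attraction counts tally, per fold, how many reclassified
#' queries were assigned to it.
#'
#' @param original Classification tibble ([classification_table()]).
#' @param results Query-result tibble ([classify_queries()]) or
#'   `holdout_result`; may contain several methods.
#' @param method Optional method filter (required when `results` carries
#'   more than one method).
#' @returns A `comparison_summary`: list with `n_queries`,
#'   `n_disagreements`, `disagreement_fraction`, and `attraction` (tibble
#'   `fold_id`, `n_attracted` over disagreeing queries only).
#' @export
reclassification_rate <- function(original, results, method = NULL) {
  if (inherits(results, "holdout_result")) results <- results$results
  tbl <- results |>
    dplyr::distinct(.data$query_id, .data$method, .data$assigned_fold,
                    dplyr::across(dplyr::any_of("repeat")))
  if (!is.null(method)) tbl <- tbl[tbl$method == method, ]
  if (length(unique(tbl$method)) != 1) {
    abort("`results` carries several methods; pick one with `method`.")
  }
  lookup <- setNames(original$fold_id, original$domain_id)
  if (any(!tbl$query_id %in% names(lookup))) {
    missing_q <- setdiff(tbl$query_id, names(lookup))
    abort(paste0("queries missing from the original classification: ",
                 paste(head(missing_q, 5), collapse = ", ")))
  }
  tbl$original_fold <- lookup[tbl$query_id]
  n <- nrow(tbl)
  dis <- tbl[tbl$assigned_fold != tbl$original_fold, ]
  attraction <- dis |>
    dplyr::count(fold_id = .data$assigned_fold, name = "n_attracted") |>
    dplyr::arrange(.data$fold_id)
  structure(list(n_queries = n, n_disagreements = nrow(dis),
                 disagreement_fraction = nrow(dis) / n,
                 attraction = attraction, method = unique(tbl$method)),
            class = "comparison_summary")
}

#' @export
print.comparison_summary <- function(x, ...) {
  cat(sprintf("<comparison_summary> %s: %d / %d queries reclassified (%.1f%%)\n",
              x$method, x$n_disagreements, x$n_queries,
              100 * x$disagreement_fraction))
  if (nrow(x$attraction)) {
    top <- dplyr::arrange(x$attraction, dplyr::desc(.data$n_attracted))
    cat("  attracting folds:",
        paste(sprintf("%s (%d)", head(top$fold_id, 5), head(top$n_attracted, 5)),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.comparison_summary <- function(x, ...) x$attraction

#' @exportS3Method generics::glance
glance.comparison_summary <- function(x, ...) {
  tibble::tibble(method = x$method, n_queries = x$n_queries,
                 n_disagreements = x$n_disagreements,
                 disagreement_fraction = x$disagreement_fraction)
}

## Spearman-type rank correlation: Pearson correlation of mid-ranks
rank_correlation <- function(a, b) {
  cor(rank(a), rank(b))
}

#' Correlation between fold properties and reclassification attraction
#'
#' Spearman-type rank correlation between a fold property (within-fold
#' TM_max mean, SD, or fold size) and the number of reclassified queries
#' attracted to the fold. Folds attracting no queries enter as zeros. The
#' two-sided p-value comes from seeded label permutations — exact in spirit
#' at the small fold counts of synthetic universes, with no asymptotic
#' approximation.
#'
#' @param profiles Named list of `fold_profile`s ([build_profiles()]).
#' @param summary A `comparison_summary` ([reclassification_rate()]) or a
#'   tibble with `fold_id` and `n_attracted`.
#' @param property `"sd_x"`, `"mean_x"` or `"n"`.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed for the permutations.
#' @returns Tibble with `property`, `rho`, `p_value`, `n_folds`, `n_perm`.
#' @export
heterogeneity_attraction_correlation <- function(profiles, summary,
                                                 property = c("sd_x", "mean_x", "n"),
                                                 n_perm = 10000, seed = NULL) {
  property <- match.arg(property)
  if (length(profiles) < 3) abort("need at least 3 folds.")
  attraction <- if (inherits(summary, "comparison_summary")) {
    summary$attraction
  } else {
    tibble::as_tibble(summary)
  }
  het <- heterogeneity_table(profiles)
  counts <- setNames(rep(0, nrow(het)), het$fold_id)
  hit <- intersect(attraction$fold_id, names(counts))
  counts[hit] <- attraction$n_attracted[match(hit, attraction$fold_id)]
  prop <- het[[property]]
  if (length(unique(prop)) < 2 || length(unique(counts)) < 2) {
    abort("rank correlation undefined: property or attraction counts are constant.")
  }
  rho <- rank_correlation(prop, counts)
  if (!is.null(seed)) set.seed(seed)
  perm <- purrr::map_dbl(seq_len(n_perm), function(i) {
    rank_correlation(prop, sample(counts))
  })
  p <- (1 + sum(abs(perm) >= abs(rho) - 1e-12)) / (n_perm + 1)
  tibble::tibble(property = property, rho = rho, p_value = p,
                 n_folds = nrow(het), n_perm = n_perm)
}

#' Three-way consistency of two classification methods and the original
#'
#' Counts queries where methods A, B and the original classification agree
#' or differ, plus the "same-way" fractions: among A's reclassifications,
#' the share that B reclassified to the same fold (and vice versa).
#'
#' @param results_a,results_b Query-result tibbles for the same query set
#'   (single method each).
#' @param original Classification tibble.
#' @returns A `method_overlap` list: `counts` (tibble of the five
#'   consistency cells), `same_way_a_in_b`, `same_way_b_in_a`,
#'   `consistency_ab` (fraction where A = B), `n_queries`.
#' @export
method_overlap <- function(results_a, results_b, original) {
  pick <- function(r) {
    dplyr::distinct(r, .data$query_id, .data$assigned_fold,
                    dplyr::across(dplyr::any_of("repeat")))
  }
  a <- pick(results_a); b <- pick(results_b)
  key <- intersect(names(a), c("query_id", "repeat"))
  merged <- dplyr::inner_join(a, b, by = key, suffix = c("_a", "_b"))
  if (nrow(merged) != nrow(a) || nrow(merged) != nrow(b)) {
    abort("`results_a` and `results_b` must cover the same query set.")
  }
  lookup <- setNames(original$fold_id, original$domain_id)
  merged$orig <- lookup[merged$query_id]
  if (anyNA(merged$orig)) abort("some queries lack an original fold.")
  cell <- dplyr::case_when(
    merged$assigned_fold_a == merged$orig & merged$assigned_fold_b == merged$orig ~ "all_agree",
    merged$assigned_fold_a == merged$assigned_fold_b ~ "ab_agree_not_original",
    merged$assigned_fold_a == merged$orig ~ "a_original_not_b",
    merged$assigned_fold_b == merged$orig ~ "b_original_not_a",
    TRUE ~ "all_differ"
  )
  counts <- tibble::tibble(
    cell = c("all_agree", "ab_agree_not_original", "a_original_not_b",
             "b_original_not_a", "all_differ")
  ) |>
    dplyr::left_join(tibble::tibble(cell = cell) |> dplyr::count(.data$cell),
                     by = "cell") |>
    dplyr::mutate(n = tidyr::replace_na(.data$n, 0L))
  re_a <- merged$assigned_fold_a != merged$orig
  re_b <- merged$assigned_fold_b != merged$orig
  same <- merged$assigned_fold_a == merged$assigned_fold_b
  structure(list(
    counts = counts,
    same_way_a_in_b = if (any(re_a)) mean(same[re_a]) else NA_real_,
    same_way_b_in_a = if (any(re_b)) mean(same[re_b]) else NA_real_,
    consistency_ab = mean(same),
    n_queries = nrow(merged)
  ), class = "method_overlap")
}

#' @export
print.method_overlap <- function(x, ...) {
  cat(sprintf("<method_overlap> %d queries; A=B for %.1f%%\n",
              x$n_queries, 100 * x$consistency_ab))
  print(x$counts)
  if (!is.na(x$same_way_a_in_b)) {
    cat(sprintf("  of A's reclassifications, %.0f%% reclassified the same way by B\n",
                100 * x$same_way_a_in_b))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.method_overlap <- function(x, ...) x$counts

#' Relative length difference between a query and its partner domain
#'
#' `|L_query - L_partner| / min(L_query, L_partner)`: symmetric, zero iff
#' the lengths are equal. Large values flag Russian-doll pairs, whose global
#' TM-scores are depressed by the length mismatch while local scores are
#' not.
#'
#' @param l_query,l_partner Positive residue counts (vectorized).
#' @returns Non-negative numeric vector.
#' @examples
#' relative_length_difference(150, 100) # 0.5
#' @export
relative_length_difference <- function(l_query, l_partner) {
  if (any(l_query < 1 | l_partner < 1)) abort("lengths must be >= 1 residue.")
  abs(l_query - l_partner) / pmin(l_query, l_partner)
}

#' Two-group location comparison (convenience)
#'
#' Thin wrapper over [stats::wilcox.test()] for comparing, e.g., relative
#' length differences of two query sets, returned as a one-row tibble.
#'
#' @param a,b Numeric vectors.
#' @param paired Passed to `wilcox.test` (default FALSE: Mann-Whitney U).
#' @returns Tibble with `statistic`, `p_value`, `n_a`, `n_b`.
#' @export
compare_groups <- function(a, b, paired = FALSE) {
  t <- stats::wilcox.test(a, b, paired = paired, exact = FALSE)
  tibble::tibble(statistic = unname(t$statistic), p_value = t$p.value,
                 n_a = length(a), n_b = length(b))
}
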