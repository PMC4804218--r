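#' Configuration for a synthetic fold universe
#'
#' Describes a fold universe with known truth: per-fold within-score
#' distributions (pairwise TM-scores among members), a between-fold base
#' distribution, optional continuity "bridge" domains with elevated scores
#' into a target fold, and optional Russian-doll fold pairs where the local
#' score exceeds the global score because one domain resembles a
#' substructure of the other. Scores are generated directly as matrix
#' entries — the classifiers consume only scores — and clipped to
#' (0.01, 1].
#'
#' Default within-fold means span 0.95 down to 0.65 with SDs anti-correlated
#' with the mean (tight folds are tight everywhere; heterogeneous folds owe
#' their low mean to a long lower tail), mirroring the spread observed
#' across large CATH folds.
#'
#' @param n_folds Number of folds (default 8).
#' @param members_per_fold Members per fold, scalar or vector (default 30).
#' @param within_means Per-fold mean of pairwise within-fold scores
#'   (default: evenly spaced 0.95 down to 0.65).
#' @param within_sds Per-fold SD (default: `0.02 + 0.25 * (0.97 -
#'   within_means)`, anti-correlated with the mean).
#' @param within_support Clip range for within-fold scores (default
#'   c(0.45, 0.99): real TM-score distributions carry no atom at 1, so the
#'   generating Normals should sit inside the clip window).
#' @param between_mean,between_sd Base cross-fold score distribution
#'   (defaults 0.3, 0.05).
#' @param between_support Clip range for cross-fold scores (default
#'   c(0.05, 0.4); keep the upper end below the within-fold support for a
#'   discrete universe).
#' @param bridges Optional tibble/data.frame with columns `n_domains`,
#'   `source_fold`, `target_fold`, `level`: the last `n_domains` members of
#'   `source_fold` receive scores ~ Normal(level, 0.02) to every member of
#'   `target_fold`.
#' @param russian_doll Optional tibble with columns `fold_a`, `fold_b`,
#'   `length_ratio`, `local_boost`, `global_penalty`: cross-pair scores
#'   between the two folds get `local = base + boost`,
#'   `global = base - penalty` (clipped), and `fold_a` lengths are scaled to
#'   `length_ratio` of `fold_b`'s.
#' @param length_mean,length_sd Per-fold domain length model in residues
#'   (defaults 150, 20; scalar or per-fold vectors).
#' @returns A `universe_config` list.
#' @export
universe_config <- function(n_folds = 8, members_per_fold = 30,
                            within_means = NULL, within_sds = NULL,
                            within_support = c(0.45, 0.99),
                            between_mean = 0.3, between_sd = 0.05,
                            between_support = c(0.05, 0.4),
                            bridges = NULL, russian_doll = NULL,
                            length_mean = 150, length_sd = 20) {
  n_folds <- as.integer(n_folds)
  stopifnot(n_folds >= 1)
  members <- rep_len(as.integer(members_per_fold), n_folds)
  if (any(members < 2)) abort("every fold needs at least 2 members.")
  within_means <- within_means %||% seq(0.95, 0.65, length.out = n_folds)
  within_means <- rep_len(within_means, n_folds)
  within_sds <- within_sds %||% (0.02 + 0.25 * (0.97 - within_means))
  within_sds <- rep_len(within_sds, n_folds)
  if (any(within_means <= 0.01 | within_means > 1)) {
    abort("within-fold score means must lie in (0.01, 1].")
  }
  if (!is.null(bridges)) {
    bridges <- tibble::as_tibble(bridges)
    need <- c("n_domains", "source_fold", "target_fold", "level")
    if (!all(need %in% names(bridges))) {
      abort(paste0("`bridges` needs columns: ", paste(need, collapse = ", ")))
    }
    if (any(bridges$level > 1 | bridges$level <= 0.01)) {
      abort("bridge score levels must lie in (0.01, 1].")
    }
  }
  if (!is.null(russian_doll)) {
    russian_doll <- tibble::as_tibble(russian_doll)
    need <- c("fold_a", "fold_b", "length_ratio", "local_boost", "global_penalty")
    if (!all(need %in% names(russian_doll))) {
      abort(paste0("`russian_doll` needs columns: ", paste(need, collapse = ", ")))
    }
  }
  structure(list(n_folds = n_folds, members_per_fold = members,
                 within_means = within_means, within_sds = within_sds,
                 within_support = within_support,
                 between_mean = between_mean, between_sd = between_sd,
                 between_support = between_support,
                 bridges = bridges, russian_doll = russian_doll,
                 length_mean = rep_len(length_mean, n_folds),
                 length_sd = rep_len(length_sd, n_folds)),
            class = "universe_config")
}

#' Discrete-universe configuration
#'
#' Within-fold scores at or above 0.8, cross-fold scores at or below 0.4, no
#' bridges: fold space as isolated islands, under which TM_max, CEP and C3P
#' classifications always agree with the truth.
#'
#' @param n_folds,members_per_fold Universe size (defaults 8 x 30).
#' @returns A `universe_config`.
#' @export
discrete_universe_config <- function(n_folds = 8, members_per_fold = 30) {
  ## means sit well inside the clip window so the score distributions keep
  ## no atom at the boundaries (an artifact real TM-scores do not show)
  universe_config(
    n_folds = n_folds, members_per_fold = members_per_fold,
    within_means = seq(0.92, 0.85, length.out = n_folds),
    within_sds = rep(0.025, n_folds),
    within_support = c(0.8, 0.99),
    between_mean = 0.3, between_sd = 0.05, between_support = c(0.05, 0.4)
  )
}

#' Continuum-universe configuration
#'
#' A heterogeneity gradient across folds plus bridge domains whose scores
#' into the most heterogeneous (highest-SD) folds fall between the two
#' folds' within-score supports, emulating fold-space continuity: bridges
#' are candidates for reclassification and heterogeneous folds attract them.
#' The default of 12 folds resolves the gradient finely enough for rank
#' statistics across folds to carry signal (with very few folds a
#' permutation test over fold labels cannot reach conventional
#' significance no matter how strong the attraction pattern is).
#'
#' @param n_folds,members_per_fold Universe size (defaults 12 x 30).
#' @param n_bridges Total bridge domains (default 10), split between the two
#'   highest-SD folds as targets.
#' @param bridge_level Score level of bridge-target pairs (default 0.9: a
#'   bridge shares near-duplicate substructure with the target fold, so its
#'   cross score is comparable to its own fold's within scores and falls in
#'   the upper range of the target fold's within-fold TM_max distribution).
#' @returns A `universe_config`.
#' @export
continuum_universe_config <- function(n_folds = 12, members_per_fold = 30,
                                      n_bridges = 10, bridge_level = 0.9) {
  if (n_folds < 4) abort("a continuum universe needs at least 4 folds.")
  ## a gradient of mostly-tight folds plus two markedly heterogeneous folds
  ## (the attractors): heterogeneity is concentrated in a few folds rather
  ## than spread along a shallow ramp. The within-fold TM_max statistic (a
  ## maximum over members) compresses generating SDs heavily, so the
  ## attractors' generating SDs must be several-fold larger than the ramp's
  ## for the realized TM_max spread to single them out
  means <- c(seq(0.90, 0.72, length.out = n_folds - 2), 0.62, 0.60)
  sds <- c(0.02 + 0.15 * (0.97 - means[seq_len(n_folds - 2)]), 0.16, 0.18)
  ## the two highest-SD folds are the last two; bridges come from the two
  ## tightest folds so their home fit is sharp but the target accommodates
  fold_ids <- sprintf("F%02d", seq_len(n_folds))
  bridges <- tibble::tibble(
    n_domains = c(ceiling(n_bridges / 2), floor(n_bridges / 2)),
    source_fold = fold_ids[c(1, 2)],
    target_fold = fold_ids[c(n_folds, n_folds - 1)],
    level = bridge_level
  )
  universe_config(n_folds = n_folds, members_per_fold = members_per_fold,
                  within_means = means, within_sds = sds,
                  within_support = c(0.45, 0.99),
                  between_mean = 0.3, between_sd = 0.05,
                  between_support = c(0.05, 0.4),
                  bridges = bridges[bridges$n_domains > 0, ])
}

clip_scores <- function(s, support) {
  pmin(pmax(s, max(support[1], 0.0101)), min(support[2], 1))
}

#' Generate a synthetic fold universe
#'
#' Draws a classification table, symmetric local and global score matrices
#' with unit diagonal, and a truth record holding every generating parameter
#' plus the bridge domain ids.
#'
#' @param config A [universe_config()].
#' @param seed Integer seed.
#' @returns List with `classification` (tibble), `local` and `global`
#'   ([tm_matrix()]), and `truth` (list: `config`, `bridge_domains`,
#'   `fold_ids`, `members`).
#' @examples
#' u <- generate_universe(discrete_universe_config(4, 10), seed = 1)
#' u$classification
#' @export
generate_universe <- function(config, seed = NULL) {
  stopifnot(inherits(config, "universe_config"))
  if (!is.null(seed)) set.seed(seed)
  nf <- config$n_folds
  fold_ids <- sprintf("F%02d", seq_len(nf))
  members <- purrr::map2(fold_ids, config$members_per_fold, function(fid, m) {
    sprintf("%s_D%03d", fid, seq_len(m))
  })
  names(members) <- fold_ids
  all_ids <- unlist(members, use.names = FALSE)
  n <- length(all_ids)
  fold_of <- rep(fold_ids, config$members_per_fold)
  names(fold_of) <- all_ids

  lengths <- unlist(purrr::map(seq_len(nf), function(i) {
    pmax(40L, as.integer(round(rnorm(config$members_per_fold[i],
                                     config$length_mean[i],
                                     config$length_sd[i]))))
  }), use.names = FALSE)
  names(lengths) <- all_ids

  loc <- matrix(NA_real_, n, n, dimnames = list(all_ids, all_ids))
  ## between-fold base scores
  base <- rnorm(n * n, config$between_mean, config$between_sd)
  loc[] <- clip_scores(base, config$between_support)
  loc[lower.tri(loc)] <- t(loc)[lower.tri(loc)]
  ## within-fold blocks
  for (i in seq_len(nf)) {
    ids <- members[[i]]
    m <- length(ids)
    s <- clip_scores(rnorm(m * (m - 1) / 2, config$within_means[i],
                           config$within_sds[i]),
                     config$within_support)
    blk <- matrix(0, m, m)
    blk[upper.tri(blk)] <- s
    blk <- blk + t(blk)
    loc[ids, ids] <- blk
  }
  glo <- loc

  ## Russian-doll pairs: local inflated, global deflated, nested lengths
  rd <- config$russian_doll
  if (!is.null(rd)) {
    for (r in seq_len(nrow(rd))) {
      ia <- members[[rd$fold_a[r]]]; ib <- members[[rd$fold_b[r]]]
      loc[ia, ib] <- clip_scores(loc[ia, ib] + rd$local_boost[r], c(0.0101, 1))
      loc[ib, ia] <- t(loc[ia, ib])
      glo[ia, ib] <- clip_scores(glo[ia, ib] - rd$global_penalty[r], c(0.0101, 1))
      glo[ib, ia] <- t(glo[ia, ib])
      lengths[ia] <- pmax(40L, as.integer(round(
        rd$length_ratio[r] * mean(lengths[ib]))))
    }
  }

  ## bridge domains: structurally intermediate between the two folds, so
  ## (a) elevated scores to every member of the target fold and (b)
  ## peripheral standing in the home fold — their within-fold scores sit
  ## about 1.5 SD below the fold mean, the boundary members that continuity
  ## arguments are about
  bridge_domains <- character(0)
  br <- config$bridges
  if (!is.null(br)) {
    for (r in seq_len(nrow(br))) {
      src_fold <- br$source_fold[r]
      src <- members[[src_fold]]
      nb <- br$n_domains[r]
      if (nb > length(src) - 2) {
        abort("bridge count leaves fewer than 2 non-bridge members in the source fold.")
      }
      bd <- tail(src, nb)
      i <- match(src_fold, fold_ids)
      peri_mean <- config$within_means[i] - 1.5 * config$within_sds[i]
      for (b in bd) {
        others <- setdiff(src, b)
        v <- clip_scores(rnorm(length(others), peri_mean, config$within_sds[i]),
                         config$within_support)
        loc[b, others] <- v
        loc[others, b] <- v
        glo[b, others] <- v
        glo[others, b] <- v
      }
      tgt <- members[[br$target_fold[r]]]
      s <- matrix(clip_scores(rnorm(nb * length(tgt), br$level[r], 0.02),
                              c(0.0101, 1)),
                  nb, length(tgt))
      loc[bd, tgt] <- s
      loc[tgt, bd] <- t(s)
      glo[bd, tgt] <- s
      glo[tgt, bd] <- t(s)
      bridge_domains <- c(bridge_domains, bd)
    }
  }

  diag(loc) <- 1
  diag(glo) <- 1
  classification <- classification_table(all_ids, fold_of[all_ids],
                                         lengths[all_ids], "synthetic")
  list(classification = classification,
       local = tm_matrix(loc, "local"),
       global = tm_matrix(glo, "global"),
       truth = list(config = config, bridge_domains = bridge_domains,
                    fold_ids = fold_ids, members = members))
}

#' Generate perturbed alpha-helical toy structures
#'
#' Test substrate for the TM-score code: an ideal alpha-helical CA trace
#' (rise 1.5 A, radius 2.3 A, 100 degrees twist per residue) plus i.i.d.
#' Gaussian coordinate noise per copy, optionally truncated to a leading
#' fraction of residues (nested substructures). Identity correspondences on
#' shared residues are returned for every pair.
#'
#' @param n Number of structures.
#' @param length Residues in the full-length trace (>= 10).
#' @param perturbation_sd Coordinate noise SD in Angstroms (>= 0).
#' @param truncation Optional vector of per-structure fractions in (0, 1];
#'   structure `i` keeps the first `ceiling(truncation[i] * length)`
#'   residues.
#' @param seed Integer seed.
#' @returns List with `structures` (list of `ca_structure`, ids `"1"`,
#'   `"2"`, ...) and `correspondences` (named list of [alignment_pairs()],
#'   keys `"i-j"`).
#' @export
generate_toy_structures <- function(n, length = 60, perturbation_sd = 0,
                                    truncation = NULL, seed = NULL) {
  if (length < 10) abort("`length` must be >= 10 residues.")
  if (perturbation_sd < 0) abort("`perturbation_sd` must be >= 0.")
  if (!is.null(seed)) set.seed(seed)
  i <- seq_len(length)
  theta <- i * 100 * pi / 180
  base <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i)
  trunc <- rep_len(truncation %||% 1, n)
  structures <- purrr::map(seq_len(n), function(s) {
    keep <- ceiling(trunc[s] * length)
    if (keep < 4) abort("truncation leaves fewer than 4 residues.")
    coords <- base[seq_len(keep), , drop = FALSE] +
      matrix(rnorm(keep * 3, 0, perturbation_sd), keep, 3)
    ca_structure(as.character(s), coords)
  })
  correspondences <- list()
  if (n > 1) {
    for (a in seq_len(n - 1)) {
      for (b in (a + 1):n) {
        shared <- min(structures[[a]]$length, structures[[b]]$length)
        correspondences[[paste0(a, "-", b)]] <-
          alignment_pairs(seq_len(shared), seq_len(shared))
      }
    }
  }
  list(structures = structures, correspondences = correspondences)
}

#' Draw samples from a Gaussian mixture
#'
#' Sampler test substrate: i.i.d. draws from `sum_j w_j N(mu_j, sd_j^2)`,
#' clipped to (0.01, 1) with a warning when more than 1% of draws required
#' clipping.
#'
#' @param weights Mixture weights (a simplex).
#' @param means,sds Component means and SDs.
#' @param n Number of draws.
#' @param seed Integer seed.
#' @returns Numeric vector of length `n`.
#' @export
generate_gmm_data <- function(weights, means, sds, n, seed = NULL) {
  if (abs(sum(weights) - 1) > 1e-9 || any(weights < 0)) {
    abort("`weights` must be a simplex.")
  }
  if (any(sds <= 0)) abort("`sds` must be positive.")
  if (length(means) != length(weights) || length(sds) != length(weights)) {
    abort("`weights`, `means`, `sds` must have equal length.")
  }
  if (!is.null(seed)) set.seed(seed)
  j <- sample.int(length(weights), n, replace = TRUE, prob = weights)
  x <- rnorm(n, means[j], sds[j])
  clipped <- x <= 0.01 | x >= 1
  if (mean(clipped) > 0.01) {
    warn(sprintf("%.1f%% of mixture draws clipped to (0.01, 1).",
                 100 * mean(clipped)))
  }
  pmin(pmax(x, 0.0101), 0.9999)
}
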