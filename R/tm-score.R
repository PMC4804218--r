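#' TM-score distance scale d0
#'
#' The length-dependent scale that makes the expected TM-score of random
#' structure pairs independent of protein size:
#' `d0 = max(1.24 * (L - 15)^(1/3) - 1.8, 0.5)` Angstroms.
#'
#' @param l_norm Normalizing length in residues (>= 1).
#' @returns d0 in Angstroms.
#' @examples
#' d0_scale(100) # ~3.65
#' d0_scale(15)  # floor engaged: 0.5
#' @export
d0_scale <- function(l_norm) {
  if (any(l_norm < 1)) abort("`l_norm` must be >= 1 residue.")
  raw <- 1.24 * sign(l_norm - 15) * abs(l_norm - 15)^(1 / 3) - 1.8
  pmax(raw, 0.5)
}

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimizing the (weighted) RMSD
#' of `Q` onto `P`. Reflections are excluded by the sign correction on the
#' smallest singular value.
#'
#' @param p,q Numeric n x 3 coordinate matrices, n >= 3, not all collinear.
#' @param weights Optional non-negative weights, length n.
#' @returns List with `rotation` (3 x 3, det +1), `translation` (length-3),
#'   and `rmsd`; the transform maps `q` onto `p` as
#'   `q %*% t(rotation) + translation`.
#' @export
kabsch_superpose <- function(p, q, weights = NULL) {
  p <- as.matrix(p); q <- as.matrix(q)
  n <- nrow(p)
  if (n != nrow(q) || ncol(p) != 3 || ncol(q) != 3) {
    abort("`p` and `q` must be n x 3 matrices of equal size.")
  }
  if (n < 3) abort("at least 3 points are required for superposition.")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(w < 0) || sum(w) == 0) {
    abort("`weights` must be non-negative with positive sum.")
  }
  w <- w / sum(w)
  cp <- colSums(p * w); cq <- colSums(q * w)
  pc <- sweep(p, 2, cp); qc <- sweep(q, 2, cq)
  h <- t(qc * w) %*% pc  # covariance, q -> p
  s <- svd(h)
  if (min(s$d) <= 1e-12 && s$d[2] <= 1e-12) {
    abort("degenerate (collinear) point set: superposition is ill-defined.")
  }
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  trans <- cp - as.vector(rot %*% cq)
  moved <- qc %*% t(rot)
  rmsd <- sqrt(sum(w * rowSums((moved - pc)^2)))
  list(rotation = rot, translation = trans, rmsd = rmsd)
}

#' Residue correspondence between two structures
#'
#' A sequential alignment: both index vectors strictly increasing, 1-based.
#'
#' @param a_idx,b_idx Integer residue indices into structures A and B.
#' @returns An `alignment_pairs` object with `l_ali = length(a_idx)`.
#' @export
alignment_pairs <- function(a_idx, b_idx) {
  a_idx <- as.integer(a_idx); b_idx <- as.integer(b_idx)
  if (length(a_idx) != length(b_idx) || length(a_idx) < 1) {
    abort("`a_idx` and `b_idx` must be non-empty and of equal length.")
  }
  if (any(diff(a_idx) <= 0) || any(diff(b_idx) <= 0)) {
    abort("alignment indices must be strictly increasing (sequential alignment).")
  }
  if (min(a_idx, b_idx) < 1) abort("alignment indices are 1-based.")
  structure(list(a_idx = a_idx, b_idx = b_idx, l_ali = length(a_idx)),
            class = "alignment_pairs")
}

#' TM-score of two structures under a fixed residue correspondence
#'
#' Computes `TM = max over superpositions of (1/L_norm) * sum_i
#' 1 / (1 + (d_i/d0)^2)` where `d_i` are distances between aligned CA pairs.
#' `L_norm` is the length of the shorter structure (`mode = "local"`,
#' emphasizing substructure similarity) or the mean length rounded half-up
#' (`mode = "global"`, penalizing length mismatch). The maximization uses a
#' deterministic seed-and-refine search: every contiguous alignment fragment
#' of length `l_ali`, `l_ali/2` and `l_ali/4` (minimum 4 pairs, all offsets)
#' seeds a Kabsch superposition which is refined for up to 20 rounds by
#' re-superposing on pairs closer than a cutoff that starts at d0 and grows
#' by 0.5 A whenever fewer than 3 pairs qualify.
#'
#' @param a,b `ca_structure` objects.
#' @param pairs An [alignment_pairs()] correspondence (>= 4 pairs).
#' @param mode `"local"` or `"global"`.
#' @returns A `tm_score_result`: list with `score`, `mode`, `d0`, `l_norm`,
#'   `rotation`, `translation` (mapping `b` onto `a`), and `distances` (one
#'   per aligned pair at the best superposition).
#' @examples
#' helix <- generate_toy_structures(2, length = 40, perturbation_sd = 0, seed = 1)
#' tm_score(helix$structures[[1]], helix$structures[[2]],
#'          helix$correspondences[["1-2"]], mode = "local")$score
#' @export
tm_score <- function(a, b, pairs, mode = c("local", "global")) {
  mode <- match.arg(mode)
  stopifnot(inherits(a, "ca_structure"), inherits(b, "ca_structure"),
            inherits(pairs, "alignment_pairs"))
  if (pairs$l_ali < 4) abort("at least 4 aligned pairs are required.")
  if (max(pairs$a_idx) > a$length || max(pairs$b_idx) > b$length) {
    abort("alignment indices out of bounds for the structures.")
  }
  l_norm <- switch(mode,
    local = min(a$length, b$length),
    global = floor((a$length + b$length) / 2 + 0.5)  # half-up
  )
  d0 <- d0_scale(l_norm)
  pa <- a$ca[pairs$a_idx, , drop = FALSE]
  pb <- b$ca[pairs$b_idx, , drop = FALSE]
  l_ali <- pairs$l_ali

  score_of <- function(d2) sum(1 / (1 + d2 / d0^2)) / l_norm

  best <- list(score = -Inf)
  frag_lens <- unique(pmax(4L, c(l_ali, l_ali %/% 2L, l_ali %/% 4L)))
  frag_lens <- frag_lens[frag_lens <= l_ali]
  for (fl in frag_lens) {
    for (off in seq_len(l_ali - fl + 1L)) {
      subset <- off:(off + fl - 1L)
      for (round in seq_len(20L)) {
        fit <- tryCatch(
          kabsch_superpose(pa[subset, , drop = FALSE], pb[subset, , drop = FALSE]),
          error = function(e) NULL
        )
        if (is.null(fit)) break
        moved <- pb %*% t(fit$rotation) +
          matrix(fit$translation, l_ali, 3, byrow = TRUE)
        d2 <- rowSums((moved - pa)^2)
        sc <- score_of(d2)
        if (sc > best$score) {
          best <- list(score = sc, rotation = fit$rotation,
                       translation = fit$translation, d2 = d2)
        }
        d_cut <- d0
        repeat {
          new_subset <- which(sqrt(d2) < d_cut)
          if (length(new_subset) >= 3) break
          d_cut <- d_cut + 0.5
        }
        if (identical(new_subset, subset)) break
        subset <- new_subset
      }
    }
  }
  structure(list(score = best$score, mode = mode, d0 = d0, l_norm = l_norm,
                 rotation = best$rotation, translation = best$translation,
                 distances = sqrt(best$d2)),
            class = "tm_score_result")
}

#' @export
print.tm_score_result <- function(x, ...) {
  cat(sprintf("<tm_score_result> %s TM-score = %.4f (L_norm = %d, d0 = %.3f A)\n",
              x$mode, x$score, x$l_norm, x$d0))
  invisible(x)
}

#' Batch pairwise TM-score matrix
#'
#' @param structures List of `ca_structure` objects (named or using their
#'   `domain_id`s).
#' @param correspondences Named list of [alignment_pairs()]; names are
#'   `"idA-idB"` for each required unordered pair.
#' @param mode `"local"` or `"global"`.
#' @returns A [tm_matrix()] with unit diagonal.
#' @export
pairwise_matrix <- function(structures, correspondences,
                            mode = c("local", "global")) {
  mode <- match.arg(mode)
  ids <- purrr::map_chr(structures, "domain_id")
  if (anyDuplicated(ids)) abort("duplicate domain ids among structures.")
  names(structures) <- ids
  n <- length(ids)
  m <- diag(1, n)
  dimnames(m) <- list(ids, ids)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        key <- paste0(ids[i], "-", ids[j])
        key_rev <- paste0(ids[j], "-", ids[i])
        pr <- correspondences[[key]]
        swap <- FALSE
        if (is.null(pr)) { pr <- correspondences[[key_rev]]; swap <- TRUE }
        if (is.null(pr)) {
          abort(paste0("missing correspondence for pair ", key))
        }
        res <- if (swap) {
          tm_score(structures[[j]], structures[[i]], pr, mode)
        } else {
          tm_score(structures[[i]], structures[[j]], pr, mode)
        }
        m[i, j] <- m[j, i] <- res$score
      }
    }
  }
  tm_matrix(m, mode)
}
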