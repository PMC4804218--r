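#' Pairwise structure-similarity matrix
#'
#' A `tm_matrix` stores symmetric pairwise TM-scores between protein domains,
#' tagged with the length normalization under which they were computed:
#' `"local"` (normalized by the shorter domain's length, emphasizing
#' substructure similarity) or `"global"` (normalized by the mean length,
#' penalizing length mismatch). Scores lie in (0, 1]; the diagonal is 1.
#' Absent pairs are `NA`.
#'
#' @param scores Square numeric matrix with identical row/column names
#'   (domain identifiers).
#' @param mode `"local"` or `"global"`.
#' @returns A `tm_matrix` object.
#' @examples
#' m <- matrix(c(1, 0.7, 0.7, 1), 2, 2,
#'             dimnames = list(c("a", "b"), c("a", "b")))
#' tm_matrix(m, "local")
#' @export
tm_matrix <- function(scores, mode = c("local", "global")) {
  mode <- match.arg(mode)
  if (!is.matrix(scores) || !is.numeric(scores)) {
    abort("`scores` must be a numeric matrix.")
  }
  if (nrow(scores) != ncol(scores)) {
    abort("`scores` must be square.")
  }
  ids <- rownames(scores)
  if (is.null(ids) || !identical(ids, colnames(scores))) {
    abort("`scores` must have identical row and column names (domain ids).")
  }
  if (anyDuplicated(ids)) {
    abort("duplicate domain ids in similarity matrix.")
  }
  vals <- scores[!is.na(scores)]
  if (any(vals <= 0 | vals > 1)) {
    abort("similarity scores must lie in (0, 1].")
  }
  if (!isTRUE(all.equal(unname(diag(scores)), rep(1, nrow(scores))))) {
    abort("similarity matrix diagonal must be 1 (self-similarity).")
  }
  if (!isSymmetric(unname(scores))) {
    abort("similarity matrix must be symmetric.")
  }
  structure(list(scores = scores, mode = mode), class = "tm_matrix")
}

#' @export
print.tm_matrix <- function(x, ...) {
  n <- nrow(x$scores)
  off <- x$scores[upper.tri(x$scores)]
  off <- off[!is.na(off)]
  cat(sprintf("<tm_matrix> %d domains, %s normalization\n", n, x$mode))
  if (length(off)) {
    cat(sprintf("  %d stored pairs, score range [%.3f, %.3f]\n",
                length(off), min(off), max(off)))
  }
  invisible(x)
}

#' @export
dim.tm_matrix <- function(x) dim(x$scores)

#' Domain identifiers of a similarity matrix
#' @param x A [tm_matrix()].
#' @returns Character vector of domain ids.
#' @export
domain_ids <- function(x) {
  stopifnot(inherits(x, "tm_matrix"))
  rownames(x$scores)
}

#' Look up pairwise scores
#'
#' @param x A [tm_matrix()].
#' @param a,b Domain id vectors (recycled against each other).
#' @returns Numeric vector of scores (`NA` when the pair is absent).
#' @export
tm_lookup <- function(x, a, b) {
  stopifnot(inherits(x, "tm_matrix"))
  x$scores[cbind(a, b)]
}

#' Submatrix of scores between two domain sets
#' @param x A [tm_matrix()].
#' @param rows,cols Domain ids.
#' @returns Numeric matrix of scores.
#' @export
tm_block <- function(x, rows, cols) {
  stopifnot(inherits(x, "tm_matrix"))
  missing_ids <- setdiff(c(rows, cols), domain_ids(x))
  if (length(missing_ids)) {
    abort(paste0("domains absent from similarity matrix: ",
                 paste(missing_ids, collapse = ", ")))
  }
  x$scores[rows, cols, drop = FALSE]
}

#' @exportS3Method tibble::as_tibble
as_tibble.tm_matrix <- function(x, ...) {
  ids <- domain_ids(x)
  idx <- which(upper.tri(x$scores) & !is.na(x$scores), arr.ind = TRUE)
  tibble::tibble(
    domain_a = ids[idx[, 1]],
    domain_b = ids[idx[, 2]],
    score = x$scores[idx],
    mode = x$mode
  ) |>
    dplyr::arrange(.data$domain_a, .data$domain_b)
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble
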