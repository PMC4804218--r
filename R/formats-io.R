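#' Build a domain classification table
#'
#' The classification table is the "initial classification": one row per
#' domain, each assigned to exactly one fold (CATH topology level or SCOP fold
#' level).
#'
#' @param domain_id Character vector of unique domain identifiers.
#' @param fold_id Character vector of fold identifiers (dot-separated
#'   hierarchy prefix such as `"1.20.120"` or `"a.1"`).
#' @param length Integer residue counts (`NA` allowed when unknown).
#' @param source One of `"CATH"`, `"SCOP"`, `"synthetic"`.
#' @returns A tibble with columns `domain_id`, `fold_id`, `length`, `source`.
#' @export
classification_table <- function(domain_id, fold_id, length = NA_integer_,
                                 source = c("synthetic", "CATH", "SCOP")) {
  source <- match.arg(source)
  tbl <- tibble::tibble(
    domain_id = as.character(domain_id),
    fold_id = as.character(fold_id),
    length = as.integer(length),
    source = source
  )
  validate_classification(tbl)
}

validate_classification <- function(tbl) {
  if (anyDuplicated(tbl$domain_id)) {
    dup <- unique(tbl$domain_id[duplicated(tbl$domain_id)])
    abort(paste0("duplicate domain id(s): ", paste(head(dup, 5), collapse = ", ")))
  }
  if (any(!nzchar(tbl$fold_id) | is.na(tbl$fold_id))) {
    abort("every domain must have a non-empty fold_id.")
  }
  bad_len <- !is.na(tbl$length) & tbl$length < 1
  if (any(bad_len)) {
    abort("domain lengths must be >= 1 residue.")
  }
  tbl
}

#' Read a CATH `CathDomainList`-style classification file
#'
#' Whitespace-delimited text with `#` comment lines. Each data line carries a
#' domain id, the integer C, A, T, H (and deeper) hierarchy levels, and the
#' domain length as the last column. The fold id is the `C.A.T` prefix joined
#' with dots (the topology level, equivalent to a SCOP fold).
#'
#' @param path File path.
#' @returns A classification tibble (see [classification_table()]).
#' @export
read_cath_domain_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (!length(keep)) {
    return(classification_table(character(), character(), integer(), "CATH"))
  }
  recs <- purrr::map(keep, function(i) {
    fields <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(fields) < 5) {
      abort(sprintf("line %d: expected a domain id, >= 3 hierarchy levels and a length (got %d columns).",
                    i, length(fields)))
    }
    num <- suppressWarnings(as.numeric(fields[-1]))
    if (anyNA(num) || any(num != floor(num))) {
      abort(sprintf("line %d: hierarchy levels and length must be integers.", i))
    }
    list(domain_id = fields[1],
         fold_id = paste(fields[2:4], collapse = "."),
         length = as.integer(fields[length(fields)]))
  })
  tbl <- tibble::tibble(
    domain_id = purrr::map_chr(recs, "domain_id"),
    fold_id = purrr::map_chr(recs, "fold_id"),
    length = purrr::map_int(recs, "length"),
    source = "CATH"
  )
  validate_classification(tbl)
}

#' Read a SCOP `dir.cla`-style classification file
#'
#' Tab-delimited rows: sid, PDB id, region, sccs string (e.g. `"a.1.1.1"`),
#' sunid, hierarchy field. Lines starting with `#` are skipped. The fold id is
#' the first two dot-fields of the sccs (class.fold). When the region string
#' carries explicit residue ranges (e.g. `"A:1-120"`), the summed span is used
#' as the domain length; otherwise the length is `NA`.
#'
#' @param path File path.
#' @returns A classification tibble.
#' @export
read_scop_cla <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (!length(keep)) {
    return(classification_table(character(), character(), integer(), "SCOP"))
  }
  recs <- purrr::map(keep, function(i) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 4 || !nzchar(fields[4])) {
      abort(sprintf("line %d: missing sccs field.", i))
    }
    sccs <- strsplit(fields[4], ".", fixed = TRUE)[[1]]
    if (length(sccs) < 2) {
      abort(sprintf("line %d: sccs '%s' has fewer than two dot-fields.", i, fields[4]))
    }
    list(domain_id = fields[1],
         fold_id = paste(sccs[1:2], collapse = "."),
         length = scop_region_length(fields[3]))
  })
  tbl <- tibble::tibble(
    domain_id = purrr::map_chr(recs, "domain_id"),
    fold_id = purrr::map_chr(recs, "fold_id"),
    length = purrr::map_int(recs, "length"),
    source = "SCOP"
  )
  validate_classification(tbl)
}

## "A:1-120,B:5-30" -> 146; segments without an explicit range give NA
scop_region_length <- function(region) {
  if (is.na(region) || !nzchar(region)) return(NA_integer_)
  segs <- strsplit(region, ",", fixed = TRUE)[[1]]
  spans <- purrr::map_int(segs, function(s) {
    m <- regmatches(s, regexec("(-?\\d+)-(-?\\d+)\\s*$", s))[[1]]
    if (length(m) != 3) return(NA_integer_)
    as.integer(m[3]) - as.integer(m[2]) + 1L
  })
  if (anyNA(spans)) NA_integer_ else sum(spans)
}

#' Read a tab-separated table of precomputed TM-scores
#'
#' Expected columns: `domain_a`, `domain_b`, `score_local`, `score_global`,
#' with scores in (0, 1]. If both orientations of a pair are present with
#' unequal scores, the maximum is kept with a warning (structure-alignment
#' programs are not perfectly symmetric, and TM_max statistics consume the
#' higher score).
#'
#' @param path File path.
#' @returns A list with elements `local` and `global`, each a [tm_matrix()].
#' @export
read_score_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("domain_a", "domain_b", "score_local", "score_global")
  if (!all(need %in% names(tbl))) {
    abort(paste0("score table must have columns: ", paste(need, collapse = ", ")))
  }
  for (col in c("score_local", "score_global")) {
    s <- tbl[[col]]
    if (any(is.na(s) | s <= 0 | s > 1)) {
      abort(sprintf("%s values must lie in (0, 1].", col))
    }
  }
  self <- tbl$domain_a == tbl$domain_b
  if (any(self & (tbl$score_local != 1 | tbl$score_global != 1))) {
    abort("self-pairs must have score 1.")
  }
  ids <- sort(unique(c(tbl$domain_a, tbl$domain_b)))
  build <- function(col) {
    m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
    diag(m) <- 1
    conflicts <- 0L
    for (r in seq_len(nrow(tbl))) {
      a <- tbl$domain_a[r]; b <- tbl$domain_b[r]; s <- tbl[[col]][r]
      prev <- m[a, b]
      if (!is.na(prev) && a != b && prev != s) {
        conflicts <- conflicts + 1L
        s <- max(prev, s)
      }
      m[a, b] <- s
      m[b, a] <- s
    }
    if (conflicts > 0) {
      warn(sprintf("%d asymmetric duplicate pair(s) in %s; kept the maximum score.",
                   conflicts, col))
    }
    m
  }
  list(local = tm_matrix(build("score_local"), "local"),
       global = tm_matrix(build("score_global"), "global"))
}

#' Write a pair of local/global similarity matrices as a score table
#'
#' Inverse of [read_score_table()]: one row per stored pair (upper triangle),
#' sorted by ids, scores printed with six decimals.
#'
#' @param scores A list with `local` and `global` [tm_matrix()] elements (as
#'   returned by [read_score_table()] or [generate_universe()]).
#' @param path Output file path.
#' @returns `path`, invisibly.
#' @export
write_score_table <- function(scores, path) {
  stopifnot(inherits(scores$local, "tm_matrix"), inherits(scores$global, "tm_matrix"))
  loc <- as_tibble(scores$local)
  glo <- as_tibble(scores$global)
  tbl <- dplyr::full_join(
    dplyr::select(loc, "domain_a", "domain_b", score_local = "score"),
    dplyr::select(glo, "domain_a", "domain_b", score_global = "score"),
    by = c("domain_a", "domain_b")
  ) |>
    dplyr::arrange(.data$domain_a, .data$domain_b) |>
    dplyr::mutate(score_local = sprintf("%.6f", .data$score_local),
                  score_global = sprintf("%.6f", .data$score_global))
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}

#' Read C-alpha coordinates from a PDB file
#'
#' Extracts the CA trace of the first model: altloc blank or `'A'`, residues
#' ordered by (chain, residue number, insertion code). Duplicate CA records
#' for one residue keep the first occurrence with a warning.
#'
#' @param path PDB file path.
#' @param chain Optional chain identifier; default keeps all chains.
#' @param domain_id Identifier for the resulting structure (defaults to the
#'   file name without extension).
#' @returns A `ca_structure`: list with `domain_id`, `ca` (L x 3 matrix, in
#'   Angstroms) and `length`.
#' @export
read_ca_coordinates <- function(path, chain = NULL, domain_id = NULL) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$elety == "CA" & at$type == "ATOM", , drop = FALSE]
  alt <- at$alt
  at <- at[is.na(alt) | alt %in% c("", "A"), , drop = FALSE]
  if (!is.null(chain)) at <- at[at$chain %in% chain, , drop = FALSE]
  if (nrow(at) == 0) abort("no CA atoms found.")
  ins <- ifelse(is.na(at$insert), "", at$insert)
  at <- at[order(at$chain, at$resno, ins), , drop = FALSE]
  key <- paste(at$chain, at$resno, ins[order(at$chain, at$resno, ins)])
  if (anyDuplicated(key)) {
    warn("duplicate CA records for some residues; kept the first of each.")
    at <- at[!duplicated(key), , drop = FALSE]
  }
  id <- domain_id %||% sub("\\.[^.]*$", "", basename(path))
  ca_structure(id, as.matrix(at[, c("x", "y", "z")]))
}

#' Construct a CA-trace structure
#'
#' @param domain_id Identifier.
#' @param ca Numeric L x 3 matrix of CA coordinates in Angstroms.
#' @returns A `ca_structure` object.
#' @export
ca_structure <- function(domain_id, ca) {
  ca <- as.matrix(ca)
  if (ncol(ca) != 3 || !all(is.finite(ca))) {
    abort("`ca` must be an L x 3 matrix of finite coordinates.")
  }
  dimnames(ca) <- NULL
  structure(list(domain_id = as.character(domain_id), ca = ca,
                 length = nrow(ca)),
            class = "ca_structure")
}

#' @export
print.ca_structure <- function(x, ...) {
  cat(sprintf("<ca_structure> %s: %d residues\n", x$domain_id, x$length))
  invisible(x)
}

#' Write a tab-separated classification report
#'
#' One row per query (sorted by query id) with the original fold, the fold
#' assigned by each method present in `results`, and the top three folds by
#' query-fold TM_max score. Deterministic: rerunning on the same input yields
#' a byte-identical file.
#'
#' @param results A query-result tibble from [classify_queries()] (or a list
#'   of `query_result` objects).
#' @param path Output file path.
#' @returns `path`, invisibly.
#' @export
write_classification_report <- function(results, path) {
  if (inherits(results, "query_result")) results <- list(results)
  if (is.list(results) && !is.data.frame(results)) {
    results <- purrr::map_dfr(results, tidy_query_result)
  }
  if (!is.data.frame(results) || nrow(results) == 0) {
    abort("`results` must be a non-empty query-result table.")
  }
  wide <- results |>
    dplyr::distinct(.data$query_id, .data$method, .data$assigned_fold,
                    .data$original_fold) |>
    tidyr::pivot_wider(names_from = "method", values_from = "assigned_fold",
                       names_prefix = "assigned_") |>
    dplyr::arrange(.data$query_id)
  top3 <- results |>
    dplyr::distinct(.data$query_id, .data$fold_id, .data$tm_max) |>
    dplyr::group_by(.data$query_id) |>
    dplyr::arrange(dplyr::desc(.data$tm_max), .data$fold_id, .by_group = TRUE) |>
    dplyr::slice_head(n = 3) |>
    dplyr::summarise(top_folds = paste(sprintf("%s:%.4f", .data$fold_id, .data$tm_max),
                                       collapse = ";"),
                     .groups = "drop")
  out <- dplyr::left_join(wide, top3, by = "query_id")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
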