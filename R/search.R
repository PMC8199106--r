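#' Hit-filtering threshold bundles
#'
#' Constructs the threshold set applied to candidate hits. Bounds are
#' inclusive: a hit passes with identity >= `min_identity`, query coverage
#' >= `min_coverage`, e-value <= `max_evalue` and (when set) alignment
#' length >= `min_align_length`. `NA` disables a bound.
#'
#' Three named bundles cover the pipeline's analyses:
#' \describe{
#'   \item{rhizome}{identity 20 / coverage 30 / e-value 0.001 — best-hit
#'     origin attribution and ORFan calling.}
#'   \item{phyletic}{identity 30 / e-value 0.001, no coverage bound —
#'     family presence/absence detection.}
#'   \item{marker}{identity 20 / alignment length 70 / e-value 0.001 —
#'     conserved-marker ortholog retrieval.}
#' }
#'
#' @param min_identity Minimum percent identity in `[0, 100]`.
#' @param min_coverage Minimum percent query coverage in `[0, 100]`, or `NA`.
#' @param max_evalue Maximum e-value (finite, >= 0).
#' @param min_align_length Minimum alignment length in residues, or `NA`.
#' @return An object of class `search_thresholds`.
#' @export
#' @examples
#' search_thresholds("rhizome")
#' search_thresholds(min_identity = 40, min_coverage = 50, max_evalue = 1e-10)
search_thresholds <- function(min_identity = 20, min_coverage = 30,
                              max_evalue = 0.001, min_align_length = NA) {
  if (is.character(min_identity) && length(min_identity) == 1L) {
    bundle <- match.arg(min_identity, c("rhizome", "phyletic", "marker"))
    return(switch(bundle,
      rhizome  = search_thresholds(20, 30, 0.001, NA),
      phyletic = search_thresholds(30, NA, 0.001, NA),
      marker   = search_thresholds(20, NA, 0.001, 70)))
  }
  chk01 <- function(x, nm) {
    if (!is.na(x) && (!is.numeric(x) || x < 0 || x > 100)) {
      rz_stop(sprintf("search_thresholds: %s must be in [0, 100]", nm))
    }
  }
  chk01(min_identity, "min_identity")
  chk01(min_coverage, "min_coverage")
  if (!is.numeric(max_evalue) || !is.finite(max_evalue) || max_evalue < 0) {
    rz_stop("search_thresholds: max_evalue must be finite and >= 0")
  }
  if (!is.na(min_align_length) && min_align_length < 1) {
    rz_stop("search_thresholds: min_align_length must be >= 1")
  }
  structure(list(min_identity = min_identity, min_coverage = min_coverage,
                 max_evalue = max_evalue, min_align_length = min_align_length),
            class = "search_thresholds")
}

#' @export
print.search_thresholds <- function(x, ...) {
  cat(sprintf(
    "search thresholds: identity >= %s, coverage >= %s, e-value <= %s, length >= %s\n",
    x$min_identity, ifelse(is.na(x$min_coverage), "-", x$min_coverage),
    format(x$max_evalue), ifelse(is.na(x$min_align_length), "-", x$min_align_length)))
  invisible(x)
}

## apply a threshold bundle to a hit table; NULL thresholds = keep all
apply_thresholds <- function(hits, thresholds) {
  if (is.null(thresholds) || nrow(hits) == 0L) return(hits)
  stopifnot(inherits(thresholds, "search_thresholds"))
  keep <- rep(TRUE, nrow(hits))
  if (!is.na(thresholds$min_identity)) keep <- keep & hits$identity >= thresholds$min_identity
  if (!is.na(thresholds$min_coverage)) {
    if (is.null(hits$coverage)) rz_stop("apply_thresholds: hits lack a coverage column")
    keep <- keep & hits$coverage >= thresholds$min_coverage
  }
  keep <- keep & hits$evalue <= thresholds$max_evalue
  if (!is.na(thresholds$min_align_length)) {
    keep <- keep & hits$align_length >= thresholds$min_align_length
  }
  hits[keep, , drop = FALSE]
}

## deterministic hit ordering: bitscore desc, e-value asc, identity desc,
## subject id lexicographic (C locale)
order_hits <- function(hits) {
  ord <- order(-hits$bitscore, hits$evalue, -hits$identity, hits$subject_id,
               method = "radix")
  hits[ord, , drop = FALSE]
}

#' Search a query protein against a labeled reference collection
#'
#' Aligns the query against every database record with [local_align()],
#' attaches Karlin-Altschul e-values and bitscores (database size = total
#' residues of `db`), applies `thresholds`, and sorts hits by bitscore
#' (descending) with ties broken by lower e-value, higher identity, then
#' lexicographic subject id — so output is invariant under database input
#' order.
#'
#' @param query One-row protein record data.frame (or character sequence).
#' @param db Protein record data.frame (columns `id`, `sequence`, and
#'   `taxon_id` carried through as `subject_taxon`).
#' @param matrix Substitution matrix, default [blosum62_matrix()].
#' @param gap_open,gap_extend Gap penalties, defaults 11/1.
#' @param thresholds A [search_thresholds()] bundle, or `NULL` to keep every
#'   hit with a positive score.
#' @param params Karlin-Altschul parameters, default [karlin_params()].
#' @param .validated Internal: set by callers that have already validated
#'   `db` and `matrix`, to skip re-validation in tight loops.
#' @return Hit data.frame: dialect columns plus `score`, `coverage`,
#'   `subject_taxon`.
#' @export
search_database <- function(query, db, matrix = blosum62_matrix(),
                            gap_open = 11, gap_extend = 1,
                            thresholds = search_thresholds("rhizome"),
                            params = karlin_params(), .validated = FALSE) {
  if (!.validated) {
    validate_protein_records(db, "search_database: db")
    matrix <- validate_substitution_matrix(matrix)
  }
  q <- as_record(query, "query")
  db_residues <- sum(nchar(db$sequence))
  qlen <- nchar(q$sequence)
  alphabet <- paste(rownames(matrix), collapse = "")

  stats <- sw_search_cpp(q$sequence, db$sequence, matrix, alphabet,
                         as.integer(gap_open), as.integer(gap_extend))
  keep <- stats[, "score"] > 0
  stats <- stats[keep, , drop = FALSE]
  if (nrow(stats) == 0L) return(empty_hits())
  ev <- estimate_evalue(stats[, "score"], qlen, db_residues, params)
  hits <- data.frame(
    query_id = q$id, subject_id = db$id[keep],
    identity = 100 * stats[, "identities"] / stats[, "align_length"],
    align_length = stats[, "align_length"], mismatches = stats[, "mismatches"],
    gap_opens = stats[, "gap_opens"],
    qstart = stats[, "qstart"], qend = stats[, "qend"],
    sstart = stats[, "sstart"], send = stats[, "send"],
    evalue = ev$evalue, bitscore = ev$bitscore,
    score = stats[, "score"],
    coverage = 100 * (stats[, "qend"] - stats[, "qstart"] + 1) / qlen,
    subject_taxon = if ("taxon_id" %in% names(db)) db$taxon_id[keep] else NA_character_,
    stringsAsFactors = FALSE)
  hits <- apply_thresholds(hits, thresholds)
  rownames(hits) <- NULL
  order_hits(hits)
}

empty_hits <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             identity = numeric(0), align_length = numeric(0),
             mismatches = numeric(0), gap_opens = numeric(0),
             qstart = numeric(0), qend = numeric(0),
             sstart = numeric(0), send = numeric(0),
             evalue = numeric(0), bitscore = numeric(0),
             score = numeric(0), coverage = numeric(0),
             subject_taxon = character(0), stringsAsFactors = FALSE)
}

#' Reconstruct query coverage for ingested tabular hits
#'
#' External tabular hit files do not carry coverage; it is recomputed as
#' `100 * (qend - qstart + 1) / query_length` on the query side, the
#' convention that makes ORFan calling a property of the gene rather than of
#' the subject.
#'
#' @param hits Hit data.frame from [read_tabular_hits()].
#' @param query_lengths Named numeric vector mapping query id to length.
#' @return `hits` with a `coverage` column appended.
#' @export
attach_coverage <- function(hits, query_lengths) {
  if (nrow(hits) == 0L) {
    hits$coverage <- numeric(0)
    return(hits)
  }
  idx <- match(hits$query_id, names(query_lengths))
  if (anyNA(idx)) {
    rz_stop(sprintf("attach_coverage: unknown query id(s): %s",
                    paste(unique(hits$query_id[is.na(idx)]), collapse = ", ")))
  }
  if (any(hits$qend < hits$qstart)) {
    rz_stop("attach_coverage: qend < qstart")
  }
  hits$coverage <- 100 * (hits$qend - hits$qstart + 1) / query_lengths[idx]
  hits
}
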