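#' BLOSUM62 substitution matrix over the 20 standard residues plus X
#'
#' The scoring table used by the built-in aligner, taken from
#' `Biostrings::BLOSUM62` and restricted to the 21-letter alphabet the
#' pipeline accepts. The ambiguity residue X is neutral: it scores 0 against
#' everything (including itself), so runs of unknown residues neither reward
#' nor punish an alignment.
#'
#' @return A symmetric 21 x 21 integer matrix with dimnames.
#' @export
blosum62_matrix <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  m <- env$BLOSUM62[AA_ALPHABET, AA_ALPHABET]
  m["X", ] <- 0L
  m[, "X"] <- 0L
  storage.mode(m) <- "integer"
  attr(m, "name") <- "BLOSUM62"
  m
}

## validate a substitution matrix: symmetric, covers the pipeline alphabet
validate_substitution_matrix <- function(matrix) {
  if (!is.matrix(matrix) || is.null(rownames(matrix)) ||
      !identical(rownames(matrix), colnames(matrix))) {
    rz_stop("substitution matrix must be square with matching dimnames")
  }
  miss <- setdiff(AA_ALPHABET, rownames(matrix))
  if (length(miss)) {
    rz_stop(sprintf("substitution matrix missing residue(s): %s",
                    paste(miss, collapse = ", ")))
  }
  if (!isTRUE(all.equal(matrix, t(matrix)))) {
    rz_stop("substitution matrix must be symmetric")
  }
  storage.mode(matrix) <- "integer"
  matrix
}

#' Optimal local alignment of two protein sequences
#'
#' Affine-gap Smith-Waterman: a gap of length k costs
#' `gap_open + k * gap_extend` (the BLAST convention; the defaults 11/1 are
#' the standard protein-search settings). Percent identity is computed over
#' all alignment columns including gap columns, matching the blast-tab
#' convention, so built-in and ingested hits share semantics. Query coverage
#' is the aligned query span over the query length.
#'
#' @param query,subject Either single-row protein record data.frames or
#'   plain character sequences.
#' @param matrix Substitution matrix, default [blosum62_matrix()].
#' @param gap_open,gap_extend Positive gap penalties (defaults 11 and 1).
#' @return A one-row data.frame: `query_id`, `subject_id`, `score`,
#'   `identity`, `align_length`, `mismatches`, `gap_opens`, `coverage`,
#'   `qstart`, `qend`, `sstart`, `send` (1-based inclusive; all-zero spans
#'   denote an empty optimal alignment).
#' @export
local_align <- function(query, subject, matrix = blosum62_matrix(),
                        gap_open = 11, gap_extend = 1) {
  q <- as_record(query, "query")
  s <- as_record(subject, "subject")
  matrix <- validate_substitution_matrix(matrix)
  if (gap_open < 0 || gap_extend <= 0) {
    rz_stop("local_align: gap penalties must be positive")
  }
  res <- sw_align_cpp(q$sequence, s$sequence, matrix,
                      paste(rownames(matrix), collapse = ""),
                      as.integer(gap_open), as.integer(gap_extend))
  qlen <- nchar(q$sequence)
  aln_len <- res$align_length
  identity <- if (aln_len > 0) 100 * res$identities / aln_len else 0
  coverage <- if (aln_len > 0) 100 * (res$qend - res$qstart + 1) / qlen else 0
  data.frame(query_id = q$id, subject_id = s$id,
             score = res$score, identity = identity,
             align_length = aln_len, mismatches = res$mismatches,
             gap_opens = res$gap_opens, coverage = coverage,
             qstart = res$qstart, qend = res$qend,
             sstart = res$sstart, send = res$send,
             stringsAsFactors = FALSE)
}

## coerce a character sequence or 1-row record df to list(id, sequence)
as_record <- function(x, what) {
  if (is.character(x) && length(x) == 1L) {
    seq <- toupper(x)
    if (!nzchar(seq)) rz_stop(sprintf("local_align: empty %s sequence", what))
    return(list(id = what, sequence = seq))
  }
  if (is.data.frame(x) && nrow(x) == 1L && all(c("id", "sequence") %in% names(x))) {
    seq <- toupper(x$sequence)
    if (!nzchar(seq)) rz_stop(sprintf("local_align: empty %s sequence", what))
    return(list(id = x$id, sequence = seq))
  }
  rz_stop(sprintf("local_align: %s must be a sequence string or one-row record", what))
}

#' Karlin-Altschul parameters for e-value estimation
#'
#' Defaults are the published gapped BLOSUM62 values (lambda = 0.267,
#' K = 0.041) for gap penalties 11/1. These are bypassed entirely when hits
#' are ingested from an external search tool, which reports its own
#' e-values.
#'
#' @param lambda,K Positive scale parameters of the extreme-value score
#'   distribution.
#' @return A list with elements `lambda` and `K`.
#' @export
karlin_params <- function(lambda = 0.267, K = 0.041) {
  if (!is.numeric(lambda) || lambda <= 0 || !is.numeric(K) || K <= 0) {
    rz_stop("karlin_params: lambda and K must be positive")
  }
  list(lambda = lambda, K = K)
}

#' Karlin-Altschul e-value and bitscore for a raw alignment score
#'
#' `E = K * m * n * exp(-lambda * S)` with m the query length and n the
#' total residue count of the database searched; the bitscore is
#' `(lambda * S - ln K) / ln 2`. E is strictly decreasing in the score and
#' linear in the database size.
#'
#' @param score Raw alignment score (>= 0).
#' @param query_len Query length in residues (>= 1).
#' @param db_residues Total database residues (>= 1).
#' @param params Karlin-Altschul parameters, default [karlin_params()].
#' @return A list with elements `evalue` and `bitscore`.
#' @export
estimate_evalue <- function(score, query_len, db_residues,
                            params = karlin_params()) {
  if (any(score < 0)) rz_stop("estimate_evalue: score must be >= 0")
  if (query_len < 1 || db_residues < 1) {
    rz_stop("estimate_evalue: lengths must be >= 1")
  }
  if (params$lambda <= 0 || params$K <= 0) {
    rz_stop("estimate_evalue: lambda and K must be positive")
  }
  list(evalue = params$K * query_len * db_residues * exp(-params$lambda * score),
       bitscore = (params$lambda * score - log(params$K)) / log(2))
}
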