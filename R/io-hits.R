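#' Column order of the 12-field tabular hit format
#'
#' The standard blast-tab dialect (`-outfmt 6` and equivalents): query id,
#' subject id, percent identity (0-100), alignment length, mismatches, gap
#' opens, query start, query end, subject start, subject end, e-value,
#' bitscore. Coordinates are 1-based inclusive.
#'
#' @return Character vector of the 12 column names, in file order.
#' @export
hit_table_dialect <- function() {
  c("query_id", "subject_id", "identity", "align_length", "mismatches",
    "gap_opens", "qstart", "qend", "sstart", "send", "evalue", "bitscore")
}

#' Read a 12-column tabular hit file
#'
#' Adapter so precomputed searches from external tools can replace the
#' built-in aligner. Coverage is left unset; reconstruct it against the
#' query lengths with [attach_coverage()].
#'
#' @param path Path to the tab-separated hit file. An empty file yields a
#'   zero-row table.
#' @param dialect Column order, default [hit_table_dialect()].
#' @return data.frame of hits with the dialect's columns, numeric fields
#'   parsed.
#' @export
read_tabular_hits <- function(path, dialect = hit_table_dialect()) {
  if (!file.exists(path)) rz_stop(sprintf("read_tabular_hits: no such file: %s", path))
  if (length(dialect) != 12L) {
    rz_stop("read_tabular_hits: dialect must name exactly 12 columns")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  numeric_cols <- c("identity", "align_length", "mismatches", "gap_opens",
                    "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  if (length(lines) == 0L) {
    out <- as.data.frame(setNames(rep(list(character(0)), 12L), dialect),
                         stringsAsFactors = FALSE)
    for (cl in intersect(numeric_cols, dialect)) out[[cl]] <- numeric(0)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    bad <- which(nf != 12L)[1]
    rz_stop(sprintf("read_tabular_hits: line %d of %s has %d fields, expected 12",
                    bad, path, nf[bad]))
  }
  mat <- do.call(rbind, fields)
  out <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(out) <- dialect
  for (cl in intersect(numeric_cols, dialect)) {
    v <- suppressWarnings(as.numeric(out[[cl]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      rz_stop(sprintf("read_tabular_hits: line %d of %s: non-numeric '%s' field",
                      bad, path, cl))
    }
    out[[cl]] <- v
  }
  if (any(out$evalue < 0)) {
    rz_stop(sprintf("read_tabular_hits: line %d of %s: negative e-value",
                    which(out$evalue < 0)[1], path))
  }
  if (any(out$identity < 0 | out$identity > 100)) {
    rz_stop(sprintf("read_tabular_hits: line %d of %s: identity outside [0,100]",
                    which(out$identity < 0 | out$identity > 100)[1], path))
  }
  if (any(out$align_length < 1)) {
    rz_stop(sprintf("read_tabular_hits: line %d of %s: alignment length < 1",
                    which(out$align_length < 1)[1], path))
  }
  out
}

#' Write hits in the 12-column tabular format
#'
#' Emits the same dialect [read_tabular_hits()] consumes, so built-in and
#' external hits are interchangeable downstream. Extra columns (score,
#' coverage, subject taxon) are dropped.
#'
#' @param hits data.frame carrying at least the 12 dialect columns.
#' @param path Output path.
#' @param dialect Column order, default [hit_table_dialect()].
#' @return `path`, invisibly.
#' @export
write_tabular_hits <- function(hits, path, dialect = hit_table_dialect()) {
  miss <- setdiff(dialect, names(hits))
  if (length(miss)) {
    rz_stop(sprintf("write_tabular_hits: missing column(s): %s",
                    paste(miss, collapse = ", ")))
  }
  out <- hits[, dialect, drop = FALSE]
  # as.character keeps full double precision so round trips are exact
  lines <- do.call(paste, c(lapply(out, function(x) {
    if (is.numeric(x)) vapply(x, format, "", digits = 15) else as.character(x)
  }), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
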