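#' Read an amino-acid FASTA file into a protein record table
#'
#' Parses protein FASTA via [Biostrings::readAAStringSet()] and returns one
#' row per record with columns `id`, `sequence`, `taxon_id`. The record id is
#' the first whitespace-delimited token of the header. The source taxon is
#' resolved, in order of precedence, from a `taxon=<id>` token in the header,
#' from `taxon_map`, or from the scalar `taxon_id` applied to every record;
#' unresolved taxa are `NA`.
#'
#' Sequences are uppercased on ingest. Stop codons (`*`) are stripped with a
#' warning rather than rejected, since annotation pipelines routinely leave a
#' trailing stop on translated ORFs.
#'
#' @param path Path to a FASTA file.
#' @param taxon_id Optional taxon id applied to all records.
#' @param taxon_map Optional named character vector mapping record id to
#'   taxon id (a sidecar mapping).
#' @return A data.frame with columns `id`, `sequence`, `taxon_id`, in file
#'   order.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".faa")
#' writeLines(c(">g1 taxon=t1", "MKVLA"), tf)
#' read_fasta(tf)
read_fasta <- function(path, taxon_id = NA_character_, taxon_map = NULL) {
  if (!file.exists(path)) rz_stop(sprintf("read_fasta: no such file: %s", path))
  if (file.size(path) == 0L) rz_stop(sprintf("read_fasta: empty file: %s", path))
  # pre-scan: the FASTA parser silently drops invalid one-letter codes, but
  # the contract here is an error naming the offending line
  bad_re <- sprintf("[^%s]", paste(AA_ALPHABET, collapse = ""))
  raw <- readLines(path, warn = FALSE)
  seq_lines <- !startsWith(raw, ">") & nzchar(raw)
  bad_line <- which(seq_lines & grepl(bad_re, toupper(gsub("\\*", "", raw))))
  if (length(bad_line)) {
    frag <- toupper(gsub("\\*", "", raw[bad_line[1]]))
    ch <- regmatches(frag, regexpr(bad_re, frag))
    rz_stop(sprintf(
      "read_fasta: residue '%s' outside alphabet [%s] at line %d of %s",
      ch, paste(AA_ALPHABET, collapse = ""), bad_line[1], path))
  }
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) rz_stop(sprintf("read_fasta: cannot parse %s: %s",
                                        path, conditionMessage(e)))
  )
  if (length(set) == 0L) rz_stop(sprintf("read_fasta: no records in %s", path))

  headers <- names(set)
  ids <- unname(sub("\\s.*$", "", headers))
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    rz_stop(sprintf("read_fasta: duplicate record id(s) in %s: %s",
                    path, paste(dup, collapse = ", ")))
  }

  seqs <- unname(toupper(as.character(set)))
  if (any(grepl("*", seqs, fixed = TRUE))) {
    n_stop <- sum(lengths(regmatches(seqs, gregexpr("\\*", seqs))))
    warning(sprintf("read_fasta: stripped %d stop codon(s) ('*') from %s",
                    n_stop, path), call. = FALSE)
    seqs <- gsub("*", "", seqs, fixed = TRUE)
  }
  if (any(!nzchar(seqs))) {
    rz_stop(sprintf("read_fasta: record(s) with empty sequence in %s: %s",
                    path, paste(ids[!nzchar(seqs)], collapse = ", ")))
  }

  tax <- rep(as.character(taxon_id), length(ids))
  if (!is.null(taxon_map)) {
    hitidx <- match(ids, names(taxon_map))
    tax[!is.na(hitidx)] <- unname(taxon_map[hitidx[!is.na(hitidx)]])
  }
  tok <- regmatches(headers, regexpr("taxon=\\S+", headers))
  has_tok <- grepl("taxon=\\S+", headers)
  tax[has_tok] <- sub("^taxon=", "", tok)

  data.frame(id = ids, sequence = seqs, taxon_id = tax, stringsAsFactors = FALSE)
}

#' Write protein records to FASTA
#'
#' Inverse of [read_fasta()]: the header is the record id, followed by a
#' `taxon=<id>` token when the record's `taxon_id` is not `NA`, so that a
#' write/read round trip is lossless.
#'
#' @param records data.frame with columns `id`, `sequence` and optionally
#'   `taxon_id`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  validate_protein_records(records, "write_fasta")
  headers <- records$id
  if ("taxon_id" %in% names(records)) {
    has <- !is.na(records$taxon_id)
    headers[has] <- paste0(records$id[has], " taxon=", records$taxon_id[has])
  }
  set <- Biostrings::AAStringSet(records$sequence)
  names(set) <- headers
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}
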