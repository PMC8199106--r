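#' Read a taxonomy table
#'
#' The pipeline carries its own explicit taxonomy rather than querying a live
#' database, so runs are reproducible. The file is tab-separated with a
#' header row naming at least `taxon_id`, `genus`, `group` and `lineage`
#' (semicolon-joined rank labels, root first).
#'
#' @param path Path to the TSV file.
#' @param groups Allowed origin-group label set; rows with a `group` outside
#'   it are rejected. Defaults to [default_origin_groups()].
#' @return A data.frame keyed by unique `taxon_id`, with columns `taxon_id`,
#'   `genus`, `group`, `lineage`.
#' @export
read_taxonomy_table <- function(path, groups = default_origin_groups()) {
  if (!file.exists(path)) rz_stop(sprintf("read_taxonomy_table: no such file: %s", path))
  tab <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = "character")
  validate_taxonomy(tab, groups, what = sprintf("read_taxonomy_table(%s)", path))
}

#' Validate an in-memory taxonomy table
#'
#' @param taxonomy data.frame with columns `taxon_id`, `genus`, `group`,
#'   `lineage`.
#' @param groups Allowed origin-group labels.
#' @param what Label used in error messages.
#' @return The validated data.frame (invisibly usable), row names cleared.
#' @export
validate_taxonomy <- function(taxonomy, groups = default_origin_groups(),
                              what = "taxonomy") {
  need <- c("taxon_id", "genus", "group", "lineage")
  miss <- setdiff(need, names(taxonomy))
  if (length(miss)) {
    rz_stop(sprintf("%s: missing column(s): %s", what, paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(taxonomy$taxon_id)) {
    dup <- unique(taxonomy$taxon_id[duplicated(taxonomy$taxon_id)])
    rz_stop(sprintf("%s: duplicate taxon_id(s): %s", what, paste(dup, collapse = ", ")))
  }
  if (ORFAN_LABEL %in% taxonomy$group) {
    rz_stop(sprintf("%s: '%s' is a reserved label, not a taxonomic group",
                    what, ORFAN_LABEL))
  }
  unknown <- setdiff(unique(taxonomy$group), groups)
  if (length(unknown)) {
    rz_stop(sprintf("%s: unknown group label(s) %s; allowed: %s",
                    what, paste(unknown, collapse = ", "),
                    paste(groups, collapse = ", ")))
  }
  if (any(!nzchar(taxonomy$lineage))) {
    rz_stop(sprintf("%s: empty lineage for taxon_id(s): %s", what,
                    paste(taxonomy$taxon_id[!nzchar(taxonomy$lineage)], collapse = ", ")))
  }
  rownames(taxonomy) <- NULL
  taxonomy[, need]
}

#' Write a taxonomy table to TSV
#'
#' @param taxonomy data.frame as returned by [read_taxonomy_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy_table <- function(taxonomy, path) {
  write.table(taxonomy, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## taxon_id -> group lookup with a clear error for unresolvable taxa
taxon_group <- function(taxon_ids, taxonomy, what = "taxon_group") {
  idx <- match(taxon_ids, taxonomy$taxon_id)
  if (anyNA(idx)) {
    missing <- unique(taxon_ids[is.na(idx)])
    rz_stop(sprintf("%s: taxon id(s) not in taxonomy: %s",
                    what, paste(missing, collapse = ", ")))
  }
  taxonomy$group[idx]
}
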