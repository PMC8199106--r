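## Shared internal helpers: residue alphabet, rounding, validation.

# 20 standard residues; X is the ambiguity code accepted on ingest.
AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AA_ALPHABET <- c(AA_STANDARD, "X")

#' Round half away from zero
#'
#' Fixed-precision rounding where a half always rounds up (for positive
#' values), matching how percentages are conventionally printed
#' (e.g. 506/935 = 54.1176... -> 54.12). Base [round()] uses round-half-even
#' and would disagree on exact halves.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2).
#' @return Numeric vector rounded to `digits` places.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## stop() with a consistent prefix; all user-facing errors funnel through here
rz_stop <- function(..., call. = FALSE) {
  stop(..., call. = call.)
}

## Assert a scalar string
is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x) && nzchar(x)

## Validate a protein record data.frame (id, sequence, taxon_id)
validate_protein_records <- function(records, what = "protein records") {
  stopifnot(is.data.frame(records))
  need <- c("id", "sequence")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    rz_stop(sprintf("%s: missing column(s) %s", what, paste(miss, collapse = ", ")))
  }
  if (nrow(records) == 0L) rz_stop(sprintf("%s: empty record set", what))
  if (anyDuplicated(records$id)) {
    dup <- unique(records$id[duplicated(records$id)])
    rz_stop(sprintf("%s: duplicate id(s): %s", what, paste(dup, collapse = ", ")))
  }
  if (any(!nzchar(records$sequence))) {
    rz_stop(sprintf("%s: zero-length sequence(s)", what))
  }
  bad <- grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), records$sequence)
  if (any(bad)) {
    rz_stop(sprintf("%s: sequence(s) with residues outside [%s]: %s",
                    what, paste(AA_ALPHABET, collapse = ""),
                    paste(records$id[bad], collapse = ", ")))
  }
  invisible(records)
}

## Build a protein record data.frame from parallel vectors
protein_records <- function(id, sequence, taxon_id = NA_character_) {
  out <- data.frame(id = as.character(id),
                    sequence = toupper(as.character(sequence)),
                    taxon_id = as.character(taxon_id),
                    stringsAsFactors = FALSE)
  validate_protein_records(out)
  out
}
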