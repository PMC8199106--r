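## Small in-code fixtures shared across test files.

## three-group taxonomy covering taxa tax_Bacteria / tax_CPR / tax_Archaea
## plus the query's own taxon
fixture_taxonomy <- function() {
  data.frame(
    taxon_id = c("tax_Bacteria", "tax_CPR", "tax_Archaea", "self", "tax_Rick"),
    genus = c("Genus_Bacteria", "Genus_CPR", "Genus_Archaea", "Genus_self",
              "Rickettsia"),
    group = c("Bacteria", "CPR", "Archaea", "Bacteria", "Bacteria"),
    lineage = c("cellular;Bacteria", "cellular;CPR", "cellular;Archaea",
                "cellular;Bacteria;self", "cellular;Bacteria;Rickettsia"),
    stringsAsFactors = FALSE)
}

## a hand-built hit table row
make_hit <- function(query_id = "g1", subject_id = "s1", identity = 50,
                     align_length = 100, mismatches = 50, gap_opens = 0,
                     qstart = 1, qend = 100, sstart = 1, send = 100,
                     evalue = 1e-30, bitscore = 100, score = 250,
                     coverage = 100, subject_taxon = "tax_Bacteria") {
  data.frame(query_id = query_id, subject_id = subject_id, identity = identity,
             align_length = align_length, mismatches = mismatches,
             gap_opens = gap_opens, qstart = qstart, qend = qend,
             sstart = sstart, send = send, evalue = evalue,
             bitscore = bitscore, score = score, coverage = coverage,
             subject_taxon = subject_taxon, stringsAsFactors = FALSE)
}

## attribution rows without running any alignment
make_attribution <- function(gene_id, origin, identity = 90) {
  orfan <- origin == orfan_label()
  data.frame(gene_id = gene_id, origin = origin,
             subject_id = ifelse(orfan, NA, paste0("s_", gene_id)),
             subject_taxon = ifelse(orfan, NA, paste0("tax_", origin)),
             identity = ifelse(orfan, NA, identity),
             coverage = ifelse(orfan, NA, 100),
             evalue = ifelse(orfan, NA, 1e-40),
             bitscore = ifelse(orfan, NA, 120),
             stringsAsFactors = FALSE)
}
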