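#' Reference gene-family set
#'
#' A named collection of gene families (for instance informational COGs,
#' translation-category COGs, or fold superfamily domains), each represented
#' by one or more reference protein sequences. Presence of a family in a
#' genome is detected by homology of any genome gene to any representative.
#'
#' @param name Set name (e.g. `"informational-COGs"`).
#' @param representatives Protein record data.frame with an extra
#'   `family_id` column; every family needs at least one representative and
#'   representative ids must be unique.
#' @param expected_size Optional expected family count (metadata only; a
#'   mismatch is an error to catch truncated inputs).
#' @return An object of class `reference_family_set`.
#' @export
reference_family_set <- function(name, representatives, expected_size = NULL) {
  stopifnot(is_string(name))
  validate_protein_records(representatives, "reference_family_set")
  if (is.null(representatives$family_id) || any(!nzchar(representatives$family_id))) {
    rz_stop("reference_family_set: representatives need a family_id column")
  }
  fams <- unique(representatives$family_id)
  if (!is.null(expected_size) && length(fams) != expected_size) {
    rz_stop(sprintf("reference_family_set '%s': %d families found, expected %d",
                    name, length(fams), expected_size))
  }
  structure(list(name = name, families = fams,
                 representatives = representatives),
            class = "reference_family_set")
}

#' @export
print.reference_family_set <- function(x, ...) {
  cat(sprintf("reference family set '%s': %d families, %d representatives\n",
              x$name, length(x$families), nrow(x$representatives)))
  invisible(x)
}

#' Read a family set from a table + FASTA pair
#'
#' The family table is a TSV with columns `family_id` and `rep_id`; the
#' representative sequences are read from `fasta_path` and joined on record
#' id.
#'
#' @param name Set name.
#' @param table_path TSV mapping representative id to family.
#' @param fasta_path FASTA of representative sequences.
#' @param expected_size Optional expected family count.
#' @return A [reference_family_set()].
#' @export
read_family_set <- function(name, table_path, fasta_path, expected_size = NULL) {
  tab <- read.delim(table_path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, colClasses = "character")
  miss <- setdiff(c("family_id", "rep_id"), names(tab))
  if (length(miss)) {
    rz_stop(sprintf("read_family_set: table missing column(s): %s",
                    paste(miss, collapse = ", ")))
  }
  recs <- read_fasta(fasta_path)
  idx <- match(tab$rep_id, recs$id)
  if (anyNA(idx)) {
    rz_stop(sprintf("read_family_set: representative(s) missing from FASTA: %s",
                    paste(tab$rep_id[is.na(idx)], collapse = ", ")))
  }
  reps <- recs[idx, , drop = FALSE]
  reps$family_id <- tab$family_id
  rownames(reps) <- NULL
  reference_family_set(name, reps, expected_size)
}

#' Is a gene family present in a genome?
#'
#' A family is present (1) iff at least one genome gene aligns to at least
#' one family representative passing the detection thresholds (default:
#' identity >= 30 percent and e-value <= 0.001, no coverage bound). The scan
#' short-circuits on the first passing pair.
#'
#' @param genome Protein record data.frame.
#' @param family_reps Protein records of one family's representatives.
#' @param thresholds A [search_thresholds()] bundle, default the phyletic
#'   bundle.
#' @param db_residues Database size used for e-value scaling; defaults to
#'   the representatives' total residue count, but when called from
#'   [build_phyletic_matrix()] the whole family set's size is used so that
#'   e-values are comparable across families.
#' @param matrix,gap_open,gap_extend,params Alignment settings.
#' @return Integer 0 or 1.
#' @export
detect_family_presence <- function(genome, family_reps,
                                   thresholds = search_thresholds("phyletic"),
                                   db_residues = sum(nchar(family_reps$sequence)),
                                   matrix = blosum62_matrix(),
                                   gap_open = 11, gap_extend = 1,
                                   params = karlin_params()) {
  validate_protein_records(genome, "detect_family_presence: genome")
  validate_protein_records(family_reps, "detect_family_presence: family_reps")
  matrix <- validate_substitution_matrix(matrix)
  alphabet <- paste(rownames(matrix), collapse = "")
  for (g in seq_len(nrow(genome))) {
    qlen <- nchar(genome$sequence[g])
    for (r in seq_len(nrow(family_reps))) {
      res <- sw_align_cpp(genome$sequence[g], family_reps$sequence[r],
                          matrix, alphabet,
                          as.integer(gap_open), as.integer(gap_extend))
      if (res$score <= 0 || res$align_length == 0) next
      ev <- estimate_evalue(res$score, qlen, db_residues, params)
      pass <- (is.na(thresholds$min_identity) ||
                 100 * res$identities / res$align_length >= thresholds$min_identity) &&
        (is.na(thresholds$min_coverage) ||
           100 * (res$qend - res$qstart + 1) / qlen >= thresholds$min_coverage) &&
        ev$evalue <= thresholds$max_evalue &&
        (is.na(thresholds$min_align_length) ||
           res$align_length >= thresholds$min_align_length)
      if (pass) return(1L)
    }
  }
  0L
}

#' Presence/absence matrix of genomes against a family set
#'
#' The phyletic-pattern matrix: entry (g, f) is 1 iff genome g contains at
#' least one detectable ortholog of family f, else 0. Families with no hit
#' in any genome keep their all-zero column. Row order follows the input
#' genome order; the result is deterministic.
#'
#' @param genomes Named list of protein record data.frames (names = genome
#'   ids).
#' @param family_set A [reference_family_set()].
#' @param thresholds Detection thresholds, default the phyletic bundle.
#' @param matrix,gap_open,gap_extend,params Alignment settings.
#' @return Integer matrix, rows = genomes, columns = family ids.
#' @export
build_phyletic_matrix <- function(genomes, family_set,
                                  thresholds = search_thresholds("phyletic"),
                                  matrix = blosum62_matrix(),
                                  gap_open = 11, gap_extend = 1,
                                  params = karlin_params()) {
  stopifnot(inherits(family_set, "reference_family_set"))
  if (length(genomes) < 2L) rz_stop("build_phyletic_matrix: need >= 2 genomes")
  if (is.null(names(genomes)) || any(!nzchar(names(genomes)))) {
    rz_stop("build_phyletic_matrix: genomes must be a named list")
  }
  db_residues <- sum(nchar(family_set$representatives$sequence))
  fams <- family_set$families
  out <- matrix(0L, nrow = length(genomes), ncol = length(fams),
                dimnames = list(names(genomes), fams))
  reps_by_fam <- split(family_set$representatives,
                       factor(family_set$representatives$family_id, levels = fams))
  for (g in seq_along(genomes)) {
    for (f in seq_along(fams)) {
      out[g, f] <- detect_family_presence(
        genomes[[g]], reps_by_fam[[f]], thresholds = thresholds,
        db_residues = db_residues, matrix = matrix,
        gap_open = gap_open, gap_extend = gap_extend, params = params)
    }
  }
  out
}

#' Euclidean distance matrix of phyletic patterns
#'
#' For 0/1 rows the Euclidean distance reduces to the square root of the
#' Hamming distance (the number of families present in exactly one of the
#' two genomes).
#'
#' @param matrix Binary matrix (rows = genomes).
#' @return Symmetric numeric distance matrix with zero diagonal.
#' @export
euclidean_distance_matrix <- function(matrix) {
  if (nrow(matrix) < 2L) rz_stop("euclidean_distance_matrix: need >= 2 rows")
  if (!all(matrix %in% c(0, 1))) {
    rz_stop("euclidean_distance_matrix: non-binary entry")
  }
  as.matrix(dist(matrix, method = "euclidean"))
}

#' Agglomerative hierarchical clustering of genomes
#'
#' Standard agglomerative clustering over a precomputed distance matrix via
#' [stats::hclust()]. Average linkage (UPGMA) is the default; merge heights
#' are non-decreasing root-ward for the supported linkages.
#'
#' @param distances Symmetric distance matrix (or `dist`).
#' @param linkage One of `"average"`, `"complete"`, `"single"`,
#'   `"ward.D2"`, `"mcquitty"`.
#' @return An `hclust` object.
#' @export
agglomerative_cluster <- function(distances, linkage = "average") {
  allowed <- c("average", "complete", "single", "ward.D2", "mcquitty")
  if (!is_string(linkage) || !(linkage %in% allowed)) {
    rz_stop(sprintf("agglomerative_cluster: unknown linkage '%s'; allowed: %s",
                    paste(linkage, collapse = ","), paste(allowed, collapse = ", ")))
  }
  d <- if (inherits(distances, "dist")) distances else as.dist(distances)
  hclust(d, method = linkage)
}

#' Cut a dendrogram and score the partition against known groups
#'
#' Cuts into k clusters and reports the adjusted Rand index (ARI) against a
#' reference labeling: 1 for perfect recovery, about 0 for a random
#' partition, negative for worse-than-chance agreement. ARI compares
#' partition topology only, which is the right statistic when the claim
#' under test is "these genomes form k separate clades".
#'
#' @param dendrogram An `hclust` object.
#' @param k Number of clusters, `1 <= k <=` leaf count.
#' @param true_groups Reference labels, named by leaf or in leaf order.
#' @return List with `partition` (named integer vector) and `ari`.
#' @export
cut_and_score <- function(dendrogram, k, true_groups) {
  stopifnot(inherits(dendrogram, "hclust"))
  n <- length(dendrogram$labels)
  if (k < 1 || k > n) {
    rz_stop(sprintf("cut_and_score: k = %s out of range [1, %d]", k, n))
  }
  part <- cutree(dendrogram, k = k)
  if (!is.null(names(true_groups))) {
    miss <- setdiff(names(part), names(true_groups))
    if (length(miss)) {
      rz_stop(sprintf("cut_and_score: leaves missing from true_groups: %s",
                      paste(miss, collapse = ", ")))
    }
    true_groups <- true_groups[names(part)]
  } else if (length(true_groups) != n) {
    rz_stop("cut_and_score: true_groups must cover every leaf")
  }
  ari <- mclust::adjustedRandIndex(part, true_groups)
  if (is.nan(ari)) {
    # degenerate cases (all-singleton or single-cluster partitions) have a
    # zero denominator; agreement is then exact iff the partitions coincide
    same <- identical(as.integer(factor(part, levels = unique(part))),
                      as.integer(factor(true_groups,
                                        levels = unique(true_groups))))
    ari <- if (same) 1 else 0
  }
  list(partition = part, ari = ari)
}

#' Filter hits for conserved-marker ortholog retrieval
#'
#' Retains exactly the hits suitable for downstream marker alignment and
#' tree building: alignment length >= 70 residues, identity >= 20 percent
#' and e-value <= 0.001 by default (bounds inclusive). Used to pull
#' orthologs of deeply conserved genes (RNA polymerase II, DNA polymerase A,
#' ribonucleotide reductase, topoisomerase IIA, elongation factor 1,
#' thymidylate synthase, FEN1, PCNA) out of a hit table; the multiple
#' alignment and tree inference themselves are left to external tools.
#'
#' @param hits Hit data.frame carrying `align_length`, `identity`, `evalue`.
#' @param thresholds A [search_thresholds()] bundle, default the marker
#'   bundle (20 / length 70 / 0.001).
#' @return The retained hits, input order preserved.
#' @export
select_marker_hits <- function(hits, thresholds = search_thresholds("marker")) {
  if (is.null(hits$align_length)) {
    rz_stop("select_marker_hits: hits lack an align_length column")
  }
  apply_thresholds(hits, thresholds)
}

#' Write a phyletic matrix or distance matrix as TSV
#'
#' @param matrix Matrix with genome row names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(matrix, path) {
  df <- data.frame(genome_id = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
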