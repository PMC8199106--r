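#' Self-taxon exclusion rule
#'
#' Before a gene's origin is called, hits to the query organism itself must
#' be removed, otherwise every gene trivially matches its own genome. The
#' rule removes hits whose subject shares, depending on `exclusion_rank`,
#' the query's taxon id, genus, or whole origin group; the query's own taxon
#' ids are excluded under every rank.
#'
#' @param self_taxon_ids Character vector of the query organism's taxon
#'   id(s); always excluded.
#' @param self_genus The query organism's genus (required for rank
#'   `"genus"`).
#' @param exclusion_rank One of `"genus"` (default), `"taxon_id"`,
#'   `"group"`.
#' @return An object of class `self_taxon_rule`.
#' @export
self_taxon_rule <- function(self_taxon_ids = character(0), self_genus = NULL,
                            exclusion_rank = c("genus", "taxon_id", "group")) {
  exclusion_rank <- match.arg(exclusion_rank)
  if (length(self_taxon_ids) == 0L && is.null(self_genus)) {
    rz_stop("self_taxon_rule: need self_taxon_ids and/or self_genus")
  }
  if (exclusion_rank == "genus" && is.null(self_genus) &&
      length(self_taxon_ids) == 0L) {
    rz_stop("self_taxon_rule: genus rank requires self_genus or self_taxon_ids")
  }
  structure(list(self_taxon_ids = as.character(self_taxon_ids),
                 self_genus = self_genus, exclusion_rank = exclusion_rank),
            class = "self_taxon_rule")
}

#' Remove hits from the query's own genus or taxon
#'
#' Drops every hit whose subject matches the exclusion rule; input order is
#' preserved for the survivors. Under rank `"genus"` the subject's genus is
#' compared with the rule's genus (falling back to the genus of the rule's
#' taxon ids when `self_genus` is unset); under `"taxon_id"` only the listed
#' taxon ids are removed; under `"group"` the whole origin group of the
#' query is removed.
#'
#' @param hits Hit data.frame carrying a `subject_taxon` column.
#' @param rule A [self_taxon_rule()].
#' @param taxonomy Taxonomy table resolving every subject taxon.
#' @return The filtered hit data.frame.
#' @export
exclude_self_hits <- function(hits, rule, taxonomy) {
  stopifnot(inherits(rule, "self_taxon_rule"))
  if (nrow(hits) == 0L) return(hits)
  if (is.null(hits$subject_taxon) || anyNA(hits$subject_taxon)) {
    rz_stop("exclude_self_hits: hits lack resolvable subject_taxon")
  }
  idx <- match(hits$subject_taxon, taxonomy$taxon_id)
  if (anyNA(idx)) {
    rz_stop(sprintf("exclude_self_hits: subject taxon(s) not in taxonomy: %s",
                    paste(unique(hits$subject_taxon[is.na(idx)]), collapse = ", ")))
  }
  drop <- hits$subject_taxon %in% rule$self_taxon_ids
  if (rule$exclusion_rank == "genus") {
    genus <- rule$self_genus
    if (is.null(genus) && length(rule$self_taxon_ids)) {
      genus <- taxonomy$genus[match(rule$self_taxon_ids, taxonomy$taxon_id)]
      genus <- genus[!is.na(genus)]
    }
    if (length(genus)) drop <- drop | taxonomy$genus[idx] %in% genus
  } else if (rule$exclusion_rank == "group") {
    self_groups <- unique(taxonomy$group[match(rule$self_taxon_ids, taxonomy$taxon_id)])
    self_groups <- self_groups[!is.na(self_groups)]
    if (length(self_groups)) drop <- drop | taxonomy$group[idx] %in% self_groups
  }
  hits[!drop, , drop = FALSE]
}

#' Call one gene's origin from its self-excluded hit list
#'
#' Applies the threshold bundle; if no hit survives the gene is an ORFan
#' (devoid of detectable homologs in the supplied database). Otherwise the
#' origin is the taxonomic group of the single top surviving hit under the
#' deterministic ordering (bitscore desc, e-value asc, identity desc,
#' subject id lexicographic).
#'
#' @param gene_id Gene identifier.
#' @param hits Self-excluded hit data.frame for this gene.
#' @param thresholds A [search_thresholds()] bundle.
#' @param taxonomy Taxonomy table resolving subject taxa to groups.
#' @return One-row data.frame: `gene_id`, `origin`, `subject_id`,
#'   `subject_taxon`, `identity`, `coverage`, `evalue`, `bitscore` (hit
#'   fields `NA` for ORFans).
#' @export
attribute_gene <- function(gene_id, hits,
                           thresholds = search_thresholds("rhizome"),
                           taxonomy) {
  surv <- apply_thresholds(hits, thresholds)
  if (nrow(surv) == 0L) {
    return(data.frame(gene_id = gene_id, origin = ORFAN_LABEL,
                      subject_id = NA_character_, subject_taxon = NA_character_,
                      identity = NA_real_, coverage = NA_real_,
                      evalue = NA_real_, bitscore = NA_real_,
                      stringsAsFactors = FALSE))
  }
  top <- order_hits(surv)[1, , drop = FALSE]
  data.frame(gene_id = gene_id,
             origin = taxon_group(top$subject_taxon, taxonomy, "attribute_gene"),
             subject_id = top$subject_id, subject_taxon = top$subject_taxon,
             identity = top$identity, coverage = top$coverage,
             evalue = top$evalue, bitscore = top$bitscore,
             stringsAsFactors = FALSE)
}

#' Attribute every gene of a genome
#'
#' The whole-genome loop: for each gene, search the reference collection,
#' exclude self hits, and call the origin or ORFan. Exactly one attribution
#' per gene, in input order.
#'
#' @param genome Protein record data.frame (the query proteome).
#' @param db Labeled reference protein records (`taxon_id` set).
#' @param taxonomy Taxonomy table covering every db taxon.
#' @param rule A [self_taxon_rule()] for the query organism.
#' @param thresholds A [search_thresholds()] bundle (default the
#'   identity 20 / coverage 30 / e-value 0.001 rhizome bundle).
#' @param matrix,gap_open,gap_extend,params Forwarded to
#'   [search_database()].
#' @param keep_hits If `TRUE`, attach the per-gene post-exclusion,
#'   pre-threshold hit tables as attribute `"hits"` (a named list), useful
#'   for re-attributing under different thresholds without re-aligning.
#' @return data.frame of attributions, one row per gene.
#' @export
attribute_genome <- function(genome, db, taxonomy, rule,
                             thresholds = search_thresholds("rhizome"),
                             matrix = blosum62_matrix(),
                             gap_open = 11, gap_extend = 1,
                             params = karlin_params(),
                             keep_hits = FALSE) {
  validate_protein_records(genome, "attribute_genome: genome")
  validate_protein_records(db, "attribute_genome: db")
  matrix <- validate_substitution_matrix(matrix)
  hit_lists <- if (keep_hits) vector("list", nrow(genome)) else NULL
  rows <- vector("list", nrow(genome))
  for (i in seq_len(nrow(genome))) {
    hits <- search_database(genome[i, , drop = FALSE], db, matrix = matrix,
                            gap_open = gap_open, gap_extend = gap_extend,
                            thresholds = NULL, params = params,
                            .validated = TRUE)
    hits <- exclude_self_hits(hits, rule, taxonomy)
    if (keep_hits) hit_lists[[i]] <- hits
    rows[[i]] <- attribute_gene(genome$id[i], hits, thresholds, taxonomy)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (keep_hits) {
    names(hit_lists) <- genome$id
    attr(out, "hits") <- hit_lists
  }
  out
}

#' Per-genome mosaicism profile: gene counts and percentages by origin
#'
#' The quantitative core of a rhizome: how many genes trace to each origin
#' group (or are ORFans), as counts and as percentages of the genome's gene
#' total. Percentages are rounded half-up to two decimals, matching the
#' conventional printed precision (e.g. 506 of 935 genes -> 54.12).
#'
#' @param genome_id Genome identifier.
#' @param attributions Attribution data.frame from [attribute_genome()], or
#'   `NULL` when `counts` is given directly.
#' @param counts Optional named integer vector of per-origin gene counts,
#'   bypassing `attributions` (useful for published count tables).
#' @return An object of class `mosaicism_profile`: list with `genome_id`,
#'   `counts` (named, insertion order), `total_genes`, `percentages`.
#' @export
#' @examples
#' p <- mosaicism_profile("cpr_genome",
#'                        counts = c(Bacteria = 506, CPR = 282,
#'                                   ORFan = 142, Archaea = 5))
#' p$percentages
mosaicism_profile <- function(genome_id, attributions = NULL, counts = NULL) {
  if (is.null(counts)) {
    if (is.null(attributions) || nrow(attributions) == 0L) {
      rz_stop("mosaicism_profile: empty attribution list")
    }
    tab <- table(factor(attributions$origin, levels = unique(attributions$origin)))
    counts <- setNames(as.integer(tab), names(tab))
  } else {
    if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
      rz_stop("mosaicism_profile: counts must be named by origin label")
    }
    if (any(counts < 0) || sum(counts) == 0) {
      rz_stop("mosaicism_profile: counts must be non-negative with positive total")
    }
    counts <- setNames(as.integer(counts), names(counts))
  }
  total <- sum(counts)
  structure(list(genome_id = genome_id, counts = counts, total_genes = total,
                 percentages = round_half_up(100 * counts / total, 2)),
            class = "mosaicism_profile")
}

#' @export
print.mosaicism_profile <- function(x, ...) {
  cat(sprintf("Mosaicism profile of %s (%d genes)\n", x$genome_id, x$total_genes))
  for (l in names(x$counts)) {
    cat(sprintf("  %-14s %6d  (%6.2f%%)\n", l, x$counts[l], x$percentages[l]))
  }
  invisible(x)
}

#' Combined share of a set of origin labels
#'
#' Sums the gene counts of the listed labels and expresses them as a
#' percentage of the genome total, rounded half-up to two decimals. Summing
#' counts before rounding means the combined share can differ from the sum
#' of the individually rounded shares by at most one unit in the last
#' decimal.
#'
#' @param profile A [mosaicism_profile()].
#' @param labels Character vector of origin labels (subset of the profile's
#'   labels; empty set gives 0).
#' @return Percentage (numeric scalar, two decimals).
#' @export
combine_origin_shares <- function(profile, labels) {
  stopifnot(inherits(profile, "mosaicism_profile"))
  if (length(labels) == 0L) return(0)
  unknown <- setdiff(labels, names(profile$counts))
  if (length(unknown)) {
    rz_stop(sprintf("combine_origin_shares: unknown label(s): %s",
                    paste(unknown, collapse = ", ")))
  }
  round_half_up(100 * sum(profile$counts[labels]) / profile$total_genes, 2)
}

#' Build the gene -> origin-group rhizome network
#'
#' A bipartite directed graph with one node per gene and one node per origin
#' label occurring among the attributions (ORFan included). Every non-ORFan
#' gene carries a single edge to its origin group, weighted by best-hit
#' percent identity; ORFan genes are isolated gene nodes.
#'
#' @param attributions Attribution data.frame from [attribute_genome()].
#' @return An igraph object with vertex attribute `kind` (`"gene"` or
#'   `"group"`) and edge attribute `weight`.
#' @export
build_rhizome_network <- function(attributions) {
  groups <- unique(attributions$origin)
  vertices <- data.frame(
    name = c(attributions$gene_id, groups),
    kind = c(rep("gene", nrow(attributions)), rep("group", length(groups))),
    stringsAsFactors = FALSE)
  non_orfan <- attributions[attributions$origin != ORFAN_LABEL, , drop = FALSE]
  edges <- data.frame(from = non_orfan$gene_id, to = non_orfan$origin,
                      weight = non_orfan$identity, stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = vertices)
}

#' Pairwise total-variation distance between mosaicism profiles
#'
#' Compares genomes by the shape of their origin composition: half the L1
#' distance between percentage vectors over the union of labels, so two
#' disjoint compositions are 100 apart and identical ones 0.
#'
#' @param profiles List of two or more [mosaicism_profile()] objects.
#' @return Symmetric numeric matrix with zero diagonal, dimnames = genome
#'   ids.
#' @export
compare_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 2,
            all(vapply(profiles, inherits, TRUE, "mosaicism_profile")))
  labels <- unique(unlist(lapply(profiles, function(p) names(p$counts))))
  pct <- matrix(0, nrow = length(profiles), ncol = length(labels),
                dimnames = list(NULL, labels))
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    pct[i, names(p$counts)] <- 100 * p$counts / p$total_genes
  }
  ids <- vapply(profiles, function(p) p$genome_id, "")
  n <- length(profiles)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d[i, j] <- d[j, i] <- sum(abs(pct[i, ] - pct[j, ])) / 2
    }
  }
  d
}
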