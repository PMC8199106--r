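## Seeded generators producing ground-truthed inputs for every pipeline
## stage. All functions are pure in their spec (seed included): the same
## spec yields byte-identical output.
##
## Each generator scrambles the user seed with its own stream constant, so
## passing the same integer seed to, say, generate_reference_db and
## generate_mosaic_genome yields independent random streams. Without this,
## a "fresh" ORFan sequence could replay the exact draws that produced a
## database sequence and silently be its identical twin.

mix_seed <- function(seed, stream) {
  bitwAnd(bitwXor(as.integer(seed), as.integer(stream)), 0x7FFFFFFFL)
}
STREAM_REFERENCE_DB <- 0x1A2B3C4L
STREAM_MOSAIC <- 0x0F9D21BL
STREAM_MUTATE <- 0x27D4EB3L
STREAM_COHORT <- 0x3C6EF35L

#' Largest-remainder apportionment of proportions to integer counts
#'
#' Gives each label the floor of its exact share, then distributes the
#' remaining units by largest fractional remainder (ties broken by label
#' input order). Deterministic, so planted truth counts are exactly
#' testable.
#'
#' @param proportions Named numeric vector summing to 1 (tolerance 1e-9).
#' @param n Total count to apportion.
#' @return Named integer vector summing to `n`.
#' @export
#' @examples
#' apportion_counts(c(Bacteria = 0.5, ORFan = 0.5), 935)  # 468 / 467
apportion_counts <- function(proportions, n) {
  if (is.null(names(proportions)) || any(!nzchar(names(proportions)))) {
    rz_stop("apportion_counts: proportions must be named")
  }
  if (abs(sum(proportions) - 1) > 1e-9) {
    rz_stop(sprintf("apportion_counts: proportions sum to %.12f, not 1",
                    sum(proportions)))
  }
  exact <- proportions * n
  base <- floor(exact)
  left <- n - sum(base)
  if (left > 0) {
    rem <- exact - base
    # order by remainder desc, then input position: stable and deterministic
    idx <- order(-rem, seq_along(rem))[seq_len(left)]
    base[idx] <- base[idx] + 1
  }
  setNames(as.integer(base), names(proportions))
}

## one random amino-acid sequence over the background frequencies
random_sequence <- function(len, freqs = NULL) {
  if (is.null(freqs)) {
    paste(sample(AA_STANDARD, len, replace = TRUE), collapse = "")
  } else {
    paste(sample(AA_STANDARD, len, replace = TRUE, prob = freqs), collapse = "")
  }
}

#' Generate a labeled synthetic reference database
#'
#' Random sequences over background amino-acid frequencies (uniform over the
#' 20 standard residues by default — the simplest null, under which
#' unrelated sequences share no detectable homology), partitioned into
#' origin groups. Each group gets one taxon with its own genus, so
#' self-taxon exclusion and group attribution are both exercised.
#'
#' @param groups Character vector of >= 2 origin-group labels.
#' @param sequences_per_group Records per group.
#' @param length_range Integer range (min, max) of sequence lengths.
#' @param seed Integer seed.
#' @param freqs Optional length-20 background frequency vector.
#' @return List with `records` (protein record data.frame) and `taxonomy`.
#' @export
generate_reference_db <- function(groups, sequences_per_group = 20,
                                  length_range = c(150, 250), seed = 1,
                                  freqs = NULL) {
  if (length(groups) < 2L) rz_stop("generate_reference_db: need >= 2 groups")
  if (anyDuplicated(groups)) rz_stop("generate_reference_db: duplicate groups")
  withr::with_seed(mix_seed(seed, STREAM_REFERENCE_DB), {
    recs <- lapply(groups, function(g) {
      lens <- sample(seq(length_range[1], length_range[2]),
                     sequences_per_group, replace = TRUE)
      data.frame(
        id = sprintf("%s_%03d", g, seq_len(sequences_per_group)),
        sequence = vapply(lens, random_sequence, "", freqs = freqs),
        taxon_id = paste0("tax_", g),
        stringsAsFactors = FALSE)
    })
    records <- do.call(rbind, recs)
    taxonomy <- data.frame(
      taxon_id = paste0("tax_", groups),
      genus = paste0("Genus_", groups),
      group = groups,
      lineage = paste0("cellular;", groups),
      stringsAsFactors = FALSE)
    list(records = records, taxonomy = taxonomy)
  })
}

#' Mutate a sequence to a target expected identity
#'
#' Point substitutions at i.i.d. rate `1 - identity_target`; the substitute
#' residue is drawn from the background excluding the original, so every
#' substitution really changes the residue and the realized identity is
#' binomial around the target. No indels by default: realized query coverage
#' of a mutated copy against its donor stays at (essentially) 100 percent,
#' making the identity threshold the only binding constraint in recovery
#' experiments.
#'
#' @param seq Amino-acid sequence (character scalar).
#' @param identity_target Expected fraction of conserved sites, in (0, 1].
#' @param seed Optional integer seed (omit to use the current RNG stream).
#' @return The mutated sequence.
#' @export
mutate_sequence <- function(seq, identity_target, seed = NULL) {
  if (!is_string(seq)) rz_stop("mutate_sequence: empty sequence")
  if (identity_target <= 0 || identity_target > 1) {
    rz_stop("mutate_sequence: identity_target must be in (0, 1]")
  }
  run <- function() {
    chars <- strsplit(seq, "")[[1]]
    hit <- runif(length(chars)) < (1 - identity_target)
    if (any(hit)) {
      chars[hit] <- vapply(chars[hit], function(orig) {
        sample(setdiff(AA_STANDARD, orig), 1L)
      }, "")
    }
    paste(chars, collapse = "")
  }
  if (is.null(seed)) run() else withr::with_seed(mix_seed(seed, STREAM_MUTATE), run())
}

#' Specification of a synthetic mosaic genome
#'
#' @param n_genes Number of genes (>= 1).
#' @param origin_proportions Named fractions per origin label (ORFan
#'   allowed), summing to 1 within 1e-9.
#' @param donor_identity_target Expected identity of mutated donor copies,
#'   in (0, 1].
#' @param gene_length_range Length range for fresh ORFan sequences.
#' @param seed Integer seed.
#' @return An object of class `mosaic_genome_spec`.
#' @export
mosaic_genome_spec <- function(n_genes,
                               origin_proportions,
                               donor_identity_target = 0.9,
                               gene_length_range = c(150, 250),
                               seed = 1) {
  if (n_genes < 1) rz_stop("mosaic_genome_spec: n_genes must be >= 1")
  if (abs(sum(origin_proportions) - 1) > 1e-9) {
    rz_stop("mosaic_genome_spec: origin_proportions must sum to 1")
  }
  if (donor_identity_target <= 0 || donor_identity_target > 1) {
    rz_stop("mosaic_genome_spec: donor_identity_target must be in (0, 1]")
  }
  structure(list(n_genes = as.integer(n_genes),
                 origin_proportions = origin_proportions,
                 donor_identity_target = donor_identity_target,
                 gene_length_range = gene_length_range,
                 seed = as.integer(seed)),
            class = "mosaic_genome_spec")
}

#' Generate a mosaic query genome with planted origins
#'
#' Each gene is either a mutated copy of a donor sequence drawn uniformly
#' from its assigned origin group in the reference database, or (for the
#' ORFan share) a fresh random sequence unrelated to anything in the
#' database. Per-label gene counts follow the spec proportions exactly via
#' largest-remainder apportionment, so the planted truth is deterministic.
#' The genome's own taxon (`self`) does not occur in the database.
#'
#' An ORFan is, by definition, a gene with no database homolog passing the
#' detection thresholds — so the truth label "ORFan" is only valid if the
#' planted sequence actually has that property. A purely random sequence
#' occasionally does align to an unrelated database sequence with
#' E < 0.001 (long, low-identity gapped alignments; roughly at the rate
#' the e-value threshold itself implies). Planted ORFans are therefore
#' rejection-sampled: a draw with any hit passing `orfan_thresholds` is
#' discarded and redrawn, which keeps the truth table correct without
#' touching the attribution pipeline. Set `orfan_thresholds = NULL` to
#' plant unchecked random sequences.
#'
#' @param spec A [mosaic_genome_spec()].
#' @param db Reference records from [generate_reference_db()].
#' @param taxonomy Matching taxonomy (used to check group availability).
#' @param orfan_thresholds Threshold bundle a planted ORFan must fail
#'   against every database sequence (default: the rhizome bundle);
#'   `NULL` disables the check.
#' @return List with `records` (the genome), `truth` (data.frame `gene_id`,
#'   `origin`, `donor_id`), and `taxonomy` extended with the query's own
#'   `self` taxon.
#' @export
generate_mosaic_genome <- function(spec, db, taxonomy,
                                   orfan_thresholds = search_thresholds("rhizome")) {
  stopifnot(inherits(spec, "mosaic_genome_spec"))
  labels <- names(spec$origin_proportions)
  planted_groups <- setdiff(labels, ORFAN_LABEL)
  db_groups <- unique(taxon_group(db$taxon_id, taxonomy, "generate_mosaic_genome"))
  unknown <- setdiff(planted_groups, db_groups)
  if (length(unknown)) {
    rz_stop(sprintf("generate_mosaic_genome: group(s) absent from db: %s",
                    paste(unknown, collapse = ", ")))
  }
  counts <- apportion_counts(spec$origin_proportions, spec$n_genes)
  origins <- rep(names(counts), counts)
  db_group <- taxon_group(db$taxon_id, taxonomy, "generate_mosaic_genome")

  withr::with_seed(mix_seed(spec$seed, STREAM_MOSAIC), {
    seqs <- character(length(origins))
    donors <- rep(NA_character_, length(origins))
    for (i in seq_along(origins)) {
      if (origins[i] == ORFAN_LABEL) {
        for (attempt in 1:1000) {
          len <- sample(seq(spec$gene_length_range[1], spec$gene_length_range[2]), 1L)
          seqs[i] <- random_sequence(len)
          if (is.null(orfan_thresholds)) break
          hits <- search_database(
            data.frame(id = "orfan_draw", sequence = seqs[i],
                       stringsAsFactors = FALSE),
            db, thresholds = orfan_thresholds)
          if (nrow(hits) == 0L) break
          if (attempt == 1000L) {
            rz_stop("generate_mosaic_genome: cannot draw a homolog-free ORFan")
          }
        }
      } else {
        pool <- which(db_group == origins[i])
        donor <- if (length(pool) == 1L) pool else sample(pool, 1L)
        donors[i] <- db$id[donor]
        seqs[i] <- mutate_sequence(db$sequence[donor], spec$donor_identity_target)
      }
    }
    ids <- sprintf("gene_%04d", seq_along(origins))
    self_taxonomy <- rbind(taxonomy, data.frame(
      taxon_id = "self", genus = "Genus_self", group = taxonomy$group[1],
      lineage = "cellular;self", stringsAsFactors = FALSE))
    list(records = data.frame(id = ids, sequence = seqs, taxon_id = "self",
                              stringsAsFactors = FALSE),
         truth = data.frame(gene_id = ids, origin = origins, donor_id = donors,
                            stringsAsFactors = FALSE),
         taxonomy = self_taxonomy)
  })
}

#' Specification of a synthetic phyletic cohort
#'
#' @param n_groups Number of planted genome groups (>= 2).
#' @param genomes_per_group Genomes per group.
#' @param n_families Total families (>= `n_groups`); split into
#'   group-characteristic blocks of near-equal size.
#' @param p_within Presence probability of a genome's own block families.
#' @param p_background Presence probability elsewhere.
#' @param seed Integer seed.
#' @return An object of class `phyletic_profile_spec`.
#' @export
phyletic_profile_spec <- function(n_groups = 5, genomes_per_group = 12,
                                  n_families = 200, p_within = 0.9,
                                  p_background = 0.05, seed = 1) {
  if (n_groups < 2) rz_stop("phyletic_profile_spec: n_groups must be >= 2")
  if (n_families < n_groups) {
    rz_stop("phyletic_profile_spec: n_families must be >= n_groups")
  }
  for (p in c(p_within, p_background)) {
    if (!is.numeric(p) || p < 0 || p > 1) {
      rz_stop("phyletic_profile_spec: probabilities must be in [0, 1]")
    }
  }
  structure(list(n_groups = as.integer(n_groups),
                 genomes_per_group = as.integer(genomes_per_group),
                 n_families = as.integer(n_families),
                 p_within = p_within, p_background = p_background,
                 seed = as.integer(seed)),
            class = "phyletic_profile_spec")
}

#' Generate a phyletic presence/absence cohort with planted groups
#'
#' Families are partitioned into `n_groups` characteristic blocks; a
#' genome's entries are Bernoulli(`p_within`) inside its own group's block
#' and Bernoulli(`p_background`) elsewhere. This emulates
#' lifestyle-correlated gene content: genomes sharing a lifestyle share a
#' block of families the others mostly lack.
#'
#' @param spec A [phyletic_profile_spec()].
#' @return List with `matrix` (0/1 integer matrix, rows = genomes) and
#'   `groups` (named character vector of true group labels).
#' @export
generate_phyletic_cohort <- function(spec) {
  stopifnot(inherits(spec, "phyletic_profile_spec"))
  n_genomes <- spec$n_groups * spec$genomes_per_group
  block <- apportion_counts(
    setNames(rep(1 / spec$n_groups, spec$n_groups),
             paste0("G", seq_len(spec$n_groups))), spec$n_families)
  fam_group <- rep(names(block), block)
  genome_group <- rep(names(block), each = spec$genomes_per_group)
  ids <- sprintf("genome_%02d", seq_len(n_genomes))
  withr::with_seed(mix_seed(spec$seed, STREAM_COHORT), {
    p <- ifelse(outer(genome_group, fam_group, "=="),
                spec$p_within, spec$p_background)
    m <- matrix(as.integer(runif(length(p)) < p), nrow = n_genomes,
                dimnames = list(ids, sprintf("fam_%03d", seq_len(spec$n_families))))
    list(matrix = m, groups = setNames(genome_group, ids))
  })
}
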