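## End-to-end commands tying the stages together. Each command takes a
## config (YAML path or list), writes its artifacts plus a machine-readable
## manifest into the output directory, and returns the paths invisibly.

#' Read and validate a run configuration
#'
#' YAML (or JSON, which is a YAML subset) with top-level keys `output_dir`,
#' `seed`, and per-command blocks `rhizome`, `phyletic`, `simulate`.
#' Threshold sets come as named bundles (`"rhizome"`, `"phyletic"`,
#' `"marker"`) or as explicit `{min_identity, min_coverage, max_evalue,
#' min_align_length}` maps; explicit fields override bundle defaults.
#'
#' @param config Path to a config file, or an already-parsed list.
#' @return The validated config list (class `rz_config`).
#' @export
read_run_config <- function(config) {
  if (is_string(config)) {
    if (!file.exists(config)) {
      rz_stop(sprintf("config error: no such config file: %s", config))
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) rz_stop("config error: config must be a file path or list")
  if (is.null(config$output_dir)) rz_stop("config error: output_dir is required")
  if (is.null(config$seed)) config$seed <- 1L
  structure(config, class = c("rz_config", "list"))
}

## thresholds from a config entry: bundle name, explicit map, or both
config_thresholds <- function(x, default_bundle) {
  base <- search_thresholds(default_bundle)
  if (is.null(x)) return(base)
  if (is_string(x)) return(search_thresholds(x))
  vals <- as.list(base)
  for (f in intersect(names(x), names(vals))) vals[[f]] <- x[[f]]
  do.call(search_thresholds, vals)
}

write_manifest <- function(dir, command, config, extra = list()) {
  manifest <- c(list(command = command,
                     package_version = as.character(packageVersion("rhizomer")),
                     seed = config$seed,
                     config = unclass(config)),
                extra)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

ensure_outdir <- function(config) {
  dir <- config$output_dir
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE, showWarnings = FALSE)) {
    rz_stop(sprintf("config error: cannot create output_dir '%s'", dir))
  }
  dir
}

#' Run the rhizome analysis end to end
#'
#' Reads a query proteome, a labeled reference FASTA and a taxonomy table;
#' attributes every gene; and writes the per-gene attribution TSV, the
#' mosaicism profile TSV and the rhizome network GEXF, plus a manifest.
#'
#' Config block `rhizome`: `genome_fasta`, `db_fasta`, `taxonomy`,
#' `genome_id` (default: FASTA basename), `thresholds` (default bundle
#' `"rhizome"`), `exclusion` with `self_taxon_ids` / `self_genus` /
#' `rank`.
#'
#' @param config Path or list accepted by [read_run_config()].
#' @return Invisibly, a list of written paths and the attribution table.
#' @export
cmd_rhizome <- function(config) {
  config <- read_run_config(config)
  blk <- config$rhizome
  if (is.null(blk)) rz_stop("config error: missing 'rhizome' block")
  for (f in c("genome_fasta", "db_fasta", "taxonomy")) {
    if (is.null(blk[[f]])) rz_stop(sprintf("config error: rhizome.%s is required", f))
    if (!file.exists(blk[[f]])) {
      rz_stop(sprintf("io_formats error: rhizome.%s: no such file: %s", f, blk[[f]]))
    }
  }
  dir <- ensure_outdir(config)
  genome <- read_fasta(blk$genome_fasta, taxon_id = "self")
  db <- read_fasta(blk$db_fasta)
  groups <- if (is.null(blk$groups)) default_origin_groups() else blk$groups
  taxonomy <- read_taxonomy_table(blk$taxonomy, groups = groups)
  thresholds <- config_thresholds(blk$thresholds, "rhizome")
  exc <- blk$exclusion
  rule <- self_taxon_rule(
    self_taxon_ids = if (is.null(exc$self_taxon_ids)) "self" else exc$self_taxon_ids,
    self_genus = exc$self_genus,
    exclusion_rank = if (is.null(exc$rank)) "genus" else exc$rank)
  genome_id <- if (is.null(blk$genome_id)) {
    tools::file_path_sans_ext(basename(blk$genome_fasta))
  } else blk$genome_id

  attributions <- attribute_genome(genome, db, taxonomy, rule, thresholds)
  profile <- mosaicism_profile(genome_id, attributions)
  network <- build_rhizome_network(attributions)

  paths <- list(attributions = file.path(dir, "attributions.tsv"),
                profile = file.path(dir, "profile.tsv"),
                network = file.path(dir, "rhizome.gexf"))
  write.table(attributions, paths$attributions, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_profile_table(profile, paths$profile)
  write_gexf(network, paths$network)
  n_orfan <- sum(attributions$origin == ORFAN_LABEL)
  message(sprintf("cmd_rhizome: %d genes, %d ORFans; thresholds: identity>=%s coverage>=%s evalue<=%s",
                  nrow(attributions), n_orfan, thresholds$min_identity,
                  thresholds$min_coverage, format(thresholds$max_evalue)))
  paths$manifest <- write_manifest(dir, "rhizome", config,
                                   list(n_genes = nrow(attributions),
                                        n_orfans = n_orfan))
  invisible(list(paths = paths, attributions = attributions, profile = profile))
}

#' Run the phyletic clustering analysis end to end
#'
#' Builds the presence/absence matrix of the supplied genomes against a
#' reference family set, computes Euclidean distances, clusters
#' hierarchically, and writes the matrix TSV, distance TSV and Newick
#' dendrogram (plus an ARI report when true labels are supplied).
#'
#' Config block `phyletic`: `genome_fastas` (>= 2 paths), `family_table`,
#' `family_fasta`, optional `set_name`, `thresholds` (default bundle
#' `"phyletic"`), `linkage` (default `"average"`), optional `k` and
#' `true_groups` (map genome id -> label) for the recovery report.
#'
#' @param config Path or list accepted by [read_run_config()].
#' @return Invisibly, a list of written paths, the matrix and the
#'   dendrogram.
#' @export
cmd_phyletic <- function(config) {
  config <- read_run_config(config)
  blk <- config$phyletic
  if (is.null(blk)) rz_stop("config error: missing 'phyletic' block")
  if (is.null(blk$genome_fastas) || length(blk$genome_fastas) < 2L) {
    rz_stop("config error: phyletic.genome_fastas needs >= 2 genomes")
  }
  linkage <- if (is.null(blk$linkage)) "average" else blk$linkage
  # fail fast on a bad linkage before any alignment work
  agglomerative_cluster(matrix(c(0, 1, 1, 0), 2, 2,
                               dimnames = list(c("a", "b"), c("a", "b"))), linkage)
  for (f in c("family_table", "family_fasta")) {
    if (is.null(blk[[f]])) rz_stop(sprintf("config error: phyletic.%s is required", f))
  }
  dir <- ensure_outdir(config)
  genomes <- lapply(blk$genome_fastas, read_fasta)
  names(genomes) <- vapply(blk$genome_fastas,
                           function(p) tools::file_path_sans_ext(basename(p)), "")
  set_name <- if (is.null(blk$set_name)) "families" else blk$set_name
  famset <- read_family_set(set_name, blk$family_table, blk$family_fasta)
  thresholds <- config_thresholds(blk$thresholds, "phyletic")

  pam <- build_phyletic_matrix(genomes, famset, thresholds = thresholds)
  distances <- euclidean_distance_matrix(pam)
  dendrogram <- agglomerative_cluster(distances, linkage)

  paths <- list(matrix = file.path(dir, "phyletic_matrix.tsv"),
                distances = file.path(dir, "distances.tsv"),
                dendrogram = file.path(dir, "dendrogram.nwk"))
  write_matrix_tsv(pam, paths$matrix)
  write_matrix_tsv(round(distances, 6), paths$distances)
  write_newick(dendrogram, paths$dendrogram)
  if (!is.null(blk$true_groups)) {
    k <- if (is.null(blk$k)) length(unique(unlist(blk$true_groups))) else blk$k
    score <- cut_and_score(dendrogram, k, unlist(blk$true_groups))
    paths$ari <- file.path(dir, "ari.json")
    jsonlite::write_json(list(k = k, ari = score$ari), paths$ari,
                         auto_unbox = TRUE, digits = NA)
  }
  message(sprintf("cmd_phyletic: %d genomes x %d families, linkage %s",
                  nrow(pam), ncol(pam), linkage))
  paths$manifest <- write_manifest(dir, "phyletic", config,
                                   list(n_genomes = nrow(pam),
                                        n_families = ncol(pam)))
  invisible(list(paths = paths, matrix = pam, dendrogram = dendrogram))
}

#' Generate a synthetic dataset directory
#'
#' Materializes a reference database, a mosaic query genome with planted
#' origins, and the ground-truth table as FASTA/TSV files plus a manifest
#' recording the seed — the same files a real analysis would consume, with
#' truth attached.
#'
#' Config block `simulate`: `groups`, `sequences_per_group`,
#' `db_length_range`, `n_genes`, `origin_proportions` (map incl. `ORFan`),
#' `donor_identity`, `gene_length_range`.
#'
#' @param config Path or list accepted by [read_run_config()].
#' @return Invisibly, a list of written paths.
#' @export
cmd_simulate <- function(config) {
  config <- read_run_config(config)
  blk <- config$simulate
  if (is.null(blk)) rz_stop("config error: missing 'simulate' block")
  props <- unlist(blk$origin_proportions)
  if (is.null(props)) rz_stop("config error: simulate.origin_proportions is required")
  groups <- if (is.null(blk$groups)) setdiff(names(props), ORFAN_LABEL) else blk$groups
  dir <- ensure_outdir(config)

  db <- generate_reference_db(
    groups,
    sequences_per_group = if (is.null(blk$sequences_per_group)) 20 else blk$sequences_per_group,
    length_range = if (is.null(blk$db_length_range)) c(150, 250) else unlist(blk$db_length_range),
    seed = config$seed)
  spec <- mosaic_genome_spec(
    n_genes = if (is.null(blk$n_genes)) 100 else blk$n_genes,
    origin_proportions = props,
    donor_identity_target = if (is.null(blk$donor_identity)) 0.9 else blk$donor_identity,
    gene_length_range = if (is.null(blk$gene_length_range)) c(150, 250) else unlist(blk$gene_length_range),
    seed = config$seed)
  genome <- generate_mosaic_genome(spec, db$records, db$taxonomy)

  paths <- list(db_fasta = file.path(dir, "reference_db.faa"),
                genome_fasta = file.path(dir, "genome.faa"),
                taxonomy = file.path(dir, "taxonomy.tsv"),
                truth = file.path(dir, "truth.tsv"))
  write_fasta(db$records, paths$db_fasta)
  write_fasta(genome$records, paths$genome_fasta)
  write_taxonomy_table(genome$taxonomy, paths$taxonomy)
  write.table(genome$truth, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  message(sprintf("cmd_simulate: %d reference records, %d genes (seed %d)",
                  nrow(db$records), nrow(genome$records), config$seed))
  paths$manifest <- write_manifest(dir, "simulate", config,
                                   list(n_db = nrow(db$records),
                                        n_genes = nrow(genome$records)))
  invisible(paths)
}
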