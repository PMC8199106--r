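#' Export a rhizome network as GEXF 1.2
#'
#' Writes the gene -> origin-group bipartite network in the GEXF dialect
#' consumed by network-drawing tools such as Gephi: one node per gene and
#' per origin group (ORFan included), one directed edge per non-ORFan
#' attribution, weighted by best-hit percent identity. No installed package
#' emits GEXF, so the (small) document is assembled directly with xml2.
#'
#' @param network An igraph object from [build_rhizome_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gexf <- function(network, path) {
  stopifnot(inherits(network, "igraph"))
  doc <- xml2::xml_new_root("gexf",
                            xmlns = "http://www.gexf.net/1.2draft",
                            version = "1.2")
  graph <- xml2::xml_add_child(doc, "graph", mode = "static",
                               defaultedgetype = "directed")
  nodes <- xml2::xml_add_child(graph, "nodes")
  vname <- igraph::V(network)$name
  vtype <- igraph::V(network)$kind
  for (i in seq_along(vname)) {
    xml2::xml_add_child(nodes, "node", id = vname[i], label = vname[i],
                        kind = vtype[i])
  }
  edges <- xml2::xml_add_child(graph, "edges")
  if (igraph::ecount(network) > 0) {
    el <- igraph::as_edgelist(network, names = TRUE)
    w <- igraph::E(network)$weight
    for (i in seq_len(nrow(el))) {
      xml2::xml_add_child(edges, "edge", id = as.character(i - 1L),
                          source = el[i, 1], target = el[i, 2],
                          weight = format(w[i], digits = 6))
    }
  }
  tryCatch(xml2::write_xml(doc, path),
           error = function(e) rz_stop(sprintf("write_gexf: cannot write %s: %s",
                                               path, conditionMessage(e))))
  invisible(path)
}

#' Write a hierarchical-clustering dendrogram as Newick
#'
#' Leaves sit at the full merge height of their shallowest cluster: a
#' two-genome dendrogram merging at height h serializes as `(A:h,B:h);`.
#' (`ape::as.phylo.hclust` places leaves at half the merge height so that
#' leaf-to-leaf path length equals the height; edge lengths are rescaled
#' here so branch lengths read directly as merge heights.)
#'
#' @param dendrogram An `hclust` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(dendrogram, path) {
  stopifnot(inherits(dendrogram, "hclust"))
  phy <- ape::as.phylo(dendrogram)
  phy$edge.length <- phy$edge.length * 2
  tryCatch(ape::write.tree(phy, file = path),
           error = function(e) rz_stop(sprintf("write_newick: cannot write %s: %s",
                                               path, conditionMessage(e))))
  invisible(path)
}

#' Write mosaicism profiles as a TSV table
#'
#' One row per genome; for every origin label in the union of the profiles'
#' labels, a `<label>_count` column and a `<label>_pct` column (two decimals,
#' half-up), plus `total_genes`. Labels absent from a profile count as zero.
#'
#' @param profiles A single `mosaicism_profile` or a list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(profiles, path) {
  if (inherits(profiles, "mosaicism_profile")) profiles <- list(profiles)
  stopifnot(length(profiles) >= 1,
            all(vapply(profiles, inherits, TRUE, "mosaicism_profile")))
  labels <- unique(unlist(lapply(profiles, function(p) names(p$counts))))
  rows <- lapply(profiles, function(p) {
    cnt <- setNames(rep(0L, length(labels)), labels)
    cnt[names(p$counts)] <- p$counts
    pct <- round_half_up(100 * cnt / p$total_genes, 2)
    row <- data.frame(genome_id = p$genome_id, total_genes = p$total_genes,
                      stringsAsFactors = FALSE)
    for (l in labels) {
      row[[paste0(l, "_count")]] <- unname(cnt[l])
      row[[paste0(l, "_pct")]] <- sprintf("%.2f", pct[l])
    }
    row
  })
  tab <- do.call(rbind, rows)
  tryCatch(write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE),
           error = function(e) rz_stop(sprintf("write_profile_table: cannot write %s: %s",
                                               path, conditionMessage(e))))
  invisible(path)
}
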