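tax <- fixture_taxonomy()

test_that("self-taxon exclusion removes exactly the rule's subset", {
  hits <- rbind(make_hit(subject_id = "a", subject_taxon = "tax_Rick"),
                make_hit(subject_id = "b", subject_taxon = "tax_Bacteria"),
                make_hit(subject_id = "c", subject_taxon = "tax_Rick"),
                make_hit(subject_id = "d", subject_taxon = "tax_CPR"))

  # genus rank: everything in the query's genus goes
  rule <- self_taxon_rule(self_genus = "Rickettsia")
  out <- exclude_self_hits(hits, rule, tax)
  expect_identical(out$subject_id, c("b", "d"))

  # all hits from the query's own genus -> empty list
  own <- hits[hits$subject_taxon == "tax_Rick", ]
  expect_equal(nrow(exclude_self_hits(own, rule, tax)), 0L)

  # no overlap with the rule -> input unchanged
  rule2 <- self_taxon_rule(self_taxon_ids = "self")
  expect_identical(exclude_self_hits(hits, rule2, tax), hits)

  # set-difference oracle on a mixed list
  expect_identical(out, hits[!(hits$subject_taxon %in% "tax_Rick"), ])
})

test_that("exclusion ranks taxon_id and group behave as documented", {
  hits <- rbind(make_hit(subject_id = "a", subject_taxon = "tax_Bacteria"),
                make_hit(subject_id = "b", subject_taxon = "tax_Rick"),
                make_hit(subject_id = "c", subject_taxon = "tax_CPR"))
  # taxon_id rank: only the listed taxa
  r_tax <- self_taxon_rule(self_taxon_ids = "tax_Rick",
                           exclusion_rank = "taxon_id")
  expect_identical(exclude_self_hits(hits, r_tax, tax)$subject_id, c("a", "c"))
  # group rank: the query's whole origin group
  r_grp <- self_taxon_rule(self_taxon_ids = "tax_Rick",
                           exclusion_rank = "group")
  expect_identical(exclude_self_hits(hits, r_grp, tax)$subject_id, "c")
  # unresolvable subject taxon names the offender
  bad <- make_hit(subject_taxon = "tax_unknown")
  expect_error(exclude_self_hits(bad, r_tax, tax), "tax_unknown")
})

test_that("attribute_gene applies thresholds and the top-hit ordering", {
  thr <- search_thresholds("rhizome")
  # no hits -> ORFan
  a0 <- attribute_gene("g1", make_hit()[0, ], thr, tax)
  expect_identical(a0$origin, orfan_label())
  expect_true(is.na(a0$subject_id))

  # one surviving hit -> its group
  a1 <- attribute_gene("g1", make_hit(identity = 45, coverage = 80,
                                      evalue = 1e-30,
                                      subject_taxon = "tax_Bacteria"), thr, tax)
  expect_identical(a1$origin, "Bacteria")

  # bitscore decides between two passing hits
  two <- rbind(make_hit(subject_id = "b", bitscore = 120,
                        subject_taxon = "tax_Bacteria"),
               make_hit(subject_id = "e", bitscore = 95,
                        subject_taxon = "tax_CPR"))
  expect_identical(attribute_gene("g1", two, thr, tax)$origin, "Bacteria")

  # hits failing thresholds do not rescue a gene from ORFan status
  weak <- make_hit(identity = 10, coverage = 10, evalue = 1)
  expect_identical(attribute_gene("g1", weak, thr, tax)$origin, orfan_label())
})

test_that("tie-breaking chain is deterministic through subject id", {
  thr <- search_thresholds("rhizome")
  ties <- rbind(make_hit(subject_id = "zeta", subject_taxon = "tax_CPR"),
                make_hit(subject_id = "alpha", subject_taxon = "tax_Archaea"))
  expect_identical(attribute_gene("g", ties, thr, tax)$origin, "Archaea")
})

test_that("attribute_genome attributes each gene once, in order", {
  set.seed(21)
  db <- data.frame(id = c("b1", "b2", "c1"),
                   sequence = c(rand_aa(80), rand_aa(80), rand_aa(80)),
                   taxon_id = c("tax_Bacteria", "tax_Bacteria", "tax_CPR"),
                   stringsAsFactors = FALSE)
  # one gene identical to a bacterial db sequence
  genome <- data.frame(id = "g1", sequence = db$sequence[1], taxon_id = "self",
                       stringsAsFactors = FALSE)
  att <- attribute_genome(genome, db, tax, self_taxon_rule("self"))
  expect_identical(att$origin, "Bacteria")

  # random genes against an unrelated db: all ORFans
  genome2 <- data.frame(id = paste0("g", 1:5),
                        sequence = replicate(5, rand_aa(120)),
                        taxon_id = "self", stringsAsFactors = FALSE)
  att2 <- attribute_genome(genome2, db, tax, self_taxon_rule("self"))
  expect_identical(att2$gene_id, genome2$id)
  expect_true(all(att2$origin == orfan_label()))
})

test_that("synthetic genome attributions equal the planted truth at high identity", {
  db <- generate_reference_db(c("Bacteria", "CPR", "Archaea"), 10,
                              c(90, 140), seed = 31)
  spec <- mosaic_genome_spec(20, c(Bacteria = 0.5, CPR = 0.3, ORFan = 0.2),
                             donor_identity_target = 0.9, seed = 32)
  g <- generate_mosaic_genome(spec, db$records, db$taxonomy)
  att <- attribute_genome(g$records, db$records, g$taxonomy,
                          self_taxon_rule("self"))
  expect_identical(att$origin, g$truth$origin)
})

test_that("mosaicism percentages reproduce printed count arithmetic", {
  p <- mosaicism_profile("cpr_genome",
                         counts = c(Bacteria = 506, CPR = 282,
                                    ORFan = 142, Archaea = 5))
  expect_equal(unname(p$percentages),
               c(54.12, 30.16, 15.19, 0.53))
  expect_equal(p$total_genes, 935)

  p2 <- mosaicism_profile("virus", counts = c(ORFan = 387, rest = 889))
  expect_equal(unname(p2$percentages["ORFan"]), 30.33)

  p3 <- mosaicism_profile("one", counts = c(Bacteria = 1))
  expect_equal(unname(p3$percentages), 100)

  expect_error(mosaicism_profile("x", data.frame()), "empty")
})

test_that("profile percentages sum to ~100 and ignore gene order", {
  att <- make_attribution(paste0("g", 1:7),
                          c("Bacteria", "CPR", orfan_label(), "Bacteria",
                            "Archaea", "Bacteria", "CPR"))
  p <- mosaicism_profile("gnm", att)
  expect_equal(sum(p$counts), 7)
  expect_lt(abs(sum(p$percentages) - 100), 0.05 * length(p$counts))
  set.seed(1)
  p_perm <- mosaicism_profile("gnm", att[sample(7), ])
  expect_equal(p_perm$counts[names(p$counts)], p$counts)
  expect_equal(p_perm$percentages[names(p$percentages)], p$percentages)
})

test_that("combined origin shares sum counts before rounding", {
  p <- mosaicism_profile("cpr_genome",
                         counts = c(Bacteria = 506, CPR = 282,
                                    ORFan = 142, Archaea = 5))
  expect_equal(combine_origin_shares(p, c("CPR", "ORFan")), 45.35)
  expect_equal(combine_origin_shares(p, names(p$counts)), 100)
  expect_equal(combine_origin_shares(p, character(0)), 0)
  expect_error(combine_origin_shares(p, "Viruses"), "unknown label")
})

test_that("rhizome network counts nodes and edges correctly", {
  att <- make_attribution(c("g1", "g2", "g3"),
                          c("Bacteria", "Bacteria", orfan_label()))
  net <- build_rhizome_network(att)
  expect_equal(igraph::vcount(net), 5)       # 3 genes + Bacteria + ORFan node
  expect_equal(igraph::ecount(net), 2)
  genes <- igraph::V(net)[igraph::V(net)$kind == "gene"]
  expect_true(all(igraph::degree(net, genes, mode = "out") <= 1))
  # degree sum equals the non-ORFan gene count
  expect_equal(sum(igraph::degree(net, genes, mode = "out")),
               sum(att$origin != orfan_label()))

  all_orf <- make_attribution(c("g1", "g2"), rep(orfan_label(), 2))
  expect_equal(igraph::ecount(build_rhizome_network(all_orf)), 0)
})

test_that("profile distances are total variation on the percentage scale", {
  pa <- mosaicism_profile("a", counts = c(A = 10))
  pb <- mosaicism_profile("b", counts = c(B = 5))
  d <- compare_profiles(list(pa, pb))
  expect_equal(unname(d["a", "b"]), 100)
  expect_equal(unname(diag(d)), c(0, 0))
  pa2 <- mosaicism_profile("a2", counts = c(A = 40))
  expect_equal(unname(compare_profiles(list(pa, pa2))["a", "a2"]), 0)

  pc <- mosaicism_profile("c", counts = c(A = 1, B = 3))
  d3 <- compare_profiles(list(pa, pb, pc))
  expect_equal(d3, t(d3))
  # direct formula: c is {A:25, B:75}
  expect_equal(unname(d3["a", "c"]), (abs(100 - 25) + abs(0 - 75)) / 2)
  expect_equal(unname(d3["b", "c"]), (abs(100 - 75) + abs(0 - 25)) / 2)
})

test_that("injecting self hits never changes an attribution", {
  thr <- search_thresholds("rhizome")
  rule <- self_taxon_rule(self_taxon_ids = "self")
  hits <- rbind(make_hit(subject_id = "b", bitscore = 90,
                         subject_taxon = "tax_Bacteria"),
                make_hit(subject_id = "c", bitscore = 80,
                         subject_taxon = "tax_CPR"))
  base <- attribute_gene("g", exclude_self_hits(hits, rule, tax), thr, tax)
  # a self hit with an overwhelming score must not flip the call
  injected <- rbind(make_hit(subject_id = "me", bitscore = 1e6,
                             subject_taxon = "self"), hits)
  after <- attribute_gene("g", exclude_self_hits(injected, rule, tax), thr, tax)
  expect_identical(after, base)
})
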