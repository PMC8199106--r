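## small family set: three families, one short representative each
fixture_family_set <- function() {
  set.seed(77)
  reps <- data.frame(id = c("repA", "repB", "repC"),
                     sequence = c(rand_aa(80), rand_aa(80), rand_aa(80)),
                     taxon_id = NA_character_,
                     family_id = c("famA", "famB", "famC"),
                     stringsAsFactors = FALSE)
  reference_family_set("fixture", reps)
}

test_that("family presence detection finds copies and rejects noise", {
  fs <- fixture_family_set()
  reps <- fs$representatives
  genome_with <- data.frame(id = "g1", sequence = reps$sequence[1],
                            stringsAsFactors = FALSE)
  expect_equal(detect_family_presence(genome_with, reps[1, ]), 1L)
  set.seed(5)
  genome_without <- data.frame(id = "g1", sequence = rand_aa(80),
                               stringsAsFactors = FALSE)
  expect_equal(detect_family_presence(genome_without, reps[1, ]), 0L)
})

test_that("diverged copies match the explicit threshold-check verdict", {
  fs <- fixture_family_set()
  reps <- fs$representatives[1, , drop = FALSE]
  set.seed(6)
  for (target in c(0.3, 0.5, 0.7)) {
    g <- data.frame(id = "g", sequence = mutate_sequence(reps$sequence, target),
                    stringsAsFactors = FALSE)
    got <- detect_family_presence(g, reps)
    # oracle: one explicit alignment + threshold check
    a <- local_align(g$sequence, reps$sequence)
    ev <- estimate_evalue(a$score, nchar(g$sequence), nchar(reps$sequence))
    want <- as.integer(a$identity >= 30 && ev$evalue <= 0.001)
    expect_equal(got, want, info = paste("target", target))
  }
})

test_that("phyletic matrix matches per-cell calls and keeps zero columns", {
  fs <- fixture_family_set()
  reps <- fs$representatives
  set.seed(8)
  g1 <- data.frame(id = c("x1", "x2"),
                   sequence = c(reps$sequence[1], rand_aa(90)),
                   stringsAsFactors = FALSE)   # has famA only
  g2 <- data.frame(id = c("y1", "y2"),
                   sequence = c(reps$sequence[2], reps$sequence[1]),
                   stringsAsFactors = FALSE)   # has famA and famB
  m <- build_phyletic_matrix(list(G1 = g1, G2 = g2), fs)
  expect_equal(m, matrix(c(1L, 1L, 0L, 1L, 0L, 0L), nrow = 2,
                         dimnames = list(c("G1", "G2"),
                                         c("famA", "famB", "famC"))))
  # famC column is all-zero but retained; duplicated genome gives equal rows
  m2 <- build_phyletic_matrix(list(G1 = g1, G1b = g1), fs)
  expect_equal(unname(m2[1, ]), unname(m2[2, ]))
})

test_that("Euclidean distances equal sqrt of Hamming on 0/1 rows", {
  m <- rbind(a = c(1, 1, 0), b = c(0, 1, 1), c = c(1, 1, 0))
  d <- euclidean_distance_matrix(m)
  expect_equal(unname(d["a", "b"]), sqrt(2))
  expect_equal(unname(d["a", "c"]), 0)
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))

  set.seed(13)
  r <- matrix(rbinom(40, 1, 0.5), nrow = 5,
              dimnames = list(paste0("g", 1:5), NULL))
  d2 <- euclidean_distance_matrix(r)
  for (i in 1:4) {
    for (j in (i + 1):5) {
      expect_equal(unname(d2[i, j]), sqrt(sum(r[i, ] != r[j, ])))
    }
  }
  # symmetry + triangle inequality
  expect_equal(d2, t(d2))
  for (i in 1:5) for (j in 1:5) for (k in 1:5) {
    expect_lte(d2[i, j], d2[i, k] + d2[k, j] + 1e-12)
  }
  expect_error(euclidean_distance_matrix(rbind(c(1, 2), c(0, 1))), "non-binary")
})

test_that("average-linkage merges reproduce the naive step-by-step oracle", {
  d2 <- matrix(c(0, 4, 4, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  hc2 <- agglomerative_cluster(d2)
  expect_equal(hc2$height, 4)

  d3 <- matrix(c(0, 1, 10, 1, 0, 10, 10, 10, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  hc3 <- agglomerative_cluster(d3)
  expect_equal(cutree(hc3, 2)[["a"]], cutree(hc3, 2)[["b"]])

  set.seed(17)
  pts <- matrix(runif(12), nrow = 6)
  d6 <- as.matrix(dist(pts))
  dimnames(d6) <- list(paste0("g", 1:6), paste0("g", 1:6))
  hc6 <- agglomerative_cluster(d6)
  expect_equal(sort(hc6$height), sort(oracle_average_linkage_heights(d6)))

  expect_error(agglomerative_cluster(d6, "centroidal"), "unknown linkage")
})

test_that("dendrogram is invariant under genome input order", {
  set.seed(19)
  m <- matrix(rbinom(8 * 30, 1, 0.4), nrow = 8,
              dimnames = list(paste0("g", 1:8), NULL))
  h1 <- agglomerative_cluster(euclidean_distance_matrix(m))
  perm <- sample(8)
  h2 <- agglomerative_cluster(euclidean_distance_matrix(m[perm, ]))
  expect_equal(sort(h1$height), sort(h2$height))
  c1 <- as.matrix(stats::cophenetic(h1))
  c2 <- as.matrix(stats::cophenetic(h2))[rownames(c1), colnames(c1)]
  expect_equal(c1, c2)
})

test_that("duplicating a genome adds one zero merge and shifts nothing else", {
  set.seed(23)
  m <- matrix(rbinom(5 * 40, 1, 0.5), nrow = 5,
              dimnames = list(paste0("g", 1:5), NULL))
  h <- agglomerative_cluster(euclidean_distance_matrix(m))
  m_dup <- rbind(m, g1b = m["g1", ])
  h_dup <- agglomerative_cluster(euclidean_distance_matrix(m_dup))
  expect_equal(sort(h_dup$height), sort(c(0, h$height)))
})

test_that("cutting the dendrogram scores partitions with ARI", {
  cohort <- generate_phyletic_cohort(
    phyletic_profile_spec(n_groups = 2, genomes_per_group = 6,
                          n_families = 40, p_within = 1, p_background = 0,
                          seed = 3))
  hc <- agglomerative_cluster(euclidean_distance_matrix(cohort$matrix))
  # two fully separated planted blocks: perfect recovery
  expect_equal(cut_and_score(hc, 2, cohort$groups)$ari, 1)
  # k = leaf count: singleton partition agrees perfectly with singleton truth
  n <- nrow(cohort$matrix)
  singletons <- setNames(paste0("s", seq_len(n)), rownames(cohort$matrix))
  expect_equal(cut_and_score(hc, n, singletons)$ari, 1)
  expect_error(cut_and_score(hc, 0, cohort$groups), "out of range")
  expect_error(cut_and_score(hc, n + 1, cohort$groups), "out of range")
})

test_that("ARI of a random labeling is near zero", {
  set.seed(29)
  m <- matrix(rbinom(40 * 60, 1, 0.5), nrow = 40,
              dimnames = list(paste0("g", 1:40), NULL))
  hc <- agglomerative_cluster(euclidean_distance_matrix(m))
  aris <- replicate(20, {
    random_labels <- setNames(sample(paste0("grp", 1:4), 40, replace = TRUE),
                              rownames(m))
    cut_and_score(hc, 4, random_labels)$ari
  })
  expect_lt(max(abs(aris)), 0.2)
})

test_that("marker hit filtering keeps exactly the qualifying hits, bounds inclusive", {
  hits <- rbind(
    make_hit(subject_id = "h1", align_length = 69, identity = 50, evalue = 1e-10),
    make_hit(subject_id = "h2", align_length = 70, identity = 20, evalue = 0.001),
    make_hit(subject_id = "h3", align_length = 200, identity = 19.9, evalue = 1e-10),
    make_hit(subject_id = "h4", align_length = 200, identity = 50, evalue = 0.002),
    make_hit(subject_id = "h5", align_length = 71, identity = 20.1, evalue = 1e-4),
    make_hit(subject_id = "h6", align_length = 70, identity = 95, evalue = 0),
    make_hit(subject_id = "h7", align_length = 100, identity = 30, evalue = 0.01),
    make_hit(subject_id = "h8", align_length = 500, identity = 99, evalue = 1e-100),
    make_hit(subject_id = "h9", align_length = 1, identity = 100, evalue = 1e-5),
    make_hit(subject_id = "h10", align_length = 150, identity = 25, evalue = 5e-4))
  kept <- select_marker_hits(hits)
  want <- hits[hits$align_length >= 70 & hits$identity >= 20 &
                 hits$evalue <= 0.001, ]
  expect_identical(kept, want)
  expect_identical(kept$subject_id, c("h2", "h5", "h6", "h8", "h10"))
  no_len <- hits
  no_len$align_length <- NULL
  expect_error(select_marker_hits(no_len), "align_length")
})

test_that("family sets validate structure and expected size", {
  reps <- data.frame(id = c("r1", "r2"), sequence = c("MKV", "AAW"),
                     taxon_id = NA, family_id = c("f1", "f2"),
                     stringsAsFactors = FALSE)
  fs <- reference_family_set("toy", reps, expected_size = 2)
  expect_equal(length(fs$families), 2)
  expect_error(reference_family_set("toy", reps, expected_size = 737),
               "expected 737")
  reps$family_id <- NULL
  expect_error(reference_family_set("toy", reps), "family_id")
})
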