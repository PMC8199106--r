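## Independent oracles, implemented in plain R with no code shared with the
## package internals they check.

## Brute-force affine-gap Smith-Waterman score (full-matrix DP, no
## traceback). Gap of length k costs open + k * ext.
oracle_sw_score <- function(q, s, mat, open = 11, ext = 1) {
  qc <- strsplit(q, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  m <- length(qc)
  n <- length(sc)
  NEG <- -1e9
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)
  F <- matrix(NEG, m + 1, n + 1)
  best <- 0
  for (i in seq_len(m) + 1) {
    for (j in seq_len(n) + 1) {
      E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + mat[qc[i - 1], sc[j - 1]],
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

## Step-by-step naive O(n^3) average-linkage (UPGMA) agglomeration:
## repeatedly merge the closest cluster pair (ties: smallest index pair),
## recomputing inter-cluster distances as the mean over all member pairs of
## the original distance matrix. Returns the merge heights in order.
oracle_average_linkage_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- Inf
    bi <- bj <- 0
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq(i + 1, length(clusters))) {
        dij <- mean(d[clusters[[i]], clusters[[j]]])
        if (dij < best) {
          best <- dij
          bi <- i
          bj <- j
        }
      }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

## random amino-acid sequence over the 20 standard residues
rand_aa <- function(len) {
  paste(sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], len, replace = TRUE),
        collapse = "")
}

## per-site identity of two equal-length sequences (no alignment)
site_identity <- function(a, b) {
  mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
}
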