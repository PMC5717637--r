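# Small fixtures built in code, shared across test files.

aln_from <- function(...) {
  v <- c(...)
  if (is.null(names(v))) names(v) <- paste0("s", seq_along(v))
  validateAlignment(v)
}

# genotype matrix helper: rows = samples, columns = loci
gt_from <- function(m) {
  genotypeTable(m)
}

# 2-allele locus-counts object from genotype counts (nAA, nAB, nBB)
lc2 <- function(nAA, nAB, nBB) {
  cnt <- matrix(0L, 2, 2)
  cnt[1, 1] <- as.integer(nAA)
  cnt[1, 2] <- as.integer(nAB)
  cnt[2, 2] <- as.integer(nBB)
  list(alleles = c("A", "B"), counts = cnt,
       alleleCounts = c(A = 2L * nAA + nAB, B = 2L * nBB + nAB),
       n = nAA + nAB + nBB)
}

# independent Levene probability for a 2-allele table (closed form)
levene_p2 <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  nA <- 2 * nAA + nAB
  nB <- 2 * nBB + nAB
  exp(lfactorial(n) - lfactorial(nAA) - lfactorial(nAB) - lfactorial(nBB) +
        nAB * log(2) + lfactorial(nA) + lfactorial(nB) - lfactorial(2 * n))
}

# brute-force union of all minimum spanning trees over a weight matrix:
# enumerate all spanning subsets of size n-1, keep those that are trees of
# minimum total weight, return the union of their edge sets
msn_bruteforce <- function(k) {
  n <- nrow(k)
  pairs <- which(upper.tri(k), arr.ind = TRUE)
  ne <- nrow(pairs)
  best <- Inf
  trees <- list()
  for (comb in asplit(combn(ne, n - 1), 2)) {
    sel <- pairs[comb, , drop = FALSE]
    # connectivity check by label propagation
    lab <- seq_len(n)
    for (e in seq_len(nrow(sel))) {
      a <- lab[sel[e, 1]]; b <- lab[sel[e, 2]]
      if (a != b) lab[lab == b] <- a
    }
    if (length(unique(lab)) != 1L) next
    w <- sum(k[sel])
    if (w < best - 1e-9) { best <- w; trees <- list(sel) }
    else if (abs(w - best) <= 1e-9) trees[[length(trees) + 1L]] <- sel
  }
  eds <- unique(do.call(rbind, trees))
  eds[order(eds[, 1], eds[, 2]), , drop = FALSE]
}

# random integer haplotype distance matrix that satisfies the triangle
# inequality (built from random points on a line of random sequences)
random_hap_distmat <- function(n, L = 12) {
  seqs <- replicate(n, paste(sample(c("A", "C", "G", "T"), L,
                                    replace = TRUE), collapse = ""))
  while (anyDuplicated(seqs)) {
    seqs <- replicate(n, paste(sample(c("A", "C", "G", "T"), L,
                                      replace = TRUE), collapse = ""))
  }
  names(seqs) <- paste0("h", seq_len(n))
  pairwisePDistance(validateAlignment(seqs))$k
}

expect_edge_set_equal <- function(edges_df, mat, ids) {
  got <- edges_df[, c("from", "to")]
  got <- got[order(got$from, got$to), ]
  want <- data.frame(from = ids[mat[, 1]], to = ids[mat[, 2]])
  want <- want[order(want$from, want$to), ]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
}
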