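test_that("p-distance matches hand counts and respects gap policy", {
  aln <- aln_from(s1 = "AAAA", s2 = "AATT")
  pd <- pairwisePDistance(aln)
  expect_equal(pd$d["s1", "s2"], 0.5)
  expect_equal(pd$k["s1", "s2"], 2)

  same <- aln_from(a = "ACGT", b = "ACGT")
  pds <- pairwisePDistance(same)
  expect_equal(pds$d["a", "b"], 0)
  expect_equal(pds$k["a", "b"], 0)

  # 41 differences out of 519 sites -> 7.9%
  base <- rep("A", 519)
  alt <- base
  alt[1:41] <- "C"
  pd519 <- pairwisePDistance(aln_from(x = paste(base, collapse = ""),
                                      y = paste(alt, collapse = "")))
  expect_equal(pd519$d["x", "y"], 41 / 519)
  expect_equal(round(100 * pd519$d["x", "y"], 1), 7.9)

  # pairwise deletion drops N/gap sites per pair
  gp <- pairwisePDistance(aln_from(a = "ACGTN", b = "ACCT-"))
  expect_equal(gp$sites["a", "b"], 4)
  expect_equal(gp$d["a", "b"], 1 / 4)
  # complete deletion drops the site for everyone
  cd <- pairwisePDistance(aln_from(a = "ACGTN", b = "ACCTA", c = "ACCTA"),
                          gapPolicy = "complete_deletion")
  expect_equal(unique(as.vector(cd$sites[upper.tri(cd$sites)])), 4)
  expect_error(pairwisePDistance(aln_from(a = "NNNN", b = "ACGT")),
               "undefined-distance")
})

test_that("haplotype collapsing counts exact matches, N distinct", {
  aln <- aln_from(a = "ACGT", b = "ACGT", c = "ACGT", d = "AGGT")
  hs <- collapseHaplotypes(aln)
  expect_equal(sort(unname(haplotypeFreq(hs)), decreasing = TRUE), c(3, 1))
  expect_equal(sum(haplotypeFreq(hs)), length(aln))

  distinct <- aln_from(a = "AAAA", b = "CCCC", c = "GGGG")
  expect_equal(unname(haplotypeFreq(collapseHaplotypes(distinct))),
               c(1, 1, 1))
  # N is a distinct character under exact matching
  withN <- aln_from(a = "ACGT", b = "ACGN")
  expect_equal(length(collapseHaplotypes(withN)@haplotypes), 2)
})

test_that("nucleotide diversity is the mean pairwise per-site distance", {
  two <- aln_from(a = paste(rep("A", 10), collapse = ""),
                  b = paste(c("C", rep("A", 9)), collapse = ""))
  expect_equal(nucleotideDiversity(two), 0.1)

  # independent recomputation: pi == mean of the d upper triangle
  set.seed(42)
  sim <- simulateMtdna(n = 8, thetaSite = 0.02, L = 300)
  pd <- pairwisePDistance(sim$aln)
  expect_equal(nucleotideDiversity(sim$aln), mean(pd$d[upper.tri(pd$d)]))
})

test_that("population size N = pi/4u reproduces published arithmetic", {
  ps <- populationSize(0.1035, c(drosophila = 6.2e-8, daphnia = 1.5e-7))
  expect_equal(ps$N_int, c(417338, 172500))
  expect_equal(populationSize(0, 1e-7)$N, 0)
  expect_error(populationSize(0.1, -1), "domain")
  # linear in pi, inverse-linear in u
  expect_equal(populationSize(0.2, 1e-7)$N, 2 * populationSize(0.1, 1e-7)$N)
  expect_equal(populationSize(0.1, 2e-7)$N, populationSize(0.1, 1e-7)$N / 2)
})

test_that("mismatch distribution conserves the pair count", {
  aln <- aln_from(a = "AAAA", b = "AAAC", c = "AACC")
  md <- mismatchDistribution(pairwisePDistance(aln))
  expect_equal(md$n_pairs, 3)
  expect_equal(sum(md$counts), choose(3, 2))
  expect_equal(unname(md$counts[c("1", "2")]), c(2, 1))

  same <- aln_from(a = "ACGT", b = "ACGT", c = "ACGT", d = "ACGT")
  mds <- mismatchDistribution(pairwisePDistance(same))
  expect_equal(unname(mds$counts["0"]), choose(4, 2))
})

test_that("bimodality calls separate two-cluster from single-cluster k", {
  expect_equal(bimodalityTest(rep(5, 20))$call, "unimodal")
  set.seed(1)
  sep <- c(rnorm(50, 2, 1), rnorm(50, 40, 1))
  expect_equal(bimodalityTest(sep)$call, "bimodal")
  # single-Gaussian inputs stay unimodal in >= 95% of replicates
  set.seed(2)
  calls <- replicate(100, bimodalityTest(rnorm(60, 10, 2))$call)
  expect_gte(mean(calls == "unimodal"), 0.95)
  # concatenated two-deme simulations give two separated modes
  set.seed(3)
  hit <- 0
  for (i in 1:10) {
    sim <- simulateMtdna(thetaSite = 0.05, L = 702, nA = 10, nB = 10,
                         splitDepth = 10)
    md <- mismatchDistribution(pairwisePDistance(sim$aln))
    if (bimodalityTest(md)$call == "bimodal") hit <- hit + 1
  }
  expect_gte(hit, 9)
})

test_that("minimum spanning network equals brute-force union of MSTs", {
  # hand cases
  k <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hs <- collapseHaplotypes(aln_from(A = "AAA", B = "AAC", C = "ACC"))
  net <- minimumSpanningNetwork(hs, k = k)
  expect_equal(nrow(networkEdges(net)), 2)
  expect_setequal(paste(networkEdges(net)$from, networkEdges(net)$to),
                  c("h1 h2", "h2 h3"))

  ktie <- matrix(1, 3, 3) - diag(3)
  net2 <- minimumSpanningNetwork(hs, k = ktie)
  expect_equal(nrow(networkEdges(net2)), 3)  # all tied edges retained

  single <- minimumSpanningNetwork(collapseHaplotypes(aln_from(A = "AAA")))
  expect_equal(nrow(networkEdges(single)), 0)

  # property: equivalence with all-MST union for random instances
  set.seed(99)
  for (rep in 1:25) {
    n <- sample(3:7, 1)
    k <- random_hap_distmat(n)
    edges <- haplodrift:::.msnEdges(k)
    want <- msn_bruteforce(k)
    got <- unique(edges[, c("from", "to")])
    got <- got[order(got$from, got$to), ]
    rownames(got) <- NULL
    expect_equal(as.matrix(got), matrix(want, ncol = 2,
                                        dimnames = list(NULL, c("from", "to"))))
  }
})

test_that("every spanning tree inside the MSN has minimum weight", {
  set.seed(7)
  k <- random_hap_distmat(6)
  edges <- haplodrift:::.msnEdges(k)
  want <- msn_bruteforce(k)
  # MSN contains a Kruskal MST: total weight of brute-force MST equals
  # the minimum spanning weight computed from the MSN edge subset
  msn_w <- sum(k[as.matrix(want)])
  expect_true(all(paste(want[, 1], want[, 2]) %in%
                    paste(edges$from, edges$to)))
  expect_equal(sort(unique(edges$steps)),
               sort(unique(k[as.matrix(edges[, c("from", "to")])])))
})

test_that("alignment trimming reproduces a 702 -> 519 bp cut", {
  s <- paste(sample(c("A", "C", "G", "T"), 702, TRUE), collapse = "")
  aln <- aln_from(a = s, b = s)
  tr <- trimAlignment(aln, 1, 519)
  expect_equal(unique(Biostrings::width(tr)), 519)
  expect_error(trimAlignment(aln, 0, 10), "outside")
})
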