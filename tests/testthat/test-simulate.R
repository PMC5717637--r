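test_that("zero mutation rate gives identical sequences and pi = 0", {
  set.seed(1)
  sim <- simulateMtdna(n = 6, thetaSite = 0, L = 100)
  expect_equal(length(unique(as.character(sim$aln))), 1)
  expect_equal(nucleotideDiversity(sim$aln), 0)
})

test_that("coalescent expectation: mean pi * L close to theta * L", {
  set.seed(2)
  reps <- 120
  piL <- replicate(reps,
    nucleotideDiversity(simulateMtdna(n = 20, thetaSite = 10 / 2000,
                                      L = 2000)$aln) * 2000)
  se <- sd(piL) / sqrt(reps)
  expect_lt(abs(mean(piL) - 10), 3 * se)
})

test_that("deep two-deme split yields bimodal mismatch distributions", {
  set.seed(3)
  hits <- replicate(15, {
    sim <- simulateMtdna(thetaSite = 0.05, L = 702, nA = 10, nB = 10,
                         splitDepth = 10)
    md <- mismatchDistribution(pairwisePDistance(sim$aln))
    bimodalityTest(md)$call == "bimodal"
  })
  expect_gte(mean(hits), 0.9)
  # and the split is recovered by haplogroup assignment
  sim <- simulateMtdna(thetaSite = 0.05, L = 702, nA = 10, nB = 10,
                       splitDepth = 10)
  hg <- assignHaplogroups(pairwisePDistance(sim$aln))
  truth <- rep(1:2, each = 10)
  expect_gte(abs(cor(hg, truth)), 0.99)
})

test_that("panmictic genotypes are calibrated under the HWE null", {
  set.seed(4)
  ps <- replicate(40, {
    d <- simulateGenotypes(scenarioSpec("panmictic_large_N", n = 100))
    lc <- locusCounts(d$gt, "L3")  # the 12-allele locus
    hweExact(lc, mode = "mc", chain = c(500, 20, 500))$p_deficit
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("cryptic pair: theta recovery and pooled-sample LD signal", {
  set.seed(5)
  ths <- replicate(10, {
    d <- simulateGenotypes(scenarioSpec("cryptic_pair", F = 0.3,
                                        n = 100, nAlleles = 4))
    weirCockerhamFst(d$gt, d$deme)$theta
  })
  expect_gt(mean(ths), 0.2)
  expect_lt(mean(ths), 0.4)

  # pooled-sample inter-locus association: the genotypic permutation G
  # test at the strict 0.005 threshold detects a third of locus pairs on
  # average at F = 0.3 (calibrated; per-pair power at this divergence is
  # well below 1), which is two orders of magnitude above the 0.5% null
  # rate
  fr <- replicate(6, {
    d <- simulateGenotypes(scenarioSpec("cryptic_pair", F = 0.3, n = 100,
                                        nAlleles = 4))
    ld <- ldTable(d$gt, nperm = 1000)
    mean(ld$p < 0.005)
  })
  expect_gte(mean(fr), 0.15)
})

test_that("trait simulator: unimodal when means equal, bimodal when apart", {
  set.seed(6)
  specU <- scenarioSpec("panmictic_large_N", n = 60)
  uni <- replicate(15, {
    tr <- simulateTraits(specU)
    bimodalityTest(tr$trait1)$call == "unimodal"
  })
  expect_gte(mean(uni), 0.9)
  specB <- scenarioSpec("hybrid_zone", n = 60, traitMeans = c(10, 20))
  deme <- setNames(rep(1:2, each = 30), sprintf("i%03d", 1:60))
  bi <- replicate(15, {
    tr <- simulateTraits(specB, deme = deme)
    bimodalityTest(tr$trait1)$call == "bimodal"
  })
  expect_gte(mean(bi), 0.95)
  # sd = 0: constant traits, unimodal by convention
  tr0 <- simulateTraits(scenarioSpec("panmictic_large_N", traitSD = 0))
  expect_equal(bimodalityTest(tr0$trait1)$call, "unimodal")
})

test_that("coordinates: flat panmictic surface, hybrid-zone ridge", {
  set.seed(7)
  flat <- replicate(10, {
    d <- simulateScenario(scenarioSpec("panmictic_large_N"))
    net <- connectivityNetwork(d$coords)
    mp <- midpointDistances(net, d$coords, pairwisePDistance(d$aln))
    g <- gridValues(interpolateSurface(mp, 20, 20, a = 1))
    max(g) / min(g)
  })
  expect_gte(mean(flat < 3), 0.8)

  ridge <- replicate(10, {
    d <- simulateScenario(scenarioSpec("hybrid_zone"))
    net <- connectivityNetwork(d$coords)
    mp <- midpointDistances(net, d$coords, pairwisePDistance(d$aln))
    g <- interpolateSurface(mp, 20, 20, a = 1)
    v <- gridValues(g)
    third <- length(g@x) %/% 3
    centre <- v[(third + 1):(2 * third), ]
    flank <- v[c(1:third, (2 * third + 1):length(g@x)), ]
    mean(centre) > mean(flank)
  })
  expect_gte(mean(ridge), 0.9)

  # single locality: landscape stage raises its documented error
  one <- data.frame(sample = "a", x = 0, y = 0, locality = "L1",
                    haplogroup = NA)
  expect_error(connectivityNetwork(one), "at least 2")
})

test_that("generators are reproducible bit-for-bit given a seed", {
  a <- simulateScenario(scenarioSpec("cryptic_pair"), seed = 99)
  b <- simulateScenario(scenarioSpec("cryptic_pair"), seed = 99)
  expect_identical(as.character(a$aln), as.character(b$aln))
  expect_identical(genotypeCalls(a$gt), genotypeCalls(b$gt))
  expect_identical(a$traits, b$traits)
  expect_identical(a$coords, b$coords)
})

test_that("population-size recovery through N = pi / 4u", {
  # simulate at a chosen N and u with theta = 4Nu, re-estimate N.  A
  # single non-recombining locus has an irreducible coalescent CV of
  # about sqrt(2/9) ~ 0.47 in pi, so the per-replicate relative error is
  # bounded by genealogy variance, not by the estimator: the median
  # relative error sits near 0.3 and the bound is calibrated accordingly.
  set.seed(8)
  N_true <- 250000; u <- 1e-7
  theta_site <- 4 * N_true * u    # 0.1 per site
  Nhat <- replicate(60, {
    aln <- simulateMtdna(n = 25, thetaSite = theta_site, L = 702)$aln
    populationSize(nucleotideDiversity(aln), u)$N
  })
  relerr <- abs(Nhat - N_true) / N_true
  expect_lt(median(relerr), 0.35)
  # the aggregate estimate across genealogies is close to truth
  expect_lt(abs(mean(Nhat) - N_true) / N_true, 0.2)
})
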