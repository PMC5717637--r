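#' Construct a validated RunConfig
#'
#' Numeric defaults are the conventional ones for this analysis: a 50 x
#' 50 interpolation grid with distance weighting a = 1, Markov chain
#' 10000 dememorization / 100 batches / 10000 iterations per batch,
#' mixture components 1-9, and three published per-site mtDNA mutation
#' rate estimates (fruit fly 6.2e-8, water flea 1.5e-7, nematode
#' 7.6e-8 per site per generation).
#'
#' @param seed integer random seed (mandatory; echoed in all outputs).
#' @param gridSize integer length-2 (nx, ny).
#' @param weightA IDW exponent.
#' @param chain Markov chain parameters (dememorization, batches,
#'   iterations per batch).
#' @param ldPermutations permutations for LD / differentiation G tests.
#' @param kRange mixture component counts tried.
#' @param mutationRates named per-site mutation rates.
#' @param stages stages to run.
#' @return A \code{\link{RunConfig}}.
#' @export
runConfig <- function(seed,
                      gridSize = c(50, 50),
                      weightA = 1,
                      chain = c(10000, 100, 10000),
                      ldPermutations = 10000L,
                      kRange = 1:9,
                      mutationRates = c(drosophila = 6.2e-8,
                                        daphnia = 1.5e-7,
                                        nematode = 7.6e-8),
                      stages = c("mtdna", "kaks", "landscape", "nuclear",
                                 "concordance", "verdict")) {
  new("RunConfig", seed = as.integer(seed),
      gridSize = as.integer(gridSize), weightA = as.numeric(weightA),
      chain = as.numeric(chain),
      ldPermutations = as.integer(ldPermutations),
      kRange = as.integer(kRange), mutationRates = mutationRates,
      stages = stages)
}

#' Simulate a complete scenario dataset
#'
#' Draws every pipeline input (mtDNA alignment, nuclear genotypes,
#' traits, coordinates, coding-sequence pair) with the statistical
#' structure the scenario's hypothesis predicts, plus ground-truth
#' labels.
#'
#' @param spec a \code{\link{scenarioSpec}}.
#' @param seed optional integer seed (set before all draws).
#' @return list with \code{aln}, \code{gt}, \code{traits}, \code{coords},
#'   \code{codingPair} and \code{truth} (deme and ancestry labels).
#' @export
simulateScenario <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  geno <- simulateGenotypes(spec)
  deme <- geno$deme
  ids <- names(deme)
  if (spec$scenario == "panmictic_large_N") {
    sim <- simulateMtdna(n = spec$n, thetaSite = spec$thetaSite,
                         L = spec$L)
    names(sim$aln) <- ids
  } else {
    ord <- order(deme)
    nA <- sum(deme == 1L)
    sim <- simulateMtdna(thetaSite = spec$thetaSite, L = spec$L,
                         nA = nA, nB = spec$n - nA,
                         splitDepth = spec$splitDepth)
    names(sim$aln) <- ids[ord]
    sim$aln <- sim$aln[match(ids, names(sim$aln))]
  }
  traits <- simulateTraits(spec, deme = deme)
  coords <- simulateCoordinates(spec, deme = deme,
                                ancestry = geno$ancestry)
  coding <- simulateCodingPair(
    regime = if (spec$scenario == "balancing_like") "diversifying"
             else "purifying")
  list(aln = sim$aln, gt = geno$gt, traits = traits, coords = coords,
       codingPair = coding,
       truth = list(deme = deme, ancestry = geno$ancestry,
                    tmrca = sim$tmrca))
}

#' Run the full discrimination pipeline
#'
#' Orchestrates the stages in dependency order (mtDNA diversity ->
#' selection / landscape / nuclear cohesion -> concordance -> verdict),
#' derives the evidence flags and returns a result bundle holding every
#' per-stage table, the evidence summary and the configuration.  Partial
#' runs (subset of stages) are allowed; missing flags make the verdict
#' \code{inconclusive}.  Identical config and seed reproduce identical
#' results.
#'
#' Flag derivations: the three nuclear cohesion statistics (global HWE
#' deficit/excess, the LD test family, F_ST) jointly test the single
#' hypothesis of one randomly mating population and are controlled
#' familywise at alpha = 0.05 (Bonferroni: 0.05/3 each, HWE additionally
#' two-sided, LD additionally Bonferroni across locus pairs); \code{kappa_concordant} — majority-mapped Cohen's kappa
#' between the PC1-5 clusters and the mtDNA haplogroups >= 0.75;
#' \code{spatial_partition} — surface max/min ratio >= 3;
#' \code{traits_bimodal} — mixture BIC prefers two components for any
#' trait.
#'
#' @param config \code{\link{RunConfig}}.
#' @param aln \code{DNAStringSet} mtDNA alignment (ids = sample ids).
#' @param gt \code{GenotypeTable} of nuclear loci.
#' @param traits data.frame of numeric traits (rownames = sample ids).
#' @param coords coordinate data.frame (see \code{\link{readCoords}}).
#' @param codingPair 2-record \code{DNAStringSet} of in-frame coding
#'   concatenations for Ka/Ks.
#' @param nPCs principal components fed to the clustering (default 5).
#' @return A StageResultBundle: list with \code{tables} (per-stage data
#'   frames), \code{evidence} (\code{\link{EvidenceSummary}}),
#'   \code{haplogroups}, \code{config}.
#' @export
runPipeline <- function(config, aln = NULL, gt = NULL, traits = NULL,
                        coords = NULL, codingPair = NULL, nPCs = 5) {
  validObject(config)
  stages <- config@stages
  need <- function(stage, ...) {
    inputs <- list(...)
    miss <- names(inputs)[vapply(inputs, is.null, TRUE)]
    if (length(miss))
      stop("missing input for enabled stage '", stage, "': ",
           paste(miss, collapse = ", "))
  }
  # validate inputs for all enabled stages before any computation
  if ("mtdna" %in% stages) need("mtdna", aln = aln)
  if ("kaks" %in% stages) need("kaks", codingPair = codingPair)
  if ("landscape" %in% stages) need("landscape", aln = aln,
                                    coords = coords)
  if ("nuclear" %in% stages) need("nuclear", aln = aln, gt = gt)
  if ("concordance" %in% stages) need("concordance", aln = aln, gt = gt,
                                      traits = traits)
  set.seed(config@seed)
  tables <- list()
  flags <- list(spatial_partition = NA, hwe_ok = NA, ld_free = NA,
                fst_zero = NA, kappa_concordant = NA, traits_bimodal = NA)
  kaksR <- NA_real_
  haplogroups <- NULL
  pd <- NULL

  if (!is.null(aln)) {
    pd <- pairwisePDistance(aln)
    haplogroups <- assignHaplogroups(pd, k = 2)
  }

  if ("mtdna" %in% stages) {
    pi <- mean(pd$d[upper.tri(pd$d)])
    hs <- collapseHaplotypes(aln)
    md <- mismatchDistribution(pd)
    bi <- bimodalityTest(md)
    Ns <- populationSize(pi, config@mutationRates)
    tables$mtdna <- rbind(
      data.frame(stat = "pi", value = pi),
      data.frame(stat = "n_haplotypes",
                 value = length(hs@haplotypes)),
      data.frame(stat = "max_p_distance", value = max(pd$d)),
      data.frame(stat = "mismatch_call_bimodal",
                 value = as.numeric(bi$call == "bimodal")),
      data.frame(stat = paste0("N_", Ns$rate), value = Ns$N_int))
    tables$mismatch <- data.frame(k = as.integer(names(md$counts)),
                                  count = md$counts)
  }
  if ("kaks" %in% stages) {
    kk <- kaksRatio(codingPair)
    kaksR <- if (kk$ratio_defined) kk$ratio else NA_real_
    tables$kaks <- data.frame(S = kk$S, N = kk$N, Sd = kk$Sd, Nd = kk$Nd,
                              ps = kk$ps, pn = kk$pn, Ka = kk$Ka,
                              Ks = kk$Ks, ratio = kk$ratio,
                              dropped_codons = kk$dropped_codons)
  }
  if ("landscape" %in% stages) {
    net <- connectivityNetwork(coords)
    mp <- midpointDistances(net, coords, pd, mode = "raw")
    grid <- interpolateSurface(mp, nx = config@gridSize[1],
                               ny = config@gridSize[2],
                               a = config@weightA)
    v <- grid@values
    ratio <- if (min(v) > 0) max(v) / min(v) else Inf
    flags$spatial_partition <- is.infinite(ratio) || ratio >= 3
    tables$landscape <- gridToTable(grid)
  }
  if ("nuclear" %in% stages) {
    hw <- hweTable(gt, mode = "auto", chain = config@chain)
    gd <- multilocusHWE(gt, "deficit", chain = config@chain)
    ge <- multilocusHWE(gt, "excess", chain = config@chain)
    hw <- rbind(hw,
      data.frame(locus = "__global__", n_alleles = NA, n = NA,
                 p_prob = NA, p_deficit = gd$p, p_excess = ge$p,
                 se_prob = NA, se_deficit = gd$se, se_excess = ge$se,
                 method = "mc", flag = "multilocus"))
    # the three cohesion statistics (global HWE, the LD family, F_ST)
    # jointly test one hypothesis -- a single randomly mating
    # population -- and are controlled familywise at alpha = 0.05
    # (Bonferroni across the battery; HWE additionally two-sided)
    aCoh <- 0.05 / 3
    flags$hwe_ok <- gd$p >= aCoh / 2 && ge$p >= aCoh / 2
    tables$hwe <- hw
    ld <- ldTable(gt, nperm = config@ldPermutations)
    bf <- bonferroni(ld$p, alpha = 0.05)   # conventional per-pair column
    ld$significant <- bf$significant
    flags$ld_free <- !any(bonferroni(ld$p, alpha = aCoh)$significant)
    tables$ld <- ld
    fst <- weirCockerhamFst(gt, haplogroups)
    fp <- fstPermutationTest(gt, haplogroups,
                             nperm = min(1000, config@ldPermutations))
    flags$fst_zero <- fp$p >= aCoh
    tables$fst <- rbind(fst$perLocus,
                        data.frame(locus = "__multilocus__", a = NA,
                                   b = NA, c = NA, theta = fst$theta))
  }
  if ("concordance" %in% stages) {
    m <- encodeMatrix(gt, traits)
    pca <- pcaScores(m, centre = FALSE, scale = TRUE)
    k5 <- min(nPCs, ncol(pca$scores))
    cl5 <- gmmCluster(pca$scores[, seq_len(k5), drop = FALSE],
                      kRange = config@kRange)
    cl2 <- gmmCluster(pca$scores[, seq_len(min(2, k5)), drop = FALSE],
                      kRange = config@kRange)
    hg <- haplogroups[rownames(m)]
    # concordance scores the BIC-selected clustering against the mtDNA
    # partition after majority mapping: a finer clustering nested
    # cleanly inside the haplogroups is concordant, whereas clusters
    # cutting across them stay far below the 0.75 threshold
    kap <- cohensKappa(cl5$classification[rownames(m)], hg,
                       match = "majority")
    kap12 <- cohensKappa(cl2$classification[rownames(m)], hg,
                         match = "majority")
    flags$kappa_concordant <- kap$kappa >= 0.75
    tb <- vapply(traits, function(x)
      bimodalityTest(x)$call == "bimodal", TRUE)
    flags$traits_bimodal <- any(tb)
    tables$clusters <- data.frame(sample = rownames(m),
                                  haplogroup = hg,
                                  cluster_pc12 = cl2$classification,
                                  cluster_pc15 = cl5$classification)
    tables$kappa <- data.frame(
      comparison = c("haplogroup_vs_pc15", "haplogroup_vs_pc12"),
      kappa = c(kap$kappa, kap12$kappa),
      p_o = c(kap$p_o, kap12$p_o),
      p_e = c(kap$p_e, kap12$p_e),
      k_bic = c(cl5$k, cl2$k))
  }
  evidence <- NULL
  if ("verdict" %in% stages) {
    evidence <- evidenceSummary(
      kaksRatio = kaksR,
      spatial_partition = flags$spatial_partition,
      hwe_ok = flags$hwe_ok, ld_free = flags$ld_free,
      fst_zero = flags$fst_zero,
      kappa_concordant = flags$kappa_concordant,
      traits_bimodal = flags$traits_bimodal,
      provenance = c(spatial_partition = "landscape", hwe_ok = "nuclear",
                     ld_free = "nuclear", fst_zero = "nuclear",
                     kappa_concordant = "concordance",
                     traits_bimodal = "concordance"))
  }
  list(tables = tables, evidence = evidence, haplogroups = haplogroups,
       config = config)
}
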