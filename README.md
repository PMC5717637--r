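# haplodrift

Deep mitochondrial divergence inside a single population sample — two or
more haplotype clusters separated by a "barcoding gap" of several percent —
is routinely read as evidence of cryptic species.  Coalescent theory says
otherwise: a non-recombining locus in a large, stable population is
*expected* to show strongly correlated, often bimodal pairwise differences
with no taxonomic meaning.  `haplodrift` is an R package for deciding,
from one sample, among the four processes that produce such a pattern:

| hypothesis | fingerprint the pipeline looks for |
|---|---|
| large population (drift–mutation equilibrium) | Ka/Ks ≪ 1; nuclear genome cohesive (HWE, no LD, F<sub>ST</sub> ≈ 0); clusters discordant with mtDNA; no spatial structure |
| balancing selection | Ka/Ks ≥ 1 |
| cryptic species | heterozygote deficit / LD / F<sub>ST</sub> > 0, with nuclear clusters concordant with the mtDNA groups (Cohen's κ ≥ 0.75) |
| introgression (hybrid zone) | geographically localized genetic-distance ridge plus bimodal trait distributions |

The core quantities, in the field's standard notation: nucleotide
diversity π (Tajima) and the equilibrium population size **N = π/4u**;
uncorrected p-distances and the mismatch distribution with a 1-vs-2
component mixture BIC bimodality call; the ε = 0 **minimum spanning
network** (union of all minimum spanning trees); **Nei–Gojobori** Ka/Ks
with Jukes–Cantor correction under the invertebrate mitochondrial code;
exact (Levene) and Markov chain (Guo–Thompson switching, in C++)
**Hardy–Weinberg** tests with batch standard errors; permutation **G
tests** for genotypic LD and differentiation; **Weir–Cockerham θ**;
"genetic landscape shape" inverse-distance-weighted surfaces over a
Delaunay connectivity network; allele-dosage PCA + **mclust** GMM-BIC
clustering scored by **Cohen's κ**; and a rule-based verdict engine.
A coalescent scenario simulator generates data under each hypothesis so
the whole procedure is testable end to end.

## Worked example

Simulate the drift hypothesis (deep mtDNA clades in one randomly mating
population) and run the full pipeline:

```r
library(haplodrift)

spec <- scenarioSpec("panmictic_large_N")   # 58 samples, 5 loci, 702 bp
d    <- simulateScenario(spec, seed = 1)
cfg  <- runConfig(seed = 1, chain = c(1000, 100, 1000),
                  ldPermutations = 2000)
res  <- runPipeline(cfg, aln = d$aln, gt = d$gt, traits = d$traits,
                    coords = d$coords, codingPair = d$codingPair)
res$evidence
```

```
EvidenceSummary -> verdict: large_population
  Ka/Ks: 0.0366 | spatial_partition=no hwe_ok=yes ld_free=yes fst_zero=yes kappa_concordant=no traits_bimodal=no
  - Ka/Ks = 0.0366 (balancing selection requires >= 1)
  - nuclear cohesion (HWE/LD/F_ST ok): TRUE/TRUE/TRUE
  - cluster concordance with mtDNA groups: FALSE
  - spatial partition: FALSE; traits bimodal: FALSE
  - rule fired: large_population
```

Reading the output: the simulated coding pair shows strong purifying
constraint (Ka/Ks = 0.04, far below the neutral value of 1); the nuclear
sample passes the cohesion battery (random mating, no inter-locus
association, θ indistinguishable from 0 between the two mtDNA
haplogroups); the genotype/trait clusters do not line up with the mtDNA
groups; and the genetic landscape is flat.  Every alternative fingerprint
is absent, so the deep mtDNA gap is attributed to drift in a large
population.  `res$tables$mtdna` holds π and the population-size estimates
(e.g. π = 0.1035 with the fruit-fly rate u = 6.2e-8 gives N = 417 338;
with the water-flea rate 1.5e-7, N = 172 500), and
`writeReport(res, "out/")` writes every stage table plus a
machine-readable `verdict.json`.

Published desk values reproduce directly:

```r
populationSize(0.1035, c(drosophila = 6.2e-8, daphnia = 1.5e-7))$N_int
#> [1] 417338 172500
tab <- wetaClusterAssignments()   # 29 tree weta, shipped with the package
cohensKappa(tab$haplogroup, tab$cluster_pc15,
            labelMap = c("2" = "1", "3" = "2"))$kappa
#> [1] -0.05072464
```

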