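---
title: "Discriminating explanations for deep mtDNA divergence within one population"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating explanations for deep mtDNA divergence within one population}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A sample of animals from a single locality sometimes contains mitochondrial
haplotypes that differ by far more than the few percent conventionally taken
to separate species, with the pairwise differences forming two or more
well-separated clusters (a "barcoding gap").  Read naively, such a gap is
evidence of cryptic species.  But at least four distinct processes produce
it:

1. **Drift–mutation equilibrium in a large population.**  A non-recombining
   locus shares one genealogy; the deep branches of a coalescent tree in a
   large, stable population make pairwise differences strongly correlated
   and typically bimodal, with no taxonomic meaning.
2. **Balancing selection** maintaining divergent functional mtDNA variants.
3. **Cryptic species** — two reproductively isolated gene pools sampled
   together.
4. **Introgression** — recent hybridization importing a divergent mtDNA
   lineage, usually geographically localized.

The four leave different fingerprints in data the mtDNA itself cannot
provide: nuclear genotypes, morphometric traits, and the geography of the
sampling.  `haplodrift` implements the full decision procedure: each stage
produces an evidence flag, and a rule engine maps the flags to a verdict.

## Stages and their models

### mtDNA diversity

Pairwise distances are uncorrected p-distances (`pairwisePDistance`),
counted over sites where both sequences hold a plain base; sites with N or
a gap are excluded per pair (an INDEL-prone tRNA region inside a
cytb–ND1 fragment should be trimmed first with `trimAlignment`, e.g.
702 → 519 bp).
Nucleotide diversity is Tajima's estimator,
$\pi = \binom{n}{2}^{-1}\sum_{i<j} d_{ij}$, and the equilibrium population
size is $N = \pi / 4u$ for a per-site per-generation mutation rate $u$
(`populationSize`; three published invertebrate rates are the default).
Haplotypes are collapsed by exact matching (N distinct, so an ambiguous
sequence never silently merges), and the haplotype network is the
$\varepsilon = 0$ minimum spanning network: the union of *all* minimum
spanning trees, computed by processing edge-weight classes in ascending
order against the component structure as it stood before the class began.
Ties are never broken arbitrarily; all tied connections are kept.

The mismatch distribution (histogram of pairwise difference counts) is
summarised by a one- versus two-component univariate Gaussian mixture
comparison, BIC $= 2\log L - m\log n$ (larger better).  We call a
distribution bimodal only when (i) the two-component model wins on BIC and
(ii) the fitted two-component density actually has two local maxima.  The
second condition is deliberate: on tied, half-unit-rounded counts a
two-component fit often places a narrow component on a spike inside a
unimodal distribution — a better BIC, but not two modes, and calling it
bimodal would be a false alarm.

### Selection (Ka/Ks)

`kaksRatio` implements Nei–Gojobori counting with Jukes–Cantor correction
under the invertebrate mitochondrial code (translation table 5; the code is
an argument).  Per codon, the synonymous site count is the fraction of the
nine single-nucleotide changes that preserve the amino acid; differences
between codons are averaged over all orderings of single-step pathways,
excluding pathways through stop codons (if every pathway is blocked, all
are used with steps into or out of a stop counted as nonsynonymous).
$K_s = -\tfrac{3}{4}\log(1 - \tfrac{4}{3}p_s)$, likewise $K_a$; the ratio
is undefined (flagged, never silently NaN) when $K_s = 0$, and proportions
at or beyond $3/4$ raise a saturation error.  A ratio well below 1 means
purifying selection — the expectation for mtDNA in a large population — and
a ratio at or above 1 is the balancing-selection signature.  The
maximum-likelihood family of estimators is intentionally out of scope; the
counting estimator is the one validated here against an enumeration oracle.

### Genetic landscape shape

The spatial stage reproduces the "genetic landscape shape" construction: a
Delaunay connectivity network over locality centroids (empty-circumcircle
rule, $O(n^4)$ — locality counts are small; collinear localities fall back
to a path graph), the mean inter-locality p-distance $Z_i$ assigned to each
edge midpoint $(X_i, Y_i)$, and inverse-distance-weighted interpolation
$\hat z(g) = \sum_i w_i Z_i / \sum_i w_i$, $w_i = d(g, i)^{-a}$, on a
uniform grid spanning the midpoint bounding box expanded by 2.5% per side
(so no midpoint sits on the border).  Defaults are a 50 × 50 grid and
$a = 1$; surfaces are qualitatively stable across grid sizes (rank
correlation > 0.95 between 50² and 100² in the test suite) and $a \in
[0.5, 2]$.  Coordinates are treated as planar decimal degrees — the
convention of the landscape-genetics tool this stage mirrors — and raw or
residual (regression on edge length) distances are supported.  Peaks are
not detected programmatically; the surface max/min ratio ≥ 3 is the
pipeline's spatial-partition flag.

### Nuclear cohesion

Hardy–Weinberg tests condition on the allele counts (Levene's
distribution).  For few alleles the probability test is evaluated by full
enumeration of genotype tables; otherwise a Guo–Thompson style switching
chain (two random individuals swap one allele each; Metropolis–Hastings
acceptance from the Levene probability and the pathway proposal
probabilities) is run with the conventional chain sizes — 10 000
dememorization steps, 100 batches, 10 000 iterations per batch — and
p-values carry batch standard errors.  One-sided deficit/excess tests use
the total heterozygote count as score statistic; the multilocus global test
sums the per-locus statistic across independent chains per iteration.
The chain is implemented in C++ so the full-size chains run in seconds;
tests and examples use shorter chains (stated inline) because the MC/
enumeration agreement is checked at 3 batch-SEs, which is chain-length
independent.

Genotypic linkage disequilibrium uses the log-likelihood-ratio G statistic
on the genotype × genotype table with a permutation null (one locus
shuffled across individuals); genotypic differentiation applies the same
machinery to deme × genotype tables with Fisher's combination across loci.
$F_{ST}$ is the Weir–Cockerham (1984) estimator: variance components
$a, b, c$ per allele summed within loci, multilocus
$\theta = \sum a / \sum (a+b+c)$, with a label-permutation test for
departure from zero.  The estimator is exactly 1 for fixed differences and
negatively biased near zero — a negative $\theta$ in a pooled sample is
evidence *against* hidden structure, not a pathology.

**Familywise control.**  The three cohesion statistics (global HWE, the LD
family, $F_{ST}$) jointly test one hypothesis — that the sample is a single
randomly mating population — so the pipeline's flags control them
familywise at $\alpha = 0.05$ (Bonferroni, $0.05/3$ each; HWE additionally
two-sided, LD additionally Bonferroni across its locus pairs).  Testing
each at 0.05 would compound to a ~15–20% false-alarm rate for the
conjunction and routinely misclassify genuinely panmictic samples.  The
per-pair LD table still reports the conventional family-level 0.05
Bonferroni column (0.005 at ten pairs).

### Concordance and the verdict

Genotypes are coded one column per observed allele with dosage 0/1/2
(columns of a locus sum to 2 for complete genotypes; missing calls are
mean-imputed and flagged), traits appended as single columns.  PCA follows
the convention established for allele-dosage data: no centring, columns
scaled by their root mean square about zero (`prcomp(..., center = FALSE,
scale. = TRUE)`); both options are exposed.  The first five components
feed Gaussian-mixture model-based clustering with BIC over 1–9 components
across the covariance families of **mclust** (the clustering tool the
field uses; its agglomerative initialisation makes fits deterministic).

Cluster/haplogroup agreement is Cohen's
$\kappa = (p_o - p_e)/(1 - p_e)$, with $\kappa \ge 0.75$ read as
non-random concordance.  Three label-handling modes exist because label
handling is where κ is most easily abused: an explicit `labelMap`
(default; nothing is matched silently), an opt-in bijective best-match,
and an opt-in majority (many-to-one) mapping.  The pipeline uses the
majority mapping of the BIC-selected clusters onto the haplogroups: on
discrete dosage data BIC often prefers a finer clustering *nested inside*
the true groups, which any two-label κ would misread as discordance,
while clusters cutting across the haplogroups stay near κ = 0 under the
same mapping (measured at the shipped presets: panmictic κ ≤ 0.18,
isolated demes κ ≥ 0.9).  Majority mapping inflates agreement when there
are many small clusters, which is why the threshold sits at 0.75 and the
mapping is never applied silently outside the pipeline.

The verdict engine is a total function over the flags:
balancing selection iff Ka/Ks ≥ 1; cryptic species iff any cohesion flag
fails *and* clusters are concordant; introgression iff spatial partition
*and* bimodal traits; large population iff everything is clean (Ka/Ks < 1,
cohesion holds, no concordance, no spatial structure).  One refinement to
a plain one-rule table: when the cryptic-species and introgression rules
fire together the verdict is introgression, because a sampled hybrid zone
necessarily breaks nuclear cohesion too (Wahlund heterozygote deficit,
admixture LD) and often shows mtDNA/nuclear concordance among pure
parentals, whereas cryptic species carry no expectation of geographic
localisation — the spatial evidence is what discriminates.  Any other
multiple firing, and any missing flag, yields `inconclusive`, never an
error.

## The synthetic scenarios

`simulateScenario` generates every input under the four hypotheses, with
defaults mirroring the tree wētā exemplar: 58 individuals (two 29-sample
haplogroup-sized demes where demes exist), five nuclear loci with 2, 2,
12, 3 and 3 alleles, a 702-bp mtDNA fragment, half-unit-rounded trait
counts on the stridulatory-ridge/tibia-spine scale, and eight localities
sampled in near-equal numbers (a balanced design, as a field survey would
aim for).

* **mtDNA** comes from a Kingman coalescent (waiting times
  $\sim$ Exp$(k(k-1)/2)$) with mutations Poisson-placed on branches at rate
  $\theta_{site} L/2$, finite-sites by default.  θ follows the 4Nu
  convention so that $N = \pi/4u$ recovers the simulated size — note this
  is the convention of the population-size equation used here, not the
  2N<sub>f</sub>u convention usual for maternally inherited loci.
  The two-deme variant restricts coalescence to within demes until the
  split time (default 10 coalescent units: reciprocally monophyletic,
  deeply divergent clades).
* **Nuclear genotypes**: panmictic draws are exactly Hardy–Weinberg given
  Dirichlet allele frequencies; isolated demes diverge by a
  Balding–Nichols construction with parameter F.  The cryptic pair
  defaults to F = 0.7 — isolation deep enough to sort the mtDNA into
  reciprocally monophyletic clades implies near-complete nuclear
  frequency divergence — while hybrid-zone parentals default to F = 0.3
  (younger lineages in secondary contact).  The hybrid zone adds 30%
  F1/backcross individuals drawing alleles from both parental pools.
* **Traits** are per-deme normal draws rounded to half units; means are
  equal except in the hybrid zone (10 vs 20, sd 1), where selection
  against hybrids predicts a bimodal distribution.
* **Coordinates**: hybrid-zone parentals occupy west/east localities with
  mixed-ancestry individuals in a central band, producing the
  interpolated ridge; all other scenarios are sympatric and flat.
* The **balancing-like** scenario keeps free nuclear exchange and deep
  mtDNA clades but draws the coding-region pair under a diversifying
  regime (80% of accepted changes nonsynonymous); the purifying regime
  used by the other scenarios accepts 5% — forward simulation with
  explicit fitness is out of scope.

What the generators deliberately do not emulate: recombination, selection
with explicit fitness coefficients, demographic growth or decline,
genotyping error and null alleles, and non-planar geography.  Passing
end-to-end tests therefore shows the decision procedure is sound when each
hypothesis's signature is present as modelled — not that real data cannot
present mixtures or intermediates of those signatures.

## Numerical choices and degenerate inputs

* Exact HWE enumeration is used up to 3 alleles (or any 2-allele table);
  beyond that the switching chain with batch SEs.  Enumeration
  probabilities sum to 1 within 1e-10 (asserted in tests); ties in the
  probability test are included at a 1e-9 log tolerance.
* Monomorphic loci: HWE and LD p-values are 1 with an explicit
  "test undefined" flag, never NA.
* A pair of sequences with no comparable sites, a zero-RMS column under
  scaling, a stop codon inside a coding sequence, an unwritable report
  path — all raise named errors; nothing is silently dropped.
* Mixture fits that collapse (vanishing covariance) are excluded from the
  BIC table with a warning, not fatal; component counts ≥ n are skipped.
* Degenerate geography: two localities connect by a single edge, collinear
  localities by a path graph; a node coinciding with a midpoint takes that
  midpoint's value exactly.
* All randomness flows from the single seed in `RunConfig`; reruns are
  byte-identical (asserted on file hashes).

A note on calibration: the per-replicate error of $N = \pi/4u$ is bounded
below by coalescent genealogy variance — for one non-recombining locus the
CV of π approaches $\sqrt{2/9} \approx 0.47$ regardless of sequence length
or sample size — so the recovery test asserts a median relative error
below 0.35 (measured ≈ 0.27–0.31 at the simulated settings) and a
20% bound on the aggregate mean, not a tighter figure no single-locus
estimator can attain.

## Problem sizes used by the test suite

The suite fits its validation budget by choice of problem size, stated
here as the package's own: Markov chains of 500–1000 dememorization /
50–100 batches / 200–1000 iterations per batch in tests (the 3-SE
agreement criterion is chain-length independent); 500–2000 permutations
for G tests; 200 random ≤ 7-haplotype instances against the brute-force
all-MST oracle; 100 random 30-codon pairs against the pathway-enumeration
oracle; every 2-allele table with n ≤ 30 against enumeration; 200
coalescent replicates for the E(π) check; and 20 seeded replicates per
scenario for end-to-end verdict recovery.

## Known limitations

* The Ka/Ks stage is the counting estimator only; for divergences where
  pathway saturation matters, an ML estimator should be preferred.
* Haplogroup assignment cuts the distance tree at k = 2 by default; more
  than two deep clades require the caller to set k.
* The landscape stage is planar; at continental scales great-circle
  distances (exposed as an option in the distance utilities) and a
  projection would be needed.
* Cohen's κ is reported without a significance test, as agreement
  thresholds (≥ 0.75) are the working convention.
* The verdict engine is deliberately coarse: it weighs flags, not effect
  sizes, and mixed or intermediate histories land on `inconclusive`.
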