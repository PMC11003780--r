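---
title: "Quantifying genetic parallelism of marine-freshwater adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying genetic parallelism of marine-freshwater adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fwparallel)
```

## The scientific problem

When a marine fish lineage repeatedly invades freshwater, the colonists can
reuse the same adaptive haplotypes, drawn from standing genetic variation in
the marine source population. The degree of such *genetic parallelism*
varies with demographic history: isolated freshwater populations drift,
bottleneck and inbreed, while connected ones keep exchanging genes with the
sea. `fwparallel` quantifies parallelism from SNP data in genomic regions
where marine and freshwater ecotypes carry distinct, tightly linked
haplotype groups (high-LD clusters, some of which are chromosomal
inversions), and pairs that scoring with standard genetic-diversity
analyses (nucleotide diversity, heterozygosity, runs of homozygosity,
F~ST~) so both questions — how much diversity was lost, and how parallel is
adaptation — can be asked of the same dataset.

## The scoring model

For each LD cluster the package fits, per individual, the probability of
carrying the freshwater haplotype:

1. **Cluster PCA.** Genotypes at the cluster's loci are centered at
   $2\hat p$ and scaled by $\sqrt{2\hat p(1-\hat p)}$ per locus and
   decomposed by SVD. Two pathways are provided, mirroring the two ways
   practitioners handle unequal sample sizes and genotype uncertainty:
   `method = "gl"` uses expected dosages from genotype likelihoods over
   *all* samples; `method = "projected"` fits the PCA on the reference
   (training) samples only — hard calls, missing data imputed by the
   population mean, loci with more than 20% missing data removed — and
   projects every other sample with the training constants. Projection
   with training constants makes self-projection exact, which the test
   suite asserts to 1e-8. Because these loci separate ecotypes, PC1 is the
   ecotype axis; its sign is fixed so the freshwater training centroid is
   positive.
2. **QDA with model selection.** On the training individuals' scores we
   fit quadratic discriminant models using the first 1, 2, 3 and 4
   components, score each by leave-one-out cross-validation at a 0.5
   posterior threshold, and keep the most accurate model (ties go to the
   fewest components). A cluster is *retained* only when the chosen
   accuracy is strictly above 0.75.
3. **PFG and PI.** The QDA posterior of the freshwater class, computed in
   log space, is the Probability of Freshwater Genotype (PFG) of each
   individual in that cluster. The Parallelism Index (PI) of a population
   is the mean PFG across its individuals, averaged (unweighted) across
   retained clusters — the expected proportion of freshwater-adapted
   haplotype carriers.

### Numerical choices in the classifier

Class covariances are the unbiased sample covariances, with two
safeguards. First, any covariance whose condition number exceeds 1e10 is
ridged until well conditioned. Second, every class covariance has its
eigenvalues floored at 1% of the total training-score variance. The floor
matters for near-fixed clusters: when both classes are almost point
masses, the class variance estimates are sampling noise, and the posterior
for a genuinely intermediate individual (a heterozygous inversion
karyotype, say) would otherwise be decided by the arbitrary ratio of two
noise terms — coherently for all intermediate individuals in the cluster.
With the floor, such individuals are assigned by distance to the class
centroids, and their population-mean PFG correctly estimates the
freshwater-haplotype frequency. Classes with genuine variance on the
problem scale are unaffected, and the package's posterior agrees with an
independent implementation (and with `MASS::qda`) to high precision on
well-conditioned data.

Priors default to training class proportions (the common library default);
an equal-priors mode exists because training designs are often
habitat-unbalanced. The LOO threshold is fixed at posterior 0.5; a fold
whose refit is impossible counts as incorrect.

## Diversity analyses

* **Folded SFS, π and H~O~.** Per population, minor-allele counts are
  tallied per site; sites with differing numbers of called chromosomes are
  projected hypergeometrically down to the population's minimum complete
  count, which keeps π unbiased under random missingness. π is the
  standard folded-spectrum form
  $\sum_j j(n-j)\eta_j / \binom{n}{2} / L$, verified in the tests against
  a brute-force mean pairwise difference (exact on complete data). H~O~ is
  the per-individual heterozygous fraction of called sites.
* **ROH.** A two-state HMM over each chromosome's sites, emission-aware of
  genotype likelihoods: the non-autozygous state emits under Hardy-
  Weinberg at the population allele frequency, the autozygous state emits
  homozygotes (with a residual heterozygote probability, default 0.01, for
  genotyping error). Transition probabilities over an inter-site gap of
  $d$ bp are $1-e^{-\rho d}$ with default entry and exit intensities of
  5e-9 and 5e-7 per bp (prior tract scale of megabases, stationary
  autozygosity about 1%). The Viterbi path is decoded — verified against
  exhaustive path enumeration on small instances — segments need at least
  10 sites, and per-segment posteriors (forward-backward) are reported for
  diagnostics. F~ROH~ uses no length cut-off; the genome length defaults
  to the summed span of observed positions per chromosome, because an
  assembly length is not always at hand, and can be overridden.
* **F~ST~.** Weir-Cockerham (1984) two-population θ, combined across loci
  as a ratio of sums. Negative estimates near zero are reported as
  computed. Populations with fewer than two individuals are dropped before
  the pairwise matrix.
* **Site filters** read their inequalities literally: genotypes kept when
  GQ is strictly above the threshold, sites kept when missingness is
  strictly below and minor allele frequency strictly above theirs; the GQ
  mask is applied before the missingness fraction is computed (the
  conservative order). Distance thinning is the greedy per-chromosome
  "no closer than" rule, so a gap exactly equal to the minimum is kept.

## Regional statistics

Population-level π is modelled by OLS on latitude and habitat and
population-mean F~ROH~ by a gamma GLM with log link (IRLS, relative
tolerance 1e-8, Pearson dispersion), habitat coded marine = 1 (the coding
is recorded in every fit object). Sequential (type-I) F tests are reported
in the order latitude then habitat. One-way ANOVAs (groups with fewer than
two observations removed first) compare π and PI across regions, with
Tukey post-hoc tests — the Kramer unequal-n correction by default,
coinciding with plain HSD at equal sizes. The intraclass correlation
ICC(1) of latitude grouped by habitat, with the average group size in the
denominator, serves as the predictor-collinearity diagnostic; this use of
ICC on a predictor pair is a diagnostic convention rather than a
variance-component estimate, and values below 0.5 are read as "no strong
correlation". The gene-swamping helper evaluates $m/s > \alpha/|1-\alpha|$
exactly and refuses $\alpha = 1$.

## The synthetic-data generator

Every stage is validated against data with known truth, produced by
`simulate_dataset()`:

* **Neutral structure.** Ancestral allele frequencies are Beta(0.8, 0.8);
  each population's frequency is Balding-Nichols
  $\mathrm{Beta}(p_0(1-F)/F,\,(1-p_0)(1-F)/F)$ with a per-population drift
  parameter $F$ (at $F=0$ the ancestral frequency is used exactly), and
  haplotype alleles are Bernoulli draws. This was chosen over coalescent
  simulation deliberately: it is parameterized directly in the F~ST~-like
  quantity the analyses estimate and runs at desk scale.
* **Parallel clusters.** Cluster loci are generated haplotype-first: each
  individual draws two haplotype classes (freshwater with the population's
  configured frequency — the quantity PI should recover), then per-locus
  alleles at class frequencies $(1\pm\delta)/2$, jittered per locus with
  SD 0.05 by default. High within-cluster LD therefore arises by
  construction, without a recombination model, matching how such clusters
  are defined (LD network membership, not map distance). The default
  jitter keeps a little within-class polymorphism, as real ecotype
  haplotype groups show; setting it to zero produces exactly fixed
  classes.
* **Autozygosity.** Tracts with exponential lengths (mean 1 Mb) are
  planted per individual until the covered fraction reaches the target
  exactly (the last tract is trimmed), by overwriting one haplotype with
  the other — so truth intervals are exact and recovery can be scored at
  base level.
* **Likelihoods.** Read depth is Poisson (default mean 20), alt-read
  counts binomial with error 0.005, genotype likelihoods are the binomial
  probabilities stored as integer Phred PLs, GQ is the second-smallest PL,
  and entries are missing at the configured rate or at zero depth.

What the generator does *not* emulate: linkage among neutral loci,
recombination gradients within clusters, selection through time, reference
bias, and batch effects in depth. Passing tests on these data therefore
demonstrate the correctness and calibration of the estimators under the
stated statistical model, not robustness to every artifact of real
RAD-seq data.

## Problem sizes

The shipped demo study uses eleven populations of eight individuals, four
clusters and 1600 neutral loci on a 20 Mb two-chromosome genome — small
enough to run in seconds while exercising every stage. The validation
suite uses 5000-locus Balding-Nichols pairs for F~ST~ (25 diploids per
population), 8000 loci over 20 Mb for ROH recovery, and a 250-sample,
10-cluster study for PI recovery; these sizes give Monte-Carlo error
comfortably inside the tolerances asserted.

## Known limitations

* LD clusters are refined by fixed-threshold connected components of the
  composite-r² network (default r² ≥ 0.5, computed on the reference
  samples), not by the full LD-network tree-and-threshold machinery some
  pipelines use; the refinement keeps, per cluster, the component with the
  strongest mean marine-freshwater allele-frequency contrast.
* The GL-aware estimators use a single EM sweep for expected dosages
  rather than full iterative individual-allele-frequency estimation; at
  moderate depth the two agree closely, and the projected pathway provides
  the exact-arithmetic alternative.
* ROH calling depends on its transition intensities; the defaults are
  stated above and stored with every call, but F_ROH values are not
  claimed numerically comparable to other callers' output.
* PI compares individuals with the *training* populations' haplotypes; in
  a population fixed for a freshwater haplotype unrelated to the training
  set's, PI underestimates parallelism — a limitation inherent to
  reference-trained classification.
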