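# islandpop

Population-genetic inference for small, fragmented populations typed
with two complementary markers: a maternally inherited haploid sequence
locus (mitochondrial D-loop) and a panel of diploid microsatellites.
The motivating setting is an endangered island endemic sampled at a
handful of montane sites in three mountain regions, where the questions
are: how deep are the divisions between regions, when did they arise,
is there finer structure within regions, and do the maternal and
nuclear markers tell the same story?

The package is aimed at conservation and population geneticists who
want the full chain — marker statistics, Bayesian clustering, and
coalescent-simulation ABC — in one tested, scriptable toolbox, with a
synthetic-study generator for validating every step against known
truth.

## What it computes

**mtDNA tier.** Sequence diversity (S, parsimony-informative sites,
eta, singletons, pi, Hd); mismatch distributions against the
sudden-expansion expectation F(i | theta0, theta1, tau) with
Harpending's raggedness r = sum (x_i - x_{i-1})^2; Fu & Li's D* and F*
and Ramos-Onsins & Rozas' R2 with coalescent-simulation p-values;
Tamura-3-parameter distances with gamma rate heterogeneity,
d = h a[(1 - P/h - Q)^{-1/a} - 1] + (1-h)/2 a[(1-2Q)^{-1/a} - 1]; and
distance dating T = D/(2r). Median-joining haplotype networks with
consensus median vectors, and ancestral-haplotype identification by
outgroup proximity.

**Microsatellite tier.** Nei & Chesser gene diversities; hypergeometric
rarefied allelic richness; Weir–Cockerham f, theta, F from summed
variance components with bootstrap-over-loci CIs; pairwise theta with
genotype-permutation tests and Bonferroni correction;
Queller–Goodnight relatedness; maximum-likelihood individual
inbreeding coefficients; HWE permutation tests; neighbor-joining trees
with Fitch–Margoliash (1/d^2) non-negative least-squares branch
lengths.

**Clustering tier.** A STRUCTURE-type admixture Gibbs sampler
(independent Dirichlet frequencies, Metropolis alpha, optional
location prior), Evanno's delta-K, CLUMPP-style replicate alignment,
and DAPC with BIC cluster search and a-scores.

**ABC tier.** A structured-coalescent simulator (splits, size changes,
admixture pulses; HKY+G+I sequence mutation; generalized stepwise
microsatellite mutation on a bounded allele window), reference tables,
scenario choice by LDA projection with multinomial logistic regression,
local-linear posterior estimation with logit transformation,
pods-based error analysis and posterior predictive model checks.

## Worked example

```r
library(islandpop)

# a complete synthetic two-marker study with known truth
study <- generate_study(study_config(), seed = 1)
study
#> <synthetic_study> 168 genotyped, 96 sequenced, 13 sites

d <- seq_diversity(study$alignment)
c(S = d$S, PI = d$PI, Hd = round(d$Hd, 3))
#>       S      PI      Hd
#> 108.000 107.000   0.763

fs <- wc_fstats(study$genotypes, "region", n_boot = 200, seed = 1)
round(fs$overall, 3)
#>   FIS   FST   FIT
#> 0.065 0.193 0.246

net <- median_joining(collapse_haplotypes(study$alignment))
net
#> <haplo_network> 13 nodes (0 median vectors), 17 edges, total length 115
```

The mtDNA locus shows many segregating sites (the northern haplogroup
is deeply diverged in the default truth), haplotype diversity in the
observed field range, little within-deme heterozygote
deficit (f = 0.07) with strong regional differentiation
(theta = 0.19), and a haplotype
network whose total length is dominated by the deep north–south
separation.

A demographic scenario comparison on the same machinery:

```r
scens <- list(
  split  = scenario("split", c("A", "B"), list(A = "Ne", B = "Ne"),
                    list(event_merge("t", "B", "A"))),
  panmix = scenario("panmix", c("A", "B"), list(A = "Ne", B = "Ne"),
                    list(event_merge(0, "B", "A"))))
priors <- list(Ne = prior_logunif(100, 1e5), t = prior_logunif(1e3, 1e6))
cfg <- sim_config_seq(c(A = 20, B = 20), mu = 1e-6)
ref <- build_reference_table(scens, priors, cfg, n_sim = 2000, seed = 1)

obs <- summary_stats(simulate_dataset(scens$split,
                                      c(Ne = 5000, t = 2e5), cfg))
scenario_choice(ref, obs)$posterior
#>  panmix   split
#>       0       1
```

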