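---
title: "Mapping host-genetic and dietary control of gut microbial communities: methods"
author: "mycoQTL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping host-genetic and dietary control of gut microbial communities: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

mycoQTL implements the statistical chain used to connect host genetics, diet,
and gut fungal/bacterial communities in a four-founder advanced intercross
line (AIL) of mice: founder-haplotype reconstruction from array genotypes,
kinship-corrected additive and interaction LOD scans with permutation
genome-wide thresholds and 1.5-LOD support intervals, variance decomposition,
covariate-adjusted community ecology statistics, and compositionality-aware
inter-kingdom correlation networks. Because the deposited cohort data are not
required, the package ships a first-class synthetic-data generator that
produces AIL genotypes, covariates and overdispersed taxon counts with known
planted effects, so every downstream stage can be validated against ground
truth.

# The synthetic cohort generator

`simulateFounders()` draws four binary founder haplotypes; a `diversity`
parameter (default 1) forces every marker to separate at least two founders,
as array content selected for a multiparental cross would. Genetic positions
are uniform per chromosome; physical positions derive from the genetic map at
2 Mb/cM, the reciprocal of the package's default 0.5 cM/Mb conversion.

`simulateAIL()` breeds the population forward by random mating with at least
50 breeding pairs per generation, matching the husbandry of large AIL
colonies. Gametes form under the Haldane (no-interference) model: crossover
counts are Poisson with mean equal to the map length in Morgans and positions
uniform in cM. No-interference is the simplest model consistent with the
downstream transition kernel; the X chromosome is simulated as autosomal (the
mapping models carry no dosage-compensation convention), and users can simply
exclude it. Observed genotypes are founder-allele sums at the true origins,
flipped per allele with probability `geno_error` and masked with probability
`missing_rate`; the true origins are returned as a `TrueDiplotypes` object
for validation.

`assignCovariates()` reproduces the cohort structure of the study design:
diet fractions default to 250/145/196 over 591 (calorie-restricted CAL = 0,
control CON = 1, Western WES = 2), sex is a fair coin (males = 1,
females = 0), generation labels are 18-20, and cages fill to capacity within
diet. Cage capacity and litter structure are not reported for the real
colony; capacity 5 is a typical housing density and is exposed as a
parameter without any claim of fidelity.

`simulateTaxonCounts()` builds per-sample log-means from a taxon baseline,
cage random intercepts (log-scale SD 0.5 by default), small generation
offsets, log library-size factors (library sizes log-uniform over
`libsize_range`, exercising the size-factor code), and the planted genetic
effects; counts are negative binomial with one dispersion per taxon (default
0.5), matching the variance-stabilizing transform's NB assumption. A planted
effect's target variance fraction refers to log-scale counts: the generator
simulates a pilot draw of the same taxon without the effect, measures the
non-genetic log1p-count variance v0, and scales the genetic term g so that
var(g) = f/(1-f) v0. Regression of log counts on the true founder dosage
then recovers R-squared close to f (the test suite checks 0.10 +/- 0.03 at
n = 400 averaged over 20 seeds). Interaction effects multiply g by a
per-level factor (for example c(0, 0, 1) for a WES-only effect).

`simulateCoupledCompositions()` provides ground truth for the network stage:
log-normal basis abundances with a user-supplied correlation matrix, split
into a fungal and a bacterial block and multinomially sampled to a fixed
depth (default 5000, the rarefaction depth used throughout).

What the generator deliberately does not emulate: real taxonomic
co-occurrence structure, phylogenetic signal among taxa, sequencing-read
level artifacts, and the real mouse genetic map. Passing tests therefore
demonstrate the correctness and calibration of the statistical machinery
under the stated model, not robustness to every feature of real amplicon
data.

# Founder-haplotype reconstruction

Markers are first filtered (`filterMarkers()`): minor allele frequency
strictly above 0.05, missingness strictly below 0.10, and at least two
distinct founder genotypes — markers at which all four founders share a
homozygous call carry no ancestry information.

`reconstructFounderPosteriors()` runs a forward-backward HMM per chromosome.
Although a four-founder cross is sometimes described by four genotype
states, four founders define 10 unordered diplotypes; the package implements
the 10-state diplotype HMM (internally 16 ordered states, collapsed after
smoothing) and exposes 4-founder additive dosages — the expected per-founder
allele counts, summing to 2 — which is exactly the predictor the additive
scan fits. Transitions between adjacent markers use the Haldane recombination
fraction r = (1 - exp(-2d))/2 with map distance d in Morgans multiplied by an
effective-generation factor, default `n_generations/2`, the standard
expansion of the genetic map accumulated by an AIL. Emissions give the
probability of the observed call given the two founder alleles with
per-allele error `geno_error` (default 0.01, array-typical; set 0 for
error-free simulations); missing calls emit uniformly. Single-marker
chromosomes reduce to emission-only posteriors, and a panel in which no
marker distinguishes the founders returns exactly uniform posteriors with a
warning. When the map lacks genetic positions, physical positions convert at
0.5 cM/Mb (configurable).

Decoding fidelity depends on marker density relative to the AIL's mosaic
block length: at generation 20 a ~40 cM chromosome carries roughly ten
ancestry junctions per diplotype, so argmax accuracy is junction-limited on
sparse maps. At array-like density (20 markers/cM; genotyping arrays for the
mouse run denser still) argmax decoding of error-free data exceeds 99%,
which is what the acceptance checks measure.

`kinshipFromPosteriors()` averages, over loci, the probability that two mice
occupy the same founder-origin state — the inner product of their 10-state
probability vectors. A fully certain mouse has self-kinship 1 and uniform
posteriors give 1/10 everywhere. Whether the original analysis used state
probabilities or dosages is not documented; both are implemented
(`method = "probs"` is the default, `"dosage"` the alternative).

# Trait construction

Rare taxa are removed first: a taxon is kept iff at least 20% of samples
reach a read count of 5. The quoted filter rule ("count < 5 present in
< 20% of samples") is ambiguous as written; this is the only reading that
removes rare taxa rather than common ones. `rarefyCounts()` subsamples
without replacement to 5000 reads (samples below depth are dropped with a
warning).

`vstCounts()` stabilizes NB count variance with the closed form
y = (2/sqrt(a)) asinh(sqrt(a K / s)): median-of-ratios size factors s (the
reference is the geometric mean over taxa positive in all samples, with a
positive-subset fallback), and a per-taxon moment estimator of the
dispersion a on size-normalized counts, floored at 1e-8 where the transform
reduces to the Poisson form 2 sqrt(K/s). This is deliberately a
deterministic, dependency-free stabilizer with the same goal as the
regularized-dispersion VSTs of count-model packages; it does not fit a
dispersion-mean trend, so its output is not numerically identical to those
implementations (the size-factor step is cross-checked against DESeq2 in the
test suite).

`residualizeTrait()` fits a REML random-intercept model (generation fixed,
cage random), subtracts the fixed-effect fit and the predicted (shrunken)
cage intercepts, and standardizes to unit variance. Conditional residuals
are the default because the scan should not re-discover cage structure;
`conditional = FALSE` gives marginal residuals for users who prefer to leave
shrinkage to the kinship term. Standardizing makes the h2 formula's n the
only scale carrier in reported effects. Residualization is idempotent in
practice; with a single cage or a degenerate fit the model reduces to fixed
effects only.

# Genome scans

`scanAdditive()` estimates the genetic variance proportion once per trait by
REML under the covariates-only model on the eigendecomposition of the
kinship matrix, rotates the data to independence, and tests each marker by
generalized least squares: null = intercept + sex + two diet contrasts
(CON, WES against the CAL baseline, following the 0/1/2 coding); full adds
three free founder-dosage columns (one founder dropped for
identifiability); LOD = (n/2) log10(RSS0/RSS1). The one-REML-fit-per-trait
scheme is the standard fast eQTL-style approximation; with an identity
kinship the scan reduces exactly to ordinary least squares (validated to
1e-6 against a brute-force fit). Rank-deficient marker blocks lose their
collinear columns through rank-aware QR.

`scanInteraction()` adds products of the dosage columns with the interaction
term (diet as the two indicator contrasts, or sex) and reports the LOD
difference between the full and the genotype-only model, floored at zero.
Missing diet levels are an explicit error.

`permutationThreshold()` permutes the rotated (whitened) phenotype — the
permutation unit is not documented in the field's descriptions, and
shuffling the whitened trait preserves the covariate design while honoring
the kinship approximately — recomputes the genome-wide maximum of the
relevant statistic (the full-null difference for interaction models) per
permutation, and returns the empirical (1 - alpha) quantile with type-7
interpolation. Defaults are 1000 permutations at alpha = 0.05; the
calibration checks in this package run 200 permutations over 100 null
traits, a deliberate scaled-down design that still bounds the realized
genome-wide type-I error within [0.01, 0.12].

`supportInterval()` spans the contiguous run of markers around the peak
whose LOD stays within 1.5 of the maximum; ties at the peak resolve to the
lowest genomic coordinate, intervals touching a chromosome end are flagged
one-sided, and the width column is exactly (end - start)/1e6.

`varianceExplained()` converts a LOD to the proportion of variance via
h2 = 1 - 10^(-(2/n) LOD). The effective n behind published tables is rarely
printed; `inferEffectiveN()` inverts the formula. On the fungal QTL table
shipped with the package the lineage-level rows (phylum to genus) invert to
n = 417 within +-0.3 across eleven rows, while species/OTU rows invert to
n = 427 (the full ITS2 sample count); the acceptance checks therefore infer
n from the lineage rows at run time rather than hard-coding it.

`partitionVariance()` computes the cage fraction from a random-intercept
model and then sequential (type-I) sums of squares of the cage-free
residuals on sex, generation and diet, in that order; covariate fractions
are scaled by the non-cage share so the full decomposition can never exceed
1. `spearmanCovariateRho()` reports rank correlations against the numeric
covariate codings. `deconvolveFounders()` labels each mouse by the
maximum-posterior founder state at a peak (ties to the lowest state index)
and compares residuals across labels within each diet by Kruskal-Wallis and
BH-adjusted pairwise rank tests, excluding labels with fewer than three mice
per diet from the pairwise stage.

# Community ecology statistics

Alpha diversity: Chao1 (bias-corrected when doubletons are absent), Shannon
in nats, Simpson as 1 minus the sum of squared proportions.
`adjustedAlphaAnova()` Box-Cox transforms each index (profile maximum
likelihood on a [-2, 2] grid at step 0.01, zeros shifted by 1e-6),
residualizes on sex and generation, and compares diets by one-way ANOVA with
Tukey pairwise comparisons re-adjusted by FDR — the Box-Cox path is
deliberately separate from the count VST, mirroring the two-track treatment
of diversity indices and abundance traits.

Beta diversity uses Bray-Curtis; the "abundance-based Jaccard" distance is
the monotone transform 2B/(1+B) of Bray-Curtis, the standard quantitative
generalization. `constrainedOrdination()` wraps vegan's capscale with diet
as the constraint and sex + generation as conditioning variables and tests
the constrained pseudo-F by 999 permutations (anova.cca). Because exact
post-hoc tests are unavailable for constrained ordinations, pairwise diet
contrasts are evaluated on the constrained site scores by a resampling
procedure: the centroid-distance statistic, a label-permutation p-value with
Holm step-down adjustment, and a bootstrap confidence interval. This mirrors
the estimate/CI/adjusted-p reporting style of resampling-based multivariate
ANOVA.

`kwMwuFdr()` performs the per-taxon Kruskal-Wallis screen (alpha = 0.05)
followed by pairwise two-sided Mann-Whitney tests with BH adjustment across
the pairwise family. `lefseLite()` is a biomarker caller in the LEfSe mold:
a KW screen, then a single-feature linear-discriminant effect size — the
log10 of the largest between-class separation of per-million relative
abundances on the discriminant axis, thresholded at 2.0 — and a
diet-specificity filter that removes taxa also significant for sex or
generation. The subclass (within-class) stage of the original algorithm is
omitted because the design declares no subclass; LDA scaling constants are
version-dependent in the original, so effect sizes are comparable in rank
rather than numerically identical. `indicatorSpecies()` computes
group-equalized IndVal.g = sqrt(A B) over all single diets and diet
combinations short of the full set, with label-permutation p-values and the
same nuisance-exclusion rule.

# Inter-kingdom correlation networks

`sparccCorrelation()` implements the log-ratio basis-variance estimator for
compositional data: Dirichlet-resampled fractions with a unit pseudocount
(averaged over 20 estimation iterations), the pairwise log-ratio variance
matrix, basis variances solved from the sparsity-assumption linear system,
and up to 10 rounds of excluding the most strongly correlated pair
(|r| > 0.1) from the system, re-solving each round — the defaults of the
original algorithm. Estimates are clipped to [-1, 1]. The fungal and
bacterial tables are analyzed jointly in one concatenated composition and
restricted to inter-kingdom pairs afterwards; whether the original analysis
ran jointly or blockwise is not documented, and the joint run uses strictly
more information about the shared composition.

`sparccBootstrap()` follows the cited tool's permutation scheme: every
taxon's counts are shuffled independently across samples, the full estimator
is recomputed, and the two-sided p-value per pair is
(1 + #{|r_boot| >= |r_obs|})/(n_boot + 1) with BH adjustment across pairs.
The sources describe both "1000 bootstrap permutations" and "n = 999
permutations"; the default is 999 and the count is configurable. Note a
structural property of permutation-BH: with a p-value floor of
1/(n_boot + 1), a lone true edge among m pairs can only survive BH when
1/(n_boot + 1) <= alpha/m, so small panels need n_boot at the thousand scale.

`interkingdomEdges()` keeps fungal-bacterial pairs with adjusted p below
0.05, discards intra-kingdom edges, and computes node degrees on the
retained set; `keyDrivers()` applies the inclusive degree >= 10 rule;
`conservedEdges()` intersects the standing (DNA) and active (RNA) networks
on unordered pairs, taking sign from the DNA network and dropping
discordant-sign pairs with a message.

# Numerical choices and degenerate inputs

Posterior rows renormalize after every forward/backward step with a uniform
fallback for all-zero rows; dispersions floor at 1e-8; basis variances that
solve non-positive floor at a small positive value; interaction LOD floors
at zero; Box-Cox shifts non-positive indices by 1e-6; ties at equal LOD
resolve to the lowest genomic coordinate and posterior ties to the lowest
state index; empty samples yield zero diversity records with a flag;
all-zero samples yield zero distances with a warning; constant traits yield
NA rank correlations with a warning.

# Problem sizes used by the validation suite

The package validates itself on scaled-down designs chosen to be both
informative and quick: a 400-mouse cohort on five 40 cM chromosomes of 100
markers for calibration and power (100 null traits and 25 planted-effect
replicates per model, 200 permutations each), a 60-mouse cohort at 20
markers/cM for decoding fidelity, and 50-taxon compositions at depth 5000
with 200 samples for the network estimator. These sizes are the package's
own validation design; all of them can be scaled up by the user through the
generator parameters.

# Known limitations

The generator's populations are neutral (no selection or family structure
beyond random mating) and its taxa are statistically independent given the
planted effects; the VST uses a moment dispersion rather than a shrunken
trend; the permutation scheme treats the whitened phenotype as exchangeable,
which is approximate under strong population structure; LEfSe-style effect
sizes are rank-comparable rather than identical to the original tool; and
the resampling post hoc for constrained ordination is an approximation whose
coverage is validated only under the simulated designs described above.
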