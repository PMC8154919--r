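---
title: "Methods: from multi-breed SNP panels to projected future genotype frequencies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from multi-breed SNP panels to projected future genotype frequencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caprascape)
```

## Overview

`caprascape` implements a landscape-genomics workflow for livestock SNP-array
panels sampled across an environmental gradient — the motivating system is a
multi-breed goat panel spanning Mediterranean to alpine climates. The chain
is: quality control of the genotype matrix; population-structure summaries
(identity-by-state distances, classical MDS, Reynolds-distance
neighbor-joining trees); breed-level identity-by-descent haplotype sharing;
per-genotype logistic likelihood-ratio association between genotypes and
bioclimatic variables with principal-component structure correction; and a
final projection stage that groups breeds by Köppen-Geiger climate class and
projects allele and genotype frequencies forward under a changed climate.

Every stage can be exercised without external data through
`simulateDataset()`, a seeded generator that reproduces the statistical
structure the analysis assumes.

## The genotype container

`GenotypeData` stores an individuals-by-loci matrix of biallelic calls coded
as copies of the B allele (0/1/2, `NA` missing), plus per-individual breed
codes and coordinates, and per-locus map positions and allele symbols.
Orientation is fixed at load time (`readPlinkText()` makes B the minor
allele by default) and the nucleotide labels travel with the locus so report
output can print genotypes such as `GG`. Physical positions are 1-based, as
in PLINK MAP files; segment intervals are closed `[start, end]` in bp. When
phased, two haplotype matrices are carried and validity enforces that their
sum reproduces the calls — planted identity-by-descent segments therefore
survive any round trip. Missing calls are never imputed in the container;
each stage states its own handling (pairwise deletion in distances,
per-locus mean imputation inside PCA only, exclusion from logistic fits).

## The synthetic-data generator

The generator draws each breed's allele frequency at neutral loci from the
Balding–Nichols model: a Beta distribution with mean the ancestral frequency
$p_0$ and variance $F_{ST}\,p_0(1-p_0)$. Optionally the drift is
hierarchical (`nClusters`, `fstBetween`): cluster frequencies drift from the
ancestor and breeds drift from their cluster, emulating panels whose breeds
fall into a few deep historical groups (the three-way north/central-south/
island structure typical of Italian goat data) with shallow differentiation
inside each group. Adaptive loci instead follow a deterministic cline,
$p_k = \mathrm{clamp}(\alpha + \beta\,x_k,\ 0.02,\ 0.98)$ in the breed-level
environmental value $x_k$; the clamp bounds keep planted loci polymorphic so
a 5% MAF filter cannot silently delete the signal. Genotypes arise from two
independent Bernoulli($p_k$) haplotype draws, hence Hardy–Weinberg
proportions within breed and phased output for free. Identity-by-descent
segments are planted by copying a haplotype stretch verbatim between
designated breed pairs; each plant targets a fresh recipient haplotype while
`n_pairs` does not exceed twice the recipient breed's size.

Default conditions (10 breeds of 30, 500 neutral + 20 adaptive loci,
$F_{ST} = 0.05$, an equally spaced 0–1 gradient with future values shifted
by −0.1) describe a moderately differentiated national panel on a
standardized bioclim scale. What the generator does **not** emulate:
linkage disequilibrium beyond drift, site-frequency-spectrum realism,
selection dynamics through time, genotyping error. Passing tests therefore
validate the estimators' statistical behavior under the stated model, not
robustness to array artifacts.

## Quality control

The cascade mirrors standard PLINK practice and is order-fixed: SNP call
rate and MAF first, then individual call rate, then duplicates and
relatives, then per-analysis steps (LD pruning, representative subsampling,
kinship). Defaults: SNP call rate > 98%, individual call rate > 95%,
MAF > 5%, LD $r^2 \le 0.2$ in 50-SNP windows advancing by 5 (the
`--indep-pairwise` convention; only the threshold is fixed by the study
design, window and step are configurable), duplicate identity-by-state
> 99%, relatedness flagged when the pairwise opposing-homozygote count
falls below 100, breeds subsampled to ≤ 30, kinship cut at $\hat\pi >
0.25$ (the conventional second-degree midpoint). Two interpretation notes:

* *Opposing homozygotes.* Without pedigrees, a "Mendelian error count"
  between two animals is computable only as the number of loci where they
  are opposite homozygotes; that count scales with panel size (≈
  $\sum_l 2p_l^2q_l^2$ for unrelated pairs, thousands on a 50k array), so
  the threshold of 100 presumes a dense panel and must be scaled down for
  small panels. Removal follows the rule: the animal occurring in multiple
  flagged pairs, otherwise the higher-missingness member, iterated.
* *Representative subsampling.* The reference workflow reduces
  over-represented breeds "while maintaining within-population diversity"
  without specifying an algorithm. We use farthest-point traversal on the
  within-breed identity-by-state distance matrix from a seeded random
  start: deterministic given the seed, and it provably covers all clusters
  of a heterogeneous breed before densifying any one of them. Tests verify
  expected heterozygosity of the kept subset stays within 5% of the full
  breed.

Every removal is attributed (id, stage, reason, statistic) and counts
reconcile with input − output.

## Population structure

Identity-by-state distance is $d(i,j) = 1 - s_{ij}/(2m_{ij})$ with $s$ the
shared-allele count and $m$ the jointly non-missing locus count (pairwise
deletion, no imputation). Classical MDS is Torgerson scaling
(`stats::cmdscale`): eigendecomposition of the double-centered squared
distances, axes scaled by the square root of their eigenvalues; negative
eigenvalues are excluded from variance proportions and requesting more axes
than positive eigenvalues truncates with a warning.

The Reynolds co-ancestry distance between two breeds is
$$\theta = \frac{\sum_l (p_{1l}-p_{2l})^2}{\sum_l \left(1 - p_{1l}p_{2l} - q_{1l}q_{2l}\right)}$$
(the per-locus factor 2 of numerator and denominator cancels for biallelic
loci). Since "Reynolds distance" is used in the literature for $\theta$,
$\sqrt{\theta}$ and $-\ln(1-\theta)$, the variant is selectable; the plain
coefficient is the default and the one used by the tree stage. Trees are
Saitou–Nei neighbor-joining on the breed matrix; support comes from
resampling **loci** with replacement (individuals fixed — the standard SNP
bootstrap), majority-rule consensus, and the percentage of replicates
containing each bipartition. The outgroup roots the displayed tree only;
distances and supports are unrooted quantities.

## Haplotype sharing

`detectIbdNaive()` reports maximal runs of identical alleles between every
pair of haplotypes from different individuals, kept when the physical span
reaches `minLenBp` (default 0.2 Mb, the conventional reporting floor). It
is an exact detector for simulated data where segments are copied verbatim
— it is *not* a probabilistic IBD model, makes no allowance for genotyping
error, and will extend a planted segment by however many flanking alleles
match by chance (geometric with mean ≈ 1 SNP per side on a 50%-match
background). Real RefinedIBD-style segment files are ingested instead via
`readIbdSegments()`.

The breed-level statistic is the median over all inter-breed individual
pairs of the per-pair **summed** segment length (the four haplotype
pairings of a pair are added), with pairs sharing nothing contributing
zero and even counts using the midpoint convention. Because of the zero
fill, an entry is positive only when at least half the pairs share — which
naturally produces the sparse sharing patterns seen between isolated
breeds. Whether multi-segment pairs should be summed before the median is
genuinely ambiguous in the source workflow; `summarise = "per_segment"`
provides the alternative reading. Entries are megabases.

## Environmental layer

Grids use the ESRI ASCII text raster dialect (6-line header; row 1 north).
Extraction is containing-cell lookup with no interpolation; out-of-bounds
points return `NA` with a warning. Slope uses Horn's eight-neighbor
gradient in degrees, border cells absent; elevation and cell size must
share one length unit. Variable reduction iteratively removes one member
of the most correlated pair — chosen by a seeded coin flip, since the
reference procedure removes "randomly" — until the maximum squared
correlation drops below 0.7. The threshold is applied to $r^2$ as the
study states, though the commonly wrapped routine
(`caret::findCorrelation`) thresholds $|r|$; `corOn = "r"` restores that
behavior. The returned exclusion map links every removed variable to its
surviving proxy (chains resolved), and the post-condition
$\max r^2 < $ threshold is asserted.

## Genotype–environment association

Structure covariates are principal components of the centered, unit-variance
genotype matrix (missing calls mean-imputed per locus for the decomposition
only; monomorphic loci dropped). `k = "auto"` keeps the leading run of
eigenvalues above the broken-stick expectation, floored at two; the scree
criterion of the reference workflow is a visual judgement, and broken-stick
is its common automated stand-in.

Each biallelic locus yields up to three binary responses — presence of the
AA, AB and BB genotype — tested separately (the Samβada-style coding).
Genotypes carried by fewer than 5 individuals are skipped: rare-genotype
models are separation-prone and contribute nothing but unstable fits.
For one response $y$, variable $x$ (standardized internally) and PC matrix
$S$, two logistic models are fitted by IRLS (≤ 50 iterations, deviance
tolerance $10^{-8}$): null $y \sim S$ and alternative $y \sim S + x$. The
statistic $G = D_0 - D_1$ is referred to $\chi^2_1$. Separation is flagged
via diverging coefficients ($|\hat\beta| > 15$ on the standardized scale)
and non-convergence is reported, the result retained with its flag.
Benjamini–Hochberg control is applied over the pooled family of all
(genotype × variable) tests by default (`per_variable` optional); the
step-up transform is implemented directly and cross-checked in tests
against both `p.adjust` and a brute-force evaluation of the definition.

Gene annotation treats gene tables as BED-like 0-based half-open intervals;
a SNP at 1-based position $p$ overlaps $[s, e)$ iff $s \le p-1 < e$.

### Calibration experiment

The test suite validates the engine on two simulated designs, fixed by a
pre-hoc power analysis:

* *Size*: 1000 datasets of $n = 500$ with three informative structure
  covariates and an independent standard-normal variable; the rejection
  rate at $\alpha = 0.05$ must fall in $[0.03, 0.07]$.
* *Power and error control*: one clustered panel of 12 breeds × 42
  individuals (n = 504), 2000 neutral and 25 adaptive loci, four ancestral
  clusters ($F_{ST}$ 0.05 between, 0.005 within), cline
  $p = 0.25 + 0.5x$, three PCs. At least 70% of adaptive SNPs must reach
  $q < 0.05$ and at most 7% of neutral SNPs may.

The clustered design matters: when adaptive loci are a large fraction of a
weakly structured panel, the leading principal component *is* the planted
cline and the null model absorbs the signal — an instance of the general
collinearity between breed-level environments and structure corrections.
Keeping adaptive loci rare (25 of 2025) and giving the PCs genuine deep
structure to capture reproduces the regime in which this class of analysis
operates: cluster membership, not the cline, dominates the top of the
spectrum, while weak within-cluster drift keeps residual confounding — and
hence the neutral false-positive rate — small. With environments constant
within breeds, structure correction and environmental signal trade off
unavoidably; analyses of panels where the gradient coincides with the
deepest structure axis will sacrifice exactly the loci collinear with it.

## Köppen grouping and projection

Breeds are grouped from their **current** Köppen-Geiger class. Humidity:
`Csa`, `Csb`, `BSk` (and `BSh`) → DRY; `Cfa`, `Cfb`, `Dfa`, `Dfb`, `Dfc`,
`ET`, `EF` → NOTDRY. Temperature: `Csa`, `Cfa` → HOT, the rest NOTHOT. The
temperature map follows the bundled class table's assignments (which mark
the `Cfa` breeds hot) rather than a literal {Csa, Dfa} reading that names a
class absent from the panel; both maps are arguments, so any regrouping is
one call away. An input class missing from a map is an error naming the
breed — silent misgrouping would poison everything downstream.

Per SNP, breed frequencies are screened by one-way ANOVA between the two
groups ($F$ with df $(1, n-2)$), then regressed on the group-associated
variable's per-breed current mean by OLS **pooled across both groups** — a
single slope $b$ serves both groups, matching the published worked example
that applies one regressor to DRY and NOTDRY alike. SNPs with a significant
slope (default $p < 0.05$, unadjusted — the projection gate, configurable)
are projected:

$$p_{\text{future}} = \mathrm{clamp}\left(p_{\text{current}} + b\,\Delta,\ 0,\ 1\right),
\qquad \Delta = \bar{x}_{\text{future}} - \bar{x}_{\text{current}},$$

with genotype frequencies now and in the future given by Hardy–Weinberg,
$(1-p)^2,\ 2p(1-p),\ p^2$. The sign convention $\Delta$ = future − current
is calibrated so the published worked example reproduces exactly: a G
frequency of 0.4296 with $b = 0.3278$ and $\Delta = -0.1253$ gives 0.3885
(and a GG frequency of 0.1509); 0.6109 with $\Delta = -0.0935$ gives
0.5802 (GG 0.3366). Clamping is flagged when it occurs. This is a
deliberately simplified linear response model — it ignores drift,
selection intensity and gene flow, and is meant as a directional
projection of current clines, not a forecast.

The focal allele is the one composing the genotype flagged by the
association stage (G for a GG association), not the minor allele per se;
MAF is used only in the ANOVA screen. Both readings of the screen input
(MAF or oriented frequency) are available since `alleleFrequencies()`
exposes both columns.

## Numerical and reporting choices

* Even-count medians: midpoint. Sharing entries: Mb, 3-decimal reporting.
* Projection outputs follow the published table layout (AA/AG/GG triples,
  current then future).
* The two-group ANOVA, OLS and logistic fits delegate to `stats`
  (`aov`, `lm`, `glm.fit`); trees to `ape`; interval overlap to `IRanges`.
  Hand-written components (Reynolds, BH step-up, the generator, the IBD
  run detector, Weir–Cockerham $F_{ST}$, Horn slope, farthest-point
  subsampling, method-of-moments kinship) all carry oracle tests.
* All stochastic steps (generator, bootstrap, subsample start, variable
  reduction tie-breaks) take explicit integer seeds; a pipeline run is
  bit-reproducible given (inputs, config, seed), and the run manifest
  records md5 checksums of every output.
* Test problem sizes (hundreds of individuals, a few thousand loci, 100
  regression replicates, 1000 null fits) are chosen so the full suite
  reflects estimator behavior at realistic per-breed sample sizes while
  remaining comfortably desk-scale.

## Known limitations

* Genome-scale panel results (tens of thousands of loci, full breed
  panels) require the real deposited genotypes; the package validates the
  machinery on synthetic data with the same statistical structure.
* The naive IBD detector is for simulated/error-free haplotypes only.
* ADMIXTURE-style model-based clustering, phasing/imputation, latent-factor
  association models, and gene-set enrichment are out of scope; external
  results (Q matrices, segment files, gene tables) are consumed as files.
* The projection model is linear in the environmental shift and ignores
  evolutionary dynamics; treat its output as a direction and rough
  magnitude, not a prediction.
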