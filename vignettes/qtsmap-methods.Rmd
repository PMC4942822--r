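---
title: "Methods: QTS mapping in biparental RIL populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: QTS mapping in biparental RIL populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`qtsmap` analyses quantitative traits in a biparental recombinant-inbred-line
(RIL) population genotyped at dense SNPs: quality control, linkage
disequilibrium (LD) structure, three SNP-set strategies, a two-step
mixed-linear-model scan with permutation thresholds, Gibbs-sampler effect
estimation with heritability partitioning, and breeding-value prediction.
This vignette records the model, the conventions, and the design choices the
implementation makes where reasonable alternatives existed.

# The genetic model

For line $k$ in environment $h$ the phenotype is

$$
y_{hk} = \mu + \sum_i a_i x_{ik} + \sum_{i<j} aa_{ij}\, x_{ik} x_{jk}
 + e_h + \sum_i ae_{hi} x_{ik} + \sum_{i<j} aae_{hij}\, x_{ik} x_{jk}
 + \varepsilon_{hk},
$$

with $x_{ik} = +1$ for the paternal homozygote and $-1$ for the maternal
homozygote. Because RILs are (nearly) fully homozygous, dominance terms do
not appear — they are inestimable in this material, and the package makes no
attempt to model them. $\mu$, the additive effects $a_i$ and the
additive×additive epistatic effects $aa_{ij}$ are fixed; the environment main
effects $e_h$, the interactions $ae_{hi}$, $aae_{hij}$ and the residual are
independent normal random effects with their own variance components. One
$e_h$ is drawn per environment and shared by every line in it.

Relatedness/kinship corrections are deliberately absent: all lines descend
from the same two parents with essentially uniform pairwise relatedness, so
the population-structure confounding that plagues natural-population panels
does not arise.

# Genotype coding and quality control

Calls are coded to $\{+1, -1, \mathrm{NA}\}$ against a configurable parental
assignment (for VCF input, REF-is-paternal by default). Heterozygous calls —
possible artifacts at low sequencing coverage — default to missing rather
than an error. Three per-SNP filters are provided and applied in a fixed
order in the pipeline:

1. **Missing rate**: SNPs with missing fraction *strictly greater* than 5%
   are removed ("exceeds" read literally).
2. **Segregation distortion**: Pearson chi-square goodness-of-fit of the
   $+1{:}-1$ counts against the 1:1 RIL expectation, 1 df, no continuity
   correction, removing SNPs beyond the $\alpha = 0.01$ critical value
   (6.635). Plain Pearson was chosen because nothing in the method requires
   small-sample correction at $n \approx 138$ informative calls.
3. **MAF** (off by default): in a biparental RIL panel MAF is an outcome of
   the segregation filter, not an independent screen, so the pipeline treats
   it as optional.

Missing genotypes surviving QC are mean-imputed per SNP for all model
fitting; at a ≤5% missing rate the distortion from mean imputation is
negligible and it keeps every design matrix complete.

# LD structure

Pairwise $r^2$ is the squared Pearson correlation of the ±1 codes over lines
non-missing at both SNPs, computed for all same-chromosome pairs within a
1 Mb window (complete pairs, not k-nearest neighbours: restricting each SNP
to a few adjacent partners biases the decay distance sharply downward, which
the package exposes only as an explicit choice of window). Pairs are pooled
across chromosomes first and then averaged in half-open 1 kb distance bins
(a boundary distance belongs to the upper bin). The half-decay distance is
the start of the first bin whose mean $r^2$ falls to half the *empirical*
maximum bin mean — not half of the theoretical $r^2 = 1$ — matching how a
decay curve is read off a figure; when the curve never reaches half-maximum
the result is flagged undefined rather than extrapolated. No smoothing is
applied before the search.

# SNP-set strategies

The three strategies differ only in the SNP set entering the scan:

* **GWA** — every SNP surviving QC.
* **QBA** — SNPs inside previously mapped QTL intervals, supplied as BED
  (0-based half-open, converted on read).
* **GBA** — SNPs inside annotated gene spans from GFF3 (1-based inclusive),
  taking the *full* span including UTRs and introns, consistent with how
  genic SNP fractions are usually quoted for rice gene models.

Internal SNP positions are 1-based (VCF convention). A SNP hit by several
intervals is kept once with all hit labels recorded.

# Candidate screening

Exhaustive mixed-model scanning of $10^5$–$10^6$ SNPs (and their pairs) is
not necessary for detection: the package first ranks SNPs per trait and
environment by a one-way F statistic of within-environment line means on the
±1 codes, and SNP pairs by the F statistic of the product term given both
marginals, keeping the `top_m` (default 1000) of each. Per-environment
candidate lists are merged by union. This F-ranking screen deliberately
replaces the multifactor-dimensionality-reduction tool used in the original
GPU pipeline: the screen's only role is filtering, and an F-based filter has
the auditable property that with `top_m = n_snps` the downstream result is
*identical* to running without screening (asserted in the test suite). The
2D screen's pair universe defaults to pairs among the top 2000 marginal SNPs
for tractability and is configurable to exhaustive.

# Two-step mapping and permutation thresholds

**Step 1 (1D)**: every SNP is tested by the partial F statistic for its
additive term in a fixed-effects model with an environment block, fitted on
replicate-level data. Monomorphic SNPs yield `NA` and are excluded; a
zero-residual fit is reported as `Inf` (a sentinel, not an error).

**Step 2 (2D)**: with the step-1 hits as additive covariates, each candidate
pair is tested by the partial F of its product term given the environment
block, the covariates and the pair's marginals. Pairs whose product is
collinear with the model are skipped and counted.

**Thresholds**: each scan's experiment-wise threshold $F^*$ is the empirical
$(1-\alpha)$ quantile (type-1, so $\alpha = 1$ returns the sample minimum) of
the max-F distribution over permutations in which line labels are shuffled
*within each environment*, keeping replicates attached to their line. This
preserves the environment and replicate structure exactly while breaking all
genotype–phenotype association. The default is 1000 permutations at
$\alpha = 0.05$; at least 100 are required. Within each permutation,
non-finite per-unit F values are dropped before taking the maximum; such
values arise only from degenerate zero-residual permutations and carry no
ordering information. Environment enters the scans as a *fixed* block (it
makes the permutation scheme exact and the scan vectorisable) even though the
final estimation model treats it as random; the scan only ranks and
thresholds, it does not estimate.

**Selection**: significant loci and pairs become stepwise units — a locus is
one column, a pair is its two marginal columns plus the product, entered and
removed as a block. Forward steps add the unit with the smallest partial-F
p-value below `entry_alpha` (default 0.05); backward steps drop units whose
partial p exceeds `stay_alpha` (default 0.05); iteration continues until
stable. A unit adding no rank to the design can never enter, so of two
perfectly correlated loci exactly one is selected; residual ties break by
larger F, then smaller chromosome/position — an arbitrary but deterministic
rule.

# Gibbs estimation

The selected model is estimated by a Gibbs sampler: flat priors on the fixed
effects; scaled-inverse-chi-square priors on all variance components in the
Jeffreys limit ($\nu_0 = 0$, $s_0 = 0$, i.e. $p(\sigma^2) \propto
1/\sigma^2$), so each variance is drawn as $SS/\chi^2_q$. The Jeffreys limit
was chosen over a $\nu_0 = -2$ flat-variance prior because with only two
environments the latter gives a zero-df draw for the environment variance.
Draws are guarded below by $10^{-10}\max(\mathrm{var}(y), 1)$ so a
zero-residual (noise-free) model cannot produce degenerate arithmetic.

Two identification choices matter:

* Every random-effect design block is projected onto the orthogonal
  complement of the fixed design before sampling (a sum-to-zero-style
  constraint). Without this, $\mu$ is exactly confounded with the mean of
  $e_h$, and each $a_i$ with the environment-average of its $ae_{hi}$ — a
  direction in which a Gibbs chain mixes arbitrarily slowly as the residual
  variance shrinks. With the projection, the fixed effects are identified by
  the data alone, and noise-free data is recovered exactly (a test asserts
  recovery to $10^{-3}$).
* The default chain is 20,000 iterations with the first 25% discarded as
  burn-in and no thinning; the fixed-effect conditional is sampled jointly,
  so autocorrelation is mild and posterior summaries stabilise well within
  that budget. A fixed seed gives bit-identical summaries.

Point estimates are posterior means, standard errors posterior standard
deviations, and p-values a Wald-type normal approximation
$2\Phi(-|\hat\theta|/\mathrm{SE})$, reported as $-\log_{10} P$ (computed on
the log scale to avoid underflow at large $|z|$).

**Heritability.** $h^2_i = 100\, \hat a_i^2\,\mathrm{var}(x_i)/V_P$ per cent
for additive terms, with $\mathrm{var}(x_i x_j)$ replacing
$\mathrm{var}(x_i)$ for epistatic terms; the total is the sum over terms.
$V_P$ is the sample variance of line-by-environment mean phenotypes. This is
the one formula the package infers rather than copies: it is the only
convention under which published per-QTS $h^2$ tables satisfy
$h^2_i / h^2_j = (a_i/a_j)^2$ within rounding across all rows of the bundled
effect table, a property asserted in the acceptance tests.

# Breeding-value prediction

The total genetic value of a homozygous genotype is
$G = \sum_i a_i x_i + \sum_{i<j} aa_{ij} x_i x_j$; with no selected
environment-interaction terms $G$ is constant across environments, and the
predicted phenotype is $\mu + G$. The best line (BL) maximises $G$ over the
observed panel (ties break by input order and are reported). The superior
line (SL) maximises $G$ over all $2^k$ homozygous genotypes — heterozygotes
are outside the model for pure-line material. For additive models the
optimum is closed-form ($x_i = \mathrm{sign}(a_i)$, $G = \sum |a_i|$); with
epistasis the search is exhaustive for $k \le 20$ and seeded simulated
annealing (geometric temperature ladder, 50 restarts of 2000 single-flip
steps with incremental-delta evaluation) beyond that. The annealing search is
a documented stand-in for the published prediction method, whose algorithm is
not specified in detail; its equivalence to brute force is asserted on 50
random 12-locus epistatic models.

# The simulator: what it emulates and what it does not

`simulate_ril_genotypes()` performs forward single-seed-descent simulation:
an F1 with intact parental haplotypes, then (by default) 12 selfing
generations — an F13 population, the design of the bundled rice panel — with one
offspring kept per generation. Crossovers follow the Haldane model
($r = (1-e^{-2d/100})/2$, no interference), independently per meiosis. The
defaults mirror the study conditions the package is tested under: 138 lines,
two environments × two replicates, MAF ≈ 0.5, missing calls injected
uniformly at a configurable rate (default 0, filtered downstream at 5%), and
within-chromosome LD decaying over hundreds of kb at the default marker
spacing and bp/cM scale. Residual heterozygosity after 12 selfing
generations (~0.02% per locus) is forced homozygous by a fair coin flip by
default, because the analysed coding is fully homozygous and no published
handling rule exists; `het_policy = "code-missing"` is the alternative.

Under selfing the effective recombination between adjacent markers is
$R = 2r/(1+2r)$, giving an expected genotype correlation $(1-2r)/(1+2r)$ —
the closed form the LD tests check at $n = 50{,}000$ lines.

Limits worth stating: the simulator draws all random terms normal; it does
not emulate genotyping error beyond uniform missingness, segregation
distortion, non-normal residuals, selection during line development, or
crossover interference. Passing tests therefore validate the *statistical
machinery* under the stated model, not robustness to these real-data
departures.

# Problem sizes and numerical conventions

The test and acceptance suites run at desk scale, chosen to keep the full
suite within minutes while leaving Monte-Carlo noise well inside the asserted
bands: null calibration uses 200 simulated datasets of 2000 SNPs × 138 lines
with 200 permutations each (the type-I band checked is 3–7% against the
5.5% expectation of the type-1 quantile rule at 200 permutations);
effect-recovery uses 100 replicates of a six-QTS architecture with effects
1.88–3.03 and total $h^2 \approx 40\%$ at $n = 138$; LD checks use two-marker
chromosomes at $n = 50{,}000$. Degenerate-input conventions: monomorphic
SNPs are `NA` in scans and skipped in LD pairs; constant phenotypes give
all-zero F with a warning; perfect fits give an `Inf` sentinel; collinear
fixed-effect columns are pruned with a warning before estimation.

# Known limitations

* With two environments the environment-variance posterior is heavy-tailed
  (2-df draws); $\mu$'s interval is honest but wide in small-$H$ designs.
* The Wald $-\log_{10}P$ is an approximation to the posterior tail, adequate
  at the effect sizes where declarations happen but not calibrated for
  near-zero effects.
* The epistasis pair universe defaults to pairs among top-ranked 1D SNPs;
  purely epistatic architectures with *no* marginal signal are only reachable
  through the optional 2D screen or an explicit pair universe.
* Heritability uses the fixed-effect point estimates and ignores estimation
  uncertainty in $V_P$; totals can exceed 100% in principle at extreme
  overfitting, which the permutation-guarded selection is designed to avoid.
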