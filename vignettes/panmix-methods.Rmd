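---
title: "Methods: models, estimators and simulation engine in panmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and simulation engine in panmix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panmix)
```

# Scope

`panmix` implements the population-genetic analysis chain used in marine
connectivity studies that combine a mitochondrial sequence marker (such
as COI) with a reduced-representation SNP panel (such as ddRADseq).  The
sequence track covers haplotype collapsing and diversity, rarefaction,
minimum spanning networks, neutrality tests, mismatch-distribution
demographic inference and AMOVA-based Phi-ST; the SNP track covers read
and locus filters, Hardy–Weinberg screening and three differentiation
estimators with across-locus bootstrap intervals.  A coalescent and
Balding–Nichols simulation engine supplies null distributions, bootstrap
replicates and synthetic data for testing.  Upstream steps that belong
to other tools — chromatogram QC, alignment construction, demultiplexing,
stack assembly and SNP calling, Bayesian outlier or clustering models —
are deliberately out of scope.

# Sequence-track models

## Haplotype statistics

Sites carrying `N` or `-` in *any* sequence are removed before
comparison (complete deletion, the convention of standard
haplotype-statistics software); sequences identical over the remaining
sites share a haplotype.  A pairwise-deletion mode exists for distance
computations (`pairwise_diffs(..., deletion = "pairwise")`) because
AMOVA-style software compares each pair over their mutually unambiguous
sites; the Phi-ST module uses that convention.

Haplotype (gene) diversity is Nei's unbiased
$h = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)$, and nucleotide
diversity is the mean pairwise difference divided by the number of
compared sites.  Rarefaction draws `reps` subsamples of fixed `size`
without replacement (defaults 30 × 15, the usual choice when the
smallest analysed population holds 15 individuals) and reports the mean
and standard error ($\mathrm{sd}/\sqrt{\text{reps}}$) of the haplotype
count and of $h$.  Haplotype identity is assigned once on the full
alignment, so subsample statistics are deterministic functions of the
drawn ids; this keeps replicates comparable across populations.

## Minimum spanning network

Edge weights are Hamming distances between haplotypes over the compared
sites.  An edge $(u, v, w)$ is part of the network iff $u$ and $v$ are
not connected using only edges of weight strictly less than $w$ — the
cut criterion for membership in at least one minimum spanning tree.  The
result is the exact union of all MSTs: deterministic, connected, and a
superset of any single tie-broken tree a permutation procedure could
produce.  We prefer this definition to stochastic tie exploration
because it is reproducible and directly testable (the suite compares it
with exhaustive spanning-tree enumeration for up to six haplotypes).

## Neutrality tests

Tajima's D contrasts the mean-pairwise-difference estimator of $\theta$
with the Watterson estimator $S/a_1$, standardized with the classical
$a_1, a_2, b_1, b_2, c_1, c_2, e_1, e_2$ constants.  With no segregating
site the statistic is undefined and reported as `NA`, never as 0.

Fu's Fs is $\ln(S'/(1-S'))$ with
$S' = \Pr(K \ge k_{\mathrm{obs}} \mid \theta = \hat\theta_\pi)$ under
the Ewens sampling distribution
$\Pr(K = j) \propto |S_n^{(j)}|\,\theta^j$.  Unsigned Stirling numbers
of the first kind are accumulated in log space through the recurrence
$|S_{n+1}^{(j)}| = |S_n^{(j-1)}| + n|S_n^{(j)}|$, so samples well beyond
$n = 60$ (where naive doubles overflow) remain exact to machine
precision; the suite verifies agreement with brute-force enumeration for
all $n \le 8$ at $10^{-10}$.

P-values come from a stationary neutral coalescent null.  By default
the null is conditioned on the observed number of segregating sites
(each simulated genealogy receives exactly $S$ mutations placed
multinomially by branch length), which removes the nuisance-$\theta$
sensitivity of D; a $\theta$-conditioned mode (mutation rate set to
$\hat\theta_\pi$) is available, and the two agree only approximately.
The D p-value is one-tailed in the direction of the observed statistic,
the Fs p-value is the lower tail, and both use the add-one correction
$(\text{hits}+1)/(\text{nsim}+1)$, so no reported p-value is exactly 0.
The conventional reading that Fs requires $\alpha = 0.02$ for a 0.05
test is a reporting convention left to the user.

## Mismatch distributions and the sudden-expansion model

The observed mismatch distribution is the relative histogram of
pairwise difference counts.  Under instantaneous expansion from
mutation-drift equilibrium at $\theta_0$ to $\theta_1$, $\tau$
mutational time units ago, the expected class probabilities are

$$F_i = \hat F_i(\theta_1) + e^{-\tau(\theta_1+1)/\theta_1}
  \sum_{j=0}^{i} \frac{\tau^j}{j!}
  \left[\hat F_{i-j}(\theta_0) - \hat F_{i-j}(\theta_1)\right],
\qquad \hat F_i(\theta) = \frac{\theta^i}{(1+\theta)^{i+1}}.$$

At $\tau = 0$ this is the $\theta_0$ equilibrium; as $\tau \to \infty$
it approaches the $\theta_1$ equilibrium.  Model probabilities are
evaluated on classes $0..\max(2d, 50)$ and renormalized before the
observed classes are compared, which bounds the truncation error (the
raw series sums to 1 within $10^{-6}$ on the tested parameter ranges).

Estimation is constrained least squares: minimize
$\mathrm{SSD} = \sum_i (F_{\mathrm{obs},i} - F_{\mathrm{exp},i})^2$
subject to $\tau \ge 0$, $0 \le \theta_0 \le \theta_1 \le 10^4$.  A
deterministic coarse grid seeds a Nelder–Mead simplex (parameters enter
squared, so constraints hold by construction), making the fit
reproducible for fixed input.  The $\theta_1$ cap contains the
well-known flat ridge in $\theta_1$ — on real data $\hat\theta_1$ can
run into the thousands with almost no change in SSD, so its point value
and upper bound should not be over-interpreted.  Because the published
implementations of this fit use their own (undocumented) estimation
details, parameter estimates are expected to match published tables
approximately, not bit-exactly.

The raggedness index is implemented as
$r = \sum \mathrm{diff}(c(0, F_0..F_d, 0))^2$, i.e. the sum of squared
successive differences with zero padding at both ends, so a
distribution concentrated on one class gives $r = 2$ and smooth
unimodal distributions give small values.  This leading-term convention
is the package's definition; it differs from the textbook sum (which
starts at $F_1 - F_0$) only when $F_0 > 0$.

Goodness of fit uses a parametric bootstrap: `nboot` samples of `n`
sequences are simulated under the fitted $(\tau, \theta_0, \theta_1)$,
re-fitted, and $p_{\mathrm{SSD}} = \#\{\mathrm{SSD}_b \ge
\mathrm{SSD}_{\mathrm{obs}}\}/\text{nboot}$ (the raggedness p-value is
analogous).  Percentile 2.5/97.5 bounds of the re-fitted parameters
give the reported intervals.  Replicate re-fits start the simplex from
the parent estimates (the replicates are generated there), which speeds
the bootstrap several-fold without changing its distribution in any way
the calibration test can detect: simulated-under-the-model data reject
at the nominal 0.05 level within binomial error.

## AMOVA Phi-ST

The squared molecular distance between two sequences is their number of
pairwise differences (the haplotypic-AMOVA convention), compared with
pairwise deletion.  For two populations, variance components follow the
standard AMOVA layout; the estimator can go slightly negative, which is
retained (not clipped).  Significance uses permutation of individuals
between the two populations with sizes preserved.  When
$\binom{N}{n_A} \le \text{nperm}$ the test enumerates *all* distinct
reassignments and reports the exact $\#\{\Phi_{\mathrm{perm}} \ge
\Phi_{\mathrm{obs}}\}/\text{total}$; otherwise it draws `nperm` random
permutations with the add-one correction.  The full-matrix mode runs
all pairs and applies the Benjamini–Hochberg step-up adjustment jointly
across every pairwise test (`stats::p.adjust`); applying it within
subsets of pairs is not supported because joint correction is the more
conservative, and more common, reading.

# SNP-track estimators

## Filters

The chimera filter removes any read containing a restriction
recognition motif (defaults: EcoRI `GAATTC`, MspI `CCGG`) as an exact
substring, scanning reads in sequenced orientation; reverse-complement
scanning is available behind a flag but off by default, since
orientation-aware libraries place genuine sites at read starts only.
Locus filters run in fixed order — first SNP per radtag (smallest
within-radtag position), missingness (retain when missing/individuals
$\le$ 0.20), minor allele frequency (retain when MAF, computed over
non-missing allele copies, strictly exceeds 0.06) — and each step logs
reconciling counts.  The MAF rule is frequency-based rather than
carrier-count-based: with 33 individuals a single heterozygous carrier
gives MAF $1/66 \approx 0.015$ and is removed, which matches the
carrier-count reading at that sample size while generalizing cleanly.
A per-genotype stack-depth filter is not implemented because depth is a
property of the upstream assembler's output, not of the genotype
matrix; when a VCF supplies DP it can be filtered upstream.

## Per-population statistics and HWE

Per locus and population: major-allele frequency, observed
heterozygosity, expected heterozygosity $H_{\mathrm{exp}} = 1 - \sum
p^2$, nucleotide diversity $\pi = \frac{2n}{2n-1} H_{\mathrm{exp}}$
(the unbiased correction — the two columns of a summary table are
linked exactly by this factor), and $F_{IS} = (\pi -
H_{\mathrm{obs}})/\pi$ with $F_{IS} = 0$ at monomorphic loci.  Averages
are taken over loci polymorphic in the full dataset; restricting to
loci polymorphic within each population is a documented alternative
reading that would raise every average.

Hardy–Weinberg screening uses the exact conditional test: all
heterozygote counts compatible with the observed allele counts are
enumerated with probability $\propto \frac{n!}{n_{AA}!\,n_{AB}!\,n_{aa}!}
2^{n_{AB}}$, and the two-sided p-value sums configurations no more
probable than the observed one.  A locus is excluded from divergence
statistics when p < 0.05 in any population.  The upstream Bayesian
outlier scan used alongside HWE screening in practice is a separate
tool and out of scope; its place in the chain is taken by the HWE
screen alone.

## Differentiation estimators

Weir–Cockerham $\theta$ uses the two-population variance components
$a, b, c$; the multilocus estimate is the ratio of sums $\sum a / \sum
(a+b+c)$, never the mean of per-locus ratios.  $G'_{ST}$ and Jost's D
are built from Nei & Chesser unbiased $H_S$ and $H_T$ (harmonic-mean
sample sizes), averaged across loci before forming the ratios, with
$k = 2$ demes.  All three estimators are slightly negative in finite
samples from identical populations; that bias vanishes as sample size
grows and is left visible.

Confidence intervals resample loci with replacement (`B = 100` by
default) and use the bias-corrected (BC, not BCa) percentile method:
$z_0$ from the fraction of replicates below the point estimate, levels
$\Phi(2z_0 \pm z_{0.025})$, acceleration omitted.  Degenerate resamples
(all replicate values identical) return a zero-width interval at the
point estimate.  An interval containing 0 is flagged non-significant.

# Simulation engine

Time is measured in mutational units of $1/(2u)$ generations, so
$\tau$, $\theta_0$, $\theta_1$ are directly the expansion-model
parameters: $k$ lineages coalesce at rate $k(k-1)/(2\theta(s))$ with
$\theta(s) = \theta_1$ for $s < \tau$ and $\theta_0$ beyond, and
mutations fall at rate $1/2$ per lineage per unit time.  A stationary
pair then has mean difference $\theta$ and geometric mismatch law
$\theta^i/(1+\theta)^{i+1}$, which the suite verifies at 50 000
replicates within 2%; segregating sites follow the Watterson identity
$E[S] = \theta a_1(n)$.  $\theta_0 = 0$ is handled as instantaneous
coalescence of all lineages surviving at $\tau$ (a star beyond the
expansion), and the epoch switch uses the memorylessness of the
exponential rather than explicit time rescaling.  Mutations are
rendered under infinite sites — each mutation claims a fresh site
(ancestral base `A`, derived base drawn from `C/G/T`), so $S$ mutations
give exactly $S$ segregating sites; finite-site recurrent mutation is
not modelled, which is adequate for the low-diversity mitochondrial
regime the engine emulates ($\theta \ll L$).

Multi-population sequence samples have two regimes: `divergence = 0`
draws one panmictic genealogy for the pooled sample (true
differentiation exactly nil — the calibration regime), while
`divergence > 0` gives each population an independent genealogy plus a
Poisson-distributed count of private fixed mutations (the power
regime).  Neither regime models migration at intermediate rates; tests
that need a *specific* nonzero Phi-ST therefore do not exist, only
ordering properties.

Diploid genotypes follow the Balding–Nichols model: ancestral frequency
uniform on [0.05, 0.95], population frequencies
$\mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)$, genotypes Binomial(2, $p_k$),
optional uniform missingness.  The expected Weir–Cockerham $\theta$
between two populations is approximately $F$, verified at
$F = 0.05$ with 5000 loci and 30+30 individuals (estimate within
[0.04, 0.06]) and monotone over $F \in \{0.01, 0.05, 0.2\}$.

What the generator does *not* emulate about real data: sequencing and
PCR error, allele dropout and depth-dependent missingness (missing
calls are uniform), linkage between loci, selection, recombination and
migration.  Passing tests therefore demonstrate correctness of the
estimators under their own model assumptions, not robustness to these
artefacts.

# Randomness, determinism and problem sizes

Every stochastic function takes an explicit `seed`; pipelines reuse one
top-level seed, so a rerun with the same configuration is byte-identical
(the suite asserts this on the report files).  Monte-Carlo p-values are
add-one corrected; exhaustive enumeration, where triggered, is exact and
seed-free.  The test suite runs its statistical checks at the scales
stated above (e.g. 50 000 simulator calibration replicates, 200
parameter-recovery datasets, 200 × 200 bootstrap calibration, 5000-locus
FST recovery); the pipelines' analysis-scale defaults (10 000
permutations and bootstrap replicates) remain the package defaults and
can be reduced through the configuration for desk-scale work.

# Known limitations

- Hierarchical (multi-level) AMOVA is not implemented; only pairwise
  two-population Phi-ST.
- The mismatch fit reproduces published tables approximately; the
  $\theta_1$ direction is nearly unidentifiable and its bounds are wide
  by construction.
- Fu's Fs p-values depend on the null conditioning choice (S vs
  $\theta$); both modes are provided and differ slightly.
- The SNP track assumes biallelic loci throughout; multi-allelic
  records are rejected at load time rather than recoded.
- No spatial-expansion mismatch model, median-joining network, R2/Fay–Wu
  statistics, or LD-based filters.
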