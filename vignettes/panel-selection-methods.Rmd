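---
title: "Delta-based SNP panel selection and discriminant breed assignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delta-based SNP panel selection and discriminant breed assignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snptrace)
```

# Overview

`snptrace` implements a complete workflow for building reduced SNP panels
that trace animal products back to a breed: quality control of
medium-density chip genotypes, marker ranking by the delta statistic,
deterministic panel construction, simulation of purebred and F1-hybrid
cohorts, and breed assignment by a shared-covariance discriminant model
with a minimum-posterior threshold for hybrid detection. This vignette
records the statistical model behind each stage, the tunable parameters
and their defaults, the numerical conventions, and what the synthetic
data generator does and does not establish about real data.

# Data model

Genotypes are diploid, biallelic dosages: entry `g` for a sample and SNP
means `g` copies of that SNP's *counted allele* (0, 1 or 2), with `NA`
for a missing call. Keeping the counted allele explicit per SNP makes
frequency arithmetic well-defined across chip versions: when two datasets
record the same marker with counted/other alleles swapped, merging
recodes the second as `2 − g`. No strand flipping is attempted — for an
A/T or C/G marker a coding swap is indistinguishable from a strand flip,
so such markers are dropped unless the two datasets record the allele
pair identically. This is the conservative convention of common merging
practice; the dropped markers are listed in the merge report.

# Quality control

Three filters run in a fixed order, each recomputed on the survivors of
the previous one:

1. samples with call rate below `min_sample_call_rate` (default 0.95);
2. SNPs with call rate below `min_snp_call_rate` (default 0.95);
3. SNPs deviating from Hardy–Weinberg equilibrium at
   `hwe_alpha / n_tested` (default α = 0.01, Bonferroni over the SNPs
   actually tested at this stage — the denominator is not stated in
   common workflows, and tying it to the tested set keeps the correction
   exact).

The HWE test is the two-sided exact conditional test: given the allele
counts, the probability of every possible heterozygote count is
accumulated by the standard outward recurrence from the modal
configuration, and the p-value sums the configurations no more probable
than the observed one (no mid-p adjustment, matching the default
behavior of standard genotype-QC software). A chi-square variant is
available via `hwe_test = "chisq"` for large samples. HWE can be tested
within a single focal population (`hwe_population`), which is the
default analysis choice here because equilibrium is only expected within
a randomly mating population, not across a pooled multi-breed dataset;
testing across all samples is also supported.

Deliberately, there is **no minor-allele-frequency filter**: a rare or
private allele is exactly what makes a marker diagnostic for one breed.

# The delta statistic and panel construction

For populations $i, j$ and a SNP with counted-allele frequencies $p_i,
p_j$, the informativeness measure is

$$\Delta = |p_i - p_j| \in [0, 1],$$

which is invariant to which allele is counted and equals 1 at a fixed
difference. Frequencies are computed from genotype dosages (missing
calls excluded from numerator and denominator), which is equivalent to
allele counting under the non-inbred sampling assumed throughout.

Panels are built by processing an ordered list of breed comparisons,
taking each comparison's highest-Δ SNPs. Three rules make the result
reproducible and well-sized:

* **Deduplication** — a SNP may fill only one slot; a later comparison
  whose top SNP is taken moves to its next-ranked SNP, so the panel size
  always equals the scheme's count total.
* **Tie-breaking** — equal deltas are resolved by marker id ascending.
* **Stages** — every entry records its source pair, its Δ at selection,
  and whether it came from the core scheme, the MDS-guided additions or
  the augmentation.

The default five-breed scheme (`study_selection_schemes()`) takes 3, 3,
2 and 1 SNPs from the focal breed's comparisons with LR, LW, WB and DU —
fewer markers suffice against WB and DU because those populations are
already well separated in the IBS/MDS embedding — then 3 more SNPs for
the near-clustering LR–LW pair (12 SNPs total), and finally 8 SNPs over
the non-focal pairs to support hybrid discrimination (20 total). The
original augmentation counts per pair are not recoverable from the study
design, which states only the total of 8 chosen to help the most
confusable breeds; the default here fixes LR–LW at 3 and each of the
other five non-focal pairs at 1, weighting the hardest pair, and is
fully configurable. "MDS-guided" selection is likewise operationalized
as delta ranking restricted to the near-clustering pairs — the pairs are
identified from the MDS plot, the markers still by Δ — since no other
selection criterion is stated.

# Identity-by-state MDS

Population structure is visualized by classical (Torgerson)
multidimensional scaling of the distance $D = 1 - \mathrm{IBS}$, where
IBS between two samples is the mean over co-genotyped SNPs of
$(2 - |g_a - g_b|)/2$. The $1 - \mathrm{IBS}$ transform is the
convention of the GenABEL lineage of tools. Scaling is delegated to
`stats::cmdscale` (double-centering of squared distances,
eigendecomposition, coordinates scaled by root eigenvalues; negative
eigenvalues contribute nothing). Sign and rotation of the axes are not
identified, so all tests compare inter-point distances and group
separations, never raw coordinates.

# Simulation of purebreds and hybrids

Cohorts are generated from population allele frequencies rather than by
resampling observed alleles: a purebred dosage is Binomial(2, $p$), an
F1 dosage is Bernoulli($p_A$) + Bernoulli($p_B$). This
frequency-parametric scheme is distributionally equivalent to pooled
allele resampling for the cohort sizes used here, and is simpler to
seed deterministically. Its closed forms anchor the tests: F1
heterozygosity is $p_A(1-q_B)$-style, i.e. $p(1-q) + q(1-p)$ (0.74 at
$p = 0.9, q = 0.2$), the F1 counted-allele frequency is $(p+q)/2$, and a
fixed difference forces every F1 to be heterozygous.

Loci are treated as unlinked (the default panels span many chromosomes)
and populations as in Hardy–Weinberg equilibrium — the same assumptions
the discriminant treats implicitly.

`build_study_populations()` assembles the four benchmark cohorts:

| cohort | content | default size |
|---|---|---|
| PTP | real purebreds with complete panel genotypes | data-dependent |
| HTP | PTP + simulated F1s, truth label "HY" | PTP + 10 crossings × 20 |
| PVP | simulated purebreds | 5 breeds × 40 = 200 |
| HVP | PVP + simulated F1s | PVP + 10 crossings × 10 |

Every sub-cohort draws from its own seed derived from the plan's master
seed, so training and validation hybrids are independent.

# Discriminant assignment

With per-class means $\mu_k$, pooled within-class covariance $W$ and
priors $\pi_k$, the posterior for class $k$ at dosage vector $x$ is

$$P(k \mid x) \propto \pi_k \exp\left(-\tfrac12 (x-\mu_k)^\top W^{-1}
(x-\mu_k)\right),$$

computed via the Cholesky factor of $W$ with a log-sum-exp
normalization. Canonical axes — eigenvectors of the whitened
between-class scatter, at most one fewer than the number of classes —
are retained for projection and plotting; classification uses the full
shared-covariance rule, which is equivalent to classifying in the
complete canonical space. Dosages enter unscaled: the discriminant is
affine-invariant, so per-marker scaling would not change assignments.

Design choices that were genuinely open:

* **Priors** default to training class frequencies (the standard
  discriminant default); `priors = "equal"` is provided because the
  hybrid training cohort is unbalanced (200 HY against ≤ 93 per breed)
  and equal priors remove the resulting pull toward HY.
* **Hybrids form one pooled class** "HY", not ten per-crossing classes —
  the operational question is "purebred or not", and per-crossing
  classes of 20 would be too small to estimate stably.
* **Ridge regularization** (`ridge`, default 0) adds
  `ridge × mean(diag(W))` to the diagonal of $W$; it is needed only when
  a panel marker is monomorphic in the training cohort, which can happen
  in small synthetic runs. The error message for a singular fit points
  to the flag rather than silently regularizing.
* **Ties** in the posterior argmax go to the lexicographically smallest
  class label, and class labels are kept sorted, so results are
  platform-independent.

The hybrid threshold implements the study's decision rule: an individual
keeps its predicted breed only if its top posterior reaches
$\tau = 0.65$; otherwise it is reassigned to "HY". The threshold can
only move individuals *into* the fallback class, so hybrid recall is
monotonically non-decreasing in $\tau$ while purebred specificity falls.
The default of 0.65 sits between the typical mean posteriors of
correctly and incorrectly assigned validation individuals and is a
tunable `threshold_rule()` parameter.

# The synthetic-study generator

Real multi-breed chip data of this kind is typically not public, so the
generator emulates the study shape under the Balding–Nichols model: per
SNP an ancestral frequency $p \sim U(0.05, 0.95)$, and per population a
frequency drawn from $\mathrm{Beta}\!\left(p\frac{1-F}{F},
(1-p)\frac{1-F}{F}\right)$, which has mean $p$ and variance $F p (1-p)$;
$F = 0$ degenerates to $p$ exactly. Defaults: cohort sizes
NS 93, LW 44, LR 37, DU 44, WB 88 (the study's 306 individuals), 5,000
SNPs, a single $F = 0.2$ for all populations (a typical differentiation
level among pig breeds and wild boar; per-population $F$ can be supplied,
e.g. higher for WB), and 1.5% missing calls injected completely at
random, matching a 98.5% mean genotyping rate. 5,000 SNPs rather than
the chip's ~43,700 keeps routine runs fast while leaving hundreds of
high-Δ markers for every pair, which is what panel selection consumes;
the full scale is a config value away.

What the generator does **not** emulate: linkage disequilibrium,
realistic chromosome maps, ascertainment bias of chip design, admixture
or relatedness within populations, and informative missingness. Passing
tests on synthetic data therefore establish the internal correctness and
calibration of the pipeline — selection picks the provably top-Δ
markers, assignment matches the Bayes rule, simulated divergence is
recovered — but not field performance on any real breed, which depends
on those unmodeled features.

# Numerical conventions and problem sizes

* HWE exact p-values accumulate probabilities with a `1 + 1e-10`
  relative guard when comparing configuration probabilities, so
  mathematically tied configurations are included regardless of
  floating-point rounding; the suite verifies agreement with direct
  log-factorial enumeration to 1e-12 for all configurations of up to 30
  diploids.
* Posteriors are validated against a dense matrix-inverse Bayes
  computation to 1e-10 on random 5-class, 20-marker problems, and
  against an independent reference LDA implementation.
* Tests run at deliberately desk-sized problem dimensions (hundreds to a
  few thousand SNPs, the study-shaped 306-sample design, 20,000 SNPs for
  the divergence-calibration check), chosen so the full suite completes
  in about a minute while keeping every Monte-Carlo check at ≥ 3
  standard errors of headroom.
* All randomness flows from integer seeds through per-stage derived
  streams; a fixed seed reproduces every artifact byte for byte.

# Limitations

The discriminant assumes a shared within-class covariance; strongly
breed-specific LD around panel markers would violate it. F1 detection
does not extend to backcrosses or later generations, whose expected
heterozygosity sits between purebreds and F1s. Panel selection is
greedy per comparison — it does not search the combinatorial space of
k-SNP subsets — which is the point of the delta approach: transparent,
assay-ready marker lists rather than optimized black boxes.
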