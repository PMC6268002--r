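---
title: "Models and design choices in finecoloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in finecoloc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finecoloc)
```

This vignette documents the statistical models the package implements,
the assumptions behind them, the parameters that matter, and the design
choices made where the design was genuinely open. It is the reference the
test suite is written against.

## The summary-statistic locus model

All fine-mapping engines share one generative model. For a locus of $m$
SNPs with LD correlation matrix $\Sigma$, binary causal indicator $C$ and
non-centrality vector $\lambda$ (the expected z-score magnitude at causal
SNPs), the observed association z-scores are

$$ Z \sim N(\Sigma(\lambda \circ C),\ \Sigma). $$

The model assumes the summary statistics and the LD matrix come from the
same (or a well-matched) population, that effects are well-approximated
on the z-scale, and that one locus is analysed at a time. Effect sizes
relate to z through the standardized-trait convention
$\beta = z/\sqrt{n}$, $se = 1/\sqrt{n}$, which keeps summary tables
internally consistent without individual-level data.

## Bayes-factor configuration posteriors

With a $N(0, s^2 I_k)$ prior on the non-centrality of the $k$ causal
SNPs, integrating $\lambda$ out gives the marginal likelihood
$Z \sim N(0,\ \Sigma + s^2 \Sigma_C \Sigma_C^\top)$, where $\Sigma_C$
holds the causal columns of $\Sigma$. The Bayes factor of a configuration
against the null is the corresponding density ratio. Because
$\Sigma^{-1}\Sigma_C$ is simply the causal-column selector, the ratio
reduces exactly to $k \times k$ algebra:

$$ \log BF = -\tfrac12 \log\det(I_k + s^2\Sigma_{cc})
   + \tfrac{s^2}{2}\, z_c^\top (I_k + s^2\Sigma_{cc})^{-1} z_c, $$

with $\Sigma_{cc} = \Sigma[\text{causal}, \text{causal}]$ and
$z_c = z[\text{causal}]$. This identity is used throughout: it is exact,
fast, and remains well-defined when $\Sigma$ itself is singular
(duplicated SNPs), since $I_k + s^2\Sigma_{cc}$ is always positive
definite. The prior-integrated (centered) form is used rather than a
plug-in mean form; the two parameterizations agree in ranking but not in
scale, and the centered form is the one with a clean marginal-likelihood
interpretation.

The unnormalized posterior of a size-$k$ configuration is
$\binom{m}{k}^{-1} p_k \, BF$; $m$ is the number of SNPs in the locus, so
$\binom{m}{k}$ counts the size-$k$ configurations. Normalization is over
the evaluated set, in log space with log-sum-exp.

Parameters and defaults:

- `prior_sd` ($s$), default **3** on the z scale. Genome-wide-significant
  associations typically arrive with $|z|$ between 5 and 8; a prior SD of
  3 covers that range without swamping moderate signals. It is the one
  knob worth revisiting for very large or very small studies.
- `p_k`, default **uniform over $k = 0..k_{max}$**, with the null
  included so "no causal variant" is a scored hypothesis.
- `k_max`, default **5** (configurable); exhaustive enumeration is capped
  at $m \le 25$.

### Shotgun stochastic search

`posterior_sss()` starts from the null configuration and, per iteration,
expands one configuration — sampled from the evaluated-but-unexpanded
pool with probability proportional to its unnormalized posterior — by
scoring its full add/delete/swap neighborhood. Expanding each
configuration at most once pushes every iteration into new territory
while concentrating effort where the mass is; all scores are cached, the
posterior is normalized over everything evaluated, and a fixed seed gives
an identical trajectory. For a 15-SNP locus with $k_{max}=3$ (577
configurations) 500 iterations evaluate the space essentially completely,
which is how the package verifies search against enumeration.

### Numerical choices

Cholesky factorization is attempted on $\Sigma$ as given; a ridge of
$10^{-6}$ on the diagonal is added **only if factorization fails**
(perfect-LD duplicates). An unconditional ridge would perturb every Bayes
factor by a small but needless amount; the adaptive ridge keeps
well-conditioned problems exact and degenerate ones solvable. Ties in
credible-set construction break by SNP id after PIP, so output is stable.

## PICS-style permutation posteriors

`pics_posterior()` asks, for each candidate causal SNP $j$ (all SNPs at
$r^2 > 0.5$ to the lead, plus the lead itself): how plausible is the
observed $-\log_{10} p$ profile if $j$ were causal at the lead's observed
strength $S$? Under hypothesis $j$, SNP $i$'s association is drawn from
$N(r_{ij}^2 S,\ sd(r_{ij}, S))$ with the empirical dispersion

$$ sd(r, S) = \sqrt{1 - |r|^{6.4}} \cdot \sqrt{S}/2, $$

exposed as a configurable callable (`pics_sd`); $|r|$ is used because a
fractional power of a negative correlation is undefined and LD strength
is what matters here. The likelihood of the observed profile is
estimated from `n_perm` permutation draws per SNP via a Gaussian kernel
density (Silverman bandwidth, independence across SNPs), and posteriors
follow Bayes' rule with equal priors. A closed-form Normal-density
variant (`method = "normal"`) skips the permutations and must agree in
ranking — a standing cross-check in the tests.

Two guards matter in degenerate corners. The Silverman bandwidth is
floored at $10^{-8}$ so identical draws (perfect LD) still define a
density, and the model dispersion itself is floored at `sd_floor = 0.05`
on the $-\log_{10}p$ scale: at $|r| = 1$ the model's dispersion is
exactly zero, and because the mapping between $z$ and $-\log_{10} p$ is
not exactly quadratic, a zero-dispersion hypothesis would be annihilated
by rounding-level mismatches rather than judged on its merits. The floor
is two orders of magnitude below typical dispersions
($\sqrt{S}/2 \approx 1.5$) and leaves non-degenerate hypotheses
untouched. Defaults `n_perm = 10000` and `r2_min = 0.5` are the
conventional operating point for this procedure.

## Annotation-informed empirical Bayes

`em_fit()` couples the locus likelihood (plug-in form: the density of
$Z$ at mean $\Sigma(\lambda \circ C)$ with $\lambda_j = z_j$ at causal
positions — the practice of annotation-aware fine-mapping tools; the
prior-integrated alternative is available through the Bayes-factor
engine) with a logistic prior per SNP,
$P(\text{causal}) = \text{logistic}(\gamma_0 + \gamma \cdot A_j)$. The
E-step enumerates configurations with $k \le k_{max}$ per locus
(default **2**: full $2^m$ enumeration is intractable and $k_{max}=2$ is
the conventional per-locus cap); the M-step refits $\gamma$ by weighted
logistic regression of the per-SNP posterior causal probabilities on the
annotations, via Newton–Raphson with step halving (tolerance $10^{-6}$,
coefficients clipped at $\pm 10$ with a warning under separation). The
expected complete-data log-likelihood is exactly the weighted logistic
objective, so this is a proper EM and the marginal log-likelihood is
non-decreasing — asserted in every test run. Because the likelihood does
not depend on $\gamma$, per-configuration likelihoods are computed once
per locus (using the same $k \times k$ reduction as the Bayes-factor
engine) and reused across iterations.

## SMR and HEIDI

The SMR statistic at an instrument SNP is
$T_{SMR} = z_g^2 z_e^2/(z_g^2 + z_e^2)$ on one chi-square df, with the
ratio estimate $b_{xy} = \beta_{GWAS}/\beta_{eQTL}$ (trait units per unit
expression). HEIDI tests whether $b_{xy}$ is homogeneous across cis-SNPs:
under a single shared causal variant it is constant; under linkage it
varies. For each secondary SNP the difference
$d_i = b_{xy}(i) - b_{xy}(\text{top})$ is standardized using delta-method
variances with LD-induced covariance (GWAS and eQTL samples independent),
and $\sum z_{d_i}^2$ is referred to a two-moment Satterthwaite-scaled
chi-square: $E[Q] = q$, $Var[Q] = 2\lVert R_d\rVert_F^2$ where $R_d$ is
the correlation matrix of the $z_{d_i}$. Satterthwaite avoids
eigen-decomposition edge cases; an eigenvalue mixture-of-chi-squares
Monte-Carlo mode is provided for cross-checking and agrees within
simulation error.

Secondary-SNP selection defaults are the conventional ones: eQTL
$p < 1.57\times10^{-3}$ (i.e. $|z| > 3.16$), $0.05 \le r^2 \le 0.9$ with
the instrument, at most 20 SNPs (most significant first), and a minimum
of 3 — fewer returns a missing p-value with a reason code rather than an
error. The pipeline thresholds (cis-eQTL $P < 5\times10^{-5}$, GWAS
$P < 0.05$ at the instrument, colocalized iff $P_{SMR} < 0.05$ and
$P_{HEIDI} > 0.05$) are applied nominally, with no multiple-testing
correction, matching the decision rule as printed.

## Motif machinery

PWMs carry counts, a background composition and a pseudocount (default
**0.8**, distributed across bases proportionally to the background — the
common convention in the JASPAR ecosystem; relative scores depend on it,
which is why it is exposed). Scores are summed log2-odds; the relative
score is $(S - S_{min})/(S_{max} - S_{min})$, computed on the log-odds
scale (the scan-tool convention), so the consensus scores exactly 1 and
the value is invariant to per-column constant shifts. The background
defaults to uniform 0.25 for allele scoring; for genome-style scans the
documented composition is (0.29, 0.21, 0.21, 0.29), settable per call.

`score_pvalue()` computes $P(S \ge s)$ exactly by convolving per-column
score distributions on an integer grid (granularity $10^{-3}$ log-odds
units — small enough that discretization error is far below any
decision threshold, large enough that the state space stays tiny).
Scores above the maximum return the boundary mass $P(S = S_{max})$; the
minimum returns 1. `scan_sequences()` scans both strands by default with
a $10^{-4}$ p-value cutoff and greedy non-overlapping selection
(descending score; ties leftmost, then '+' strand). Hits use 0-based
half-open starts; a '−' hit's start refers to the forward-strand window.
`allele_best_scores()` builds both haplotype sequences across a variant
(alleles may differ in length, so a 1-bp deletion shifts the frame) and
maximizes the relative score over every window overlapping the allele on
either strand. `density_profile()` bins target sites at signed offsets
from reference centers (defaults ±10,000 bp, 500-bp windows) and
normalizes globally by $n_{ref}\, n_{target}\, w / L_{genome}$ so a
uniform target field gives fold change 1 in every bin.

## Allelic expression imbalance

The calibration curve regresses measured log2 fluorescence ratio on true
log2 allele ratio from the 4:1, 2:1, 1:1, 1:2, 1:4 mixing series (true
log2 ratios 2, 1, 0, −1, −2). Correction inverts the fit,
$(measured - intercept)/slope$, for cDNA and gDNA alike; the normalized
allelic ratio is $2^{\,corrected_{cDNA} - corrected_{gDNA}}$, so a
balanced heterozygote sits at exactly 1. The cohort test is a one-sample
t-test of log2 ratios against 0 (matching mean ± SD reporting; a
Wilcoxon option exists), symmetric under allele relabeling. All ratios
exactly 1 is reported as "no evidence" (p = 1). The identical operation
normalizes allele-specific ChIP ratios with input DNA in the gDNA role.

## What the synthetic generator does and does not emulate

`sim_haplotypes()` uses a first-order Markov copy process: each SNP
copies its left neighbour's allele with probability `rho`, else redraws
at its own target frequency. This gives tunable, geometrically decaying
LD at desk scale — sufficient for every statistical property the engines
rely on — but it is not a coalescent: no recombination hotspots, no
demography, no mutation-age structure, no imputation error. Frequencies
are drawn uniformly from `maf_range`; when adjacent target frequencies
differ, realized adjacent correlation falls slightly below `rho`.
Passing tests on these panels demonstrates correctness of the
statistical machinery under the stated model, not robustness to
real-panel pathologies (strand errors, structural variants, population
mismatch) — of those, only allele-orientation errors are modelled, and
they are handled by `harmonize_alleles()` which flips swapped alleles
and refuses anything else (no silent frequency-based strand flipping;
that is the classic summary-statistics bug).

## Problem sizes in tests and acceptance runs

The shipped checks use: 20 loci of 15 SNPs for search-vs-enumeration; 100
single-causal loci of 12 SNPs at $\lambda = 6$, $\rho = 0.7$ for
planted-causal recovery (at $\rho = 0.9$ each causal SNP has flanking
partners near $r = 0.9$, and the identifiability ceiling
$\Phi(\lambda\sqrt{(1-r)/2}) \approx 0.91$ per partner makes high
recovery unattainable for any method — moderate LD is the regime where
recovery is a meaningful property of the engine rather than of the
panel); 50 loci of 20 SNPs with two causal SNPs each at $\lambda = 7$
for enrichment recovery (two causal SNPs per locus double the effective
annotation draws, making the ±0.5 recovery band a ~2.3σ event rather
than a coin flip) and 100 × 100-SNP loci at baseline annotation rate 0.5
for the null; 2,000 pleiotropy and 500 linkage replicates on a 30-SNP
panel for HEIDI calibration; and 4-column matrices (256 sequences) for
exact PWM enumeration. These sizes were chosen so each property is
measured with comfortable statistical resolution.

## Known limitations

- Single-SNP conditioning only (`conditional_z`); stepwise multi-SNP
  joint model selection is out of scope.
- The individual-level likelihood mode of configuration fine-mapping is
  not implemented; everything runs from summary statistics.
- HEIDI relies on delta-method variances; with very weak secondary
  instruments the ratio distribution is heavy-tailed and the
  approximation degrades (the selection threshold $|z| > 3.16$ is the
  guard).
- The enrichment EM enumerates up to `k_max` causal SNPs per locus;
  strongly polygenic loci violate that truncation.
- PWM scanning assumes independent positions (PWM model) and a 0-order
  background; no dinucleotide background or motif discovery.
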