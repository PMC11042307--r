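---
title: "Genetic paths: model, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic paths: model, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(giftpath)
```

## The model

Conventional single-marker association tests compare group means: the
phenotype is stratified by genotype at one SNP and a regression or t-type
statistic asks whether the strata differ in location. Everything inside a
stratum is exchangeable to such a test, so any association that does not move
the group means — in particular one whose sign depends on where an individual
sits in the phenotype distribution — is invisible to it.

`giftpath` implements the genetic-path alternative (the GIFT approach).
Each diploid genotype at a bi-allelic SNP is collapsed to a *microstate*:

* `+1` for A/A and T/T homozygotes,
* `-1` for G/G and C/C homozygotes,
* `0` for anything else (heterozygotes and the strand-ambiguous A/T, G/C
  pairs).

Individuals are ordered by ascending phenotypic residual and the microstates
are cumulatively summed into the *genetic path*
$\theta(i) = \sum_{j \le i} m_{(j)}$, with $\theta(0) = 0$. If the ranking
carries no information about the genotype, scrambling the string leaves the
path statistically unchanged: the permutation-mean path is the straight line
$\theta_0(i) = \tan(\alpha)\, i$ with $\tan(\alpha) = (N_+ - N_-)/N$. All
structure therefore lives in the anchored difference
$\Delta\theta(i) = \theta(i) - \theta_0(i)$, which is exactly zero at both
ends because $\theta(N) = N_+ - N_-$ is a conserved quantity of the
multiset.

Two shapes matter. A constant allelic effect segregates `+1` and `-1`
microstates to opposite ends of the ranking and produces a *paraboloid*
$\Delta\theta$ with one dominant interior extremum — exactly the situation
mean-comparison tests also detect. A scale-dependent effect, with opposite
sign in the lower and upper part of the residual range, produces a *sigmoid*
$\Delta\theta$ that crosses zero in the interior while leaving the group
means nearly equal — invisible to the mean-based test, plainly visible in
the path.

## The path p-value

The first-occurring maximum and minimum of $\Delta\theta$ over positions
$1..N$ split the string into three blocks of lengths
$\Delta i_1, \Delta i_2, \Delta i_3$. With $n_q^p$ microstates of type $q$
in block $p$, the number of arrangements of the multiset that reproduce the
block compositions is $N_1 N_2 N_3$ with
$N_p = \Delta i_p! / (n_+^p!\, n_0^p!\, n_-^p!)$, and

$$\hat p = \frac{N_1 N_2 N_3}{N^0_{\text{path}}},
  \qquad N^0_{\text{path}} = \frac{N!}{N_+!\,N_0!\,N_-!}$$

is the fraction of all arrangements sharing them. A strongly ordered path is
reproduced by very few arrangements, so small $\hat p$ means strong
association. For every multiset with $N \le 8$ the test suite checks this
formula against brute-force enumeration (counting matching arrangements
directly, without the multinomial formula); the two routes agree exactly.

**$\hat p$ is a score, not a uniform p-value.** The extremum partition is an
extreme-value selection, so even under the permutation null $\hat p$ is far
below uniform (at $N = 565$ its null median is near $10^{-5}$). Significance
is therefore calibrated empirically: `calibrate_thresholds()` simulates `K`
null paths for each of six "theoretic" SNP count presets (N = 565, a fixed
`+1` count and 100 microstates transferred between the `-1` and `0` classes
across presets), pools the $-\log_{10}\hat p$ values, and takes the pooled
95th/99th percentiles as the significance lines. Fresh null paths exceed
those lines at 5%/1% by construction, which the acceptance suite verifies.

Two consequences of the score nature are handled explicitly:

* **FDR.** Benjamini–Hochberg applied to raw $\hat p$ would declare nearly
  every SNP of an all-null panel significant. `gift_scan()` still reports
  `p_gift = bh_adjust(p_hat)` because that is the conventional output
  column, but for genuine FDR control `null_calibrated_pvalues()` first maps
  each observed $-\log_{10}\hat p$ to an empirical p-value against the
  pooled null sample of a calibration object; those are approximately
  uniform under the null and BH behaves as intended. The all-null-panel FDR
  check in the test suite uses this route.
* **Sample-size dependence.** The null distribution of $-\log_{10}\hat p$
  shifts upward by roughly 0.6–0.7 decades per doubling of $N$ at fixed
  microstate frequencies (measured: pooled q95 ≈ 6.3 at N = 280, 7.0 at
  N = 565, 7.7 at N = 1130). Thresholds should therefore be calibrated at
  counts comparable to the cohort being scanned; the between-SNP variation
  at fixed $N$ is small (median spread well inside the pooled IQR), which is
  what makes one threshold pair per cohort size reasonable. Note the
  *variance of the null path itself* is genuinely size-invariant once
  normalised — $\mathrm{Var}\,\theta_0(i) = \frac{i(N-i)}{N-1}\sigma^2_m$
  with $\sigma^2_m$ the population variance of the microstate values, a
  pure function of $i/N$ and the frequencies — the two statements are not in
  tension.

## Numerical choices

* All arrangement counting is done in log-gamma space; at $N = 565$ the
  factorials overflow any fixed-width type.
* Extrema of $\Delta\theta$ are located on the integer-scaled path
  $N\theta(i) - (N_+ - N_-)i$, so ties are exact and resolved to the
  smallest index deterministically. A flat (monomorphic) path degenerates to
  $i_{\max} = i_{\min} = 1$ and $\hat p = 1$.
* Region boundaries follow the half-open convention $(0, i_1], (i_1, i_2],
  (i_2, N]$: the extremum's microstate terminates its region, because the
  path value at $i$ is determined by microstates $1..i$. The alternative
  convention (extremum opens the next region) is available via
  `path_partition(boundary = "open")` for cross-checking published tables.
* Residual ties are broken by input (canonical) order; the ranking is
  otherwise "small to large".
* Missing genotype calls are pairwise-deleted per SNP — the individual
  drops out of that SNP's path — never imputed to `0`, which would distort
  the path shape.
* Dominance is reported as $d = \mu_0 - (\mu_+ + \mu_-)/2$ (Falconer); the
  alternative reading $d = a - \mu_0$ of some published table footnotes is
  available behind `gene_effect_dominance(convention = "a_minus_mu0")`.
* Seeding: `calibrate_thresholds()` derives one RNG stream per theoretic
  SNP from the master seed by a stable string hash, so results do not depend
  on the order in which SNPs are listed.

## The simulators and what they emulate

`simulate_fisher_cohort()` draws one SNP in Hardy–Weinberg proportions and
an additive phenotype. Defaults are the package's reference conditions:
n = 1000, genotype class frequencies (0.64, 0.32, 0.04) (allele frequency
0.8), phenotype mean 68 and standard deviation 2 units, gene effect equal to
the phenotype standard deviation, no dominance. Noise is drawn per
individual with sd equal to the phenotype sd, so each microstate class is
normally distributed about its own mean — the class-conditional convention,
chosen over fixing the total phenotype variance.

`simulate_sign_flip_cohort()` is the minimal mechanism for scale-dependent
association: two equally likely latent subpopulations occupy disjoint
residual ranges (separation $4\sigma + 2|a|$ by default) and the allelic
effect flips sign between them. Group means then almost coincide while the
ranked path is sigmoid. This is a concrete instantiation of the
phenomenology, not a published generative equation.

`simulate_theoretic_snp()` scrambles exact count multisets (the six presets
above) for pure-null calibration work, and `simulate_genome_panel()` mixes
null, linear and sign-flip SNPs across fake chromosomes for end-to-end scan
and ROC experiments.

What the simulators deliberately do **not** model: linkage disequilibrium
between SNPs, relatedness/pedigree structure, epistasis, genotyping error,
and multi-allelic sites. Passing tests on these cohorts therefore
demonstrate the statistical machinery under idealised sampling, not
robustness to the correlation structure of real genotype panels.

## Problem sizes used by the checks

The test suite and the acceptance script run at deliberately chosen sizes:
threshold calibration uses the six presets at K = 1000 null paths each;
the power-contrast experiment uses 200 sign-flip cohorts of n = 500 with
effect 2 at noise sd 1; parameter recovery uses 200–500 additive cohorts of
n = 1000; the all-null FDR experiment uses 30 panels of 200 SNPs at
n = 300 with thresholds calibrated from K = 2000 nulls per preset. These
sizes put Monte-Carlo error comfortably inside the asserted bands.

## Baseline caveat

The bundled single-marker baseline is ordinary least squares on microstate
dosage (plus pooled-variance t-tests between microstate groups). It is not
a kinship-corrected mixed model, so on real, structured cohorts its
p-values will differ from mixed-model GWAS output; comparisons against
published mixed-model columns are qualitative. Fixed-effect adjustment
(`adjust_fixed_effects()`, e.g. farm + sex, optional natural-log transform)
is provided for pre-correcting phenotypes before ranking.

## A worked miniature

```{r example, eval = FALSE}
set.seed(1)
co <- simulate_sign_flip_cohort(n = 500, a_true = 2, seed = 7)
scan <- gift_scan(co)
th <- calibrate_thresholds(theoretic_snp_presets(), K = 1000, seed = 1)
scan$mlog10_p_hat        # far beyond th$level99
scan$p_gwas              # unremarkable: the OLS baseline sees nothing
autoplot(genetic_path(co$phenotypes$phenotype,
                      encode_genotypes(co$genotypes)$microstate))
```
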