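---
title: "Screening SNPs for variance heterogeneity with Levene-type multiple contrast tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening SNPs for variance heterogeneity with Levene-type multiple contrast tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(levenemct)
```

## Why test variances at a SNP?

A biallelic SNP partitions a cohort into three genotype groups (0, 1 or 2
copies of an allele). Association studies usually compare the *means* of a
quantitative trait across these groups. The variances carry complementary
information: if the locus interacts with another locus or with an
environmental exposure that is not in the model, the trait variance differs
among its genotype groups even when the means do not. A
variance-heterogeneity test therefore screens for *potentially interacting*
loci (variance QTLs, "vQTLs") without enumerating candidate partners — a
single genome scan instead of a quadratic number of pairwise interaction
tests.

## The model and the two test families

Let $Y_{ji}$ be the trait value of individual $i$ in genotype group
$j \in \{0, 1, 2\}$, with group sizes $n_j$, $N = \sum_j n_j$ and $J$
non-empty groups. All tests act on the median-based Levene residuals
$$Z_{ji} = |Y_{ji} - \mathrm{median}(Y_{j\cdot})|,$$
which turn a variance difference among the $Y$ into a mean difference among
the $Z$ (the Brown–Forsythe variant; the median makes the transformation
robust to skewness and outliers).

**Global Levene test** (`levene_test()`): the one-way ANOVA F statistic on
the $Z_{ji}$,
$$T^2 = \frac{(N-J)\sum_j n_j (\bar Z_{j\cdot} - \bar Z_{\cdot\cdot})^2}
             {(J-1)\sum_j \sum_i (Z_{ji} - \bar Z_{j\cdot})^2},$$
referred to $F(J-1,\, N-J)$. It answers "are the variances unequal?" but
not "which genotype is responsible?".

**Multiple contrast tests** (`mct_test()`): for a contrast matrix
$C = (c_{kj})$ with zero row sums,
$$T_k = \frac{\sum_j c_{kj}\, \bar Z_{j\cdot}}
             {S \sqrt{\sum_j c_{kj}^2 / n_j}},$$
where $S^2$ is the pooled residual mean square of the one-way model on $Z$
with $\nu = N - J$ degrees of freedom. Under homoscedasticity the vector
$(T_1,\dots,T_K)$ is jointly multivariate $t$ with $\nu$ degrees of freedom
and correlation matrix
$$\rho_{kk'} = \frac{\sum_j c_{kj} c_{k'j}/n_j}
  {\sqrt{(\sum_j c_{kj}^2/n_j)(\sum_j c_{k'j}^2/n_j)}},$$
which depends only on $C$ and the group sizes. The max-$|t|$ statistic
yields single-step adjusted p-values
$\tilde p_k = 1 - P(\max_m |T_m| \le |t_k|)$, computed by
`mvt_rectangle_prob()`; the smallest adjusted p-value is the global test,
and each contrast keeps an interpretable, familywise-error-controlled
p-value of its own.

Two contrast families are built in:

* **Grand-mean ("Ave") contrasts** (`ave_contrasts()`): each genotype group
  versus the average of the other two — rows $(-1, \tfrac12, \tfrac12)$ and
  permutations for $J = 3$. The optional `weights` argument (typically the
  group sizes) replaces the simple average by the group-size-weighted grand
  mean, $c_k = n/N - e_k$; for balanced groups the two versions give
  identical statistics, while for unbalanced designs the weighted version
  down-weights sparsely observed groups and has noticeably better power.
* **Pairwise contrasts** (`pairwise_contrasts()`): all $J(J-1)/2$
  group-versus-group comparisons, Tukey-style.

The rejection of the global hypothesis is accompanied by elementary
decisions: e.g. "the heterozygote variance differs from the homozygotes" —
exactly the kind of allele-level statement a follow-up study needs.

### Design choices

* **Two-sided by default.** The maximum is taken over $|T_k|$, so both
  inflated and deflated group variances are detected; this matches the
  convention of general-purpose simultaneous-inference software and keeps
  the per-contrast p-values interpretable in both directions. A one-sided
  variant (`alternative = "greater"`) is available for screens that only
  care about variance increases.
* **Contrast labels name both sides** ("var(AG) vs avg var(AA,GG)") so no
  directional claim is implied by a sign convention.
* **$S$ uses denominator $N - J$**, consistent with $\nu = \sum_j (n_j-1)$.
* **Degenerate data are classed errors**, not silent results: an empty
  group, $N - J < 1$, or zero residual variance raise conditions that the
  scan driver converts into an `untestable` flag.

## Numerical details

The rectangle probabilities $P(\max_k |T_k| \le b)$ are evaluated with the
Genz–Bretz quasi-Monte-Carlo algorithm (package \pkg{mvtnorm}) to an
absolute tolerance of $10^{-4}$, under a locally set seed that is part of
the call contract — repeated calls give identical p-values, and the
caller's RNG stream is untouched. The contrast-induced correlation
matrices are singular (rank $J-1$); the integrator handles this directly.
For $K = 1$ the probability reduces analytically to the univariate $t$.
The test suite cross-checks the integrals against a $10^6$-draw Monte-Carlo
oracle and the exact chi-mixture integral
$E[(2\Phi(b\,s) - 1)^K]$, $s^2 \sim \chi^2_\nu/\nu$, for uncorrelated
coordinates (note the components always share one $\chi^2$ denominator, so
even the identity-correlation case does not factorise into univariate
probabilities).

In the simulation engine the decision `global p < alpha` is taken by
comparing $\max_k |T_k|$ with the critical value solving
$P(\max|T| \le q) = 1-\alpha$ (`mct_critical_value()`), which is equivalent
by monotonicity and removes thousands of integrations; critical values are
memoised per (contrast family, group sizes, $\alpha$, seed).

## The simulation engine: what it emulates

`run_simulation()` reproduces a classical size/power study design for these
tests: standard normal traits whose group standard deviations follow a mode
of inheritance, $\sigma_j$ indexed by the number of copies of the
variance-increasing (dominant) allele —

| mode | $(\sigma_0, \sigma_1, \sigma_2)$ |
|------|-----------------------------------|
| additive  | $(1,\; 1+\delta,\; 1+2\delta)$ |
| dominant  | $(1,\; 1+2\delta,\; 1+2\delta)$ |
| recessive | $(1,\; 1,\; 1+2\delta)$ |

with $\delta = 0$ the homoscedastic null. Samples are allocated to
genotype groups under Hardy–Weinberg equilibrium at recessive-allele
frequency $p$, i.e. group proportions $(p^2,\, 2p(1-p),\, (1-p)^2)$: at
$p = 0.75$ only $6\%$ of samples carry two dominant alleles, the severely
unbalanced case where the weighted grand-mean contrasts matter.

Two allocation schemes are provided:

* `allocation = "multinomial"` (default): every replicate redraws each
  sample's genotype from the HWE frequencies. Replicates in which any
  genotype group has fewer than two observations are counted as
  **non-rejections** (their group variance is not estimable) and reported
  as `n_excluded`. This convention is what produces the strongly
  sub-nominal empirical sizes at small $N$ and large $p$ (down to
  $\approx 0.014$ at $p = 0.75$, $N = 25$, where half the replicates are
  affected): the effective test is conservative exactly where the design is
  most fragile.
* `allocation = "fixed"`: deterministic largest-remainder allocation
  (`hwe_group_sizes()`, minimum group size 2), a variance-reduced design
  whose power at unbalanced configurations is higher than the
  multinomial scheme's because no replicates are forfeited.

Replicates are drawn from a single seeded stream with all data generated
before any test is applied, so results are bit-for-bit reproducible and
identical regardless of which subset of tests is requested.
`replicate_table()` runs the full grid $p \in \{0.5, 0.75\}$,
$N \in \{25, 50, 75, 100\}$, $\delta \in \{0, 0.5, 1\}$. At these problem
sizes a 2,000-replicate grid of all three modes completes in a few minutes
on one CPU; the bundled acceptance script uses 10,000 replicates per
reported cell.

What the generator does **not** emulate: non-normal trait distributions,
linkage disequilibrium between SNPs, population structure, covariates, or
mean effects co-occurring with variance effects. Passing simulation checks
therefore demonstrate correctness of the statistical machinery under the
stated model, not robustness on arbitrary real cohorts.

## The genome scan

`vqtl_scan()` applies all three tests SNP-by-SNP with pairwise-complete
missing-data handling, per-SNP empty-group reduction (a SNP with no
minor-allele homozygotes is tested with $J = 2$ and flagged `reduced`),
and a per-SNP integration seed derived from the master seed and the SNP
identifier, so results are independent of SNP order. Genotypes are coded
0/1/2 by minor-allele count.

Reporting filters follow the customary practice for variance tests:
`apply_group_filters()` flags SNPs where a genotype category holds less
than 1% of the samples or where fewer than 5 minor-allele homozygotes were
observed — group variances estimated from a handful of observations are
unstable, and a significant variance test driven by 2 or 3 individuals is
not evidence worth following up. Filters **flag, never drop**, so the
denominator of the Bonferroni correction (`bonferroni_flag()`, default:
post-filter count) remains an explicit, auditable choice.
`qq_manhattan_tables()` emits plotting tables pairing observed
$-\log_{10} p$ with uniform order-statistic quantiles $(i - 0.5)/m$.

## Synthetic data

`generate_fixture()` draws genotypes per SNP under HWE at uniform-random
minor-allele frequencies and a standard normal phenotype, optionally
planting one vQTL whose genotype scales the phenotype's standard deviation
by a `variance_profile()`. The end-to-end check plants a dominant-mode
vQTL with $\delta = 1$ at $N = 1000$ among 200 null SNPs (minor-allele
frequencies 0.2–0.5, so the planted signal is never removed by the
group-size filters) and requires the planted SNP to be the unique
Bonferroni-significant hit in at least 90% of 20 seeds — at these settings
the per-SNP power is essentially 1 while roughly one scan in twenty shows
an additional chance hit at the $\alpha/m$ threshold.

## Known limitations

* The multivariate-$t$ adjustment assumes approximately normal,
  homoscedastic Levene residuals; for very small groups ($n_j < 5$) the
  approximation, like the underlying variance estimate, is fragile — hence
  the reporting filters.
* At loci with a rare minor allele the tests lose both power and stability;
  the scan reports such SNPs but flags them.
* The weighted and unweighted grand-mean contrasts answer slightly
  different questions in unbalanced designs (weighted: deviation from the
  cohort-wide mean residual; unweighted: deviation from the simple average
  of the other groups' means). The simulation engine defaults to the
  weighted form, which is the behaviour of the reference size/power study
  it reproduces; `mct_test()` on real data defaults to the unweighted,
  equal-coefficient form, which is the printed definition of the method.
* Covariate adjustment and related samples are out of scope; residualise
  the trait beforehand if needed.
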