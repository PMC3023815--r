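---
title: "Genome-wide significance thresholds under linkage disequilibrium"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-wide significance thresholds under linkage disequilibrium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwasthresh)
```

## The problem

A case/control genome-wide association scan tests hundreds of thousands of
SNPs, so the probability of at least one false positive across the study —
the family-wise error rate (FWER) — is $1 - (1-\alpha)^n$ for $n$
*independent* tests at per-test level $\alpha$. A Bonferroni correction
$\alpha/n$ with $n$ equal to the SNP count controls this, but SNPs in
linkage disequilibrium (LD) are correlated, so the number of *effectively
independent* comparisons is smaller than the SNP count and plain Bonferroni
over-corrects. This package implements, on one common interface, the four
families of corrections practitioners use to account for that dependence,
plus the evaluation logic that gauges each of them against the permutation
null:

1. **Permutation minP** (`permute_minp()`): permute case/control labels $B$
   times, re-run the Cochran–Armitage trend scan each time, and keep the
   genome-wide minimum p-value. The empirical $\alpha$-quantile of those
   minima is the exact threshold for the realised genotype data; the ECDF of
   the distribution maps any candidate threshold to the study-wide error it
   really implies (`corresponding_alpha()`). This is the gold standard and
   the common gauge for everything else.
2. **Multivariate-normal sliding window** (`band_correlation()` +
   `sample_null_minp()`): per-SNP Z-scores are approximately jointly normal
   with correlation equal to the genotype (composite-LD) correlation, which
   is the same under binary and quantitative phenotype codings. Sampling
   $Z \sim \mathrm{MVN}(0, \Sigma_\text{banded})$ sequentially — each
   coordinate conditioned on the previous `window − 1` coordinates —
   reproduces the minP null without touching the phenotype.
3. **Effective number of tests** (`simplem_meff()`): the smallest $m$ such
   that the $m$ largest eigenvalues of the composite LD correlation matrix
   hold at least $C = 99.5\%$ of its total variance, summed over regions;
   $M_\mathrm{eff}$ replaces $n$ in Bonferroni.
4. **LD-block counts** (`gabriel_blocks()`, `solid_spine_blocks()`,
   `four_gamete_blocks()` + `block_test_count()`): Bonferroni with $n$ =
   number of haplotype blocks plus singleton SNPs, under the three classical
   block definitions (D′ confidence intervals; a solid spine of D′ ≥ 0.8;
   absence of the fourth gamete at 1%).

`compare_methods()` runs all of them on one dataset and reports, per method,
the threshold at level $\alpha$ and its corresponding alpha read off one
shared permutation distribution — anti-conservative methods stand out as
rows with corresponding alpha above $\alpha$.

## The trend test

The per-SNP test is the 1-df Cochran–Armitage trend test with additive
scores $x \in \{0,1,2\}$ (dosage of the counted allele):

$$Z = \frac{\sum_i x_i (y_i - \bar y)}
          {\sqrt{\bar y (1-\bar y) \sum_i (x_i - \bar x)^2}},$$

with $y$ the case indicator; $Z$ is asymptotically standard normal under
the null and $Z^2$ is the usual trend chi-square. P-values are two-sided.
Missing dosages are dropped per SNP (pairwise complete), which preserves
per-SNP exchangeability under label permutation; SNPs monomorphic among the
used samples are flagged and excluded from minima. Whether reference
permutation engines handle missingness identically is not documented
anywhere we know of; pairwise-complete is standard GWAS practice and is the
package's fixed convention.

## Pairwise LD from unphased genotypes

Two-locus haplotype frequencies come from the standard EM algorithm on the
3×3 joint dosage table: every cell is phase-unambiguous except the double
heterozygote, which the E-step splits between cis and trans phases in
proportion to their current likelihood. The EM start is linkage equilibrium
plus a tiny ($10^{-4}$-scale) cis-ward perturbation: a table consisting
entirely of double heterozygotes makes the equilibrium point a stationary
saddle of the EM map, and the nudge lets the iteration reach a likelihood
maximum there while being numerically irrelevant whenever any
phase-informative cell is present. From the fitted frequencies:
$D = p_{AB} - p_A p_B$, $D' = |D|/D_{\max}$ with the usual
marginal-constrained bound, and $r^2 = D^2/(p_A p_a p_B p_b)$.

The |D′| confidence interval behind the Gabriel definition is
likelihood-based: the genotype-table likelihood is evaluated on a 101-point
grid of |D′| values (haplotype frequencies parameterised by |D′| at the
observed allele frequencies, in the direction of the EM sign of D),
normalised to unit mass, and the 5%/95% tail bounds reported (90% two-sided
coverage). Grid size, coverage and all block-definition parameters are
exposed; the defaults follow common Haploview usage (strong LD: lower bound
≥ 0.70 and upper bound ≥ 0.98; recombination: upper bound < 0.90; at most
5% of informative pairs recombinant, i.e. `strong_fraction = 0.95`; Gabriel
candidate blocks accepted longest-first, ties to the leftmost). Pairs are
computed within a sliding window (default 250 SNPs, `ld_window`), which is
exact whenever the data's LD range is shorter than the window; the
`chunked_blocks()` mode re-includes the last full block of each chunk in
the next one and reproduces the single-pass partition on such data.

Reading of the "5% of informative markers" rule: we require at least 95% of
informative pairs to be in strong LD. The opposite reading (only 5% strong)
would accept essentially any region as a block and is incompatible with the
method producing meaningfully fewer tests than SNPs.

## The synthetic-data generator

There is no public genotype resource attached to this package's evaluation,
so all study conditions are emulated by `simulate_panel()` +
`simulate_genotypes()` + `assign_phenotypes()`:

* each LD block carries a pool of `K` haplotypes with Dirichlet(1)
  frequencies; a sample is two independent haplotype draws per block;
  blocks are independent (free recombination between blocks, none within);
* haplotype pools are generated on a **random perfect phylogeny**: every
  SNP mutates exactly once on a random binary tree over the `K`
  haplotypes. This guarantees that no within-block pair shows all four
  gametes, i.e. population $|D'| = 1$ inside blocks — which is what makes
  a pool a haplotype *block*. (An unconstrained random pool with
  $K \ge 3$ contains recombinant haplotypes at ~9% of its pairs, and block
  detectors then split it, correctly, into smaller blocks.) For $K = 2$
  the construction reduces to two complementary haplotypes;
* blocks are resampled until every SNP's implied minor allele frequency
  reaches `maf_min` (default 0.01, the usual QC floor);
* phenotypes are independent Bernoulli draws: constant probability under
  the null, per-dosage probabilities $(p_0, p_1, p_2)$ at one causal SNP
  under the additive alternative.

What the generator does **not** emulate: physical recombination maps and
LD that decays gradually with distance, long-range LD, population
stratification, relatedness, genotyping error and missingness patterns.
Passing tests on this generator therefore show that each method behaves as
designed when LD truly is blockwise and samples are exchangeable — they do
not certify behaviour on stratified or admixed cohorts.

Two fixture-design notes used by the test-suite and worth stating as
methodology. First, calibration fixtures that are supposed to represent
*detectable* independence use common SNPs (MAF floor 0.2): the four-gamete
test can only see recombination between two SNPs when the rarest haplotype
product clears its 1% frequency cutoff, so "independent but rare" SNP pairs
are invisibly merged by construction — a real property of the method, not
of the implementation. Second, simpleM region sizes are kept well below
the sample size (regions of ~100 SNPs at $n$ of a few hundred): the
composite correlation matrix of $m$ SNPs from $n$ samples has rank at most
$n - 1$, and letting $m$ approach $n$ deflates $M_\mathrm{eff}$ through
rank deficiency rather than through LD.

## Numerical and design choices

* **Quantile convention.** The threshold is the $\lceil \alpha B\rceil$-th
  smallest minimum p-value; corrected p-values use add-one smoothing,
  $(\#\{p_{\min} \le p\} + 1)/(B + 1)$, so they never return zero.
* **Permutation engine.** The case count is invariant under label
  permutation, so the denominator of $Z$ is fixed per SNP and a whole batch
  of permutations reduces to one matrix product; permutations are generated
  from a single seeded stream in batches, making the full run deterministic
  given `seed` regardless of batch size. SNPs with missing entries fall
  back to a per-permutation pairwise-complete path.
* **MVN regularisation.** Conditional variances below `ridge` ($10^{-6}$)
  are raised to it — exactly duplicated SNPs otherwise make the banded
  system singular. Bands never cross chromosome boundaries. The window
  default (100 SNPs) exceeds any block the generator produces; the test
  suite checks that widening it further leaves the threshold inside Monte
  Carlo error.
* **Eigenvalues.** Pairwise-complete correlation matrices need not be
  positive semi-definite; eigenvalues down to $-10^{-8}$ are clipped to
  zero, anything more negative raises an error.
* **HWE.** The exact conditional (Levene–Haldane) test, well-defined at any
  sample size, rather than the asymptotic chi-square; the p-value cutoff
  default is $10^{-6}$ and is exposed because published analyses rarely
  state theirs. QC removal precedence (call rate, then MAF, then HWE) is a
  reporting convention only — membership of the removed set is
  order-independent.
* **PLINK text I/O.** A 4-column `.map` carries no allele labels, so dosage
  orientation on re-read depends on first-seen allele order; the writer
  therefore emits a 6-column allele-bearing map by default, making
  `read_ped_map(write_ped_map(x))` an exact round trip. `"0"` is the
  missing-allele token; phenotype 1/2 maps to control/case.
* **Subset sensitivity sign.** `subset_delta()` reports signed
  `threshold_subset − threshold_full`. Published tables of this quantity
  are not always internally sign-consistent; the signed convention here is
  fixed and documented.

## Problem sizes used by the tests and the acceptance script

The package's evaluation runs at desk scale, chosen so each check finishes
in seconds to a couple of minutes while keeping Monte Carlo error well
inside the asserted tolerances: independence calibration on 1,000
uncorrelated SNPs at $n = 500$ with $B = 2{,}000$ permutations; the
method-comparison table on a 200-block × 5-SNP panel ($K = 2$–$4$,
$n = 1{,}000$, $B = 5{,}000$ permutations and MVN iterations); threshold
calibration over 500 independent null replicates of a 100-block panel at
$n = 200$; region re-cut stability on 150 blocks at $n = 2{,}000$; subset
sensitivity with 500 cases / 125 controls subset to 125/125 over 20 draws.

## Known limitations

* At the desk scales above, the block-count corrections measure
  corresponding alphas around 0.09–0.10 — anti-conservative and strictly
  above the eigenvalue/MVN/permutation group, but milder than on dense
  real GWAS panels, simply because a $K \le 4$ pool of 5 SNPs carries at
  most ~2 effective tests per counted block while real block partitions
  average far more SNPs (and effective tests) per block.
* The Gabriel informative-pair bookkeeping and tie-breaking in historical
  Haploview versions cannot be reconstructed exactly; parameters are
  exposed and the conventions fixed here are stated above.
* Thresholds are for the additive trend test only; covariate-adjusted
  models, survival and longitudinal phenotypes are out of scope (the MVN
  and eigenvalue routes are precisely the ones a practitioner would adapt
  for such tests).

## A worked example

```{r example, eval = FALSE}
panel <- simulate_panel(50, block_sizes = 5, pool_size = 2:4, seed = 1)
geno  <- simulate_genotypes(panel, 600, seed = 2) |>
  assign_phenotypes("null", prob = 0.5, seed = 3)

report <- compare_methods(geno, B = 2000, n_iter = 2000,
                          ld_window = 25, target_region_size = 60, seed = 4)
report
autoplot(report)
```
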