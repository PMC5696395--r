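---
title: "Measuring phylogenetic signal in compositional fatty-acid profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring phylogenetic signal in compositional fatty-acid profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylofa)
```

## The question and the model

Fatty-acid (FA) composition of consumer tissue is a functional trait: some
FAs are diet biomarkers (absolute bacterial markers such as a15:0, i15:0,
16:1w5, 16:1w7, i16:0, i17:0, cy17:0, 18:1w7 and cy19:0; the relative plant
marker 18:1w9; the relative fungal marker 18:2w6,9), while long-chain
polyunsaturated FAs such as 20:4w6 and 20:5w3 relate to physiological
functions. Whether related species resemble each other in these traits —
phylogenetic signal — is the question this package answers for replicated,
compositional FA measurements of species placed on a rooted ultrametric
phylogeny.

Both statistics implemented here assume Brownian motion (BM) as the
reference model: trait covariance between two species is proportional to
their shared root-to-MRCA branch length, collected in the phylogenetic
covariance matrix `C` (`phylo_covariance()`).

**Blomberg's K** compares the observed ratio of the trait variance about
the phylogenetic (GLS) mean under an identity structure (`MSE0`) and under
`C` (`MSE`) with the ratio expected under BM:

\[
K = \frac{MSE_0 / MSE}{\left[\operatorname{tr}(C) - n/(\mathbf{1}^\top
C^{-1}\mathbf{1})\right] / (n - 1)} .
\]

K = 1 matches the BM expectation, K > 1 means stronger resemblance among
relatives, K near 0 means none. K is invariant to affine trait maps and to
rescaling all branch lengths (both are tested properties).

**Measurement error.** Species means estimated from few replicate
measurements carry sampling error, which deflates K if ignored. When
per-species standard errors are supplied, the BM rate \(\sigma^2\) is first
estimated by maximizing the normal likelihood of the trait under
\(\sigma^2 C + \mathrm{diag}(se^2)\), and K is computed with the
error-inflated structure \(C + \mathrm{diag}(se^2)/\hat\sigma^2\). With all
`se = 0` this reduces exactly to plain K. Species with a single measurement
get `se = 0` (no within-species variance estimate exists), so the statistic
degrades gracefully to the plain form for those tips; such species are
flagged in messages. When the likelihood is monotone decreasing in
\(\sigma^2\), the MLE sits on the zero boundary (all variance attributed to
measurement error); this is reported as a warning, not an error.

**Pagel's lambda** multiplies the off-diagonal entries of `C` by
\(\lambda\) (`lambda_transform()`) and maximizes the profile likelihood over
\(\lambda \in [0, \lambda_{max}]\), where
\(\lambda_{max} = \) tree height / depth of the deepest internal node — the
largest value for which the transform is still a valid covariance. The test
compares `logL` at \(\hat\lambda\) against `logL0` at \(\lambda = 0\) (star
phylogeny) with an upper \(\chi^2_1\) tail on the likelihood ratio. On
small trees many estimates sit exactly on the \(\lambda_{max}\) ceiling; the
result carries an `at_ceiling` flag. On an equal-depth star tree the
likelihood is constant in \(\lambda\); the fit reports that flat condition
(`flat = TRUE`) instead of an arbitrary estimate.

## Null models and decisions

* **Permutation test (H0: no signal).** The assignment of (trait, se) pairs
  to tips is shuffled uniformly; the one-tailed add-one estimator
  \(p = (1 + \#\{K_{perm} \ge K_{obs}\})/(n_{perm} + 1)\) avoids p = 0 and is
  slightly conservative. Default 10,000 permutations. With measurement
  error, the error-standardizing rate \(\hat\sigma^2\) is held at the
  observed ML estimate across permutations by default — the standardization
  metric is part of the observed geometry, and re-estimating it per
  permutation (available as `sigma2_refit = "per_perm"`) changes p-values
  little at roughly a hundredfold cost.
* **BM simulation test (H0: K = 1).** Default 5,000 BM traits simulated on
  the tree; the observed K is classified against the 2.5% and 97.5%
  quantiles of the log simulated K values, and the two-tailed p doubles the
  smaller tail. Simulated traits carry no measurement error, so simulated K
  values use the plain statistic (adding replicate noise to the simulations
  is available behind the `se` argument of `bm_simulation_test()`, default
  off). In `signal_scan()` this test runs only for traits whose unadjusted
  permutation p is below `alpha`, mirroring the usual reporting practice.
* **Multiple testing.** Permutation and likelihood-ratio p-values are
  adjusted by Benjamini–Hochberg within each trait family — PC scores,
  individual FAs, FA indices — because each family forms its own reported
  table; a single global family is available by scanning all traits in one
  call. FA–PC correlation p-values use Holm's step-down adjustment across
  all (trait, axis) pairs.
* **Dual decision.** Signal in a trait is accepted only when both the
  adjusted permutation test of K and the adjusted LR test of lambda are
  significant, with strict inequality at `alpha` (default 0.05). Requiring
  both metrics guards against the different sensitivities of K and lambda
  on small trees.

## Compositional preprocessing

FA proportions (% of total) are compositional, so the pipeline:

1. **Eliminates rare FAs** (`filter_rare()`): FAs detected in fewer than
   `min_occurrence = 2` measurements, or with mean proportion below
   `min_pct = 1`%. "Contributing less than 1% of total FAs" is read as the
   mean across all measurements; both rules are evaluated simultaneously
   against the original table (applying them sequentially would make the
   result order-dependent through renormalization). Both thresholds are
   configurable.
2. **Renormalizes** surviving FAs to 100% per measurement (idempotent).
3. **Logit-transforms** each FA column on the unit scale. Columns containing
   an exact 0 or 1 are first remapped to `eps + (1 - 2 eps) p` with
   `eps = 0.025`, the usual adjusted-logit convention, applied column-wise
   only where boundaries occur so that interior columns invert exactly.
4. **Averages per species** (irrespective of site and habitat) with the
   standard error of the mean as the measurement-error input.

FA indices (bacterial sums, P:F, B:F, B:P ratios, Unsaturation Index, class
sums, U:S ratio) are computed per measurement on the renormalized %
profiles and then averaged per species. The Unsaturation Index is defined on
unit fractions, \(UI = \sum_i f_i d_i\) with \(f_i \in [0,1]\) and \(d_i\)
the double-bond count; the scale choice matters only by a factor of 100 and
is recorded here. Cyclopropane and methyl-branched FAs carry no double bond
and count as saturated; users can override the classification table shipped
in `inst/extdata/fa_classification.csv`. Ratios with a zero denominator
propagate as `NA`, never as silent zeros. The FA-number index counts FAs
present in the species mean profile (configurable at the call level by
computing it per measurement instead).

## Ordination

PCA is an eigendecomposition of the covariance matrix (divisor n − 1) of
the species-mean logit profiles — covariance, not correlation, because all
columns share the logit scale. Individual measurements are projected with
the same center and eigenvectors to examine intraspecific variation.
Eigenvector signs are fixed by making each axis's largest-magnitude loading
positive, so reports are reproducible. Axes are retained while they explain
more variance than the broken-stick expectation
\(b_k = (1/p)\sum_{i=k}^{p} 1/i\), taken as the leading consecutive run;
because reports conventionally show the first few axes regardless, the
signal scan covers the first `n_axes = 4` axes (or the broken-stick run if
longer), and the eigenvalue table always reports the broken-stick decision.

## The synthetic-data generator

`synthetic_fa_table()` emulates the statistical structure of a replicated
field FA study, not any real taxon's values: a Yule tree (default 40
species, birth rate 1, built from a root split with an `Exp(n b)` segment
after the last split, so expected height is \(\sum_{k=2}^{n} 1/(kb)\));
latent per-FA log abundances with a fixed baseline offset per FA (standard
normal draw, making the composition uneven as real profiles are); a
conserved block evolving by BM with rate 1 on the latent scale (defaults:
10 of 20 FAs) and a labile block drawn independently per species; replicate
noise with sd 0.25 on the latent scale (defaults: 3 replicates per
species), a noise-to-signal choice reflecting that replicated GC
measurements of the same species scatter much less than species differ;
closure to 100% by exponentiation and renormalization. Synthetic FAs carry
real nomenclature (frequent physiological FAs form the conserved block,
bacterial markers sit in the labile block) so the biomarker and index layers
run unchanged.

What the generator does **not** emulate: the closure couples FAs, so a
labile FA's proportion inherits a small amount of phylogenetic structure
through the shared denominator — with ~20 FAs of moderate spread this leak
is small but it is the reason the labile false-positive criterion is a rate
bound, not zero; real data additionally contain detection-limit zeros,
habitat effects, and non-normal replicate error that the generator omits.
Passing recovery tests on generated data therefore demonstrates the
statistical machinery, not field-data robustness.

One integer seed drives every run; sub-seeds for each operation are derived
by fixed documented offsets, and identical seeds give bitwise-identical
tables and reports.

## Numerical choices

* All matrix solves use Cholesky factorization of `C` (never explicit
  inverses); agreement with dense explicit-inverse oracles to 1e-10 is a
  tested contract.
* Canonical taxon order is `sort(tip.label)` wherever a matrix or vector is
  paired with taxa, removing silent misalignment; named trait vectors are
  realigned by harmonized species names (whitespace trimmed, underscores
  and spaces interchangeable).
* Lambda optimization: 25-point grid pre-scan, then bounded scalar
  optimization (tol 1e-8) around the grid optimum, with the interval
  endpoints always candidates; the boundary-mixture distribution of the LR
  statistic at lambda = 0 is ignored (plain \(\chi^2_1\)), matching common
  reporting practice, which makes the LR test slightly conservative.
* The sigma-squared search for the measurement-error model runs on
  log-scale over 36 log-units around the plain GLS rate; a monotone
  likelihood yields the zero-boundary MLE with a warning, an optimum at the
  upper bound is an error.
* Ultrametricity tolerance defaults to 1e-6 relative to tree height,
  because chronogram exports lose decimal precision.
* Pruning retains the stem from the original root to the MRCA of the kept
  tips as a root edge, so pruning commutes exactly with taking the
  covariance submatrix (a tested property); tree height and
  `lambda_max()` account for the stem.
* Trees are accepted with internal labels/support values (ignored); every
  edge must carry a branch length; a basal polytomy is treated as a hard
  polytomy of a rooted tree.

## Problem sizes used in the checks

The packaged statistical checks run at sizes chosen to give stable Monte
Carlo estimates on a single CPU: oracle equivalence on 200 random trees of
up to 8 tips; BM calibration with 1,000 simulations on a 50-tip tree;
type-I error from 1,000 white-noise traits at 500 permutations each; lambda
recovery from 200 traits per generating value on a 100-tip tree; and
end-to-end recovery over 100 generator seeds at the default 40-species,
3-replicate specification with 500 permutations per trait. The full-size
defaults (10,000 permutations, 5,000 simulations) remain the analysis
defaults.

## A worked example

```{r example, eval = FALSE}
dat <- synthetic_fa_table(synthetic_spec(n_species = 13, seed = 5))
an <- run_analysis(dat$table, dat$tree, n_perm = 1000, n_sim = 1000,
                   seed = 9)
an
tidy(an)          # the full per-trait report
autoplot(an$pca)  # scree vs broken stick
autoplot(an)      # K per trait with the dual decision
```

## Known limitations

* Only rooted ultrametric input trees are supported; no tree inference,
  dating, networks, or unrooted trees.
* No other signal statistics (Moran's I, Abouheif's Cmean, delta),
  no multivariate K, no Ornstein–Uhlenbeck models.
* Proportions only — no chromatogram processing or absolute
  quantification.
* Whether a field analysis should use a large tree pruned to the sampled
  species or a separately estimated small tree is left to the caller;
  `prune_to_taxa()` exposes the pruning, and `run_analysis(allow_prune =
  TRUE)` prunes automatically.
* The combined-literature mode assumes each literature row is already a
  species-by-context mean and imputes unreported FAs as zero; both
  assumptions follow standard compilation practice but cannot be validated
  from within the package.
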