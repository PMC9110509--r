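---
title: "Methods: conditional FDR analysis of cross-trait pleiotropy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conditional FDR analysis of cross-trait pleiotropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleiocfdr)
library(dplyr)
```

## The problem

Two complex traits can share genetic architecture: a variant that shifts one
phenotype may also shift the other (pleiotropy). Single-trait genome-wide
association studies (GWAS) rank SNPs by their marginal p-values and, at
stringent genome-wide thresholds, miss variants whose signal is real but
sub-threshold in each trait alone. The conditional false discovery rate
(cFDR) borrows strength across a *pair* of GWAS: if small p-values for trait
2 are enriched among SNPs with small p-values for trait 1, then conditioning
on trait 2 sharpens inference for trait 1. This package implements that
analysis for any pair of summary-statistic files — reading and harmonizing
the two tables, thinning SNPs by linkage disequilibrium (LD), visualising
enrichment, computing per-SNP cFDR in both trait orderings and their
conjunction, and following up with a simplified shared-causal-variant
fine-mapping model and two-sample Mendelian randomization (MR).

## The estimator

For SNP $i$ with observed p-values $(p_{1i}, p_{2i})$, let

$$\hat F(p_{1i} \mid p_{2i}) \;=\;
  \frac{\#\{j : p_{1j} \le p_{1i} \text{ and } p_{2j} \le p_{2i}\}}
       {\#\{j : p_{2j} \le p_{2i}\}}$$

be the empirical conditional cdf of the principal trait's p-value given the
conditional trait's exceedance. The empirical cFDR is

$$\widehat{\mathrm{cFDR}}_i \;=\;
  \min\!\Bigl(1,\; \frac{p_{1i}}{\hat F(p_{1i} \mid p_{2i})}\Bigr),$$

an estimate of the probability that the SNP is null for the principal trait
given that both p-values are at least as small as observed. Conventions that
matter and are fixed here:

* **Inclusive comparisons.** Both counts use $\le$, so the index SNP counts
  itself, the denominator is never zero, and ties are counted inclusively
  (no jitter is added).
* **Exact counting.** Counts are computed exactly for every SNP by a
  sort-and-sweep over p-value ranks (a Fenwick tree; $O(M\log M)$), not by
  an interpolated lookup grid. The test suite proves the sweep identical to
  the quadratic definition on hundreds of random tables, ties included.
* **Bounds.** $\widehat{\mathrm{cFDR}}_i \ge p_{1i}$ always (the empirical
  cdf is $\le 1$); a floating-point guard enforces this exactly. Values are
  clamped at 1.
* **Conjunction.** The ccFDR is the per-SNP maximum of the two orderings,
  $\max(\widehat{\mathrm{cFDR}}_{1|2}, \widehat{\mathrm{cFDR}}_{2|1})$;
  it is small only when both orderings are small, flagging pleiotropy.
* **Strict significance.** Calls use strict inequality (`cFDR < 0.05`,
  `ccFDR < 0.05` by default); a value exactly at the threshold is not
  called.

With a degenerate conditional trait (all $p_2 = 1$) the estimator collapses
to the unconditional empirical FDR $p \cdot M / \mathrm{rank}(p)$ — the
Benjamini–Hochberg quantity for distinct p-values — which the tests check
exactly.

The estimator is *empirical* and only approximately controls the FDR; the
package's calibration experiment (no pleiotropic SNPs, 5% non-null signal
per trait, $\sigma = 3$, $m = 20{,}000$, 200 seeds) keeps the realized mean
false-discovery proportion among `cFDR < 0.05` calls near 0.04–0.05, well
inside the 0.10 conservativeness band asserted by the tests.

## Stratified conditional Q-Q curves

Enrichment is visualised by nested strata: for conditional thresholds
$t \in \{1, 0.1, 0.01, 0.001, 0.0001\}$ (all five configurable; strata use
strict $p_2 < t$), the empirical quantiles of $p_1$ within the stratum are
drawn against the nominal quantiles on the $-\log_{10}$ scale. Under
independence every curve follows $x = y$; leftward deflection that grows
with conditioning stringency indicates pleiotropic enrichment.

Two per-stratum scalars are reported. `enrichment` is the nominal
$-\log_{10} p$ at empirical quantile $q = 0.01$ relative to the all-SNP
stratum — a tail summary that matches how the curves are read, but in a
stratum of a few hundred SNPs it is a first/second order statistic with a
$\log_{10}$ sd near 0.35 and is therefore noisy. `mean_neglog_p` is the
stratum mean of $-\log_{10} p$, whose conditional expectation increases
strictly with nesting whenever a pleiotropic component is present; the
monotone-enrichment acceptance check is asserted on this stable statistic.
Quantiles use the inverse-ecdf convention (`type = 1`), and curves are
evaluated on a shared grid of 512 points from $0$ to $\log_{10} m$; below
$q = 1/n$ the curve saturates at the stratum minimum. The null-band test
uses a Dvoretzky–Kiefer–Wolfowitz 99% *simultaneous* band on the stratum
ecdf rather than pointwise bands: with hundreds of correlated grid points,
pointwise bands are crossed somewhere by chance at a non-trivial rate even
under the null.

## LD pruning

The sliding-window pruning used before cFDR mirrors the classic
`--indep-pairwise`-style procedure, re-implemented so its post-condition is
auditable: within a window of 50 consecutive currently-retained SNPs, every
pair is examined in position order; when $r^2 > 0.2$ (strictly) the member
with the smaller minor allele frequency is removed immediately (MAF ties
drop the later-position SNP — a deterministic choice the procedure's usual
descriptions leave open); the window advances 5 SNPs; passes repeat until a
full scan removes nothing. Because a stepped scan can in principle skip a
window offset containing a violating pair at distance close to the window
size, a final every-offset sweep runs at fixpoint, guaranteeing that **no**
window of 50 consecutive retained SNPs contains a pair with $r^2 > 0.2$.
$r^2$ is the squared Pearson correlation of dosages over pairwise-complete
samples; pairs at exactly the threshold are kept. The tests verify the
post-condition exhaustively and match a naive fixpoint re-implementation on
block-structured panels.

Pruning needs a reference genotype panel (VCF or a tab-delimited dosage
matrix); instrument clumping for MR reuses the same $r^2$ with a greedy
ascending-p rule and no window limit.

## The synthetic two-trait generator

All calibration and power claims rest on a generator with known truth. Each
of $m$ SNPs draws a component from $(\pi_{00}, \pi_{10}, \pi_{01},
\pi_{11})$ — null, trait-1-only, trait-2-only, pleiotropic. Given the
component, the trait's z-score is $N(0, 1)$ when null for that trait and
$N(0, 1 + \sigma^2)$ when non-null; p-values are two-sided normal. Defaults
describe a desk-scale study: $m = 20{,}000$ SNPs (the scale of a pruned
two-trait intersection that remains fast enough for hundreds of simulation
replicates), 2% non-null per trait alone, 2% pleiotropic, $\sigma = 3$
(marginal sd $\approx 3.2$ for non-null z-scores, typical of well-powered
GWAS hits).

Deliberate simplifications, hence limits of what passing tests show about
real data:

* **Effects live on the z scale.** No per-SNP beta/se decomposition for the
  cFDR path (the estimator consumes only p-values); the MR generator
  simulates beta/se explicitly under its own model.
* **Summary statistics are simulated without LD.** The cFDR analysis is
  meant to run on pruned data, so post-pruning independence is taken as the
  operative assumption; residual LD in real data induces correlation among
  test statistics that these simulations do not probe.
* **Genotypes come from a thresholded latent AR(1).** Two independent
  latent Gaussian haplotypes per sample, AR(1) within blocks with parameter
  `rho_block`, thresholded at $\Phi^{-1}(f)$ with $f \sim U(\text{maf
  range})$ and summed — the simplest construction with tunable adjacent
  $r^2$ (verified against a $10^6$-sample Monte-Carlo rendering). No
  coalescent realism, no population stratification.

The FDR-control experiment sets $\pi_{11} = 0$ with $\pi_{10} = 0.05$ and —
a choice the experiment's description leaves open — $\pi_{01} = 0.05$, so
that conditioning on trait 2 is genuinely exercised: with no pleiotropic
component, trait-2 signal is independent of trait-1 labels and FDR control
must survive the conditioning.

## Fine-mapping

The locus-level model is a *shared single causal variant* approximation:
per trait, each SNP's evidence is the Wakefield-style approximate Bayes
factor for its z-score under a $N(0, W)$ prior on the non-centrality,

$$\mathrm{ABF}(z, W) = \sqrt{\tfrac{1}{1+W}}\,
  \exp\!\Bigl(\tfrac{z^2 W}{2(1+W)}\Bigr)
  = \frac{N(z;\,0,\,1+W)}{N(z;\,0,\,1)},$$

multiplied across the two traits and normalized (with a uniform causal
prior by default) into per-SNP posterior probabilities of being the shared
causal variant. $W = 10$ on the $z^2$ scale by default — weakly informative
for GWAS-scale z-scores — and configurable. All arithmetic is in log space
with log-sum-exp normalization so z-scores up to $\pm 40$ cannot overflow;
MAP ties break to the smaller position. An LD matrix can be attached for
reporting and plotting but does not enter the likelihood: under exactly one
causal variant the marginal z at the causal SNP is sufficient for ranking
in this approximation. This is a deliberate simplification relative to
annotation-weighted multi-causal fine-mapping frameworks: no functional
annotations, no multi-causal configurations, no MCMC.

## Mendelian randomization

Instruments are exposure SNPs with $p < 5\times10^{-8}$, clumped to mutual
$r^2 \le 0.01$. Per instrument the Wald ratio is $\beta_Y/\beta_X$ with
first-order delta SE $se_Y/|\beta_X|$ — adequate for strong instruments,
which the selection threshold enforces. Two estimators:

* **IVW** (fixed-effect): the inverse-variance weighted mean of Wald
  ratios, $se = 1/\sqrt{\sum w_i}$. No multiplicative random-effect
  inflation by default.
* **ML**: the joint normal likelihood $\beta_{Xi} \sim N(\xi_i, se_{Xi}^2)$,
  $\beta_{Yi} \sim N(\theta \xi_i, se_{Yi}^2)$ maximized over $(\theta,
  \xi)$. The $\xi_i$ have a closed-form profile given $\theta$; $\theta$
  starts at IVW and is polished by safeguarded Newton steps on the scalar
  profile score to gradient norm $< 10^{-8}$, with $se(\theta)$ from the
  observed information after eliminating the $\xi$ block. As
  $se_X \to 0$, ML coincides with IVW — checked to $10^{-6}$.

The MR simulator draws $\xi_i \sim N(0.1, 0.02^2)$ with $se_X = 0.005$,
$se_Y = 0.02$: strong instruments of the kind genome-wide-significant
selection yields, under which both estimators' 95% CIs cover a true
$\theta = 0.25$ at the nominal rate (the tests assert 93–97% over 1,000
datasets at $k = 46$ instruments). Pleiotropy-robust estimators (Egger,
weighted median) are out of scope.

## Harmonization and input conventions

* p–z conversions use the two-sided standard normal; `z = beta/se` fills a
  missing z and is cross-checked (to $10^{-6}$ relative) when both are
  present. p-values of exactly 0 are floored at $10^{-300}$ with a warning,
  since the estimator needs strictly positive p.
* Genomic control estimates $\lambda = \mathrm{median}(z^2)/0.4549364$; if
  $\lambda > 1$, $z^2$ is deflated by $\lambda$ and p recomputed; $\lambda
  \le 1$ never inflates (no deflation below 1). The default pipeline
  assumes inputs already corrected upstream; the correction is an explicit
  call, applied only when the user asks.
* Allele harmonization flips the second trait's z when effect/other alleles
  are swapped, resolves opposite-strand representations by complementing,
  and drops strand-ambiguous (A/T, C/G) SNPs — the conservative default,
  counted and logged — along with irreconcilable pairs.
* Coordinates: summary statistics and SNP positions are 1-based with
  chromosomes as strings; BED gene intervals are 0-based half-open on disk
  and converted on import. SNP-to-gene distance is edge distance (0 inside
  a gene), with deterministic (distance, symbol) tie-breaks.
* Every pipeline stage can append a provenance block (stage, parameters,
  counts) to a run log configured via `options(pleiocfdr.log_file = ...)`.

## Problem sizes used by the checks

The shipped experiments use $m = 20{,}000$ SNPs for calibration and power
runs (200 and 100 seeds), $10^5$ SNPs for the single null-band check, 100
random 2,000-row tables per oracle batch, 1,000 MR datasets at $k = 46$,
and 100 fine-mapping loci of 51 SNPs — sizes chosen so the full suite
completes in a few minutes on one CPU while keeping Monte-Carlo error well
below the asserted margins.

## Known limitations

* The empirical cFDR is approximate; its conservativeness is demonstrated
  by simulation under this generator, not proved, and LD beyond pruning,
  sample overlap between the two GWAS, and shared controls are not
  modelled.
* The fine-mapping posterior conditions on exactly one shared causal
  variant; loci violating that assumption get posteriors that rank
  marginal evidence, nothing more.
* Fixed-effect IVW and the ML model assume no directional pleiotropy of
  instruments; with invalid instruments both are biased.
* Novelty flagging is only as good as the user-supplied catalog and proxy
  list; no live database queries are made by design.
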