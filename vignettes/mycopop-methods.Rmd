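---
title: "Population-genomic methods in mycopop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-genomic methods in mycopop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mycopop)
```

mycopop analyses resequenced collections of dikaryotic fungal strains —
the motivating system is shiitake (*Lentinula edodes*), where wild and
cultivated strains fall into a few divergent genetic groups and occasional
hybrids between groups carry striking excess heterozygosity. Each dikaryon
holds two haploid nuclei and is genotyped as a diploid, so every strain
contributes two allele observations per SNP. This vignette documents the
models, the tunable parameters and the numerical choices, and is explicit
about what the synthetic-data generator does and does not emulate.

## The genotype container and site filters

`geno_mat` stores a strains × loci matrix of alternate-allele dosages
{0, 1, 2} with per-locus metadata. `filter_variants()` applies the
standard resequencing filters in one pass: biallelic SNPs only, site
QUAL ≥ 30, mean per-sample depth ≥ 5, no missing genotype, and minor
allele frequency ≥ 0.05 computed over the 2N called alleles (the bound is
inclusive; frequencies come from allele counts, not genotype frequencies,
matching VCF-convention filters). "Mean depth" averages DP over samples
that report one — the alternative (dividing by all samples) would penalise
missingness twice. `thin_by_distance()` prunes linked sites greedily from
the left end of each scaffold, keeping a locus only when it lies at least
1,000 bp (default) beyond the last kept one; greedy left-to-right is the
conventional distance-thinning algorithm and is deterministic.

A locus is "detected" in a group when it is polymorphic among that group's
strains (both alleles observed). An alternative rule — alternate allele
present — is available via `rule = "alt_present"` everywhere membership
matters, because per-group SNP tallies in the literature do not always say
which convention they used; polymorphic-within-group is the default since
a site fixed for the alternate allele within a group carries no
within-group variation.

## Diversity statistics

Per-site nucleotide diversity is the unbiased pairwise heterozygosity
$\hat\pi = 2\hat p(1-\hat p)\,\frac{2N}{2N-1}$; window π sums site values
over non-overlapping windows (5 kb default, tiled from position 1) and
divides by the window width — the per-bp convention of VCFtools
`--window-pi`, giving values of order 10⁻³ on realistic data. Tajima's D
uses the 1989 constants with n = 2N sampled alleles and the window's
segregating-site count; it is undefined (NA) in windows without a
segregating site, and refuses n < 4 where the variance terms degenerate.

Per-strain inbreeding follows the observed-versus-expected homozygosity
form (VCFtools `--het`): $F = (N_o - E[\mathrm{hom}])/(L - E[\mathrm{hom}])$
with the expectation from pooled cohort allele frequencies. Pass a group
subset to estimate F within a group; pooling across divergent groups
inflates expected heterozygosity (the Wahlund effect), which is exactly
why admixed hybrids show strongly negative F against the pooled cohort.

## AMOVA

`amova()` partitions variance across three levels — among populations,
among strains within populations, within individual strains — treating
each strain as two allele observations per locus and summing squared
allele-indicator deviations over loci. With mean squares MS = SS/df
(df = P−1, N−P, N), the moment equations are

$$E[\mathrm{MS}_w] = \sigma^2_w,\quad
  E[\mathrm{MS}_s] = \sigma^2_w + 2\sigma^2_s,\quad
  E[\mathrm{MS}_p] = \sigma^2_w + 2\sigma^2_s + n_0\,\sigma^2_p,$$

with $n_0 = (A - \sum_k A_k^2/A)/(P-1)$ over allele-observation counts
$A_k = 2n_k$. `amova_components_from_ss()` exposes this back-end so a
published AMOVA table can be re-solved from its printed SS/df — the
package's acceptance script does precisely that. Negative variance
components (possible when a level explains less than its sampling
expectation) are reported as-is with a warning rather than truncated,
so percentages always reconcile with the printed components.

## Distance, tree and bootstrap

The genotype distance is the allele-sharing distance
$d(i,j) = \frac{1}{L}\sum_l |g_{il}-g_{jl}|/2$: 0 for identical strains,
1 for opposite homozygotes everywhere. The tree is Saitou–Nei
neighbour joining (via ape), with negative branch lengths clamped to zero
and counted; rooting places the root on a designated outgroup's pendant
edge. Bootstrap support resamples loci with replacement (seeded) and
reports clade recovery fractions. The distance metric is a package
decision — tools cited in the strain-collection literature take "a
distance matrix" without naming one — and is isolated behind
`genotype_distance()` so an alternative can be swapped in.

## The Bayesian F_ST outlier scan

The scan implements the multinomial-Dirichlet outlier model: for locus i
and population j, allele counts are binomial given a population frequency
that is beta-distributed around the ancestral frequency $p_i$ with
precision $(1-F_{ST}^{ij})/F_{ST}^{ij}$; integrating the frequency out
yields a beta-binomial likelihood. Differentiation decomposes on the logit
scale, $\mathrm{logit}(F_{ST}^{ij}) = \alpha_i + \beta_j$, and a
reversible-jump MCMC toggles the locus effect $\alpha_i$ in and out of the
model with configurable prior odds (default 10) in favour of the neutral
model. This is a from-scratch desk-scale implementation of the published
model, not a wrapper around the external program, and no numerical
agreement with that program's binaries is claimed.

Choices that matter:

* **Priors.** $\alpha_i \sim N(0, 2)$, $\beta_j \sim N(-1, 2)$,
  $p_i \sim U(0,1)$. The β prior centres genome-wide F_ST near
  $\mathrm{logit}^{-1}(-1) \approx 0.27$, the right scale for strongly
  structured strain collections, and is weak enough to adapt well below
  that. The α scale accommodates the logit shift (~2.5) needed to move a
  locus from background F_ST ≈ 0.1 to ≈ 0.6.
* **Proposals.** A pilot phase (default 2,000 sweeps with all locus
  effects included) records per-locus posterior means and SDs of α; the
  reversible-jump birth move proposes from the pilot-tuned Gaussian, which
  keeps jump acceptance healthy for both weak and strong loci. Random-walk
  updates handle $p_i$, included $\alpha_i$, and $\beta_j$.
* **Defaults.** 5,000 burn-in + 20,000 kept sweeps, thinning 10. The MCMC
  core is compiled (Rcpp) and uses R's RNG, so `set.seed()` makes runs
  bit-reproducible.
* **Convergence.** Posterior inclusion probabilities are compared between
  the two halves of the kept chain; a maximum disagreement above
  `se_threshold` (default 0.1) triggers a warning carrying the diagnostic.

Posterior error probability is PEP = 1 − inclusion probability, and the
q-value of a locus is the mean PEP over loci at least as confident — the
Bayesian FDR of the list that calls this locus and everything stronger.
`call_outliers()` applies the conventional compound rule: q < 0.05 *and*
posterior locus F_ST above the scan-wide mean ("above the mean" is read as
posterior locus F_ST, not α, which is the natural scale the rule is
quoted in).

A calibration fact worth knowing: under the Balding–Nichols generator a
"planted" locus draws each population's frequency independently, so some
planted loci *realise* little divergence; their true posterior supports
the neutral model, and no correct sampler will call them. The acceptance
suite computes the scan's power and FDR under exactly these conditions;
the package's own validation of the sampler compared its inclusion
probabilities against direct numerical integration of the marginal
likelihoods on a fixed fixture, which bounds the Monte-Carlo error well
below the biological variability just described. Detection is an
honest function of realised, not nominal, divergence.

## Divergence windows and candidate assignment

Windowed F_ST aggregates Weir–Cockerham (1984) site components by ratio
of sums, $\theta_w = \sum a / \sum(a+b+c)$ — the weighted convention of
VCFtools' windowed output; mean-of-ratios is *not* used. The W&C point
estimator subtracts expected sampling variance, so single-locus estimates
can be negative even for identical samples; that is correct behaviour,
not a bug. Top-window selection is nearest-rank: the
$\lceil 0.05\,N_{\mathrm{defined}}\rceil$ highest windows, with every
window tied at the cutoff value also kept (tie handling is a package
decision; deterministic ordering is θ descending, then scaffold, then
start).

Candidate assignment applies the pairwise-intersection rule: an outlier
SNP supports the divergence of group X iff it lies in top-5% windows of
*both* pairwise comparisons involving X; a SNP in all three pairs'
windows supports all three groups, and one in at most a single pair's
windows supports none but still appears in the per-pair Venn tallies.
Assignment is order-invariant in the pairs. Genes are then collected per
group via the annotation table, deduplicated, and cross-tabulated for
sharing.

## Enrichment

Group-specific SNPs (detected in exactly one group) are filtered to
missense annotations, mapped to genes, and tested per GO term with the
one-sided hypergeometric tail $P[X \ge k]$ against the background of all
genes carrying at least one analysed SNP. This is plain Fisher testing —
the graph-decorrelation variants ("elim"/"weight") are deliberately out
of scope. No ancestor-term propagation is applied to the GO map (none is
assumed present in the input). Significance stars at 0.05/0.01 accompany
the Fig-style log2 odds $\log_2\frac{k/n}{K/N}$ (undefined and flagged
when k or K is 0); a Benjamini–Hochberg column is emitted as a clearly
optional extra for users who want FDR control across terms.

## Phenotypes

Traits are min–max normalised per trait,
$(P_{pi} - \min_p)/(\max_p - \min_p)$, over non-missing entries; constant
traits map to all zeros with a warning; missing values stay missing
through normalisation. Clustering of strains and of traits uses complete
linkage on Euclidean distances — the classic two-way heatmap ordering —
with missing cells imputed by the trait mean and flagged in the output;
the complete-linkage merge heights are non-decreasing, which the tests
assert as the ultrametric sanity check.

## The synthetic-data generator

`simulate_genotypes()` draws, per locus, an ancestral frequency uniformly
from `ancestral_freq_range`, then per-population frequencies from the
Balding–Nichols beta, $\mathrm{Beta}\!\left(p\frac{1-c}{c},
(1-p)\frac{1-c}{c}\right)$, where the divergence c equals the expected
locus F_ST — the single property that makes every downstream estimator
testable by parameter recovery, and the reason this model was chosen over
a coalescent. Genotypes use inbreeding-adjusted Hardy–Weinberg
probabilities; hybrids draw one allele from each of two parent
populations; loci failing the overall MAF floor are redrawn at most 100
times, with an error (not silent omission) on exhaustion.

Defaults mirror a shiitake-scale design: 3 populations of 26/6/26 strains
plus 2 hybrids, baseline divergences (0.30, 0.30, 0.18) giving pairwise
F_ST ≈ 0.23–0.30, 1% outlier loci at c = 0.6, within-population
inbreeding (0.40, 0.45, 0.20), 10 scaffolds of 500 kb, 13 traits of which
all but NF and SL separate the groups (shifts ±1.5 noise-SD units —
roughly the separation visible in real trait heatmaps). One global seed
deterministically derives per-stage seeds so stages can be re-run
independently.

What the generator does **not** emulate, and what that means for test
evidence: loci are exchangeable and unlinked (no LD blocks beyond what
positional thinning would remove, so thinning is exercised only
mechanically); the ancestral frequency is uniform rather than following a
coalescent site-frequency spectrum, so simulated Tajima's D is positive
on average — convenient, since the real collection's D is also positive,
but it means the neutrality-centred behaviour of D is tested on a
purpose-built 1/i frequency spectrum instead; there is no sequencing
error, no missingness in genotypes, and no indels. Passing tests
therefore validate the estimators and the pipeline logic, not the
upstream read-processing reality of resequencing data.

## Problem sizes used by the test suite

Chosen to make the statistical assertions stable while keeping a full run
on one CPU comfortable: parameter recovery uses 5,000 loci × 60 strains;
the power/FDR evaluation runs five seeded replicates of 1,050 loci with a
2,000 + 8,000 (thin 8) chain after a 1,000-sweep pilot; the null control
runs twenty 300-locus scans with a 1,000 + 4,000 chain; oracle-equivalence
suites use 50 random fixtures per statistic; the end-to-end pipeline test
uses 800 loci. The scan defaults (5,000 + 20,000, thin 10) remain the
recommendation for real analyses.

## Known limitations

* The scan targets biallelic counts in 2+ populations; no haplotype-based
  statistics (iHS/XP-EHH) are provided.
* AMOVA reports no permutation p-values; negative components are possible
  and are surfaced, not hidden.
* q-values from mean PEP are only as calibrated as the model; with very
  few loci the discrete PEP distribution makes q granular.
* The NJ distance choice is a convention, not an inference; biological
  conclusions should not hinge on it without checking an alternative
  metric.
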