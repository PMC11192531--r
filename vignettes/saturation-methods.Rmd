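---
title: "Estimating the size of a pan-repertoire: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the size of a pan-repertoire: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pansat)
```

## The problem

Very large gene families — fish NLR immune receptors being an extreme
example — are dominated by presence/absence variation: a population may
harbour thousands of distinct family members while any one individual
carries only a few hundred. A survey of such a family with a finite sample
of individuals therefore observes only part of the "pan-repertoire", and
two quantities matter: how discovery accrues with sample size, and what the
accrual extrapolates to. `pansat` implements this analysis from a gene ×
individual presence/absence matrix upward, together with the repertoire's
occupancy structure (core/shell/cloud), cross-population sharing, and
per-exon nucleotide diversity.

## Exact accumulation curves

Given `n` sampled individuals and per-gene occupancies `m_g` (the number of
carriers), the expected number of distinct genes discovered in a uniformly
random subset of `x` individuals is

$$G(x) \;=\; \sum_g \left[ 1 - \binom{n-m_g}{x} \Big/ \binom{n}{x} \right].$$

This is the mean over *all* $\binom{n}{x}$ subsets, i.e. the textbook
rarefaction expectation, computed per gene from the hypergeometric
probability of missing every carrier. The package computes it in
`O(\text{genes} \times n)` with the binomial ratio expanded as a product of
at most `x` factors (never through factorials, which would overflow);
`brute_force_curve()` enumerates all subsets for `n ≤ 12` and is used in the
test suite to pin the closed form to the enumeration at `1e-9`. An
equivalent formulation averages per-step increments over the
$\binom{n}{x}\,x$ ways of extending an `(x−1)`-subset; `subset_weight()`
exposes that count and asserts the identity
$\binom{n}{x-1}(n-x+1) = \binom{n}{x}\,x$.

Properties guaranteed (and property-tested): `G` is nondecreasing and
concave (nonincreasing increments `delta`), `G(n)` equals the observed pan
size, and the curve is invariant to individual order. One property that does
*not* hold, although it is tempting to assume: the pooled curve of two
populations need not dominate each population's curve at the same `x`. If
one population is gene-poor, the pooled average at fixed `x` samples its
individuals too and can fall below the gene-rich population's own curve.
What does hold — and what the tests assert — is endpoint dominance:
`G_pooled(n_pooled) ≥ G_pop(n_pop)`, because the union pan size dominates
each population's pan size.

## The saturation model

Increments of empirical accumulation curves decay approximately as a power
law, which motivates fitting the cumulative curve to

$$y(x) = \alpha\, H(x, \beta), \qquad
  H(x, \beta) = \sum_{k=1}^{x} k^{-\beta},$$

the generalized harmonic number: `α` is the expected yield of the first
individual (`H(1, β) = 1` for any `β`) and `β` the decay rate of novelty.
The dichotomy at `β = 1` carries the biology: for `β > 1` the series
converges, the repertoire is *closed*, and its total size is
`α·ζ(β)`; for `β ≤ 1` it is *open* — unbounded under the model. `β = 1`
itself classifies as open, and fits landing within `1e-6` of 1 trigger a
boundary warning because limit estimates explode there (the limit diverges
like `1/(β−1)`).

### Evaluating H at any scale

`gharmonic()` sums directly up to `x = 1e6`. Beyond that it switches to an
Euler–Maclaurin tail expansion — for `β > 1` anchored at `ζ(β)`:

$$H(x,\beta) = \zeta(\beta) - \frac{x^{1-\beta}}{\beta-1}
  + \frac{x^{-\beta}}{2} - \frac{\beta x^{-\beta-1}}{12}
  + \frac{\beta(\beta+1)(\beta+2) x^{-\beta-3}}{720},$$

and for `β ≤ 1` anchored at the exact partial sum `H(10^6, β)`. The two
branches agree to better than `1e-10` relative on their overlap, which the
tests verify on `10^4 ≤ x ≤ 10^6`; this is what justifies trusting the
asymptotic branch where direct summation is infeasible (capture sample
sizes in the billions occur for `β` near 1.1). `ζ` itself is delegated to
`pracma::zeta`; evaluating the zeta function precisely is a solved
special-function problem and not something to re-derive here.

### Fitting

`fit_saturation()` minimises $\sum_x (G(x) - \alpha H(x,\beta))^2$ with
bounded Levenberg–Marquardt (`minpack.lm::nls.lm`), `α > 0`,
`β ∈ (10^{-3}, 10)`. The *cumulative* curve is the fit target; an
increments-based fit is available as a diagnostic (`fit_increments = TRUE`)
but is not the default, because the cumulative totals are what the
saturation question is about and what the model's limit interprets. All
`x = 1..n` points enter, unweighted.

Initialisation matters near the `β ≈ 1` ridge, where `α` and `β` are
strongly correlated: the default start takes `α₀ = G(1)` and `β₀` from an
ordinary regression of `log delta(x)` on `log x`, and three further starts
at `β ∈ {0.8, 1.2, 2.0}` guard against local minima; the best residual sum
of squares wins. On noiseless model curves the fit recovers `(α, β)` to
`1e-6` relative; with increment noise of 1% of `G(n)` at `n = 20`, the
median relative error of `β̂` stays within 5% (both are acceptance-tested
at 200 replicates).

### Capture quantiles

The minimal sample size capturing a fraction `q` of a closed repertoire is
`x_q = min{x : H(x, β) ≥ q·ζ(β)}` (`α` cancels). The search first walks the
exact cumulative sum up to `10^6`; beyond that it inverts the leading tail
term analytically, bisects on `log x` with the Euler–Maclaurin branch (the
log scale keeps the search finite even when `β` barely exceeds 1 and the
crossing sits beyond any floating-point integer range), and finally refines
to the exact crossing integer while adjacent integers remain representable
(`x < 2^53`). The returned value always satisfies the bracketing invariant
`H(x_q, β) ≥ q·ζ(β) > H(x_q − 1, β)`, which the tests assert across a `β`
grid.

### Auditing published parameter tables

Fitted parameter tables in the literature print `α`, `β`, the limit and a
90%-capture sample size side by side, and these columns can disagree with
one another (rounding, transposed digits). `audit_fit_table()` recomputes
limit and quantile from `(α, β)` and reports per-row consistency; quantile
discrepancies of exactly one integer are classed `"boundary"` rather than
`"inconsistent"`, because printed parameters carry ~6 significant digits
and a crossing within ~`1e-6` of an integer boundary legitimately flips on
unprinted digits. The package flags such rows; it never silently adopts a
printed value.

## Occupancy partition and sharing

`classify_occupancy()` classes each detected gene by its occupancy
fraction `m_g/n`: *core* at `≥ 0.80` (inclusive), *cloud* at `< 0.20`
(exclusive), *shell* in the half-open remainder. The boundary semantics are
a deliberate choice: verbal definitions of the three classes often overlap
at the 20% boundary, and the inclusive-core / exclusive-cloud convention is
the reading under which the classes are a true partition. Fractions are
reported relative to genes detected in scope, not the global gene pool.
`population_sharing()` tallies, per gene, the set of populations with at
least one carrier, by cardinality and by exact combination (Venn cells).

## Nucleotide diversity

Per exon and population, `exon_diversity()` computes the number of
segregating sites `S` (segregation is population-relative: a site fixed for
the alternate allele within the population is not segregating there),
per-site pairwise diversity summed over sites and divided by the *full*
exon length `l`,

$$\theta_\pi = \frac{1}{l}\sum_{\text{sites}}
  \frac{2\,n_{\mathrm{ref}}\,n_{\mathrm{alt}}}{n(n-1)},$$

and Watterson's estimator `θ_w = S/(H(n_hap−1, 1)·l)`. Dividing by the full
`l` (not just variant positions) matches the per-site scale on which the
two estimators are comparable. For diploid genotypes, `n` is counted in
haplotypes: twice the individuals with a non-missing call, per site for
`θ_π` and as the minimum across retained sites for `θ_w`; missing genotypes
are excluded per site without imputation, and sites left with fewer than two
haplotypes are dropped. With `n_hap = 2` both estimators reduce to `S/l`
exactly — a useful identity the tests exploit. The ratio `θ_π/θ_w` is
reported only for exons with `S ≥ 1`; values below 1 indicate an excess of
rare alleles.

One caveat is inherent to collapsing a multi-copy family onto reference
exon sequences: reads from unrecognised paralogs can inflate apparent
heterozygosity. The package computes diversity at face value from the
genotypes it is given and does not model this confounding.

Only biallelic SNPs enter; multiallelic and non-SNP records are skipped
with a count reported by `read_genotypes()`.

## The synthetic-data generator

The generator exists so that every stage is testable without sequencing
data. Its default scales are frozen to the regime of a wild zebrafish NLR
survey: a pool of 1500 genes, three populations of 20 individuals, exon
lengths 1761 bp (FISNA-NACHT class) and 540 bp (B30.2 class), and per-site
`θ` of a few parts per thousand.

Three design points deserve explanation:

* **Two tiers, kept distinct.** `simulate_model_curve()` draws exactly from
  `y = αH(x, β)` (noise applied to increments and truncated at zero, so
  noisy curves remain valid accumulation curves) and is the harness for
  parameter-recovery claims. `simulate_presence()` draws matrices from a
  carrier-frequency spectrum — a `rare_weight = 0.65` mixture of a
  rare-heavy Beta(0.5, 10) and a broad Beta(0.8, 1.2) component — whose
  *induced* accumulation curve is not exactly `αH(x, β)` (no closed-form
  inverse exists). Matrix-level tests therefore assert regime properties
  (per-fish gene counts within 100–550, core fraction below 10%, fitted
  `β̂` typically near or above 1), never exact parameter values. Conflating
  the two tiers would fake precision the generative model does not have.
* **Calibrated neutrality.** `simulate_genotypes()` draws `S ~
  Poisson(θ·H(n_hap−1,1)·l)` per exon (the Watterson relation inverted) and
  derived-allele counts `i` with probability `∝ 1/i` — the neutral site
  frequency spectrum — then assigns alleles to haplotypes uniformly and
  pairs haplotypes into diploids. Population labels are metadata over a
  panmictic pool; since an exchangeable subsample of a neutral sample is
  itself neutral, per-population estimates remain calibrated
  (`E[θ̂_w] = θ`, mean `θ_π/θ_w ≈ 1`), which the tests check within
  Monte-Carlo error.
* **Counts keep presence recoverable.** `simulate_read_counts()` draws
  `max(1, NB(μ = depth × thinning, size = 1/dispersion))` for present cells
  (Poisson in the zero-dispersion limit), so a present gene always has at
  least one read and thresholding at `min_reads = 1` inverts the
  simulation exactly; per-individual thinning mimics low-coverage samples,
  which lose genes as the presence threshold rises.

What the generator does **not** emulate: linkage between genes (haplotype
blocks carrying sets of family members together), mechanistic gene
birth–death, sequencing batch effects, or paralog cross-mapping. Passing
tests on synthetic data therefore demonstrate correctness of the
*computations* under the stated statistical structure, not robustness to
every artefact of real capture sequencing.

## Presence calls and thresholds

Presence from read counts defaults to `min_reads = 1` — any mapped evidence
counts as "present in at least one copy". A stricter cutoff is a flag, not
a default, because requiring more reads conflates presence with depth; the
separate `display_filter()` (`min_max_reads = 10`) exists for the distinct
purpose of restricting heatmap displays to genes with solid support in at
least one individual. Missing cells in input matrices are rejected rather
than imputed: there is no missing-data model for presence here.

## Problem sizes in the tests

The test suite and acceptance checks run at deliberately modest scales —
brute-force oracle matrices up to `n = 10` individuals (100 random cases),
200 fit replicates at `n = 20`, 200–250 simulated exons for the neutrality
calibrations, and one end-to-end pipeline run at the full default scale
(1500 genes × 60 individuals). These sizes give the comparisons their
stated resolution (e.g. 3-standard-error bands on calibration means) while
keeping the whole suite around ten seconds; the deterministic model
evaluations (limits, quantiles) are exact at any scale and need no
replication.

## Known limitations

* The saturation model assumes exchangeable individuals within a scope;
  strong within-population structure (families, batches) biases `β̂`.
* Near `β = 1` the limit `α·ζ(β)` is numerically honest but statistically
  fragile — tiny changes in `β̂` move it by orders of magnitude. Report `β̂`
  and its position relative to 1 alongside any limit.
* Diversity estimates inherit whatever reference and genotyping choices
  produced the VCF, including paralog collapse (see above).
* The open/closed call is a statement about the fitted power-law model of
  increments, not a model-free property of the population.
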