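---
title: "Estimating somatic variant richness: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating somatic variant richness: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raremut)
```

## The problem

Most somatic variants ever observed in tumor sequencing cohorts are rare:
in whole-exome catalogs upwards of 90% of distinct non-synonymous single
nucleotide variants (SNVs) are singletons, seen in exactly one tumor. A new
tumor therefore routinely carries variants that no catalog has recorded.
Classical likelihood estimation assigns those variants probability zero,
which is useless for downstream questions — classifying the tissue of origin
of a cancer of unknown primary, scoring clonal relatedness of tumor pairs,
interpreting ctDNA — where the probability of encountering a *new* variant
in a given gene and tissue is exactly the quantity of interest.

`raremut` treats the problem the way ecology treats unseen species and
computational linguistics treats unseen words. The data are reduced to
frequency-of-frequency vectors: for a scope (one gene, the whole catalog, or
a gene pair), the pairs $(r, N_r)$ where $N_r$ is the number of distinct
variants observed in exactly $r$ of $m$ tumors. Everything downstream is a
function of these vectors.

## Estimators

**Good-Turing recurrence probability.** A variant seen $r \ge 1$ times is
assigned probability

$$q^{GT} = \frac{r+1}{m+1}\,\frac{S(N_{r+1})}{S(N_r)}$$

of occurring in one new tumor, where $S$ smooths the frequency counts. The
per-tumor framing matters: $m$ counts tumors profiled (not mutated), and a
variant contributes at most once per tumor, so $q^{GT}$ is a per-new-tumor
Bernoulli probability rather than a multinomial token share.

**Unseen-variant probability.** The probability that a new tumor carries at
least one never-observed variant of a gene is approximated by
$1 - \exp\{-N_1/(m+1)\}$, which depends only on the singleton count — the
unknown number of unseen variants never enters. `unseen_rate()` exposes the
underlying Poisson rate $N_1/(m+1)$.

**Good-Toulmin extrapolation.** The expected number of new distinct variants
in $t\,m$ further tumors is the alternating series
$\Delta(t) = \sum_{r\ge1} (-1)^{r+1} t^r N_r$. The plain series is used for
$t \le 1$; beyond the observed sample size it diverges, so for $t > 1$ each
term is damped by the binomial tail weight $P(L \ge r)$,
$L \sim \mathrm{Bin}(k,\, 2/(t+2))$ with
$k = \lceil \tfrac12 \log_2( m t^2/(t-1))\rceil$ — the standard Euler
smoothing of this series. Negative estimates (possible when even frequency
classes dominate) are truncated to zero with a warning. The series is always
evaluated exactly over all observed classes; nothing is dropped.

**Standard errors** for $\Delta(t)$ come from resampling tumors with
replacement (`gt_bootstrap()`, default $B = 200$, seeded). An analytic SE
would need distributional assumptions the frequency vector alone cannot
support.

**Concordance.** Train-on-one-cohort / validate-on-another comparisons are
scored by Lin's concordance correlation coefficient with population
($n$-denominator) moments,
$\rho_c = 2\,\mathrm{cov}(x,y)\,/\,(\sigma_x^2 + \sigma_y^2 + (\bar x - \bar y)^2)$,
which penalises location and scale departures from the identity line and is
bounded by the Pearson correlation in absolute value.

## Smoothing

With identity smoothing ($S(N_r) = N_r$) the estimator is exact but breaks
on empty interior classes; the package raises an explicit "unsmoothable gap"
error rather than silently returning zero, because a gap below the largest
observed frequency is an estimation problem, not evidence of impossibility.
An empty class *above* the largest observed frequency legitimately yields
$q = 0$.

The default is Simple Good-Turing (Gale–Sampson): the averaging transform
$Z_r = N_r / \tfrac12(r'' - r')$ over neighbouring non-empty classes, a
least-squares line $\log Z = a + b \log r$, and a switch from raw to fitted
counts at the first class where the raw and fitted Turing-adjusted counts
differ by less than 1.96 standard deviations of the raw estimate (staying on
the fit thereafter). Hotspot-dominated vectors — 24 singletons, then nothing
until $r = 44$, 120, 142, as in *KRAS* — are exactly the vectors this
handles gracefully. With fewer than three non-empty classes the fit is not
identifiable and the smoother falls back to identity with a warning.
Probabilities are clamped to $[0,1]$ with a warning; ratio estimators can
exceed 1 in tiny scopes.

## Cohort stratification

Hypermutated tumors would otherwise dominate every frequency vector, so
tumors are stratified first: a dominant-signature label in one of the five
single-base-substitution groups (APOBEC, Smoking, MMR, UV, POLE) assigns
that group outright; unlabeled tumors below the burden threshold are
non-hypermutated; unlabeled tumors at or above it are excluded. The
threshold is strict (`burden < threshold` is the non-hypermutated side); 500
mutations is the conventional whole-exome value, and
`scale_hypermutation_threshold()` carries it across assays by the ratio of
median total burdens, rounded up (ceiling is the only rounding that
reproduces the conventional panel value of 38 from 500 × 4/54). Signature
deconvolution itself is out of scope — labels (or exposure vectors, via the
`dominant_signature()` argmax helper with a configurable SBS-to-group map)
are inputs.

## Tissue specificity

For a gene, per-tissue unseen-variant probabilities are computed from
tissue-stratified frequency vectors — each tissue contributes its own $m_c$
and its own singleton count. The dependence of the binary event on the
tissue label $T$ is scored by normalized mutual information,
$I(T;E)/H(T)$, built from the joint $P(T{=}c, E{=}1) = w_c p_c$ with
weights $w_c = m_c/m$. Normalizing by $H(T)$ makes a tissue-deterministic
event score 1 and any lineage-independent event score 0; because the
"right" normalizer is a genuine design choice, $H(E)$, $\min$, and
$\sqrt{H(T)H(E)}$ are selectable and the choice is reported in the output.

Observed NMIs are judged against a permutation null: tissue labels are
randomly reallocated across tumors (preserving each tissue's sample count),
the per-tissue probabilities and NMI recomputed, and the 95th percentile of
the null sample used as the reference cutoff. Because the observed
allocation is exchangeable with the permuted ones under lineage
independence, the null is exactly calibrated by construction; the test suite
verifies ~5% exceedance on independent genes and >95% detection of tenfold
tissue effects.

For gene pairs, co-mutation (both genes mutated in a tumor) and mutual
exclusivity (exactly one mutated) are gene-level, per-tumor binary events;
the two are disjoint and, with "neither", exhaustive. Pair frequency vectors
pool all pairs within a user-supplied panel so the $N_r$ classes stay
populated; a genome-wide universe is allowed but warned against. Per-tissue
pair-event probabilities feeding the index-tissue NMI contrast use the
empirical per-tissue tumor fractions: pair events are common enough at the
gene level that the Good-Turing adjustment is immaterial there, and the
empirical rates keep the permutation null exact.

## The synthetic generator and its oracles

`simulate_cohort()` implements the model the estimators assume: each tumor
draws a tissue (and, optionally, a hypermutation multiplier), then every
variant occurs independently with its tissue-adjusted probability — a
product-binomial model. Three probability laws cover the observed regimes:
`probs_zipf()` (power-law pools), `probs_hotspot()` (oncogene-like spikes on
a power-law tail), and `probs_log_series()`, the continuous analogue of the
Fisher log-series abundance model, sampled by rejection from
$f(p) \propto e^{-\beta p}/p$ on $[p_{\min}, p_{\max}]$, which yields the
$N_r \propto x^r/r$ frequency-of-frequency decay characteristic of real
catalogs.

Because the generator retains every generative probability,
`true_unseen_probability()` and `true_new_variant_count()` are *exact*
oracles: $1 - \prod_{v\,\text{unseen}}(1 - p_v)$ for one new tumor, and
$\sum_{v\,\text{unseen}} (1 - (1-\bar p_v)^{tm})$ for a $t m$-tumor
extension, marginalised over the tissue mix. Calibration tests compare the
estimators with these oracles across replicate cohorts, not with other
estimators.

What the generator deliberately does not emulate: co-occurrence dependence
between variants (the product-binomial assumption is exactly what real
catalogs violate when variants are co-selected or mutually exclusive),
trinucleotide context and realistic signature spectra (signature labels are
assigned, not derived), and panel-versus-exome capture differences. Passing
calibration on simulated data therefore demonstrates correctness of the
estimators *under the stated model*, not robustness to its violations — the
cross-cohort concordance analysis is the tool for the latter question.

A note on the zipf exponent as a richness dial: with $p_v \propto v^{-s}$, a
*larger* exponent concentrates incidences in the head of the pool and
*lowers* the realized singleton fraction (the hotspot regime); shallow
exponents give singleton-dominated, tumor-suppressor-like catalogs. The
package's tests assert this direction after verifying it against exact
binomial expectations.

## Problem sizes and numerical choices

The test suite calibrates at sizes a single core verifies in minutes, chosen
as small-scale analogues of real cohort analyses: 200 log-series genes at
$m = 2000$ over 100 replicate cohorts for the extrapolation and
unseen-probability calibrations ($t \in \{0.5, 1, 2\}$, agreement within 3
replicate standard errors); 100 independent plus 60 tenfold-effect genes at
1000 permutations for the NMI null; and a 200-gene, 5000/5000 train/validate
split — with deep rare-variant reservoirs (pools of 6000 variants per gene,
probabilities down to $5 \times 10^{-7}$) so that the unseen mass is not
artificially exhausted — on which Lin's CCC for predicted versus observed
unseen-variant quantities exceeds 0.9. The tissue-effect ranking check
shares one variant pool across genes so that rank agreement measures the
injected effect rather than pool-realization noise.

Other conventions: variant identity defaults to protein-level keys
(`"KRAS:G12D"`), with genomic keying available, and a variant counts at most
once per tumor; samples with zero surviving variants stay in $m$; all seeds
are explicit arguments and the callers' RNG state is restored; TSV for
tables, JSON for summaries.

## Known limitations

* Ultra-hypermutated POLE tumors are over-predicted by this model family;
  they are stratified out and reported, not specially modeled.
* The estimators assume exchangeable tumors within a scope; strong intra-
  tissue substructure will show up as NMI signal, not be corrected.
* Indels and fusions are out of scope: the filter keeps non-synonymous SNVs.
* $N_0$ (the number of unseen variants) is never estimated — all quantities
  are chosen specifically to avoid it.

## A worked call sequence

```{r example, eval = FALSE}
library(raremut)

cohort <- read_maf("cohort.maf",
                   annotations = read_sample_annotations("samples.tsv")) |>
  filter_nonsynonymous()

# keep the non-hypermutated subgroup
sub <- assign_subgroups(cohort$samples, threshold = 500)
nh <- filter_samples(cohort, sub$sample_id[sub$subgroup == "non_hypermutated"])

# per-gene unseen-variant probabilities and their tissue specificity
unseen_by_gene(nh, genes = c("KRAS", "FAT1", "PTEN"))
nmi_null(nh, "PTEN", n_permutations = 1000, seed = 7)

# how many new variants would 1.08x more tumors bring?
good_toulmin(variant_frequency(nh), t = 1.08)
```
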