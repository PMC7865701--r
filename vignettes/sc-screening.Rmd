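---
title: "Screening synthetic-cytotoxic gene pairs: models, parameters and design choices"
author: "scpairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening synthetic-cytotoxic gene pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scpairs)
library(survival)
```

## The problem

A synthetic-cytotoxic (SC) gene pair is a conditional synthetic-lethal
interaction with a drug: disrupting either gene alone leaves sensitivity to a
cytotoxic agent unchanged, but disrupting both lowers the half-maximal
inhibitory concentration (IC50). Mining such pairs from cell-line panels —
somatic mutation calls, copy-number estimates and ln IC50 response tables of
the kind distributed by GDSC/COSMIC — yields candidate biomarker pairs, and a
patient cohort with survival follow-up (TCGA-style MAF plus clinical tables)
can then be used to ask whether carrying more disrupted SC partners of a
frequently mutated anchor gene such as *TP53* is prognostic.

`scpairs` implements that pipeline end to end: gene-disruption calling, the
all-pairs rank-sum screen, SC-burden analysis, the SC interaction network,
and Firth-penalized Cox survival validation, together with synthetic cohort
generators that make every stage testable against known ground truth.

## Gene disruption

A gene is *disrupted* in a sample when any of the following holds:

* an intolerant missense variant: consequence `missense_variant` with SIFT
  score strictly below 0.05. Missense variants with a missing SIFT score are
  **not** counted — the rule requires evidence of intolerance, and silently
  treating a missing score as 0 would inflate disruption calls;
* a loss-of-function variant: `stop_gained`, `frameshift_variant`,
  `start_lost`, or a splice-site-region term. We read "splice site region"
  as including `splice_region_variant` alongside the canonical
  donor/acceptor terms; the set is a parameter (`lof` in
  `is_disruptive_variant()`) so the narrower reading is one argument away;
* a homozygous deletion: total copy number exactly 0. Heterozygous losses
  and amplifications are never disruptive, and no segment-level or
  biallelic logic is attempted.

Variants are first cleaned of likely germline calls and sequencing
artifacts by population allele frequency: a variant is kept only when its
ESP frequency is missing or `< 0.00025` and its 1000 Genomes frequency is
missing or `< 0.0014`. The direction — removing *common* variants — follows
the stated purpose of the filter; variants absent from the population
panels are retained.

The result is the binary disruption matrix `D` (samples × genes), with a
per-cell provenance tag (`variant`, `copy_number`, `both`, `none`). A cell
is 1 iff at least one disruptive event exists; absence of evidence is
absence of disruption.

## The SC screen

For a drug with ln IC50 response `y` and a gene pair (A, B), samples are
partitioned by `(D[,A], D[,B])` into **both**, **A-only**, **B-only**,
**neither**. The jointly disrupted group is compared with each of the other
three by a one-sided Mann–Whitney rank-sum test of the alternative "both is
stochastically smaller". A pair is declared SC when all three p-values fall
below `alpha = 0.05` **and** the both-group median is strictly the lowest
of the four.

Decisions worth making explicit:

* **Test direction.** The SC definition is inherently directional
  ("significantly lower IC50"), so one-sided tests are the default. A
  two-sided mode (`screen_params(alternative = "two.sided")`) combined with
  the median-direction rule is available as the alternative reading.
* **Gene filter.** Only genes disrupted in strictly more than 5% of the
  response-bearing samples enter the pair scan (`min_gene_freq = 0.05`,
  strict `>`).
* **Group occupancy.** A pair is tested only when each of the four groups
  holds at least `ceiling(0.025 * n)` samples; under-occupied pairs are
  returned as untested rather than silently dropped. Ceiling is chosen so
  that "at least 2.5%" is never satisfied by a fractional sample.
* **Multiplicity.** No multiple-testing correction is applied by default —
  the conjunction of three α-level tests plus the direction constraint is
  already far stricter than a single test (the measured null declaration
  rate in the acceptance suite is ~0.02 per tested pair). A
  Benjamini–Hochberg switch (`p_adjust = "BH"`, applied to the worst of
  the three p-values across pairs) is provided as a documented deviation.
* **Ties and exactness.** `rank_sum_test()` uses the exact permutation
  null when both groups are ≤ `exact_cutoff = 25` and the data are
  tie-free, and the tie-corrected normal approximation with continuity
  correction otherwise. The exact branch refuses tied data. The exact
  branch is verified against brute-force enumeration of all
  `choose(n_x + n_y, n_x)` rank assignments in the test suite.

`sc_screen()` scans every unordered pair of filter-passing genes once, in
lexicographic order, invariantly to input row/column order.

## SC burden

A sample's burden is the number of declared SC pairs whose two genes are
both disrupted in it. Burdens are binned into the four groups G1 (0), G2
(1–2), G3 (3–9), G4 (> 9); the breakpoints are parameters of
`assign_burden_groups()` with these defaults. Response across groups is
compared by the tie-corrected Kruskal–Wallis test, and cross-drug
robustness by one-sided rank-sum tests between *consecutive* burden groups
(G1 vs G2, G2 vs G3, G3 vs G4) — the comparison scheme that matches
per-boxplot annotation; comparing G1 against every group is the obvious
alternative and is one `split()` away for users who prefer it. Groups
without response data are skipped.

Note that the default bins presuppose a *network-scale* pair set: with
~140 SC pairs of ~3% joint frequency the expected burden is ≈ 4 and all
four bins are populated, whereas a screen that declares only a dozen pairs
concentrates everyone in G1–G2. This matters when choosing simulation
conditions (below).

## The SC network

Declared pairs form an undirected simple graph (genes as nodes, pairs as
edges; duplicates collapse, self-pairs are rejected). `network_summary()`
reports node/edge counts, average degree `2E/N`, connected components and
the top-degree genes. Communities come from the Louvain two-phase
modularity maximisation as implemented in `igraph`; because the sweep
order is randomised internally, `detect_communities()` seeds the RNG so a
recorded seed reproduces the labels exactly. The resolution parameter
defaults to 1. Exports are GraphML (with degree and community node
attributes) or a two-column edge TSV, both round-tripping losslessly.

## Survival validation with Firth-penalized Cox regression

Mutation-defined patient subgroups are often small and can exhibit
monotone likelihood — e.g., every death in one arm — under which the
ordinary Cox maximum partial-likelihood estimate diverges. `firth_coxph()`
therefore maximises the penalized partial log-likelihood

$$ \ell^*(\beta) \;=\; \ell(\beta) + \tfrac12 \log \det I(\beta), $$

where $\ell$ is the Breslow partial log-likelihood and $I$ the observed
information. The Jeffreys-prior-style penalty keeps estimates finite for
any data set with at least one event.

Implementation notes:

* **Ties** use the Breslow approximation — the simplest standard choice;
  the unpenalized mode (`penalized = FALSE`) reproduces
  `coxph(..., ties = "breslow")` coefficients to 5+ digits, which the test
  suite asserts.
* **Optimisation** is Newton–Raphson on the Firth-modified score
  $U^*_r = U_r + \tfrac12\,\mathrm{tr}\!\left(I^{-1}\,\partial I/\partial\beta_r\right)$
  (the derivative computed from exact third moments over each risk set),
  with step-halving so the penalized log-likelihood never decreases along
  accepted steps, a step cap of 5 per iteration, convergence at
  $\max_r |U^*_r| < 10^{-6}$, and at most 100 iterations. Non-convergence
  is flagged on the returned object, never silent.
* **Inference** is by penalized likelihood-ratio tests: the covariate is
  profiled at the null value and twice the drop in $\ell^*$ is referred to
  $\chi^2_1$. This is the established recommendation for Firth-type fits
  under sparse events, where Wald intervals misbehave; `confint()` inverts
  the same test by root-finding, so interval endpoints and p-values agree.
  Wald standard errors from $I^{-1}$ are reported for orientation only.
* **Degenerate designs** — constant columns, collinear columns, zero
  events — are rejected with errors naming the offending covariate.

For the anchor/partner analysis, `stratify_pair_groups()` labels patients
`both_mut` / `anchor_only` / `partner_only` / `wild_type` with `both_mut`
as the factor reference, so reported hazard ratios above 1 read "worse
survival than the double-disrupted group". `partner_burden()` counts
disrupted partners per patient and carries the anchor stratum flag, so the
burden effect can be fitted separately with and without the anchor
mutation. Tumour stage enters as a single ordinal code I–IV
(`encode_stage()`); per-stage dummies are unstable at realistic subgroup
sizes, but a `dummies = TRUE` flag exists.

Kaplan–Meier curves use the product-limit estimator via
`survival::survfit`; subjects censored at `t` remain at risk at `t`. Curve
rows are reported at event times (where the step function moves), with
censoring reflected in the separate risk table.

## The synthetic cohorts

`simulate_cell_cohort()` draws, per sample and gene, an independent
Bernoulli disruption with per-gene frequency $f_g$, realises each
disruption as either a disruptive variant row (intolerant missense with
SIFT < 0.05, or a loss-of-function consequence) or a homozygous-deletion
row with equal probability, and generates
$$ y_{s} = \mu + \textstyle\sum_p \delta_p\,
   \mathbf 1[\text{both genes of pair } p \text{ disrupted in } s]
   + \varepsilon_s,\qquad \varepsilon_s \sim N(0, \sigma^2) $$
for each drug that shares the planted effects; other drugs get pure noise.
Additivity on the ln IC50 scale gives analytically checkable group means.
Defaults — $n = 400$, 50 genes, $f = 0.15$, $\mu = -3$, $\sigma = 1$ —
are the screen-calibration conditions used throughout the acceptance
suite. Every generated event row classifies as disruptive under the
default rules, so the reconstructed matrix equals the latent Bernoulli
draw exactly (asserted in tests).

`simulate_patient_cohort()` draws anchor and partner disruptions
independently, then exponential survival with hazard
$h = h_0 \cdot \mathrm{HR}^{\,\text{burden}\times\text{anchor}}$ and
independent exponential censoring; stage is independent of everything.
Defaults: 800 patients, anchor frequency 0.4 and partner frequency 0.3
(the ballpark of *TP53*/*SYNE2* mutation rates in bladder-cancer cohorts),
HR 0.4 per disrupted partner inside the anchor-mutant stratum, baseline
hazard 1/1000 per day with censoring rate 1/1500 (≈ 60% events at
baseline). Closed-form hazards make parameter-recovery targets exact in
expectation.

**What the generators do not emulate** — and hence what passing tests do
not establish about real data: mutational signatures and hypermutators,
tumour purity and subclonality, co-mutation correlation structure (a
`pair_corr` knob exists for stress tests but defaults to independence),
gene-length and tissue-specific mutation rates, dose–response curve-fit
error in IC50 values, and treatment heterogeneity in survival cohorts.

## Two structural facts about the screen, quantified by simulation

The recovery analysis (10 planted disjoint pairs, $\delta = -2.5$,
$\sigma = 1$, $f = 0.15$, $n = 400$) exposes two properties worth knowing
before applying the screen to real panels:

1. **Occupancy is the recall bottleneck.** The jointly disrupted group is
   Binomial$(400, f^2)$ with mean 9.0, while the 2.5% rule demands ≥ 10, so
   only ~41% of true pairs are even *tested*; given occupancy, power at
   $\delta = -2.5\sigma$ is essentially 1. Measured recall across seeds is
   ~0.4. On real panels this means pairs of genes mutated near the
   frequency floor are systematically untestable at these thresholds.
2. **Signal leakage caps precision.** If (A, B) is a true pair, then for
   any third gene C the jointly-disrupted group of (A, C) contains
   B-disrupted samples at rate $f$, acquiring a real mean shift of about
   $f\delta$. These induced declarations are genuine features of the
   additive generative model, not false positives of the test machinery;
   they produce a measured precision of ~0.15–0.2 under these conditions.
   On real data the analogue is that correlated mutation patterns
   propagate SC signal to neighbouring pairs.

Both numbers are recomputed, not asserted, by the acceptance suite and
`scripts/acceptance.R`.

## Simulation sizes used by the test and acceptance suites

Chosen as the smallest sizes at which each property is statistically
decisive: null calibration, 20 cohorts of 400 × 50; recovery, 10 cohorts
of the same size; Firth hazard-ratio recovery, 200 replicates at
$n = 400$ with true HR 2.5 and ~50% censoring; stratum contrast, 50
patient cohorts of 800; cross-drug robustness, one cohort of 800 samples
with 100 network-scale planted pairs ($f = 0.18$, $\delta = -0.75$,
joint frequency ≈ 3.2%) so that all four burden bins are populated
(~30/150/350/250) and the weakest consecutive contrast retains high
power, plus 30 independent drugs for the null rejection rate.

## Known limitations

* The screen tests marginal pair effects only; no higher-order
  interactions, no interaction-term regression, no dose–response
  modelling.
* The Louvain implementation is `igraph`'s; determinism is guaranteed
  only via the recorded seed, not bit-for-bit against other tools.
* The Firth engine supports right censoring and time-fixed covariates
  only; no stratified baselines, competing risks or time-varying effects.
* Gene identifiers are opaque case-sensitive strings; no symbol
  normalisation is attempted, so upstream harmonisation is the user's
  responsibility.
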