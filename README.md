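# scpairs

Inference of **synthetic-cytotoxic (SC) gene pairs** — conditional
synthetic-lethal interactions with a drug — from cancer cell-line panels,
with survival validation in patient cohorts. The package is aimed at
computational biologists working with GDSC/COSMIC-style cell-line tables
(annotated variants, copy number, ln IC50 drug response) and TCGA-style
patient data (MAF mutations plus clinical follow-up).

## What it computes

1. **Disruption matrix.** A gene is disrupted in a sample when it carries
   an intolerant missense variant (SIFT < 0.05), a loss-of-function
   variant (nonsense, frameshift, start-loss, splice-site region), or a
   homozygous deletion (total copy number 0). Variants at population
   allele frequency ≥ 0.00025 (ESP) or ≥ 0.0014 (1000 Genomes) are
   removed first as likely germline/artifact calls. The result is the
   binary matrix *D* (samples × genes).

2. **All-pairs SC screen.** For each pair (A, B) of genes disrupted in
   > 5% of samples, samples split into *both / A-only / B-only / neither*
   by (D[,A], D[,B]). With every group holding ≥ ⌈0.025 n⌉ samples, three
   one-sided Mann–Whitney tests compare ln IC50 of *both* against each
   other group; the pair is SC when all three p < 0.05 and median(*both*)
   is strictly the minimum.

3. **SC burden.** Per sample, the number of SC pairs with both genes
   disrupted; binned into G1 (0), G2 (1–2), G3 (3–9), G4 (> 9) and
   compared across groups by the Kruskal–Wallis test, plus consecutive
   rank-sum comparisons for other drugs (cross-drug robustness).

4. **SC network.** Genes as nodes, SC pairs as edges; degree summaries,
   Louvain communities (seeded, reproducible), GraphML/TSV export.

5. **Survival validation.** Firth-penalized Cox proportional hazards,
   maximising ℓ*(β) = ℓ(β) + ½ log det I(β) (Breslow ties), which stays
   finite under the monotone likelihood of small mutation-defined
   subgroups; penalized likelihood-ratio p-values and profile-likelihood
   intervals; Kaplan–Meier curves with risk tables; anchor/partner
   stratification with the double-mutant group as reference.

6. **Synthetic cohorts.** Seed-deterministic generators for both cohort
   types with planted ground truth (additive ln IC50 effects for jointly
   disrupted pairs; burden-by-anchor proportional hazards for survival),
   so every stage is testable without external downloads.

## Worked example

```r
library(scpairs); library(survival)

cfg <- cell_cohort_config(n_samples = 400, n_genes = 50,
                          disruption_freq = 0.3,
                          planted_pairs = planted_pair_grid(5, delta = -2.5),
                          seed = 42)
sim <- simulate_cell_cohort(cfg)
m <- build_disruption_matrix(sim$variants, sim$copy_number,
                             samples = cfg$samples, genes = cfg$genes)
m
#> Disruption matrix: 400 samples x 50 genes, 5988 disrupted cells (29.9%)

scr <- sc_screen(m, sim$response, drug = "drug_01")
summary(scr)
#> SC screen summary
#>   samples:             400
#>   genes screened:      50
#>   pairs tested:        1225 / 1225
#>   SC pairs declared:  56 (29 distinct genes)

recovery_metrics(cfg$planted_pairs, scr)[c("precision", "recall")]
#> $precision
#> [1] 0.08928571
#> $recall
#> [1] 1
```

All five planted pairs are recovered (recall 1). The many extra
declarations are *induced* pairs: at disruption frequency 0.3 a pair
sharing one gene with a true pair inherits part of its effect, so its
jointly disrupted group genuinely is more sensitive — see the methods
vignette for the quantitative analysis of this leakage.

```r
burden <- compute_burden(m, sc_pairs(scr))
groups <- assign_burden_groups(burden)
table(groups$group)
#>  G1  G2  G3  G4
#>  33 111 195  61

burden_response_test(groups, sim$response, drug = "drug_01")
#> Kruskal-Wallis: H = 162.43 on 3 df, p = < 2.22e-16
#> group medians: -2.479, -2.982, -4.259, -6.664

network_summary(build_sc_network(scr))
#> SC network: 29 nodes, 56 edges, 3 components
#>   average degree: 3.862
#>   top degrees: G010=10, G002=8, G005=8, G009=8, G003=7
```

Median ln IC50 falls monotonically with SC burden — the boxplot pattern
the burden analysis is after. On the patient side:

```r
pt <- simulate_patient_cohort(patient_cohort_config(seed = 7))
d <- data.frame(time = pt$clinical$os_time, status = pt$clinical$os_event,
                burden = pt$truth$burden, anchor = pt$truth$anchor_mut)
firth_coxph(Surv(time, status) ~ burden, d[d$anchor == 1, ])
#> Firth-penalized Cox proportional-hazards fit
#> n = 331 , events = 163
#>           coef     HR    se p
#> burden -0.6664 0.5135 0.136 0
```

The fitted hazard ratio per disrupted partner inside the anchor-mutant
stratum (0.51) recovers the generator's truth (0.4 per partner,
log-scale estimate within two standard errors); the same fit restricted
to anchor-wild-type patients shows no effect.

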