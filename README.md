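# tfredist

Statistical pipeline for **rapid transcription-factor depletion**
experiments in regulatory genomics, written for analysts working with
degron (dTAG-style) time courses of chromatin accessibility (ATAC-seq),
factor binding (ChIP-seq), and nascent transcription (PRO-seq), plus the
patient-cohort follow-up such studies end with.

The motivating biology: a repressive GATA-family factor (TRPS1) is
acutely degraded in luminal breast cancer cells. Its loss opens proximal
regulatory elements, estrogen receptor (ER) binding *redistributes* from
factor-distal to factor-proximal sites, target genes respond in both
directions, and a regulon defined from the primary response stratifies
patients by inferred factor activity. Every stage of that downstream
analysis is implemented here as reusable, tested R functions, exercised
end to end on seeded synthetic data with planted effects — no external
data required.

## What is implemented

| Stage | Functions |
|---|---|
| I/O and data model | `read_peaks`, `write_peaks`, `read_count_table`, `read_meme_motif`, `read_survival_table`, `peak_set`, `count_matrix` |
| Synthetic data with planted truth | `sim_config`, `simulate_peak_landscape`, `simulate_timecourse_counts`, `simulate_cohort`, `simulate_growth` |
| NB differential testing | `size_factors`, `estimate_dispersions`, `wald_test`, `lrt_timecourse`, `shrink_lfc`, `bh_adjust`, `classify_features` |
| Motifs | `log_odds_score`, `score_pvalue_table`, `scan_intervals`, `prevalence_test`, `prevalence_timecourse` |
| Interval geometry | `nearest_distance`, `filter_peaks_overlapping`, `count_in_intervals`, `ecdf_ks`, `composite_profile` |
| Response kinetics | `standardize_profiles`, `cluster_profiles` |
| TF redistribution | `fc_by_gene_class`, `fc_by_distance_to_anchor`, `rank_sum_compare` |
| Gene sets / activity score | `fisher_ora`, `gsea_es`, `gsea_permutation_p`, `cohort_zscore_rank`, `patient_activity`, `regulon` |
| Survival / growth | `km_estimate`, `logrank_test`, `growth_interaction_test` |

Core statistics, briefly. Counts are negative binomial with variance
`mu + alpha*mu^2`; size factors are median-of-ratios; dispersions are
moment estimates shrunk toward a mean-dispersion trend with an adaptive
empirical weight; contrasts use Wald `z = log2FC/SE`, time courses a
likelihood-ratio chi-square; features are classed increased / decreased /
unchanged at FDR 0.1. Motif p-values are exact under a 0-order background
via dynamic programming over 1/1000-bit score bins. The per-patient
activity score ranks a patient's genes by cohort z-score and computes
`dES = ES(depletion-up regulon half) − ES(depletion-down half)` with the
classic weighted running-sum ES; high factor activity means the
depletion-up (factor-repressed) half is significantly negatively enriched
and the depletion-down half positively enriched. Growth fits
`ln N ~ day * treatment` and F-tests the interaction.

## Worked example

Simulate the landscape, test ER differential binding 30 min after
depletion, and group fold changes by summit-to-summit distance to the
nearest anchor peak:

```r
library(tfredist)

cfg  <- sim_config(seed = 42)
land <- simulate_peak_landscape(cfg, sequences = FALSE)

er_counts <- simulate_timecourse_counts(land$truth, cfg, features = "er")
keep <- er_counts$meta$timepoint %in% c(0, 30)
er30 <- count_matrix(er_counts$counts[, keep], er_counts$meta[keep, ])
er_diff <- wald_test(er30, contrast = c("dTAG", "DMSO"), fdr = 0.1)

redis <- fc_by_distance_to_anchor(er_diff, land$er, land$trps1)
print(redis$summary, digits = 3)
#>           group   n mean_log2fc       t        p stars
#> 1     [0,10000) 270      0.7184  29.165 2.82e-85   ***
#> 2 [10000,1e+05)  90     -0.0224  -0.521 6.03e-01  N.S.
#> 3   [1e+05,Inf) 240     -0.8731 -33.185 1.88e-91   ***
```

ER sites proximal to the depleted factor gain binding (mean +0.72 log2,
planted +0.8), distal sites lose it (−0.87, planted −0.8), the middle bin
is null — the redistribution signature, recovered from raw counts.

Score a synthetic patient cohort with the two-tailed regulon dES and
stratify survival:

```r
coh <- simulate_cohort(cfg)
act <- patient_activity(coh$expression, coh$regulon, n_perm = 199, seed = 42)
head(act, 3)
#>   patient_id  es_up es_down   p_up  p_down   dES class
#> 1       p047 -0.965   0.946 0.0105 0.01075 -1.91  high
#> 2       p049 -0.885   0.865 0.0111 0.01064 -1.75  high
#> 3       p093 -0.843   0.856 0.0100 0.00862 -1.70  high
table(act$class)
#>         high intermediate          low
#>           82           45           73

surv <- merge(act, coh$survival, by = "patient_id")
lr <- logrank_test(surv, surv$class)
#> logrank chi-square = 69.2 (df = 2), p = 9.31e-16
```

The most negative dES marks the highest inferred factor activity (its
depletion-up targets are suppressed); the three activity classes separate
survival sharply because the generator couples hazard to the same latent
score.

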