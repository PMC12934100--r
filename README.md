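# dormsig

Quantifying the dormancy-proliferation axis in melanoma transcriptomes.

Melanoma cells switch between a proliferative, melanocytic state and a
dormant, mesenchymal-like state linked to invasion and therapy resistance.
`dormsig` scores bulk RNA-seq samples along that axis with an eight-gene
composite signature, re-derives signatures from labelled cohorts,
identifies dormancy-associated co-expression modules and their hub gene
(TROP2/TACSTD2), tabulates DNA-versus-RNA variant allele fraction (VAF)
concordance, and stratifies survival and therapy response. A seeded
synthetic-cohort generator plants every structure the pipeline is expected
to recover, so the whole analysis is testable without external data.

## The score

For a sample *s*, z-score each gene's `log2(TPM + 1)` values across the
cohort, sum the up-regulated signature genes (TACSTD2, EREG, SOX9, LPPR4)
into `U_s` and the down-regulated genes (LAMA1, TMEM27, AMIGO2, MGAT5B)
into `D_s`, and form the normalized difference

```
S_s = (U_s - D_s) / (|U_s| + |D_s|)        (S_s = 0 when the denominator is 0)
```

`S` spans -1 (proliferative) to +1 (dormant) with zero as the decision
boundary; `S > 0` labels a sample dormant. See the methods vignette
(`vignettes/dormancy-signature.Rmd`) for the full model, parameter
defaults, and design rationale.

## Worked example

```r
library(dormsig)

cfg    <- sim_config(seed = 1)                 # 11 dormant + 11 proliferative
cohort <- simulate_expression(cfg)
scores <- score_samples(cohort$expression)     # packaged 8-gene signature
head(scores, 4)
#>   sample_id    U     D score   label
#> 1     DOR01 5.37 -4.08     1 dormant
#> 2     DOR02 1.36 -1.93     1 dormant
#> 3     DOR03 3.01 -3.41     1 dormant
#> 4     DOR04 4.11 -3.65     1 dormant

roc_auc(scores, cohort$phenotype)
#> AUC = 1.0000 (3 ROC points)
```

The positive `U` and negative `D` components agree for every dormant
sample, so their scores saturate at +1 and the signature separates the two
phenotypes perfectly (AUC 1.0 on this resubstitution cohort).

```r
net <- coexpression_analysis(cohort$expression, trait = scores$score)
mod <- net$modules[[1]]
sprintf("module of %d genes, hub %s, trait r = %.2f (p = %.3g)",
        length(mod$genes), mod$hub, mod$trait_r, mod$trait_p)
#> "module of 13 genes, hub TACSTD2, trait r = 0.62 (p = 0.00189)"

clin <- simulate_clinical(cfg, cohort$phenotype)
lr   <- logrank_test(clin$time, clin$event, clin$phenotype)
sprintf("log-rank chi-square = %.2f (p = %.3g)", lr$statistic, lr$p)
#> "log-rank chi-square = 4.77 (p = 0.0289)"
```

The network stage recovers the planted 13-gene module with TACSTD2 as its
hub and an eigengene-score correlation near the planted 0.6; the dormant
arm's higher hazard shows up in the log-rank test.

Variant concordance on the packaged transcription of the study's DNA/RNA
variant table:

```r
tab2 <- read_variant_table(system.file("extdata", "table2_variants.tsv",
                                       package = "dormsig"))
summarize_concordance(tab2)
#>   gene n_total n_confirmed n_with_both_vafs n_rna_higher n_rna_lower ...
#> 1 BRAF      18          16               14           12           2
#> 2 NRAS       7           4                3            3           0
```

Of the 14 BRAF-mutant tumours with both VAFs, 12 show a higher VAF at the
RNA level — consistent with elevated mutant transcript expression.

A command-line interface wrapping the same stages is installed at
`exec/dormsig` (subcommands `simulate`, `score`, `derive`, `network`,
`concordance`, `survival`, `response`, `sc-summary`).

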