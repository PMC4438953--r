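# mirmrna

Integrated miRNA–mRNA differential-expression and network analysis for
two-group (tumor vs. normal) microarray designs, with tongue squamous cell
carcinoma (TSCC)-style cohort layouts as the motivating use case.

MicroRNAs repress their target mRNAs through seed-region complementarity, so
a miRNA that goes *up* in tumors should push its targets *down* (and vice
versa). `mirmrna` turns that reasoning into a tested, reusable pipeline:

1. **Differential expression** — empirical-Bayes moderated t-tests per
   feature. Residual variances s²_g are shrunk toward a moment-matched prior
   (s²_g ~ s₀²·F(d, d₀) marginally), giving the moderated statistic
   t̃_g = (x̄_T − x̄_N) / √(s̃²_g(1/n_T + 1/n_N)) with
   s̃²_g = (d·s²_g + d₀·s₀²)/(d + d₀) and d + d₀ degrees of freedom.
   Threshold filters: fold-change > 4 (miRNA), P < 0.01, FDR < 0.01
   (Benjamini–Hochberg), with a configurable blacklist for retracted array
   probes.
2. **Hierarchical clustering** — Pearson-correlation distance d = 1 − r with
   average linkage (UPGMA), deterministic tie-breaking, and a two-cluster
   root cut of the sample tree.
3. **Seed-match target prediction** — TargetScan-style canonical sites in
   3'UTRs: `8mer` (perfect Watson–Crick complement of miRNA nucleotides 2–8
   followed by A), `7mer-m8` (complement of 2–8), `7mer-A1` (complement of
   2–7 plus A); no G:U wobble, strongest class wins per position.
   Precomputed prediction tables can be imported instead.
4. **Anti-correlation integration** — keep a predicted (miRNA, gene) pair
   only when both are differentially expressed with *opposite* directions.
5. **Gene-set enrichment** — one-sided Fisher exact (hypergeometric tail)
   and Pearson χ² per term, fold enrichment Re = (nf/n)/(Nf/N), and the
   paired-test run-level FDR = 1 − Nk/T where Nk counts terms whose Fisher p
   undercuts its χ² partner.
6. **Bipartite networks** — miRNA–GO and miRNA–mRNA adjacency A = (a_i,j)
   with binary degrees; key nodes are ranked by degree.
7. **Cross-cohort confirmation** — direction-of-change concordance of the
   network genes in an independent cohort.
8. **Synthetic data with known truth** — a generator that plants
   fold-changes, implants exact seed sites for planted pairs (and screens
   all other miRNA×UTR combinations to be site-free), and builds annotation
   terms enriched for the planted targets, so every stage is measurable
   against ground truth.

## Worked example

```r
library(mirmrna)

cfg <- synth_config(n_mirnas = 60, n_genes = 500, n_de_mirnas = 8,
                    targets_per_de_mirna = 4, n_terms = 20, seed = 42)
ds <- synth_generate(cfg)
ds$mirna_expr
#> ExpressionMatrix: 60 features x 18 samples [log2 scale]
#>   groups: normal=3, tumor=15

de_mir <- apply_thresholds(moderated_t_test(ds$mirna_expr),
                           de_thresholds(4, 0.01, 0.01),
                           blacklist = "hsa-mir-923")
head(de_mir[, c("feature_id", "log_fc", "fold_change", "p_value", "fdr")], 3)
#>    feature_id    log_fc fold_change      p_value          fdr
#> 1 hsa-mir-037 -3.529739  0.08658500 7.385584e-27 4.431351e-25
#> 2 hsa-mir-025 -3.457091  0.09105671 7.865599e-26 2.359680e-24
#> 3 hsa-mir-010 -3.234649  0.10623644 8.143646e-23 1.628729e-21

de_gene <- apply_thresholds(moderated_t_test(ds$mrna_test),
                            de_thresholds(1, 0.01, 0.01))
pred  <- predict_targets(ds$mirna_seqs[de_mir$feature_id], ds$utr_seqs)
pairs <- intersect_and_filter(pred, de_mir, de_gene)
nrow(pairs)   # 32 anti-correlated regulatory pairs (all 32 planted ones)

res <- enrich(unique(pairs$gene_id), ds$gene_sets, max_p = 0.01, max_fdr = 1)
head(res[, c("term_id", "nf", "n", "Nf", "N", "fisher_p", "fold_enrichment")], 3)
#>   term_id nf  n Nf   N     fisher_p fold_enrichment
#> 1 TERM002 23 32 28 500 9.118149e-28        12.83482
#> 2 TERM001 14 32 17 500 4.949997e-16        12.86765
#> 3 TERM003 11 32 13 500 8.481060e-13        13.22115

net <- build_mirna_mrna(pairs)
net
#> BipartiteNetwork: 8 miRNAs x 32 genes, 32 edges
confirm_directions(net$right_nodes, moderated_t_test(ds$mrna_test),
                   moderated_t_test(ds$mrna_confirm))
#> ConcordanceReport: 32 candidates, 32 detected, 32 concordant (100.0%)
```

The three recovered miRNAs with the largest negative fold-changes are the
planted down-regulated ones; `TERM001`–`TERM003` are the generator's three
"true" terms (built from planted target genes), which rank at the top of the
enrichment table; and the twin confirmation cohort reproduces every
direction of change, as it shares the planted truth.

## End-to-end runs

`run_all(run_config(...))` executes the whole pipeline from file inputs (TSV
expression + groups TSV + FASTA + GMT) and writes per-stage TSV/GraphML/JSON
outputs plus a `report.json` of stage counts. The same stages are available
as CLI subcommands via `inst/cli/mirmrna`:

```sh
Rscript inst/cli/mirmrna simulate --out run1 --seed 7
Rscript inst/cli/mirmrna run-all  --out run1 --seed 7
```

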