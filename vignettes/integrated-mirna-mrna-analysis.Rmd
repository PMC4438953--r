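---
title: "Integrated miRNA-mRNA analysis: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated miRNA-mRNA analysis: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirmrna)
```

## The problem

MicroRNAs (miRNAs) silence mRNAs whose 3'UTRs carry matches to the miRNA
seed region (nucleotides 2-8). In a tumor/normal microarray design this
predicts a signature: targets of an up-regulated miRNA should be enriched
among the down-regulated mRNAs and vice versa. `mirmrna` implements the
complete inference chain — differential expression on both molecular
levels, seed-based target prediction, an anti-correlation filter, gene-set
enrichment, bipartite network ranking, and an independent-cohort direction
check — as separately testable stages with a synthetic ground-truth
generator underneath.

Two practical constraints shaped the design. First, the miRNA and mRNA
cohorts come from *different patients*, so sample-level miRNA-mRNA
correlation is undefined; "negative correlation" must mean opposite
directions of differential expression, computed from the two cohorts'
fold-changes. Second, microarrays measure probes; probe-to-gene collapsing
(maximum |log2 fold-change| per gene) is deferred until the integration
step so that differential expression itself stays probe-level.

## Differential expression

Expression values are analyzed on the log2 scale (`log_transform` refuses
to transform twice; an `offset` handles zeros in count-like data). For each
feature the two-group contrast is the difference of group means,
`log_fc = mean(tumor) − mean(normal)`, reported alongside the linear
`fold_change = 2^log_fc`.

Variance moderation follows the standard empirical-Bayes hierarchical
model: the pooled residual variance of feature *g*, `s2_g` on `d` degrees
of freedom, is marginally `s0^2 * F(d, d0)` under an inverse-chi-squared
prior. We estimate `(s0^2, d0)` by matching the first two moments of the
observed `s2` distribution: with `c = var(s2)/mean(s2)^2`,

```
d0 = (2*(d - 2) + 4*c*d) / (c*d - 2),     s0^2 = mean(s2) * (d0 - 2)/d0
```

and `c*d <= 2` (variances less dispersed than pure chi-squared noise)
yields `d0 = Inf`, i.e. complete shrinkage to the common variance. The
moderated statistic uses the posterior variance
`(d*s2 + d0*s0^2)/(d + d0)` with `d + d0` degrees of freedom.
`prior_df_mode = "none"` disables shrinkage entirely, reducing exactly to
the ordinary pooled two-sample t — this is the oracle-testable limit, and
the acceptance suite verifies the identity to 1e-10. The moment-matched
prior differs numerically from profile-likelihood fits in other
implementations (e.g. limma's `fitFDist`); on simulated data the
t-statistics agree to correlation > 0.99, which the test suite checks, but
identity is neither expected nor claimed.

Multiple testing uses Benjamini-Hochberg throughout the DE stage. The
bespoke paired-test FDR (below) is defined for — and used only in — the
enrichment stage.

### Thresholds

The default cuts are the published ones for this study design: miRNA
fold-change > 4 (two-sided: keep > 4 or < 1/4, since down-regulated
features are listed with fold-changes like 0.17), P < 0.01, FDR < 0.01;
mRNA series use P and FDR alone. `de_thresholds(min_fold_change = 1)`
expresses "no fold cut" — a deliberate relaxation of the nominal
`min_fold_change > 1` field invariant, because the mRNA configuration needs
the boundary value. The source study's figure legend mentions a 2-fold cut
where its methods state 4-fold; the methods value is the default, and the
threshold is a configuration value, never hard-coded, so either analysis is
reproducible. The blacklist defaults to hsa-miR-923, an array probe later
found not to be a real miRNA.

## Clustering

Samples (or features) are clustered with the Pearson correlation distance
`d = 1 − r` (range [0, 2]) and unweighted average linkage (UPGMA),
implemented directly so that merge ties break deterministically by
(distance, lexicographically smallest member pair) on every platform. The
two reported sample clusters come from removing the root merge; the
component containing the lexicographically smallest normal sample is
`cluster1`. A cut at fixed height was the alternative reading; the root cut
was chosen because a two-branch description of the tree is exactly what a
two-cluster claim asserts. Heat-map exports are plain reordered-matrix TSVs
plus a Newick tree; image rendering is intentionally out of the tested
surface.

## Seed-match target prediction

Canonical TargetScan-style site classes, scanned 5'→3' along the UTR:

| class   | definition                                            | length |
|---------|-------------------------------------------------------|--------|
| 8mer    | complement of seed 2-8, followed by A in the UTR      | 8      |
| 7mer-m8 | complement of seed 2-8                                | 7      |
| 7mer-A1 | complement of seed 2-7, followed by A in the UTR      | 7      |

The position-1 A is a literal UTR adenosine (not complementarity to the
miRNA's first base), G:U wobble is not allowed, and when classifications
overlap only the strongest class is reported per position (8mer > 7mer-m8 >
7mer-A1). Matching uses zero-width-lookahead regular expressions so
overlapping occurrences of repetitive seeds are not missed; the test suite
proves equivalence with a character-by-character brute-force scanner on
random sequences. 3'-compensatory sites and conservation filtering are out
of scope; imported prediction tables (`import_predictions`) may contain
them and are taken at face value.

## Integration and enrichment

A predicted pair (m, g) survives `intersect_and_filter` iff m is in the
filtered miRNA DE list, g in the filtered (gene-level) mRNA DE list, and
`sign(log_fc_m) * sign(log_fc_g) < 0`; an exactly-zero log fold-change has
no direction and drops the pair. The association weight is
`|log_fc_m| * |log_fc_g|` — the source material never defines its
"association weight", so the product of effect sizes was chosen as the
simplest symmetric option — but *degrees* are always computed on binary
adjacency, because published degree listings are small integers (edge
counts), and the weighted matrix is exported separately.

Enrichment of the filtered target genes against GO-term or pathway GMT
collections reports, per term with at least one query hit: the one-sided
Fisher exact p (hypergeometric tail `P(X >= nf)`), the two-sided 1-df
Pearson chi-squared p without continuity correction (degenerate tables
return p = 1 with a warning), and fold enrichment `Re = (nf/n)/(Nf/N)` —
the standard over-representation ratio, adopted because the original
"enrichment" measure is undefined beyond being a specificity score. The
run-level paired-test FDR is `1 − Nk/T` with `Nk = #{Fisher p < chi2 p}`;
it admits no per-term interpretation, so a BH adjustment of the Fisher p is
also reported (clearly labeled `bh_p`) for practical ranking. The default
universe is every gene with at least one annotation in the collection,
configurable to the full array. Note that when no Fisher p undercuts its
chi-squared partner the run FDR equals exactly 1; the GO significance
default therefore applies the P cut only (`max_fdr = 1` disables the FDR
cut), while pathway runs use P < 0.05 and FDR < 0.05.

GO hierarchy propagation is deliberately not performed: terms are used
exactly as given in the GMT, so published term counts (which depend on a
specific annotation release) are not an acceptance surface.

## Networks and confirmation

Both networks are strictly bipartite. miRNA-GO edges require a *filtered*
regulatory gene shared between the miRNA and a significant term — being a
predicted target is not enough, matching a pipeline that builds networks
after filtering. Key nodes are ranked by binary degree, ties
lexicographically. Exports: edge TSV, GraphML with node `type`/`direction`
attributes (via igraph), and a characteristics TSV mirroring the published
degree listings.

Confirmation maps the mRNA-network genes onto an independent cohort:
"detected" means present on the confirmation platform at all (significance
is not re-required — the check is about direction, not power), and
concordance compares `sign(log_fc)` between cohorts. The test cohort alone
determines DE membership; the confirmation cohort is never used for
selection, only for direction checking.

## The synthetic world

`synth_config()` defaults state the emulated conditions: cohort shapes
15v3 (miRNA), 26v12 (mRNA test) and 37v20 (mRNA confirmation); 200 miRNAs,
2,000 genes; 20 planted differential miRNAs at |log2 effect| 3.0 with 5
disjoint targets each (targets planted with the opposite sign); residual
noise sd 0.5 on the log2 scale; 50 annotation terms of 10-40 members, 3 of
them "true" terms drawing 80% of their members from planted targets; 60-nt
UTRs and 22-nt miRNAs. Baseline log2 means are uniform on [6, 12]. Where
the stated world needed values nothing published fixes (UTR length, term
count, enrichment strength, baselines), the choices are one-time judgments
of what makes a small but realistic instance, and they are not tuned
against test outcomes. A zero effect size means "nothing is differential":
the planted truth is empty and the data are pure null, which is what the
null-calibration tests consume.

Sequence generation guarantees a sharp oracle: every planted pair receives
one implanted 8mer site at a random UTR position, and *all other*
miRNA×UTR combinations are screened to contain no canonical site of any
class. Screening repeatedly rescans and mutates one flank base inside any
spurious site window, never touching implanted regions; to make this
always convergent, miRNA seeds are sampled pairwise non-conflicting (no
seed's site string, nor its 6mer-core+A, occurs inside another's implanted
8mer). The practical cap is 60 screening rounds — random 60-nt UTRs clear
in a handful.

What the generator does *not* emulate: probe-level artifacts (saturation,
background), cross-array batch effects, correlated gene modules,
non-Gaussian heavy tails, many-to-many probe maps. A green recovery test
therefore establishes algorithmic correctness under the stated model, not
robustness to real-array pathology.

## Numerical and degenerate-input choices

- BH adjustment: step-up `p*m/rank` with cumulative-minimum monotonicity,
  capped at 1.
- Pearson distance clamps tiny negative values (floating-point noise near
  r = 1) to 0; zero-variance vectors are an error naming the vector.
- Fisher p uses the exact hypergeometric tail; the acceptance suite checks
  it against full binomial-coefficient enumeration for every table with
  N <= 60.
- Missing expression values are *absent*, never zero; features over 20%
  missing are excluded, the rest mean-imputed within group (configurable).
  This default is conservative and deliberately boring.
- Empty DE lists are not errors: the pipeline completes with empty
  downstream outputs, a warning, and a well-formed report.
- All orderings (DE tables, pairs, network nodes, merge ties) are total and
  deterministic, so byte-identical reruns are a tested property.

## Known limitations

- The moment-matched prior can differ from likelihood-based estimates when
  very few features are available; with under ~10 features the `d0`
  estimate is noisy (shrinkage then tends toward the common-variance
  limit).
- The paired-test FDR is reported faithfully but is a blunt instrument: it
  is constant across a run and highly sensitive to the Fisher-vs-chi-squared
  tie structure. Use `bh_p` for per-term decisions.
- De novo prediction treats every supplied UTR as 1:1 with a gene;
  alternative UTR isoforms must be resolved upstream.
- The CLI covers the pipeline stages and conventional file layout; it is a
  thin layer over the exported functions, not a workflow manager.
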