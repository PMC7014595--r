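# synmir

Discovery of synergistically acting microRNA pairs from matched
tumor/normal expression profiles.

MicroRNAs (miRNAs) repress target mRNAs post-transcriptionally, and pairs
of miRNAs whose predicted repression programs overlap strongly are
candidates for cooperative regulation — a mechanism of particular interest
in tumors, where coordinated miRNA loss can de-repress whole pathways.
`synmir` is for computational biologists who have matched tumor/normal
miRNA + mRNA profiles (or want to study the method itself on synthetic
data) and need a tested, reproducible implementation of the full chain
from differential expression to a significance-assessed miRNA–miRNA
synergy network.

## The method

1. **Paired differential expression.** Per feature, within-pair
   differences d_i = tumor_i − normal_i; moderated t (empirical-Bayes
   variance shrinkage, the standard s²_post = (d₀s₀² + νs²)/(d₀+ν)
   construction) or ordinary one-sample t; DE at |logFC| > 0.585 (1.5-fold)
   and Benjamini–Hochberg FDR < 0.05.
2. **miRNA–target network.** Pearson correlation r of every DE miRNA
   against every DE gene over the pooled samples; an edge (M, G) needs
   r ≤ −0.6 *and* a sequence-based target prediction with PCT > 0.5, and
   carries the prediction's context+ score w(M, G).
3. **Synergism score.** Each miRNA is its target-weight vector
   V_M = (w(M,G1), w(M,G2), …). For a pair, the vectors are aligned on the
   union of their target sets (zero-filled) and the score is the Fisher
   z-transform s = atanh(r) of their Pearson correlation (raw scale
   optional; |r| clamped at 1 − 1e−7). Pairs with < 3 shared targets are
   not scored.
4. **Randomization significance.** Gene-to-weight assignment of one vector
   is permuted; exact enumeration up to 8! arrangements, Monte Carlo with
   add-one p beyond; one-sided (high score = synergy).
5. **Synergy network + hubs.** Edges at s ≥ 1.400 (equivalently
   r ≥ tanh(1.400) ≈ 0.885), deterministic degree/score hub ranking.
6. **GO co-regulation.** Hypergeometric over-representation of each
   miRNA's targets against a GMT annotation (BH < 0.05 within miRNA);
   N = terms significant in both miRNAs of a pair; high group at N > 10;
   random-group control over all pairs including self-pairs (28 miRNAs →
   406 pairs).

A synthetic-data generator plants DE features, repressive miRNA→target
links, a calibrated synergistic pair and co-regulated GO terms, so every
stage is testable against known truth without any download.

## Worked example

The `analysis/` directory is a numbered workflow over the package; run it
from the repository root (stages read the previous stage's files under
`results/`):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_diffexpr.R
Rscript analysis/03_target_network.R
Rscript analysis/04_synergy.R
Rscript analysis/05_go_coreg.R
```

Output of an actual run:

```
01: planted DE miRNAs: miR-007, miR-016, miR-035, ... (10 total)
    planted synergistic pair: miR-007 + miR-016 (20 shared targets, profile r = 0.95)
02: 10 DE miRNAs, 141 DE genes
    planted miRNA recall: 1
03: miRNA-target network: 10 miRNAs, 87 target genes, 167 edges
    planted edge recall: 0.84;  false-edge rate: 0
04: 20 scored pairs of 45
    top pair: miR-007 + miR-016  score 0.281 (r = 0.274, p = 0.121, 15 shared targets)
    planted pair recovered as top: TRUE
05: 45 miRNA pairs; high co-regulation (N > 10): 3
    observed high fraction (55 pairs incl. self): 0.109
    random-group mean high fraction: 0.013  (empirical p = 0.0198)
```

Reading this: all 10 planted DE miRNAs pass the 1.5-fold/FDR filter; 84%
of planted repressive edges survive the r ≤ −0.6 + PCT > 0.5 double
filter with no false edges; the planted pair miR-007/miR-016 is the
top-scoring of all 20 scorable pairs (absolute scores are diluted by
imperfect edge recovery under union alignment — rankings are the stable
quantity, see the methods vignette); and the network miRNAs share
significantly more co-regulated GO terms than random groups of the same
size (0.109 vs 0.013 high-pair fraction, empirical p ≈ 0.02).

The same pipeline runs as a single call:

```r
library(synmir)
res <- run_pipeline(pipeline_config(out_dir = "run1", seed = 1))
top_pair(res$pairs)
```

Real data enter through `pipeline_config(simulate = FALSE, ...)` with six
TSV/GMT paths: expression + design for both assays (log2, normalized),
a prediction table (`mirna_id`, `gene_id`, `context_score`, `pct`) and a
GMT annotation.

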