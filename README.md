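# adipolnc

Novel lncRNA discovery and browning-candidate prioritization from
assembled adipocyte transcriptomes.

White adipose tissue can acquire a thermogenic, brown-like phenotype
("browning"), and long non-coding RNAs are candidate regulators of that
switch. Given a merged transcript assembly, a reference annotation,
genome sequence and a transcript count matrix from white, brown and
beige adipocytes, this package:

1. **identifies novel lncRNAs** among unannotated transcripts with a
   four-stage filter — length > 200 nt and FPKM > 0.5 in ≥ 1 sample; no
   base-level overlap with known exons; > 2 kb from any known
   single-exon transcript; coding-potential score < 0 — with a full
   per-transcript audit trail;
2. **characterizes** them against annotated lncRNAs and coding genes
   (length, expression, coding potential, exon/intron conservation);
3. **tests differential expression** across the three adipocyte types
   with a simplified negative-binomial pipeline (median-of-ratios size
   factors, trend-moderated method-of-moments dispersions, delta-method
   Wald test, BH adjustment; significant ⇔ padj < 0.05 and
   |log2FC| > 1);
4. **integrates** the contrasts: Venn intersection of DEG sets, cis
   target genes by nearest coding gene within 100 kb (position and
   strand in the target gene's orientation), and hypergeometric term
   enrichment.

The coding-potential scorer is trainable: ORF length/coverage, the
Fickett TESTCODE statistic, and in-frame hexamer log-odds, combined by
logistic regression into a signed score whose sign is the
coding/noncoding verdict (score < 0 ⇔ noncoding,
P(coding) < 0.5).

A synthetic-data generator (`simulate_experiment()`) emulates the
three-type, two-replicate design with planted ground truth — true-novel
lncRNAs that satisfy every filter criterion by construction, five decoy
classes each violating exactly one criterion, planted fold changes and
planted cis geometry — so the whole pipeline is testable end to end
without downloads.

## Worked example

The analysis lives in `analysis/01_simulate.R` … `analysis/06_report.R`;
each stage reads only files written by earlier stages under `results/`.

```sh
Rscript analysis/01_simulate.R 1     # seed 1
Rscript analysis/02_identify_lncrnas.R
Rscript analysis/03_characterize.R
Rscript analysis/04_diffexp.R
Rscript analysis/05_integrate.R
Rscript analysis/06_report.R
```

Stage 2 prints the filter funnel and its agreement with the planted
truth — 100 unannotated candidates (50 planted novels + 50 decoys, 10
per violation class), each decoy removed at exactly its designated
stage:

```
funnel: unannotated=100  length_fpkm=80  overlap=70  distance=60  coding=50
novel lncRNAs: 50 identified; precision 1.000, recall 1.000
```

Stage 3 recovers the planted class structure — coding genes longer and
with high scores and conserved exons; novel lncRNAs expressed above
annotated ones; introns unconserved everywhere:

```
             class             feature   n       median
            coding              length 230 1710
      novel_lncRNA              length  50  707.5
            coding        coding_score 230   11.08
  annotated_lncRNA        coding_score 100  -10.50
            coding   exon_conservation 230    0.804
  annotated_lncRNA   exon_conservation 100    0.295
            coding intron_conservation 200    0.192
```

Stage 4 calls DEGs per contrast (fold changes read "up in the
first-named type") and checks them against the planted effects:

```
White_vs_Brown: 36 called, planted recall 0.97, empirical FDR 0.03
White_vs_Beige: 61 called, planted recall 1.00, empirical FDR 0.05
Beige_vs_Brown: 53 called, planted recall 1.00, empirical FDR 0.00
```

Stage 5 intersects the contrasts and assigns cis targets; with seed 1,
15 features are differential in all three comparisons, and every DE
novel lncRNA's nearest-gene call matches the planted geometry:

```
common DEGs across all three contrasts: 15
14 of 14 DE novel lncRNAs received a cis target; positions: downstream=6 upstream=8
cis calls matching the planted geometry: 1.00
```

Stage 6 ranks identified novel lncRNAs by beige-specific expression
(mean beige FPKM over mean white+brown FPKM) — the planted beige-up
lncRNAs, the synthetic analogues of browning candidates, come out on
top with ratios near the planted 2^3:

```
     lncrna_id beige_fpkm other_fpkm beige_ratio
 MSTRG.10023.1   4720.031   514.1109    9.180800
 MSTRG.10093.1   7814.470   980.7707    7.967612
```

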