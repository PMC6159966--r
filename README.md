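# dmmrscan

Detection and immunogenomic characterisation of mismatch-repair
deficient (dMMR) tumors from next-generation sequencing data.

dMMR tumors fail to repair replication slippage, producing
microsatellite instability (MSI) and a distinctive hypermutated genome.
Because the clinical assays for dMMR (MMR-protein immunohistochemistry,
PCR fragment analysis of five mononucleotide markers) often disagree —
particularly in advanced prostate cancer, where the dMMR subgroup is
small but clinically aggressive and potentially immunotherapy-responsive
— sequencing-based readouts are attractive. This package implements
that toolkit end to end:

* **MSI scoring from read histograms** (`msings_score`): per locus, the
  number of allele lengths supported by ≥ 5% of the modal read count is
  compared to an MMR-intact baseline; a locus is unstable when its count
  exceeds *mean + 2·SD*, and the sample score is the unstable fraction
  of evaluated loci. Includes enriched-locus selection, a fixed 0.209
  harmonization factor for exome-derived scores, and a Promega-style PCR
  classifier (MSI-high at ≥ 2 unstable markers of BAT-25, BAT-26,
  NR-21, NR-24, MONO-27).
* **Mutational signatures** (`fit_signatures`): SNVs are tabulated over
  the 96 pyrimidine-strand trinucleotide channels; the count matrix V is
  factorised as V ≈ WᵀH by multi-restart NMF under the generalised
  Kullback–Leibler divergence (multiplicative updates, minimum-residual
  run selected), with rank diagnostics (cophenetic coefficient,
  residual, RSS), optimal cosine-similarity matching to reference
  signatures, per-sample exposure proportions, and the MMR-dominant flag
  (> 50% of mutations on MMR-type signatures).
* **Tumor-only somatic filtering** (`filter_variants`): quality removal
  (haplotype score > 200, MAPQ < 40, depth < 60, alt fraction < 5%,
  multiallelic, indel, blacklisted), germline removal (cohort AF > 5%,
  ≥ 2 population databases, alt fraction > 99.9%), COSMIC rescue of
  point mutations reported somatic ≥ 10 times, mutation load per
  megabase with dichotomization at 5.5, and MMR-gene event
  classification (biallelic-LOF / germline / single-allele).
* **Immune transcript association** (`associate_genes`): per-gene
  Pearson correlation of expression with dMMR signature activity,
  BH-corrected overall (FDR 0.1) with a per-biopsy-site consistency
  requirement (nominal p < 0.05 in every adequately sized stratum),
  geometric-mean checkpoint score over a 32-gene panel, LD-TIL pooled
  density, and crude contingency odds ratios.
* **Biomarker and survival metrics** (`youden_cutoff`,
  `km_median_and_logrank`): Mann–Whitney AUC, Youden-optimal cutoffs
  under a `score ≥ cutoff` convention, Kaplan–Meier medians and the
  log-rank test.
* **A synthetic cohort generator** (`simulate_cohort`) producing
  stutter-noise allele histograms, signature-mixture mutation catalogs
  with a concrete reference chromosome, spiked variant tables,
  expression matrices with a latent infiltrate factor, and survival
  data — all with complete ground truth, so every stage is testable
  without patient data.

## Worked example

```r
library(dmmrscan)
res <- run_pipeline("out", cfg = sim_config(seed = 7))
res$roc
res$signatures
```

prints, for the default synthetic cohort (40 samples, 25% dMMR, 200
microsatellite loci, ~500 mutations/sample on a 1-Mb synthetic
chromosome):

```
ROC: AUC 1.000; optimal cutoff 0.125 (sens 100.0%, spec 100.0%, J = 1.000)
Mutational signature model (KL-NMF)
  rank: 4  restarts: 20  best seed: 240303763
  residual divergence: 1822.69
  samples: 40  channels: 96
  reference assignments:
    S1 -> Aging1 (cosine 0.999)
    S2 -> MMR6 (cosine 0.989)
    S3 -> MMR26 (cosine 0.985)
    S4 -> HRD3 (cosine 0.941)
```

The MSI score separates the simulated dMMR and pMMR groups perfectly at
this instability rate (AUC 1.0; the Youden-optimal cutoff 0.125 sits
between the two score distributions), and all four discovered signatures
match their generating references (cosines 0.941–0.999; the flat HRD-like
profile is always the hardest). Downstream, `res$km$medians` shows the
simulated survival disadvantage of the dMMR group (2.48 vs 5.44 years;
log-rank p = 0.071 at n = 40), and the MMR-dominant fraction (0.25)
recovers the simulated dMMR fraction. At this small cohort size the
checkpoint-gene association table finds no gene passing FDR < 0.1 with
the default infiltrate effect of r = 0.24 — detecting an effect that
small takes closer to the 168-sample scale used in the association
tests. All outputs are written as plain TSV under `out/` and the run is
byte-identical under a fixed seed.

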