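---
title: "Detecting mismatch-repair deficiency from sequencing panels: methods and design"
author: "dmmrscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting mismatch-repair deficiency from sequencing panels: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmmrscan)
```

# The problem

Mismatch-repair deficient (dMMR) tumors fail to correct replication
slippage, so they accumulate length changes at microsatellites
(microsatellite instability, MSI) and a characteristic excess of point
mutations. dMMR status matters clinically — it predicts response to
immune checkpoint blockade — but the standard assays
(immunohistochemistry for the MMR proteins, PCR fragment analysis of five
mononucleotide markers) frequently disagree, especially in metastatic
prostate cancer where the dMMR subgroup is small. This package implements
a sequencing-based toolkit for the problem: MSI scoring from read
histograms, mutational-signature deconvolution, tumor-only somatic
filtering and mutation load, immune-transcript association, and the
biomarker metrics used to compare assays. A synthetic cohort generator
with complete ground truth makes every stage testable without patient
data.

# MSI scoring from allele-length histograms

The substrate is, per sample and per microsatellite locus, a histogram of
supporting reads over allele repeat lengths. The statistic per locus is
the **supported allele count**: the number of repeat lengths whose read
count is at least `peak_fraction` (default 0.05) of the modal count. An
MMR-intact **baseline** stores, per locus, the mean and SD of this count
across baseline samples; a sample's locus is called unstable when its
count strictly exceeds `mean + sd_multiplier * sd` (default multiplier
2). The per-sample MSI score is the unstable fraction of evaluated loci.

Numerical choices, all configurable:

* **Population SD** (divisor *n*) for the baseline — it is treated as a
  reference population, not a sample from one.
* **`sd = 0` loci**: the strict inequality means any extra allele is a
  call. This is intended: well-behaved mononucleotide runs should be
  tightly reproducible in MMR-intact tissue.
* **Coverage gates**: histograms with fewer than `min_reads = 30` reads
  do not contribute; samples with fewer than `min_evaluated = 20`
  evaluated loci are an error (not a silent zero). Loci missing from the
  baseline are *not evaluated* and excluded from the denominator, which
  avoids deflating scores.
* Exome-derived scores live on a different scale from targeted-panel
  scores and are multiplied by a fixed harmonization factor, default
  0.209, kept as a configuration constant rather than re-derived.

`select_enriched_loci()` reduces a large candidate panel to the
informative subset: loci callable in most normals, stable in every
normal, and unstable in at least one known-dMMR tumor. This is one
defensible reading of "enrichment from tumor and normal samples"; the
exact rule used to produce published enriched sets is not specified
anywhere we could follow, so the rule here is documented and
deterministic (ordering by locus id).

`promega_classify()` emulates the PCR assay rule exactly: instability at
2 or more of BAT-25, BAT-26, NR-21, NR-24, MONO-27 is MSI-high, exactly
one is MSI-low, none is MSS, and dichotomized analyses group MSI-low
with MSS.

# Mutational signatures

Single-nucleotide variants are classified on the pyrimidine strand into
96 trinucleotide-context channels (6 substitutions x 16 flank pairs),
ordered substitution-major then 5' then 3' base, alphabetically. The
sample-by-channel count matrix is factorised as `t(V) ~ W H` by
non-negative matrix factorisation under the generalised Kullback–Leibler
divergence with the classical multiplicative updates. Design points:

* **Pseudocount** `1e-9` is added to `V` inside the updates so zero
  channels cannot produce divisions by zero; the divergence trace is
  monotone non-increasing and is asserted as such in the tests.
* **Convergence** stops when the relative divergence decrease per sweep
  falls below `1e-8` (or at `max_iter = 5000`). The tolerance is
  deliberately tight: flat, low-contrast signatures keep sharpening long
  after the divergence has nearly plateaued, and a looser stop visibly
  degrades their recovery while barely changing the objective.
* **Restarts**: NMF is non-deterministic, so `fit_signatures()` runs
  `n_runs` factorisations from seeds `seed, seed+1, ...` and keeps the
  minimum-divergence run (ties to the lowest seed). Deriving run seeds
  from one master seed makes the multi-restart procedure reproducible.
* **Normalisation**: signature columns of `W` sum to one, with the
  compensating scale moved into `H`, so exposures are on the
  mutation-count scale and row-normalised exposures are proportions.
* **Rank selection is reported, not automated.** `rank_diagnostics()`
  emits, per rank, the cophenetic coefficient of the consensus matrix
  (co-assignment of samples by argmax exposure, average-linkage
  clustering), the best run's divergence, and its residual sum of
  squares; the analyst chooses the rank. The default analysis rank is 4.
* **Matching**: discovered signatures are assigned one-to-one to
  reference signatures by exhaustively maximising total cosine
  similarity (feasible for ranks up to 8); pairs under 0.8 cosine are
  flagged unmatched.
* A tumor is **MMR-dominant** when strictly more than 50% of its
  exposure proportion lies on the MMR-type signatures; both MMR-type
  signatures are summed by default (configurable via the index set).
  Proportions, not raw counts, are used as "activity" throughout.
* A Frobenius-objective variant of the updates is available as a config
  option; KL is the default and the tested path. Bayesian NMF is out of
  scope.

The four bundled reference signatures are **synthetic**: qualitative
analogues of an aging-like clock process (spiky C>T at NpCpG), a flat
HRD-like process, and two MMR-type processes with distinct flank
profiles. They are constructed in code, not copied from any catalogue,
and their pairwise cosine similarities are enforced to be at most 0.6 so
recovery problems posed with them are well identified. Real catalogue
matrices can be supplied via `read_signature_table()`.

# Tumor-only somatic filtering and mutation load

`filter_variants()` applies three stages with per-record dispositions and
a balanced report:

1. **Quality**: remove when haplotype score > 200, mapping quality < 40,
   depth < 60, alternate fraction < 5%, multiallelic, indel, or
   blacklisted site. Missing quality fields fail **closed** (removed,
   reason `missing-field`).
2. **Germline**: cohort allele frequency strictly above 5%, presence in
   2 or more population databases, or alternate fraction strictly above
   99.9%. Missing population fields fail **open** — a variant is not
   called germline on absent evidence. Both conventions are conservative
   for mutation load and logged.
3. **COSMIC rescue**: germline-removed *point mutations* with a COSMIC
   somatic occurrence count of at least 10 re-enter the mutation count,
   and count toward per-megabase load identically to never-filtered
   records.

Every boundary (59/60, 0.05/0.0501, 1/2 databases, 0.999/0.9991, 9/10)
is pinned by paired tests, and the whole table is checked against a
literal restatement of the rules on random records. Mutation load is the
surviving count, optionally per megabase of panel territory (default
0.6 Mb), dichotomized at 5.5 (so 6 or more mutations is "high").
Indels are excluded from the SNV load path by the quality rule; a
`keep_indels` switch routes them through an indel path under the same
germline rules.

# Immune transcript association

The immunomodulatory score is the geometric mean of TPM across the
32-gene checkpoint/T cell panel, with an offset of +1 inside the log by
default because zero TPM values are common (offset 0 is available and
errors on zeros). Associations of per-gene expression with dMMR
signature activity are Pearson correlations; the published practice of
manually reviewing scatterplots and removing outliers is automated as an
explicit **robust-z policy** (remove points whose least-squares residual
exceeds 3.5 MAD-scaled units, always reporting removals); `"none"`
reproduces plain Pearson. Genes pass the primary criterion when their
overall BH q-value is below 0.1 **and** every adequately sized
biopsy-site stratum has nominal p below 0.05; strata under `min_n = 10`
samples drop out of the consistency requirement and are recorded. BH is
also the obvious within-site correction; the consistency flag is defined
on nominal per-site p, and per-site q-values can be computed by
re-running `bh_fdr` within a stratum when wanted.

LD-TIL density is the pooled ratio (total T cells over total tumor area
across images), never the mean of per-image ratios. The crude 2x2 odds
ratio uses ad/bc with an optional Haldane–Anscombe +0.5 correction when
a zero cell is present and a Woolf log-scale confidence interval;
mixed-effects models are out of scope.

# Biomarker metrics and survival

AUC uses the Mann–Whitney identity with ties counted half. The optimal
cutoff maximises Youden's J over every distinct observed score under a
uniform `score >= cutoff` positivity convention (plus the all-negative
rule, so J is never negative); ties break toward the lower cutoff
(favouring sensitivity) with a switch for the other direction.
Kaplan–Meier medians (first time the curve reaches 0.5 or below) and the
log-rank test delegate to the survival package; the tests verify the
statistic against a literal O−E/V computation.

# The synthetic cohort generator

The generator is first-class, tested code, and its ground truth is the
only label source downstream recovery tests use. What it emulates, and
what it does not:

* **Histograms**: reads pile up at the reference repeat length; stutter
  support decays geometrically by `stutter_decay` per repeat unit,
  truncated at ±5. The default decay of 0.1 keeps stutter at ±2 units
  and beyond below the 5% allele-counting threshold, so the novel
  alleles of unstable loci — placed at least 2 units from the mode with
  at least 10% of the modal support — are distinguishable from stutter
  by construction. In dMMR samples each locus is unstable independently
  with probability `p_unstable_locus` (default 0.2, chosen for test
  power; real per-locus rates are not published).
* **Catalogs**: per-sample Dirichlet exposures over the four reference
  signatures (dMMR samples draw from a concentration elevated on the
  MMR-type components), negative-binomial mutation counts
  (overdispersion as in real tumors; Poisson available), and concrete
  SNVs placed at genome positions of a simulated 1-Mb chromosome whose
  flanks realise the assigned context, on either strand. Every emitted
  record round-trips through context classification.
* **Variant tables**: germline spike-ins (high cohort frequency,
  database presence, or near-100% alternate fraction) and artifact
  spike-ins (each quality rule), all respecting the filter thresholds by
  a margin, with a configurable fraction of germline spike-ins made
  COSMIC-rescuable.
* **Expression**: a latent infiltrate factor equal to
  `e * standardized(activity) + sqrt(1 - e^2) * noise` (so its
  population correlation with activity is `e`, default 0.24), with the
  32 panel genes loading on it log-normally (mean loading 0.4) and
  background genes independent.
* **Survival**: exponential times with a configurable dMMR:pMMR hazard
  ratio (default 4) around a 7-year pMMR median, uniform censoring.

Not emulated: read-level data (FASTQ/BAM), indel realism beyond
microsatellite length shifts, count-level RNA-seq, batch effects,
copy-number segments. Passing recovery tests therefore demonstrates
correctness of the algorithms under the generator's assumptions, not
performance on real tumors — in particular, real stutter is
locus-specific and asymmetric, real signatures overlap more than the
enforced 0.6 cosine separation, and real cohort structure (shared
patients, biopsy-site confounding) is richer than the independent draws
here.

# Problem sizes and reproducibility

The shipped analyses use desk-scale problem sizes chosen to make every
stochastic recovery property comfortably detectable: signature recovery
runs 150 samples at ~500 mutations each with 20 NMF restarts on a 200-kb
synthetic chromosome; MSI recovery uses 200 loci with 10 dMMR and 30
pMMR samples; association tests use 168 samples. The full default
pipeline (40 samples, 200 loci, 1-Mb chromosome, 20 restarts) runs in
well under a minute and re-runs byte-identically under a fixed master
seed, which fans out to per-stage seeds by stable hashing of stage
names.

```{r example, eval = FALSE}
res <- run_pipeline("out", cfg = sim_config(seed = 7))
res$roc                       # MSI score vs simulated dMMR labels
res$signatures$assignments    # discovered-to-reference matching
head(res$association)         # checkpoint-gene association table
```

# Known limitations

* The MSI scorer consumes repeat-length histograms; calling them from
  alignments is upstream and out of scope.
* The enrichment rule for informative loci is one defensible reading of
  a procedure that is not fully specified in the literature.
* The 0.209 exome harmonization factor is taken as given; whether the
  exome score uses a different per-locus statistic before scaling is not
  documented in its source.
* CIBERSORT-style deconvolution is not reimplemented; when an inferred
  infiltrate column is available from any source the package correlates
  it like any other per-sample covariate.
* The Youden cutoff is data-derived; no fixed published cutoff is baked
  in.
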