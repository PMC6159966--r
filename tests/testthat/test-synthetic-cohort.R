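test_that("a fixed seed reproduces the cohort exactly", {
  cfg <- sim_config(n_samples = 8, n_loci = 15, mutations_per_sample = 40,
                    n_genes = 50, genome_length = 2e4, seed = 1)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$histograms, b$histograms)
  expect_identical(a$mutations, b$mutations)
  expect_identical(a$expression, b$expression)
  expect_identical(a$clinical, b$clinical)
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(frac_dmmr = 1.2), "proportions")
  expect_error(sim_config(n_loci = 0), "counts")
  expect_error(sim_config(read_depth = 0), "read_depth")
  cfg <- sim_config(n_samples = 2, n_loci = 2)
  cfg$read_depth <- 0
  expect_error(simulate_locus_histograms(cfg), "read_depth")
})

test_that("zero stutter decay produces single-allele histograms", {
  cfg <- sim_config(n_samples = 3, n_loci = 10, frac_dmmr = 0,
                    stutter_decay = 0, seed = 3)
  hs <- simulate_locus_histograms(cfg)
  per <- table(hs$histograms$sample_id, hs$histograms$locus_id)
  expect_true(all(per == 1))
  expect_equal(hs$histograms$repeat_length,
               hs$loci$reference_repeat_count[
                 match(hs$histograms$locus_id, hs$loci$locus_id)])
})

test_that("without instability, MSI scores stay near zero", {
  cfg <- sim_config(n_samples = 16, n_loci = 60, p_unstable_locus = 0,
                    frac_dmmr = 0.5, seed = 4)
  hs <- simulate_locus_histograms(cfg)
  normals <- names(hs$truth$dmmr)[!hs$truth$dmmr]
  base <- build_baseline(
    hs$histograms[hs$histograms$sample_id %in% normals, ])
  sc <- msings_score(hs$histograms, base)
  expect_lte(max(sc$score), 0.05)
})

test_that("dMMR novel alleles sit at least two units from the mode", {
  cfg <- sim_config(n_samples = 10, n_loci = 40, p_unstable_locus = 0.5,
                    frac_dmmr = 0.5, seed = 8)
  hs <- simulate_locus_histograms(cfg)
  expect_gt(nrow(hs$truth$unstable), 0)
  for (i in seq_len(nrow(hs$truth$unstable))) {
    h <- hs$histograms[
      hs$histograms$sample_id == hs$truth$unstable$sample_id[i] &
        hs$histograms$locus_id == hs$truth$unstable$locus_id[i], ]
    ref_len <- hs$loci$reference_repeat_count[
      hs$loci$locus_id == hs$truth$unstable$locus_id[i]]
    far <- h$repeat_length[abs(h$repeat_length - ref_len) >= 2]
    expect_gt(length(far), 0)
    modal <- h$read_count[h$repeat_length == ref_len]
    expect_gte(max(h$read_count[abs(h$repeat_length - ref_len) >= 2]),
               0.1 * modal)
  }
})

test_that("mutation catalogs conserve counts and match the reference", {
  cfg <- sim_config(n_samples = 5, mutations_per_sample = 60,
                    genome_length = 3e4, seed = 6)
  mc <- simulate_mutation_catalogs(cfg)
  expect_equal(nrow(mc$mutations), sum(mc$truth$mutation_counts))
  ref_bases <- substr(rep(mc$reference[["chrSim"]], nrow(mc$mutations)),
                      mc$mutations$pos, mc$mutations$pos)
  expect_equal(ref_bases, mc$mutations$ref)
  expect_true(all(abs(rowSums(mc$truth$exposures) - 1) < 1e-12))
})

test_that("catalog simulation rejects a mismatched signature matrix", {
  cfg <- sim_config(n_samples = 2, mutations_per_sample = 10,
                    genome_length = 1e4)
  S <- reference_signatures()[, 1:3]
  expect_error(simulate_mutation_catalogs(cfg, S), "concentration")
  S4 <- reference_signatures(); S4[1, 1] <- S4[1, 1] + 1e-3
  expect_error(simulate_mutation_catalogs(cfg, S4), "sum to 1")
})

test_that("annotation spike-ins land on the intended side of each filter", {
  cfg <- sim_config(n_samples = 6, mutations_per_sample = 300,
                    genome_length = 3e4, germline_rate = 0.15,
                    artifact_rate = 0.15, seed = 12)
  mc <- simulate_mutation_catalogs(cfg)
  va <- simulate_variant_annotations(mc$mutations, cfg)
  cls <- va$truth$spike_class
  rec <- va$records
  som <- cls == "somatic"
  expect_true(all(rec$depth[som] >= 60))
  expect_true(all(rec$mapq[som] >= 40))
  expect_true(all(rec$cohort_af[som] <= 0.05))
  expect_true(all(rec$db_hits[som] < 2))
  g <- cls == "germline"
  expect_true(all(rec$cohort_af[g] > 0.05 | rec$db_hits[g] >= 2 |
                    rec$alt_reads[g] / rec$depth[g] > 0.999))
  expect_true(any(va$truth$cosmic_rescuable))
  expect_true(all(rec$cosmic_count[va$truth$cosmic_rescuable] >= 10))
})

test_that("zero spike-in rates leave every record somatic", {
  cfg <- sim_config(n_samples = 4, mutations_per_sample = 100,
                    genome_length = 2e4, germline_rate = 0,
                    artifact_rate = 0, seed = 13)
  mc <- simulate_mutation_catalogs(cfg)
  va <- simulate_variant_annotations(mc$mutations, cfg)
  f <- filter_variants(va$records)
  expect_equal(nrow(f$final), nrow(va$records))
  expect_true(all(f$dispositions == "somatic"))
})

test_that("the infiltrate factor tracks dMMR activity as configured", {
  # null effect: correlation indistinguishable from zero
  cfg0 <- sim_config(n_samples = 200, infiltrate_effect = 0, seed = 30)
  act <- stats::runif(200)
  e0 <- simulate_expression(cfg0, act)
  r0 <- stats::cor(act, attr(e0, "infiltrate"))
  expect_lt(abs(r0), 3 / sqrt(200))
  # effect 0.24 at n = 168: recovered r within the Fisher-z 95% interval
  cfg1 <- sim_config(n_samples = 168, infiltrate_effect = 0.24, seed = 31)
  act1 <- stats::runif(168)
  e1 <- simulate_expression(cfg1, act1)
  r1 <- stats::cor(act1, attr(e1, "infiltrate"))
  expect_gt(r1, 0.09)
  expect_lt(r1, 0.39)
})

test_that("panel genes load on the factor; background genes do not", {
  cfg <- sim_config(n_samples = 120, infiltrate_effect = 0.5,
                    n_genes = 150, seed = 32)
  X <- simulate_expression(cfg, stats::runif(120))
  f <- attr(X, "infiltrate")
  panel <- attr(X, "panel")
  rs <- apply(log(X + 1), 1, stats::cor, y = f)
  expect_gt(mean(rs[panel]), mean(rs[setdiff(rownames(X), panel)]))
  expect_true(all(X >= 0))
})

test_that("survival generator honours the hazard ratio", {
  hits <- 0; reps <- 40
  for (i in seq_len(reps)) {
    cfg <- sim_config(n_samples = 124, frac_dmmr = 0.3, hazard_ratio = 4,
                      followup_max = 60, seed = 100 + i)
    cl <- simulate_clinical(cfg, .dmmr <- stats::setNames(
      seq_len(124) <= 37, sprintf("S%03d", 1:124)))
    med <- tapply(cl$os_years, cl$dmmr, stats::median)
    if (med["TRUE"] < med["FALSE"]) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.95)
})

test_that("fully censored survival data is flagged degenerate", {
  out <- km_median_and_logrank(times = rep(1, 10), events = rep(0, 10),
                               groups = rep(c("a", "b"), 5))
  expect_true(out$degenerate)
  expect_true(all(is.na(out$medians)))
})
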