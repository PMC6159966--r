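base_record <- function(...) {
  rec <- data.frame(sample_id = "S1", chrom = "chrSim", pos = 100L,
                    ref = "C", alt = "T", variant_type = "SNV",
                    depth = 200L, alt_reads = 60L, mapq = 55,
                    haplotype_score = 50, cohort_af = 0.01, db_hits = 0L,
                    cosmic_count = 0L, multiallelic = FALSE,
                    poorly_sequenced_site = FALSE, gene = "",
                    stringsAsFactors = FALSE)
  mods <- list(...)
  for (k in names(mods)) rec[[k]] <- mods[[k]]
  rec
}

test_that("each quality threshold removes exactly its own side", {
  keep <- function(rec) nrow(quality_filter(rec)$kept) == 1
  expect_false(keep(base_record(mapq = 39.9)))
  expect_true(keep(base_record(mapq = 40)))
  expect_false(keep(base_record(depth = 59L)))
  expect_true(keep(base_record(depth = 60L, alt_reads = 30L)))
  expect_false(keep(base_record(haplotype_score = 200.1)))
  expect_true(keep(base_record(haplotype_score = 200)))
  expect_false(keep(base_record(depth = 100L, alt_reads = 4L)))   # 4% < 5%
  expect_true(keep(base_record(depth = 100L, alt_reads = 5L)))    # 5% kept
  expect_false(keep(base_record(multiallelic = TRUE)))
  expect_false(keep(base_record(variant_type = "indel")))
  expect_true(nrow(quality_filter(base_record(variant_type = "indel"),
                                  keep_indels = TRUE)$kept) == 1)
  expect_false(keep(base_record(poorly_sequenced_site = TRUE)))
  # missing quality fields fail closed
  rem <- quality_filter(base_record(mapq = NA))$removed
  expect_equal(rem$reason, "missing-field")
})

test_that("each germline rule splits exactly at its stated boundary", {
  germ <- function(rec) nrow(germline_filter(rec)$germline) == 1
  expect_false(germ(base_record(cohort_af = 0.05)))
  expect_true(germ(base_record(cohort_af = 0.0501)))
  expect_true(germ(base_record(cohort_af = 0.06)))
  expect_false(germ(base_record(db_hits = 1L)))
  expect_true(germ(base_record(db_hits = 2L)))
  expect_false(germ(base_record(depth = 10000L, alt_reads = 9990L)))  # 0.999
  expect_true(germ(base_record(depth = 10000L, alt_reads = 9991L)))   # 0.9991
  expect_true(germ(base_record(depth = 2000L, alt_reads = 1999L)))    # 0.9995
  # missing population annotations fail open
  expect_false(germ(base_record(cohort_af = NA, db_hits = NA)))
})

test_that("COSMIC rescue re-admits recurrent point mutations only", {
  g10 <- base_record(cohort_af = 0.2, cosmic_count = 10L)
  g9 <- base_record(cohort_af = 0.2, cosmic_count = 9L)
  ind <- base_record(cohort_af = 0.2, cosmic_count = 50L,
                     variant_type = "indel")
  expect_equal(nrow(cosmic_rescue(g10)), 1)
  expect_equal(nrow(cosmic_rescue(g9)), 0)
  expect_equal(nrow(cosmic_rescue(ind)), 0)
  f <- filter_variants(g10)
  expect_equal(f$dispositions, "rescued-cosmic")
  expect_equal(nrow(f$final), 1)
})

test_that("dispositions match the literal filtering sentence on random tables", {
  rec <- random_records(2000, seed = 77)
  f <- filter_variants(rec)
  expected <- vapply(seq_len(nrow(rec)), function(i)
    oracle_disposition(rec[i, ]), character(1))
  expect_equal(f$dispositions, expected)
  # report balances: input = final + removals - rescues
  n <- stats::setNames(f$report$n, f$report$stage)
  expect_equal(n[["input"]],
               n[["final"]] + n[["removed_quality"]] +
                 n[["removed_germline"]] - n[["rescued_cosmic"]])
  expect_equal(sum(f$dispositions %in% c("somatic", "rescued-cosmic")),
               nrow(f$final))
})

test_that("filter outcomes are independent of row order", {
  rec <- random_records(400, seed = 78)
  f1 <- filter_variants(rec)
  set.seed(1); perm <- sample.int(nrow(rec))
  f2 <- filter_variants(rec[perm, ])
  expect_equal(f2$dispositions, f1$dispositions[perm])
})

test_that("spiked cohorts are recovered with near-perfect precision/recall", {
  cfg <- sim_config(n_samples = 8, mutations_per_sample = 400,
                    genome_length = 5e4, seed = 55)
  mc <- simulate_mutation_catalogs(cfg)
  va <- simulate_variant_annotations(mc$mutations, cfg)
  f <- filter_variants(va$records)
  truth_final <- va$truth$spike_class == "somatic" |
    va$truth$cosmic_rescuable
  called_final <- f$dispositions %in% c("somatic", "rescued-cosmic")
  tp <- sum(called_final & truth_final)
  expect_gte(tp / sum(called_final), 0.99)  # precision
  expect_gte(tp / sum(truth_final), 0.99)   # recall
})

test_that("mutation load converts counts to the per-megabase scale", {
  rec <- do.call(rbind, c(replicate(6, base_record(), simplify = FALSE),
                          replicate(3, base_record(sample_id = "S2"),
                                    simplify = FALSE)))
  load <- mutation_load(rec, panel_size_mb = 0.6)
  expect_equal(load$per_mb[load$sample_id == "S1"], 10)
  expect_equal(load$n_mutations[load$sample_id == "S2"], 3L)
  expect_error(mutation_load(rec, panel_size_mb = 0), "positive")
  expect_equal(dichotomize_load(c(5, 6, 0)), c(FALSE, TRUE, FALSE))
  expect_true(dichotomize_load(5.5))
})

test_that("MMR gene status follows the biallelic precedence rules", {
  expect_equal(classify_mmr_status("MSH2", homozygous_deletion = TRUE),
               "biallelic-LOF")
  expect_equal(classify_mmr_status("MLH1", n_nonsynonymous = 1, loh = TRUE),
               "biallelic-LOF")
  expect_equal(classify_mmr_status("PMS2", n_nonsynonymous = 2),
               "biallelic-LOF")
  expect_equal(classify_mmr_status("MSH6", n_nonsynonymous = 1),
               "single-allele-nonsynonymous")
  expect_equal(classify_mmr_status("MSH6", n_nonsynonymous = 1,
                                   germline = TRUE), "germline")
  expect_equal(classify_mmr_status("MSH2"), "none")
  expect_error(classify_mmr_status("BRCA2"), "unknown MMR gene")
})
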