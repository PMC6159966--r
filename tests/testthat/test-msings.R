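test_that("allele counting thresholds on the modal peak", {
  expect_equal(count_alleles(c(`15` = 100, `14` = 6, `16` = 3), 0.05), 2)
  expect_equal(count_alleles(c(`15` = 100), 0.5), 1)
  expect_equal(count_alleles(c(`15` = 100, `14` = 100), 0.05), 2)
  expect_equal(count_alleles(c(`15` = 100, `14` = 5, `16` = 4), 0.05), 2)
  expect_error(count_alleles(numeric(0)), "empty histogram")
  expect_error(count_alleles(c(`15` = 0)), "empty histogram")
})

test_that("baseline statistics use the population SD", {
  h <- rbind(make_hist("N1", "L1", 15, 100),
             make_hist("N2", "L1", 15, 100),
             make_hist("N3", "L1", c(15, 14), c(100, 80)),
             make_hist("N4", "L1", c(15, 14), c(100, 80)))
  b <- build_baseline(h, min_reads = 30)
  expect_equal(b$mean_allele_count, 1.5)
  expect_equal(b$sd_allele_count, 0.5)       # population divisor
  expect_equal(b$n_baseline_samples, 4L)
  bs <- build_baseline(h, min_reads = 30, sd_type = "sample")
  expect_equal(bs$sd_allele_count, sqrt(1 / 3))
})

test_that("identical baseline histograms give zero SD everywhere", {
  h <- do.call(rbind, lapply(c("N1", "N2", "N3"), function(s)
    rbind(make_hist(s, "L1", c(15, 14), c(90, 10)),
          make_hist(s, "L2", 20, 80))))
  b <- build_baseline(h)
  expect_true(all(b$sd_allele_count == 0))
})

test_that("underpowered loci are dropped from the baseline with a warning", {
  h <- rbind(make_hist("N1", "L1", 15, 100),
             make_hist("N2", "L1", 15, 100),
             make_hist("N1", "L2", 12, 100))  # only one baseline sample
  expect_warning(b <- build_baseline(h), "dropped")
  expect_equal(b$locus_id, "L1")
})

test_that("instability calls use a strict exceedance rule", {
  expect_true(call_locus_instability(3, 1.2, 0.4, 2.0))    # 3 > 2.0
  expect_false(call_locus_instability(2, 1.2, 0.4, 2.0))   # 2 <= 2.0
  expect_false(call_locus_instability(1.5, 1.5, 0, 2.0))   # equality: stable
  expect_true(call_locus_instability(2, 1.5, 0, 2.0))      # sd 0: any extra
})

test_that("the MSI score is the unstable fraction of evaluated loci", {
  # 5 loci, 2 samples; T1 unstable at 2 loci, T2 at none
  base_h <- do.call(rbind, lapply(c("N1", "N2", "N3"), function(s)
    do.call(rbind, lapply(paste0("L", 1:5), function(l)
      make_hist(s, l, c(15, 14), c(90, 10))))))
  b <- build_baseline(base_h)
  t_h <- rbind(
    do.call(rbind, lapply(paste0("L", 1:5), function(l)
      make_hist("T2", l, c(15, 14), c(90, 10)))),
    make_hist("T1", "L1", c(15, 14, 10), c(90, 10, 40)),
    make_hist("T1", "L2", c(15, 14, 11), c(90, 10, 30)),
    do.call(rbind, lapply(paste0("L", 3:5), function(l)
      make_hist("T1", l, c(15, 14), c(90, 10)))))
  sc <- msings_score(t_h, b, min_evaluated = 5)
  expect_equal(sc$score[sc$sample_id == "T1"], 2 / 5)
  expect_equal(sc$score[sc$sample_id == "T2"], 0)
  expect_equal(sc$n_evaluated, c(5L, 5L))
  # adding one stable locus to T1 lowers the score; an unstable one raises it
  extra_stable <- make_hist("T1", "L6", c(15, 14), c(90, 10))
  b6 <- build_baseline(rbind(base_h,
    do.call(rbind, lapply(c("N1", "N2", "N3"), function(s)
      make_hist(s, "L6", c(15, 14), c(90, 10))))))
  sc2 <- msings_score(rbind(t_h, extra_stable), b6, min_evaluated = 5)
  expect_lte(sc2$score[sc2$sample_id == "T1"], 2 / 5)
  extra_unstable <- make_hist("T1", "L6", c(15, 14, 9), c(90, 10, 50))
  sc3 <- msings_score(rbind(t_h, extra_unstable), b6, min_evaluated = 5)
  expect_gte(sc3$score[sc3$sample_id == "T1"], 2 / 5)
})

test_that("scoring errors when too few loci are evaluated", {
  h <- rbind(make_hist("N1", "L1", 15, 100),
             make_hist("N2", "L1", 15, 100))
  b <- build_baseline(h)
  expect_error(msings_score(make_hist("T1", "L9", 15, 100), b,
                            min_evaluated = 1),
               "T1")
})

test_that("scores match a literal brute-force scorer on small cohorts", {
  cfg <- sim_config(n_samples = 10, n_loci = 18, p_unstable_locus = 0.4,
                    frac_dmmr = 0.5, seed = 44)
  hs <- simulate_locus_histograms(cfg)
  normals <- names(hs$truth$dmmr)[!hs$truth$dmmr]
  b <- build_baseline(hs$histograms[hs$histograms$sample_id %in% normals, ])
  sc <- msings_score(hs$histograms, b, min_evaluated = 1)
  orc <- oracle_msings(hs$histograms, b)
  orc <- orc[match(sc$sample_id, orc$sample_id), ]
  expect_equal(sc$score, orc$score)
  expect_equal(sc$n_unstable, orc$n_unstable)
  expect_equal(sc$n_evaluated, orc$n_evaluated)
  expect_true(all(sc$score >= 0 & sc$score <= 1))
})

test_that("a baseline scored against itself makes almost no calls", {
  cfg <- sim_config(n_samples = 12, n_loci = 50, frac_dmmr = 0, seed = 45)
  hs <- simulate_locus_histograms(cfg)
  b <- build_baseline(hs$histograms)
  sc <- msings_score(hs$histograms, b)
  expect_lte(mean(sc$score), 0.05)
})

test_that("enriched locus selection keeps exactly the informative loci", {
  loci <- paste0("L", sprintf("%02d", 1:30))
  informative <- loci[c(3, 7, 11, 19, 23, 28)]
  normals <- c("N1", "N2", "N3")
  base_h <- do.call(rbind, lapply(normals, function(s)
    do.call(rbind, lapply(loci, function(l)
      make_hist(s, l, c(15, 14), c(90, 10))))))
  tumor_h <- do.call(rbind, lapply(loci, function(l)
    if (l %in% informative)
      make_hist("T1", l, c(15, 14, 10), c(90, 10, 40))
    else make_hist("T1", l, c(15, 14), c(90, 10))))
  b <- build_baseline(base_h)
  sel <- select_enriched_loci(rbind(base_h, tumor_h), tumor_ids = "T1",
                              normal_ids = normals, baseline = b)
  expect_equal(sel, sort(informative))
  # a locus unstable in a normal is dropped even if unstable in the tumor
  noisy <- make_hist("N1", "L03", c(15, 14, 9), c(90, 10, 30))
  h2 <- rbind(base_h[!(base_h$sample_id == "N1" &
                         base_h$locus_id == "L03"), ], noisy, tumor_h)
  sel2 <- select_enriched_loci(h2, "T1", normals,
                               build_baseline(h2[h2$sample_id %in% normals, ]))
  expect_false("L03" %in% sel2)
  expect_error(select_enriched_loci(base_h, character(0), normals, b),
               "no dMMR tumors")
})

test_that("exome scores harmonize by the fixed 0.209 factor", {
  expect_equal(harmonize_exome_score(1.0), 0.209)
  expect_equal(harmonize_exome_score(0), 0)
  expect_equal(harmonize_exome_score(0.5), 0.1045)
  expect_equal(harmonize_exome_score(0.5, factor = 1), 0.5)
  expect_error(harmonize_exome_score(-0.1), "nonnegative")
})

test_that("the PCR classifier follows the two-or-more rule", {
  expect_equal(promega_classify(c("BAT-25", "BAT-26"))$status, "MSI-high")
  expect_equal(promega_classify(c("BAT-25", "BAT-26"))$dichotomized,
               "positive")
  one <- promega_classify("NR-21")
  expect_equal(one$status, "MSI-low")
  expect_equal(one$dichotomized, "negative")
  none <- promega_classify(character(0))
  expect_equal(none$status, "MSS")
  expect_equal(none$dichotomized, "negative")
  # named-logical interface must cover all five markers
  expect_error(promega_classify(c(`BAT-25` = TRUE, `BAT-26` = FALSE)),
               "NR-21")
  expect_error(promega_classify("BAT-99"), "unknown marker")
})
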