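# Independent brute-force oracles used to cross-check the package
# implementations. These deliberately re-derive each quantity from its
# literal definition and share no code with R/.

oracle_auc <- function(score, truth) {
  truth <- as.logical(truth)
  pos <- score[truth]; neg <- score[!truth]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

oracle_youden <- function(score, truth) {
  truth <- as.logical(truth)
  cuts <- c(sort(unique(score)), max(score) + 1)
  best_J <- -Inf; best_cut <- NA
  for (ct in cuts) {
    pos <- score >= ct
    sens <- sum(pos & truth) / sum(truth)
    spec <- sum(!pos & !truth) / sum(!truth)
    J <- sens + spec - 1
    if (J > best_J + 1e-12) { best_J <- J; best_cut <- ct }
  }
  list(J = best_J, cutoff = best_cut)
}

oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  # step-up: enforce monotonicity from the largest p downward
  if (n > 1)
    for (i in (n - 1):1)
      q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  q <- numeric(n)
  q[o] <- pmin(q_sorted, 1)
  q
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  r <- sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), n - 2))
}

# two-group log-rank: O-E and hypergeometric variance summed over the
# distinct event times
oracle_logrank <- function(times, events, group1) {
  ts <- sort(unique(times[events == 1]))
  O1 <- 0; E1 <- 0; V1 <- 0
  for (t in ts) {
    at_risk <- times >= t
    n <- sum(at_risk); n1 <- sum(at_risk & group1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & group1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1)
      V1 <- V1 + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V1
}

oracle_kl_divergence <- function(V, W, H, pseudocount = 1e-9) {
  A <- t(V) + pseudocount
  WH <- W %*% t(H)
  sum(A * log(A / WH) - A + WH)
}

# literal record-by-record restatement of the filtering rules
oracle_disposition <- function(rec) {
  quality_removed <-
    rec$haplotype_score > 200 || rec$mapq < 40 || rec$depth < 60 ||
    rec$alt_reads / rec$depth < 0.05 || isTRUE(rec$multiallelic) ||
    rec$variant_type == "indel" || isTRUE(rec$poorly_sequenced_site)
  if (quality_removed) return("removed-quality")
  germline <- rec$cohort_af > 0.05 || rec$db_hits >= 2 ||
    rec$alt_reads / rec$depth > 0.999
  if (!germline) return("somatic")
  if (rec$variant_type == "SNV" && rec$cosmic_count >= 10)
    return("rescued-cosmic")
  "removed-germline"
}

# literal per-locus MSI scorer for small instances
oracle_msings <- function(histograms, baseline, sd_multiplier = 2,
                          peak_fraction = 0.05, min_reads = 30) {
  samples <- unique(histograms$sample_id)
  out <- list()
  for (s in samples) {
    hs <- histograms[histograms$sample_id == s, ]
    unstable <- 0; evaluated <- 0
    for (l in unique(hs$locus_id)) {
      h <- hs[hs$locus_id == l, ]
      if (sum(h$read_count) < min_reads) next
      b <- baseline[baseline$locus_id == l, ]
      if (nrow(b) == 0) next
      evaluated <- evaluated + 1
      n_all <- sum(h$read_count >= peak_fraction * max(h$read_count))
      if (n_all > b$mean_allele_count +
            sd_multiplier * b$sd_allele_count)
        unstable <- unstable + 1
    }
    out[[s]] <- data.frame(sample_id = s, n_unstable = unstable,
                           n_evaluated = evaluated,
                           score = unstable / evaluated)
  }
  do.call(rbind, out)
}

# histogram-table constructor for hand-built fixtures
make_hist <- function(sample_id, locus_id, lengths, counts) {
  data.frame(sample_id = sample_id, locus_id = locus_id,
             repeat_length = lengths, read_count = counts,
             stringsAsFactors = FALSE)
}

# random candidate-variant table spanning both sides of every threshold
random_records <- function(n, seed) {
  set.seed(seed)
  data.frame(
    sample_id = sample(sprintf("S%02d", 1:8), n, replace = TRUE),
    chrom = "chrSim", pos = sample.int(1e6, n), ref = "C", alt = "T",
    variant_type = sample(c("SNV", "indel"), n, replace = TRUE,
                          prob = c(0.85, 0.15)),
    depth = sample(30:300, n, replace = TRUE),
    mapq = stats::runif(n, 20, 60),
    haplotype_score = stats::runif(n, 0, 400),
    cohort_af = stats::runif(n, 0, 0.12),
    db_hits = sample(0:3, n, replace = TRUE),
    cosmic_count = sample(0:20, n, replace = TRUE),
    multiallelic = stats::runif(n) < 0.05,
    poorly_sequenced_site = stats::runif(n) < 0.05,
    gene = "", stringsAsFactors = FALSE
  ) -> rec
  rec$alt_reads <- pmax(0L, pmin(rec$depth,
                                 round(stats::runif(n, 0, 1.02) * rec$depth)))
  rec
}
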