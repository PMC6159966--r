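#' Count supported alleles in a repeat-length histogram
#'
#' An allele (repeat length) counts as supported when its read count is at
#' least `peak_fraction` of the most supported allele's count. Unstable
#' microsatellites show more supported alleles than the stutter background
#' of MMR-intact samples.
#'
#' @param counts Named or unnamed numeric vector of read counts per repeat
#'   length (a single sample x locus histogram).
#' @param peak_fraction Minimum support relative to the modal count
#'   (default 0.05).
#' @return Integer number of supported alleles.
#' @export
#' @examples
#' count_alleles(c(`14` = 6, `15` = 100, `16` = 3))  # 2
count_alleles <- function(counts, peak_fraction = 0.05) {
  counts <- counts[counts > 0]
  if (length(counts) == 0 || sum(counts) == 0)
    stop("empty histogram: no reads")
  sum(counts >= peak_fraction * max(counts))
}

.hist_split <- function(histograms) {
  split(histograms, list(histograms$sample_id, histograms$locus_id),
        drop = TRUE)
}

.allele_count_table <- function(histograms, peak_fraction, min_reads = 0) {
  # long table (sample_id, locus_id, n_alleles, total_reads)
  agg <- lapply(.hist_split(histograms), function(h) {
    data.frame(sample_id = h$sample_id[1], locus_id = h$locus_id[1],
               n_alleles = count_alleles(h$read_count, peak_fraction),
               total_reads = sum(h$read_count),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}

#' Build an MMR-intact baseline reference
#'
#' Per locus, the mean and standard deviation of the supported-allele
#' count across MMR-intact baseline samples. The population SD (divisor
#' n) is used by default: the baseline is treated as a reference
#' population, not a sample from one. Loci observed with adequate
#' coverage in fewer than `min_baseline` samples are dropped (with a
#' warning).
#'
#' @param histograms Histogram data frame (`sample_id`, `locus_id`,
#'   `repeat_length`, `read_count`) restricted to MMR-intact samples.
#' @param peak_fraction See [count_alleles()].
#' @param min_reads Minimum total reads for a histogram to contribute.
#' @param min_baseline Minimum baseline samples per locus (default 2).
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return Data frame: `locus_id`, `mean_allele_count`, `sd_allele_count`,
#'   `n_baseline_samples`.
#' @export
build_baseline <- function(histograms, peak_fraction = 0.05,
                           min_reads = 30, min_baseline = 2L,
                           sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (nrow(histograms) == 0) stop("no baseline samples provided")
  tab <- .allele_count_table(histograms, peak_fraction)
  tab <- tab[tab$total_reads >= min_reads, , drop = FALSE]
  if (nrow(tab) == 0) stop("no baseline histograms pass the read threshold")
  out <- do.call(rbind, lapply(split(tab, tab$locus_id), function(d) {
    x <- d$n_alleles
    n <- length(x)
    v <- if (n > 1) sum((x - mean(x))^2) / (if (sd_type == "population") n
                                            else n - 1) else 0
    data.frame(locus_id = d$locus_id[1], mean_allele_count = mean(x),
               sd_allele_count = sqrt(v), n_baseline_samples = n,
               stringsAsFactors = FALSE)
  }))
  dropped <- out$n_baseline_samples < min_baseline
  if (any(dropped))
    warning(sum(dropped), " locus/loci dropped from the baseline ",
            "(fewer than ", min_baseline, " covered baseline samples): ",
            paste(utils::head(out$locus_id[dropped], 5), collapse = ", "))
  out <- out[!dropped, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call per-locus instability against the baseline
#'
#' A locus is unstable when its supported-allele count strictly exceeds
#' `mean + sd_multiplier * sd` from the MMR-intact baseline. With a zero
#' baseline SD any extra allele therefore triggers a call — the intended
#' behaviour for tightly behaved mononucleotide runs.
#'
#' @param n_alleles Observed supported-allele count.
#' @param baseline_mean,baseline_sd Baseline statistics for the locus.
#' @param sd_multiplier Number of SDs above the mean (default 2).
#' @return Logical.
#' @export
call_locus_instability <- function(n_alleles, baseline_mean, baseline_sd,
                                   sd_multiplier = 2.0) {
  n_alleles > baseline_mean + sd_multiplier * baseline_sd
}

#' MSINGS-style MSI score for each sample
#'
#' Per sample, the fraction of evaluated loci called unstable against the
#' baseline. A locus is evaluated for a sample when its histogram has at
#' least `min_reads` reads and the locus is present in the baseline; loci
#' missing from the baseline are "not evaluated" and excluded from the
#' denominator.
#'
#' @param histograms Histogram data frame for the samples to score.
#' @param baseline Data frame from [build_baseline()].
#' @param sd_multiplier,peak_fraction,min_reads Calling parameters.
#' @param min_evaluated Minimum evaluated loci per sample (error below).
#' @return Data frame of class `msings_result`: `sample_id`, `n_unstable`,
#'   `n_evaluated`, `score`.
#' @export
msings_score <- function(histograms, baseline, sd_multiplier = 2.0,
                         peak_fraction = 0.05, min_reads = 30,
                         min_evaluated = 20L) {
  samples_in <- unique(histograms$sample_id)
  tab <- .allele_count_table(histograms, peak_fraction)
  tab <- tab[tab$total_reads >= min_reads, , drop = FALSE]
  tab <- merge(tab, baseline, by = "locus_id")
  none <- setdiff(samples_in, unique(tab$sample_id))
  if (length(none))
    stop("0 evaluated loci for sample(s): ", paste(none, collapse = ", "))
  out <- do.call(rbind, lapply(split(tab, tab$sample_id), function(d) {
    unstable <- call_locus_instability(d$n_alleles, d$mean_allele_count,
                                       d$sd_allele_count, sd_multiplier)
    data.frame(sample_id = d$sample_id[1],
               n_unstable = sum(unstable), n_evaluated = nrow(d),
               score = sum(unstable) / nrow(d), stringsAsFactors = FALSE)
  }))
  low <- out$n_evaluated < min_evaluated
  if (any(low))
    stop("fewer than ", min_evaluated, " evaluated loci for sample(s): ",
         paste(out$sample_id[low], collapse = ", "))
  rownames(out) <- NULL
  class(out) <- c("msings_result", "data.frame")
  out
}

#' Select an enriched informative locus subset
#'
#' Mirrors the construction of an enriched reference set from tumor and
#' normal samples: a locus is retained when it is (a) callable (adequate
#' reads) in at least `min_fraction` of normals, (b) unstable in at least
#' one known-dMMR tumor, and (c) stable in every normal. Ordering is
#' deterministic by `locus_id`.
#'
#' @param histograms Combined histogram table for tumors and normals.
#' @param tumor_ids,normal_ids Character vectors of sample ids; tumors in
#'   `tumor_ids` are the known-dMMR set.
#' @param baseline Baseline built from the normals (for the calls).
#' @param min_fraction Minimum fraction of normals with coverage.
#' @param sd_multiplier,peak_fraction,min_reads Calling parameters.
#' @return Character vector of retained locus ids, sorted.
#' @export
select_enriched_loci <- function(histograms, tumor_ids, normal_ids,
                                 baseline, min_fraction = 0.9,
                                 sd_multiplier = 2.0, peak_fraction = 0.05,
                                 min_reads = 30) {
  if (length(tumor_ids) == 0) stop("no dMMR tumors provided")
  tab <- .allele_count_table(histograms, peak_fraction)
  tab <- tab[tab$total_reads >= min_reads, , drop = FALSE]
  tab <- merge(tab, baseline, by = "locus_id")
  tab$unstable <- call_locus_instability(tab$n_alleles,
                                         tab$mean_allele_count,
                                         tab$sd_allele_count, sd_multiplier)
  keep <- vapply(split(tab, tab$locus_id), function(d) {
    nrm <- d[d$sample_id %in% normal_ids, , drop = FALSE]
    tum <- d[d$sample_id %in% tumor_ids, , drop = FALSE]
    nrow(nrm) >= min_fraction * length(normal_ids) &&
      !any(nrm$unstable) && any(tum$unstable)
  }, logical(1))
  sort(names(keep)[keep])
}

#' Harmonize an exome-derived MSI score with targeted-panel scores
#'
#' Exome-wide MSI scores live on a different scale from targeted-panel
#' scores; they are multiplied by a fixed factor (default 0.209) for
#' comparison. The factor is a configuration constant, not re-derived.
#'
#' @param raw_score MSI score in [0,1] from exome data.
#' @param factor Scaling factor (default 0.209).
#' @return Harmonized score.
#' @export
harmonize_exome_score <- function(raw_score, factor = 0.209) {
  if (any(raw_score < 0)) stop("score must be nonnegative")
  if (any(raw_score > 1)) stop("score must be <= 1")
  raw_score * factor
}

.PROMEGA_MARKERS <- c("BAT-25", "BAT-26", "NR-21", "NR-24", "MONO-27")

#' Classify PCR MSI status from the five mononucleotide markers
#'
#' Emulates the Promega-style PCR assay rule: instability at 2 or more of
#' the five mononucleotide markers is MSI-high, exactly one is MSI-low,
#' none is MSS. For dichotomized analyses MSI-low is grouped with MSS
#' ("negative"); only MSI-high is "positive".
#'
#' @param unstable Named logical vector over exactly the markers BAT-25,
#'   BAT-26, NR-21, NR-24, MONO-27 (order free), or a character vector of
#'   unstable marker names.
#' @return List with `status` ("MSI-high", "MSI-low", "MSS"),
#'   `dichotomized` ("positive"/"negative"), `n_unstable`.
#' @export
#' @examples
#' promega_classify(c("BAT-25", "BAT-26"))$status  # "MSI-high"
promega_classify <- function(unstable) {
  if (is.character(unstable)) {
    bad <- setdiff(unstable, .PROMEGA_MARKERS)
    if (length(bad)) stop("unknown marker(s): ", paste(bad, collapse = ", "))
    unstable <- stats::setNames(.PROMEGA_MARKERS %in% unstable,
                                .PROMEGA_MARKERS)
  }
  missing <- setdiff(.PROMEGA_MARKERS, names(unstable))
  if (length(missing))
    stop("markers not evaluated: ", paste(missing, collapse = ", "))
  n <- sum(unstable[.PROMEGA_MARKERS])
  status <- if (n >= 2) "MSI-high" else if (n == 1) "MSI-low" else "MSS"
  list(status = status,
       dichotomized = if (status == "MSI-high") "positive" else "negative",
       n_unstable = n)
}
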