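#' Remove low-quality variant calls
#'
#' A record is removed when ANY of the following holds: haplotype score
#' > 200, mapping quality < 40, coverage depth < 60, alternate allele
#' supported by < 5% of reads, a multiallelic call, an indel, or a known
#' poorly sequenced site (blacklist flag). Boundaries are exactly as
#' stated: depth 59 is removed, depth 60 is kept; alternate fraction 0.05
#' is kept. Missing quality fields fail closed (the record is removed with
#' reason "missing-field").
#'
#' @param records Data frame with columns `haplotype_score`, `mapq`,
#'   `depth`, `alt_reads`, `multiallelic`, `variant_type`,
#'   `poorly_sequenced_site`.
#' @param keep_indels If `TRUE`, indels are not removed by the indel rule
#'   (used by the indel-specific load path; default `FALSE`).
#' @return List with `kept` and `removed` data frames; `removed` carries a
#'   `reason` column (first matching reason).
#' @export
quality_filter <- function(records, keep_indels = FALSE) {
  need <- c("haplotype_score", "mapq", "depth", "alt_reads")
  missing_field <- rowSums(is.na(records[, need, drop = FALSE])) > 0
  alt_frac <- records$alt_reads / records$depth
  reasons <- cbind(
    `missing-field` = missing_field,
    `haplotype-score` = !missing_field & records$haplotype_score > 200,
    `mapping-quality` = !missing_field & records$mapq < 40,
    `low-depth` = !missing_field & records$depth < 60,
    `low-alt-fraction` = !missing_field & alt_frac < 0.05,
    `multiallelic` = isTRUE_vec(records$multiallelic),
    `indel` = if (keep_indels) rep(FALSE, nrow(records)) else
      records$variant_type == "indel",
    `blacklist` = isTRUE_vec(records$poorly_sequenced_site)
  )
  removed <- rowSums(reasons) > 0
  rem <- records[removed, , drop = FALSE]
  if (nrow(rem)) {
    first <- apply(reasons[removed, , drop = FALSE], 1,
                   function(r) colnames(reasons)[which(r)[1]])
    rem$reason <- unname(first)
  } else rem$reason <- character(0)
  list(kept = records[!removed, , drop = FALSE], removed = rem)
}

isTRUE_vec <- function(x) {
  if (is.null(x)) return(FALSE)
  !is.na(x) & x
}

#' Split candidate variants into somatic and putative germline
#'
#' A variant is called germline when its cohort allele frequency strictly
#' exceeds 5%, or it is present in 2 or more population databases (of
#' ExAC, 1000 Genomes, dbSNP), or more than 99.9% of its reads carry the
#' alternate allele. Missing population annotations fail open (no germline
#' call on absent evidence) — conservative for mutation load.
#'
#' @param records Data frame with `cohort_af`, `db_hits`, `alt_reads`,
#'   `depth`.
#' @return List with `somatic` and `germline` data frames; `germline`
#'   carries a `reason` column.
#' @export
germline_filter <- function(records) {
  af <- records$cohort_af; af[is.na(af)] <- 0
  db <- records$db_hits; db[is.na(db)] <- 0L
  frac <- records$alt_reads / records$depth
  frac[is.na(frac)] <- 0
  reasons <- cbind(`cohort-af` = af > 0.05,
                   `population-db` = db >= 2,
                   `alt-fraction` = frac > 0.999)
  germ <- rowSums(reasons) > 0
  g <- records[germ, , drop = FALSE]
  if (nrow(g)) {
    g$reason <- apply(reasons[germ, , drop = FALSE], 1,
                      function(r) colnames(reasons)[which(r)[1]])
  } else g$reason <- character(0)
  list(somatic = records[!germ, , drop = FALSE], germline = g)
}

#' Rescue recurrent COSMIC point mutations from the germline filter
#'
#' Point mutations (SNVs only) removed as putative germline but described
#' as somatic in COSMIC at least 10 times are added back into the
#' mutation count.
#'
#' @param germline Data frame of germline-filtered records (with
#'   `cosmic_count`, `variant_type`).
#' @return Data frame of rescued records.
#' @export
cosmic_rescue <- function(germline) {
  cc <- germline$cosmic_count; cc[is.na(cc)] <- 0L
  germline[germline$variant_type == "SNV" & cc >= 10, , drop = FALSE]
}

#' Full somatic filter with a staged report
#'
#' Applies [quality_filter()], then [germline_filter()], then
#' [cosmic_rescue()], and returns the surviving records together with a
#' balanced per-stage report and per-record dispositions. Rescued records
#' count toward mutation load exactly like never-filtered records.
#'
#' @param records Candidate variant data frame.
#' @param keep_indels Passed to [quality_filter()].
#' @return List with `final` (surviving records), `report` (data frame of
#'   stage counts), and `dispositions` (per input record:
#'   somatic / removed-quality / removed-germline / rescued-cosmic).
#' @export
filter_variants <- function(records, keep_indels = FALSE) {
  records$.row <- seq_len(nrow(records))
  q <- quality_filter(records, keep_indels = keep_indels)
  g <- germline_filter(q$kept)
  r <- cosmic_rescue(g$germline)
  final <- rbind(g$somatic, r[, names(g$somatic), drop = FALSE])
  final <- final[order(final$.row), , drop = FALSE]
  disp <- rep("somatic", nrow(records))
  disp[q$removed$.row] <- "removed-quality"
  disp[g$germline$.row] <- "removed-germline"
  disp[r$.row] <- "rescued-cosmic"
  report <- data.frame(
    stage = c("input", "removed_quality", "removed_germline",
              "rescued_cosmic", "final"),
    n = c(nrow(records), nrow(q$removed), nrow(g$germline), nrow(r),
          nrow(final)))
  stopifnot(report$n[1] == report$n[5] + report$n[2] + report$n[3] -
              report$n[4])
  final$.row <- NULL
  list(final = final, report = report, dispositions = disp)
}

#' Mutation load, total and per megabase
#'
#' @param final_records Surviving records (after [filter_variants()]).
#' @param panel_size_mb Targeted territory in megabases (default 0.6).
#' @return Data frame: `sample_id`, `n_mutations`, `per_mb`.
#' @export
mutation_load <- function(final_records, panel_size_mb = 0.6) {
  if (panel_size_mb <= 0) stop("panel_size_mb must be positive")
  tab <- table(final_records$sample_id)
  data.frame(sample_id = names(tab), n_mutations = as.integer(tab),
             per_mb = as.integer(tab) / panel_size_mb,
             stringsAsFactors = FALSE)
}

#' Dichotomize mutation load at a count threshold
#'
#' High load is a count at or above the threshold (default 5.5, i.e. 6 or
#' more mutations on the 0.6-Mb panel).
#'
#' @param count Mutation counts.
#' @param threshold Cutoff (default 5.5); `count >= threshold` is high.
#' @return Logical vector (`TRUE` = high load).
#' @export
dichotomize_load <- function(count, threshold = 5.5) count >= threshold

.MMR_GENES <- c("MSH2", "MSH6", "MLH1", "PMS2")

#' Classify MMR-gene event status for a sample
#'
#' Biallelic loss of function is a homozygous deletion, one or more
#' nonsynonymous mutations plus loss of heterozygosity, or two or more
#' nonsynonymous mutations. Precedence: biallelic-LOF > germline >
#' single-allele-nonsynonymous > none. Copy-number inputs are consumed as
#' flags; calling them is upstream.
#'
#' @param gene One of MSH2, MSH6, MLH1, PMS2.
#' @param n_nonsynonymous Count of nonsynonymous mutations in the gene.
#' @param loh Loss-of-heterozygosity flag.
#' @param homozygous_deletion Homozygous deletion flag.
#' @param germline Pathogenic germline mutation flag.
#' @return One of "biallelic-LOF", "germline",
#'   "single-allele-nonsynonymous", "none".
#' @export
classify_mmr_status <- function(gene, n_nonsynonymous = 0L, loh = FALSE,
                                homozygous_deletion = FALSE,
                                germline = FALSE) {
  if (!gene %in% .MMR_GENES)
    stop("unknown MMR gene '", gene, "'; expected one of ",
         paste(.MMR_GENES, collapse = ", "))
  if (homozygous_deletion || (n_nonsynonymous >= 1 && loh) ||
      n_nonsynonymous >= 2) return("biallelic-LOF")
  if (germline) return("germline")
  if (n_nonsynonymous == 1) return("single-allele-nonsynonymous")
  "none"
}
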