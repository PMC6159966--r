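#' Derive a stage seed from the master seed
#'
#' Stable fan-out of one master seed to per-stage seeds by hashing the
#' stage name, keeping the result a valid 32-bit integer.
#'
#' @param master Integer master seed.
#' @param stage Stage name.
#' @return Integer seed.
#' @export
stage_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 7919 + h * 104729) %% 2147483647L)
}

#' Run the full synthetic dMMR analysis pipeline
#'
#' Generates a synthetic cohort, then runs every analysis stage in
#' dependency order: MSI scoring against an MMR-intact baseline, somatic
#' variant filtering and mutation load, signature extraction with
#' reference matching, immune transcript association against dMMR
#' signature activity, and biomarker/survival metrics. All inputs and
#' outputs are written as plain TSV/FASTA/BED files under `out_dir`,
#' together with the resolved configuration; a fixed seed reproduces the
#' directory byte for byte.
#'
#' @param out_dir Output directory (created if needed).
#' @param cfg A [sim_config()]; its `seed` drives the generator and fans
#'   out to per-stage seeds.
#' @param rank NMF rank (default 4).
#' @param n_runs NMF restarts (default 20).
#' @param stages Character vector of stages to run, a subset of
#'   `c("msings", "mutsig", "immune", "metrics")` (simulation always
#'   runs); disabling `mutsig` makes `immune` error, since it needs an
#'   activity estimate.
#' @return Invisibly, a list of the main in-memory results.
#' @export
run_pipeline <- function(out_dir, cfg = sim_config(),
                         rank = 4L, n_runs = 20L,
                         stages = c("msings", "mutsig", "immune",
                                    "metrics")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)

  co <- simulate_cohort(cfg)
  write_fasta(co$reference, p("reference.fa"))
  write_bed(co$loci, p("loci.bed"))
  write_histograms(co$histograms, p("histograms.tsv"))
  write_maf(co$mutations, p("mutations.tsv"))
  write_tsv_matrix(co$expression, p("expression.tsv"), id_col = "gene")
  utils::write.table(co$clinical, p("cohort.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth_tab <- data.frame(sample_id = names(co$truth$dmmr),
                          dmmr = unname(co$truth$dmmr),
                          dmmr_activity =
                            unname(co$truth$dmmr_activity[
                              names(co$truth$dmmr)]))
  utils::write.table(truth_tab, p("ground_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg_lines <- vapply(names(unclass(cfg)), function(k)
    paste0(k, " = ", paste(format(cfg[[k]]), collapse = ", ")),
    character(1))
  writeLines(c(cfg_lines, paste0("rank = ", rank),
               paste0("n_runs = ", n_runs)), p("config.txt"))

  results <- list(cohort = co)

  if ("msings" %in% stages) {
    normals <- names(co$truth$dmmr)[!co$truth$dmmr]
    base <- build_baseline(
      co$histograms[co$histograms$sample_id %in% normals, ])
    scores <- msings_score(co$histograms, base)
    utils::write.table(scores, p("msings_scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    results$msings <- scores
  }

  filt <- filter_variants(co$mutations)
  utils::write.table(filt$report, p("filter_report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  load <- mutation_load(filt$final)
  utils::write.table(load, p("mutation_load.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  results$filter <- filt
  results$load <- load

  if ("mutsig" %in% stages) {
    V <- build_context_matrix(filt$final, co$reference,
                              samples = names(co$truth$dmmr))
    write_tsv_matrix(V, p("context_matrix.tsv"), id_col = "sample_id")
    model <- fit_signatures(V, rank = rank, n_runs = n_runs,
                            seed = stage_seed(cfg$seed, "mutsig"))
    model <- match_signatures(model, reference_signatures())
    write_tsv_matrix(model$W, p("signatures.tsv"), id_col = "channel")
    write_tsv_matrix(model$H, p("exposures.tsv"), id_col = "sample_id")
    dmmr_idx <- which(model$assignments$reference %in% c("MMR6", "MMR26"))
    activity <- rowSums(model$proportions[, dmmr_idx, drop = FALSE])
    act_tab <- data.frame(sample_id = rownames(model$H),
                          dmmr_activity = unname(activity),
                          mmr_dominant = unname(
                            mmr_dominant(model$proportions, dmmr_idx)))
    utils::write.table(act_tab, p("dmmr_activity.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    results$signatures <- model
    results$activity <- stats::setNames(act_tab$dmmr_activity,
                                        act_tab$sample_id)
  }

  if ("immune" %in% stages) {
    if (is.null(results$activity))
      stop("stage 'immune' requires a dMMR activity estimate: enable ",
           "the 'mutsig' stage or supply an activity column")
    act <- pmin(pmax(results$activity, 0), 1)
    sites <- stats::setNames(co$clinical$biopsy_site,
                             co$clinical$sample_id)
    assoc <- associate_genes(co$expression, act, sites,
                             genes = checkpoint_panel(),
                             min_n = 5L)
    utils::write.table(format(assoc, digits = 10),
                       p("immune_association.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    results$association <- assoc
  }

  if ("metrics" %in% stages && "msings" %in% stages) {
    truth <- co$truth$dmmr[results$msings$sample_id]
    roc <- youden_cutoff(results$msings$score, truth)
    roc_tab <- data.frame(auc = roc$auc, cutoff = roc$optimal_cutoff,
                          sensitivity = roc$sensitivity,
                          specificity = roc$specificity, J = roc$J)
    utils::write.table(roc_tab, p("roc_msings.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    km <- km_median_and_logrank(co$clinical$os_years,
                                co$clinical$os_event,
                                ifelse(co$clinical$dmmr, "dMMR", "pMMR"))
    km_tab <- data.frame(group = names(km$medians),
                         median_os = unname(km$medians),
                         chisq = km$chisq, p = km$p)
    utils::write.table(km_tab, p("survival.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    results$roc <- roc
    results$km <- km
  }

  invisible(results)
}
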