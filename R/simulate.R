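#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates every tunable of the simulator. Defaults describe
#' a small metastatic prostate cancer cohort with a dMMR subgroup:
#' mononucleotide microsatellite loci read out as allele-length histograms
#' with PCR-stutter noise, exome-like mutation catalogs drawn from four
#' reference signatures, tumor-only variant tables with germline and
#' artifact spike-ins, TPM expression in which an immune-infiltrate factor
#' tracks dMMR signature activity, and survival with a configurable hazard
#' ratio.
#'
#' @param n_samples Number of tumor samples.
#' @param n_loci Number of microsatellite loci.
#' @param frac_dmmr Fraction of samples that are mismatch-repair deficient.
#' @param p_unstable_locus Per-locus probability that a dMMR sample shows a
#'   novel (unstable) allele at that locus.
#' @param stutter_decay Geometric decay of PCR stutter allele support per
#'   repeat unit away from the modal allele, in (0,1); 0 disables stutter.
#'   The default 0.1 keeps stutter two or more units from the mode below
#'   the default 5% allele-counting threshold, so novel dMMR alleles
#'   (placed at >= 2 units) remain distinguishable from stutter by
#'   construction.
#' @param read_depth Mean reads per locus (Poisson).
#' @param n_signatures Number of mutational signatures (must match the
#'   signature matrix supplied to [simulate_mutation_catalogs()]).
#' @param mutations_per_sample Mean somatic mutation count per sample.
#' @param count_model `"nbinom"` (default, overdispersed) or `"poisson"`.
#' @param nb_dispersion Negative-binomial size parameter.
#' @param exposure_concentration Dirichlet concentration for pMMR samples
#'   (length `n_signatures`).
#' @param dmmr_concentration Dirichlet concentration for dMMR samples
#'   (elevated on the MMR-type signatures).
#' @param germline_rate,artifact_rate Spike-in rates for
#'   [simulate_variant_annotations()].
#' @param cosmic_rescuable_frac Fraction of germline spike-ins carrying a
#'   COSMIC somatic occurrence count >= 10.
#' @param n_genes Total genes in the expression matrix (includes the
#'   32-gene checkpoint panel).
#' @param infiltrate_effect Target correlation between dMMR signature
#'   activity and the latent infiltrate factor (default 0.24).
#' @param panel_loading Mean loading of panel genes on the infiltrate
#'   factor (log scale).
#' @param genome_length Length of the single synthetic chromosome (bp).
#' @param hazard_ratio dMMR vs pMMR hazard ratio for overall survival.
#' @param median_os_pmmr Median overall survival of the pMMR group, years.
#' @param followup_max Administrative censoring horizon, years.
#' @param seed Integer master seed; fixed seed gives byte-identical output.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_samples = 40L, n_loci = 200L, frac_dmmr = 0.25,
                       p_unstable_locus = 0.2, stutter_decay = 0.1,
                       read_depth = 100, n_signatures = 4L,
                       mutations_per_sample = 500,
                       count_model = c("nbinom", "poisson"),
                       nb_dispersion = 10,
                       exposure_concentration = c(4, 2, 0.5, 0.5),
                       dmmr_concentration = c(1, 1, 4, 4),
                       germline_rate = 0.10, artifact_rate = 0.10,
                       cosmic_rescuable_frac = 0.3,
                       n_genes = 500L, infiltrate_effect = 0.24,
                       panel_loading = 0.4, genome_length = 1e6,
                       hazard_ratio = 4, median_os_pmmr = 7,
                       followup_max = 20, seed = 1L) {
  count_model <- match.arg(count_model)
  cfg <- list(n_samples = as.integer(n_samples),
              n_loci = as.integer(n_loci), frac_dmmr = frac_dmmr,
              p_unstable_locus = p_unstable_locus,
              stutter_decay = stutter_decay, read_depth = read_depth,
              n_signatures = as.integer(n_signatures),
              mutations_per_sample = mutations_per_sample,
              count_model = count_model, nb_dispersion = nb_dispersion,
              exposure_concentration = exposure_concentration,
              dmmr_concentration = dmmr_concentration,
              germline_rate = germline_rate, artifact_rate = artifact_rate,
              cosmic_rescuable_frac = cosmic_rescuable_frac,
              n_genes = as.integer(n_genes),
              infiltrate_effect = infiltrate_effect,
              panel_loading = panel_loading,
              genome_length = as.integer(genome_length),
              hazard_ratio = hazard_ratio,
              median_os_pmmr = median_os_pmmr, followup_max = followup_max,
              seed = as.integer(seed))
  props <- c(frac_dmmr = frac_dmmr, p_unstable_locus = p_unstable_locus,
             stutter_decay = stutter_decay,
             germline_rate = germline_rate, artifact_rate = artifact_rate,
             cosmic_rescuable_frac = cosmic_rescuable_frac)
  bad <- props < 0 | props > 1
  if (any(bad)) stop("proportions out of [0,1]: ",
                     paste(names(props)[bad], collapse = ", "))
  counts <- c(n_samples = cfg$n_samples, n_loci = cfg$n_loci,
              n_signatures = cfg$n_signatures, n_genes = cfg$n_genes,
              genome_length = cfg$genome_length)
  if (any(counts <= 0)) stop("counts must be positive: ",
                             paste(names(counts)[counts <= 0], collapse = ", "))
  if (read_depth <= 0) stop("read_depth must be positive")
  class(cfg) <- "sim_config"
  cfg
}

.sample_ids <- function(n) sprintf("S%03d", seq_len(n))

.dmmr_labels <- function(cfg) {
  n_dmmr <- round(cfg$n_samples * cfg$frac_dmmr)
  stats::setNames(seq_len(cfg$n_samples) <= n_dmmr,
                  .sample_ids(cfg$n_samples))
}

.rdirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Simulate microsatellite allele-length histograms
#'
#' For each sample x locus, reads pile up at the reference repeat length
#' (the modal allele) with PCR stutter: support at a length offset of k
#' repeat units decays geometrically as `stutter_decay^|k|`, truncated at
#' +/- 5 units. In dMMR samples each locus independently, with probability
#' `p_unstable_locus`, gains a novel allele at least 2 repeat units from
#' the mode, supported by at least 10% of the modal read count — far
#' enough from the mode to be distinguishable from stutter by
#' construction.
#'
#' @param cfg A [sim_config()].
#' @return List with `histograms` (data frame: `sample_id`, `locus_id`,
#'   `repeat_length`, `read_count`), `loci` (locus table, BED-style
#'   0-based half-open coordinates), and `truth` (list: `dmmr` named
#'   logical per sample; `unstable` data frame of sample/locus instability
#'   flags).
#' @export
simulate_locus_histograms <- function(cfg) {
  if (cfg$read_depth <= 0) stop("read_depth must be positive")
  set.seed(cfg$seed)
  ids <- .sample_ids(cfg$n_samples)
  dmmr <- .dmmr_labels(cfg)
  ref_len <- sample(10:25, cfg$n_loci, replace = TRUE)
  loci <- data.frame(locus_id = sprintf("MS%04d", seq_len(cfg$n_loci)),
                     chrom = "chrSim",
                     start = seq_len(cfg$n_loci) * 3000L,
                     end = seq_len(cfg$n_loci) * 3000L + ref_len,
                     repeat_unit = "A",
                     reference_repeat_count = ref_len,
                     stringsAsFactors = FALSE)
  offsets <- -5:5
  w <- if (cfg$stutter_decay == 0) as.numeric(offsets == 0) else
    cfg$stutter_decay^abs(offsets)
  w <- w / sum(w)

  rows <- vector("list", cfg$n_samples * cfg$n_loci)
  unstable <- matrix(FALSE, cfg$n_samples, cfg$n_loci,
                     dimnames = list(ids, loci$locus_id))
  k <- 0L
  for (s in seq_along(ids)) {
    for (l in seq_len(cfg$n_loci)) {
      depth <- stats::rpois(1, cfg$read_depth)
      if (depth == 0) depth <- 1L
      counts <- as.vector(stats::rmultinom(1, depth, w))
      lens <- ref_len[l] + offsets
      novel_len <- NA_integer_; novel_reads <- 0L
      if (dmmr[s] && stats::runif(1) < cfg$p_unstable_locus) {
        unstable[s, l] <- TRUE
        novel_off <- sample(c(-5:-2, 2:5), 1)
        novel_len <- ref_len[l] + novel_off
        modal <- counts[offsets == 0]
        novel_reads <- max(1L, ceiling(stats::runif(1, 0.15, 0.40) * modal))
      }
      keep <- counts > 0
      df_len <- lens[keep]; df_cnt <- counts[keep]
      if (!is.na(novel_len)) {
        hit <- df_len == novel_len
        if (any(hit)) df_cnt[hit] <- df_cnt[hit] + novel_reads
        else { df_len <- c(df_len, novel_len); df_cnt <- c(df_cnt, novel_reads) }
      }
      ord <- order(df_len)
      k <- k + 1L
      rows[[k]] <- data.frame(sample_id = ids[s],
                              locus_id = loci$locus_id[l],
                              repeat_length = df_len[ord],
                              read_count = df_cnt[ord],
                              stringsAsFactors = FALSE)
    }
  }
  hist <- do.call(rbind, rows[seq_len(k)])
  rownames(hist) <- NULL
  un <- which(unstable, arr.ind = TRUE)
  truth_un <- data.frame(sample_id = ids[un[, 1]],
                         locus_id = loci$locus_id[un[, 2]],
                         stringsAsFactors = FALSE)
  list(histograms = hist, loci = loci,
       truth = list(dmmr = dmmr, unstable = truth_un))
}

#' Simulate a reference chromosome
#'
#' One contiguous synthetic chromosome of i.i.d. bases, used as the
#' context source for simulated mutation catalogs.
#'
#' @param cfg A [sim_config()].
#' @return Named character vector of length 1 (`chrSim`).
#' @export
simulate_reference_genome <- function(cfg) {
  set.seed(cfg$seed + 101L)
  bases <- sample(c("A", "C", "G", "T"), cfg$genome_length, replace = TRUE)
  stats::setNames(paste(bases, collapse = ""), "chrSim")
}

.trinuc_index <- function(seq) {
  v <- strsplit(seq, "")[[1]]
  n <- length(v)
  tri <- paste0(v[1:(n - 2)], v[2:(n - 1)], v[3:n])
  split(2:(n - 1), tri)
}

.channel_trinuc <- function(channel) {
  # forward pyrimidine trinucleotide realizing the channel
  paste0(substr(channel, 1, 1), substr(channel, 3, 3), substr(channel, 7, 7))
}

#' Simulate somatic mutation catalogs from a signature mixture
#'
#' Per sample: exposure proportions are drawn from a Dirichlet (dMMR
#' samples use `dmmr_concentration`, elevating the MMR-type signatures), a
#' mutation count is drawn (negative binomial by default), each mutation
#' is assigned one of the 96 context channels from the mixture
#' `signatures %*% exposures`, and a concrete SNV is placed at a genome
#' position whose flanking bases realise that context (forward pyrimidine
#' or reverse-complement strand with equal probability).
#'
#' @param cfg A [sim_config()].
#' @param signatures 96 x K matrix, columns summing to 1 (within 1e-9);
#'   default [reference_signatures()]. Columns named; the MMR-type columns
#'   are identified by name prefix "MMR" for the dMMR exposure bias.
#' @param reference Optional named chromosome vector; generated from `cfg`
#'   when missing.
#' @return List with `mutations` (data frame: `sample_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `variant_type`, `channel`), `reference`, and `truth`
#'   (list: `dmmr`, `exposures` samples x K proportions, `signatures`,
#'   `mutation_counts`).
#' @export
simulate_mutation_catalogs <- function(cfg,
                                       signatures = reference_signatures(),
                                       reference = NULL) {
  if (any(abs(colSums(signatures) - 1) > 1e-9))
    stop("signature columns must sum to 1")
  K <- ncol(signatures)
  if (K != length(cfg$exposure_concentration) ||
      K != length(cfg$dmmr_concentration))
    stop("number of signatures (", K,
         ") does not match length of concentration parameters")
  if (is.null(reference)) reference <- simulate_reference_genome(cfg)
  set.seed(cfg$seed + 202L)
  ids <- .sample_ids(cfg$n_samples)
  dmmr <- .dmmr_labels(cfg)
  channels <- context_channels()
  idx <- .trinuc_index(reference[[1]])
  chrom <- names(reference)[1]

  fwd_tri <- vapply(channels, .channel_trinuc, character(1))
  rev_tri <- vapply(fwd_tri, .revcomp, character(1))
  alt_base <- substr(channels, 5, 5)

  exposures <- matrix(0, cfg$n_samples, K,
                      dimnames = list(ids, colnames(signatures)))
  counts <- integer(cfg$n_samples)
  out <- vector("list", cfg$n_samples)
  for (s in seq_along(ids)) {
    alpha <- if (dmmr[s]) cfg$dmmr_concentration else
      cfg$exposure_concentration
    e <- .rdirichlet(alpha)
    exposures[s, ] <- e
    n_mut <- if (cfg$count_model == "nbinom")
      stats::rnbinom(1, mu = cfg$mutations_per_sample,
                     size = cfg$nb_dispersion)
    else stats::rpois(1, cfg$mutations_per_sample)
    counts[s] <- n_mut
    if (n_mut == 0) { out[[s]] <- NULL; next }
    p <- as.vector(signatures %*% e)
    ch_idx <- sample.int(96L, n_mut, replace = TRUE, prob = p)
    strand_fwd <- stats::runif(n_mut) < 0.5
    pos <- integer(n_mut); ref_b <- character(n_mut); alt_b <- character(n_mut)
    for (i in seq_len(n_mut)) {
      tri <- if (strand_fwd[i]) fwd_tri[ch_idx[i]] else rev_tri[ch_idx[i]]
      cand <- idx[[tri]]
      if (is.null(cand)) {  # fall back to the other strand
        strand_fwd[i] <- !strand_fwd[i]
        tri <- if (strand_fwd[i]) fwd_tri[ch_idx[i]] else rev_tri[ch_idx[i]]
        cand <- idx[[tri]]
        if (is.null(cand))
          stop("context ", tri, " absent from the reference; use a longer genome")
      }
      pos[i] <- cand[sample.int(length(cand), 1L)]
      if (strand_fwd[i]) {
        ref_b[i] <- substr(fwd_tri[ch_idx[i]], 2, 2)
        alt_b[i] <- alt_base[ch_idx[i]]
      } else {
        ref_b[i] <- .COMPLEMENT[substr(fwd_tri[ch_idx[i]], 2, 2)]
        alt_b[i] <- .COMPLEMENT[alt_base[ch_idx[i]]]
      }
    }
    out[[s]] <- data.frame(sample_id = ids[s], chrom = chrom, pos = pos,
                           ref = ref_b, alt = unname(alt_b),
                           variant_type = "SNV",
                           channel = channels[ch_idx],
                           stringsAsFactors = FALSE)
  }
  mutations <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(mutations) <- NULL
  list(mutations = mutations, reference = reference,
       truth = list(dmmr = dmmr, exposures = exposures,
                    signatures = signatures, mutation_counts = counts))
}

#' Spike germline variants and sequencing artifacts into a mutation table
#'
#' Annotates each record with the quality and population fields the
#' somatic filter consumes. A fraction of records is converted to germline
#' spike-ins (cohort allele frequency above 5%, presence in two or more
#' population databases, or alternate-read fraction above 99.9%) and
#' another fraction to low-quality artifacts (low mapping quality, shallow
#' depth, low alternate fraction, high haplotype score, multiallelic or
#' blacklisted sites). Spike-ins respect each filter threshold by a
#' margin. A configurable fraction of germline spike-ins carries a COSMIC
#' somatic occurrence count of at least 10, making them rescuable.
#'
#' @param records Mutation data frame from [simulate_mutation_catalogs()].
#' @param cfg A [sim_config()].
#' @return List with `records` (annotated data frame) and `truth` (data
#'   frame: per-record `spike_class` in somatic/germline/artifact and
#'   `cosmic_rescuable` flag).
#' @export
simulate_variant_annotations <- function(records, cfg) {
  if (nrow(records) == 0) stop("no records to annotate")
  set.seed(cfg$seed + 303L)
  n <- nrow(records)
  depth <- 80L + stats::rpois(n, 120)
  alt_frac <- stats::runif(n, 0.10, 0.60)
  rec <- records
  rec$depth <- depth
  rec$alt_reads <- pmax(1L, round(alt_frac * depth))
  rec$mapq <- stats::runif(n, 50, 60)
  rec$haplotype_score <- stats::runif(n, 0, 100)
  rec$cohort_af <- stats::runif(n, 0, 0.03)
  rec$db_hits <- 0L
  rec$cosmic_count <- stats::rpois(n, 0.2)
  rec$multiallelic <- FALSE
  rec$poorly_sequenced_site <- FALSE
  if (!"gene" %in% names(rec)) rec$gene <- ""

  u <- stats::runif(n)
  cls <- rep("somatic", n)
  cls[u < cfg$germline_rate] <- "germline"
  cls[u >= cfg$germline_rate &
        u < cfg$germline_rate + cfg$artifact_rate] <- "artifact"

  g <- which(cls == "germline")
  if (length(g)) {
    mech <- sample(1:3, length(g), replace = TRUE)
    i <- g[mech == 1]
    rec$cohort_af[i] <- stats::runif(length(i), 0.08, 0.5)
    i <- g[mech == 2]
    rec$db_hits[i] <- sample(2:3, length(i), replace = TRUE)
    i <- g[mech == 3]
    rec$alt_reads[i] <- rec$depth[i]
    rescuable <- stats::runif(length(g)) < cfg$cosmic_rescuable_frac
    rec$cosmic_count[g[rescuable]] <-
      sample(10:50, sum(rescuable), replace = TRUE)
    rec$cosmic_count[g[!rescuable]] <- 0L
  }
  a <- which(cls == "artifact")
  if (length(a)) {
    mech <- sample(1:5, length(a), replace = TRUE)
    i <- a[mech == 1]; rec$mapq[i] <- stats::runif(length(i), 5, 35)
    i <- a[mech == 2]; rec$depth[i] <- sample(20:55, length(i), replace = TRUE)
    rec$alt_reads[i] <- pmax(1L, round(0.3 * rec$depth[i]))
    i <- a[mech == 3]
    rec$alt_reads[i] <- pmax(1L, round(stats::runif(length(i), 0.005, 0.04) *
                                         rec$depth[i]))
    i <- a[mech == 4]
    rec$haplotype_score[i] <- stats::runif(length(i), 220, 400)
    i <- a[mech == 5]; rec$multiallelic[i] <- TRUE
  }
  truth <- data.frame(spike_class = cls,
                      cosmic_rescuable = rec$cosmic_count >= 10 &
                        cls == "germline",
                      stringsAsFactors = FALSE)
  list(records = rec, truth = truth)
}

#' Simulate a TPM expression matrix with an infiltrate factor
#'
#' A latent immune-infiltrate factor is constructed as
#' `infiltrate_effect * standardized(dmmr_activity) + sqrt(1 - e^2) * noise`,
#' so its population correlation with dMMR activity equals
#' `infiltrate_effect`. The 32 checkpoint-panel genes load positively on
#' the factor (gene-specific loadings around `panel_loading` on the log
#' scale); remaining genes are independent log-normal noise. Values are
#' nonnegative and TPM-like in magnitude.
#'
#' @param cfg A [sim_config()].
#' @param dmmr_activity Numeric vector in [0,1], one value per sample
#'   (e.g. true or estimated dMMR signature exposure proportion).
#' @return Matrix genes x samples with the panel genes first; attributes
#'   `infiltrate` (the latent factor) and `panel` (panel gene names).
#' @export
simulate_expression <- function(cfg, dmmr_activity) {
  if (any(dmmr_activity < 0 | dmmr_activity > 1))
    stop("activities must lie in [0,1]")
  set.seed(cfg$seed + 404L)
  n <- length(dmmr_activity)
  e <- cfg$infiltrate_effect
  z <- as.vector(scale(dmmr_activity))
  if (any(!is.finite(z))) z <- rep(0, n)  # constant activity: no signal
  f <- e * z + sqrt(max(0, 1 - e^2)) * stats::rnorm(n)
  panel <- checkpoint_panel()
  others <- sprintf("GENE%04d", seq_len(max(0L, cfg$n_genes - length(panel))))
  genes <- c(panel, others)
  loadings <- c(stats::runif(length(panel), 0.75, 1.25) * cfg$panel_loading,
                rep(0, length(others)))
  mu <- stats::runif(length(genes), 1, 4)
  logx <- outer(mu, rep(1, n)) + outer(loadings, f) +
    matrix(stats::rnorm(length(genes) * n), length(genes), n)
  X <- exp(logx)
  dimnames(X) <- list(genes, .sample_ids(n))
  attr(X, "infiltrate") <- stats::setNames(f, .sample_ids(n))
  attr(X, "panel") <- panel
  X
}

#' Simulate clinical and survival data
#'
#' Exponential overall-survival times with a configurable dMMR:pMMR hazard
#' ratio, uniform independent censoring on `[0, followup_max]`, and biopsy
#' sites drawn from bone / lymph node / other.
#'
#' @param cfg A [sim_config()].
#' @param labels Named logical vector of dMMR status per sample.
#' @return Data frame: `sample_id`, `patient_id`, `biopsy_site`, `dmmr`,
#'   `os_years`, `os_event`.
#' @export
simulate_clinical <- function(cfg, labels) {
  if (!is.logical(labels)) stop("labels must be logical")
  set.seed(cfg$seed + 505L)
  n <- length(labels)
  rate_p <- log(2) / cfg$median_os_pmmr
  rate <- ifelse(labels, rate_p * cfg$hazard_ratio, rate_p)
  t_event <- stats::rexp(n, rate)
  t_cens <- stats::runif(n, 0, cfg$followup_max)
  data.frame(sample_id = names(labels),
             patient_id = sub("^S", "P", names(labels)),
             biopsy_site = sample(c("bone", "lymph_node", "other"), n,
                                  replace = TRUE, prob = c(0.45, 0.4, 0.15)),
             dmmr = unname(labels),
             os_years = pmin(t_event, t_cens),
             os_event = as.integer(t_event <= t_cens),
             stringsAsFactors = FALSE)
}

#' Simulate a complete synthetic cohort
#'
#' Runs every generator with sub-seeds derived from the master seed and
#' returns all tables plus the ground truth downstream recovery tests
#' read.
#'
#' @param cfg A [sim_config()].
#' @return List: `histograms`, `loci`, `mutations` (annotated), `reference`,
#'   `expression`, `clinical`, `truth`.
#' @export
simulate_cohort <- function(cfg) {
  hs <- simulate_locus_histograms(cfg)
  mc <- simulate_mutation_catalogs(cfg)
  va <- simulate_variant_annotations(mc$mutations, cfg)
  dmmr_prop <- rowSums(mc$truth$exposures[, grep("^MMR",
                         colnames(mc$truth$exposures)), drop = FALSE])
  expr <- simulate_expression(cfg, dmmr_prop)
  clin <- simulate_clinical(cfg, hs$truth$dmmr)
  clin$dmmr_activity <- unname(dmmr_prop[clin$sample_id])
  list(histograms = hs$histograms, loci = hs$loci,
       mutations = va$records, reference = mc$reference,
       expression = expr, clinical = clin,
       truth = list(dmmr = hs$truth$dmmr,
                    unstable = hs$truth$unstable,
                    exposures = mc$truth$exposures,
                    signatures = mc$truth$signatures,
                    mutation_counts = mc$truth$mutation_counts,
                    dmmr_activity = dmmr_prop,
                    infiltrate = attr(expr, "infiltrate"),
                    variant_class = va$truth))
}
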