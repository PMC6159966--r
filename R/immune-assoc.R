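#' The 32-gene immune checkpoint and T cell activity panel
#'
#' Curated immune checkpoint genes together with markers of T cell
#' infiltrate and activity used for the immunomodulatory expression score.
#'
#' @return Character vector of 32 gene symbols.
#' @export
checkpoint_panel <- function() {
  c("CD28", "ICOSLG", "ICOS", "TNFRSF9", "TNFSF9", "TNFSF4", "TNFRSF4",
    "CD70", "CD27", "CTLA4", "PDCD1", "CD274", "PDCD1LG2", "CD47",
    "HAVCR2", "LGALS9", "ADORA2A", "CD200", "CD200R1", "CD276", "VTCN1",
    "TNFSF14", "BTLA", "TIGIT", "CD8A", "PRF1", "IL10", "CD80", "GZMA",
    "CD86", "IFNG", "LAG3")
}

#' Geometric-mean immunomodulatory expression score
#'
#' Per sample, `exp(mean(log(TPM + offset)))` across the panel genes,
#' optionally excluding one gene (e.g. CD8A when correlating the score of
#' the other 31 genes against CD8A itself). The default offset of 1
#' tolerates zero TPM values; with `offset = 0` any zero raises an error.
#'
#' @param expr Matrix genes x samples (TPM).
#' @param panel Character vector of panel genes (default the 32-gene
#'   checkpoint panel).
#' @param exclude Optional single gene to drop from the panel.
#' @param offset Added inside the log (default 1); the score is reported
#'   on the offset scale (no back-subtraction).
#' @return Named numeric vector of per-sample scores.
#' @export
geometric_mean_score <- function(expr, panel = checkpoint_panel(),
                                 exclude = NULL, offset = 1) {
  if (!is.null(exclude)) panel <- setdiff(panel, exclude)
  missing <- setdiff(panel, rownames(expr))
  if (length(missing))
    stop("panel genes absent from the matrix: ",
         paste(missing, collapse = ", "))
  x <- expr[panel, , drop = FALSE] + offset
  if (any(x <= 0))
    stop("nonpositive values under offset ", offset,
         "; use a positive offset for matrices containing zeros")
  exp(colMeans(log(x)))
}

#' Pearson correlation with an explicit outlier policy
#'
#' Computes Pearson's r and its two-sided p-value (t approximation).
#' `policy = "robust-z"` automates scatterplot-based outlier review:
#' points whose residual from the least-squares line exceeds 3.5
#' MAD-scaled units are removed and the correlation recomputed; removals
#' are always reported. `policy = "none"` reproduces plain Pearson.
#'
#' @param x,y Numeric vectors.
#' @param policy `"none"` or `"robust-z"`.
#' @param z_cut Robust-z threshold (default 3.5).
#' @return List: `r`, `p`, `n`, `outliers_removed`.
#' @export
pearson_with_outlier_policy <- function(x, y,
                                        policy = c("none", "robust-z"),
                                        z_cut = 3.5) {
  policy <- match.arg(policy)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  removed <- 0L
  if (policy == "robust-z" && length(x) >= 4) {
    fit <- stats::lm(y ~ x)
    res <- stats::residuals(fit)
    s <- stats::mad(res)
    if (s > 0) {
      out <- abs(res) / s > z_cut
      removed <- sum(out)
      x <- x[!out]; y <- y[!out]
    }
  }
  if (length(x) < 3) stop("fewer than 3 points after outlier removal")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       outliers_removed = removed)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up BH with monotonicity enforcement; ties handled stably.
#'
#' @param p Numeric vector of p-values in [0,1].
#' @return Vector of q-values in the input order.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Associate gene expression with dMMR signature activity
#'
#' Per gene: the overall Pearson correlation of expression with activity
#' across all samples, with BH correction over the gene set, and
#' per-biopsy-site correlations. A gene `passes_overall` when its overall
#' q-value is below `fdr`; it `passes_consistent` when additionally every
#' adequately sized site stratum has nominal p below `site_p` — the
#' stringent criterion that filters out genes associated only in specific
#' metastatic settings. Strata with fewer than `min_n` samples are
#' excluded from the consistency requirement (and recorded in the
#' `strata_used` attribute).
#'
#' @param expr Matrix genes x samples.
#' @param activity Named numeric vector of per-sample dMMR activity
#'   (proportions in [0,1]).
#' @param sites Named character vector of biopsy sites per sample.
#' @param genes Genes to test (default all rows of `expr`).
#' @param fdr Overall FDR level (default 0.1).
#' @param site_p Per-site nominal significance level (default 0.05).
#' @param min_n Minimum stratum size (default 10).
#' @param policy Outlier policy for every correlation (default "none").
#' @return Data frame with one row per gene: `gene`, `r`, `p`, `q`,
#'   per-site `r_<site>`/`p_<site>` columns, `passes_overall`,
#'   `passes_consistent`, `outliers_removed`.
#' @export
associate_genes <- function(expr, activity, sites,
                            genes = rownames(expr), fdr = 0.1,
                            site_p = 0.05, min_n = 10L,
                            policy = "none") {
  if (length(genes) == 0) stop("empty gene set")
  samples <- colnames(expr)
  act <- activity[samples]
  st <- sites[samples]
  site_levels <- names(which(table(st) >= min_n))
  if (length(site_levels) < 1)
    warning("no site stratum reaches min_n = ", min_n,
            "; consistency flag reduces to the overall test")
  res <- lapply(genes, function(g) {
    o <- pearson_with_outlier_policy(act, expr[g, ], policy = policy)
    row <- data.frame(gene = g, r = o$r, p = o$p,
                      outliers_removed = o$outliers_removed,
                      stringsAsFactors = FALSE)
    for (s in site_levels) {
      i <- st == s
      os <- pearson_with_outlier_policy(act[i], expr[g, i], policy = policy)
      row[[paste0("r_", s)]] <- os$r
      row[[paste0("p_", s)]] <- os$p
    }
    row
  })
  out <- do.call(rbind, res)
  out$q <- bh_fdr(out$p)
  out$passes_overall <- out$q < fdr
  if (length(site_levels)) {
    site_ok <- rep(TRUE, nrow(out))
    for (s in site_levels)
      site_ok <- site_ok & out[[paste0("p_", s)]] < site_p
  } else site_ok <- rep(TRUE, nrow(out))
  out$passes_consistent <- out$passes_overall & site_ok
  attr(out, "strata_used") <- site_levels
  rownames(out) <- NULL
  out
}

#' Lymphocyte density of tumor-infiltrating lymphocytes
#'
#' Pooled ratio across images: total T lymphocytes over total tumor area
#' — not the mean of per-image densities.
#'
#' @param counts Per-image T cell counts (>= 0).
#' @param areas_mm2 Per-image tumor areas in mm^2 (> 0 in total).
#' @return Cells per mm^2.
#' @export
ldtil_density <- function(counts, areas_mm2) {
  if (length(counts) != length(areas_mm2)) stop("length mismatch")
  if (any(counts < 0) || any(areas_mm2 < 0)) stop("negative inputs")
  total_area <- sum(areas_mm2)
  if (total_area <= 0) stop("zero total tumor area")
  sum(counts) / total_area
}

#' Crude contingency odds ratio with Woolf confidence interval
#'
#' OR = ad/bc for the 2x2 table (a, b / c, d), with optional
#' Haldane-Anscombe correction (+0.5 to every cell) applied when any cell
#' is zero; the 95% CI uses the Woolf log-OR standard error.
#'
#' @param a,b,c,d Cell counts: a = exposed cases, b = exposed non-cases,
#'   c = unexposed cases, d = unexposed non-cases.
#' @param correction Apply +0.5 when a zero cell is present (default
#'   `TRUE`).
#' @return List: `or`, `ci_low`, `ci_high`, `corrected`.
#' @export
contingency_odds_ratio <- function(a, b, c, d, correction = TRUE) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("cell counts must be nonnegative")
  corrected <- FALSE
  if (any(cells == 0)) {
    if (correction) { cells <- cells + 0.5; corrected <- TRUE }
    else {
      or <- (a * d) / (b * c)  # may be Inf/NaN; flagged uncorrected
      return(list(or = or, ci_low = NA_real_, ci_high = NA_real_,
                  corrected = FALSE))
    }
  }
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- stats::qnorm(0.975)
  list(or = or, ci_low = exp(log(or) - z * se),
       ci_high = exp(log(or) + z * se), corrected = corrected)
}
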