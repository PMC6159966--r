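#' Nonnegative matrix factorisation by Brunet-style multiplicative updates
#'
#' Factorises a nonnegative samples-by-channels count matrix `V` as
#' `t(V) ~ W %*% t(H)` under the generalised Kullback-Leibler divergence,
#' using the classical multiplicative update rules. A small pseudocount is
#' added to `V` before the updates so that channels observed zero times do
#' not produce divisions by zero; the divergence is non-increasing across
#' iterations.
#'
#' @param V Nonnegative numeric matrix, samples x channels (rows are
#'   mutational catalogs when used for signature extraction).
#' @param rank Number of components K; must satisfy `K < min(dim(V))`.
#' @param seed Integer seed for the uniform random initialisation.
#' @param max_iter Maximum number of update sweeps.
#' @param tol Stop when the relative divergence decrease over a sweep falls
#'   below this value. The tight default (1e-8) matters for flat,
#'   low-contrast signatures, whose recovery keeps improving long after
#'   the divergence has nearly plateaued.
#' @param pseudocount Added to `V` before updating (default `1e-9`).
#' @param objective `"kl"` (default) or `"frobenius"`; the latter uses the
#'   Euclidean multiplicative updates instead.
#' @return List with `W` (channels x K, columns sum to 1), `H` (samples x
#'   K, carrying the scale), `divergence` (final objective value),
#'   `divergence_trace` (per-sweep objective), `n_iter`, and `seed`.
#' @export
nmf_brunet <- function(V, rank, seed = 1L, max_iter = 5000L, tol = 1e-8,
                       pseudocount = 1e-9, objective = c("kl", "frobenius")) {
  objective <- match.arg(objective)
  if (!all(is.finite(V))) stop("V must be finite")
  if (any(V < 0)) stop("V must be nonnegative")
  if (rank >= min(dim(V))) stop("rank must be < min(dim(V))")
  A <- t(V) + pseudocount            # channels x samples
  n <- nrow(A); m <- ncol(A); K <- as.integer(rank)
  eps <- .Machine$double.eps

  set.seed(as.integer(seed))
  W <- matrix(stats::runif(n * K), n, K)
  H <- matrix(stats::runif(K * m), K, m)

  kl_div <- function(A, WH) sum(A * log(A / WH) - A + WH)

  WH <- W %*% H
  d_prev <- if (objective == "kl") kl_div(A, WH) else 0.5 * sum((A - WH)^2)
  trace <- d_prev
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    if (objective == "kl") {
      H <- H * (t(W) %*% (A / (WH + eps))) / (colSums(W) + eps)
      WH <- W %*% H
      W <- W * ((A / (WH + eps)) %*% t(H)) / matrix(rowSums(H) + eps,
                                                    n, K, byrow = TRUE)
      WH <- W %*% H
      d <- kl_div(A, WH)
    } else {
      H <- H * (t(W) %*% A) / (t(W) %*% WH + eps)
      WH <- W %*% H
      W <- W * (A %*% t(H)) / (WH %*% t(H) + eps)
      WH <- W %*% H
      d <- 0.5 * sum((A - WH)^2)
    }
    trace <- c(trace, d)
    if (d_prev > 0 && abs(d_prev - d) / (abs(d_prev) + eps) < tol) {
      d_prev <- d
      break
    }
    d_prev <- d
  }
  # move column scale of W into H so signature columns sum to 1
  scale <- colSums(W)
  scale[scale == 0] <- 1
  W <- sweep(W, 2L, scale, "/")
  H <- H * scale
  dimnames(W) <- list(colnames(V), paste0("S", seq_len(K)))
  Hs <- t(H)
  dimnames(Hs) <- list(rownames(V), paste0("S", seq_len(K)))
  list(W = W, H = Hs, divergence = d_prev, divergence_trace = trace,
       n_iter = it, seed = as.integer(seed))
}

#' Extract mutational signatures by multi-restart NMF
#'
#' Because NMF is non-deterministic, the factorisation is repeated from
#' `n_runs` random initialisations (seeds `seed`, `seed + 1`, ...); the run
#' with the minimum divergence is kept (ties broken toward the lowest
#' seed). This mirrors standard practice of selecting signatures and
#' per-tumor activities from the best of many restarts.
#'
#' @inheritParams nmf_brunet
#' @param n_runs Number of independent restarts (>= 1).
#' @param ... Passed on to [nmf_brunet()].
#' @return A `signature_model` object: list with `W` (96 x K, columns sum
#'   to 1), `H` (samples x K exposures on the mutation-count scale),
#'   `proportions` (rows of `H` normalised to 1), `residual` (divergence of
#'   the selected run), `rank`, `n_runs`, `best_seed`, and `assignments`
#'   (populated by [match_signatures()]).
#' @export
fit_signatures <- function(V, rank, n_runs = 200L, seed = 1L, ...) {
  if (n_runs < 1L) stop("n_runs must be >= 1")
  best <- NULL
  for (s in seq.int(seed, seed + n_runs - 1L)) {
    fit <- nmf_brunet(V, rank = rank, seed = s, ...)
    if (is.null(best) || fit$divergence < best$divergence) best <- fit
  }
  model <- list(W = best$W, H = best$H,
                proportions = exposure_proportions(best$H),
                residual = best$divergence, rank = as.integer(rank),
                n_runs = as.integer(n_runs), best_seed = best$seed,
                assignments = NULL)
  class(model) <- "signature_model"
  model
}

#' @export
print.signature_model <- function(x, ...) {
  cat("Mutational signature model (KL-NMF)\n")
  cat("  rank:", x$rank, " restarts:", x$n_runs,
      " best seed:", x$best_seed, "\n")
  cat("  residual divergence:", format(x$residual, digits = 6), "\n")
  cat("  samples:", nrow(x$H), " channels:", nrow(x$W), "\n")
  if (!is.null(x$assignments)) {
    cat("  reference assignments:\n")
    a <- x$assignments
    for (i in seq_len(nrow(a)))
      cat(sprintf("    %s -> %s (cosine %.3f%s)\n", a$discovered[i],
                  a$reference[i], a$cosine[i],
                  if (a$matched[i]) "" else ", unmatched"))
  }
  invisible(x)
}

#' @export
summary.signature_model <- function(object, ...) {
  cat("Mean exposure proportions per signature:\n")
  print(round(colMeans(object$proportions, na.rm = TRUE), 4))
  invisible(object)
}

#' @export
coef.signature_model <- function(object, ...) object$H

#' Per-sample exposure proportions
#'
#' Normalises each row of an exposure matrix to sum to one. Rows that are
#' entirely zero have no defined proportion and are returned as `NA` (they
#' are excluded from dominance calls).
#'
#' @param H Nonnegative samples x K exposure matrix.
#' @return Matrix of the same shape with rows summing to 1 (or `NA` rows).
#' @export
exposure_proportions <- function(H) {
  if (any(H < 0)) stop("exposures must be nonnegative")
  rs <- rowSums(H)
  P <- H / ifelse(rs == 0, NA_real_, rs)
  P
}

#' Flag samples whose mutations are dominated by dMMR signatures
#'
#' A tumor is "MMR-dominant" when strictly more than half of its mutations
#' are attributed to the dMMR-associated signatures (by default both
#' MMR-type signatures are summed).
#'
#' @param proportions Samples x K matrix of exposure proportions.
#' @param dmmr_indices Column indices (or names) of the dMMR signatures.
#' @param threshold Dominance threshold (default 0.5, strict).
#' @return Logical vector; `NA` where proportions are undefined.
#' @export
mmr_dominant <- function(proportions, dmmr_indices, threshold = 0.5) {
  p <- rowSums(proportions[, dmmr_indices, drop = FALSE])
  p > threshold
}

.permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in .permutations(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], rest)
  out
}

#' Match discovered signatures to reference signatures
#'
#' Finds the one-to-one assignment of discovered signature columns to
#' reference columns that maximises the total cosine similarity
#' (exhaustive search; intended for K <= 8). Pairs below
#' `report_threshold` are flagged unmatched but still reported.
#'
#' @param W 96 x K matrix of discovered signatures (or a
#'   `signature_model`).
#' @param reference 96 x R matrix of reference signatures (R >= K), same
#'   channel order.
#' @param report_threshold Cosine below which a pair is considered
#'   unmatched (default 0.8).
#' @return Data frame with columns `discovered`, `reference`, `cosine`,
#'   `matched`. If `W` is a `signature_model` the model is returned with
#'   `$assignments` filled in.
#' @export
match_signatures <- function(W, reference, report_threshold = 0.8) {
  model <- NULL
  if (inherits(W, "signature_model")) { model <- W; W <- model$W }
  if (nrow(W) != nrow(reference))
    stop("channel count mismatch between discovered and reference matrices")
  K <- ncol(W); R <- ncol(reference)
  if (K > R) stop("more discovered signatures than references to match")
  if (R > 8L && K > 8L) stop("exhaustive matching supported for K <= 8")
  cmat <- matrix(0, K, R)
  for (i in seq_len(K))
    for (j in seq_len(R))
      cmat[i, j] <- cosine_similarity(W[, i], reference[, j])
  # enumerate injections K -> R via permutations of reference indices
  best <- NULL; best_total <- -Inf
  for (perm in .permutations(seq_len(R))) {
    sel <- perm[seq_len(K)]
    total <- sum(cmat[cbind(seq_len(K), sel)])
    if (total > best_total) { best_total <- total; best <- sel }
  }
  ref_names <- colnames(reference)
  if (is.null(ref_names)) ref_names <- paste0("R", seq_len(R))
  disc_names <- colnames(W)
  if (is.null(disc_names)) disc_names <- paste0("S", seq_len(K))
  out <- data.frame(discovered = disc_names,
                    reference = ref_names[best],
                    cosine = cmat[cbind(seq_len(K), best)],
                    stringsAsFactors = FALSE)
  out$matched <- out$cosine >= report_threshold
  if (!is.null(model)) { model$assignments <- out; return(model) }
  out
}

#' NMF rank diagnostics: cophenetic coefficient, residual, RSS
#'
#' For each candidate rank, runs the factorisation from `runs_per_rank`
#' random restarts, builds the consensus matrix of sample co-assignment
#' (two samples co-assigned when their argmax exposures agree), and
#' reports the cophenetic coefficient of the consensus (correlation
#' between consensus dissimilarities and the cophenetic distances of their
#' average-linkage clustering), together with the best run's divergence
#' and residual sum of squares. Rank selection is left to the analyst:
#' high cophenetic coefficients and low residuals are preferred.
#'
#' @inheritParams nmf_brunet
#' @param ranks Integer vector of ranks to evaluate (each in
#'   `[2, min(dim(V)) - 1]`).
#' @param runs_per_rank Restarts per rank (>= 2; the consensus is
#'   undefined for a single run).
#' @return Data frame with columns `rank`, `cophenetic`, `residual`,
#'   `rss`.
#' @export
rank_diagnostics <- function(V, ranks = 2:8, runs_per_rank = 50L,
                             seed = 1L, ...) {
  if (runs_per_rank < 2L) stop("runs_per_rank must be >= 2")
  if (any(ranks < 2L) || any(ranks >= min(dim(V))))
    stop("ranks must lie in [2, min(dim(V)) - 1]")
  S <- nrow(V)
  res <- data.frame(rank = integer(0), cophenetic = numeric(0),
                    residual = numeric(0), rss = numeric(0))
  for (K in ranks) {
    consensus <- matrix(0, S, S)
    best <- NULL
    for (r in seq_len(runs_per_rank)) {
      fit <- nmf_brunet(V, rank = K, seed = seed + (K * 1000L) + r - 1L, ...)
      cl <- max.col(fit$H, ties.method = "first")
      consensus <- consensus + outer(cl, cl, "==")
      if (is.null(best) || fit$divergence < best$divergence) best <- fit
    }
    consensus <- consensus / runs_per_rank
    dis <- stats::as.dist(1 - consensus)
    hc <- stats::hclust(dis, method = "average")
    coph <- suppressWarnings(stats::cor(dis, stats::cophenetic(hc)))
    if (is.na(coph)) coph <- 1  # perfect consensus: zero variance in dis
    recon <- best$W %*% t(best$H)
    rss <- sum((t(V) - recon)^2)
    res <- rbind(res, data.frame(rank = K, cophenetic = coph,
                                 residual = best$divergence, rss = rss))
  }
  res
}
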