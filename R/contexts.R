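#' Trinucleotide substitution channels
#'
#' Single-nucleotide variants are summarised on the pyrimidine strand as one
#' of six substitution classes (C>A, C>G, C>T, T>A, T>C, T>G) in their
#' immediate trinucleotide context, giving 6 x 4 x 4 = 96 channels. The
#' channel order is fixed: substitution-major, then the 5' flanking base,
#' then the 3' flanking base, each alphabetical. All context matrices and
#' signature matrices in this package use this order, so they are directly
#' comparable to each other and to user-supplied reference signatures laid
#' out the same way.
#'
#' @return Character vector of the 96 channel labels, e.g. `"A[C>A]A"`.
#' @export
#' @examples
#' head(context_channels())
context_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (s in subs)
    for (b5 in bases)
      for (b3 in bases)
        out <- c(out, paste0(b5, "[", s, "]", b3))
  out
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

.revcomp <- function(x) {
  paste(rev(.COMPLEMENT[strsplit(x, "")[[1]]]), collapse = "")
}

#' Classify an SNV into its trinucleotide substitution channel
#'
#' Looks up the reference base and its immediate 5'/3' neighbours at the
#' variant position; purine-reference variants (A or G) are
#' reverse-complemented onto the pyrimidine strand, with the flanks swapped
#' and complemented accordingly.
#'
#' @param chrom Chromosome name (must be present in `reference`).
#' @param pos 1-based position of the variant.
#' @param ref,alt Single reference and alternate bases.
#' @param reference Named character vector of chromosome sequences (as
#'   produced by [read_fasta()]).
#' @return One of the 96 labels of [context_channels()].
#' @export
#' @examples
#' ref <- c(chr1 = "GGACAGG")
#' classify_context("chr1", 4, "C", "T", ref)  # "A[C>T]A"
classify_context <- function(chrom, pos, ref, alt, reference) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (nchar(ref) != 1L || nchar(alt) != 1L)
    stop("indels and multi-nucleotide variants cannot be context-classified")
  if (!chrom %in% names(reference))
    stop("chromosome '", chrom, "' not found in reference")
  seq <- reference[[chrom]]
  n <- nchar(seq)
  if (pos < 2L || pos > n - 1L)
    stop("position ", pos, " too close to the contig edge for context lookup")
  tri <- toupper(substr(seq, pos - 1L, pos + 1L))
  mid <- substr(tri, 2L, 2L)
  if (mid != ref)
    stop("REF mismatch at ", chrom, ":", pos, " (table says ", ref,
         ", reference has ", mid, ")")
  if (ref %in% c("A", "G")) {
    tri <- .revcomp(tri)
    ref <- unname(.COMPLEMENT[ref])
    alt <- unname(.COMPLEMENT[alt])
  }
  paste0(substr(tri, 1L, 1L), "[", ref, ">", alt, "]", substr(tri, 3L, 3L))
}

#' Build a sample-by-channel mutation context matrix
#'
#' Tabulates each sample's SNVs over the 96 trinucleotide substitution
#' channels. Non-SNV records (indels) are skipped and counted in the
#' `n_skipped` attribute.
#'
#' @param mutations Data frame with columns `sample_id`, `chrom`, `pos`,
#'   `ref`, `alt` (1-based positions; MAF/VCF convention).
#' @param reference Named character vector of chromosome sequences.
#' @param samples Optional character vector fixing the row order (and
#'   including samples with zero mutations).
#' @return Integer matrix, samples x 96; row sums equal per-sample SNV
#'   counts.
#' @export
build_context_matrix <- function(mutations, reference, samples = NULL) {
  channels <- context_channels()
  is_snv <- nchar(mutations$ref) == 1L & nchar(mutations$alt) == 1L &
    toupper(mutations$ref) %in% c("A", "C", "G", "T") &
    toupper(mutations$alt) %in% c("A", "C", "G", "T")
  skipped <- sum(!is_snv)
  snv <- mutations[is_snv, , drop = FALSE]
  if (is.null(samples)) samples <- sort(unique(mutations$sample_id))
  V <- matrix(0L, nrow = length(samples), ncol = 96L,
              dimnames = list(samples, channels))
  if (nrow(snv) > 0L) {
    lab <- vapply(seq_len(nrow(snv)), function(i) {
      classify_context(snv$chrom[i], snv$pos[i], snv$ref[i], snv$alt[i],
                       reference)
    }, character(1))
    tab <- table(factor(snv$sample_id, levels = samples),
                 factor(lab, levels = channels))
    V <- V + as.matrix(unclass(tab))
    storage.mode(V) <- "integer"
    dimnames(V) <- list(samples, channels)
  }
  attr(V, "n_skipped") <- skipped
  V
}

#' Cosine similarity between two nonnegative vectors
#'
#' @param a,b Numeric vectors of equal length with nonzero norm.
#' @return `sum(a*b) / (||a|| ||b||)`.
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("vectors differ in length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for zero vector")
  sum(a * b) / (na * nb)
}
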