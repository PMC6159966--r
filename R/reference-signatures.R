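#' Synthetic reference mutational signatures
#'
#' Four synthetic 96-channel signatures with the qualitative shapes of the
#' processes most relevant to mismatch-repair analysis of prostate cancer
#' exomes: an aging-like clock signature (spiky C>T at NpCpG), a flat
#' homologous-recombination-deficiency-like signature, and two
#' C>T/T>C-rich MMR-deficiency-like signatures with distinct flanking-base
#' profiles. They are constructed in code (no external catalogue is
#' bundled) and are deliberately well separated: all pairwise cosine
#' similarities are at most 0.6, so signature-recovery problems posed with
#' them are well identified. Real catalogue matrices can be supplied
#' instead via [read_signature_table()].
#'
#' @return 96 x 4 matrix with columns `Aging1`, `HRD3`, `MMR6`, `MMR26`;
#'   each column sums to 1; rows in [context_channels()] order.
#' @export
#' @examples
#' S <- reference_signatures()
#' colSums(S)
reference_signatures <- function() {
  ch <- context_channels()
  sub <- substr(ch, 3, 5)
  b5 <- substr(ch, 1, 1)
  b3 <- substr(ch, 7, 7)

  # Aging-like: dominated by C>T at NpCpG (deamination of methylated CpG)
  aging <- rep(0.1 / 92, 96)
  aging[sub == "C>T" & b3 == "G"] <- 0.9 / 4

  # HRD-like: near-uniform ("flat") profile with gentle smooth variation
  hrd <- 1 + 0.3 * cos(2 * pi * seq_len(96) / 96)
  hrd <- hrd / sum(hrd)

  # MMR-like #1: C>T rich, 5' G preference, depleted at 3' G
  w5 <- c(A = 1, C = 2, G = 4, T = 0.5)
  w3 <- c(A = 2, C = 1.5, G = 0.2, T = 1)
  mmr6 <- rep(0.02, 96)
  idx <- sub == "C>T"
  mmr6[idx] <- mmr6[idx] + 3 * w5[b5[idx]] * w3[b3[idx]]
  mmr6 <- mmr6 / sum(mmr6)

  # MMR-like #2: mixed C>T (5' A/T preference) and T>C component
  v5 <- c(A = 4, C = 0.5, G = 0.3, T = 2)
  v3 <- c(A = 0.3, C = 2, G = 0.2, T = 2)
  mmr26 <- rep(0.01, 96)
  idx <- sub == "C>T"
  mmr26[idx] <- mmr26[idx] + 1.5 * v5[b5[idx]] * v3[b3[idx]]
  idx <- sub == "T>C"
  mmr26[idx] <- mmr26[idx] + 2 * v5[b5[idx]]
  mmr26 <- mmr26 / sum(mmr26)

  S <- cbind(Aging1 = aging, HRD3 = hrd, MMR6 = mmr6, MMR26 = mmr26)
  rownames(S) <- ch
  for (i in 1:3) for (j in (i + 1):4) {
    cs <- cosine_similarity(S[, i], S[, j])
    if (cs > 0.6)
      stop("fixture signatures insufficiently separated: cosine(",
           colnames(S)[i], ",", colnames(S)[j], ") = ", round(cs, 3))
  }
  S
}

#' Read a reference-signature table
#'
#' Reads a TSV with one row per signature: a name column followed by 96
#' channel columns whose headers must be the labels of
#' [context_channels()] (in any order; they are rearranged).
#'
#' @param path Path to the TSV file.
#' @return 96 x R numeric matrix, columns named by signature, each column
#'   renormalised to sum to 1.
#' @export
read_signature_table <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  ch <- context_channels()
  if (!all(ch %in% colnames(tab)))
    stop("signature table lacks channel columns: ",
         paste(setdiff(ch, colnames(tab))[1:5], collapse = ", "), " ...")
  S <- t(as.matrix(tab[, ch]))
  colnames(S) <- tab[[1]]
  sweep(S, 2, colSums(S), "/")
}

#' Write a reference-signature table
#'
#' @param S 96 x R signature matrix in [context_channels()] order.
#' @param path Output TSV path.
#' @export
write_signature_table <- function(S, path) {
  tab <- data.frame(signature = colnames(S), t(S), check.names = FALSE,
                    stringsAsFactors = FALSE)
  colnames(tab) <- c("signature", context_channels())
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
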