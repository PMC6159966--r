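#' Read a FASTA reference
#'
#' @param path FASTA file.
#' @return Named character vector of sequences (names truncated at the
#'   first whitespace).
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write a FASTA reference
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Read a microsatellite locus BED file
#'
#' BED is 0-based half-open; columns: chrom, start, end, locus_id, and
#' optionally repeat_unit and reference_repeat_count.
#'
#' @param path BED file (tab-separated, no header).
#' @return Locus data frame.
#' @export
read_bed <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 4) stop("BED needs at least chrom, start, end, name")
  names(tab)[1:4] <- c("chrom", "start", "end", "locus_id")
  if (ncol(tab) >= 5) names(tab)[5] <- "repeat_unit"
  if (ncol(tab) >= 6) names(tab)[6] <- "reference_repeat_count"
  bad <- which(tab$end <= tab$start)
  if (length(bad)) stop("malformed BED interval at line ", bad[1])
  tab[c("locus_id", "chrom", "start", "end",
        intersect(c("repeat_unit", "reference_repeat_count"), names(tab)))]
}

#' Write a microsatellite locus BED file
#'
#' @param loci Locus data frame (as from [simulate_locus_histograms()]).
#' @param path Output path.
#' @export
write_bed <- function(loci, path) {
  cols <- c("chrom", "start", "end", "locus_id")
  extra <- intersect(c("repeat_unit", "reference_repeat_count"),
                     names(loci))
  utils::write.table(loci[c(cols, extra)], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write allele-length histogram tables
#'
#' TSV with header `sample_id  locus_id  repeat_length  read_count`.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_histograms <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "locus_id", "repeat_length", "read_count")
  if (!all(need %in% names(tab)))
    stop("histogram TSV must have columns: ", paste(need, collapse = ", "))
  if (any(tab$read_count < 0)) stop("negative read counts")
  tab
}

#' @rdname read_histograms
#' @param histograms Histogram data frame.
#' @export
write_histograms <- function(histograms, path) {
  utils::write.table(histograms, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.MAF_COLS <- c("sample_id", "chrom", "pos", "ref", "alt", "variant_type",
               "depth", "alt_reads", "mapq", "haplotype_score",
               "cohort_af", "db_hits", "cosmic_count", "multiallelic",
               "poorly_sequenced_site", "gene")

#' Read / write MAF-like mutation tables
#'
#' Tab-separated with a header; positions are 1-based (MAF/VCF
#' convention). Missing annotation columns are filled with `NA`.
#'
#' @param path File path.
#' @return Mutation data frame.
#' @export
read_maf <- function(path) {
  hdr <- names(utils::read.delim(path, nrows = 1, check.names = FALSE))
  chr_cols <- intersect(c("sample_id", "chrom", "ref", "alt",
                          "variant_type", "gene", "channel"), hdr)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = stats::setNames(
                             rep("character", length(chr_cols)), chr_cols))
  need <- c("sample_id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(tab)))
    stop("mutation TSV must have columns: ", paste(need, collapse = ", "))
  for (col in .MAF_COLS)
    if (!col %in% names(tab)) tab[[col]] <- NA
  if (!"variant_type" %in% names(tab) || all(is.na(tab$variant_type)))
    tab$variant_type <- ifelse(nchar(tab$ref) == 1 & nchar(tab$alt) == 1,
                               "SNV", "indel")
  tab
}

#' @rdname read_maf
#' @param mutations Mutation data frame.
#' @export
write_maf <- function(mutations, path) {
  cols <- intersect(c(.MAF_COLS, "channel"), names(mutations))
  utils::write.table(mutations[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a minimal VCF into the mutation-table schema
#'
#' Parses `#CHROM POS ID REF ALT QUAL FILTER INFO` records. Recognised
#' INFO keys: `SAMPLE`, `DP` (depth), `AD` (alt reads), `MQ`, `HS`
#' (haplotype score), `CAF` (cohort allele frequency), `DBH` (population
#' database hits), `COSMIC` (occurrence count). Positions stay 1-based.
#'
#' @param path VCF file.
#' @return Mutation data frame in the MAF-like schema.
#' @export
read_vcf_minimal <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0) stop("VCF contains no records")
  fields <- strsplit(body, "\t")
  bad <- which(vapply(fields, length, integer(1)) < 8)
  if (length(bad)) stop("malformed VCF line ", bad[1])
  info_get <- function(info, key, default = NA) {
    kv <- strsplit(strsplit(info, ";")[[1]], "=")
    hit <- vapply(kv, function(x) x[1] == key, logical(1))
    if (!any(hit)) return(default)
    kv[[which(hit)[1]]][2]
  }
  rec <- lapply(fields, function(f) {
    info <- f[8]
    data.frame(sample_id = info_get(info, "SAMPLE", "unknown"),
               chrom = f[1], pos = as.integer(f[2]), ref = f[4],
               alt = f[5],
               variant_type = if (nchar(f[4]) == 1 && nchar(f[5]) == 1)
                 "SNV" else "indel",
               depth = as.numeric(info_get(info, "DP")),
               alt_reads = as.numeric(info_get(info, "AD")),
               mapq = as.numeric(info_get(info, "MQ")),
               haplotype_score = as.numeric(info_get(info, "HS")),
               cohort_af = as.numeric(info_get(info, "CAF")),
               db_hits = as.integer(info_get(info, "DBH")),
               cosmic_count = as.integer(info_get(info, "COSMIC")),
               multiallelic = grepl(",", f[5]),
               poorly_sequenced_site = FALSE, gene = "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rec)
}

#' Read / write TSV matrices (genes x samples and the like)
#'
#' @param path File path.
#' @return Numeric matrix with row and column names.
#' @export
read_tsv_matrix <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_tsv_matrix
#' @param m Matrix.
#' @param id_col Name of the leading identifier column.
#' @export
write_tsv_matrix <- function(m, path, id_col = "id") {
  tab <- data.frame(rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  colnames(tab) <- c(id_col, colnames(m))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
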