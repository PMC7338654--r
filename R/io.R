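#' Write a features-x-samples matrix as TSV
#'
#' First column `feature_id`, then one column per sample; deterministic row
#' order (as given).
#' @param mat Numeric matrix with row and column names.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(feature_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a features-x-samples TSV written by [write_expression_tsv()]
#' @param path Input path.
#' @return Numeric matrix.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read a methylation TSV (cpg_id, chrom, pos, one column per sample)
#' @param path Input path.
#' @return A [methylation_table()].
#' @export
read_methylation_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  beta <- as.matrix(df[, -(1:3), drop = FALSE])
  rownames(beta) <- df$cpg_id
  methylation_table(df[, 1:3], beta)
}

#' Write a methylation table as TSV
#' @param meth A [methylation_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_methylation_tsv <- function(meth, path) {
  df <- cbind(meth$sites, as.data.frame(meth$beta, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read CNV segments (BED+2: chrom, start, end, kind, q_value; no header)
#' @param path Input path.
#' @return Data frame `chrom`, `start`, `end`, `kind`, `q_value`.
#' @export
read_cnv_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("chrom", "start", "end", "kind", "q_value")
  df
}

#' Read ChIP peaks (BED+1: chrom, start, end, signal; no header)
#' @param path Input path.
#' @return Data frame `chrom`, `start`, `end`, `signal`.
#' @export
read_peaks_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("chrom", "start", "end", "signal")
  df
}

#' Read a bedGraph-like score track (chrom, start, end, score; no header)
#' @param path Input path.
#' @return Data frame `chrom`, `start`, `end`, `score`.
#' @export
read_bedgraph <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("chrom", "start", "end", "score")
  df
}

#' Read a survival cohort TSV (patient_id, time_days, event, gene columns)
#' @param path Input path.
#' @return Data frame.
#' @export
read_survival_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read transcript sequences from FASTA
#' @param path Input path.
#' @return Named character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ss), names(ss))
}

#' Write named sequences as FASTA
#' @param sequences Named character vector.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta_sequences <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}
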