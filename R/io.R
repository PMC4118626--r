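# file-format helpers (FASTA/FASTQ via Biostrings, GFF3/BED via rtracklayer)

#' Read a FASTQ file (Phred+33)
#'
#' @param path FASTQ file.
#' @return A list with character vectors `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  # Biostrings warns about dropping its own metadata columns here; benign
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  list(id = names(x),
       seq = as.character(x),
       qual = as.character(Biostrings::quality(x)))
}

#' Write a FASTQ file (Phred+33)
#'
#' @param id,seq,qual Parallel character vectors.
#' @param path Output file.
#' @export
write_fastq <- function(id, seq, qual, path) {
  stopifnot(length(id) == length(seq), length(seq) == length(qual))
  lines <- character(4L * length(id))
  idx <- seq_along(id)
  lines[4L * idx - 3L] <- paste0("@", id)
  lines[4L * idx - 2L] <- seq
  lines[4L * idx - 1L] <- "+"
  lines[4L * idx] <- qual
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector (DNA space)
#' @param path FASTA file.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(to_dna(as.character(x)), names(x))
}

#' Write named sequences to FASTA
#' @param seqs Named character vector.
#' @param path Output file.
#' @param rna Write in RNA space (U) if TRUE.
#' @export
write_fasta <- function(seqs, path, rna = FALSE) {
  s <- if (rna) to_rna(seqs) else to_dna(seqs)
  x <- Biostrings::BStringSet(s)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# write a minimal GFF3 from a feature data.frame
# (seqid, source, type, start, end, strand, ID, Parent) -- 1-based inclusive
write_gff3 <- function(feat, path) {
  attrs <- vapply(seq_len(nrow(feat)), function(i) {
    a <- paste0("ID=", feat$ID[i])
    if (!is.na(feat$Parent[i]) && nzchar(feat$Parent[i]))
      a <- paste0(a, ";Parent=", feat$Parent[i])
    a
  }, character(1))
  lines <- c("##gff-version 3",
             paste(feat$seqid, feat$source %||% "saltmir", feat$type,
                   feat$start, feat$end, ".", feat$strand, ".", attrs,
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

# write a BED file from a data.frame (chrom, start 0-based, end, name)
write_bed <- function(bed, path) {
  lines <- paste(bed$chrom, bed$start, bed$end, bed$name,
                 0L, bed$strand %||% "+", sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
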