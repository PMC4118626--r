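#' Default read-cleaning parameters
#'
#' @param min_len,max_len Retained insert length range (closed interval,
#'   default 18--30 nt).
#' @param adapter_k Length of the adapter seed searched in the read
#'   (default 8).
#' @param min_mean_q Minimum mean Phred quality (default 20).
#' @param max_n Maximum number of N bases tolerated (default 2).
#' @param polya_frac Insert fraction of A at or above which it is a polyA
#'   artifact (default 0.8).
#' @param polya_run Length of a consecutive A run that flags polyA
#'   (default 10).
#' @param trim Locate and trim the 3' adapter (default TRUE; set FALSE for
#'   input that is already adapter-free, e.g. re-cleaning clean inserts).
#' @return A named list of parameters.
#' @export
clean_params <- function(min_len = 18L, max_len = 30L, adapter_k = 8L,
                         min_mean_q = 20, max_n = 2L,
                         polya_frac = 0.8, polya_run = 10L, trim = TRUE) {
  list(min_len = as.integer(min_len), max_len = as.integer(max_len),
       adapter_k = as.integer(adapter_k), min_mean_q = min_mean_q,
       max_n = as.integer(max_n), polya_frac = polya_frac,
       polya_run = as.integer(polya_run), trim = isTRUE(trim))
}

#' Clean a small RNA library
#'
#' Converts raw reads into adapter-trimmed inserts, removing contaminants in
#' a fixed, mutually exclusive order: low-quality reads, 5' adapter
#' contaminants, reads without a 3' adapter (adapter null), reads whose
#' trimmed insert is empty (insert null), polyA artifacts, and inserts
#' outside the retained length range. The 3' adapter is located by exact
#' match of its first `adapter_k` bases at any position; a match at
#' position 1 means the read carries no insert.
#'
#' @param fastq Path to a FASTQ file (Phred+33), or a list with character
#'   vectors `seq` and `qual` (parallel, qual may be NULL to skip the
#'   quality filter).
#' @param adapter3 3' adapter sequence (required, non-empty).
#' @param adapter5 5' adapter sequence (required, non-empty).
#' @param params See [clean_params()].
#' @return A list with `seqs` (character vector of clean inserts, DNA
#'   space) and `stats`, an object of class `clean_stats` with fields
#'   `raw_reads`, `removed` (named counts), `clean_reads` and
#'   `length_histogram`.
#' @export
clean_reads <- function(fastq, adapter3, adapter5, params = clean_params()) {
  stopifnot(nzchar(adapter3), nzchar(adapter5))
  if (is.character(fastq) && length(fastq) == 1L) {
    rec <- read_fastq(fastq)
  } else if (is.list(fastq)) {
    rec <- list(seq = as.character(fastq$seq), qual = fastq$qual)
  } else stopf("fastq must be a file path or a list(seq=, qual=)")
  seqs <- to_dna(rec$seq)
  n <- length(seqs)
  removed <- c(low_quality = 0L, adapter5_contaminant = 0L, adapter_null = 0L,
               insert_null = 0L, polyA = 0L, length_out_of_range = 0L)
  if (n == 0L) {
    stats <- structure(list(raw_reads = 0L, removed = removed, clean_reads = 0L,
                            length_histogram = integer(0)), class = "clean_stats")
    return(list(seqs = character(0), stats = stats))
  }
  alive <- rep(TRUE, n)

  # 1. low quality: mean Phred < min_mean_q or too many N
  if (!is.null(rec$qual)) {
    qint <- lapply(rec$qual, function(q) utf8ToInt(q) - 33L)
    meanq <- vapply(qint, function(v) if (length(v)) mean(v) else 0, numeric(1))
    nN <- vapply(gregexpr("N", seqs, fixed = TRUE),
                 function(m) sum(m > 0L), integer(1))
    bad <- alive & (meanq < params$min_mean_q | nN > params$max_n)
    removed["low_quality"] <- sum(bad); alive[bad] <- FALSE
  }

  if (isTRUE(params$trim)) {
    # 2. 5' adapter contaminants: read begins with the adapter5 seed
    seed5 <- substr(to_dna(adapter5), 1L, params$adapter_k)
    bad <- alive & startsWith(seqs, seed5)
    removed["adapter5_contaminant"] <- sum(bad); alive[bad] <- FALSE

    # 3./4. locate the 3' adapter seed
    seed3 <- substr(to_dna(adapter3), 1L, params$adapter_k)
    pos <- regexpr(seed3, seqs, fixed = TRUE)
    bad <- alive & pos < 0L
    removed["adapter_null"] <- sum(bad); alive[bad] <- FALSE
    bad <- alive & pos == 1L
    removed["insert_null"] <- sum(bad); alive[bad] <- FALSE
    inserts <- substr(seqs, 1L, pmax(pos - 1L, 0L))
  } else {
    inserts <- seqs
  }

  # 5. polyA artifacts
  nA <- nchar(inserts) - nchar(gsub("A", "", inserts, fixed = TRUE))
  run <- strrep("A", params$polya_run)
  bad <- alive & (nA / pmax(nchar(inserts), 1L) >= params$polya_frac |
                    grepl(run, inserts, fixed = TRUE))
  removed["polyA"] <- sum(bad); alive[bad] <- FALSE

  # 6. length filter (closed interval [min_len, max_len])
  len <- nchar(inserts)
  bad <- alive & (len < params$min_len | len > params$max_len)
  removed["length_out_of_range"] <- sum(bad); alive[bad] <- FALSE

  clean <- inserts[alive]
  hist <- table(factor(nchar(clean), levels = params$min_len:params$max_len))
  stats <- structure(list(raw_reads = n, removed = removed,
                          clean_reads = length(clean),
                          length_histogram = as.integer(hist) |>
                            setNames(names(hist))),
                     class = "clean_stats")
  list(seqs = clean, stats = stats)
}

#' @export
print.clean_stats <- function(x, ...) {
  cat(sprintf("clean_stats: %d raw -> %d clean\n", x$raw_reads, x$clean_reads))
  print(x$removed)
  invisible(x)
}

#' Collapse clean reads into unique tags with per-library counts
#'
#' @param libraries A named list; each element is the character vector of
#'   clean insert sequences of one library.
#' @return A data.frame of class `srna_tags`: column `sequence` plus one
#'   integer count column per library.
#' @export
collapse_tags <- function(libraries) {
  stopifnot(is.list(libraries), !is.null(names(libraries)))
  all_seqs <- sort(unique(unlist(lapply(libraries, unique), use.names = FALSE)))
  tags <- data.frame(sequence = all_seqs, stringsAsFactors = FALSE)
  for (lib in names(libraries)) {
    tags[[lib]] <- tabulate(match(libraries[[lib]], all_seqs),
                            nbins = length(all_seqs))
  }
  class(tags) <- c("srna_tags", "data.frame")
  tags
}

# library count columns of a tag table
tag_libs <- function(tags) setdiff(colnames(tags), "sequence")

#' Percentage table for common and library-specific tags
#'
#' Builds the standard four-row (total / common / A-specific / B-specific)
#' summary from raw unique-tag and total-read counts, with percentages of
#' the respective totals rounded to 2 decimals.
#'
#' @param unique_counts,total_counts Named numeric vectors with elements
#'   `common`, `a_specific`, `b_specific`.
#' @param libA,libB Library display names.
#' @return A data.frame with columns class, unique_count, unique_pct,
#'   total_count, total_pct.
#' @export
specificity_percentages <- function(unique_counts, total_counts,
                                    libA = "A", libB = "B") {
  need <- c("common", "a_specific", "b_specific")
  stopifnot(all(need %in% names(unique_counts)),
            all(need %in% names(total_counts)))
  u <- unique_counts[need]; t <- total_counts[need]
  ut <- sum(u); tt <- sum(t)
  data.frame(
    class = c("Total sRNAs", paste(libA, "&", libB),
              paste0(libA, "-specific"), paste0(libB, "-specific")),
    unique_count = c(ut, u[["common"]], u[["a_specific"]], u[["b_specific"]]),
    unique_pct = round(100 * c(ut, u[["common"]], u[["a_specific"]],
                               u[["b_specific"]]) / ut, 2),
    total_count = c(tt, t[["common"]], t[["a_specific"]], t[["b_specific"]]),
    total_pct = round(100 * c(tt, t[["common"]], t[["a_specific"]],
                              t[["b_specific"]]) / tt, 2),
    stringsAsFactors = FALSE)
}

#' Common/specific sequence summary between two libraries
#'
#' Classifies every tag observed in either library as common (count >= 1 in
#' both) or specific to one library, and tabulates unique-tag and
#' total-read counts with percentages.
#'
#' @param tags A tag table from [collapse_tags()].
#' @param libA,libB Library column names.
#' @return See [specificity_percentages()].
#' @export
common_specific_summary <- function(tags, libA, libB) {
  if (!libA %in% colnames(tags)) stopf("unknown library id '%s'", libA)
  if (!libB %in% colnames(tags)) stopf("unknown library id '%s'", libB)
  a <- tags[[libA]]; b <- tags[[libB]]
  keep <- a > 0L | b > 0L
  a <- a[keep]; b <- b[keep]
  common <- a > 0L & b > 0L
  u <- c(common = sum(common), a_specific = sum(a > 0L & !common),
         b_specific = sum(b > 0L & !common))
  t <- c(common = sum(a[common]) + sum(b[common]),
         a_specific = sum(a[a > 0L & !common]),
         b_specific = sum(b[b > 0L & !common]))
  specificity_percentages(u, t, libA, libB)
}
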