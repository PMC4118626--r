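#' Predict miRNA targets by mismatch-limited complementarity
#'
#' Scans each miRNA against every transcript at every gapless offset,
#' scoring the antiparallel duplex (miRNA 5'->3' against the site read
#' 3'->5' on the transcript sense strand) with plant-style
#' position-weighted penalties: a mismatch costs `mm_penalty` (1.0), a G:U
#' wobble `gu_penalty` (0.5), penalties are multiplied by `seed_mult` (2)
#' at miRNA positions `seed_range` (2--13), and a true mismatch at the
#' cleavage-site positions `cleavage_range` (10--11) rejects the site
#' unless `allow_cleavage_mm`. Sites with total penalty at most
#' `max_score` (4, the classic "at most four mismatches" rule) are
#' reported.
#'
#' @param mirnas Named character vector of mature sequences (names are
#'   miRNA ids), or a data.frame with columns `id` and `mature_seq`.
#' @param transcripts Named character vector / `DNAStringSet` / FASTA path.
#' @param max_score Maximum penalty score (default 4.0).
#' @param mm_penalty,gu_penalty,seed_range,seed_mult,cleavage_range,allow_cleavage_mm
#'   Scoring scheme knobs (defaults above).
#' @param strict_hamming If TRUE, G:U wobbles are charged as full
#'   mismatches.
#' @return A data.frame of target sites: `mirna_id`, `transcript_id`,
#'   `site_start` (0-based), `site_end` (exclusive), `mismatches`,
#'   `gu_wobbles`, `score`, sorted by score then coordinates.
#' @export
predict_targets <- function(mirnas, transcripts, max_score = 4.0,
                            mm_penalty = 1.0, gu_penalty = 0.5,
                            seed_range = c(2L, 13L), seed_mult = 2.0,
                            cleavage_range = c(10L, 11L),
                            allow_cleavage_mm = FALSE,
                            strict_hamming = FALSE) {
  if (is.data.frame(mirnas)) mirnas <- setNames(mirnas$mature_seq, mirnas$id)
  if (is.character(transcripts) && length(transcripts) == 1L &&
      file.exists(transcripts) && is.null(names(transcripts)))
    transcripts <- read_fasta(transcripts)
  if (methods::is(transcripts, "XStringSet"))
    transcripts <- setNames(as.character(transcripts), names(transcripts))
  stopifnot(length(transcripts) > 0L, !is.null(names(mirnas)),
            !is.null(names(transcripts)))
  hits <- c_target_scan(to_dna(unname(mirnas)), to_dna(unname(transcripts)),
                        max_score, mm_penalty, gu_penalty,
                        seed_range[1], seed_range[2], seed_mult,
                        cleavage_range[1], cleavage_range[2],
                        allow_cleavage_mm, strict_hamming)
  out <- data.frame(
    mirna_id = names(mirnas)[hits$mirna],
    transcript_id = names(transcripts)[hits$transcript],
    site_start = hits$site_start,
    site_end = hits$site_start + nchar(unname(mirnas))[hits$mirna],
    mismatches = hits$mismatches,
    gu_wobbles = hits$gu_wobbles,
    score = hits$score,
    stringsAsFactors = FALSE)
  out <- out[order(out$score, out$mirna_id, out$transcript_id, out$site_start), ]
  rownames(out) <- NULL
  out
}

#' Per-miRNA target counts
#'
#' Counts distinct targeted transcripts per miRNA (multiple sites on one
#' transcript count once).
#'
#' @param sites Output of [predict_targets()].
#' @return data.frame `mirna_id`, `n_targets`, `n_sites`.
#' @export
target_counts <- function(sites) {
  if (nrow(sites) == 0L)
    return(data.frame(mirna_id = character(0), n_targets = integer(0),
                      n_sites = integer(0)))
  sp <- split(sites, sites$mirna_id)
  out <- data.frame(
    mirna_id = names(sp),
    n_targets = vapply(sp, function(s) length(unique(s$transcript_id)), integer(1)),
    n_sites = vapply(sp, nrow, integer(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Join predicted sites with user-supplied functional annotation
#'
#' Left join of target sites with a two-column TSV mapping transcript ids
#' to functional terms (e.g. GO/KEGG labels exported from an external
#' resource). No enrichment statistic is computed. Duplicate rows for one
#' transcript are concatenated with ';' after deduplication; unannotated
#' transcripts keep empty labels.
#'
#' @param sites Output of [predict_targets()].
#' @param annotation Path to a TSV (columns: transcript_id, terms) or a
#'   data.frame.
#' @return `sites` with an added `terms` column.
#' @export
annotate_targets <- function(sites, annotation) {
  if (is.character(annotation)) {
    lines <- readLines(annotation)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L) {
      ann <- data.frame(transcript_id = character(0), terms = character(0))
    } else {
      parts <- strsplit(lines, "\t", fixed = TRUE)
      bad <- which(lengths(parts) < 2L)
      if (length(bad))
        stopf("malformed annotation TSV at line %d: expected 2 tab-separated columns", bad[1])
      ann <- data.frame(transcript_id = vapply(parts, `[[`, "", 1L),
                        terms = vapply(parts, `[[`, "", 2L),
                        stringsAsFactors = FALSE)
    }
  } else ann <- annotation
  if (nrow(ann)) {
    agg <- tapply(ann$terms, ann$transcript_id, function(v)
      paste(unique(unlist(strsplit(v, ";", fixed = TRUE))), collapse = ";"))
  } else agg <- character(0)
  sites$terms <- ifelse(sites$transcript_id %in% names(agg),
                        unname(agg[sites$transcript_id]), "")
  sites
}
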