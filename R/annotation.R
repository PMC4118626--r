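#' Map tags to a genome with perfect matching
#'
#' Finds all zero-mismatch occurrences of each tag on both strands of the
#' genome. A minus-strand hit at `[start, end)` means the reverse
#' complement of the tag equals the forward-strand genome there.
#'
#' @param sequences Character vector of tag sequences (T/U identified).
#' @param genome A named `DNAStringSet` (or named character vector) of
#'   chromosomes.
#' @return A data.frame with columns `tag` (index into `sequences`),
#'   `sequence`, `chrom`, `start` (0-based), `end` (exclusive), `strand`.
#'   Tags absent from the result are unmapped.
#' @export
map_perfect <- function(sequences, genome) {
  if (!methods::is(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(to_dna(genome))
  seqs <- Biostrings::DNAStringSet(to_dna(sequences))
  out <- list()
  for (strand in c("+", "-")) {
    pats <- if (strand == "+") seqs else Biostrings::reverseComplement(seqs)
    groups <- split(seq_along(pats), Biostrings::width(pats))
    for (grp in groups) {
      if (length(grp) == 0L) next
      pd <- Biostrings::PDict(pats[grp])
      for (chrom in names(genome)) {
        m <- Biostrings::matchPDict(pd, genome[[chrom]])
        counts <- S4Vectors::elementNROWS(m)
        if (sum(counts) == 0L) next
        hit_pat <- rep(grp, counts)
        r <- unlist(m)
        out[[length(out) + 1L]] <- data.frame(
          tag = hit_pat,
          chrom = chrom,
          start = BiocGenerics::start(r) - 1L,
          end = BiocGenerics::end(r),
          strand = strand,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(tag = integer(0), sequence = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  hits <- do.call(rbind, out)
  hits$sequence <- as.character(sequences)[hits$tag]
  hits <- hits[order(hits$tag, hits$chrom, hits$start, hits$strand), ]
  rownames(hits) <- NULL
  hits[, c("tag", "sequence", "chrom", "start", "end", "strand")]
}

#' Match tags against reference sequences allowing mismatches
#'
#' Slides each tag along each reference with full overlap (gapless) and
#' reports references whose best-window Hamming distance is at most
#' `max_mm`. T and U are identified. Tags longer than a reference have no
#' alignment window against it.
#'
#' @param sequences Character vector of tags.
#' @param refs Named character vector (or `XStringSet`) of references.
#' @param max_mm Maximum Hamming distance (default 2).
#' @return A data.frame `tag` (index), `sequence`, `ref_id`, `mismatches`,
#'   `offset` (0-based best window start), sorted by tag, then distance,
#'   then reference id.
#' @export
match_with_mismatches <- function(sequences, refs, max_mm = 2L) {
  if (methods::is(refs, "XStringSet")) refs <- setNames(as.character(refs), names(refs))
  stopifnot(!is.null(names(refs)))
  hits <- c_match_many(as.character(sequences), unname(refs), as.integer(max_mm))
  hits$ref_id <- names(refs)[hits$ref]
  hits$sequence <- as.character(sequences)[hits$tag]
  hits <- hits[order(hits$tag, hits$mismatches, hits$ref_id), ]
  rownames(hits) <- NULL
  hits[, c("tag", "sequence", "ref_id", "mismatches", "offset")]
}

# derive intron ranges from exon features of the same parent transcript
derive_introns <- function(exons) {
  if (length(exons) == 0L) return(GenomicRanges::GRanges())
  parent <- S4Vectors::mcols(exons)$Parent
  if (methods::is(parent, "CharacterList"))
    parent <- vapply(parent, function(p) if (length(p)) p[[1]] else NA_character_,
                     character(1))
  parts <- split(exons, parent)
  introns <- lapply(parts, function(ex) {
    if (length(ex) < 2L) return(GenomicRanges::GRanges())
    GenomicRanges::setdiff(range(ex), ex)
  })
  out <- suppressWarnings(do.call(c, unname(introns)))
  out
}

#' Annotation category priority order
#' @export
annotation_priority <- function() {
  c("known_miRNA", "ncRNA", "repeat", "exon_sense", "exon_antisense",
    "intron_sense", "intron_antisense", "unknown")
}

#' Assign one annotation category to every tag
#'
#' Tags are mapped to the genome (perfect match only); unmapped tags get
#' category `unmapped` and are excluded downstream. Mapped tags receive
#' exactly one category by winner-takes-all priority (configurable,
#' default `known_miRNA > ncRNA > repeat > exon_sense > exon_antisense >
#' intron_sense > intron_antisense > unknown`). Known-miRNA membership is
#' sequence-level (at most `max_mm_mirna` mismatches against the mature
#' reference); ncRNA membership is an exact substring of the ncRNA
#' reference; repeat/exon/intron require at least 1 bp genomic overlap,
#' with exon/intron split by strand. Multi-locus tags take the best
#' category over all their hits and are counted once.
#'
#' @param tags A tag table from [collapse_tags()] (or character vector).
#' @param genome Named `DNAStringSet`/character of chromosomes.
#' @param mature_ref Named character vector of mature miRNA references.
#' @param ncrna_ref Named character vector of non-coding RNA references.
#' @param gff Path to a GFF3 file with exon features, or a `GRanges`.
#' @param repeat_bed Path to a BED file of repeats, or a `GRanges`, or NULL.
#' @param max_mm_mirna Mismatch allowance vs the mature reference (default 2).
#' @param priority Category priority order.
#' @return A list: `annotation` (data.frame sequence, category), `hits`
#'   (the perfect-match hit table).
#' @export
annotate_tags <- function(tags, genome, mature_ref, ncrna_ref, gff,
                          repeat_bed = NULL, max_mm_mirna = 2L,
                          priority = annotation_priority()) {
  seqs <- if (is.data.frame(tags)) tags$sequence else as.character(tags)
  hits <- map_perfect(seqs, genome)
  mapped <- sort(unique(hits$tag))
  category <- rep("unmapped", length(seqs))

  ranked <- function(cat) match(cat, priority)
  best <- rep(ranked("unknown"), length(seqs))
  best[-mapped] <- NA_integer_

  consider <- function(idx, cat) {
    r <- ranked(cat)
    sel <- idx[!is.na(best[idx]) & best[idx] > r]
    best[sel] <<- r
  }

  if (length(mapped)) {
    # sequence-level classes
    if (length(mature_ref)) {
      mm <- match_with_mismatches(seqs[mapped], mature_ref, max_mm_mirna)
      consider(mapped[unique(mm$tag)], "known_miRNA")
    }
    if (length(ncrna_ref)) {
      nc <- match_with_mismatches(seqs[mapped], ncrna_ref, 0L)
      consider(mapped[unique(nc$tag)], "ncRNA")
    }
    # genomic-overlap classes
    gr <- GenomicRanges::GRanges(hits$chrom,
                                 IRanges::IRanges(hits$start + 1L, hits$end),
                                 strand = hits$strand)
    overlap_tags <- function(subject, same_strand = NA) {
      if (length(subject) == 0L) return(integer(0))
      ov <- GenomicRanges::findOverlaps(gr, subject, minoverlap = 1L,
                                        ignore.strand = TRUE)
      qh <- S4Vectors::queryHits(ov)
      if (!is.na(same_strand)) {
        ss <- as.character(GenomicRanges::strand(gr))[qh] ==
          as.character(GenomicRanges::strand(subject))[S4Vectors::subjectHits(ov)]
        qh <- qh[if (same_strand) ss else !ss]
      }
      unique(hits$tag[qh])
    }
    if (!is.null(repeat_bed)) {
      rep_gr <- if (methods::is(repeat_bed, "GRanges")) repeat_bed
                else rtracklayer::import(repeat_bed, format = "BED")
      consider(overlap_tags(rep_gr), "repeat")
    }
    if (!is.null(gff)) {
      feats <- if (methods::is(gff, "GRanges")) gff
               else rtracklayer::import(gff, format = "GFF3")
      exons <- feats[S4Vectors::mcols(feats)$type == "exon"]
      introns <- derive_introns(exons)
      consider(overlap_tags(exons, TRUE), "exon_sense")
      consider(overlap_tags(exons, FALSE), "exon_antisense")
      if (length(introns)) {
        consider(overlap_tags(introns, TRUE), "intron_sense")
        consider(overlap_tags(introns, FALSE), "intron_antisense")
      }
    }
    category[mapped] <- priority[best[mapped]]
  }
  list(annotation = data.frame(sequence = seqs, category = category,
                               stringsAsFactors = FALSE),
       hits = hits)
}

#' Per-library category distribution
#'
#' Tallies annotation categories by total reads and by unique tags for each
#' library, the category-distribution summary of a small RNA study.
#'
#' @param annotation The `annotation` element from [annotate_tags()].
#' @param tags The matching tag table.
#' @return A data.frame: category, library, reads, unique_tags, plus
#'   percentage columns over mapped totals.
#' @export
category_summary <- function(annotation, tags) {
  stopifnot(identical(annotation$sequence, tags$sequence))
  libs <- tag_libs(tags)
  cats <- c(annotation_priority(), "unmapped")
  out <- do.call(rbind, lapply(libs, function(lib) {
    cnt <- tags[[lib]]
    reads <- vapply(cats, function(cc)
      sum(cnt[annotation$category == cc]), numeric(1))
    uniq <- vapply(cats, function(cc)
      sum(annotation$category == cc & cnt > 0L), numeric(1))
    data.frame(category = cats, library = lib, reads = reads,
               unique_tags = uniq, stringsAsFactors = FALSE)
  }))
  mapped_tot <- tapply(out$reads[out$category != "unmapped"],
                       out$library[out$category != "unmapped"], sum)
  out$reads_pct <- ifelse(out$category == "unmapped", NA,
                          round(100 * out$reads /
                                  as.numeric(mapped_tot[out$library]), 2))
  rownames(out) <- NULL
  out
}
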