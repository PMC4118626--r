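#' Parameters for miRNA discovery
#'
#' @param min_reads Minimum total read count across libraries (default 5;
#'   lower-expressed candidates are removed).
#' @param max_mm Mismatch allowance against the mature reference (default 2).
#' @param min_stem_pairs,mfe_max Hairpin acceptance thresholds, see
#'   [is_hairpin()].
#' @param flanks Precursor excision flanks (nt, each side) tried around a
#'   candidate mature locus (default 30/60/100/150).
#' @param mature_len Length range of a novel mature candidate.
#' @param max_unpaired_mature Maximum unpaired mature bases in the duplex.
#' @param require_star Demand star-read support for novel calls (default
#'   TRUE; star detection is robust evidence of true biogenesis).
#' @param star_overhang Accepted star 3' overhang range (canonical 2 nt,
#'   tolerance for 1 nt Dicer wobble).
#' @export
discovery_params <- function(min_reads = 5L, max_mm = 2L,
                             min_stem_pairs = 16L, mfe_max = -18,
                             flanks = c(30L, 60L, 100L, 150L),
                             mature_len = c(20L, 24L),
                             max_unpaired_mature = 4L,
                             require_star = TRUE,
                             star_overhang = c(1L, 3L)) {
  list(min_reads = min_reads, max_mm = max_mm,
       min_stem_pairs = min_stem_pairs, mfe_max = mfe_max,
       flanks = flanks, mature_len = mature_len,
       max_unpaired_mature = max_unpaired_mature,
       require_star = require_star, star_overhang = star_overhang)
}

# family token from a reference name, e.g. "ptc-miR156a" -> "miR156"
mirna_family <- function(ids) {
  unname(vapply(seq_along(ids), function(i) {
    m <- regexpr("miR[0-9]+", ids[i])
    if (m > 0) regmatches(ids[i], m) else ids[i]
  }, character(1)))
}

# locate star-supporting tags on the opposite precursor arm
find_star <- function(fold, mature_range, tag_set, params) {
  pt <- pair_table(fold$structure)
  mi <- mature_range[1]:mature_range[2]
  partners <- pt[mi]; partners <- partners[partners > 0L]
  if (length(partners) == 0L) return(NULL)
  pmax <- max(partners)
  pseq <- to_dna(fold$sequence)
  for (se in (pmax + params$star_overhang[1]):(pmax + params$star_overhang[2])) {
    for (L in 18L:26L) {
      ss <- se - L + 1L
      if (ss < 1L || se > nchar(pseq)) next
      cand <- substr(pseq, ss, se)
      if (!cand %in% tag_set) next
      dc <- duplex_check(fold, mature_range, c(ss, se))
      if (isTRUE(dc$opposite_arms) && dc$paired_fraction >= 0.5 &&
          !is.na(dc$overhang3) &&
          dc$overhang3 >= params$star_overhang[1] &&
          dc$overhang3 <= params$star_overhang[2]) {
        return(list(star_seq = cand, star_range = c(ss, se), check = dc))
      }
    }
  }
  NULL
}

# which arm a range sits on, given a hairpin's terminal loop
arm_of <- function(loop, range) {
  if (range[2] < loop[1]) "5p" else if (range[1] > loop[2]) "3p" else NA_character_
}

new_record <- function(id, class, family, mature, star, precursor, locus,
                       arm, mfe, counts) {
  structure(list(id = id, class = class, family = family,
                 mature_seq = to_rna(mature),
                 star_seq = if (is.null(star)) NA_character_ else to_rna(star),
                 precursor_seq = to_rna(precursor),
                 precursor_locus = locus, arm = arm, mfe = mfe,
                 first_nt = substr(to_rna(mature), 1L, 1L),
                 counts = counts[counts >= 1L]),
            class = "mirna_record")
}

#' @export
print.mirna_record <- function(x, ...) {
  cat(sprintf("%s [%s%s] %s arm=%s mfe=%.1f reads=%d\n", x$id, x$class,
              if (!is.na(x$family)) paste0(":", x$family) else "",
              x$mature_seq, x$arm, x$mfe, sum(x$counts)))
  invisible(x)
}

#' Identify conserved miRNAs by reference-guided matching
#'
#' Tags matching a mature reference within `max_mm` mismatches are grouped
#' by their best reference hit (lowest mismatch count, ties by reference
#' name). A group becomes a conserved miRNA record when its total reads
#' reach `min_reads` and its precursor (the reference precursor of the same
#' name, else a genomic window around the most abundant tag's locus) folds
#' into a qualifying hairpin. Star support is searched on the opposite arm.
#'
#' @param tags Tag table from [collapse_tags()].
#' @param mature_ref Named character vector of mature reference sequences.
#' @param precursor_ref Named character vector of precursor references
#'   (names matching `mature_ref`), or NULL.
#' @param genome Genome (for the fallback precursor window), or NULL.
#' @param params See [discovery_params()].
#' @return A list of `mirna_record` objects (class `conserved`).
#' @export
call_conserved <- function(tags, mature_ref, precursor_ref = NULL,
                           genome = NULL, params = discovery_params()) {
  libs <- tag_libs(tags)
  mm <- match_with_mismatches(tags$sequence, mature_ref, params$max_mm)
  if (nrow(mm) == 0L) return(list())
  # best reference per tag: rows are sorted by tag, mismatches, ref_id
  best <- mm[!duplicated(mm$tag), ]
  tag_set <- tags$sequence
  totalv <- rowSums(as.matrix(tags[, libs, drop = FALSE]))
  records <- list()
  for (ref in sort(unique(best$ref_id))) {
    members <- best$tag[best$ref_id == ref]
    counts <- vapply(libs, function(l) sum(tags[[l]][members]), numeric(1))
    if (sum(counts) < params$min_reads) next
    # representative mature: most abundant member tag
    tot <- totalv[members]
    mature <- tags$sequence[members[order(-tot, tags$sequence[members])][1]]
    # precursor sequence
    prec <- NULL
    if (!is.null(precursor_ref) && ref %in% names(precursor_ref)) {
      prec <- precursor_ref[[ref]]
    } else if (!is.null(genome)) {
      h <- map_perfect(mature, genome)
      if (nrow(h)) {
        h <- h[1, ]
        chrlen <- nchar(as.character(genome[[h$chrom]]))
        a <- max(1L, h$start + 1L - 150L); b <- min(chrlen, h$end + 150L)
        prec <- substr(as.character(genome[[h$chrom]]), a, b)
        if (h$strand == "-") prec <- revcomp(prec)
      }
    }
    if (is.null(prec)) {
      warning(sprintf("no precursor available for %s; record skipped", ref))
      next
    }
    fold <- rna_fold(prec)
    hp <- is_hairpin(fold, params$min_stem_pairs, params$mfe_max)
    if (!hp$is_hairpin) next
    # locate the mature on the precursor
    loc <- match_with_mismatches(mature, setNames(to_dna(prec), "p"), params$max_mm)
    if (nrow(loc) == 0L) next
    mrange <- c(loc$offset[1] + 1L, loc$offset[1] + nchar(mature))
    arm <- arm_of(hp$loop, mrange)
    if (is.na(arm)) next
    star <- find_star(fold, mrange, tag_set, params)
    locus <- {
      h <- if (!is.null(genome)) map_perfect(mature, genome) else
        data.frame()
      if (nrow(h)) h[1, c("chrom", "start", "end", "strand")] else NULL
    }
    records[[length(records) + 1L]] <-
      new_record(id = paste0("peu-", sub("^[a-z]{3,4}-", "", ref)),
                 class = "conserved",
                 family = mirna_family(ref), mature = mature,
                 star = if (is.null(star)) NULL else star$star_seq,
                 precursor = prec, locus = locus, arm = arm,
                 mfe = fold$mfe, counts = counts)
  }
  records
}

#' Identify novel miRNAs from unannotated genome-mapped tags
#'
#' Genome-guided (Mireap-style) discovery: each unannotated tag with
#' sufficient expression and mature-like length is treated as a candidate
#' mature; genomic windows with increasing flanks are excised around each
#' of its loci and folded, and the minimum-MFE window that passes the
#' hairpin criteria -- with the mature on a single arm, a bounded number of
#' unpaired mature bases, and (by default) a star-supporting tag on the
#' opposite arm with a 2-nt 3' overhang -- yields a novel record. Loci
#' sharing a mature sequence are deduplicated.
#'
#' @param tags Tag table.
#' @param annotation Annotation data.frame from [annotate_tags()].
#' @param genome Named `DNAStringSet`/character of chromosomes.
#' @param params See [discovery_params()].
#' @param hits Optional precomputed perfect-match hit table.
#' @param exclude_loci Optional data.frame (chrom, start, end) of loci --
#'   typically conserved precursor loci -- whose overlapping candidates are
#'   skipped. Candidates are processed in decreasing abundance and a locus
#'   yields at most one record, so star reads of an already-called hairpin
#'   do not produce a duplicate call.
#' @return A list of `mirna_record` objects (class `novel`).
#' @export
call_novel <- function(tags, annotation, genome, params = discovery_params(),
                       hits = NULL, exclude_loci = NULL) {
  stopifnot(identical(annotation$sequence, tags$sequence))
  if (!methods::is(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(to_dna(genome))
  libs <- tag_libs(tags)
  total <- rowSums(as.matrix(tags[, libs, drop = FALSE]))
  len <- nchar(tags$sequence)
  cand <- which(annotation$category == "unknown" &
                  total >= params$min_reads &
                  len >= params$mature_len[1] & len <= params$mature_len[2])
  if (length(cand) == 0L) return(list())
  cand <- cand[order(-total[cand], tags$sequence[cand])]
  if (is.null(hits)) hits <- map_perfect(tags$sequence[cand], genome)
  else hits <- hits[hits$sequence %in% tags$sequence[cand], ]
  tag_set <- tags$sequence
  records <- list()
  seen_mature <- character(0)
  called_loci <- if (is.null(exclude_loci))
    data.frame(chrom = character(0), start = integer(0), end = integer(0)) else
      exclude_loci[, c("chrom", "start", "end")]
  overlaps_called <- function(h) {
    any(called_loci$chrom == h$chrom &
          called_loci$start < h$end & h$start < called_loci$end)
  }
  for (ci in cand) {
    mseq <- tags$sequence[ci]
    h <- hits[hits$sequence == mseq, , drop = FALSE]
    if (nrow(h) == 0L) next
    keep <- !vapply(seq_len(nrow(h)), function(r) overlaps_called(h[r, ]),
                    logical(1))
    h <- h[keep, , drop = FALSE]
    if (nrow(h) == 0L) next
    if (nrow(h) > 5L) h <- h[1:5, ]             # cap multi-locus search
    best <- NULL
    for (r in seq_len(nrow(h))) {
      chrom <- h$chrom[r]
      chrseq <- as.character(genome[[chrom]])
      chrlen <- nchar(chrseq)
      for (f in params$flanks) {
        a <- max(1L, h$start[r] + 1L - f)
        b <- min(chrlen, h$end[r] + f)
        wseq <- substr(chrseq, a, b)
        if (h$strand[r] == "-") wseq <- revcomp(wseq)
        if (nchar(wseq) < 15L) next
        fold <- rna_fold(wseq)
        hp <- is_hairpin(fold, params$min_stem_pairs, params$mfe_max)
        if (!hp$is_hairpin) next
        # mature position within the window
        moff <- if (h$strand[r] == "+") h$start[r] + 1L - a else b - h$end[r]
        mrange <- c(moff + 1L, moff + nchar(mseq))
        arm <- arm_of(hp$loop, mrange)
        if (is.na(arm)) next
        pt <- pair_table(fold$structure)
        if (sum(pt[mrange[1]:mrange[2]] == 0L) > params$max_unpaired_mature) next
        star <- find_star(fold, mrange, tag_set, params)
        if (params$require_star && is.null(star)) next
        entry <- list(fold = fold, arm = arm, star = star,
                      locus = data.frame(chrom = chrom, start = a - 1L, end = b,
                                         strand = h$strand[r],
                                         stringsAsFactors = FALSE))
        if (is.null(best) || fold$mfe < best$fold$mfe) best <- entry
      }
    }
    if (is.null(best)) next
    if (mseq %in% seen_mature) next            # deduplicate by mature
    seen_mature <- c(seen_mature, mseq)
    called_loci <- rbind(called_loci, best$locus[, c("chrom", "start", "end")])
    counts <- vapply(libs, function(l) as.numeric(tags[[l]][ci]), numeric(1))
    records[[length(records) + 1L]] <-
      new_record(id = sprintf("peu-sM%d", length(records) + 1L),
                 class = "novel", family = NA_character_, mature = mseq,
                 star = if (is.null(best$star)) NULL else best$star$star_seq,
                 precursor = best$fold$sequence, locus = best$locus,
                 arm = best$arm, mfe = best$fold$mfe, counts = counts)
  }
  records
}

#' Conserved miRNA family abundance per library
#'
#' @param records A list of `mirna_record` objects.
#' @param libs Library ids; default: union over records.
#' @return A data.frame family x library with reads and `fraction` of total
#'   conserved reads in that library (fractions sum to 1 per library).
#' @export
family_summary <- function(records, libs = NULL) {
  records <- Filter(function(r) r$class == "conserved", records)
  if (length(records) == 0L) stopf("no conserved records")
  if (is.null(libs))
    libs <- sort(unique(unlist(lapply(records, function(r) names(r$counts)))))
  fams <- vapply(records, function(r) r$family, character(1))
  out <- do.call(rbind, lapply(libs, function(lib) {
    reads <- vapply(records, function(r) {
      v <- r$counts[lib]; if (is.na(v)) 0 else as.numeric(v)
    }, numeric(1))
    agg <- tapply(reads, fams, sum)
    tot <- sum(agg)
    data.frame(family = names(agg), library = lib, reads = as.numeric(agg),
               fraction = if (tot > 0) as.numeric(agg) / tot else 0,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Flatten miRNA records to a catalog table
#'
#' @param records List of `mirna_record`.
#' @param libs Library ids for count columns.
#' @return data.frame, one row per record.
#' @export
mirna_catalog <- function(records, libs = NULL) {
  if (length(records) == 0L)
    return(data.frame(id = character(0), class = character(0)))
  if (is.null(libs))
    libs <- sort(unique(unlist(lapply(records, function(r) names(r$counts)))))
  df <- do.call(rbind, lapply(records, function(r) {
    loc <- r$precursor_locus
    cnt <- setNames(vapply(libs, function(l) {
      v <- r$counts[l]; if (is.na(v)) 0 else as.numeric(v)
    }, numeric(1)), libs)
    cbind(data.frame(id = r$id, class = r$class, family = r$family,
                     mature_seq = r$mature_seq, star_seq = r$star_seq,
                     precursor_seq = r$precursor_seq,
                     chrom = if (is.null(loc)) NA else loc$chrom,
                     start = if (is.null(loc)) NA else loc$start,
                     end = if (is.null(loc)) NA else loc$end,
                     strand = if (is.null(loc)) NA else loc$strand,
                     arm = r$arm, mfe = r$mfe, first_nt = r$first_nt,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(cnt), check.names = FALSE))
  }))
  rownames(df) <- NULL
  df
}
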