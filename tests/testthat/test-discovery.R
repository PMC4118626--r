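test_that("conserved calling applies the minimum-read filter", {
  fx <- small_sim()
  b <- fx$build
  ref1 <- b$mature_ref[1]
  prec1 <- b$precursor_ref[names(ref1)]
  # a tag equal to the reference mature with 100 reads -> record
  tags_hi <- collapse_tags(list(L1 = rep(unname(ref1), 60),
                                L2 = rep(unname(ref1), 40)))
  rec <- call_conserved(tags_hi, ref1, prec1)
  expect_length(rec, 1)
  expect_equal(rec[[1]]$class, "conserved")
  expect_equal(chartr("U", "T", rec[[1]]$mature_seq), unname(ref1))
  expect_equal(rec[[1]]$family, saltmir:::mirna_family(names(ref1)))
  expect_equal(sum(rec[[1]]$counts), 100)
  # 4 total reads -> rejected by the <5 reads rule
  tags_lo <- collapse_tags(list(L1 = rep(unname(ref1), 2),
                                L2 = rep(unname(ref1), 2)))
  expect_length(call_conserved(tags_lo, ref1, prec1), 0)
})

test_that("conserved records carry star evidence from opposite-arm tags", {
  fx <- small_sim()
  b <- fx$build
  tr <- b$truth[b$truth$class == "conserved", ][1, ]
  ref <- b$mature_ref[tr$locus_id]
  prec <- b$precursor_ref[tr$locus_id]
  tags <- collapse_tags(list(L1 = c(rep(unname(ref), 50), rep(tr$star_seq, 8))))
  rec <- call_conserved(tags, ref, prec)
  expect_length(rec, 1)
  expect_equal(chartr("U", "T", rec[[1]]$star_seq), tr$star_seq)
})

test_that("recovery on the synthetic design meets the recall targets", {
  fx <- small_sim()
  b <- fx$build
  cons <- call_conserved(fx$tags, b$mature_ref, b$precursor_ref, b$genome)
  truth_cons <- b$truth[b$truth$class == "conserved", ]
  rec_ids <- vapply(cons, function(r) sub("^peu-", "", r$id), character(1))
  truth_ids <- sub("^[a-z]{3,4}-", "", truth_cons$locus_id)
  expect_gte(sum(truth_ids %in% rec_ids) / nrow(truth_cons), 0.9)
  # every emitted precursor re-passes the hairpin check
  for (r in cons[1:5])
    expect_true(is_hairpin(rna_fold(r$precursor_seq))$is_hairpin)

  cons_loci <- do.call(rbind, lapply(cons, function(r)
    data.frame(chrom = r$precursor_locus$chrom,
               start = r$precursor_locus$start - 160L,
               end = r$precursor_locus$end + 160L)))
  nov <- call_novel(fx$tags, fx$annot$annotation, b$genome,
                    exclude_loci = cons_loci)
  truth_nov <- b$truth[b$truth$class == "novel", ]
  got <- vapply(nov, function(r) chartr("U", "T", r$mature_seq), character(1))
  expect_gte(sum(truth_nov$mature_seq %in% got) / nrow(truth_nov), 0.8)
  # false calls: matures not planted
  expect_lte(sum(!got %in% truth_nov$mature_seq), max(1, 0.05 * length(got)))
  # novel records have no family; all re-pass the hairpin criteria
  for (r in nov) {
    expect_true(is.na(r$family))
    expect_true(is_hairpin(rna_fold(r$precursor_seq))$is_hairpin)
    expect_true(r$first_nt %in% c("A", "C", "G", "U"))
  }
})

test_that("novel calling requires star support when configured", {
  fx <- small_sim()
  b <- fx$build
  tr <- b$truth[b$truth$class == "novel", ][1, ]
  # tags: mature only, no star reads
  tags <- collapse_tags(list(L1 = rep(tr$mature_seq, 30)))
  annot <- data.frame(sequence = tags$sequence, category = "unknown",
                      stringsAsFactors = FALSE)
  expect_length(call_novel(tags, annot, b$genome), 0)
  # with star reads the locus is called
  tags2 <- collapse_tags(list(L1 = c(rep(tr$mature_seq, 30),
                                     rep(tr$star_seq, 5))))
  annot2 <- data.frame(sequence = tags2$sequence, category = "unknown",
                       stringsAsFactors = FALSE)
  rec <- call_novel(tags2, annot2, b$genome)
  expect_gte(length(rec), 1)
  expect_equal(chartr("U", "T", rec[[1]]$mature_seq), tr$mature_seq)
  expect_equal(rec[[1]]$arm, tr$arm)
  # without the star requirement the mature-only locus is callable
  rec2 <- call_novel(tags, annot, b$genome,
                     params = discovery_params(require_star = FALSE))
  expect_gte(length(rec2), 1)
})

test_that("tags annotated as exonic are never called novel", {
  fx <- small_sim()
  b <- fx$build
  ex <- b$truth[b$truth$class == "exon", ][1, ]
  chrseq <- as.character(b$genome[[ex$chrom]])
  tag <- substr(chrseq, ex$start + 20, ex$start + 40)
  if (ex$strand == "-") tag <- saltmir:::revcomp(tag)
  tags <- collapse_tags(list(L1 = rep(tag, 50)))
  annot <- data.frame(sequence = tags$sequence, category = "exon_sense",
                      stringsAsFactors = FALSE)
  expect_length(call_novel(tags, annot, b$genome), 0)
})

test_that("family_summary fractions are exact and sum to one", {
  mk <- function(id, fam, counts) {
    r <- list(id = id, class = "conserved", family = fam, counts = counts)
    class(r) <- "mirna_record"; r
  }
  one <- list(mk("m1", "miR1", c(L = 10)))
  fs <- family_summary(one)
  expect_equal(fs$fraction, 1.0)
  two <- list(mk("m1", "miR1", c(L = 25)), mk("m2", "miR2", c(L = 25)))
  fs2 <- family_summary(two)
  expect_equal(sort(fs2$fraction), c(0.5, 0.5))
  # designed 60% family share is recovered from the synthetic run
  fx <- small_sim()
  cons <- call_conserved(fx$tags, fx$build$mature_ref, fx$build$precursor_ref,
                         fx$build$genome)
  fs3 <- family_summary(cons)
  for (lib in unique(fs3$library))
    expect_equal(sum(fs3$fraction[fs3$library == lib]), 1, tolerance = 1e-9)
  f156 <- fs3$fraction[fs3$family == "miR156" & fs3$library == "3dCKL"]
  expect_gt(f156, 0.5); expect_lt(f156, 0.72)
})
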