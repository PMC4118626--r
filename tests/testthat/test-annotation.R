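test_that("map_perfect finds all and only exact occurrences on both strands", {
  set.seed(7)
  chr1 <- rand_seq(500)
  tag_fwd <- substr(chr1, 101, 121)
  tag_rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(chr1, 201, 222))))
  absent <- "GGGGGGGGGGGGGGGGGGGGG"  # essentially never in a 500-nt random seq
  hits <- map_perfect(c(tag_fwd, tag_rev, absent), c(chr1 = chr1))
  h1 <- hits[hits$tag == 1, ]
  expect_true(any(h1$start == 100 & h1$end == 121 & h1$strand == "+"))
  h2 <- hits[hits$tag == 2, ]
  expect_true(any(h2$start == 200 & h2$end == 222 & h2$strand == "-"))
  expect_equal(sum(hits$tag == 3), 0L)
  # every reported hit is verifiable against the genome string
  for (r in seq_len(nrow(hits))) {
    sub <- substr(chr1, hits$start[r] + 1, hits$end[r])
    expected <- if (hits$strand[r] == "+") hits$sequence[r] else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(hits$sequence[r])))
    expect_identical(sub, expected)
  }
})

test_that("match_with_mismatches respects the mismatch bound", {
  ref <- c(mirA = "ACGTACGTACGTACGTACGTAC")
  tag0 <- substr(ref, 1, 21)
  hits <- match_with_mismatches(tag0, ref, 2)
  expect_equal(hits$mismatches[1], 0L)
  tag3 <- paste0("TTT", substr(tag0, 4, 21))      # 3 substitutions
  expect_equal(nrow(match_with_mismatches(tag3, ref, 2)), 0L)
  long <- strrep("A", 30)
  expect_equal(nrow(match_with_mismatches(long, ref, 2)), 0L)
})

test_that("match_with_mismatches agrees with the exhaustive Hamming oracle", {
  set.seed(13)
  for (i in 1:300) {
    tag <- rand_seq(sample(15:30, 1))
    ref <- setNames(list(rand_seq(sample(15:50, 1))), "r")
    refv <- unlist(ref)
    oracle <- brute_hamming(tag, refv)
    got <- match_with_mismatches(tag, refv |> setNames("r"), max_mm = 10)
    if (is.infinite(oracle)) {
      expect_equal(nrow(got), 0L)
    } else if (oracle <= 10) {
      expect_equal(got$mismatches[1], as.integer(oracle))
    } else {
      expect_equal(nrow(got), 0L)
    }
  }
})

test_that("categorize applies winner-takes-all priority", {
  set.seed(17)
  # genome: an exon region that also contains a mature-miRNA-matching tag
  exon_seq <- rand_seq(200)
  chr <- paste0(rand_seq(100), exon_seq, rand_seq(100))
  tag_in_exon <- substr(exon_seq, 50, 70)
  gff <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 300),
                                strand = "+", type = "exon",
                                ID = "g1.e1", Parent = "g1")
  mature_ref <- c(mirX = tag_in_exon)   # also a perfect mature match
  res <- annotate_tags(collapse_tags(list(L = tag_in_exon)), c(chr1 = chr),
                       mature_ref, character(0), gff)
  expect_equal(res$annotation$category, "known_miRNA")
  # without the miRNA reference it falls through to exon_sense
  res2 <- annotate_tags(collapse_tags(list(L = tag_in_exon)), c(chr1 = chr),
                        character(0), character(0), gff)
  expect_equal(res2$annotation$category, "exon_sense")
  # antisense-only overlap
  tag_rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(tag_in_exon)))
  res3 <- annotate_tags(collapse_tags(list(L = tag_rc)), c(chr1 = chr),
                        character(0), character(0), gff)
  expect_equal(res3$annotation$category, "exon_antisense")
  # mapped but matching nothing
  tag_bg <- substr(chr, 10, 30)
  res4 <- annotate_tags(collapse_tags(list(L = tag_bg)), c(chr1 = chr),
                        character(0), character(0), NULL)
  expect_equal(res4$annotation$category, "unknown")
  # unmapped
  res5 <- annotate_tags(collapse_tags(list(L = strrep("G", 21))), c(chr1 = chr),
                        character(0), character(0), NULL)
  expect_equal(res5$annotation$category, "unmapped")
})

test_that("annotation is invariant to reference file order", {
  fx <- small_sim()
  tags_sub <- fx$tags[sample(seq_len(nrow(fx$tags)), 400), ]
  a1 <- annotate_tags(tags_sub, fx$build$genome, fx$build$mature_ref,
                      fx$build$ncrna_ref, fx$gff, fx$bed)
  a2 <- annotate_tags(tags_sub, fx$build$genome, rev(fx$build$mature_ref),
                      rev(fx$build$ncrna_ref), fx$gff, fx$bed)
  expect_identical(a1$annotation$category, a2$annotation$category)
})

test_that("category read tallies sum to total clean reads per library", {
  fx <- small_sim()
  cs <- category_summary(fx$annot$annotation, fx$tags)
  for (lib in names(fx$clean)) {
    tot <- sum(cs$reads[cs$library == lib])   # includes unmapped
    expect_equal(tot, fx$clean[[lib]]$stats$clean_reads)
    mapped <- sum(cs$reads[cs$library == lib & cs$category != "unmapped"])
    expect_equal(mapped, sum(fx$tags[[lib]]) -
                   sum(cs$reads[cs$library == lib & cs$category == "unmapped"]))
  }
})

test_that("introns are derived from exon gaps and hit intron categories", {
  fx <- small_sim()
  ex <- fx$build$truth[fx$build$truth$class == "exon", ][1, ]
  chrseq <- as.character(fx$build$genome[[ex$chrom]])
  intron_tag <- substr(chrseq, ex$start + 250, ex$start + 270)  # inside intron
  if (ex$strand == "-") intron_tag <- saltmir:::revcomp(intron_tag)
  res <- annotate_tags(collapse_tags(list(L = intron_tag)), fx$build$genome,
                       character(0), character(0), fx$gff, fx$bed)
  expect_true(res$annotation$category %in% c("intron_sense", "repeat"))
})
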