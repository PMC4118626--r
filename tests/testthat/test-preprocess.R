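adapter3 <- "TGGAATTCTCGGGTGCCAAG"
adapter5 <- "GTTCAGAGTTCTACAGTCCG"

mk_reads <- function(inserts, qual_char = "I", read_len = 40) {
  seqs <- vapply(inserts, function(ins) {
    r <- paste0(ins, adapter3)
    if (nchar(r) >= read_len) substr(r, 1, read_len)
    else paste0(r, strrep("C", read_len - nchar(r)))
  }, character(1), USE.NAMES = FALSE)
  list(seq = seqs, qual = strrep(qual_char, nchar(seqs)))
}

test_that("adapter trimming retains the insert", {
  ins <- rand_seq(21)
  res <- clean_reads(mk_reads(ins), adapter3, adapter5)
  expect_identical(res$seqs, ins)
  expect_equal(res$stats$clean_reads, 1L)
})

test_that("length filter keeps the closed interval [18, 30]", {
  set.seed(2)
  ins <- vapply(c(17L, 18L, 30L, 31L), function(n) {
    repeat { s <- rand_seq(n); if (!grepl("AAAAAAAAAA", s)) return(s) }
  }, character(1))
  res <- clean_reads(mk_reads(ins), adapter3, adapter5)
  expect_setequal(res$seqs, ins[c(2, 3)])
  expect_equal(unname(res$stats$removed["length_out_of_range"]), 2L)
})

test_that("contaminant categories are detected in the fixed order", {
  set.seed(3)
  good <- rand_seq(21)
  polya <- strrep("A", 20)
  no_adapter <- rand_seq(40)                       # no 3' adapter seed
  a5 <- paste0(substr(adapter5, 1, 8), rand_seq(32))
  reads <- mk_reads(c(good, polya))
  reads$seq <- c(reads$seq, no_adapter, a5, paste0(adapter3, rand_seq(20)))
  reads$qual <- c(reads$qual, strrep("I", 40), strrep("I", 40), strrep("I", 40))
  # low-quality read: same as good but qualities below threshold
  lowq <- mk_reads(good, qual_char = "#")
  reads$seq <- c(reads$seq, lowq$seq); reads$qual <- c(reads$qual, lowq$qual)
  res <- clean_reads(reads, adapter3, adapter5)
  rm <- res$stats$removed
  expect_equal(unname(rm["polyA"]), 1L)
  expect_equal(unname(rm["adapter_null"]), 1L)
  expect_equal(unname(rm["adapter5_contaminant"]), 1L)
  expect_equal(unname(rm["insert_null"]), 1L)
  expect_equal(unname(rm["low_quality"]), 1L)
  expect_identical(res$seqs, good)
})

test_that("read accounting is conserved: raw = clean + removed", {
  fx <- small_sim()
  for (lib in names(fx$clean)) {
    s <- fx$clean[[lib]]$stats
    expect_equal(s$raw_reads, s$clean_reads + sum(s$removed))
  }
})

test_that("cleaning clean inserts with trimming disabled is the identity", {
  set.seed(4)
  ins <- vapply(1:50, function(i) {
    repeat { s <- rand_seq(sample(18:30, 1)); if (!grepl("AAAAAAAAAA", s)) return(s) }
  }, character(1))
  res <- clean_reads(list(seq = ins, qual = strrep("I", nchar(ins))),
                     adapter3, adapter5, clean_params(trim = FALSE))
  expect_identical(res$seqs, ins)
  expect_equal(sum(res$stats$removed), 0L)
})

test_that("empty input yields empty output and zero stats", {
  res <- clean_reads(list(seq = character(0), qual = character(0)),
                     adapter3, adapter5)
  expect_length(res$seqs, 0)
  expect_equal(res$stats$raw_reads, 0L)
})

test_that("collapse_tags counts per library and keys by exact sequence", {
  s1 <- rand_seq(21); s2 <- rand_seq(22)
  tags <- collapse_tags(list(A = c(s1, s1, s2), B = c(s1), C = character(0)))
  expect_equal(nrow(tags), 2L)
  expect_equal(tags$A[tags$sequence == s1], 2L)
  expect_equal(tags$A[tags$sequence == s2], 1L)
  expect_equal(tags$B[tags$sequence == s1], 1L)
  expect_equal(tags$B[tags$sequence == s2], 0L)
  expect_true(all(tags$C == 0L))
  # conservation: per-library tag counts sum to the library's reads
  expect_equal(sum(tags$A), 3L)
})

test_that("common/specific rows add up and identical libraries are 100% common", {
  fx <- small_sim()
  cs <- common_specific_summary(fx$tags, "3dSL", "3dCKL")
  expect_equal(cs$unique_count[1], sum(cs$unique_count[2:4]))
  expect_equal(cs$total_count[1], sum(cs$total_count[2:4]))
  same <- collapse_tags(list(A = c("ACGTACGTACGTACGTACGT"),
                             B = c("ACGTACGTACGTACGTACGT")))
  cs2 <- common_specific_summary(same, "A", "B")
  expect_equal(cs2$unique_pct[2], 100.00)
  expect_equal(cs2$unique_count[3], 0)
  expect_equal(cs2$unique_count[4], 0)
  expect_error(common_specific_summary(same, "A", "nope"), "unknown library")
})
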