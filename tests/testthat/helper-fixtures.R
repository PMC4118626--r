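# shared fixtures, built once per test run and cached in an environment

.fixtures <- new.env(parent = emptyenv())

# small four-library simulation (fast; used by module tests)
small_sim <- function() {
  if (is.null(.fixtures$small)) {
    cfg <- sim_config(seed = 101L, reads_per_library = 15000)
    build <- build_genome(cfg)
    sim <- simulate_libraries(build, cfg)
    cl <- lapply(names(sim$reads), function(lib)
      clean_reads(list(seq = sim$reads[[lib]], qual = sim$quals[[lib]]),
                  cfg$adapter3, cfg$adapter5))
    names(cl) <- names(sim$reads)
    tags <- collapse_tags(lapply(cl, `[[`, "seqs"))
    gff <- tempfile(fileext = ".gff3"); saltmir:::write_gff3(build$gff, gff)
    bed <- tempfile(fileext = ".bed"); saltmir:::write_bed(build$repeats, bed)
    an <- annotate_tags(tags, build$genome, build$mature_ref, build$ncrna_ref,
                        gff, bed)
    .fixtures$small <- list(cfg = cfg, build = build, sim = sim, clean = cl,
                            tags = tags, annot = an, gff = gff, bed = bed)
  }
  .fixtures$small
}

# brute-force sliding Hamming scan (independent oracle for
# match_with_mismatches): returns min distance over all full-overlap
# offsets, or Inf when the tag does not fit
brute_hamming <- function(tag, ref) {
  tag <- chartr("Uu", "Tt", toupper(tag)); ref <- chartr("Uu", "Tt", toupper(ref))
  m <- nchar(tag); L <- nchar(ref)
  if (m > L) return(Inf)
  tv <- strsplit(tag, "")[[1]]
  best <- Inf
  for (off in 0:(L - m)) {
    rv <- strsplit(substr(ref, off + 1, off + m), "")[[1]]
    best <- min(best, sum(tv != rv))
  }
  best
}

# brute-force target scorer (independent oracle for predict_targets)
brute_target_scan <- function(mirna, transcript, max_score = 4,
                              mm_penalty = 1, gu_penalty = 0.5,
                              seed_range = c(2, 13), seed_mult = 2,
                              cleavage_range = c(10, 11),
                              allow_cleavage_mm = FALSE) {
  mirna <- chartr("Uu", "Tt", toupper(mirna))
  transcript <- chartr("Uu", "Tt", toupper(transcript))
  m <- nchar(mirna); L <- nchar(transcript)
  mv <- strsplit(mirna, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out <- NULL
  if (m > L) return(data.frame(site_start = integer(0), score = numeric(0)))
  for (s in 0:(L - m)) {
    score <- 0; reject <- FALSE
    for (p in 1:m) {
      tb <- substr(transcript, s + m - p + 1, s + m - p + 1)
      mb <- mv[p]
      wc <- comp[[mb]] == tb
      gu <- (mb == "G" && tb == "T") || (mb == "T" && tb == "G")
      if (wc) next
      pen <- if (gu) gu_penalty else mm_penalty
      if (p >= seed_range[1] && p <= seed_range[2]) pen <- pen * seed_mult
      score <- score + pen
      if (!gu && p >= cleavage_range[1] && p <= cleavage_range[2] &&
          !allow_cleavage_mm) reject <- TRUE
    }
    if (!reject && score <= max_score + 1e-9)
      out <- rbind(out, data.frame(site_start = s, score = score))
  }
  if (is.null(out)) data.frame(site_start = integer(0), score = numeric(0)) else out
}

# direct-formula evaluation of the exact-test pmf (independent of the
# log-gamma route): stable product accumulation
brute_ac_pmf <- function(y, x, N1, N2) {
  r <- N2 / N1
  acc <- 1 / (1 + r)^(x + 1)
  if (y > 0) for (k in 1:y) acc <- acc * r * (x + k) / (k * (1 + r))
  acc
}

rand_seq <- function(n, alphabet = c("A", "C", "G", "T"))
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
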