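#' Simulation configuration for the four-library salt-stress design
#'
#' The generator emulates a small RNA sequencing study with two tissues
#' (leaf, root) x two conditions (salt treatment, control), i.e. libraries
#' 3dSL, 3dCKL, 3dSR, 3dCKR. Reads are 18--30 nt with 21 nt the modal
#' length and 24 nt second, at least 70% in 20--24 nt. Conserved and novel
#' miRNA hairpin loci, non-coding RNA loci, exon/intron gene models and
#' repeats are planted in an i.i.d. uniform ACGT background genome.
#'
#' @param seed Master seed; every byte of output is a deterministic
#'   function of the config.
#' @param n_chromosomes,chrom_length Genome dimensions (default 2 x 50 kb).
#' @param n_conserved_loci,n_novel_loci,n_ncrna_loci,n_exon_loci Planted
#'   locus counts (defaults 20/10/6/8).
#' @param reads_per_library Raw reads per library (default 1e5).
#' @param length_mixture Named probability vector over lengths 18--30 for
#'   background read lengths; must sum to 1.
#' @param contamination_rates Named rates for `adapter_null`,
#'   `insert_null`, `polyA`, `low_quality` (and optionally `adapter5`);
#'   each in `[0,1]`, summing to less than 1.
#' @param planted_log2fc Optional named vector locus_id -> log2 fold change
#'   (treatment vs control); by default the first 3 conserved loci get +2,
#'   the next 3 get -2, the first novel locus +2, the second -2, all other
#'   loci 0.
#' @param dispersion Negative-binomial dispersion of locus counts
#'   (Gamma-Poisson; 0 degenerates to Poisson). Default 0.05.
#' @param adapter3,adapter5 Adapter sequences (3' adapter is appended to
#'   every genuine read).
#' @param read_length Sequencer read length (default 40).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L, chrom_length = 50000L,
                       n_conserved_loci = 20L, n_novel_loci = 10L,
                       n_ncrna_loci = 6L, n_exon_loci = 8L,
                       reads_per_library = 1e5,
                       length_mixture = c(`18` = 0.03, `19` = 0.04,
                                          `20` = 0.10, `21` = 0.40,
                                          `22` = 0.08, `23` = 0.06,
                                          `24` = 0.20, `25` = 0.03,
                                          `26` = 0.02, `27` = 0.015,
                                          `28` = 0.01, `29` = 0.005,
                                          `30` = 0.01),
                       contamination_rates = c(adapter_null = 0.02,
                                               insert_null = 0.01,
                                               polyA = 0.01,
                                               low_quality = 0.02,
                                               adapter5 = 0.005),
                       planted_log2fc = NULL,
                       dispersion = 0.05,
                       adapter3 = "TGGAATTCTCGGGTGCCAAG",
                       adapter5 = "GTTCAGAGTTCTACAGTCCG",
                       read_length = 40L) {
  cfg <- list(seed = as.integer(seed),
              n_chromosomes = as.integer(n_chromosomes),
              chrom_length = as.integer(chrom_length),
              n_conserved_loci = as.integer(n_conserved_loci),
              n_novel_loci = as.integer(n_novel_loci),
              n_ncrna_loci = as.integer(n_ncrna_loci),
              n_exon_loci = as.integer(n_exon_loci),
              reads_per_library = as.integer(reads_per_library),
              length_mixture = length_mixture,
              contamination_rates = contamination_rates,
              planted_log2fc = planted_log2fc,
              dispersion = dispersion,
              adapter3 = to_dna(adapter3), adapter5 = to_dna(adapter5),
              read_length = as.integer(read_length),
              # class composition of genuine reads
              class_fractions = c(conserved = 0.38, novel = 0.05,
                                  ncrna = 0.08, exon = 0.05, intron = 0.02,
                                  rep = 0.02, background = 0.40),
              star_fraction = 0.15)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (abs(sum(cfg$length_mixture) - 1) > 1e-9)
    stopf("length_mixture probabilities must sum to 1 (got %.12f)",
          sum(cfg$length_mixture))
  lens <- as.integer(names(cfg$length_mixture))
  if (any(is.na(lens)) || any(lens < 18L) || any(lens > 30L))
    stopf("length_mixture keys must be lengths in 18..30")
  cr <- cfg$contamination_rates
  if (any(cr < 0) || any(cr > 1)) stopf("contamination rates must be in [0,1]")
  if (sum(cr) >= 1) stopf("contamination rates must sum to < 1")
  if (cfg$dispersion < 0) stopf("dispersion must be >= 0")
  invisible(cfg)
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# family design: miR156 dominates conserved expression (~60%), two
# mid-abundance families (~10% each), the rest share the remainder
conserved_family_design <- function(n) {
  fams <- c(rep("miR156", min(6L, n)))
  extra <- c("miR166", "miR166", "miR167", "miR167", "miR169", "miR172",
             "miR393", "miR394", "miR396", "miR398", "miR408", "miR827",
             "miR1444", "miR2119")
  fams <- c(fams, extra)[seq_len(n)]
  w <- numeric(n)
  w[fams == "miR156"] <- 0.60 / sum(fams == "miR156")
  w[fams %in% c("miR166", "miR167")] <- 0.20 / sum(fams %in% c("miR166", "miR167"))
  rest <- !(fams %in% c("miR156", "miR166", "miR167"))
  if (any(rest)) w[rest] <- 0.20 / sum(rest)
  w <- w / sum(w)
  # reference-style names with member letters
  suffix <- unlist(lapply(split(seq_len(n), fams), function(i) letters[seq_along(i)]))
  names(suffix) <- unlist(split(seq_len(n), fams))
  ids <- paste0("ptc-", fams, suffix[as.character(seq_len(n))])
  list(ids = ids, families = fams, weights = w)
}

# hairpin precursor around a mature: F5 + duplex arms + A/C loop + F3.
# Returns precursor (DNA), mature/star coordinates and the star sequence
# carrying the canonical 2-nt 3' overhang.
build_precursor <- function(mature, arm = c("5p", "3p")) {
  arm <- match.arg(arm)
  m <- nchar(mature)
  f5 <- rand_dna(10L); f3 <- rand_dna(10L)
  loop <- paste(sample(c("A", "C"), 15L, replace = TRUE), collapse = "")
  rc <- revcomp(mature)
  if (arm == "5p") {
    prec <- paste0(f5, mature, loop, rc, f3)
    mstart <- 11L
  } else {
    prec <- paste0(f5, rc, loop, mature, f3)
    mstart <- 10L + m + 15L + 1L
  }
  # partner of the mature 5' end is the far end of the rc block; the star's
  # 3' end extends 2 nt beyond it
  if (arm == "5p") {
    rc_end <- 10L + m + 15L + m
    star_end <- rc_end + 2L
  } else {
    rc_end <- 10L + m
    star_end <- rc_end + 2L
  }
  star_start <- star_end - m + 1L
  list(precursor = prec, mature_start = mstart, arm = arm,
       star_seq = substr(prec, star_start, star_end))
}

#' Build a synthetic genome with planted loci and references
#'
#' Plants conserved-miRNA, novel-miRNA, non-coding RNA, exon/intron gene
#' and repeat loci in an i.i.d. uniform ACGT genome, and derives the
#' companion references: a miRBase-style mature/precursor reference
#' (conserved matures only -- novel matures are deliberately absent), an
#' ncRNA reference, a transcript set in which every planted mature has at
#' least one near-complementary target site (0--4 mismatches), a gene
#' model GFF and a repeat BED.
#'
#' @param cfg A [sim_config()].
#' @param outdir Optional directory; when given, all artifacts are written
#'   (genome.fa, mature.fa, precursor.fa, ncrna.fa, transcripts.fa,
#'   genes.gff3, repeats.bed, ground_truth.tsv).
#' @return A list: `genome` (DNAStringSet), `truth` (ground-truth
#'   data.frame), `mature_ref`, `precursor_ref`, `ncrna_ref`,
#'   `transcripts` (named character vectors), `gff` (feature data.frame),
#'   `repeats` (data.frame), `files` (paths when written).
#' @export
build_genome <- function(cfg, outdir = NULL) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  n_mirna <- cfg$n_conserved_loci + cfg$n_novel_loci
  n_loci <- n_mirna + cfg$n_ncrna_loci + cfg$n_exon_loci
  n_repeats <- 5L
  slot <- 700L
  per_chrom <- (cfg$chrom_length - 400L) %/% slot
  if (per_chrom * cfg$n_chromosomes < n_loci + n_repeats)
    stopf(paste0("chromosomes too short to host %d loci: %d chromosomes of ",
                 "%d nt provide %d slots of %d nt; increase chrom_length to ",
                 "at least %d"),
          n_loci + n_repeats, cfg$n_chromosomes, cfg$chrom_length,
          per_chrom * cfg$n_chromosomes, slot,
          ceiling((n_loci + n_repeats) / cfg$n_chromosomes) * slot + 400L)

  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  genome_chars <- lapply(chroms, function(cc)
    sample(c("A", "C", "G", "T"), cfg$chrom_length, replace = TRUE))
  names(genome_chars) <- chroms

  slots <- do.call(rbind, lapply(chroms, function(cc)
    data.frame(chrom = cc, start0 = 200L + slot * (seq_len(per_chrom) - 1L),
               stringsAsFactors = FALSE)))
  slots <- slots[sample(nrow(slots)), ]

  design <- conserved_family_design(cfg$n_conserved_loci)
  truth <- list(); gff <- list(); repeats <- list()
  mature_ref <- character(0); precursor_ref <- character(0)
  ncrna_ref <- character(0); transcripts <- character(0)
  si <- 0L

  plant <- function(chrom, start0, seq) {
    genome_chars[[chrom]][(start0 + 1L):(start0 + nchar(seq))] <<-
      strsplit(seq, "")[[1]]
  }

  mature_lengths <- function(n) sample(c(20L, 21L, 22L, 24L), n, replace = TRUE,
                                       prob = c(0.15, 0.55, 0.10, 0.20))

  # conserved + novel miRNA loci
  mlens <- mature_lengths(n_mirna)
  for (i in seq_len(n_mirna)) {
    conserved <- i <= cfg$n_conserved_loci
    m <- mlens[i]
    mature <- if (conserved) rand_dna(m) else paste0("G", rand_dna(m - 1L))
    arm <- sample(c("5p", "3p"), 1L, prob = c(0.6, 0.4))
    bp <- build_precursor(mature, arm)
    # make sure the planted precursor actually passes the hairpin criteria
    fold <- rna_fold(bp$precursor)
    if (!is_hairpin(fold, 16L, -18)$is_hairpin) {
      bp <- build_precursor(mature, arm)   # one refresh of random flanks
      fold <- rna_fold(bp$precursor)
    }
    si <- si + 1L
    chrom <- slots$chrom[si]; start0 <- slots$start0[si]
    strand <- sample(c("+", "-"), 1L)
    placed <- if (strand == "+") bp$precursor else revcomp(bp$precursor)
    plant(chrom, start0, placed)
    id <- if (conserved) design$ids[i] else
      sprintf("novel-%02d", i - cfg$n_conserved_loci)
    truth[[length(truth) + 1L]] <- data.frame(
      locus_id = id, class = if (conserved) "conserved" else "novel",
      chrom = chrom, start = start0, end = start0 + nchar(bp$precursor),
      strand = strand, mature_seq = mature, star_seq = bp$star_seq,
      precursor_seq = bp$precursor, arm = bp$arm, mfe = fold$mfe,
      family = if (conserved) design$families[i] else NA_character_,
      weight = if (conserved) design$weights[i] else 1 / cfg$n_novel_loci,
      true_log2fc = 0, stringsAsFactors = FALSE)
    if (conserved) {
      mature_ref[id] <- mature
      precursor_ref[id] <- bp$precursor
    }
  }

  # decoy mature references (families never planted)
  for (k in 1:5) mature_ref[sprintf("ath-miR%d", 9000 + k)] <- rand_dna(21L)

  # ncRNA loci: planted and copied into the ncRNA reference
  nc_classes <- rep(c("rRNA", "tRNA", "snRNA", "snoRNA", "scRNA"),
                    length.out = cfg$n_ncrna_loci)
  for (i in seq_len(cfg$n_ncrna_loci)) {
    len <- sample(70:90, 1L)
    seq <- rand_dna(len)
    si <- si + 1L
    chrom <- slots$chrom[si]; start0 <- slots$start0[si]
    plant(chrom, start0, seq)
    id <- sprintf("%s-%d", nc_classes[i], i)
    ncrna_ref[id] <- seq
    truth[[length(truth) + 1L]] <- data.frame(
      locus_id = id, class = "ncRNA", chrom = chrom, start = start0,
      end = start0 + len, strand = "+", mature_seq = NA, star_seq = NA,
      precursor_seq = seq, arm = NA, mfe = NA, family = NA,
      weight = 1 / cfg$n_ncrna_loci, true_log2fc = 0, stringsAsFactors = FALSE)
  }

  # exon/intron gene loci (exon1 200 nt, intron 150 nt, exon2 250 nt)
  for (i in seq_len(cfg$n_exon_loci)) {
    si <- si + 1L
    chrom <- slots$chrom[si]; start0 <- slots$start0[si]
    strand <- sample(c("+", "-"), 1L)
    gid <- sprintf("gene%02d", i)
    e1 <- c(start0 + 1L, start0 + 200L)
    e2 <- c(start0 + 351L, start0 + 600L)
    gff[[length(gff) + 1L]] <- data.frame(
      seqid = chrom, source = "saltmir",
      type = c("gene", "mRNA", "exon", "exon"),
      start = c(e1[1], e1[1], e1[1], e2[1]),
      end = c(e2[2], e2[2], e1[2], e2[2]),
      strand = strand,
      ID = c(gid, paste0(gid, ".1"), paste0(gid, ".1.e1"), paste0(gid, ".1.e2")),
      Parent = c("", gid, paste0(gid, ".1"), paste0(gid, ".1")),
      stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <- data.frame(
      locus_id = gid, class = "exon", chrom = chrom, start = start0,
      end = start0 + 600L, strand = strand, mature_seq = NA, star_seq = NA,
      precursor_seq = NA, arm = NA, mfe = NA, family = NA,
      weight = 1 / cfg$n_exon_loci, true_log2fc = 0, stringsAsFactors = FALSE)
  }

  # repeats (annotation only)
  for (i in seq_len(n_repeats)) {
    si <- si + 1L
    repeats[[length(repeats) + 1L]] <- data.frame(
      chrom = slots$chrom[si], start = slots$start0[si],
      end = slots$start0[si] + 300L, name = sprintf("rep%d", i), strand = "+",
      stringsAsFactors = FALSE)
  }

  truth <- do.call(rbind, truth)
  # planted fold-changes (treatment vs control)
  lfc <- setNames(rep(0, nrow(truth)), truth$locus_id)
  if (is.null(cfg$planted_log2fc)) {
    cons <- truth$locus_id[truth$class == "conserved"]
    nov <- truth$locus_id[truth$class == "novel"]
    lfc[cons[1:3]] <- 2; lfc[cons[4:6]] <- -2
    if (length(nov) >= 2) { lfc[nov[1]] <- 2; lfc[nov[2]] <- -2 }
  } else {
    lfc[names(cfg$planted_log2fc)] <- cfg$planted_log2fc
  }
  truth$true_log2fc <- unname(lfc[truth$locus_id])

  # transcripts: one per planted mature with a near-complementary site
  # (mismatches only at duplex positions facing miRNA 3' half), plus decoys
  mir <- truth[truth$class %in% c("conserved", "novel"), ]
  for (i in seq_len(nrow(mir))) {
    m <- mir$mature_seq[i]; ml <- nchar(m)
    site <- strsplit(revcomp(m), "")[[1]]
    nmm <- sample(0:2, 1L)
    if (nmm > 0) {
      # site position k faces miRNA position ml - k + 1; keep p >= 14
      ok <- which((ml - seq_len(ml) + 1L) >= 14L)
      for (k in sample(ok, min(nmm, length(ok)))) {
        site[k] <- sample(setdiff(c("A", "C", "G", "T"), site[k]), 1L)
      }
    }
    tx <- rand_dna(400L)
    pos <- sample(50:300, 1L)
    tx <- paste0(substr(tx, 1L, pos - 1L), paste(site, collapse = ""),
                 substr(tx, pos + ml, 400L))
    transcripts[paste0("tx-", mir$locus_id[i])] <- tx
  }
  for (k in 1:5) transcripts[sprintf("tx-decoy%d", k)] <- rand_dna(400L)

  genome <- Biostrings::DNAStringSet(vapply(genome_chars, paste,
                                            character(1), collapse = ""))
  names(genome) <- chroms
  gff <- do.call(rbind, gff)
  repeats <- do.call(rbind, repeats)

  files <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    files <- list(
      genome = file.path(outdir, "genome.fa"),
      mature = file.path(outdir, "mature.fa"),
      precursor = file.path(outdir, "precursor.fa"),
      ncrna = file.path(outdir, "ncrna.fa"),
      transcripts = file.path(outdir, "transcripts.fa"),
      gff = file.path(outdir, "genes.gff3"),
      repeats = file.path(outdir, "repeats.bed"),
      truth = file.path(outdir, "ground_truth.tsv"))
    sg <- setNames(as.character(genome), names(genome))
    write_fasta(sg, files$genome)
    write_fasta(mature_ref, files$mature, rna = TRUE)
    write_fasta(precursor_ref, files$precursor, rna = TRUE)
    write_fasta(ncrna_ref, files$ncrna)
    write_fasta(transcripts, files$transcripts)
    write_gff3(gff, files$gff)
    write_bed(repeats, files$repeats)
    write_tsv(truth, files$truth)
  }
  list(genome = genome, truth = truth, mature_ref = mature_ref,
       precursor_ref = precursor_ref, ncrna_ref = ncrna_ref,
       transcripts = transcripts, gff = gff, repeats = repeats,
       files = files, cfg = cfg)
}

#' Library design of the four-library experiment
#'
#' @return data.frame: library id, tissue, treated flag.
#' @export
library_design <- function() {
  data.frame(library = c("3dSL", "3dCKL", "3dSR", "3dCKR"),
             tissue = c("leaf", "leaf", "root", "root"),
             treated = c(TRUE, FALSE, TRUE, FALSE),
             stringsAsFactors = FALSE)
}

nb_draw <- function(n, mu, dispersion) {
  if (dispersion <= 0) rpois(n, mu) else rnbinom(n, mu = mu, size = 1 / dispersion)
}

qual_string <- function(widths, lo, hi) {
  vapply(widths, function(w)
    intToUtf8(33L + sample(lo:hi, w, replace = TRUE)), character(1))
}

# windows of given lengths drawn uniformly from a [start0,end) interval
window_reads <- function(chrseq, start0, end, lens, strand) {
  maxs <- end - lens
  starts <- start0 + floor(runif(length(lens)) * (maxs - start0 + 1L))
  s <- vapply(seq_along(lens), function(i)
    substr(chrseq, starts[i] + 1L, starts[i] + lens[i]), character(1))
  if (strand == "-") s <- revcomp(s)
  s
}

#' Simulate the four FASTQ libraries
#'
#' Per-locus read counts are negative-binomial with mean proportional to
#' the locus weight, multiplied by `2^true_log2fc` in the treated library
#' of each tissue. Star reads accompany miRNA-locus reads at a fixed
#' fraction. Background reads are drawn at uniform genome positions with
#' lengths from the configured mixture. Contaminant reads (no 3' adapter,
#' empty insert, polyA, low quality, 5' adapter) are injected at the
#' configured rates. Every genuine read is the insert plus the 3' adapter,
#' padded/truncated to the read length, with Sanger (Phred+33) qualities.
#'
#' @param build Result of [build_genome()].
#' @param cfg The same [sim_config()].
#' @param outdir Optional output directory for FASTQ and the
#'   expected-count table.
#' @return A list: `reads`/`quals` (named per-library character vectors),
#'   `expected_counts` (locus x library sampled true counts),
#'   `background_lengths` (per-library insert lengths of background
#'   reads), `files`.
#' @export
simulate_libraries <- function(build, cfg, outdir = NULL) {
  validate_sim_config(cfg)
  set.seed(child_seed(cfg$seed, 7L))
  truth <- build$truth
  design <- library_design()
  cr <- cfg$contamination_rates
  rate5 <- if ("adapter5" %in% names(cr)) cr[["adapter5"]] else 0
  G <- round(cfg$reads_per_library * (1 - sum(cr)))
  fr <- cfg$class_fractions
  genome_chars <- setNames(as.character(build$genome), names(build$genome))
  lens_avail <- as.integer(names(cfg$length_mixture))

  pad_read <- function(inserts) {
    reads <- paste0(inserts, cfg$adapter3)
    reads <- vapply(reads, function(r) {
      if (nchar(r) >= cfg$read_length) substr(r, 1L, cfg$read_length)
      else paste0(r, strrep("C", cfg$read_length - nchar(r)))
    }, character(1), USE.NAMES = FALSE)
    reads
  }

  reads_out <- list(); quals_out <- list(); expected <- list(); bg_lens <- list()
  mir <- truth[truth$class %in% c("conserved", "novel"), ]
  nc <- truth[truth$class == "ncRNA", ]
  ex <- truth[truth$class == "exon", ]

  for (li in seq_len(nrow(design))) {
    lib <- design$library[li]; treated <- design$treated[li]
    inserts <- character(0); categories <- character(0)

    # --- miRNA loci (mature + star reads)
    class_n <- c(conserved = round(G * fr[["conserved"]]),
                 novel = round(G * fr[["novel"]]))
    for (cls in c("conserved", "novel")) {
      rows <- mir[mir$class == cls, ]
      mu <- rows$weight * class_n[[cls]] *
        ifelse(rep(treated, nrow(rows)), 2^rows$true_log2fc, 1)
      cnt <- nb_draw(nrow(rows), mu, cfg$dispersion)
      star_cnt <- nb_draw(nrow(rows), cfg$star_fraction * mu, cfg$dispersion)
      inserts <- c(inserts, rep(rows$mature_seq, cnt),
                   rep(rows$star_seq, star_cnt))
      categories <- c(categories, rep(cls, sum(cnt) + sum(star_cnt)))
      expected[[length(expected) + 1L]] <- data.frame(
        locus_id = rows$locus_id, library = lib, mature_count = cnt,
        star_count = star_cnt, stringsAsFactors = FALSE)
    }

    # --- ncRNA fragments (sense of the planted strand)
    n_nc <- round(G * fr[["ncrna"]])
    if (n_nc > 0 && nrow(nc) > 0) {
      pick <- sample(nrow(nc), n_nc, replace = TRUE)
      for (r in unique(pick)) {
        k <- sum(pick == r)
        lmax <- nc$end[r] - nc$start[r]
        lens <- pmin(sample(lens_avail, k, TRUE, cfg$length_mixture), lmax)
        inserts <- c(inserts, window_reads(genome_chars[[nc$chrom[r]]],
                                           nc$start[r], nc$end[r], lens, "+"))
      }
      categories <- c(categories, rep("ncrna", n_nc))
    }

    # --- exon / intron / repeat fragments
    frag_block <- function(rows, n, sense_frac, windows) {
      if (n <= 0 || nrow(rows) == 0) return(character(0))
      pick <- sample(nrow(rows), n, replace = TRUE)
      out <- character(0)
      for (r in unique(pick)) {
        k <- sum(pick == r)
        w <- windows(rows[r, ])
        lens <- sample(lens_avail, k, TRUE, cfg$length_mixture)
        sense <- runif(k) < sense_frac
        sq <- window_reads(genome_chars[[rows$chrom[r]]], w[1], w[2], lens,
                           "+")
        flip <- xor(!sense, rows$strand[r] == "-")
        sq[flip] <- revcomp(sq[flip])
        out <- c(out, sq)
      }
      out
    }
    n_ex <- round(G * fr[["exon"]]); n_in <- round(G * fr[["intron"]])
    n_rp <- round(G * fr[["rep"]])
    # exon1 of each gene occupies [start, start+200)
    sq <- frag_block(ex, n_ex, 0.75, function(row) c(row$start, row$start + 200L))
    inserts <- c(inserts, sq); categories <- c(categories, rep("exon", length(sq)))
    sq <- frag_block(ex, n_in, 0.75, function(row) c(row$start + 200L, row$start + 350L))
    inserts <- c(inserts, sq); categories <- c(categories, rep("intron", length(sq)))
    if (n_rp > 0 && nrow(build$repeats) > 0) {
      rp <- build$repeats
      sq <- frag_block(data.frame(chrom = rp$chrom, start = rp$start,
                                  end = rp$end, strand = "+",
                                  stringsAsFactors = FALSE),
                       n_rp, 0.5, function(row) c(row$start, row$end))
      inserts <- c(inserts, sq); categories <- c(categories, rep("rep", length(sq)))
    }

    # --- background: uniform positions, mixture lengths
    n_bg <- max(0L, G - length(inserts))
    chroms <- sample(names(genome_chars), n_bg, replace = TRUE)
    lens <- sample(lens_avail, n_bg, TRUE, cfg$length_mixture)
    strands <- sample(c("+", "-"), n_bg, replace = TRUE)
    sq <- vapply(seq_len(n_bg), function(i) {
      chrseq <- genome_chars[[chroms[i]]]
      a <- sample.int(nchar(chrseq) - lens[i] + 1L, 1L)
      substr(chrseq, a, a + lens[i] - 1L)
    }, character(1))
    neg <- strands == "-"
    if (any(neg)) sq[neg] <- revcomp(sq[neg])
    inserts <- c(inserts, sq)
    categories <- c(categories, rep("background", n_bg))
    bg_lens[[lib]] <- lens

    reads <- pad_read(inserts)
    quals <- qual_string(rep(cfg$read_length, length(reads)), 30L, 40L)

    # --- contaminants
    n_raw <- cfg$reads_per_library
    add <- function(rds, qls) {
      reads <<- c(reads, rds); quals <<- c(quals, qls)
    }
    k <- round(n_raw * cr[["adapter_null"]])
    if (k > 0) {
      seed3 <- substr(cfg$adapter3, 1, 8); seed5 <- substr(cfg$adapter5, 1, 8)
      rds <- vapply(seq_len(k), function(i) {
        repeat {
          r <- rand_dna(cfg$read_length)
          if (!grepl(seed3, r, fixed = TRUE) && !startsWith(r, seed5)) return(r)
        }
      }, character(1))
      add(rds, qual_string(rep(cfg$read_length, k), 30L, 40L))
    }
    k <- round(n_raw * cr[["insert_null"]])
    if (k > 0) add(pad_read(rep("", k)), qual_string(rep(cfg$read_length, k), 30L, 40L))
    k <- round(n_raw * cr[["polyA"]])
    if (k > 0) add(pad_read(strrep("A", sample(20:26, k, TRUE))),
                   qual_string(rep(cfg$read_length, k), 30L, 40L))
    k <- round(n_raw * cr[["low_quality"]])
    if (k > 0) {
      idx <- sample(length(inserts), k, replace = TRUE)
      add(pad_read(inserts[idx]), qual_string(rep(cfg$read_length, k), 2L, 12L))
    }
    k <- round(n_raw * rate5)
    if (k > 0) add(paste0(substr(cfg$adapter5, 1, 8),
                          vapply(seq_len(k), function(i)
                            rand_dna(cfg$read_length - 8L), character(1))),
                   qual_string(rep(cfg$read_length, k), 30L, 40L))

    ord <- sample(length(reads))
    reads_out[[lib]] <- reads[ord]
    quals_out[[lib]] <- quals[ord]
  }

  expected <- do.call(rbind, expected)
  files <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    files <- list(expected_counts = file.path(outdir, "expected_counts.tsv"))
    for (lib in names(reads_out)) {
      p <- file.path(outdir, paste0(lib, ".fastq"))
      write_fastq(sprintf("%s_r%06d", lib, seq_along(reads_out[[lib]])),
                  reads_out[[lib]], quals_out[[lib]], p)
      files[[lib]] <- p
    }
    write_tsv(expected, files$expected_counts)
  }
  list(reads = reads_out, quals = quals_out, expected_counts = expected,
       background_lengths = bg_lens, files = files)
}
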