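test_that("config validation enforces the stated invariants", {
  expect_error(sim_config(length_mixture = c(`21` = 0.5)), "sum to 1")
  expect_error(sim_config(contamination_rates = c(adapter_null = 0.5,
                                                  insert_null = 0.6,
                                                  polyA = 0, low_quality = 0)),
               "sum to < 1")
  expect_error(sim_config(dispersion = -1), "dispersion")
  cfg <- sim_config()
  expect_equal(sum(cfg$length_mixture), 1, tolerance = 1e-9)
  # 21 nt modal, 24 nt second, >= 70% in 20-24
  lm <- cfg$length_mixture
  expect_equal(names(which.max(lm)), "21")
  expect_equal(names(sort(lm, decreasing = TRUE))[2], "24")
  expect_gte(sum(lm[as.character(20:24)]), 0.7)
})

test_that("a too-small genome raises a sizing error naming the constraint", {
  expect_error(build_genome(sim_config(chrom_length = 3000L)),
               "too short .* increase chrom_length")
})

test_that("build_genome plants loci verifiably and fills the references", {
  cfg <- sim_config(seed = 77, n_conserved_loci = 5L, n_novel_loci = 1L,
                    reads_per_library = 1000)
  b <- build_genome(cfg)
  expect_gte(length(b$mature_ref), 5)
  expect_equal(sum(b$truth$class == "novel"), 1L)
  nov <- b$truth[b$truth$class == "novel", ]
  expect_true(is_hairpin(rna_fold(nov$precursor_seq))$is_hairpin)
  # novel matures are NOT in the mature reference
  expect_false(any(nov$mature_seq %in% chartr("U", "T", b$mature_ref)))
  # every planted locus sequence appears at its recorded coordinates
  for (i in seq_len(nrow(b$truth))) {
    tr <- b$truth[i, ]
    if (is.na(tr$precursor_seq)) next
    g <- substr(as.character(b$genome[[tr$chrom]]), tr$start + 1, tr$end)
    expected <- if (tr$strand == "+") tr$precursor_seq else
      saltmir:::revcomp(tr$precursor_seq)
    expect_identical(g, expected)
  }
})

test_that("identical seeds give byte-identical artifacts", {
  cfg <- sim_config(seed = 9, reads_per_library = 2000,
                    n_conserved_loci = 4L, n_novel_loci = 2L,
                    n_ncrna_loci = 2L, n_exon_loci = 2L)
  d1 <- file.path(tempdir(), "sim_a"); d2 <- file.path(tempdir(), "sim_b")
  b1 <- build_genome(cfg, outdir = d1); s1 <- simulate_libraries(b1, cfg, outdir = d1)
  b2 <- build_genome(cfg, outdir = d2); s2 <- simulate_libraries(b2, cfg, outdir = d2)
  for (f in c("genome.fa", "mature.fa", "transcripts.fa", "3dSL.fastq",
              "3dCKR.fastq", "ground_truth.tsv", "expected_counts.tsv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
})

test_that("count model: treated/control mean ratio tracks the planted fold change", {
  # Monte-Carlo over the generator's negative-binomial count model
  set.seed(55)
  mu <- 100
  reps <- 100
  t_counts <- saltmir:::nb_draw(reps, mu * 2^2, 0)   # log2fc = 2, Poisson limit
  c_counts <- saltmir:::nb_draw(reps, mu, 0)
  expect_equal(mean(t_counts) / mean(c_counts), 4, tolerance = 0.1)
  # null loci: ratio ~ 1 within 10%
  t0 <- saltmir:::nb_draw(reps, mu, 0); c0 <- saltmir:::nb_draw(reps, mu, 0)
  expect_equal(mean(t0) / mean(c0), 1, tolerance = 0.1)
  # and in an actual simulated library pair
  fx <- small_sim()
  ec <- fx$sim$expected_counts
  up <- fx$build$truth$locus_id[fx$build$truth$true_log2fc == 2 &
                                  fx$build$truth$class == "conserved"]
  tt <- sum(ec$mature_count[ec$library == "3dSL" & ec$locus_id %in% up])
  cc <- sum(ec$mature_count[ec$library == "3dCKL" & ec$locus_id %in% up])
  expect_gt(tt / cc, 2.8); expect_lt(tt / cc, 5.6)
})

test_that("with zero contamination every read is insert plus adapter", {
  cfg <- sim_config(seed = 12, reads_per_library = 3000,
                    contamination_rates = c(adapter_null = 0, insert_null = 0,
                                            polyA = 0, low_quality = 0,
                                            adapter5 = 0))
  b <- build_genome(cfg)
  s <- simulate_libraries(b, cfg)
  res <- clean_reads(list(seq = s$reads[["3dSL"]], qual = s$quals[["3dSL"]]),
                     cfg$adapter3, cfg$adapter5)
  rm <- res$stats$removed
  expect_equal(unname(rm["adapter_null"]), 0L)
  expect_equal(unname(rm["insert_null"]), 0L)
  expect_equal(unname(rm["low_quality"]), 0L)
  expect_equal(unname(rm["adapter5_contaminant"]), 0L)
  # everything except rare accidental polyA-looking background survives
  expect_gte(res$stats$clean_reads / res$stats$raw_reads, 0.99)
})

test_that("background read lengths follow the configured mixture", {
  fx <- small_sim()
  lens <- unlist(fx$sim$background_lengths)
  obs <- table(factor(lens, levels = 18:30))
  p <- fx$cfg$length_mixture[as.character(18:30)]
  gof <- suppressWarnings(stats::chisq.test(as.integer(obs), p = p))
  expect_gt(gof$p.value, 0.001)
})

test_that("contaminants are injected at the configured rates", {
  fx <- small_sim()
  cr <- fx$cfg$contamination_rates
  st <- fx$clean[["3dSR"]]$stats
  n <- st$raw_reads
  expect_equal(unname(st$removed["adapter_null"]) / n, cr[["adapter_null"]],
               tolerance = 0.25)
  expect_equal(unname(st$removed["low_quality"]) / n, cr[["low_quality"]],
               tolerance = 0.25)
})
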