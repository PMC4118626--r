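#' Default pipeline configuration
#'
#' One YAML-serializable list holding every stage's thresholds with the
#' pipeline defaults: cleaning bounds 18--30 nt, two mismatches against
#' the mature reference, hairpin acceptance (16 stem pairs, MFE <= -18),
#' target score cap 4, DE thresholds |log2fc| > 0.5 at p < 0.05 with a
#' 1-RPM floor, and the two treatment/control tissue pairs.
#'
#' @param seed Master seed.
#' @param outdir Output directory.
#' @return A nested list; write it with [yaml::write_yaml()] for the CLI.
#' @export
default_config <- function(seed = 1L, outdir = "saltmir_out") {
  list(seed = as.integer(seed), outdir = outdir,
       simulate = list(enabled = TRUE),
       inputs = list(),
       clean = list(min_len = 18L, max_len = 30L, adapter_k = 8L,
                    min_mean_q = 20, max_n = 2L, polya_frac = 0.8,
                    polya_run = 10L),
       annotate = list(max_mm = 2L),
       discover = list(min_reads = 5L, max_mm = 2L, min_stem_pairs = 16L,
                       mfe_max = -18, require_star = TRUE),
       targets = list(max_score = 4.0, annotation_tsv = NULL),
       de = list(fc_cut = 0.5, p_cut = 0.05, min_norm = 1.0, fdr = FALSE,
                 pairs = list(list(treatment = "3dSL", control = "3dCKL"),
                              list(treatment = "3dSR", control = "3dCKR"))))
}

load_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_config(), config)
  cfg
}

md5_of <- function(paths) unname(tools::md5sum(paths))

#' Run the full pipeline
#'
#' Executes the stages in order simulate -> clean -> annotate -> discover
#' -> targets -> de -> report, writing every stage's tables under `outdir`
#' and a `manifest.json` with the seed, per-stage record counts and an
#' md5 checksum of every output file. With `resume = TRUE` a stage whose
#' outputs already exist with matching checksums is skipped; a corrupted
#' intermediate halts the run naming the file.
#'
#' @param config A config list or path to a YAML file; see
#'   [default_config()].
#' @param outdir Output directory (default from config).
#' @param resume Reuse cached stage outputs when checksums match.
#' @return The manifest, invisibly.
#' @export
run_all <- function(config = default_config(), outdir = NULL, resume = TRUE) {
  cfg <- load_config(if (is.character(config)) config else config)
  outdir <- outdir %||% cfg$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  state_dir <- file.path(outdir, "state")
  dir.create(state_dir, showWarnings = FALSE)
  manifest_path <- file.path(outdir, "manifest.json")
  manifest <- if (resume && file.exists(manifest_path))
    jsonlite::read_json(manifest_path, simplifyVector = TRUE) else
      list(seed = cfg$seed, stages = list())
  cfg_json <- as.character(jsonlite::toJSON(cfg, auto_unbox = TRUE, null = "null"))

  stage <- function(name, outputs, fn) {
    st <- manifest$stages[[name]]
    rds <- file.path(state_dir, paste0(name, ".rds"))
    if (resume && !is.null(st) && identical(st$config, cfg_json) &&
        all(file.exists(outputs)) && file.exists(rds)) {
      sums <- md5_of(outputs)
      bad <- which(sums != unlist(st$md5))
      if (length(bad))
        stopf("stage %s: checksum mismatch for cached output '%s'",
              name, outputs[bad[1]])
      message(sprintf("[saltmir] stage %-9s cached (%d outputs)", name,
                      length(outputs)))
      return(readRDS(rds))
    }
    message(sprintf("[saltmir] stage %-9s running", name))
    res <- fn()
    stopifnot(all(file.exists(outputs)))
    manifest$stages[[name]] <<- list(config = cfg_json,
                                     outputs = outputs,
                                     md5 = as.list(md5_of(outputs)),
                                     n_records = res$n %||% NA)
    saveRDS(res, rds)
    res
  }

  # --- simulate (or locate user inputs)
  if (isTRUE(cfg$simulate$enabled)) {
    sim_dir <- file.path(outdir, "sim")
    sim_args <- cfg$simulate[setdiff(names(cfg$simulate), "enabled")]
    sim <- stage("simulate",
                 file.path(sim_dir, c("genome.fa", "mature.fa", "precursor.fa",
                                      "ncrna.fa", "transcripts.fa", "genes.gff3",
                                      "repeats.bed", "ground_truth.tsv",
                                      "expected_counts.tsv",
                                      paste0(library_design()$library, ".fastq"))),
                 function() {
                   scfg <- do.call(sim_config, c(list(seed = cfg$seed), sim_args))
                   build <- build_genome(scfg, outdir = sim_dir)
                   libs <- simulate_libraries(build, scfg, outdir = sim_dir)
                   list(n = nrow(build$truth), files = c(build$files, libs$files))
                 })
    inputs <- list(genome = file.path(sim_dir, "genome.fa"),
                   mature = file.path(sim_dir, "mature.fa"),
                   precursor = file.path(sim_dir, "precursor.fa"),
                   ncrna = file.path(sim_dir, "ncrna.fa"),
                   transcripts = file.path(sim_dir, "transcripts.fa"),
                   gff = file.path(sim_dir, "genes.gff3"),
                   repeats = file.path(sim_dir, "repeats.bed"),
                   fastq = setNames(file.path(sim_dir,
                                              paste0(library_design()$library, ".fastq")),
                                    library_design()$library),
                   adapter3 = sim_config(seed = cfg$seed)$adapter3,
                   adapter5 = sim_config(seed = cfg$seed)$adapter5)
  } else {
    inputs <- cfg$inputs
    if (is.null(inputs$fastq)) stopf("config$inputs$fastq required when simulate disabled")
  }

  # --- clean + collapse
  cl <- stage("clean",
              file.path(outdir, c("tags.tsv", "clean_stats.tsv",
                                  "length_histogram.tsv")),
              function() {
                params <- do.call(clean_params, cfg$clean)
                per_lib <- lapply(inputs$fastq, function(p)
                  clean_reads(p, inputs$adapter3, inputs$adapter5, params))
                tags <- collapse_tags(lapply(per_lib, `[[`, "seqs"))
                stats <- do.call(rbind, lapply(names(per_lib), function(lib) {
                  s <- per_lib[[lib]]$stats
                  data.frame(library = lib, raw_reads = s$raw_reads,
                             clean_reads = s$clean_reads,
                             t(as.matrix(s$removed)), stringsAsFactors = FALSE)
                }))
                hist <- do.call(rbind, lapply(names(per_lib), function(lib) {
                  h <- per_lib[[lib]]$stats$length_histogram
                  data.frame(library = lib, length = as.integer(names(h)),
                             reads = as.integer(h), stringsAsFactors = FALSE)
                }))
                write_tsv(tags, file.path(outdir, "tags.tsv"))
                write_tsv(stats, file.path(outdir, "clean_stats.tsv"))
                write_tsv(hist, file.path(outdir, "length_histogram.tsv"))
                list(n = nrow(tags), tags = tags, stats = stats)
              })
  tags <- cl$tags
  N_clean <- setNames(cl$stats$clean_reads, cl$stats$library)

  genome <- Biostrings::readDNAStringSet(inputs$genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  mature_ref <- read_fasta(inputs$mature)
  ncrna_ref <- read_fasta(inputs$ncrna)

  # --- annotate
  an <- stage("annotate",
              file.path(outdir, c("annotation.tsv", "category_summary.tsv")),
              function() {
                res <- annotate_tags(tags, genome, mature_ref, ncrna_ref,
                                     inputs$gff, inputs$repeats,
                                     max_mm_mirna = cfg$annotate$max_mm)
                cs <- category_summary(res$annotation, tags)
                write_tsv(res$annotation, file.path(outdir, "annotation.tsv"))
                write_tsv(cs, file.path(outdir, "category_summary.tsv"))
                list(n = nrow(res$annotation), annotation = res$annotation,
                     hits = res$hits)
              })

  # --- discover
  dis <- stage("discover",
               file.path(outdir, c("mirna_catalog.tsv", "family_summary.tsv",
                                   "precursors.fa")),
               function() {
                 params <- do.call(discovery_params,
                                   cfg$discover[names(cfg$discover) %in%
                                                  names(formals(discovery_params))])
                 precursor_ref <- if (!is.null(inputs$precursor))
                   read_fasta(inputs$precursor) else NULL
                 cons <- call_conserved(tags, mature_ref, precursor_ref,
                                        genome, params)
                 cons_loci <- do.call(rbind, lapply(cons, function(r) {
                   if (is.null(r$precursor_locus)) return(NULL)
                   data.frame(chrom = r$precursor_locus$chrom,
                              start = r$precursor_locus$start - 160L,
                              end = r$precursor_locus$end + 160L,
                              stringsAsFactors = FALSE)
                 }))
                 nov <- call_novel(tags, an$annotation, genome, params,
                                   exclude_loci = cons_loci)
                 recs <- c(cons, nov)
                 cat_df <- mirna_catalog(recs, names(N_clean))
                 write_tsv(cat_df, file.path(outdir, "mirna_catalog.tsv"))
                 fam <- if (length(cons)) family_summary(cons, names(N_clean)) else
                   data.frame(family = character(0))
                 write_tsv(fam, file.path(outdir, "family_summary.tsv"))
                 prec <- setNames(vapply(recs, `[[`, "", "precursor_seq"),
                                  vapply(recs, `[[`, "", "id"))
                 write_fasta(prec, file.path(outdir, "precursors.fa"), rna = TRUE)
                 list(n = length(recs), records = recs, catalog = cat_df)
               })

  # --- targets
  tg <- stage("targets", file.path(outdir, "targets.tsv"), function() {
    catal <- dis$catalog
    sites <- if (nrow(catal)) {
      predict_targets(setNames(catal$mature_seq, catal$id),
                      read_fasta(inputs$transcripts),
                      max_score = cfg$targets$max_score)
    } else data.frame()
    if (!is.null(cfg$targets$annotation_tsv) && nrow(sites))
      sites <- annotate_targets(sites, cfg$targets$annotation_tsv)
    write_tsv(sites, file.path(outdir, "targets.tsv"))
    list(n = nrow(sites), sites = sites)
  })

  # --- differential expression
  de_files <- vapply(cfg$de$pairs, function(p)
    file.path(outdir, sprintf("de_%s_vs_%s.tsv", p$treatment, p$control)),
    character(1))
  de <- stage("de", de_files, function() {
    catal <- dis$catalog
    res <- list()
    for (p in cfg$de$pairs) {
      f <- file.path(outdir, sprintf("de_%s_vs_%s.tsv", p$treatment, p$control))
      if (nrow(catal) == 0) { write_tsv(data.frame(), f); next }
      counts <- data.frame(mirna_id = catal$id,
                           catal[, c(p$treatment, p$control)],
                           check.names = FALSE)
      r <- call_de(counts, p$treatment, p$control,
                   N1 = N_clean[[p$treatment]], N2 = N_clean[[p$control]],
                   fc_cut = cfg$de$fc_cut, p_cut = cfg$de$p_cut,
                   min_norm = cfg$de$min_norm, fdr = isTRUE(cfg$de$fdr))
      write_tsv(r, f)
      res[[paste(p$treatment, p$control, sep = "_vs_")]] <- r
    }
    list(n = length(res), results = res)
  })

  # --- report: common/specific tables per DE pair
  rep_files <- vapply(cfg$de$pairs, function(p)
    file.path(outdir, sprintf("common_specific_%s_%s.tsv", p$treatment, p$control)),
    character(1))
  stage("report", rep_files, function() {
    for (p in cfg$de$pairs) {
      f <- file.path(outdir, sprintf("common_specific_%s_%s.tsv",
                                     p$treatment, p$control))
      if (all(c(p$treatment, p$control) %in% colnames(tags))) {
        write_tsv(common_specific_summary(tags, p$treatment, p$control), f)
      } else {
        message(sprintf("[saltmir] single-library run: skipping %s", f))
        write_tsv(data.frame(note = "pair not present"), f)
      }
    }
    list(n = length(cfg$de$pairs))
  })

  manifest$seed <- cfg$seed
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
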