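# internal helpers shared across modules

# canonical internal alphabet is DNA (T and U identified), uppercase
to_dna <- function(x) toupper(chartr("Uu", "Tt", x))
to_rna <- function(x) toupper(chartr("Tt", "Uu", x))

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(to_dna(x))))
}

# deterministic child seed (kept well below 2^31)
child_seed <- function(seed, k) (as.integer(seed) %% 1000000L) * 1000L + as.integer(k)

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
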