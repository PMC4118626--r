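#' Fold an RNA sequence into its minimum-free-energy secondary structure
#'
#' Computes the minimum-free-energy (MFE) structure of a single sequence
#' under a simplified nearest-neighbor thermodynamic model (Turner-style
#' stacking energies, length-dependent hairpin/bulge/internal loop
#' penalties, affine multiloop penalty, minimum hairpin loop of 3).
#' Folding is deterministic; when no favorable pairing exists the open
#' chain (all dots, 0 kcal/mol) is returned.
#'
#' @param sequence A single string over A,C,G,U (T is accepted and treated
#'   as U), at least 15 nt long.
#' @return An object of class `hairpin_fold`: a list with elements
#'   `sequence` (RNA-space, uppercase), `structure` (dot-bracket) and
#'   `mfe` (kcal/mol, `<= 0`).
#' @examples
#' rna_fold("GGGGGGGAAAACCCCCCC")
#' @export
rna_fold <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  seq <- to_rna(sequence)
  if (nchar(seq) < 15L) stopf("sequence must be at least 15 nt (got %d)", nchar(seq))
  if (grepl("[^ACGU]", seq)) stopf("invalid alphabet: sequence must be over {A,C,G,U/T}")
  res <- c_fold(seq)
  structure(list(sequence = seq, structure = res$structure, mfe = res$mfe),
            class = "hairpin_fold")
}

#' Evaluate the free energy of a given structure
#'
#' Scores an explicit dot-bracket structure by loop decomposition under the
#' same energy parameters as [rna_fold()]. This is an independent route to
#' an energy (no dynamic program involved) and is what the brute-force
#' enumeration oracle uses internally.
#'
#' @param sequence RNA/DNA string.
#' @param structure Dot-bracket string of the same length.
#' @return Free energy in kcal/mol.
#' @export
structure_energy <- function(sequence, structure) {
  c_eval_structure(to_rna(sequence), structure)
}

#' @export
print.hairpin_fold <- function(x, ...) {
  cat(x$sequence, "\n", x$structure, sprintf(" (%.2f)\n", x$mfe), sep = "")
  invisible(x)
}

# pair table from dot-bracket: integer vector, 0 = unpaired, else partner (1-based)
pair_table <- function(structure) {
  ch <- strsplit(structure, "")[[1]]
  pt <- integer(length(ch))
  stack <- integer(0)
  for (k in seq_along(ch)) {
    if (ch[k] == "(") stack <- c(stack, k)
    else if (ch[k] == ")") {
      i <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- k; pt[k] <- i
    }
  }
  pt
}

#' Decide whether a fold qualifies as a single-stem miRNA hairpin
#'
#' The structure's stems are the chains of nested pairs above each
#' terminal (hairpin) loop, followed outward while every enclosing loop
#' has a single branch (stacks, bulges, internal loops). A fold qualifies
#' when exactly one terminal loop sits on a stem of at least
#' `min_stem_pairs` pairs and the MFE is at or below `mfe_max`; incidental
#' short side-stems in flanking sequence do not disqualify a candidate,
#' but a second long stem (two substantial terminal loops) does.
#'
#' @param fold A `hairpin_fold` from [rna_fold()].
#' @param min_stem_pairs Minimum number of base pairs on the main stem
#'   (default 16).
#' @param mfe_max Maximum (least negative) acceptable MFE in kcal/mol
#'   (default -18, just below the weakest precursors typically accepted for
#'   novel plant miRNAs).
#' @return A list: `is_hairpin` (logical), `n_pairs` (pairs on the main
#'   stem), `loop` (1-based first/last position of its terminal loop, or
#'   NULL), `arm5` and `arm3` (1-based coordinate ranges of the two arms
#'   of the main stem, or NULL).
#' @export
is_hairpin <- function(fold, min_stem_pairs = 16L, mfe_max = -18) {
  stopifnot(inherits(fold, "hairpin_fold"))
  pt <- pair_table(fold$structure)
  opens <- which(pt > seq_along(pt))         # closing pairs i < j
  fail <- list(is_hairpin = FALSE, n_pairs = 0L, loop = NULL,
               arm5 = NULL, arm3 = NULL)
  if (length(opens) == 0L) return(fail)
  # parent (innermost enclosing pair) and child count of every pair
  parent <- setNames(rep(NA_integer_, length(opens)), opens)
  children <- setNames(rep(0L, length(opens)), opens)
  stack <- integer(0)
  for (k in seq_along(pt)) {
    if (pt[k] > k) {                         # opening bracket
      if (length(stack)) {
        parent[as.character(k)] <- stack[length(stack)]
        ck <- as.character(stack[length(stack)])
        children[ck] <- children[ck] + 1L
      }
      stack <- c(stack, k)
    } else if (pt[k] > 0L && pt[k] < k) {
      stack <- stack[-length(stack)]
    }
  }
  terminal <- opens[children[as.character(opens)] == 0L]
  stems <- lapply(terminal, function(i) {
    chain <- i
    repeat {
      p <- parent[as.character(chain[length(chain)])]
      if (is.na(p) || children[as.character(p)] != 1L) break
      chain <- c(chain, p)
    }
    chain
  })
  sizes <- lengths(stems)
  big <- which(sizes >= min_stem_pairs)
  if (length(big) != 1L) return(fail)
  if (fold$mfe > mfe_max) return(fail)
  stem <- unname(stems[[big]])
  i <- stem[1]; j <- pt[i]                   # innermost pair (terminal loop)
  o <- stem[length(stem)]                    # outermost pair of the stem
  list(is_hairpin = TRUE, n_pairs = unname(sizes[big]),
       loop = c(i + 1L, j - 1L),
       arm5 = c(o, i), arm3 = c(j, pt[o]))
}

#' Check a mature/star duplex on a folded precursor
#'
#' Given the precursor fold and the 1-based coordinate ranges of a mature
#' and a candidate star sequence on it, computes duplex statistics: the
#' fraction of mature bases paired, the number of unpaired (mismatched)
#' mature bases, and the star's 3' overhang relative to the duplex (2 nt is
#' the canonical Dicer signature).
#'
#' @param fold A `hairpin_fold`.
#' @param mature_range,star_range Integer vectors `c(start, end)`, 1-based
#'   inclusive, on the precursor.
#' @return A list with `paired_fraction`, `duplex_mismatches`, `overhang3`,
#'   and `opposite_arms` (logical: star pairs back into the mature range).
#' @export
duplex_check <- function(fold, mature_range, star_range) {
  pt <- pair_table(fold$structure)
  mi <- mature_range[1]:mature_range[2]
  si <- star_range[1]:star_range[2]
  if (length(intersect(mi, si)) > 0L)
    return(list(paired_fraction = 0, duplex_mismatches = length(mi),
                overhang3 = NA_integer_, opposite_arms = FALSE))
  partners <- pt[mi]
  partners <- partners[partners > 0L]
  paired_into_star <- partners[partners %in% si]
  if (length(partners) == 0L || length(paired_into_star) == 0L)
    return(list(paired_fraction = 0, duplex_mismatches = length(mi),
                overhang3 = NA_integer_, opposite_arms = FALSE))
  # star 3' overhang: how far the star's 3' end extends past the partner of
  # the mature 5' end (identical formula for 5p and 3p mature)
  overhang3 <- star_range[2] - max(partners)
  list(paired_fraction = length(paired_into_star) / length(mi),
       duplex_mismatches = sum(pt[mi] == 0L) +
         sum(!(pt[mi] == 0L) & !(pt[mi] %in% si)),
       overhang3 = as.integer(overhang3),
       opposite_arms = TRUE)
}

#' Write folds in Vienna format
#'
#' @param folds A `hairpin_fold` or list of them; names become headers.
#' @param path Output file.
#' @export
write_vienna <- function(folds, path) {
  if (inherits(folds, "hairpin_fold")) folds <- list(fold = folds)
  lines <- unlist(lapply(seq_along(folds), function(i) {
    f <- folds[[i]]
    c(paste0(">", names(folds)[i] %||% paste0("seq", i)),
      f$sequence,
      sprintf("%s (%.2f)", f$structure, f$mfe))
  }))
  writeLines(lines, path)
  invisible(path)
}
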