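#' Reads-per-million normalization
#'
#' `count * 1e6 / N`, where N is the library's total clean reads.
#'
#' @param count Raw count(s), `>= 0`.
#' @param N Total clean reads of the library, `> 0`.
#' @return Normalized expression (RPM), unrounded.
#' @export
rpm <- function(count, N) {
  if (any(N <= 0)) stopf("total clean reads N must be > 0")
  if (any(count < 0)) stopf("counts must be non-negative")
  count * 1e6 / N
}

#' Exact count-ratio probability mass p(y | x)
#'
#' The conditional distribution of observing `y` reads in library 2 given
#' `x` reads in library 1, with library sizes N1 and N2:
#' \deqn{p(y|x) = (N2/N1)^y \frac{(x+y)!}{x!\,y!\,(1+N2/N1)^{x+y+1}}}
#' computed in log space via log-gamma. Summed over all y it equals 1
#' (it is the negative-binomial NB(x+1, N1/(N1+N2)) mass at y).
#'
#' @param y,x Non-negative integer counts (vectorized over `y`).
#' @param N1,N2 Library sizes (total clean reads).
#' @param log Return the log probability.
#' @export
ac_pmf <- function(y, x, N1, N2, log = FALSE) {
  if (any(x < 0) || any(y < 0)) stopf("counts must be non-negative")
  if (N1 <= 0 || N2 <= 0) stopf("library sizes must be positive")
  r <- N2 / N1
  lp <- y * base::log(r) + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
    (x + y + 1) * log1p(r)
  if (log) lp else exp(lp)
}

#' Audic-Claverie exact test for a count difference between two libraries
#'
#' Computes the lower-tail probability `C = sum_{k<=y} p(k|x)`, the
#' upper-tail `D = sum_{k>=y} p(k|x)` (so `C + D = 1 + p(y|x)`), and the
#' two-sided p-value `min(1, 2*min(C, D))`. The smaller tail is summed
#' directly in probability space from log-gamma terms, so extreme tails
#' keep full relative precision.
#'
#' @param x,y Observed counts in library 1 and library 2.
#' @param N1,N2 Library sizes.
#' @return A list `C`, `D`, `p_two_sided`, `p_point` (the mass at y).
#' @export
ac_test <- function(x, y, N1, N2) {
  stopifnot(length(x) == 1L, length(y) == 1L)
  r <- N2 / N1
  p_y <- ac_pmf(y, x, N1, N2)
  mode_y <- x * r
  if (y <= mode_y || y <= 1) {
    C <- sum(ac_pmf(0:y, x, N1, N2))
    D <- 1 - C + p_y
  } else {
    # sum the upper tail until increments vanish
    block <- 256L
    D <- 0; k <- y
    repeat {
      ks <- k:(k + block - 1L)
      vals <- ac_pmf(ks, x, N1, N2)
      D <- D + sum(vals)
      if (vals[block] < D * 1e-17 || vals[block] == 0) break
      k <- k + block
    }
    C <- 1 - D + p_y
  }
  C <- min(max(C, 0), 1); D <- min(max(D, 0), 1)
  list(C = C, D = D, p_two_sided = min(1, 2 * min(C, D)), p_point = p_y)
}

#' Call differentially expressed miRNAs between two libraries
#'
#' Normalizes counts to reads-per-million, removes miRNAs whose normalized
#' expression is below `min_norm` in both libraries, computes
#' `log2(treatment/control)` (a zero on one side is substituted with
#' `min_norm` RPM to bound the fold-change; the substitution is flagged),
#' and tests each miRNA with the exact count-ratio test. A miRNA is `up`
#' when `log2fc > fc_cut` and `p < p_cut`, `down` when `log2fc < -fc_cut`
#' and `p < p_cut`, otherwise `unchanged`.
#'
#' @param counts data.frame with column `mirna_id` plus count columns, or a
#'   named count matrix.
#' @param treatment,control Library column names.
#' @param N1,N2 Total clean reads of treatment and control; default: column
#'   sums of `counts` (appropriate when the table covers the library).
#' @param fc_cut Absolute log2 fold-change threshold (default 0.5).
#' @param p_cut Two-sided p-value threshold (default 0.05).
#' @param min_norm RPM floor (default 1.0).
#' @param fdr Apply Benjamini-Hochberg adjustment before calling (default
#'   FALSE: single-test p-values, no multiple-testing correction).
#' @return data.frame of per-miRNA results: raw counts `x` (treatment) and
#'   `y` (control), `norm1`, `norm2`, `log2fc`, `C`, `D`, `p_two_sided`,
#'   optionally `p_adj`, `substituted`, and `call` in
#'   up/down/unchanged/filtered.
#' @export
call_de <- function(counts, treatment, control, N1 = NULL, N2 = NULL,
                    fc_cut = 0.5, p_cut = 0.05, min_norm = 1.0, fdr = FALSE) {
  if (is.matrix(counts))
    counts <- data.frame(mirna_id = rownames(counts), counts,
                         stringsAsFactors = FALSE)
  stopifnot(treatment %in% colnames(counts), control %in% colnames(counts))
  x <- counts[[treatment]]; y <- counts[[control]]
  N1 <- N1 %||% sum(x); N2 <- N2 %||% sum(y)
  norm1 <- rpm(x, N1); norm2 <- rpm(y, N2)
  filtered <- norm1 < min_norm & norm2 < min_norm
  s1 <- ifelse(norm1 == 0, min_norm, norm1)
  s2 <- ifelse(norm2 == 0, min_norm, norm2)
  substituted <- (norm1 == 0 | norm2 == 0) & !filtered
  log2fc <- log2(s1 / s2)
  tests <- lapply(seq_along(x), function(i) ac_test(x[i], y[i], N1, N2))
  C <- vapply(tests, `[[`, 0, "C")
  D <- vapply(tests, `[[`, 0, "D")
  p <- vapply(tests, `[[`, 0, "p_two_sided")
  p_eff <- p
  out <- data.frame(mirna_id = counts$mirna_id, x = x, y = y,
                    norm1 = norm1, norm2 = norm2, log2fc = log2fc,
                    C = C, D = D, p_two_sided = p,
                    substituted = substituted, stringsAsFactors = FALSE)
  if (fdr) {
    p_eff[filtered] <- NA
    p_eff[!filtered] <- p.adjust(p[!filtered], method = "BH")
    out$p_adj <- p_eff
  }
  call <- ifelse(filtered, "filtered",
                 ifelse(log2fc > fc_cut & p_eff < p_cut, "up",
                        ifelse(log2fc < -fc_cut & p_eff < p_cut, "down",
                               "unchanged")))
  out$call <- call
  out
}
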