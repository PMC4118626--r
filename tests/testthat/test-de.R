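test_that("reads-per-million normalization follows the exact formula", {
  expect_equal(rpm(50, 1e6), 50)
  expect_equal(rpm(0, 123456), 0)
  expect_equal(rpm(123, 16300000), 7.54601226993865, tolerance = 1e-12)
  expect_error(rpm(1, 0), "N must be > 0")
  expect_error(rpm(-1, 10), "non-negative")
})

test_that("exact-test pmf matches analytic values and sums to one", {
  expect_equal(ac_pmf(0, 0, 1e6, 1e6), 0.5)
  expect_equal(ac_pmf(0, 1, 1e6, 1e6), 0.25)
  # arbitrary-precision reference values (exact rational evaluation)
  expect_equal(ac_pmf(13, 7, 2e6, 1e6), 0.00189717494379716, tolerance = 1e-12)
  expect_equal(ac_pmf(5, 3, 1e6, 2e6), 0.0910430320581212, tolerance = 1e-12)
  expect_equal(ac_pmf(20, 20, 1e6, 1e6), 0.0626853438097896, tolerance = 1e-12)
  expect_equal(ac_pmf(10, 0, 1e6, 1e7), 0.0350493899481392, tolerance = 1e-12)
  expect_equal(ac_pmf(5, 50, 1e7, 1e6), 0.167276226828356, tolerance = 1e-12)
  for (x in c(0, 5, 50, 200)) {
    for (r in c(0.1, 1, 10)) {
      s <- sum(ac_pmf(0:20000, x, 1e6, r * 1e6))
      expect_equal(s, 1, tolerance = 1e-9)
    }
  }
  expect_error(ac_pmf(-1, 0, 1e6, 1e6), "non-negative")
})

test_that("pmf equals the direct product-formula oracle", {
  set.seed(41)
  for (i in 1:200) {
    x <- sample(0:80, 1); y <- sample(0:80, 1)
    r <- sample(c(0.1, 0.5, 1, 2, 10), 1)
    a <- ac_pmf(y, x, 1e6, r * 1e6)
    b <- brute_ac_pmf(y, x, 1e6, r * 1e6)
    expect_equal(a, b, tolerance = 1e-11)
  }
})

test_that("tail probabilities behave as an exact test should", {
  t0 <- ac_test(0, 0, 1e6, 1e6)
  expect_equal(t0$C, 0.5); expect_equal(t0$D, 1.0)
  # C + D = 1 + p(y|x)
  for (x in c(3, 40)) for (y in c(0, 10, 60)) {
    tt <- ac_test(x, y, 1e6, 2e6)
    expect_equal(tt$C + tt$D, 1 + ac_pmf(y, x, 1e6, 2e6), tolerance = 1e-9)
    expect_gte(tt$p_two_sided, ac_pmf(y, x, 1e6, 2e6) * 0)  # in [0,1]
    expect_lte(tt$p_two_sided, 1)
  }
  # label symmetry up to the boundary point mass: with the inclusive tail
  # definitions, C(x,y;N1,N2) = D(y,x;N2,N1) - p(x|y) exactly (the spec's
  # stated exact swap does not hold for inclusive tails; see ledger)
  a <- ac_test(12, 30, 1.5e6, 0.7e6)
  b <- ac_test(30, 12, 0.7e6, 1.5e6)
  expect_equal(a$C, b$D - b$p_point, tolerance = 1e-12)
  expect_equal(a$D - a$p_point, b$C, tolerance = 1e-12)
  # extreme difference -> vanishing p
  expect_lt(ac_test(100, 0, 1e6, 1e6)$p_two_sided, 1e-6)
  # monotonicity: C non-decreasing in y for fixed x
  Cs <- vapply(0:50, function(y) ac_test(10, y, 1e6, 1e6)$C, numeric(1))
  expect_true(all(diff(Cs) >= -1e-12))
  # independent-route check: C equals the negative-binomial CDF
  expect_equal(ac_test(25, 13, 1e6, 3e6)$C,
               stats::pnbinom(13, size = 26, prob = 1 / (1 + 3)),
               tolerance = 1e-12)
})

test_that("call_de applies thresholds, filtering and zero substitution", {
  counts <- data.frame(
    mirna_id = c("up", "flat", "low", "off"),
    T = c(800, 300, 40, 0),
    C = c(200, 300, 45, 250), stringsAsFactors = FALSE)
  res <- call_de(counts, "T", "C", N1 = 1e8, N2 = 1e8)
  expect_equal(res$log2fc[1], 2)
  expect_equal(res$call[1], "up")
  expect_equal(res$call[2], "unchanged")
  expect_equal(res$log2fc[2], 0)
  expect_equal(res$call[3], "filtered")   # both RPM < 1
  expect_equal(res$call[4], "down")
  expect_true(res$substituted[4])
  expect_equal(res$log2fc[4], log2(1 / rpm(250, 1e8)))
  # norm columns follow the formula
  expect_equal(res$norm1, rpm(counts$T, 1e8))
})

test_that("type-I error of the exact test is controlled under the null", {
  set.seed(43)
  n <- 2000
  lam <- sample(c(5, 10, 20, 50, 100, 200), n, replace = TRUE)
  x <- rpois(n, lam); y <- rpois(n, lam)
  p <- vapply(seq_len(n), function(i) ac_test(x[i], y[i], 1e6, 1e6)$p_two_sided,
              numeric(1))
  expect_lte(mean(p < 0.05), 0.07)
})

test_that("planted two-fold-change loci are called in the right direction", {
  set.seed(44)
  n <- 1000
  disp <- 0.05
  mu <- sample(c(50, 100, 400), n, replace = TRUE)
  x <- rnbinom(n, mu = 4 * mu, size = 1 / disp)   # treatment, log2fc = +2
  y <- rnbinom(n, mu = mu, size = 1 / disp)
  ok <- vapply(seq_len(n), function(i) {
    tt <- ac_test(x[i], y[i], 1e6, 1e6)
    lfc <- log2(max(x[i], 1) / max(y[i], 1))
    lfc > 0.5 && tt$p_two_sided < 0.05
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("optional BH adjustment only tightens calls", {
  set.seed(45)
  counts <- data.frame(mirna_id = paste0("m", 1:50),
                       T = rpois(50, 100), C = rpois(50, 100))
  counts$T[1] <- 600
  raw <- call_de(counts, "T", "C", N1 = 1e7, N2 = 1e7)
  adj <- call_de(counts, "T", "C", N1 = 1e7, N2 = 1e7, fdr = TRUE)
  expect_true(all(adj$p_adj >= raw$p_two_sided - 1e-12, na.rm = TRUE))
  called_raw <- raw$mirna_id[raw$call %in% c("up", "down")]
  called_adj <- adj$mirna_id[adj$call %in% c("up", "down")]
  expect_true(all(called_adj %in% called_raw))
})
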