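test_that("read_ma parses, validates and round-trips the .ma dialect", {
  path <- write_ma_fixture()
  d <- read_ma(path)
  expect_s3_class(d, "summary_dataset")
  expect_equal(d$SNP, c("rs1", "rs2", "rs3"))  # row order preserved
  expect_equal(d$b, c(0.1, -0.05, 0.02))

  # write -> read is the identity
  out <- file.path(tempdir(), "roundtrip.ma")
  write_ma(d, out)
  d2 <- read_ma(out)
  expect_equal(as.data.frame(d2), as.data.frame(d), ignore_attr = TRUE)

  # header-only file: empty dataset with a warning
  empty <- file.path(tempdir(), "empty.ma")
  writeLines("SNP A1 A2 freq b se p N", empty)
  expect_warning(e <- read_ma(empty), "no data rows")
  expect_equal(nrow(e), 0L)

  # missing column is a format error
  badcol <- file.path(tempdir(), "badcol.ma")
  writeLines(c("SNP A1 A2 freq b se p", "rs1 A G 0.2 0.1 0.01 1e-8"), badcol)
  expect_error(read_ma(badcol), "missing required column.*N")

  # duplicate SNP id named in the error
  dup <- write_ma_fixture(name = "dup.ma", snp = c("rs1", "rs1", "rs3"))
  expect_error(read_ma(dup), "duplicate SNP id.*rs1")

  # malformed numeric: fail-fast by default, skip-with-warning when lenient
  badnum <- file.path(tempdir(), "badnum.ma")
  writeLines(c("SNP A1 A2 freq b se p N",
               "rs1 A G 0.2 0.1 0.01 1e-8 1000",
               "rs2 A G 0.2 oops 0.01 1e-8 1000"), badnum)
  expect_error(read_ma(badnum), "line")
  expect_warning(lenient <- read_ma(badnum, lenient = TRUE), "dropped")
  expect_equal(lenient$SNP, "rs1")

  # missing freq is allowed (standardization unavailable, not an error)
  nafreq <- file.path(tempdir(), "nafreq.ma")
  writeLines(c("SNP A1 A2 freq b se p N", "rs1 A G NA 0.1 0.01 1e-8 1000"),
             nafreq)
  expect_true(is.na(read_ma(nafreq)$freq))
})

test_that("z-score standardization matches the closed form and preserves z", {
  # direct evaluation of b = z / sqrt(2p(1-p)(n + z^2)) as the oracle
  s <- standardize_from_z(5, 0.5, 10000)
  expect_equal(s$b, 5 / sqrt(2 * 0.25 * (10000 + 25)), tolerance = 1e-12)
  expect_equal(s$b, 0.070623, tolerance = 1e-5)
  expect_equal(s$se, 0.0141246, tolerance = 1e-5)

  z0 <- standardize_from_z(0, 0.5, 100)
  expect_equal(z0$b, 0)
  expect_equal(z0$se, 1 / sqrt(50))

  # antisymmetry and b/se == z for random valid inputs
  set.seed(11)
  for (i in 1:50) {
    z <- rnorm(1, 0, 5); p <- runif(1, 0.01, 0.99); n <- runif(1, 50, 1e6)
    s <- standardize_from_z(z, p, n)
    expect_equal(s$b / s$se, z, tolerance = 1e-10)
    sm <- standardize_from_z(-z, p, n)
    expect_equal(sm$b, -s$b)
    expect_equal(sm$se, s$se)
  }
  expect_error(standardize_from_z(1, 1.2, 100), "eaf")
  expect_error(standardize_from_z(1, 0.5, -5), "n must be")
})

test_that("inverse-variance meta-analysis matches the weighted-mean oracle", {
  m <- ivw_meta(0.1, 0.1, 0.3, 0.2)
  expect_equal(m$b, (0.1 / 0.01 + 0.3 / 0.04) / (1 / 0.01 + 1 / 0.04))
  expect_equal(m$b, 0.14)
  expect_equal(m$se, 1 / sqrt(125))

  # equal SEs -> simple average; huge se2 -> first estimate dominates
  expect_equal(ivw_meta(0.2, 0.05, 0.4, 0.05)$b, 0.3)
  lim <- ivw_meta(0.1, 0.1, 99, 1e8)
  expect_equal(lim$b, 0.1, tolerance = 1e-10)
  expect_equal(lim$se, 0.1, tolerance = 1e-10)

  # meta-analysis of a dataset with itself halves the variance
  self <- ivw_meta(0.17, 0.03, 0.17, 0.03)
  expect_equal(self$se, 0.03 / sqrt(2))
  expect_error(ivw_meta(0.1, 0, 0.2, 0.1), "must be > 0")
})

test_that("harmonize aligns alleles across all coding cases", {
  expo <- summary_dataset(SNP = paste0("rs", 1:6),
                          A1 = c("A", "A", "A", "A", "A", "A"),
                          A2 = c("G", "G", "G", "G", "T", "T"),
                          freq = c(0.2, 0.2, 0.2, 0.2, 0.5, 0.2),
                          b = rep(0.1, 6), se = rep(0.01, 6),
                          p = rep(1e-10, 6), N = rep(1e4, 6))
  # outcome codings: identical, swapped, complement, complement-swapped,
  # palindromic ambiguous-frequency, palindromic frequency-resolvable (flip)
  outc <- summary_dataset(SNP = paste0("rs", 1:6),
                          A1 = c("A", "G", "T", "C", "A", "T"),
                          A2 = c("G", "A", "C", "T", "T", "A"),
                          freq = c(0.2, 0.8, 0.2, 0.8, 0.5, 0.81),
                          b = c(0.05, -0.05, 0.05, -0.05, 0.03, -0.04),
                          se = rep(0.01, 6), p = rep(0.01, 6), N = rep(1e4, 6))
  h <- suppressMessages(harmonize(expo, outc, paste0("rs", 1:6)))
  expect_setequal(h$SNP, c("rs1", "rs2", "rs3", "rs4", "rs6"))  # rs5 dropped
  expect_equal(h$bzy[h$SNP == "rs1"], 0.05)   # identical: unchanged
  expect_equal(h$bzy[h$SNP == "rs2"], 0.05)   # swapped: sign flipped
  expect_equal(h$bzy[h$SNP == "rs3"], 0.05)   # complement strand: unchanged
  expect_equal(h$bzy[h$SNP == "rs4"], 0.05)   # complement + swapped: flipped
  # palindrome with informative frequency: aligned by frequency (flip)
  expect_equal(h$bzy[h$SNP == "rs6"], 0.04)

  # keep-palindromic retains the ambiguous SNP with a warning
  expect_warning(hk <- suppressMessages(
    harmonize(expo, outc, paste0("rs", 1:6), keep_palindromic = TRUE)),
    "palindromic")
  expect_true("rs5" %in% hk$SNP)

  # idempotence: re-harmonizing the aligned records changes nothing
  expo2 <- summary_dataset(SNP = h$SNP, A1 = h$A1, A2 = h$A2, freq = h$freq,
                           b = h$bzx, se = h$se_bzx, p = h$p_zx, N = h$n_x)
  outc2 <- summary_dataset(SNP = h$SNP, A1 = h$A1, A2 = h$A2, freq = h$freq,
                           b = h$bzy, se = h$se_bzy, p = h$p_zy, N = h$n_y)
  h2 <- harmonize(expo2, outc2, h$SNP)
  expect_equal(h2$bzy, h$bzy)
  expect_equal(h2$bzx, h$bzx)

  # irreconcilable allele pairs dropped; empty result errors
  outc_bad <- summary_dataset(SNP = "rs1", A1 = "C", A2 = "G", freq = 0.2,
                              b = 0.1, se = 0.01, p = 0.01, N = 1e4)
  expect_error(suppressMessages(harmonize(expo, outc_bad, "rs1")),
               "no SNPs survived")
})

test_that("downstream estimate is invariant to outcome allele coding", {
  set.seed(42)
  tr <- sim_truth(m = 20, b_xy = 0.25, seed = 5)
  sim <- sample_sumstats_direct(tr, n_x = 5e4, n_y = 5e4, seed = 6)
  fit1 <- gsmr(sim$exposure, sim$outcome, options = gsmr_options(force = TRUE))
  # recode outcome on swapped alleles with negated effects
  flipped <- summary_dataset(SNP = sim$outcome$SNP, A1 = sim$outcome$A2,
                             A2 = sim$outcome$A1, freq = 1 - sim$outcome$freq,
                             b = -sim$outcome$b, se = sim$outcome$se,
                             p = sim$outcome$p, N = sim$outcome$N,
                             chr = sim$outcome$chr, bp = sim$outcome$bp,
                             trait_name = "outcome")
  fit2 <- gsmr(sim$exposure, flipped, options = gsmr_options(force = TRUE))
  expect_equal(fit2$bxy, fit1$bxy, tolerance = 1e-12)
  expect_equal(fit2$se, fit1$se, tolerance = 1e-12)
})

test_that("meta_analyze combines two cohorts SNP-wise", {
  d1 <- summary_dataset(SNP = c("rs1", "rs2"), A1 = c("A", "C"),
                        A2 = c("G", "T"), freq = c(0.2, 0.4),
                        b = c(0.1, -0.2), se = c(0.1, 0.05),
                        p = c(0.32, 6.3e-5), N = c(1e4, 1e4))
  d2 <- summary_dataset(SNP = c("rs1", "rs2"), A1 = c("A", "C"),
                        A2 = c("G", "T"), freq = c(0.2, 0.4),
                        b = c(0.3, -0.2), se = c(0.2, 0.05),
                        p = c(0.13, 6.3e-5), N = c(2e4, 2e4))
  meta <- meta_analyze(d1, d2)
  expect_equal(meta$b[meta$SNP == "rs1"], 0.14)
  expect_equal(meta$se[meta$SNP == "rs2"], 0.05 / sqrt(2))
  expect_equal(meta$N, c(3e4, 3e4))
})
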