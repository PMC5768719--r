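# Shared fixture builders and independent oracles for the test suite.

# Build a harmonized instrument set directly from vectors (bypasses the
# harmonize() pipeline so estimator tests control their inputs exactly).
make_hset <- function(SNP, bzx, se_bzx, bzy, se_bzy,
                      p_zx = rep(1e-10, length(SNP)),
                      p_zy = rep(0.5, length(SNP)),
                      freq = rep(0.3, length(SNP)),
                      chr = rep("1", length(SNP)),
                      bp = seq_along(SNP) * 1e6) {
  h <- data.frame(SNP = SNP, chr = chr, bp = bp, A1 = "A", A2 = "C",
                  freq = freq, bzx = bzx, se_bzx = se_bzx, p_zx = p_zx,
                  bzy = bzy, se_bzy = se_bzy, p_zy = p_zy,
                  n_x = 5e4, n_y = 5e4, stringsAsFactors = FALSE)
  structure(h, class = c("harmonized_set", "data.frame"),
            exposure = "x", outcome = "y")
}

# Harmonize and keep only genome-wide-significant exposure instruments,
# mirroring the instrument-selection precondition of the estimator.
gws_instruments <- function(exposure, outcome, p_thresh = 5e-8) {
  ids <- exposure$SNP[exposure$p <= p_thresh]
  h <- suppressMessages(harmonize(exposure, outcome, ids))
  h[h$p_zx <= p_thresh, , drop = FALSE]
}

# Stack two summary datasets (disjoint SNP ids) into one trait.
rbind_dataset <- function(d1, d2) {
  d <- rbind(as.data.frame(d1), as.data.frame(d2))
  summary_dataset(SNP = d$SNP, A1 = d$A1, A2 = d$A2, freq = d$freq,
                  b = d$b, se = d$se, p = d$p, N = d$N,
                  chr = d$chr, bp = d$bp,
                  trait_name = attr(d1, "trait_name"),
                  trait_type = attr(d1, "trait_type"))
}

# Small .ma file on disk; returns the path.
write_ma_fixture <- function(dir = tempdir(), name = "fix.ma",
                             snp = c("rs1", "rs2", "rs3"),
                             b = c(0.1, -0.05, 0.02),
                             se = c(0.01, 0.01, 0.02),
                             p = c(1e-20, 1e-6, 0.3),
                             freq = c(0.2, 0.5, 0.4),
                             N = c(1e4, 1e4, 1e4),
                             A1 = c("A", "C", "G"), A2 = c("G", "T", "A")) {
  path <- file.path(dir, name)
  writeLines(c("SNP A1 A2 freq b se p N",
               paste(snp, A1, A2, freq, b, se, p, N)), path)
  path
}

# Independent greedy clumping oracle: direct transcription of the rule,
# O(m^2), no shared code with clump().
brute_clump <- function(snp, chr, bp, p, r, p_thresh, r2_thresh, window_kb) {
  keep <- which(p < p_thresh)
  snp <- snp[keep]; chr <- chr[keep]; bp <- bp[keep]; p <- p[keep]
  r <- r[keep, keep, drop = FALSE]
  out <- character()
  alive <- rep(TRUE, length(snp))
  while (any(alive)) {
    cand <- which(alive)
    o <- cand[order(p[cand], bp[cand], snp[cand])]
    i <- o[1]
    out <- c(out, snp[i])
    alive[i] <- FALSE
    for (j in which(alive)) {
      if (chr[j] == chr[i] && abs(bp[j] - bp[i]) <= window_kb * 1000 &&
          r[i, j]^2 >= r2_thresh)
        alive[j] <- FALSE
    }
  }
  out
}

# Random correlation matrix with unit diagonal (for clumping instances).
random_corr <- function(m) {
  A <- matrix(rnorm(m * (m + 2)), m + 2, m)
  stats::cov2cor(crossprod(A))
}

# Encode a genotype matrix (individuals x SNPs, 0/1/2/NA counts of A1) as a
# PLINK .bed/.bim/.fam fileset; independent test-side encoder used to
# validate the package's reader.
write_plink_fixture <- function(geno, prefix,
                                snp_ids = colnames(geno),
                                chr = rep("1", ncol(geno)),
                                bp = seq_len(ncol(geno)) * 1000,
                                A1 = rep("A", ncol(geno)),
                                A2 = rep("C", ncol(geno))) {
  n <- nrow(geno); m <- ncol(geno)
  code <- matrix(1L, n, m)  # 01 = missing
  code[!is.na(geno) & geno == 2] <- 0L   # hom A1
  code[!is.na(geno) & geno == 1] <- 2L   # het
  code[!is.na(geno) & geno == 0] <- 3L   # hom A2
  bpl <- ceiling(n / 4)
  bytes <- raw(0)
  for (j in seq_len(m)) {
    padded <- c(code[, j], rep(0L, bpl * 4 - n))
    for (k in seq_len(bpl)) {
      q <- padded[(4 * k - 3):(4 * k)]
      bytes <- c(bytes, as.raw(q[1] + q[2] * 4 + q[3] * 16 + q[4] * 64))
    }
  }
  writeBin(c(as.raw(c(0x6c, 0x1b, 0x01)), bytes), paste0(prefix, ".bed"))
  write.table(data.frame(chr, snp_ids, 0, bp, A1, A2),
              paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  write.table(data.frame(paste0("F", 1:n), paste0("I", 1:n), 0, 0, 0, -9),
              paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  prefix
}
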