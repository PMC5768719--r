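#' Read GWAS summary statistics in GCTA-COJO .ma format
#'
#' Parses a whitespace- or tab-delimited text file with the header
#' \code{SNP A1 A2 freq b se p N} into a validated summary dataset.
#' \code{A1} is the effect allele; \code{b} is the per-allele effect on the
#' trait (SD units for quantitative traits, logOR for binary traits),
#' \code{se} its standard error, \code{p} the association P-value and
#' \code{N} the sample size. Extra columns are ignored and \code{"NA"} is
#' treated as missing. Rows with missing \code{freq} or \code{N} are kept
#' (standardization is simply unavailable for them); rows with malformed
#' \code{b}, \code{se} or \code{p} raise an error naming the line unless
#' \code{lenient = TRUE}, in which case they are dropped with a warning.
#'
#' @param path path to a .ma file.
#' @param trait_type \code{"quantitative"} or \code{"binary"}.
#' @param trait_name label for the trait; defaults to the file name.
#' @param lenient drop malformed rows with a warning instead of failing.
#' @return An object of class \code{summary_dataset}: a data.frame with
#'   columns \code{SNP, A1, A2, freq, b, se, p, N} (plus \code{chr, bp}
#'   when present in the input) and attributes \code{trait_name} and
#'   \code{trait_type}. Row order follows the file.
#' @seealso [write_ma()], [harmonize()]
#' @export
read_ma <- function(path, trait_type = c("quantitative", "binary"),
                    trait_name = NULL, lenient = FALSE) {
  trait_type <- match.arg(trait_type)
  if (is.null(trait_name)) trait_name <- sub("\\.ma$", "", basename(path))
  raw <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           na.strings = c("NA", "na", "."),
                           colClasses = NA, check.names = FALSE)
  need <- c("SNP", "A1", "A2", "freq", "b", "se", "p", "N")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0L)
    stop("missing required column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  if (nrow(raw) == 0L) {
    warning("no data rows in ", path)
    return(new_summary_dataset(empty_ma_frame(), trait_name, trait_type))
  }
  keep <- intersect(c("SNP", "chr", "bp", "A1", "A2", "freq", "b", "se", "p", "N"),
                    names(raw))
  d <- raw[, keep, drop = FALSE]
  for (col in c("freq", "b", "se", "p", "N", if ("bp" %in% keep) "bp"))
    d[[col]] <- suppressWarnings(as.numeric(as.character(d[[col]])))
  d$SNP <- as.character(d$SNP)
  d$A1 <- toupper(as.character(d$A1))
  d$A2 <- toupper(as.character(d$A2))
  if ("chr" %in% names(d)) d$chr <- as.character(d$chr)

  # b/se/p must parse; freq/N may be missing (standardization unavailable)
  bad <- which(is.na(d$b) | is.na(d$se) | is.na(d$p))
  if (length(bad) > 0L) {
    msg <- paste0("non-numeric or missing b/se/p at line(s) ",
                  paste(bad + 1L, collapse = ", "), " of ", path)
    if (!lenient) stop(msg)
    warning(msg, "; rows dropped")
    d <- d[-bad, , drop = FALSE]
  }
  validate_summary_records(d, path, lenient = lenient) |>
    new_summary_dataset(trait_name, trait_type)
}

empty_ma_frame <- function() {
  data.frame(SNP = character(), A1 = character(), A2 = character(),
             freq = numeric(), b = numeric(), se = numeric(),
             p = numeric(), N = numeric(), stringsAsFactors = FALSE)
}

new_summary_dataset <- function(d, trait_name, trait_type) {
  rownames(d) <- NULL
  structure(d, trait_name = trait_name, trait_type = trait_type,
            class = c("summary_dataset", "data.frame"))
}

#' Construct a summary dataset from vectors
#'
#' Programmatic constructor mirroring [read_ma()]; applies the same
#' validation (unique SNP ids, alleles differ, se > 0, p in (0, 1],
#' freq strictly inside (0, 1) where present).
#'
#' @param SNP,A1,A2,freq,b,se,p,N per-SNP fields as in the .ma format.
#' @param chr,bp optional chromosome (character) and 1-based position.
#' @param trait_name,trait_type trait label and type.
#' @return A \code{summary_dataset}.
#' @export
summary_dataset <- function(SNP, A1, A2, freq, b, se, p, N,
                            chr = NULL, bp = NULL,
                            trait_name = "trait",
                            trait_type = c("quantitative", "binary")) {
  trait_type <- match.arg(trait_type)
  d <- data.frame(SNP = as.character(SNP), A1 = toupper(A1), A2 = toupper(A2),
                  freq = as.numeric(freq), b = as.numeric(b),
                  se = as.numeric(se), p = as.numeric(p), N = as.numeric(N),
                  stringsAsFactors = FALSE)
  if (!is.null(chr)) d$chr <- as.character(chr)
  if (!is.null(bp)) d$bp <- as.numeric(bp)
  d <- validate_summary_records(d, "summary_dataset()")
  new_summary_dataset(d, trait_name, trait_type)
}

validate_summary_records <- function(d, where, lenient = FALSE) {
  dup <- unique(d$SNP[duplicated(d$SNP)])
  if (length(dup) > 0L)
    stop("duplicate SNP id(s) in ", where, ": ",
         paste(utils::head(dup, 5L), collapse = ", "))
  bad <- which(d$se <= 0 | d$p <= 0 | d$p > 1 | d$A1 == d$A2 |
                 (!is.na(d$freq) & (d$freq <= 0 | d$freq >= 1)) |
                 (!is.na(d$N) & d$N <= 0))
  if (length(bad) > 0L) {
    msg <- paste0("invalid record(s) in ", where, " for SNP(s) ",
                  paste(utils::head(d$SNP[bad], 5L), collapse = ", "),
                  " (check se > 0, 0 < p <= 1, alleles differ, freq in (0,1), N > 0)")
    if (!lenient) stop(msg)
    warning(msg, "; rows dropped")
    d <- d[-bad, , drop = FALSE]
  }
  d
}

#' Write a summary dataset to GCTA-COJO .ma format
#'
#' @param dataset a \code{summary_dataset}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_ma <- function(dataset, path) {
  cols <- intersect(c("SNP", "chr", "bp", "A1", "A2", "freq", "b", "se", "p", "N"),
                    names(dataset))
  utils::write.table(as.data.frame(dataset)[, cols, drop = FALSE], path,
                     quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' Standardize a GWAS effect to SD units from its z-statistic
#'
#' Converts a z-statistic into a per-allele effect and standard error on the
#' standardized-phenotype scale, using the allele frequency and sample size:
#' \deqn{b = z / \sqrt{2p(1-p)(n + z^2)}, \quad se = 1 / \sqrt{2p(1-p)(n + z^2)}}
#' so that \code{b/se} reproduces \code{z} exactly.
#'
#' @param z z-statistic (vectorized).
#' @param eaf effect-allele frequency, strictly in (0, 1).
#' @param n sample size, > 0.
#' @return A list with components \code{b} and \code{se}.
#' @export
standardize_from_z <- function(z, eaf, n) {
  if (any(eaf <= 0 | eaf >= 1)) stop("eaf must be strictly inside (0, 1)")
  if (any(n <= 0)) stop("n must be > 0")
  denom <- sqrt(2 * eaf * (1 - eaf) * (n + z^2))
  list(b = z / denom, se = 1 / denom)
}

#' Inverse-variance-weighted meta-analysis of two effect estimates
#'
#' @param b1,se1 first estimate and its standard error.
#' @param b2,se2 second estimate and its standard error.
#' @return A list with components \code{b} and \code{se}:
#'   \code{b = (b1/se1^2 + b2/se2^2) / (1/se1^2 + 1/se2^2)},
#'   \code{se = (1/se1^2 + 1/se2^2)^(-1/2)}.
#' @export
ivw_meta <- function(b1, se1, b2, se2) {
  if (any(se1 <= 0) || any(se2 <= 0)) stop("standard errors must be > 0")
  w1 <- 1 / se1^2
  w2 <- 1 / se2^2
  list(b = (b1 * w1 + b2 * w2) / (w1 + w2), se = 1 / sqrt(w1 + w2))
}

#' Meta-analyze two summary datasets SNP-by-SNP
#'
#' Harmonizes the second dataset onto the first dataset's effect alleles and
#' applies [ivw_meta()] per SNP over the intersection.
#'
#' @param d1,d2 \code{summary_dataset} objects for the same trait.
#' @param ... passed to [harmonize()].
#' @return A \code{summary_dataset} of meta-analyzed effects on d1's alleles.
#' @export
meta_analyze <- function(d1, d2, ...) {
  h <- harmonize(d1, d2, snp_ids = intersect(d1$SNP, d2$SNP), ...)
  m <- ivw_meta(h$bzx, h$se_bzx, h$bzy, h$se_bzy)
  z2 <- (m$b / m$se)^2
  summary_dataset(SNP = h$SNP, A1 = h$A1, A2 = h$A2, freq = h$freq,
                  b = m$b, se = m$se,
                  p = stats::pchisq(z2, df = 1, lower.tail = FALSE),
                  N = h$n_x + h$n_y,
                  chr = if (all(!is.na(h$chr))) h$chr else NULL,
                  bp = if (all(!is.na(h$bp))) h$bp else NULL,
                  trait_name = attr(d1, "trait_name"),
                  trait_type = attr(d1, "trait_type"))
}

complement_allele <- function(a) {
  chartr("ACGT", "TGCA", a)
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Align exposure and outcome summary statistics to shared effect alleles
#'
#' Builds the harmonized instrument set consumed by [gsmr()] and the HEIDI
#' filter: for each requested SNP present in both datasets, the outcome
#' effect is re-oriented so that \code{bzx} and \code{bzy} refer to the same
#' effect allele. Outcome records coded on the swapped allele pair get their
#' sign flipped; records on the complementary strand are matched via base
#' complement. SNPs whose allele pairs cannot be reconciled are dropped.
#'
#' Palindromic SNPs (A/T or C/G) cannot be strand-resolved by allele letters.
#' When the exposure frequency is informative (\code{min(eaf, 1-eaf) <= 0.4})
#' they are aligned by frequency agreement; otherwise they are dropped by
#' default, or kept as-coded with a warning when
#' \code{keep_palindromic = TRUE}.
#'
#' @param exposure,outcome \code{summary_dataset} objects.
#' @param snp_ids SNP ids to harmonize (typically clump output).
#' @param keep_palindromic keep frequency-ambiguous palindromic SNPs.
#' @param freq_diff_max warn for SNPs whose aligned exposure/outcome allele
#'   frequencies differ by more than this (guards against strand errors).
#' @return An object of class \code{harmonized_set}: a data.frame with one
#'   row per surviving SNP and columns \code{SNP, chr, bp, A1, A2, freq,
#'   bzx, se_bzx, p_zx, bzy, se_bzy, p_zy, n_x, n_y}.
#' @export
harmonize <- function(exposure, outcome, snp_ids,
                      keep_palindromic = FALSE, freq_diff_max = 0.2) {
  snp_ids <- unique(as.character(snp_ids))
  ix <- match(snp_ids, exposure$SNP)
  iy <- match(snp_ids, outcome$SNP)
  present <- !is.na(ix) & !is.na(iy)
  n_absent <- sum(!present)
  if (n_absent > 0L)
    message(n_absent, " SNP(s) absent from exposure or outcome dropped")
  ex <- as.data.frame(exposure)[ix[present], , drop = FALSE]
  oy <- as.data.frame(outcome)[iy[present], , drop = FALSE]
  if (nrow(ex) == 0L) stop("no SNPs shared between exposure and outcome")

  a1x <- ex$A1; a2x <- ex$A2
  a1y <- oy$A1; a2y <- oy$A2
  same <- a1y == a1x & a2y == a2x
  swap <- a1y == a2x & a2y == a1x
  comp_same <- complement_allele(a1y) == a1x & complement_allele(a2y) == a2x
  comp_swap <- complement_allele(a1y) == a2x & complement_allele(a2y) == a1x
  pal <- is_palindromic(a1x, a2x)

  flip <- rep(NA, nrow(ex))          # NA = irreconcilable, drop
  flip[same | (comp_same & !pal)] <- FALSE
  flip[swap | (comp_swap & !pal)] <- TRUE
  if (any(pal)) {
    # for palindromes 'same' and 'comp_swap' (and 'swap'/'comp_same') coincide:
    # allele letters cannot resolve strand, so use frequency where informative
    amb <- pal & (same | swap | comp_same | comp_swap)
    informative <- amb & !is.na(ex$freq) & !is.na(oy$freq) &
      pmin(ex$freq, 1 - ex$freq) <= 0.4
    flip[informative] <-
      abs(ex$freq[informative] - oy$freq[informative]) >
      abs(ex$freq[informative] - (1 - oy$freq[informative]))
    hard <- amb & !informative
    if (any(hard)) {
      if (keep_palindromic) {
        warning(sum(hard), " frequency-ambiguous palindromic SNP(s) kept as coded")
        flip[hard] <- ifelse(swap[hard] & !same[hard], TRUE, FALSE)
      } else {
        message(sum(hard), " frequency-ambiguous palindromic SNP(s) dropped")
        flip[hard] <- NA
      }
    }
  }
  n_bad <- sum(is.na(flip) & !pal)
  if (n_bad > 0L)
    message(n_bad, " SNP(s) with irreconcilable allele pairs dropped")

  ok <- !is.na(flip)
  ex <- ex[ok, , drop = FALSE]; oy <- oy[ok, , drop = FALSE]
  flip <- flip[ok]
  if (nrow(ex) == 0L) stop("no SNPs survived harmonization")

  bzy <- ifelse(flip, -oy$b, oy$b)
  eaf_y <- ifelse(flip, 1 - oy$freq, oy$freq)
  big_diff <- !is.na(ex$freq) & !is.na(eaf_y) &
    abs(ex$freq - eaf_y) > freq_diff_max
  if (any(big_diff))
    warning(sum(big_diff), " SNP(s) with aligned allele-frequency difference > ",
            freq_diff_max, ": ", paste(utils::head(ex$SNP[big_diff], 5L),
                                       collapse = ", "))
  h <- data.frame(
    SNP = ex$SNP,
    chr = if ("chr" %in% names(ex)) ex$chr else NA_character_,
    bp = if ("bp" %in% names(ex)) ex$bp else NA_real_,
    A1 = ex$A1, A2 = ex$A2, freq = ex$freq,
    bzx = ex$b, se_bzx = ex$se, p_zx = ex$p,
    bzy = bzy, se_bzy = oy$se, p_zy = oy$p,
    n_x = ex$N, n_y = oy$N,
    stringsAsFactors = FALSE)
  rownames(h) <- NULL
  structure(h, class = c("harmonized_set", "data.frame"),
            exposure = attr(exposure, "trait_name"),
            outcome = attr(outcome, "trait_name"))
}
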