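#' Read a PLINK bed/bim/fam fileset into a genotype panel
#'
#' Decodes the bit-packed SNP-major .bed format (magic bytes 0x6c 0x1b 0x01)
#' into an individuals-by-SNPs matrix of effect-allele counts. PLINK codes
#' each genotype in 2 bits: 00 = homozygous A1, 01 = missing, 10 =
#' heterozygous, 11 = homozygous A2. Counts returned here are of the .bim
#' A1 allele (so 00 -> 2, 11 -> 0), the usual minor-allele convention.
#'
#' @param prefix path prefix; \code{prefix.bed/.bim/.fam} must exist.
#' @return A \code{genotype_panel}: list with \code{geno} (numeric matrix,
#'   individuals x SNPs, NA for missing), \code{snp} (data.frame with
#'   \code{SNP, chr, bp, A1, A2}), and \code{sample_ids}.
#' @export
read_plink <- function(prefix) {
  bim <- utils::read.table(paste0(prefix, ".bim"), stringsAsFactors = FALSE)
  names(bim) <- c("chr", "SNP", "cm", "bp", "A1", "A2")
  fam <- utils::read.table(paste0(prefix, ".fam"), stringsAsFactors = FALSE)
  n <- nrow(fam)
  m <- nrow(bim)
  raw <- readBin(paste0(prefix, ".bed"), what = "raw",
                 n = 3L + ceiling(n / 4) * m)
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK .bed file (bad magic bytes): ", prefix, ".bed")
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major .bed files are supported")
  body <- raw[-(1:3)]
  bpl <- ceiling(n / 4)  # bytes per SNP
  if (length(body) != bpl * m)
    stop(".bed size inconsistent with .bim/.fam dimensions")
  # decode 2-bit codes; lookup over the 4 codes per byte position
  codes <- matrix(0L, nrow = 4L * bpl, ncol = m)
  ints <- as.integer(body)
  dim(ints) <- c(bpl, m)
  for (k in 0:3) codes[seq_len(bpl) * 4L - 3L + k, ] <-
    bitwAnd(bitwShiftR(ints, 2L * k), 3L)
  codes <- codes[seq_len(n), , drop = FALSE]
  geno <- matrix(NA_real_, n, m)
  geno[codes == 0L] <- 2  # homozygous A1
  geno[codes == 2L] <- 1
  geno[codes == 3L] <- 0
  dimnames(geno) <- list(as.character(fam[[2]]), bim$SNP)
  new_genotype_panel(geno,
                     data.frame(SNP = bim$SNP, chr = as.character(bim$chr),
                                bp = bim$bp, A1 = toupper(bim$A1),
                                A2 = toupper(bim$A2), stringsAsFactors = FALSE))
}

#' Construct a genotype panel from an allele-count matrix
#'
#' @param geno individuals x SNPs matrix of allele counts in \{0, 1, 2\},
#'   NA for missing; column names are SNP ids unless \code{snp} is given.
#' @param snp optional data.frame with columns \code{SNP, chr, bp, A1, A2}.
#' @return A \code{genotype_panel}.
#' @export
genotype_panel <- function(geno, snp = NULL) {
  geno <- as.matrix(geno)
  if (is.null(snp)) {
    ids <- colnames(geno)
    if (is.null(ids)) ids <- paste0("snp", seq_len(ncol(geno)))
    snp <- data.frame(SNP = ids, chr = "1", bp = seq_len(ncol(geno)),
                      A1 = "A", A2 = "C", stringsAsFactors = FALSE)
  }
  colnames(geno) <- snp$SNP
  new_genotype_panel(geno, snp)
}

new_genotype_panel <- function(geno, snp) {
  ok <- is.na(geno) | geno == 0 | geno == 1 | geno == 2
  if (!all(ok)) stop("genotype entries must be 0, 1, 2 or missing")
  if (anyDuplicated(snp$SNP)) stop("duplicate SNP ids in genotype panel")
  structure(list(geno = geno, snp = snp,
                 sample_ids = rownames(geno) %||% as.character(seq_len(nrow(geno)))),
            class = "genotype_panel")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a plain-text genotype matrix as a panel
#'
#' Expects a header of SNP ids and one row of 0/1/2 counts (NA allowed) per
#' individual; a convenience format for small fixtures.
#'
#' @param path text file path.
#' @return A \code{genotype_panel}.
#' @export
read_geno_text <- function(path) {
  d <- utils::read.table(path, header = TRUE, check.names = FALSE)
  genotype_panel(as.matrix(d))
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("Genotype panel:", nrow(x$geno), "individuals x", ncol(x$geno), "SNPs\n")
  invisible(x)
}

#' Pairwise LD correlations from a reference genotype panel
#'
#' Pearson correlation of allele counts over pairwise-complete individuals.
#' When \code{effect_alleles} is supplied, each SNP's counts are first
#' oriented to the named allele (counts are mirrored as \code{2 - g} when
#' the panel counts the other allele), so the signs of \code{r} match the
#' harmonized effect alleles used downstream.
#'
#' @param panel a \code{genotype_panel}.
#' @param snp_ids SNPs to include, in the desired matrix order.
#' @param effect_alleles optional named character vector (SNP id -> allele).
#' @return An \code{ld_matrix}: symmetric correlation matrix with unit
#'   diagonal, dimnames = SNP ids.
#' @export
compute_ld <- function(panel, snp_ids = panel$snp$SNP, effect_alleles = NULL) {
  idx <- match(snp_ids, panel$snp$SNP)
  if (anyNA(idx))
    stop("SNP(s) absent from panel: ",
         paste(utils::head(snp_ids[is.na(idx)], 5L), collapse = ", "))
  g <- panel$geno[, idx, drop = FALSE]
  if (!is.null(effect_alleles)) {
    ea <- effect_alleles[snp_ids]
    snp <- panel$snp[idx, ]
    mirror <- !is.na(ea) & (ea == snp$A2 | ea == complement_allele(snp$A2))
    g[, mirror] <- 2 - g[, mirror]
  }
  sds <- apply(g, 2, stats::sd, na.rm = TRUE)
  if (any(is.na(sds) | sds == 0))
    stop("monomorphic SNP(s), LD undefined: ",
         paste(utils::head(snp_ids[is.na(sds) | sds == 0], 5L), collapse = ", "))
  r <- stats::cor(g, use = "pairwise.complete.obs")
  diag(r) <- 1
  ld_matrix(r, snp_ids)
}

#' Construct / validate an LD correlation matrix
#'
#' @param r symmetric matrix of correlations, |r| <= 1, unit diagonal.
#' @param snp_ids SNP ids in matrix order.
#' @return An \code{ld_matrix}.
#' @export
ld_matrix <- function(r, snp_ids = rownames(r)) {
  r <- as.matrix(r)
  if (is.null(snp_ids)) stop("snp_ids required when r has no dimnames")
  if (nrow(r) != ncol(r) || max(abs(r - t(r))) > 1e-8)
    stop("LD matrix must be square and symmetric")
  if (max(abs(diag(r) - 1)) > 1e-8) stop("LD matrix diagonal must be 1")
  if (max(abs(r)) > 1 + 1e-8) stop("LD correlations must satisfy |r| <= 1")
  r <- (r + t(r)) / 2
  diag(r) <- 1
  dimnames(r) <- list(snp_ids, snp_ids)
  structure(r, class = c("ld_matrix", "matrix", "array"))
}

#' Read an LD matrix from a text file
#'
#' A square whitespace-delimited matrix with a single header line of SNP
#' ids; lets every pipeline stage run without a genotype panel.
#'
#' @param path text file path.
#' @return An \code{ld_matrix}.
#' @export
read_ld_matrix <- function(path) {
  d <- utils::read.table(path, header = TRUE, check.names = FALSE)
  ld_matrix(as.matrix(d), snp_ids = names(d))
}

#' P-value-ranked greedy LD clumping
#'
#' Among SNPs with \code{p < p_thresh}, repeatedly takes the
#' smallest-P unassigned SNP as an index SNP and removes all unassigned
#' SNPs on the same chromosome within \code{window_kb} kilobases whose
#' squared LD correlation with it is at least \code{r2_thresh}. Ties in P
#' are broken by smaller position, then lexicographic SNP id. Defaults
#' follow the standard instrument-selection settings (genome-wide
#' significance, r^2 = 0.05, 1 Mb window).
#'
#' @param dataset a \code{summary_dataset} with \code{chr} and \code{bp}.
#' @param ld_source a \code{genotype_panel} or \code{ld_matrix} covering the
#'   significant SNPs (uncovered SNPs are dropped with a message).
#' @param p_thresh,r2_thresh,window_kb clumping parameters.
#' @return Character vector of index SNP ids in selection order (possibly
#'   empty).
#' @export
clump <- function(dataset, ld_source, p_thresh = 5e-8, r2_thresh = 0.05,
                  window_kb = 1000) {
  d <- as.data.frame(dataset)
  if (!all(c("chr", "bp") %in% names(d)))
    stop("clumping requires chr and bp columns in the dataset")
  d <- d[d$p < p_thresh, , drop = FALSE]
  if (nrow(d) == 0L) return(character())
  if (inherits(ld_source, "genotype_panel")) {
    covered <- d$SNP %in% ld_source$snp$SNP
  } else {
    covered <- d$SNP %in% rownames(ld_source)
  }
  if (any(!covered)) {
    message(sum(!covered), " significant SNP(s) not covered by LD source dropped")
    d <- d[covered, , drop = FALSE]
    if (nrow(d) == 0L) return(character())
  }
  r <- if (inherits(ld_source, "genotype_panel"))
    unclass(compute_ld(ld_source, d$SNP)) else
      unclass(ld_source)[d$SNP, d$SNP, drop = FALSE]
  ord <- order(d$p, d$bp, d$SNP)
  d <- d[ord, , drop = FALSE]
  r <- r[ord, ord, drop = FALSE]
  assigned <- rep(FALSE, nrow(d))
  index <- character()
  for (i in seq_len(nrow(d))) {
    if (assigned[i]) next
    assigned[i] <- TRUE
    index <- c(index, d$SNP[i])
    near <- !assigned & d$chr == d$chr[i] &
      abs(d$bp - d$bp[i]) <= window_kb * 1000 &
      r[i, ]^2 >= r2_thresh
    assigned[near] <- TRUE
  }
  index
}
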