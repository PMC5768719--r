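#' Per-SNP causal-effect ratio estimates and their variances
#'
#' For each instrument, the exposure-outcome causal effect is estimated as
#' the ratio \code{bxy = bzy / bzx}, with delta-method variance
#' \deqn{var(b_{xy}) = b_{xy}^2 \left[ \frac{var(b_{zx})}{b_{zx}^2} +
#'   \frac{var(b_{zy})}{b_{zy}^2} - \frac{var^2(b_{zx})}{b_{zx}^4} \right].}
#' The implementation evaluates the algebraically identical form
#' \code{se_zy^2/bzx^2 + bxy^2 * (se_zx^2/bzx^2 - se_zx^4/bzx^4)}, which
#' remains finite when \code{bzy = 0}.
#'
#' @param inst a \code{harmonized_set}.
#' @return data.frame with columns \code{SNP, bxy, var_bxy}.
#' @export
bxy_per_snp <- function(inst) {
  if (any(inst$bzx == 0))
    stop("degenerate instrument(s) with bzx = 0: ",
         paste(utils::head(inst$SNP[inst$bzx == 0], 5L), collapse = ", "))
  bxy <- inst$bzy / inst$bzx
  vzx <- inst$se_bzx^2
  var_bxy <- inst$se_bzy^2 / inst$bzx^2 +
    bxy^2 * (vzx / inst$bzx^2 - vzx^2 / inst$bzx^4)
  data.frame(SNP = inst$SNP, bxy = bxy, var_bxy = var_bxy,
             stringsAsFactors = FALSE)
}

# ij-th covariance of ratio estimates for SNP pairs with LD correlation r;
# plug-in: true effects replaced by their estimates. At i = j, r = 1 this
# reduces exactly to the diagonal variance above.
bxy_cov <- function(bzx_i, se_zx_i, bzx_j, se_zx_j,
                    se_zy_i, se_zy_j, bxy_i, bxy_j, r) {
  r * se_zy_i * se_zy_j / (bzx_i * bzx_j) +
    bxy_i * bxy_j * (r * se_zx_i * se_zx_j / (bzx_i * bzx_j) -
                       se_zx_i^2 * se_zx_j^2 / (bzx_i^2 * bzx_j^2))
}

#' Variance-covariance matrix of the per-SNP ratio estimates
#'
#' Assembles the m x m matrix V whose diagonal holds the [bxy_per_snp()]
#' variances and whose off-diagonal entries account for the LD correlation
#' \code{r} between instruments:
#' \deqn{cov(b_{xy(i)}, b_{xy(j)}) \approx
#'   \frac{r \, se_{zy(i)} se_{zy(j)}}{b_{zx(i)} b_{zx(j)}} +
#'   b_{xy(i)} b_{xy(j)} \left[ \frac{r \, se_{zx(i)} se_{zx(j)}}{b_{zx(i)} b_{zx(j)}}
#'   - \frac{se_{zx(i)}^2 se_{zx(j)}^2}{b_{zx(i)}^2 b_{zx(j)}^2} \right].}
#'
#' @param inst a \code{harmonized_set}.
#' @param est output of [bxy_per_snp()] for \code{inst}.
#' @param ld an \code{ld_matrix} covering all instruments, or NULL for
#'   independent instruments (identity LD).
#' @param condition_limit fail when the condition number of V exceeds this
#'   (near-non-invertible V from instruments in high LD).
#' @return Symmetric matrix V with dimnames = SNP ids.
#' @export
build_V <- function(inst, est = bxy_per_snp(inst), ld = NULL,
                    condition_limit = 1e8) {
  m <- nrow(inst)
  r <- ld_submatrix(ld, inst$SNP)
  sezy <- inst$se_bzy
  sezx <- inst$se_bzx
  bzx <- inst$bzx
  bxy <- est$bxy
  V <- r * tcrossprod(sezy) / tcrossprod(bzx) +
    tcrossprod(bxy) * (r * tcrossprod(sezx) / tcrossprod(bzx) -
                         tcrossprod(sezx^2) / tcrossprod(bzx^2))
  diag(V) <- est$var_bxy
  dimnames(V) <- list(inst$SNP, inst$SNP)
  if (m > 1L) {
    # condition the scale-free correlation structure of V: near-singularity
    # comes from instruments in high LD, not from unequal variances
    C <- stats::cov2cor(V)
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0 || max(ev) / min(ev) > condition_limit) {
      offc <- abs(C); diag(offc) <- 0
      top <- arrayInd(which.max(offc), dim(offc))
      stop("V is near-non-invertible (correlation condition number > ",
           format(condition_limit), "); most correlated instrument pair: ",
           inst$SNP[top[1]], " / ", inst$SNP[top[2]],
           " (r = ", signif(r[top], 3), "). Consider stricter clumping.")
    }
  }
  V
}

ld_submatrix <- function(ld, snp_ids) {
  if (is.null(ld)) return(diag(length(snp_ids)))
  miss <- setdiff(snp_ids, rownames(ld))
  if (length(miss) > 0L)
    stop("LD matrix does not cover instrument(s): ",
         paste(utils::head(miss, 5L), collapse = ", "))
  unclass(ld)[snp_ids, snp_ids, drop = FALSE]
}

#' Generalized least squares combination of per-SNP ratio estimates
#'
#' Combines the m correlated per-SNP estimates into a single causal-effect
#' estimate \code{bxy_hat = (1'V^-1 1)^-1 1'V^-1 bxy} with variance
#' \code{(1'V^-1 1)^-1}, tested by \code{T = bxy_hat^2 / var} against a
#' chi-squared distribution with 1 degree of freedom. Uses a symmetric
#' (Cholesky) linear solve rather than an explicit inverse.
#'
#' @param est output of [bxy_per_snp()].
#' @param V variance-covariance matrix from [build_V()].
#' @return list with \code{bxy, se, chi2, pval}.
#' @export
gls_estimate <- function(est, V) {
  ch <- tryCatch(chol(V), error = function(e)
    stop("V is not positive definite: ", conditionMessage(e)))
  ones <- rep(1, nrow(V))
  Vi1 <- backsolve(ch, forwardsolve(t(ch), ones))
  Vib <- backsolve(ch, forwardsolve(t(ch), est$bxy))
  denom <- sum(Vi1)
  bxy <- sum(Vib) / denom
  v <- 1 / denom
  chi2 <- bxy^2 / v
  list(bxy = bxy, se = sqrt(v), chi2 = chi2,
       pval = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Options controlling a GSMR analysis
#'
#' @param gwas_p_thresh instrument-selection P-value threshold on the
#'   exposure (genome-wide significance by default).
#' @param clump_r2 LD r^2 threshold for clumping.
#' @param clump_window_kb clumping window in kb (each side of the index SNP).
#' @param min_instruments minimum surviving instrument count; the analysis
#'   refuses to run below it unless \code{force = TRUE} (rule of thumb: 10
#'   or more near-independent genome-wide-significant SNPs).
#' @param heidi_p_thresh per-SNP HEIDI-outlier P-value threshold.
#' @param heidi whether to run HEIDI-outlier filtering.
#' @param heidi_iterate repeat HEIDI filtering until no SNP is removed.
#' @param condition_limit condition-number ceiling for V.
#' @param force run even with fewer than \code{min_instruments} instruments.
#' @return list of class \code{gsmr_options}.
#' @export
gsmr_options <- function(gwas_p_thresh = 5e-8, clump_r2 = 0.05,
                         clump_window_kb = 1000, min_instruments = 10,
                         heidi_p_thresh = 0.01, heidi = TRUE,
                         heidi_iterate = FALSE, condition_limit = 1e8,
                         force = FALSE) {
  stopifnot(gwas_p_thresh > 0, gwas_p_thresh <= 1, clump_r2 >= 0,
            clump_r2 <= 1, clump_window_kb > 0, min_instruments >= 1,
            heidi_p_thresh > 0, heidi_p_thresh < 1, condition_limit > 1)
  structure(list(gwas_p_thresh = gwas_p_thresh, clump_r2 = clump_r2,
                 clump_window_kb = clump_window_kb,
                 min_instruments = min_instruments,
                 heidi_p_thresh = heidi_p_thresh, heidi = heidi,
                 heidi_iterate = heidi_iterate,
                 condition_limit = condition_limit, force = force),
            class = "gsmr_options")
}

#' Fit a GSMR model: multi-instrument Mendelian randomization by GLS
#'
#' The full pipeline: select near-independent genome-wide-significant
#' instruments for the exposure by LD clumping, harmonize alleles between
#' the exposure and outcome datasets, remove putatively pleiotropic
#' instruments with the HEIDI-outlier test, and combine the per-SNP ratio
#' estimates by generalized least squares accounting for residual LD.
#'
#' @param exposure,outcome \code{summary_dataset} objects (exposure effects
#'   in SD units; binary-outcome effects as logOR).
#' @param ld_source a \code{genotype_panel}, an \code{ld_matrix}, or NULL
#'   (treat instruments as fully independent; only valid when they are).
#' @param options a [gsmr_options()] list.
#' @param snp_ids optional pre-selected instrument ids; skips clumping.
#' @param direction label stored on the result (\code{"forward"} or
#'   \code{"reverse"}).
#' @return An object of class \code{gsmr}: list with elements \code{bxy}
#'   (estimate), \code{se}, \code{chi2}, \code{pval},
#'   \code{n_instruments_input}, \code{n_instruments_used},
#'   \code{flagged_pleiotropic}, \code{per_snp} (per-SNP ratio estimates),
#'   \code{instruments} (the harmonized set used), \code{heidi}
#'   (HEIDI report or NULL), \code{options}, \code{direction},
#'   \code{exposure}, \code{outcome}.
#' @examples
#' sim <- sample_sumstats_direct(sim_truth(m = 30, b_xy = 0.2, seed = 1),
#'                               n_x = 5e4, n_y = 5e4, seed = 2)
#' fit <- gsmr(sim$exposure, sim$outcome)
#' summary(fit)
#' @export
gsmr <- function(exposure, outcome, ld_source = NULL,
                 options = gsmr_options(), snp_ids = NULL,
                 direction = "forward") {
  if (is.null(snp_ids)) {
    snp_ids <- if (!is.null(ld_source) && all(c("chr", "bp") %in% names(exposure)))
      clump(exposure, ld_source, p_thresh = options$gwas_p_thresh,
            r2_thresh = options$clump_r2, window_kb = options$clump_window_kb)
    else exposure$SNP[exposure$p < options$gwas_p_thresh]
    if (length(snp_ids) == 0L)
      stop("no exposure SNPs at p < ", options$gwas_p_thresh)
  }
  inst <- harmonize(exposure, outcome, snp_ids)
  exposure_name <- attr(inst, "exposure")
  outcome_name <- attr(inst, "outcome")
  inst <- inst[inst$p_zx <= options$gwas_p_thresh, , drop = FALSE]
  n_input <- nrow(inst)
  if (n_input < options$min_instruments) {
    msg <- paste0("only ", n_input, " instrument(s) available; the method is ",
                  "intended for ", options$min_instruments,
                  " or more near-independent genome-wide-significant SNPs")
    if (!options$force) stop(msg, " (set force = TRUE to override)")
    warning(msg, "; proceeding because force = TRUE")
  }
  ld <- resolve_ld(ld_source, inst)

  heidi_report <- NULL
  flagged <- character()
  if (options$heidi && nrow(inst) >= 2L) {
    hf <- heidi_filter(inst, ld = ld, threshold = options$heidi_p_thresh,
                       iterate = options$heidi_iterate)
    inst <- hf$instruments
    heidi_report <- hf$report
    flagged <- hf$flagged
  }
  est <- bxy_per_snp(inst)
  V <- build_V(inst, est, ld = ld_subset(ld, inst$SNP),
               condition_limit = options$condition_limit)
  g <- gls_estimate(est, V)
  structure(list(bxy = g$bxy, se = g$se, chi2 = g$chi2, pval = g$pval,
                 n_instruments_input = n_input,
                 n_instruments_used = nrow(inst),
                 flagged_pleiotropic = flagged,
                 per_snp = est, instruments = inst, heidi = heidi_report,
                 options = options, direction = direction,
                 exposure = exposure_name, outcome = outcome_name,
                 outcome_type = attr(outcome, "trait_type")),
            class = "gsmr")
}

resolve_ld <- function(ld_source, inst) {
  if (is.null(ld_source)) return(NULL)
  if (inherits(ld_source, "ld_matrix")) return(ld_source)
  if (inherits(ld_source, "genotype_panel")) {
    ea <- stats::setNames(inst$A1, inst$SNP)
    return(compute_ld(ld_source, inst$SNP, effect_alleles = ea))
  }
  stop("ld_source must be a genotype_panel, an ld_matrix, or NULL")
}

ld_subset <- function(ld, snp_ids) {
  if (is.null(ld)) return(NULL)
  ld_matrix(unclass(ld)[snp_ids, snp_ids, drop = FALSE], snp_ids)
}

#' Bidirectional GSMR analysis
#'
#' Runs GSMR in both directions: A's instruments on B (forward) and B's
#' instruments on A (reverse). Instrument sets are selected independently
#' from each trait's own GWAS, so they are disjoint whenever the traits'
#' genome-wide-significant loci do not coincide; any overlap is reported.
#' A direction that fails its instrument requirement is returned as NULL
#' with the reason recorded.
#'
#' @param traitA,traitB \code{summary_dataset} objects.
#' @param ld_source as in [gsmr()].
#' @param options a [gsmr_options()] list.
#' @return list of class \code{gsmr_bidirectional} with elements
#'   \code{forward}, \code{reverse}, \code{skipped} (named reasons), and
#'   \code{instrument_overlap}.
#' @export
gsmr_bidirectional <- function(traitA, traitB, ld_source = NULL,
                               options = gsmr_options()) {
  runs <- list(forward = NULL, reverse = NULL)
  skipped <- list()
  runs$forward <- tryCatch(
    gsmr(traitA, traitB, ld_source, options, direction = "forward"),
    error = function(e) { skipped$forward <<- conditionMessage(e); NULL })
  runs$reverse <- tryCatch(
    gsmr(traitB, traitA, ld_source, options, direction = "reverse"),
    error = function(e) { skipped$reverse <<- conditionMessage(e); NULL })
  if (is.null(runs$forward) && is.null(runs$reverse))
    stop("neither direction feasible: forward: ", skipped$forward,
         "; reverse: ", skipped$reverse)
  overlap <- if (!is.null(runs$forward) && !is.null(runs$reverse))
    intersect(runs$forward$instruments$SNP, runs$reverse$instruments$SNP)
  else character()
  if (length(overlap) > 0L)
    warning("forward and reverse instrument sets share ", length(overlap),
            " SNP(s)")
  structure(list(forward = runs$forward, reverse = runs$reverse,
                 skipped = skipped, instrument_overlap = overlap),
            class = "gsmr_bidirectional")
}

#' Convert a logOR-scale effect to an odds ratio (and back)
#'
#' For a binary outcome the GSMR estimate is on the logOR scale per SD of
#' the exposure; \code{exp()} turns it into an odds ratio.
#'
#' @param b effect on the logOR scale.
#' @return Odds ratio \code{exp(b)}.
#' @export
logor_to_or <- function(b) {
  stopifnot(is.finite(b))
  exp(b)
}

#' @rdname logor_to_or
#' @param or odds ratio, > 0.
#' @export
or_to_logor <- function(or) {
  stopifnot(or > 0)
  log(or)
}

#' Aggregate effect of simultaneous changes in several risk factors
#'
#' Approximates the joint odds ratio for a disease when each risk factor i
#' changes by \code{x_sd[i]} standard deviations, given the factors'
#' conditional per-SD logOR effects:
#' \deqn{OR = \exp\left( \sum_i x_i \log(OR_i) \right).}
#'
#' @param log_or_per_sd conditional logOR per SD for each risk factor.
#' @param x_sd SD change in each risk factor.
#' @return Aggregate odds ratio.
#' @export
aggregate_effect <- function(log_or_per_sd, x_sd = rep(1, length(log_or_per_sd))) {
  if (length(log_or_per_sd) != length(x_sd))
    stop("log_or_per_sd and x_sd must have equal length")
  exp(sum(x_sd * log_or_per_sd))
}

#' Bonferroni family-wise significance threshold
#'
#' @param fwer target family-wise error rate in (0, 1).
#' @param n_tests number of tests, >= 1.
#' @return Per-test P-value threshold \code{fwer / n_tests}.
#' @export
bonferroni_threshold <- function(fwer, n_tests) {
  if (fwer <= 0 || fwer >= 1) stop("fwer must be in (0, 1)")
  if (n_tests < 1) stop("n_tests must be >= 1")
  fwer / n_tests
}

#' Inverse-variance-weighted (IVW) comparator estimate
#'
#' Zero-intercept regression of the SNP-outcome effects on the SNP-exposure
#' effects, weighted by \code{1/se_bzy^2}; the standard two-sample MR
#' estimator that ignores sampling error in \code{bzx} and LD.
#'
#' @param inst a \code{harmonized_set} with >= 2 instruments.
#' @return list with \code{b, se, pval}.
#' @export
estimate_ivw <- function(inst) {
  if (nrow(inst) < 2L) stop("IVW requires at least 2 instruments")
  w <- 1 / inst$se_bzy^2
  b <- sum(w * inst$bzx * inst$bzy) / sum(w * inst$bzx^2)
  se <- 1 / sqrt(sum(w * inst$bzx^2))
  z2 <- (b / se)^2
  list(b = b, se = se, pval = stats::pchisq(z2, 1, lower.tail = FALSE))
}

#' MR-Egger comparator estimate
#'
#' Weighted regression of \code{bzy} on \code{bzx} with a free intercept,
#' each instrument oriented so \code{bzx > 0}; a nonzero intercept indicates
#' directional pleiotropy. Weights are \code{1/se_bzy^2}.
#'
#' @param inst a \code{harmonized_set} with >= 3 instruments.
#' @return list with \code{b, se, pval} (slope) and \code{intercept,
#'   intercept_se, intercept_pval}.
#' @export
estimate_egger <- function(inst) {
  if (nrow(inst) < 3L) stop("Egger regression requires at least 3 instruments")
  sgn <- sign(inst$bzx)
  x <- inst$bzx * sgn
  y <- inst$bzy * sgn
  w <- 1 / inst$se_bzy^2
  fit <- stats::lm(y ~ x, weights = w)
  s <- summary(fit)$coefficients
  # normal-theory p-values (large-m summary-data convention)
  zi <- s["(Intercept)", "Estimate"] / s["(Intercept)", "Std. Error"]
  zs <- s["x", "Estimate"] / s["x", "Std. Error"]
  list(b = s["x", "Estimate"], se = s["x", "Std. Error"],
       pval = stats::pchisq(zs^2, 1, lower.tail = FALSE),
       intercept = s["(Intercept)", "Estimate"],
       intercept_se = s["(Intercept)", "Std. Error"],
       intercept_pval = stats::pchisq(zi^2, 1, lower.tail = FALSE))
}
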