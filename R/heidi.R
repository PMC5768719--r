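#' Select the HEIDI target instrument
#'
#' The reference SNP against which heterogeneity is tested. Picking the top
#' exposure-associated SNP outright is unsafe — a SNP with an extreme
#' exposure effect is itself a candidate pleiotropic outlier — so the SNPs
#' are ranked by their per-SNP ratio estimate \code{bxy} and the target is
#' the SNP with the strongest exposure association (smallest \code{p_zx})
#' inside the third quintile of that ranking, operationalized as the rank
#' band \code{(0.4 m, 0.6 m]}. When the band contains no rank (possible for
#' very small m), the median rank \code{ceiling(m / 2)} is used. Ties in
#' \code{p_zx} are broken by distance of \code{bxy} from the median
#' \code{bxy}, then lexicographic SNP id.
#'
#' @param inst a \code{harmonized_set}.
#' @param est output of [bxy_per_snp()] for \code{inst}.
#' @return The target SNP id.
#' @export
select_target <- function(inst, est = bxy_per_snp(inst)) {
  m <- nrow(inst)
  if (m == 1L) return(inst$SNP[1])
  rk <- rank(est$bxy, ties.method = "first")
  band <- which(rk > 0.4 * m & rk <= 0.6 * m)
  if (length(band) == 0L) band <- which(rk == ceiling(m / 2))
  cand <- band[order(inst$p_zx[band],
                     abs(est$bxy[band] - stats::median(est$bxy)),
                     inst$SNP[band])]
  inst$SNP[cand[1]]
}

#' Per-SNP HEIDI-outlier heterogeneity test
#'
#' Tests each instrument's deviation from the causal model:
#' \code{d_i = bxy(i) - bxy(target)}, with
#' \code{var(d_i) = var(bxy(i)) + var(bxy(target)) - 2 cov(bxy(i),
#' bxy(target))}, where the covariance uses the same structural formula as
#' the off-diagonal of V with the target in place of SNP j and \code{r_i}
#' the LD correlation between SNP i and the target. \code{T = d_i^2 /
#' var(d_i)} is referred to a chi-squared distribution with 1 df. The
#' target itself has \code{d = 0}, \code{pval = 1}. A numerically
#' indeterminate variance (\code{var(d) <= 0}) yields \code{pval = NA}: the
#' SNP is conservatively retained by [heidi_filter()].
#'
#' @param inst a \code{harmonized_set}.
#' @param est output of [bxy_per_snp()].
#' @param target target SNP id (default: [select_target()]).
#' @param ld an \code{ld_matrix} covering the instruments, or NULL for
#'   independent instruments.
#' @param threshold flagging threshold recorded in the report.
#' @return An object of class \code{heidi_report}: data.frame with columns
#'   \code{SNP, d, var_d, pval, flagged}, plus attributes \code{target} and
#'   \code{threshold}.
#' @export
heidi_test <- function(inst, est = bxy_per_snp(inst),
                       target = select_target(inst, est), ld = NULL,
                       threshold = 0.01) {
  ti <- match(target, inst$SNP)
  if (is.na(ti)) stop("target SNP ", target, " not among instruments")
  r_t <- if (is.null(ld)) {
    r0 <- rep(0, nrow(inst)); r0[ti] <- 1; r0
  } else ld_submatrix(ld, inst$SNP)[, ti]
  d <- est$bxy - est$bxy[ti]
  cv <- bxy_cov(inst$bzx, inst$se_bzx, inst$bzx[ti], inst$se_bzx[ti],
                inst$se_bzy, inst$se_bzy[ti], est$bxy, est$bxy[ti], r_t)
  var_d <- est$var_bxy + est$var_bxy[ti] - 2 * cv
  pval <- ifelse(var_d > 0,
                 stats::pchisq(d^2 / pmax(var_d, .Machine$double.xmin),
                               df = 1, lower.tail = FALSE),
                 NA_real_)
  d[ti] <- 0; var_d[ti] <- 0; pval[ti] <- 1
  if (anyNA(pval))
    warning(sum(is.na(pval)), " instrument(s) with indeterminate var(d) retained")
  rep_df <- data.frame(SNP = inst$SNP, d = d, var_d = var_d, pval = pval,
                       flagged = !is.na(pval) & pval < threshold,
                       stringsAsFactors = FALSE)
  structure(rep_df, class = c("heidi_report", "data.frame"),
            target = target, threshold = threshold)
}

#' Remove putatively pleiotropic instruments (HEIDI-outlier filter)
#'
#' Single pass by default: select the target, test every instrument, and
#' drop those with HEIDI P-value below \code{threshold}. Filtering is pure
#' subset selection — retained SNPs' effects are untouched. With
#' \code{iterate = TRUE} the pass (including target re-selection) repeats
#' until no SNP is removed.
#'
#' @inheritParams heidi_test
#' @param threshold P-value threshold below which a SNP is removed. At the
#'   default 0.01, roughly 1\% of valid instruments are removed by chance
#'   under a pure causal model.
#' @param iterate repeat until no removal.
#' @return list with \code{instruments} (filtered \code{harmonized_set}),
#'   \code{report} (the [heidi_test()] report of the final pass, with
#'   attribute \code{removed} holding all SNPs removed across passes).
#' @export
heidi_filter <- function(inst, est = bxy_per_snp(inst), ld = NULL,
                         threshold = 0.01, iterate = FALSE) {
  if (nrow(inst) < 2L) {
    warning("fewer than 2 instruments; HEIDI filtering skipped")
    rep0 <- heidi_test(inst, est, ld = ld, threshold = threshold)
    attr(rep0, "removed") <- character()
    return(list(instruments = inst, report = rep0))
  }
  removed <- character()
  repeat {
    report <- heidi_test(inst, est, ld = ld, threshold = threshold)
    flagged <- report$SNP[report$flagged]
    if (length(flagged) == nrow(inst))
      stop("all instruments flagged as pleiotropic; model violation likely")
    if (length(flagged) == 0L || !iterate) {
      keep <- !(inst$SNP %in% flagged)
      inst <- inst[keep, , drop = FALSE]
      removed <- c(removed, flagged)
      break
    }
    keep <- !(inst$SNP %in% flagged)
    inst <- inst[keep, , drop = FALSE]
    est <- est[keep, , drop = FALSE]
    removed <- c(removed, flagged)
  }
  attr(report, "removed") <- removed
  list(instruments = inst, report = report,
       flagged = removed)
}
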