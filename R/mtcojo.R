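#' Assemble and validate the external inputs for an mtCOJO analysis
#'
#' The conditional adjustment needs, for the t covariate traits: marginal
#' covariate-on-target effects (usually GSMR estimates), the genetic
#' correlation matrix among covariates, SNP-based heritabilities, and the
#' sample-overlap intercepts from bivariate LD score regression — the
#' products \code{rho * r_p} of overlap fraction and phenotypic
#' correlation — between target and each covariate (\code{c_xy}) and among
#' covariates (\code{C_xx}). All are consumed as externally estimated
#' inputs; none is estimated here.
#'
#' @param beta_xy_marginal t-vector of marginal covariate-on-target effects.
#' @param Rx t x t genetic-correlation matrix (unit diagonal, |entries| <= 1).
#' @param h2 t-vector of SNP-based heritabilities in (0, 1].
#' @param c_xy t-vector of target-covariate overlap intercepts (|.| <= 1);
#'   zero for non-overlapping samples.
#' @param C_xx t x t covariate-covariate overlap intercept matrix (unit
#'   diagonal); identity for non-overlapping covariate samples.
#' @param covariate_names optional names for the t covariates.
#' @return list of class \code{mtcojo_inputs}.
#' @export
mtcojo_inputs <- function(beta_xy_marginal, Rx = diag(length(beta_xy_marginal)),
                          h2 = rep(0.5, length(beta_xy_marginal)),
                          c_xy = rep(0, length(beta_xy_marginal)),
                          C_xx = diag(length(beta_xy_marginal)),
                          covariate_names = NULL) {
  t <- length(beta_xy_marginal)
  Rx <- as.matrix(Rx); C_xx <- as.matrix(C_xx)
  stopifnot(nrow(Rx) == t, ncol(Rx) == t, length(h2) == t,
            length(c_xy) == t, nrow(C_xx) == t, ncol(C_xx) == t)
  if (max(abs(Rx - t(Rx))) > 1e-8 || max(abs(diag(Rx) - 1)) > 1e-8 ||
      max(abs(Rx)) > 1 + 1e-8)
    stop("Rx must be symmetric with unit diagonal and |entries| <= 1")
  if (any(h2 <= 0 | h2 > 1)) stop("h2 must be in (0, 1]")
  if (any(abs(c_xy) > 1)) stop("|c_xy| intercepts must be <= 1")
  if (max(abs(C_xx - t(C_xx))) > 1e-8 || max(abs(diag(C_xx) - 1)) > 1e-8 ||
      max(abs(C_xx)) > 1 + 1e-8)
    stop("C_xx must be symmetric with unit diagonal and |entries| <= 1")
  off <- abs(Rx); diag(off) <- 0
  if (any(off > 0.9))
    warning("genetic correlation |r_g| > 0.9 between covariates; ",
            "near-redundant covariates risk over-correction")
  structure(list(beta_xy_marginal = as.numeric(beta_xy_marginal), Rx = Rx,
                 h2 = as.numeric(h2), c_xy = as.numeric(c_xy), C_xx = C_xx,
                 covariate_names = covariate_names %||%
                   paste0("covariate", seq_len(t))),
            class = "mtcojo_inputs")
}

#' Read mtCOJO external inputs from a YAML file
#'
#' Expected keys: \code{beta_xy} (t-vector), and optionally \code{Rx}
#' (t x t), \code{h2}, \code{c_xy}, \code{C_xx}, \code{covariates} (names).
#'
#' @param path YAML file path.
#' @return An \code{mtcojo_inputs} list.
#' @export
read_mtcojo_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$beta_xy)) stop("YAML must define beta_xy")
  t <- length(y$beta_xy)
  as_mat <- function(m) if (is.null(m)) NULL else
    matrix(unlist(m), nrow = t, byrow = TRUE)
  mtcojo_inputs(beta_xy_marginal = unlist(y$beta_xy),
                Rx = as_mat(y$Rx) %||% diag(t),
                h2 = unlist(y$h2) %||% rep(0.5, t),
                c_xy = unlist(y$c_xy) %||% rep(0, t),
                C_xx = as_mat(y$C_xx) %||% diag(t),
                covariate_names = unlist(y$covariates))
}

#' Convert marginal covariate effects to joint effects
#'
#' Joint effects of the covariates' genetic values on the target,
#' \deqn{b_{xy} = D^{-1/2} R_x^{-1} D^{1/2} \beta_{xy},}
#' where D is diagonal with the covariates' SNP-based heritabilities and
#' R_x the genetic-correlation matrix. Identity when \code{Rx = I} or
#' \code{t = 1}.
#'
#' @param beta_xy t-vector of marginal effects.
#' @param Rx t x t genetic-correlation matrix.
#' @param h2 t-vector of SNP heritabilities, > 0.
#' @return t-vector of joint effects.
#' @export
marginal_to_joint <- function(beta_xy, Rx, h2) {
  t <- length(beta_xy)
  stopifnot(length(h2) == t, all(h2 > 0), nrow(Rx) == t, ncol(Rx) == t)
  rc <- rcond(Rx)
  if (rc < 1e-10) {
    off <- abs(Rx); diag(off) <- 0
    top <- arrayInd(which.max(off), dim(off))
    stop("Rx is singular or near-singular; most collinear covariate pair: ",
         top[1], " / ", top[2])
  }
  ds <- sqrt(h2)
  as.numeric((1 / ds) * solve(Rx, ds * beta_xy))
}

#' Conditional SNP effect given covariate genetic values
#'
#' \code{b_adj = b_zy - sum_i b_zx[i] * b_xy[i]}: the SNP's effect on the
#' target after removing the part mediated by (or shared with) the
#' covariates' genetic values.
#'
#' @param b_zy SNP effect on the target.
#' @param b_zx t-vector of SNP effects on the covariates (same effect
#'   allele as \code{b_zy}).
#' @param b_xy t-vector of joint covariate-on-target effects.
#' @return Adjusted effect.
#' @export
conditional_effect <- function(b_zy, b_zx, b_xy) {
  if (length(b_zx) != length(b_xy)) stop("b_zx and b_xy length mismatch")
  b_zy - sum(b_zx * b_xy)
}

#' Sampling covariance of two effect estimates from overlapping samples
#'
#' \code{cov = c * se_a * se_b} with \code{c = rho * r_p}, the product of
#' the sample-overlap fraction and the phenotypic correlation, approximated
#' in practice by a bivariate LD score regression intercept.
#'
#' @param se_a,se_b standard errors, > 0.
#' @param intercept_c overlap intercept, |c| <= 1.
#' @return The covariance.
#' @export
overlap_cov <- function(se_a, se_b, intercept_c) {
  if (any(se_a <= 0) || any(se_b <= 0)) stop("standard errors must be > 0")
  if (any(abs(intercept_c) > 1)) stop("|intercept| must be <= 1")
  intercept_c * se_a * se_b
}

#' Sampling variance of the conditional SNP effect
#'
#' \deqn{var(b_{adj}) = var(b_{zy}) + b_{xy}' V_{zx} b_{xy}
#'   - 2 b_{xy}' cov(b_{zy}, b_{zx}),}
#' where \code{V_zx} is the sampling variance-covariance of the SNP's
#' covariate effects and \code{cov_vec} the vector of sampling covariances
#' between the target and covariate effects. With no sample overlap
#' (\code{cov_vec = 0}) this is \code{var_zy + b'Vb}; with target and
#' covariates measured in one sample it reduces to \code{var_zy - b'Vb}.
#'
#' @param var_zy sampling variance of the SNP's target effect.
#' @param b_xy t-vector of joint covariate-on-target effects.
#' @param V_zx t x t sampling variance-covariance of covariate effects.
#' @param cov_vec t-vector of target-covariate sampling covariances.
#' @return The adjusted variance (> 0, else an error).
#' @export
conditional_variance <- function(var_zy, b_xy, V_zx,
                                 cov_vec = rep(0, length(b_xy))) {
  V_zx <- as.matrix(V_zx)
  stopifnot(nrow(V_zx) == length(b_xy), length(cov_vec) == length(b_xy))
  v <- as.numeric(var_zy + t(b_xy) %*% V_zx %*% b_xy - 2 * sum(b_xy * cov_vec))
  if (v <= 0)
    stop("conditional variance <= 0; overlap intercepts inconsistent ",
         "with the supplied standard errors")
  v
}

#' Multi-trait-based conditional GWAS adjustment (mtCOJO)
#'
#' Adjusts every SNP in the target summary dataset for the genetic values
#' of the covariate traits, producing a conditional summary dataset that
#' can feed straight back into [gsmr()] ("conditional GSMR"). Marginal
#' covariate-on-target effects are converted to joint effects via
#' [marginal_to_joint()]; each SNP's effect is shifted by
#' [conditional_effect()] and its variance updated by
#' [conditional_variance()], with per-SNP \code{V_zx} and the
#' target-covariate covariances assembled from the covariate standard
#' errors and the overlap intercepts via [overlap_cov()]. The conditional
#' P-value is the upper tail of \code{b_adj^2 / var_adj} on chi-squared(1).
#'
#' Covariate effects are aligned to the target's effect alleles by
#' [harmonize()]. SNPs missing from any covariate dataset (or dropped in
#' allele alignment) are skipped by default, or kept unadjusted for the
#' missing covariates when \code{missing_action = "zero"}.
#'
#' @param target \code{summary_dataset} to adjust.
#' @param covariates list of covariate \code{summary_dataset}s (effects in
#'   SD units).
#' @param inputs an [mtcojo_inputs()] list (length t = covariates).
#' @param missing_action \code{"skip"} or \code{"zero"}.
#' @return list of class \code{mtcojo}: \code{adjusted} (a
#'   \code{summary_dataset} of conditional effects), \code{b_xy_joint},
#'   \code{n_skipped}, \code{inputs}.
#' @export
run_mtcojo <- function(target, covariates, inputs,
                       missing_action = c("skip", "zero")) {
  missing_action <- match.arg(missing_action)
  if (!inherits(inputs, "mtcojo_inputs")) stop("inputs must be mtcojo_inputs")
  t <- length(inputs$beta_xy_marginal)
  if (length(covariates) != t)
    stop("need ", t, " covariate dataset(s), got ", length(covariates))
  b_xy <- marginal_to_joint(inputs$beta_xy_marginal, inputs$Rx, inputs$h2)

  td <- as.data.frame(target)
  m <- nrow(td)
  bzx <- sezx <- matrix(NA_real_, m, t)
  for (j in seq_len(t)) {
    shared <- intersect(td$SNP, covariates[[j]]$SNP)
    if (length(shared) > 0L) {
      h <- suppressMessages(
        harmonize(target, covariates[[j]], snp_ids = shared))
      idx <- match(h$SNP, td$SNP)
      bzx[idx, j] <- h$bzy       # covariate effect on target's A1
      sezx[idx, j] <- h$se_bzy
    }
  }
  complete <- rowSums(is.na(bzx)) == 0L
  if (missing_action == "skip") {
    usable <- complete
    if (any(!usable))
      message(sum(!usable), " SNP(s) missing from >= 1 covariate skipped")
  } else {
    usable <- rep(TRUE, m)
    bzx[is.na(bzx)] <- 0
    sezx[is.na(sezx)] <- 0
  }
  frac <- mean(usable)
  if (frac < 0.5)
    warning("only ", round(100 * frac), "% of target SNPs have complete ",
            "covariate coverage")

  b_adj <- td$b
  se_adj <- td$se
  for (i in which(usable)) {
    b_adj[i] <- conditional_effect(td$b[i], bzx[i, ], b_xy)
    se_i <- sezx[i, ]
    V_zx <- inputs$C_xx * tcrossprod(se_i)
    cov_vec <- inputs$c_xy * se_i * td$se[i]
    se_adj[i] <- sqrt(conditional_variance(td$se[i]^2, b_xy, V_zx, cov_vec))
  }
  chi2 <- (b_adj / se_adj)^2
  p_adj <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  adjusted <- new_summary_dataset(
    within(td, { b <- b_adj; se <- se_adj; p <- p_adj }),
    paste0(attr(target, "trait_name"), "_conditional"),
    attr(target, "trait_type"))
  out <- adjusted[usable | missing_action == "zero", , drop = FALSE]
  structure(list(adjusted = new_summary_dataset(
    as.data.frame(out), attr(adjusted, "trait_name"),
    attr(target, "trait_type")),
    b_xy_joint = b_xy, n_skipped = sum(!usable), inputs = inputs),
    class = "mtcojo")
}

#' @export
print.mtcojo <- function(x, ...) {
  cat("mtCOJO conditional adjustment: ", nrow(x$adjusted), " SNP(s) adjusted",
      if (x$n_skipped > 0) paste0(", ", x$n_skipped, " skipped"), "\n", sep = "")
  cat("  joint covariate effects:",
      paste(signif(x$b_xy_joint, 4), collapse = ", "), "\n")
  invisible(x)
}
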