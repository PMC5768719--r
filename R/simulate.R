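#' Configuration for the two-sample GWAS simulator
#'
#' Captures the generative model for a two-sample Mendelian randomization
#' study: m instrument SNPs with effects on an exposure, an optional causal
#' exposure-outcome effect, optional pleiotropic SNPs with direct outcome
#' effects, LD blocks among instruments, and quantitative or binary
#' (logistic) outcomes measured on a sample disjoint from the exposure
#' sample.
#'
#' @param n_exposure,n_outcome GWAS sample sizes for the two samples.
#' @param m number of instrument SNPs.
#' @param maf_range MAF drawn uniformly from this range (one per LD block).
#' @param ld_block_size SNPs per LD block (1 = independent SNPs).
#' @param ld_r within-block allele correlation (exchangeable), |r| < 1.
#' @param h2x proportion of exposure variance explained by the m SNPs.
#' @param b_xy causal effect of exposure on outcome (logOR scale for binary
#'   outcomes).
#' @param n_pleio number of SNPs with direct (pleiotropic) outcome effects.
#' @param pleio_sd SD of the pleiotropic direct effects (standardized
#'   genotype scale).
#' @param outcome_type \code{"quantitative"} or \code{"binary"}.
#' @param prevalence population prevalence for binary outcomes.
#' @param liability use a liability-threshold rather than logistic model
#'   for binary outcomes.
#' @param reverse_b optional reverse (outcome-on-exposure) effect,
#'   quantitative outcomes only.
#' @param seed integer seed; all randomness in the simulator flows from it.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(n_exposure = 50000, n_outcome = 50000, m = 100,
                       maf_range = c(0.05, 0.5), ld_block_size = 1,
                       ld_r = 0, h2x = 0.05, b_xy = 0.3, n_pleio = 0,
                       pleio_sd = 0.1,
                       outcome_type = c("quantitative", "binary"),
                       prevalence = 0.1, liability = FALSE, reverse_b = 0,
                       seed = 1) {
  outcome_type <- match.arg(outcome_type)
  stopifnot(n_exposure > 0, n_outcome > 0, m >= 1, ld_block_size >= 1,
            abs(ld_r) < 1, h2x > 0, h2x < 1, n_pleio >= 0, n_pleio <= m,
            prevalence > 0, prevalence < 1)
  if (ld_r < 0) stop("within-block allele correlation must be >= 0")
  structure(list(n_exposure = n_exposure, n_outcome = n_outcome, m = m,
                 maf_range = maf_range, ld_block_size = ld_block_size,
                 ld_r = ld_r, h2x = h2x, b_xy = b_xy, n_pleio = n_pleio,
                 pleio_sd = pleio_sd, outcome_type = outcome_type,
                 prevalence = prevalence, liability = liability,
                 reverse_b = reverse_b, seed = seed),
            class = "sim_config")
}

sim_snp_table <- function(m, block_size) {
  block <- (seq_len(m) - 1L) %/% block_size
  data.frame(SNP = sprintf("rs%04d", seq_len(m)), chr = "1",
             # 100 kb between SNPs in a block, 2 Mb between blocks
             bp = 1e6 + block * 2e6 + ((seq_len(m) - 1L) %% block_size) * 1e5,
             A1 = "A", A2 = "C", block = block, stringsAsFactors = FALSE)
}

#' Ground truth for a simulated two-sample MR study
#'
#' Draws the per-SNP exposure effects and pleiotropic direct effects once,
#' before any sampling noise, for use by [sample_sumstats_direct()] or for
#' checking parameter recovery. Exposure effects are drawn standard normal
#' on the standardized-genotype scale and rescaled so the m SNPs jointly
#' explain \code{h2x} of the exposure variance (treating SNPs as
#' independent); \code{n_pleio} SNPs additionally receive direct outcome
#' effects drawn N(0, \code{pleio_sd}^2).
#'
#' @param m,maf_range,ld_block_size,h2x,b_xy,n_pleio,pleio_sd,seed as in
#'   [sim_config()]; a \code{sim_config} can be splatted via
#'   \code{do.call}.
#' @return list of class \code{sim_truth}: \code{snp} (SNP table with
#'   \code{maf}), \code{u_zx} (standardized-scale exposure effects),
#'   \code{bzx} (per-allele scale), \code{pleio_ids}, \code{pleio_effects}
#'   (standardized scale, full-length vector), \code{b_xy}, \code{h2x},
#'   \code{ld_block_size}, \code{ld_r}, \code{seed}.
#' @export
sim_truth <- function(m = 100, maf_range = c(0.05, 0.5), ld_block_size = 1,
                      ld_r = 0, h2x = 0.05, b_xy = 0.3, n_pleio = 0,
                      pleio_sd = 0.1, seed = 1) {
  set.seed(seed)
  snp <- sim_snp_table(m, ld_block_size)
  maf_block <- stats::runif(max(snp$block) + 1L, maf_range[1], maf_range[2])
  snp$maf <- maf_block[snp$block + 1L]
  u <- stats::rnorm(m)
  u <- u * sqrt(h2x / sum(u^2))
  pleio_ids <- if (n_pleio > 0) sort(sample.int(m, n_pleio)) else integer()
  d <- numeric(m)
  d[pleio_ids] <- stats::rnorm(n_pleio, 0, pleio_sd)
  structure(list(snp = snp, u_zx = u,
                 bzx = u / sqrt(2 * snp$maf * (1 - snp$maf)),
                 pleio_ids = snp$SNP[pleio_ids], pleio_effects = d,
                 b_xy = b_xy, h2x = h2x, ld_block_size = ld_block_size,
                 ld_r = ld_r, seed = seed),
            class = "sim_truth")
}

#' Block-exchangeable LD matrix implied by a simulation truth
#'
#' @param truth a \code{sim_truth}.
#' @return An [ld_matrix()] with within-block correlation \code{ld_r} and
#'   zero across blocks.
#' @export
sim_ld_matrix <- function(truth) {
  m <- nrow(truth$snp)
  r <- outer(truth$snp$block, truth$snp$block,
             function(a, b) ifelse(a == b, truth$ld_r, 0))
  diag(r) <- 1
  ld_matrix(r, truth$snp$SNP)
}

#' Simulate a genotype panel with block-exchangeable LD
#'
#' Genotypes are sums of two independent haplotypes. Within an LD block all
#' SNPs share one MAF and each haplotype allele copies a block-level
#' "master" allele with probability \code{sqrt(ld_r)} (otherwise it is a
#' fresh Bernoulli draw), which yields Hardy-Weinberg genotype frequencies
#' and an exact exchangeable allele correlation of \code{ld_r} between any
#' two SNPs in a block. Blocks are mutually independent.
#'
#' @param n individuals.
#' @param m SNPs.
#' @param maf_range,ld_block_size,ld_r,seed as in [sim_config()].
#' @param snp optional precomputed SNP table with \code{maf} (from
#'   [sim_truth()]) so panel and truth agree.
#' @return A \code{genotype_panel}.
#' @export
simulate_genotypes <- function(n, m, maf_range = c(0.05, 0.5),
                               ld_block_size = 1, ld_r = 0, seed = 1,
                               snp = NULL) {
  set.seed(seed + 1L)
  if (is.null(snp)) {
    snp <- sim_snp_table(m, ld_block_size)
    maf_block <- stats::runif(max(snp$block) + 1L, maf_range[1], maf_range[2])
    snp$maf <- maf_block[snp$block + 1L]
  }
  q <- sqrt(ld_r)
  hap <- function() {
    h <- matrix(0L, n, m)
    for (b in unique(snp$block)) {
      cols <- which(snp$block == b)
      p <- snp$maf[cols[1]]
      master <- stats::rbinom(n, 1L, p)
      for (j in cols) {
        w <- stats::rbinom(n, 1L, q)
        h[, j] <- ifelse(w == 1L, master, stats::rbinom(n, 1L, p))
      }
    }
    h
  }
  geno <- hap() + hap()
  colnames(geno) <- snp$SNP
  genotype_panel(geno, snp[, c("SNP", "chr", "bp", "A1", "A2")])
}

#' Simulate exposure and outcome phenotypes on a genotype panel
#'
#' The exposure is \code{x = g + e} with genetic value \code{g} built from
#' the truth's standardized-scale SNP effects, rescaled so the realized
#' SNP heritability equals \code{h2x}, and residual variance \code{1 -
#' h2x}. The outcome adds the causal path, any pleiotropic direct effects
#' and noise: quantitative \code{y = b_xy x + Z d + e_y}; binary outcomes
#' are drawn from a logistic model on the same linear predictor with the
#' intercept calibrated to the target prevalence (or from a
#' liability-threshold model when \code{liability = TRUE}). The first
#' \code{n_exposure} panel rows form the exposure sample and the remaining
#' rows the outcome sample (two-sample design); each phenotype is returned
#' NA outside its own sample.
#'
#' @param panel a \code{genotype_panel} with
#'   \code{config$n_exposure + config$n_outcome} rows.
#' @param config a [sim_config()].
#' @param truth optional \code{sim_truth} (drawn from \code{config} if
#'   omitted).
#' @return list with \code{x} (exposure, NA in outcome sample), \code{y}
#'   (outcome, NA in exposure sample), \code{x_full}/\code{y_full} (the
#'   unmasked phenotypes, for oracle comparisons only), and \code{truth}
#'   (with realized heritability recorded as \code{h2x_realized}).
#' @export
simulate_traits <- function(panel, config, truth = NULL) {
  if (is.null(truth))
    truth <- sim_truth(m = config$m, maf_range = config$maf_range,
                       ld_block_size = config$ld_block_size,
                       ld_r = config$ld_r, h2x = config$h2x,
                       b_xy = config$b_xy, n_pleio = config$n_pleio,
                       pleio_sd = config$pleio_sd, seed = config$seed)
  n <- nrow(panel$geno)
  if (n != config$n_exposure + config$n_outcome)
    stop("panel rows must equal n_exposure + n_outcome")
  set.seed(config$seed + 2L)
  Zs <- scale(panel$geno)
  if (anyNA(Zs)) stop("monomorphic SNP in panel; heritability target infeasible")
  g <- as.numeric(Zs %*% truth$u_zx)
  vg <- stats::var(g)
  scl <- sqrt(config$h2x / vg)
  g <- g * scl
  truth$u_zx <- truth$u_zx * scl
  truth$bzx <- truth$bzx * scl
  truth$h2x_realized <- stats::var(g)
  x <- g + stats::rnorm(n, 0, sqrt(1 - config$h2x))
  eta <- config$b_xy * x + as.numeric(Zs %*% truth$pleio_effects)
  if (config$outcome_type == "quantitative") {
    y <- eta + stats::rnorm(n)
    if (config$reverse_b != 0) x <- x + config$reverse_b * y
  } else {
    if (config$liability) {
      liab <- eta + stats::rnorm(n)
      y <- as.numeric(liab > stats::qnorm(1 - config$prevalence,
                                          sd = stats::sd(liab)))
    } else {
      alpha <- stats::uniroot(
        function(a) mean(stats::plogis(a + eta)) - config$prevalence,
        interval = c(-30, 30))$root
      y <- stats::rbinom(n, 1L, stats::plogis(alpha + eta))
    }
  }
  ix <- seq_len(config$n_exposure)
  x_out <- rep(NA_real_, n); x_out[ix] <- x[ix]
  y_out <- rep(NA_real_, n); y_out[-ix] <- y[-ix]
  # x_full/y_full expose the complete latent phenotypes for oracle checks
  # (e.g. individual-level regression of outcome on exposure); the masked
  # x/y are what a two-sample analysis may legitimately see
  list(x = x_out, y = y_out, x_full = x, y_full = y, truth = truth)
}

#' Per-SNP GWAS scan of a phenotype on a genotype panel
#'
#' Simple linear regression (quantitative) or logistic regression (binary)
#' of the phenotype on each SNP's allele count, over the individuals with
#' both phenotype and genotype observed. Records the effect-allele (A1)
#' frequency and the per-SNP non-missing sample size. Monomorphic SNPs are
#' dropped with a message.
#'
#' @param panel a \code{genotype_panel}.
#' @param phenotype numeric vector, NA for individuals outside the sample.
#' @param binary logistic instead of linear regression.
#' @param trait_name label for the resulting dataset.
#' @return A \code{summary_dataset} with \code{chr}/\code{bp} from the
#'   panel.
#' @export
gwas_scan <- function(panel, phenotype, binary = FALSE,
                      trait_name = "trait") {
  m <- ncol(panel$geno)
  res <- matrix(NA_real_, m, 5,
                dimnames = list(NULL, c("freq", "b", "se", "p", "N")))
  for (j in seq_len(m)) {
    gj <- panel$geno[, j]
    ok <- !is.na(gj) & !is.na(phenotype)
    g <- gj[ok]; y <- phenotype[ok]
    n <- length(y)
    if (n < 3L || stats::var(g) == 0) next
    if (binary) {
      fit <- suppressWarnings(
        stats::glm(y ~ g, family = stats::binomial()))
      s <- summary(fit)$coefficients
      b <- s["g", "Estimate"]; se <- s["g", "Std. Error"]
    } else {
      sxx <- sum((g - mean(g))^2)
      b <- sum((g - mean(g)) * y) / sxx
      resid <- y - mean(y) - b * (g - mean(g))
      se <- sqrt(sum(resid^2) / (n - 2) / sxx)
    }
    chi2 <- (b / se)^2
    res[j, ] <- c(mean(g) / 2, b, se,
                  stats::pchisq(chi2, 1, lower.tail = FALSE), n)
  }
  # A1 is the counted allele; freq is its frequency in the analyzed sample
  drop <- is.na(res[, "b"])
  if (any(drop))
    message(sum(drop), " monomorphic or unusable SNP(s) dropped from scan")
  keep <- which(!drop)
  snp <- panel$snp[keep, ]
  summary_dataset(SNP = snp$SNP, A1 = snp$A1, A2 = snp$A2,
                  freq = res[keep, "freq"], b = res[keep, "b"],
                  se = res[keep, "se"],
                  p = pmax(res[keep, "p"], .Machine$double.xmin),
                  N = res[keep, "N"], chr = snp$chr, bp = snp$bp,
                  trait_name = trait_name,
                  trait_type = if (binary) "binary" else "quantitative")
}

#' Draw two-sample GWAS summary statistics directly from their sampling
#' distribution
#'
#' Fast path for simulation studies: instead of simulating individuals,
#' the estimated effect vectors are drawn from their asymptotic
#' distribution. On the standardized-genotype scale the true marginal
#' effects are \code{u_marg = R u} for the exposure and \code{w_marg =
#' b_xy u_marg + R d} for the outcome (R the LD matrix, d the pleiotropic
#' direct effects), with sampling covariance \code{S R S} where \code{S =
#' diag(1/sqrt(n))}. Per-allele effects and their standard errors follow by
#' dividing by \code{sqrt(2 p (1 - p))}. Exposure and outcome draws are
#' independent (two-sample design).
#'
#' @param truth a [sim_truth()].
#' @param ld optional [ld_matrix()]; defaults to the block-exchangeable
#'   matrix implied by the truth ([sim_ld_matrix()]).
#' @param n_x,n_y sample sizes of the exposure and outcome GWAS.
#' @param seed seed for the draws.
#' @return list with \code{exposure} and \code{outcome}
#'   \code{summary_dataset}s and \code{ld}, the LD matrix used.
#' @export
sample_sumstats_direct <- function(truth, ld = NULL, n_x = 50000,
                                   n_y = 50000, seed = 1) {
  set.seed(seed)
  m <- nrow(truth$snp)
  if (is.null(ld)) ld <- sim_ld_matrix(truth)
  R <- unclass(ld)[truth$snp$SNP, truth$snp$SNP, drop = FALSE]
  L <- tryCatch(chol(R), error = function(e)
    stop("implied sampling covariance not positive definite: ",
         conditionMessage(e)))
  u_marg <- as.numeric(R %*% truth$u_zx)
  w_marg <- truth$b_xy * u_marg + as.numeric(R %*% truth$pleio_effects)
  draw <- function(mu, n) (mu + crossprod(L, stats::rnorm(m)) / sqrt(n))[, 1]
  u_hat <- draw(u_marg, n_x)
  w_hat <- draw(w_marg, n_y)
  sc <- sqrt(2 * truth$snp$maf * (1 - truth$snp$maf))
  mk <- function(bhat, n, name, type) {
    b <- bhat / sc
    se <- 1 / (sc * sqrt(n))
    chi2 <- (b / se)^2
    summary_dataset(SNP = truth$snp$SNP, A1 = truth$snp$A1,
                    A2 = truth$snp$A2, freq = truth$snp$maf, b = b, se = se,
                    p = pmax(stats::pchisq(chi2, 1, lower.tail = FALSE),
                             .Machine$double.xmin),
                    N = rep(n, m), chr = truth$snp$chr, bp = truth$snp$bp,
                    trait_name = name, trait_type = type)
  }
  list(exposure = mk(u_hat, n_x, "exposure", "quantitative"),
       outcome = mk(w_hat, n_y, "outcome", "quantitative"),
       ld = ld)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("Simulation truth: m =", nrow(x$snp), "SNPs, b_xy =", x$b_xy,
      ", h2x =", x$h2x, "\n")
  if (length(x$pleio_ids) > 0L)
    cat("  pleiotropic SNPs:", length(x$pleio_ids), "\n")
  invisible(x)
}
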