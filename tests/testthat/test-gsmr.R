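test_that("per-SNP ratio estimates match the delta-method formula", {
  inst <- make_hset("rs1", bzx = 0.1, se_bzx = 0.01, bzy = 0.05,
                    se_bzy = 0.01)
  est <- bxy_per_snp(inst)
  expect_equal(est$bxy, 0.5)
  # direct evaluation of the printed factorized form as the oracle
  oracle <- 0.5^2 * (0.01^2 / 0.1^2 + 0.01^2 / 0.05^2 - 0.01^4 / 0.1^4)
  expect_equal(est$var_bxy, oracle, tolerance = 1e-14)
  expect_equal(est$var_bxy, 0.012475, tolerance = 1e-10)

  # stable form is finite and exact at bzy = 0
  z0 <- bxy_per_snp(make_hset("rs1", 0.1, 0.01, 0, 0.01))
  expect_equal(z0$bxy, 0)
  expect_equal(z0$var_bxy, 0.01^2 / 0.1^2)

  # scaling (bzy, se_zy) by c scales (bxy, sd) by |c| when se_zx = 0
  base <- bxy_per_snp(make_hset("rs1", 0.1, 0, 0.05, 0.01))
  scaled <- bxy_per_snp(make_hset("rs1", 0.1, 0, -3 * 0.05, 3 * 0.01))
  expect_equal(scaled$bxy, -3 * base$bxy)
  expect_equal(sqrt(scaled$var_bxy), 3 * sqrt(base$var_bxy))

  # stable and factorized forms agree over random parameter draws
  set.seed(23)
  for (i in 1:200) {
    bzx <- runif(1, 0.02, 0.5) * sample(c(-1, 1), 1)
    bzy <- rnorm(1, 0, 0.1)
    sex <- runif(1, 0.001, 0.05); sey <- runif(1, 0.001, 0.05)
    got <- bxy_per_snp(make_hset("s", bzx, sex, bzy, sey))$var_bxy
    bxy <- bzy / bzx
    lit <- bxy^2 * (sex^2 / bzx^2 + sey^2 / bzy^2 - sex^4 / bzx^4)
    if (bzy != 0) expect_equal(got, lit, tolerance = 1e-10)
  }
  expect_error(bxy_per_snp(make_hset("dz", 0, 0.01, 0.1, 0.01)),
               "degenerate.*dz")
})

test_that("V matrix matches a term-by-term oracle and collapses to the
           diagonal formula at i = j, r = 1", {
  inst <- make_hset(c("a", "b"), bzx = c(0.12, -0.08),
                    se_bzx = c(0.011, 0.013), bzy = c(0.03, -0.02),
                    se_bzy = c(0.009, 0.014))
  est <- bxy_per_snp(inst)
  r <- 0.2
  ld <- ld_matrix(matrix(c(1, r, r, 1), 2), c("a", "b"))
  V <- build_V(inst, est, ld)
  # independent term-by-term evaluation of the printed covariance
  cov_oracle <- r * sqrt(0.009^2 * 0.014^2) / (0.12 * -0.08) +
    est$bxy[1] * est$bxy[2] *
    (r * sqrt(0.011^2 * 0.013^2) / (0.12 * -0.08) -
       (0.011^2 * 0.013^2) / (0.12^2 * 0.08^2))
  expect_equal(V["a", "b"], cov_oracle, tolerance = 1e-14)
  expect_equal(V["b", "a"], V["a", "b"])
  expect_equal(diag(V), setNames(est$var_bxy, c("a", "b")))

  # m = 1: the 1x1 matrix is just var_bxy
  one <- make_hset("solo", 0.1, 0.01, 0.05, 0.01)
  expect_equal(build_V(one)[1, 1], bxy_per_snp(one)$var_bxy)

  # identity: off-diagonal formula at i = j, r = 1 equals the variance
  set.seed(31)
  for (i in 1:200) {
    bzx <- runif(1, 0.02, 0.5) * sample(c(-1, 1), 1)
    bzy <- rnorm(1, 0, 0.1)
    sex <- runif(1, 0.001, 0.05); sey <- runif(1, 0.001, 0.05)
    h <- make_hset("s", bzx, sex, bzy, sey)
    e <- bxy_per_snp(h)
    cov_ii <- gsmrkit:::bxy_cov(bzx, sex, bzx, sex, sey, sey,
                                e$bxy, e$bxy, r = 1)
    expect_equal(cov_ii, e$var_bxy, tolerance = 1e-10)
  }

  # near-perfect LD makes V non-invertible
  twin <- make_hset(c("a", "b"), c(0.1, 0.1), c(0.01, 0.01),
                    c(0.05, 0.05), c(0.01, 0.01))
  ld1 <- ld_matrix(matrix(c(1, 1 - 1e-14, 1 - 1e-14, 1), 2), c("a", "b"))
  expect_error(build_V(twin, ld = ld1), "non-invertible")
})

test_that("GLS equals the inverse-variance-weighted mean for diagonal V
           and reduces to the single-SNP estimate at m = 1", {
  est <- data.frame(SNP = c("a", "b"), bxy = c(0.2, 0.4),
                    var_bxy = c(0.01, 0.04))
  g <- gls_estimate(est, diag(est$var_bxy))
  expect_equal(g$bxy, 0.24)
  expect_equal(g$se, 1 / sqrt(125))
  expect_equal(g$chi2, 7.2)
  expect_equal(g$pval, pchisq(7.2, 1, lower.tail = FALSE))
  expect_equal(g$chi2, (g$bxy / g$se)^2)

  set.seed(37)
  for (i in 1:50) {
    m <- sample(1:20, 1)
    bxy <- rnorm(m); v <- runif(m, 0.001, 0.1)
    est <- data.frame(SNP = as.character(1:m), bxy = bxy, var_bxy = v)
    g <- gls_estimate(est, diag(v, m))
    expect_equal(g$bxy, sum(bxy / v) / sum(1 / v), tolerance = 1e-12)
    expect_equal(g$se, 1 / sqrt(sum(1 / v)), tolerance = 1e-12)
  }

  one <- make_hset("solo", 0.1, 0.01, 0.05, 0.012)
  e1 <- bxy_per_snp(one)
  g1 <- gls_estimate(e1, build_V(one))
  expect_equal(g1$bxy, e1$bxy)
  expect_equal(g1$se, sqrt(e1$var_bxy))

  # constancy: equal per-SNP estimates are returned unchanged
  estc <- data.frame(SNP = c("a", "b", "c"), bxy = rep(0.3, 3),
                     var_bxy = c(0.01, 0.02, 0.03))
  Vc <- diag(estc$var_bxy); Vc[Vc == 0] <- 0.001; diag(Vc) <- estc$var_bxy
  expect_equal(gls_estimate(estc, Vc)$bxy, 0.3, tolerance = 1e-12)

  expect_error(gls_estimate(est, matrix(c(1, 2, 2, 1), 2)),
               "not positive definite")
})

test_that("gsmr recovers a causal effect and enforces the instrument rule", {
  tr <- sim_truth(m = 50, b_xy = 0.3, h2x = 0.1, seed = 101)
  sim <- sample_sumstats_direct(tr, n_x = 5e4, n_y = 5e4, seed = 102)
  fit <- gsmr(sim$exposure, sim$outcome)
  expect_s3_class(fit, "gsmr")
  expect_lt(abs(fit$bxy - 0.3), 2 * fit$se)
  expect_equal(fit$chi2, (fit$bxy / fit$se)^2)
  expect_equal(fit$n_instruments_used,
               fit$n_instruments_input - length(fit$flagged_pleiotropic))
  # methods are coherent
  expect_equal(unname(coef(fit)), fit$bxy)
  expect_equal(unname(vcov(fit)[1, 1]), fit$se^2)
  ci <- confint(fit)
  expect_lt(ci[1], fit$bxy); expect_gt(ci[2], fit$bxy)
  expect_equal(length(residuals(fit)), fit$n_instruments_used)
  expect_output(print(summary(fit)), "GSMR")

  # guard: too few instruments unless forced
  tr5 <- sim_truth(m = 5, b_xy = 0.3, h2x = 0.05, seed = 103)
  sim5 <- sample_sumstats_direct(tr5, n_x = 5e4, n_y = 5e4, seed = 104)
  expect_error(gsmr(sim5$exposure, sim5$outcome), "10 or more")
  expect_warning(f5 <- gsmr(sim5$exposure, sim5$outcome,
                            options = gsmr_options(force = TRUE)),
                 "proceeding")
  expect_s3_class(f5, "gsmr")
})

test_that("bidirectional wrapper is symmetric and recovers opposite-sign
           effects on synthetic data", {
  # forward x -> y with b = 0.3; reverse y -> x with b = -0.05, built by
  # composing two direct draws with disjoint instrument sets
  trA <- sim_truth(m = 30, b_xy = 0.3, h2x = 0.1, seed = 201)
  simA <- sample_sumstats_direct(trA, n_x = 8e4, n_y = 8e4, seed = 202)
  trB <- sim_truth(m = 30, b_xy = -0.05, h2x = 0.1, seed = 203)
  simB <- sample_sumstats_direct(trB, n_x = 8e4, n_y = 8e4, seed = 204)
  # rename B's SNPs so the two instrument sets are distinct loci
  for (d in c("exposure", "outcome")) {
    simB[[d]]$SNP <- sub("rs", "rv", simB[[d]]$SNP)
    attr(simB[[d]], "trait_name") <- if (d == "exposure") "disease" else "bmi"
  }
  traitA <- suppressWarnings(rbind_dataset(simA$exposure, simB$outcome))
  traitB <- suppressWarnings(rbind_dataset(simA$outcome, simB$exposure))
  bd <- gsmr_bidirectional(traitA, traitB)
  expect_lt(abs(bd$forward$bxy - 0.3), 2 * bd$forward$se)
  expect_lt(abs(bd$reverse$bxy + 0.05), 2 * bd$reverse$se)
  expect_equal(length(bd$instrument_overlap), 0L)
  # swapping arguments swaps the directions exactly
  bd2 <- gsmr_bidirectional(traitB, traitA)
  expect_equal(bd2$reverse$bxy, bd$forward$bxy)
  expect_equal(bd2$forward$bxy, bd$reverse$bxy)
})

test_that("interpretation helpers match their closed forms", {
  expect_equal(logor_to_or(0), 1)
  expect_equal(logor_to_or(0.41), 1.51, tolerance = 0.005)
  expect_equal(logor_to_or(-0.21), 0.81, tolerance = 0.005)
  expect_equal(or_to_logor(logor_to_or(0.37)), 0.37)

  expect_equal(aggregate_effect(c(0, 0, 0)), 1)
  expect_equal(aggregate_effect(c(1.01, -0.17)), exp(0.84))
  expect_equal(aggregate_effect(c(0.41, 0.47, 0.14, 0.48)), exp(1.5))
  expect_equal(aggregate_effect(c(0.2, 0.3), c(2, 0)), exp(0.4))
  expect_error(aggregate_effect(c(0.1, 0.2), 1), "equal length")

  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 231), 0.05 / 231)
  expect_error(bonferroni_threshold(1.5, 10), "fwer")
  expect_error(bonferroni_threshold(0.05, 0), "n_tests")
})

test_that("IVW and Egger comparators match a normal-equations oracle", {
  # exact fit: two SNPs on a line through the origin
  line <- make_hset(c("a", "b"), bzx = c(0.1, 0.2), se_bzx = c(0.01, 0.01),
                    bzy = c(0.05, 0.10), se_bzy = c(0.01, 0.02))
  expect_equal(estimate_ivw(line)$b, 0.5, tolerance = 1e-12)

  # 5-SNP fixture against weighted least squares by normal equations
  set.seed(41)
  inst <- make_hset(paste0("s", 1:5), bzx = c(0.1, -0.15, 0.2, 0.12, -0.3),
                    se_bzx = runif(5, 0.005, 0.02),
                    bzy = c(0.03, -0.05, 0.07, 0.02, -0.11),
                    se_bzy = c(0.01, 0.02, 0.015, 0.012, 0.025))
  w <- 1 / inst$se_bzy^2
  ivw <- estimate_ivw(inst)
  expect_equal(ivw$b, sum(w * inst$bzx * inst$bzy) / sum(w * inst$bzx^2),
               tolerance = 1e-12)
  # Egger: orient so bzx > 0, solve weighted normal equations with intercept
  s <- sign(inst$bzx); x <- inst$bzx * s; y <- inst$bzy * s
  X <- cbind(1, x)
  beta <- solve(t(X) %*% (w * X), t(X) %*% (w * y))
  egger <- estimate_egger(inst)
  expect_equal(egger$intercept, beta[1], tolerance = 1e-10)
  expect_equal(egger$b, beta[2], tolerance = 1e-10)

  expect_error(estimate_ivw(line[1, ]), "at least 2")
  expect_error(estimate_egger(line), "at least 3")
})

test_that("Egger intercept is calibrated under no pleiotropy", {
  set.seed(47)
  hits <- 0L; R <- 200L
  for (i in seq_len(R)) {
    tr <- sim_truth(m = 30, b_xy = 0.2, h2x = 0.1, seed = 1000 + i)
    sim <- sample_sumstats_direct(tr, n_x = 5e4, n_y = 5e4, seed = 2000 + i)
    h <- gws_instruments(sim$exposure, sim$outcome)
    if (estimate_egger(h)$intercept_pval < 0.05) hits <- hits + 1L
  }
  # ~5% rejections expected; allow 4 binomial SDs around 0.05
  expect_lt(abs(hits / R - 0.05), 4 * sqrt(0.05 * 0.95 / R))
})
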