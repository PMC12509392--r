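design16 <- default_study_design()
X16 <- build_design_matrix(design16)

quant_from <- function(values) {
  dimnames(values) <- list(sprintf("P%03d", seq_len(nrow(values))),
                           design16$sample_id)
  protein_quant(values, "log2")
}

test_that("per-protein fits match the normal-equations oracle", {
  old <- design16$group == "old"
  # saturated contrast: young all 0, old all 1
  v <- matrix(rep(as.numeric(old), each = 2), 2, 16, byrow = FALSE)
  fit <- fit_protein_lm(quant_from(v), X16)
  expect_equal(fit$logFC, c(1, 1), tolerance = 1e-12)

  # identical values everywhere: logFC 0, zero residual variance
  fit0 <- fit_protein_lm(quant_from(matrix(5, 2, 16)), X16)
  expect_equal(fit0$logFC, c(0, 0), tolerance = 1e-12)
  expect_equal(fit0$s2, c(0, 0), tolerance = 1e-24)

  # random instances, complete and with missing values, against a direct
  # (X'X)^-1 X'y solve
  set.seed(51)
  v <- matrix(stats::rnorm(5 * 16), 5, 16)
  v[4, c(2, 9)] <- NA
  fits <- fit_protein_lm(quant_from(v), X16)
  for (i in 1:5) {
    obs <- !is.na(v[i, ])
    Xo <- X16[obs, , drop = FALSE]
    beta <- solve(t(Xo) %*% Xo, t(Xo) %*% v[i, obs])
    expect_equal(fits$logFC[i], unname(beta["groupold", 1]),
                 tolerance = 1e-10)
    resid <- v[i, obs] - as.numeric(Xo %*% beta)
    expect_equal(fits$s2[i], sum(resid^2) / (sum(obs) - ncol(Xo)),
                 tolerance = 1e-10)
    expect_equal(fits$v[i], solve(t(Xo) %*% Xo)["groupold", "groupold"],
                 tolerance = 1e-10)
  }
})

test_that("proteins with rank-deficient reduced designs are untestable", {
  # drop all hypertensive samples for one protein: hypertension column
  # becomes constant and the reduced design loses rank
  v <- matrix(stats::rnorm(2 * 16), 2, 16)
  v[1, design16$hypertension] <- NA
  fits <- fit_protein_lm(quant_from(v), X16)
  expect_false(fits$testable[1])
  expect_true(fits$testable[2])
})

test_that("covariates orthogonal to group and data leave logFC unchanged", {
  set.seed(52)
  v <- matrix(stats::rnorm(4 * 16), 4, 16)
  Xg <- build_design_matrix(design16, covariates = NULL)
  f1 <- fit_protein_lm(quant_from(v), Xg)
  extra <- stats::rnorm(16)
  # orthogonalize against current columns and the data rows
  extra <- stats::resid(stats::lm(extra ~ Xg + t(v)))
  X2 <- cbind(Xg, orth = extra)
  attr(X2, "coef") <- "groupold"
  f2 <- fit_protein_lm(quant_from(v), X2)
  expect_equal(f1$logFC, f2$logFC, tolerance = 1e-9)
})

test_that("hyperparameter estimation recovers known priors", {
  set.seed(53)
  d0 <- 6; s0 <- 0.2; d <- 12; n <- 20000
  sigma2 <- s0 * d0 / stats::rchisq(n, d0)
  s2 <- sigma2 * stats::rchisq(n, d) / d
  h <- estimate_eb_hyperparams(s2, d)
  expect_lt(abs(h$d0 - d0) / d0, 0.10)
  expect_lt(abs(h$s0_sq - s0) / s0, 0.05)

  # equal variances: infinite prior df, prior variance = the common value
  heq <- estimate_eb_hyperparams(rep(0.4, 50), 12)
  expect_identical(heq$d0, Inf)
  expect_equal(heq$s0_sq, 0.4)

  # determinism
  set.seed(99); a <- estimate_eb_hyperparams(stats::rchisq(100, 5), 10)
  set.seed(99); b <- estimate_eb_hyperparams(stats::rchisq(100, 5), 10)
  expect_identical(a, b)

  expect_error(estimate_eb_hyperparams(stats::rchisq(5, 5), 10),
               "fewer than 10")
})

test_that("hyperparameter estimates agree with an independent EB fitter", {
  skip_if_not_installed("limma")
  set.seed(54)
  s2 <- 0.05 * 4 / stats::rchisq(3000, 4) * stats::rchisq(3000, 12) / 12
  h <- estimate_eb_hyperparams(s2, 12)
  ref <- limma::fitFDist(s2, df1 = 12)
  expect_equal(h$d0, ref$df2, tolerance = 1e-6)
  expect_equal(h$s0_sq, ref$scale, tolerance = 1e-6)
})

test_that("moderated t has the stated limits and shrinkage direction", {
  # d0 = 0: ordinary t
  m0 <- moderated_t(2, 0.5, 10, 0.25, list(d0 = 0, s0_sq = 1))
  expect_equal(m0$t, 2 / sqrt(0.5 * 0.25))
  expect_equal(m0$df_total, 10)
  # d0 = Inf: posterior variance is the prior exactly, normal reference
  mi <- moderated_t(2, 0.5, 10, 0.25, list(d0 = Inf, s0_sq = 0.3))
  expect_equal(mi$t, 2 / sqrt(0.3 * 0.25))
  expect_equal(mi$p_value, 2 * stats::pnorm(-abs(mi$t)))
  # fixed point: s2 = s0 regardless of d0
  mf <- moderated_t(1, 0.3, 8, 0.25, list(d0 = 7, s0_sq = 0.3))
  expect_equal(mf$t, 1 / sqrt(0.3 * 0.25))

  # shrinkage direction: variance moves toward the prior
  hy <- list(d0 = 5, s0_sq = 0.5)
  small <- moderated_t(1, 0.1, 10, 0.25, hy)   # s2 < s0: |t| shrinks
  ord_small <- 1 / sqrt(0.1 * 0.25)
  expect_lt(abs(small$t), ord_small)
  large <- moderated_t(1, 2, 10, 0.25, hy)     # s2 > s0: |t| grows
  ord_large <- 1 / sqrt(2 * 0.25)
  expect_gt(abs(large$t), ord_large)
})

test_that("FDR adjustment reproduces hand and reference computations", {
  expect_equal(as.numeric(adjust_fdr(0.2, method = "bh")), 0.2)
  expect_equal(as.numeric(adjust_fdr(c(0.01, 0.02, 0.03, 0.04),
                                     method = "bh")),
               rep(0.04, 4))
  expect_equal(as.numeric(adjust_fdr(rep(1, 5), method = "bh")), rep(1, 5))

  set.seed(55)
  p <- stats::runif(500)
  expect_equal(as.numeric(adjust_fdr(p, method = "bh")),
               stats::p.adjust(p, method = "BH"), tolerance = 1e-12)

  q <- adjust_fdr(p, method = "tail_area")
  pi0 <- attr(q, "pi0")
  expect_true(pi0 >= 0 && pi0 <= 1)
  # q-values are a monotone function of p-values and respect the pi0 floor
  expect_true(all(diff(as.numeric(q)[order(p)]) >= -1e-15))
  expect_true(all(q >= pi0 * p - 1e-12))
  expect_error(adjust_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("run_de matches an independent moderated-t implementation", {
  skip_if_not_installed("limma")
  cfg <- sim_config(n_proteins = 120, seed = 17)
  truth <- simulate_ground_truth(cfg, design16)
  quant <- simulate_protein_matrix(truth,
                                   var_prior = list(d0 = 4, s0_sq = 0.05),
                                   missing_rate = 0.03, seed = 18)
  de <- run_de(quant, design16, fdr = "bh")
  fitl <- limma::eBayes(limma::lmFit(as.matrix(quant), X16))
  ok <- !is.na(de$t)
  expect_gt(sum(ok), 100)
  expect_equal(de$logFC[ok], unname(fitl$coefficients[ok, "groupold"]),
               tolerance = 1e-9)
  expect_equal(de$t[ok], unname(fitl$t[ok, "groupold"]), tolerance = 1e-6)
  expect_equal(de$p_value[ok], unname(fitl$p.value[ok, "groupold"]),
               tolerance = 1e-6)
  expect_equal(attr(de, "hyper")$d0, fitl$df.prior, tolerance = 1e-4)
  expect_equal(attr(de, "hyper")$s0_sq, fitl$s2.prior, tolerance = 1e-6)
})

test_that("run_de flags configured effects with the right sign", {
  cfg <- sim_config(n_proteins = 250, de_fraction = 0.1,
                    effect_size_log2 = 2, seed = 19)
  truth <- simulate_ground_truth(cfg, design16)
  quant <- simulate_protein_matrix(truth, noise_sd_log2 = 0.2, seed = 20)
  de <- run_de(quant, design16)
  m <- merge(de, truth$table, by.x = "protein", by.y = "protein_id")
  up <- m$group_effect_log2 > 0
  dn <- m$group_effect_log2 < 0
  expect_true(all(m$logFC[up] > 0))
  expect_true(all(m$logFC[dn] < 0))
  expect_true(all(m$significant[up | dn]))
  expect_identical(attr(de, "fdr_method"), "tail_area")
  # significance flag is exactly the q < alpha rule
  expect_equal(m$significant, !is.na(m$p_adjusted) & m$p_adjusted < 0.05)
})
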